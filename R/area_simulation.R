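#' Configuration for the sphere-slicing area simulation
#'
#' On a histology section a nucleus appears as a random planar cut through an
#' approximately spherical body, so the observed cross-section area
#' distribution of a ploidy class is a stereological transform of its sphere
#' radius distribution. The simulation draws, per ploidy class, sphere radii
#' from a normal distribution and, per sphere, random cut offsets uniform in
#' `[0, R]`; the cross-section area is `pi * (R^2 - h^2)`. Class standard
#' deviations follow the three-sigma shape rule `3 * sigma = a * mu`, and
#' class mean radii scale geometrically by a multiplier per ploidy doubling
#' (theoretically `2^(1/3)` for volume doubling; the default 1.18 is the
#' empirically merged value at which the pooled area histogram of normal human
#' liver becomes unimodal).
#'
#' @param mu_di mean diploid sphere radius (default 9; interpreted as pixels
#'   at H&E scale, but the simulation is unit-agnostic).
#' @param shape_factor `a` in the sigma rule `sigma = a * mu / 3`
#'   (default 0.3, giving sigma 0.9 for the diploid class).
#' @param multiplier radius scaling per ploidy doubling, in `(1, 1.3]`
#'   (default 1.18; theoretical value `2^(1/3) ~ 1.26`).
#' @param n_radii integer vector of sphere counts per class
#'   (diploid, tetraploid, octoploid); default `c(600, 350, 250)`.
#' @param n_cuts cross-sections per sphere; default equal to `n_radii`
#'   per class, giving 360000/122500/62500 sections before censoring.
#' @param min_area detection floor: sections with area below it are censored
#'   (default 200).
#' @param seed integer seed for the simulation.
#' @return a list of class `area_sim_config`.
#' @export
area_sim_config <- function(mu_di = 9, shape_factor = 0.3, multiplier = 1.18,
                            n_radii = c(600, 350, 250), n_cuts = NULL,
                            min_area = 200, seed = 1L) {
  if (is.null(n_cuts)) n_cuts <- n_radii
  stopifnot(mu_di > 0, shape_factor > 0, length(n_radii) == 3,
            length(n_cuts) == 3, all(n_radii >= 1), all(n_cuts >= 1),
            min_area >= 0)
  if (multiplier < 1 || multiplier > 1.3)
    stop("area_sim_config: multiplier must be in [1, 1.3]")
  structure(list(mu_di = mu_di, shape_factor = shape_factor,
                 multiplier = multiplier,
                 n_radii = as.integer(n_radii), n_cuts = as.integer(n_cuts),
                 min_area = min_area, seed = as.integer(seed)),
            class = "area_sim_config")
}

#' Class mean radii under the geometric multiplier
#'
#' @param config an [area_sim_config()].
#' @return named numeric vector `c(di, tetra, octo)` of mean sphere radii:
#'   `(mu_di, multiplier * mu_di, multiplier^2 * mu_di)`.
#' @examples
#' class_means(area_sim_config(mu_di = 9, multiplier = 1.18))
#' # di = 9, tetra = 10.62, octo = 12.5316
#' @export
class_means <- function(config) {
  stopifnot(inherits(config, "area_sim_config"))
  m <- config$mu_di * config$multiplier^(0:2)
  names(m) <- c("di", "tetra", "octo")
  m
}

#' Class radius standard deviations from the sigma rule
#'
#' Applies `sigma = a * mu / 3` per class.
#'
#' @inheritParams class_means
#' @return named numeric vector of standard deviations.
#' @export
class_sigmas <- function(config) {
  class_means(config) * config$shape_factor / 3
}

ploidy_levels <- c("2n", "4n", "8n")

#' Simulate nuclear cross-section areas by slicing spheres
#'
#' For each ploidy class draws `n_radii` sphere radii from
#' `Normal(mu_class, sigma_class)` (non-positive draws are resampled; at the
#' default coefficient of variation 0.1 this is a practically impossible
#' event), then for each sphere draws `n_cuts` cut offsets
#' `h ~ Uniform(0, R)` and records the section area `pi * (R^2 - h^2)`.
#' Samples with area below `min_area` are flagged as censored but retained in
#' the output; use [censor_areas()] to drop them.
#'
#' @param config an [area_sim_config()].
#' @return data frame with columns `ploidy` (factor 2n/4n/8n), `R`, `h`,
#'   `area`, `censored`.
#' @export
simulate_areas <- function(config) {
  stopifnot(inherits(config, "area_sim_config"))
  mus <- class_means(config)
  sds <- class_sigmas(config)
  withr::with_seed(config$seed, {
    parts <- lapply(1:3, function(cl) {
      nr <- config$n_radii[cl]
      nc <- config$n_cuts[cl]
      radii <- stats::rnorm(nr, mus[cl], sds[cl])
      bad <- which(radii <= 0)
      while (length(bad)) {
        radii[bad] <- stats::rnorm(length(bad), mus[cl], sds[cl])
        bad <- bad[radii[bad] <= 0]
      }
      R <- rep(radii, each = nc)
      h <- stats::runif(nr * nc, 0, R)
      area <- pi * (R^2 - h^2)
      data.frame(ploidy = ploidy_levels[cl], R = R, h = h, area = area)
    })
    out <- do.call(rbind, parts)
    out$ploidy <- factor(out$ploidy, levels = ploidy_levels)
    out$censored <- out$area < config$min_area
    rownames(out) <- NULL
    out
  })
}

#' Apply the minimum-area censoring rule
#'
#' Mimics the impossibility of detecting tiny nuclear slices on a section.
#' The default `"threshold"` strategy deterministically removes every sample
#' with area below `min_area` — the same rule applied in every class, so small
#' classes are thinned proportionally to how much of their mass sits below the
#' floor. The `"random"` strategy instead removes, per class, a uniformly
#' random subset of the same size (an alternative reading of proportional
#' dropping); it requires a seeded RNG state from the caller.
#'
#' @param samples data frame from [simulate_areas()].
#' @param min_area detection floor.
#' @param strategy `"threshold"` (default) or `"random"`.
#' @return the retained samples (censored flag recomputed).
#' @export
censor_areas <- function(samples, min_area,
                         strategy = c("threshold", "random")) {
  strategy <- match.arg(strategy)
  stopifnot(min_area >= 0)
  if (strategy == "threshold") {
    out <- samples[samples$area >= min_area, , drop = FALSE]
  } else {
    keep <- unlist(lapply(split(seq_len(nrow(samples)), samples$ploidy),
                          function(idx) {
      n_drop <- sum(samples$area[idx] < min_area)
      if (n_drop == 0) idx else idx[-sample(length(idx), n_drop)]
    }), use.names = FALSE)
    out <- samples[sort(keep), , drop = FALSE]
  }
  out$censored <- rep(FALSE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Search for the multiplier at which the class histograms merge
#'
#' In normal human liver the pooled nuclear-area histogram shows a single
#' obvious peak, so the theoretical radius multiplier `2^(1/3) ~ 1.26` (exact
#' volume doubling) overstates the separation of the ploidy classes. This
#' search decreases the multiplier from the theoretical value and returns the
#' largest candidate for which the chosen pooled distribution is unimodal.
#' Unimodality is judged on a Gaussian kernel density estimate (Silverman's
#' bandwidth): local maxima with topographic prominence below
#' `rel_prominence` of the global density maximum are ignored.
#'
#' Two choices define what "merged" is judged on. `variable = "area"`
#' (default) pools the censored cross-section areas — the quantity actually
#' observed on sections. Because uniform slicing smears each class far below
#' its maximal area, the class-weighted pooled area density is unimodal over
#' the entire candidate range at the default parameters (echoing the single
#' obvious peak of real normal-liver area histograms), and the area-based
#' search then returns the largest candidate. The merge structure lives in
#' the underlying sphere sizes: `variable = "radius"` pools the simulated
#' sphere radii instead, and `weighting = "balanced"` gives the three classes
#' equal mass (each class density normalized before pooling), so the merge
#' point reflects component separation rather than class prevalence. The
#' radius variant is computed from the known normal class densities on a
#' fine grid (no Monte-Carlo sampling), so it is fully deterministic.
#'
#' @param config an [area_sim_config()]; its `multiplier` is overridden by
#'   each candidate in turn.
#' @param candidates candidate multipliers, scanned in decreasing order
#'   (default `2^(1/3)` down to 1.10 in steps of 0.01).
#' @param rel_prominence relative prominence below which a density peak is
#'   not counted as a mode (default 0.01).
#' @param variable pool cross-section `"area"` (default) or sphere
#'   `"radius"`.
#' @param weighting `"simulated"` (class counts as simulated, default) or
#'   `"balanced"` (equal class mass).
#' @return list with `multiplier` (largest unimodal candidate, or `NA` if
#'   none) and `diagnostics`, a data frame of `multiplier` and `n_modes`.
#' @export
search_merge_multiplier <- function(config,
                                    candidates = seq(2^(1 / 3), 1.10,
                                                     by = -0.01),
                                    rel_prominence = 0.01,
                                    variable = c("area", "radius"),
                                    weighting = c("simulated", "balanced")) {
  stopifnot(inherits(config, "area_sim_config"))
  variable <- match.arg(variable)
  weighting <- match.arg(weighting)
  if (any(candidates <= 1 | candidates > 2^(1 / 3) + 1e-12))
    stop("search_merge_multiplier: candidates must lie in (1, 2^(1/3)]")
  candidates <- sort(candidates, decreasing = TRUE)
  n_modes <- vapply(candidates, function(m) {
    cfg <- config
    cfg$multiplier <- m
    if (variable == "area") {
      x <- censor_areas(simulate_areas(cfg), cfg$min_area)
      if (weighting == "simulated") {
        y <- stats::density(x$area)$y  # bw.nrd0 = Silverman's rule
      } else {
        rng <- range(x$area)
        y <- rowMeans(vapply(split(x$area, x$ploidy), function(xc) {
          stats::density(xc, from = rng[1], to = rng[2], n = 512)$y
        }, numeric(512)))
      }
    } else {
      mus <- class_means(cfg)
      sds <- class_sigmas(cfg)
      w <- if (weighting == "simulated") {
        tot <- cfg$n_radii * cfg$n_cuts
        tot / sum(tot)
      } else rep(1 / 3, 3)
      g <- seq(min(mus - 4 * sds), max(mus + 4 * sds), length.out = 1024)
      y <- w[1] * stats::dnorm(g, mus[1], sds[1]) +
        w[2] * stats::dnorm(g, mus[2], sds[2]) +
        w[3] * stats::dnorm(g, mus[3], sds[3])
    }
    count_prominent_modes(y, rel_prominence)
  }, numeric(1))
  hit <- which(n_modes == 1)
  list(multiplier = if (length(hit)) candidates[hit[1]] else NA_real_,
       diagnostics = data.frame(multiplier = candidates, n_modes = n_modes))
}

# Count local maxima of y with topographic prominence >= rel * max(y).
# Works on the run-length-compressed series so plateaus count once.
# Prominence of a peak: its height minus the higher of the two lowest points
# on the paths to higher terrain (series minimum for the global peak).
count_prominent_modes <- function(y, rel) {
  v <- rle(y)$values
  n <- length(v)
  if (n <= 1) return(n)
  peaks <- which(vapply(seq_len(n), function(i) {
    (i == 1 || v[i] > v[i - 1]) && (i == n || v[i] > v[i + 1])
  }, logical(1)))
  if (length(peaks) <= 1) return(length(peaks))
  prom <- vapply(peaks, function(p) {
    side_min <- function(idx) {
      m <- Inf
      for (i in idx) {
        if (v[i] > v[p]) return(m)   # reached higher terrain
        m <- min(m, v[i])
      }
      NA_real_                        # no higher terrain this side
    }
    lo <- if (p > 1) side_min((p - 1):1) else NA_real_
    hi <- if (p < n) side_min((p + 1):n) else NA_real_
    saddles <- c(lo, hi)
    if (all(is.na(saddles))) return(v[p] - min(v))  # global peak
    v[p] - max(saddles, na.rm = TRUE)
  }, numeric(1))
  sum(prom >= rel * max(v))
}

#' Write simulated area samples to CSV
#'
#' @param samples data frame from [simulate_areas()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_area_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}
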