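#' Fit the two-stage Gaussian mixture model for nuclear ploidy
#'
#' Nuclear ploidy classes (2n/4n/8n) are inferred from nuclear cross-section
#' areas, whose pooled distribution in normal liver shows a single obvious
#' peak. The fit therefore proceeds in two stages: stage 1 fits a single
#' Gaussian to locate the dominant peak `k` (its mean); stage 2 runs EM for a
#' three-component univariate mixture initialized at means
#' `(k, 1.4 k, 1.4^2 k)`, uniform weights and the stage-1 variance for every
#' component. The initialization is fully specified, so the fit is
#' deterministic: no random restarts. Components are sorted by mean and mapped
#' to ploidy 2n, 4n, 8n in ascending order.
#'
#' EM converges when the improvement in mean log-likelihood per observation
#' drops below `tol`; a variance floor of `1e-8` times the data variance
#' guards against component collapse.
#'
#' @param areas numeric vector of nuclear areas (>= 30 values, all positive).
#' @param tol convergence tolerance on the mean log-likelihood improvement
#'   (default 1e-4).
#' @param max_iter EM iteration cap (default 500); non-convergence is an
#'   error carrying the log-likelihood trace.
#' @param training_resolution optional micrometers-per-pixel of the images the
#'   areas were measured on; stored so the model can be applied across
#'   resolutions (see [classify_nuclei()]).
#' @return an object of class `gmm_model`: list with `weights`, `means`,
#'   `variances` (each length 3, components in ascending mean order),
#'   `ploidy_order` (component labels), `k` (stage-1 peak), `loglik`,
#'   `loglik_trace`, `n_iter`, `n_obs`, `training_resolution`.
#' @export
fit_gmm <- function(areas, tol = 1e-4, max_iter = 500L,
                    training_resolution = NULL) {
  areas <- as.numeric(areas)
  if (length(areas) < 30)
    stop("fit_gmm: need at least 30 areas, got ", length(areas))
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop("fit_gmm: areas must be finite and positive")
  n <- length(areas)

  # stage 1: single-Gaussian MLE locates the dominant peak
  k <- mean(areas)
  v1 <- sum((areas - k)^2) / n

  # stage 2: 3-component EM from the prescribed initialization
  mu <- k * c(1, 1.4, 1.4^2)
  w <- rep(1 / 3, 3)
  va <- rep(v1, 3)
  v_floor <- 1e-8 * v1
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    lp <- vapply(1:3, function(j) {
      log(w[j]) + stats::dnorm(areas, mu[j], sqrt(va[j]), log = TRUE)
    }, numeric(n))
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(lp - lse)                 # n x 3 responsibilities
    if ((ll - ll_prev) / n < tol && iter > 1) { converged <- TRUE; break }
    ll_prev <- ll
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * areas) / nk
    va <- vapply(1:3, function(j) {
      sum(resp[, j] * (areas - mu[j])^2) / nk[j]
    }, numeric(1))
    va <- pmax(va, v_floor)
  }
  if (!converged) {
    cond <- simpleError(sprintf(
      "fit_gmm: EM did not converge within %d iterations", max_iter))
    cond$loglik_trace <- trace
    stop(cond)
  }
  ord <- order(mu)
  structure(list(weights = w[ord], means = mu[ord], variances = va[ord],
                 ploidy_order = ploidy_levels, k = k,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 n_iter = length(trace), n_obs = n,
                 training_resolution = training_resolution),
            class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat("Nuclear-ploidy Gaussian mixture (3 components)\n")
  cat(sprintf("  stage-1 peak k = %.4g; fitted on %d areas, %d EM iterations\n",
              x$k, x$n_obs, x$n_iter))
  for (j in 1:3)
    cat(sprintf("  %s: weight %.3f, mean %.4g, sd %.4g\n",
                x$ploidy_order[j], x$weights[j], x$means[j],
                sqrt(x$variances[j])))
  invisible(x)
}

#' Classify nuclei into ploidy classes with the fitted mixture
#'
#' Computes, for each nucleus area, the posterior responsibility of every
#' mixture component and assigns the maximum-posterior component's ploidy
#' label (ties broken towards the lower component; posterior computation is
#' deterministic). If both the model's `training_resolution` and the query
#' `resolution` are given and differ, areas are rescaled by the squared
#' resolution ratio before evaluation, so a model frozen at one
#' micrometers-per-pixel scale applies to images at another.
#'
#' @param model a fitted [fit_gmm()] model.
#' @param nuclei data frame of nucleus records with columns `nucleus_id` and
#'   `area`, or a bare numeric vector of areas.
#' @param resolution optional micrometers-per-pixel of the query images.
#' @return data frame with `nucleus_id`, `area`, `ploidy`, `p_2n`, `p_4n`,
#'   `p_8n` (posteriors summing to 1).
#' @export
classify_nuclei <- function(model, nuclei, resolution = NULL) {
  stopifnot(inherits(model, "gmm_model"))
  if (is.numeric(nuclei))
    nuclei <- data.frame(nucleus_id = seq_along(nuclei), area = nuclei)
  areas <- nuclei$area
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop("classify_nuclei: areas must be finite and positive")
  x <- areas
  if (!is.null(resolution) && !is.null(model$training_resolution))
    x <- x * (resolution / model$training_resolution)^2
  n <- length(x)
  lp <- vapply(1:3, function(j) {
    log(model$weights[j]) +
      stats::dnorm(x, model$means[j], sqrt(model$variances[j]), log = TRUE)
  }, numeric(n))
  lp <- matrix(lp, nrow = n)
  m <- apply(lp, 1, max)
  post <- exp(lp - m)
  post <- post / rowSums(post)
  hard <- apply(post, 1, which.max)
  data.frame(nucleus_id = nuclei$nucleus_id, area = areas,
             ploidy = factor(model$ploidy_order[hard],
                             levels = ploidy_levels),
             p_2n = post[, 1], p_4n = post[, 2], p_8n = post[, 3])
}

#' Per-cell total ploidy from cellular grouping and nuclear calls
#'
#' Total ploidy of a hepatocyte is the sum of its nuclei's ploidy classes
#' (e.g. two 2n nuclei give a 4n cell). Also emits a human-readable category
#' such as `"mononuclear-4n"` or `"binuclear-2x2n"` and a distribution table
#' over categories.
#'
#' @param cells data frame of cell records from [group_nuclei()] (columns
#'   `cell_id` and list-column `members`).
#' @param calls data frame of nuclear ploidy calls from [classify_nuclei()].
#' @return list with `cells` (per-cell table: `cell_id`, `cellular_ploidy`,
#'   `total_ploidy_n`, `total_ploidy`, `category`) and `distribution`
#'   (category counts).
#' @export
summarize_total_ploidy <- function(cells, calls) {
  stopifnot(is.data.frame(cells), is.data.frame(calls))
  ploidy_n <- c(`2n` = 2L, `4n` = 4L, `8n` = 8L)
  per_cell <- lapply(seq_len(nrow(cells)), function(i) {
    ids <- cells$members[[i]]
    idx <- match(ids, calls$nucleus_id)
    if (anyNA(idx))
      stop("summarize_total_ploidy: no ploidy call for nucleus ",
           paste(ids[is.na(idx)], collapse = ", "))
    labs <- as.character(calls$ploidy[idx])
    total <- sum(ploidy_n[labs])
    word <- c("mononuclear", "binuclear")[min(length(ids), 2)]
    if (length(ids) > 2) word <- "polynuclear"
    tab <- table(factor(labs, levels = ploidy_levels))
    tab <- tab[tab > 0]
    parts <- ifelse(tab > 1, paste0(tab, "x", names(tab)), names(tab))
    data.frame(cell_id = cells$cell_id[i], cellular_ploidy = length(ids),
               total_ploidy_n = total,
               total_ploidy = paste0(total, "n"),
               category = paste0(word, "-", paste(parts, collapse = "+")))
  })
  out <- if (length(per_cell)) do.call(rbind, per_cell) else
    data.frame(cell_id = integer(), cellular_ploidy = integer(),
               total_ploidy_n = integer(), total_ploidy = character(),
               category = character())
  list(cells = out, distribution = as.data.frame(table(
    category = out$category), stringsAsFactors = FALSE))
}

#' Serialize / restore a fitted mixture model as JSON
#'
#' The frozen reference model (fitted on pooled normal-liver nuclear areas)
#' is persisted as plain JSON so downstream classification never refits.
#'
#' @param model a `gmm_model`.
#' @param path JSON file path.
#' @return `write_gmm_model`: `path` invisibly; `read_gmm_model`: the model.
#' @export
write_gmm_model <- function(model, path) {
  stopifnot(inherits(model, "gmm_model"))
  keep <- c("weights", "means", "variances", "ploidy_order", "k",
            "loglik", "n_iter", "n_obs", "training_resolution")
  jsonlite::write_json(model[keep], path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_gmm_model
#' @export
read_gmm_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$training_resolution <- if (is.null(x$training_resolution)) NULL else
    as.numeric(x$training_resolution)
  x$loglik_trace <- numeric(0)
  structure(x, class = "gmm_model")
}
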