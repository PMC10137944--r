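#' Specification for a synthetic tissue patch
#'
#' Describes a seeded synthetic liver-like patch: mono- and binuclear cells
#' with elliptical nuclei of three area classes mimicking 2n/4n/8n, placed so
#' that sibling nuclei (same cell) are close in relative distance and nuclei
#' of different cells are well separated. The generator is the package's
#' ground-truth source: every downstream stage (segmentation, calibration,
#' grouping, classification) can be tested against the exact geometry it
#' records.
#'
#' Defaults emulate the immunofluorescence calibration regime: 360x360-pixel
#' patches, mean nuclear radius 9 px with the three-sigma shape rule
#' (sd = 0.3 * 9 / 3 = 0.9), radius multiplier 1.18 per ploidy step, sibling
#' relative distance up to 4 px (below the 5.5 px calibrated threshold) and
#' inter-cell relative distance at least 12 px (above it). Ploidy class
#' fractions default to the normal-liver mix 66.05/22.48/11.47%.
#'
#' @param height,width patch size in pixels.
#' @param n_cells number of cells to place.
#' @param binuclear_fraction fraction of binuclear cells in `[0, 1]`;
#'   allocated by deterministic quota `round(fraction * n_cells)` so tests can
#'   assert exact counts.
#' @param nucleus_radius_mean,nucleus_radius_sd diploid-class equivalent
#'   radius distribution in pixels.
#' @param intra_cell_nucleus_gap maximum relative distance between sibling
#'   nuclei (pixels); must be below `min_inter_cell_gap`.
#' @param min_inter_cell_gap minimum relative distance between nuclei of
#'   different cells (pixels).
#' @param ploidy_class_fractions three fractions (2n, 4n, 8n) summing to 1.
#' @param area_multiplier mean-radius scaling per ploidy step.
#' @param seed integer seed; equal spec and seed give bit-identical output.
#' @return a list of class `synthetic_patch_spec`.
#' @export
synthetic_patch_spec <- function(height = 360, width = 360, n_cells = 40,
                                 binuclear_fraction = 0.3,
                                 nucleus_radius_mean = 9,
                                 nucleus_radius_sd = 0.9,
                                 intra_cell_nucleus_gap = 4,
                                 min_inter_cell_gap = 12,
                                 ploidy_class_fractions =
                                   c(0.6605, 0.2248, 0.1147),
                                 area_multiplier = 1.18,
                                 seed = 1L) {
  stopifnot(height > 0, width > 0, n_cells >= 0,
            nucleus_radius_mean > 0, nucleus_radius_sd >= 0,
            intra_cell_nucleus_gap > 0, min_inter_cell_gap > 0,
            area_multiplier >= 1)
  if (binuclear_fraction < 0 || binuclear_fraction > 1)
    stop("synthetic_patch_spec: binuclear_fraction must be in [0, 1]")
  if (length(ploidy_class_fractions) != 3 ||
      any(ploidy_class_fractions < 0) ||
      abs(sum(ploidy_class_fractions) - 1) > 1e-9)
    stop("synthetic_patch_spec: ploidy_class_fractions must be 3 ",
         "non-negative values summing to 1")
  if (intra_cell_nucleus_gap >= min_inter_cell_gap)
    stop("synthetic_patch_spec: sibling gap must be below the inter-cell gap")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_cells = as.integer(n_cells),
                 binuclear_fraction = binuclear_fraction,
                 nucleus_radius_mean = nucleus_radius_mean,
                 nucleus_radius_sd = nucleus_radius_sd,
                 intra_cell_nucleus_gap = intra_cell_nucleus_gap,
                 min_inter_cell_gap = min_inter_cell_gap,
                 ploidy_class_fractions = ploidy_class_fractions,
                 area_multiplier = area_multiplier,
                 seed = as.integer(seed)),
            class = "synthetic_patch_spec")
}

max_place_attempts <- 10000L

# Sample the patch geometry: cells, nuclei, ellipse parameters.
# Coordinates are 0-based (row, col), pixel centers at integer coordinates.
# Sibling ellipses have their major axis perpendicular to the line joining
# them, so footprints never overlap even at small relative distances.
sample_geometry <- function(spec) {
  n <- spec$n_cells
  n_binuc <- round(spec$binuclear_fraction * n)
  if (n == 0) {
    return(list(nuclei = empty_truth_nuclei(), n_binuc = 0L))
  }
  classes <- sample(ploidy_levels, n * 2L, replace = TRUE,
                    prob = spec$ploidy_class_fractions)
  mult <- spec$area_multiplier^(match(classes, ploidy_levels) - 1L)
  placed_row <- numeric(0); placed_col <- numeric(0)
  placed_r <- numeric(0); placed_amax <- numeric(0); placed_cell <- integer(0)
  draw_radius <- function(i) {
    r <- -1
    while (r <= 0.5)
      r <- stats::rnorm(1, spec$nucleus_radius_mean * mult[i],
                        spec$nucleus_radius_sd * mult[i])
    r
  }
  rows <- vector("list", n * 2L)
  ni <- 0L
  for (cell in seq_len(n)) {
    binuc <- cell <= n_binuc
    ok <- FALSE
    for (attempt in seq_len(max_place_attempts)) {
      ni1 <- ni + 1L
      r1 <- draw_radius(ni1)
      q1 <- stats::runif(1, 0.8, 1.0)
      if (binuc) {
        ni2 <- ni + 2L
        r2 <- draw_radius(ni2)
        q2 <- stats::runif(1, 0.8, 1.0)
        gap <- stats::runif(1, 0.5, 1) * spec$intra_cell_nucleus_gap
        sep <- r1 + r2 + gap
        ang <- stats::runif(1, 0, 2 * pi)
        amax <- max(r1 / sqrt(q1), r2 / sqrt(q2))
        lo <- amax + sep / 2 + 1
        if (2 * lo >= min(spec$height, spec$width) - 1)
          stop("cannot place cell ", cell,
               ": patch too small for a binuclear cell of this size")
        c_row <- stats::runif(1, lo, spec$height - 1 - lo)
        c_col <- stats::runif(1, lo, spec$width - 1 - lo)
        rr <- c_row + c(-1, 1) * sep / 2 * cos(ang)
        cc <- c_col + c(-1, 1) * sep / 2 * sin(ang)
        rad <- c(r1, r2); qq <- c(q1, q2)
        theta <- rep(ang + pi / 2, 2)   # major axis perpendicular to join
      } else {
        amax <- r1 / sqrt(q1)
        lo <- amax + 1
        if (2 * lo >= min(spec$height, spec$width) - 1)
          stop("cannot place cell ", cell,
               ": patch too small for nucleus radius")
        rr <- stats::runif(1, lo, spec$height - 1 - lo)
        cc <- stats::runif(1, lo, spec$width - 1 - lo)
        rad <- r1; qq <- q1
        theta <- stats::runif(1, 0, pi)
      }
      if (length(placed_r)) {
        dmat <- sqrt(outer(rr, placed_row, `-`)^2 +
                     outer(cc, placed_col, `-`)^2)
        rdmat <- dmat - outer(rad, placed_r, `+`)
        if (min(rdmat) < spec$min_inter_cell_gap) next
        # conservative footprint check against maximal semi-axes
        amax_new <- rad / sqrt(qq)
        if (min(dmat - outer(amax_new, placed_amax, `+`)) < 1) next
      }
      for (m in seq_along(rad)) {
        ni <- ni + 1L
        rows[[ni]] <- data.frame(
          nucleus_id = ni, cell_id = cell, row = rr[m], col = cc[m],
          radius_px = rad[m], area_px2 = pi * rad[m]^2,
          axis_ratio = qq[m], theta = theta[m],
          ploidy = classes[ni], class = "hepatocyte")
        placed_row <- c(placed_row, rr[m]); placed_col <- c(placed_col, cc[m])
        placed_r <- c(placed_r, rad[m])
        placed_amax <- c(placed_amax, rad[m] / sqrt(qq[m]))
        placed_cell <- c(placed_cell, cell)
      }
      ok <- TRUE
      break
    }
    if (!ok)
      stop("cannot place cell ", cell, " after ", max_place_attempts,
           " attempts: inter-cell gap constraint unsatisfiable at this density")
  }
  list(nuclei = do.call(rbind, rows[seq_len(ni)]), n_binuc = n_binuc)
}

empty_truth_nuclei <- function() {
  data.frame(nucleus_id = integer(), cell_id = integer(), row = numeric(),
             col = numeric(), radius_px = numeric(), area_px2 = numeric(),
             axis_ratio = numeric(), theta = numeric(),
             ploidy = character(), class = character())
}

truth_from_nuclei <- function(nuclei) {
  if (nrow(nuclei) == 0) {
    cells <- data.frame(cell_id = integer(), n_nuclei = integer(),
                        row = numeric(), col = numeric())
  } else {
    cells <- do.call(rbind, lapply(split(nuclei, nuclei$cell_id),
                                   function(g) {
      data.frame(cell_id = g$cell_id[1], n_nuclei = nrow(g),
                 row = mean(g$row), col = mean(g$col))
    }))
    rownames(cells) <- NULL
  }
  list(cells = cells, nuclei = nuclei)
}

# Rasterize elliptical nuclei into an integer label matrix.
# Ellipse: equivalent radius r, axis ratio q in (0,1]; semi-axes r/sqrt(q)
# (major, along theta) and r*sqrt(q), preserving area pi*r^2.
rasterize_nuclei <- function(nuclei, height, width) {
  lab <- matrix(0L, height, width)
  for (i in seq_len(nrow(nuclei))) {
    r <- nuclei$radius_px[i]; q <- nuclei$axis_ratio[i]
    a <- r / sqrt(q); b <- r * sqrt(q)
    th <- nuclei$theta[i]
    r0 <- nuclei$row[i]; c0 <- nuclei$col[i]
    ri <- max(0, floor(r0 - a)):min(height - 1, ceiling(r0 + a))
    ci <- max(0, floor(c0 - a)):min(width - 1, ceiling(c0 + a))
    dr <- outer(ri - r0, rep(1, length(ci)))
    dc <- outer(rep(1, length(ri)), ci - c0)
    u <- (dr * cos(th) + dc * sin(th)) / a
    v <- (-dr * sin(th) + dc * cos(th)) / b
    inside <- u^2 + v^2 <= 1
    block <- lab[ri + 1, ci + 1, drop = FALSE]
    block[inside] <- nuclei$nucleus_id[i]
    lab[ri + 1, ci + 1] <- block
  }
  lab
}

# Cell label image: each pixel belongs to the cell of its nearest nucleus
# centroid (siblings share a cell, so no boundary forms between them).
cell_regions <- function(nuclei, height, width) {
  if (nrow(nuclei) == 0) return(matrix(1L, height, width))
  rr <- as.vector(row(matrix(0, height, width))) - 1
  cc <- as.vector(col(matrix(0, height, width))) - 1
  d2 <- matrix(Inf, length(rr), 1)
  best <- integer(length(rr))
  for (i in seq_len(nrow(nuclei))) {
    di <- (rr - nuclei$row[i])^2 + (cc - nuclei$col[i])^2
    upd <- di < d2
    best[upd] <- nuclei$cell_id[i]
    d2[upd] <- di[upd]
  }
  matrix(best, height, width)
}

intensity_fg <- 0.8
intensity_bg <- 0.1
noise_sd <- 0.05

#' Generate a two-channel fluorescence-like synthetic patch
#'
#' Produces a nuclear-marker channel (bright elliptical nuclei on a dim
#' background), a membrane-marker channel (bright ridges along cell
#' boundaries), and the exact ground truth. Cell boundaries are the borders
#' of the nearest-nucleus partition of the patch (siblings of a binuclear
#' cell share a region), drawn about two pixels thick. Intensities are 0.8
#' foreground / 0.1 background on a `[0, 1]` scale with additive Gaussian
#' noise of sd 0.05 — comfortably separable by Otsu thresholding, which keeps
#' segmentation tests stable.
#'
#' @param spec a [synthetic_patch_spec()].
#' @return list with `nuclear` and `membrane` (numeric matrices in `[0, 1]`)
#'   and `truth`: a list with `cells` (cell_id, n_nuclei, row, col) and
#'   `nuclei` (nucleus_id, cell_id, row, col, radius_px, area_px2,
#'   axis_ratio, theta, ploidy, class), coordinates 0-based.
#' @export
generate_if_patch <- function(spec) {
  stopifnot(inherits(spec, "synthetic_patch_spec"))
  withr::with_seed(spec$seed, {
    geom <- sample_geometry(spec)
    nuclei <- geom$nuclei
    lab <- rasterize_nuclei(nuclei, spec$height, spec$width)
    nuc_ch <- matrix(intensity_bg, spec$height, spec$width)
    nuc_ch[lab > 0] <- intensity_fg
    nuc_ch <- clip01(nuc_ch + stats::rnorm(length(nuc_ch), 0, noise_sd))
    regions <- cell_regions(nuclei, spec$height, spec$width)
    memb <- matrix(intensity_bg, spec$height, spec$width)
    if (nrow(nuclei)) {
      edge <- region_edges(regions)
      memb[edge] <- intensity_fg
    }
    memb <- clip01(memb + stats::rnorm(length(memb), 0, noise_sd))
    list(nuclear = nuc_ch, membrane = memb, truth = truth_from_nuclei(nuclei))
  })
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# TRUE where a pixel touches (8-neighbourhood) a pixel of another region:
# yields a ~2 px thick boundary.
region_edges <- function(regions) {
  h <- nrow(regions); w <- ncol(regions)
  edge <- matrix(FALSE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r1 <- max(1, 1 + dr):min(h, h + dr)
    r0 <- r1 - dr
    c1 <- max(1, 1 + dc):min(w, w + dc)
    c0 <- c1 - dc
    diffmask <- regions[r0, c0] != regions[r1, c1]
    sub <- edge[r0, c0]
    edge[r0, c0] <- sub | diffmask
  }
  edge
}

non_hep_classes <- c("stroma", "lymphocyte", "macrophage",
                     "red_blood_cell", "karyorrhexis")

#' All nucleus classes the pipeline recognizes
#'
#' Hepatocyte plus the five non-hepatocyte classes an instance segmenter
#' emits for liver H&E images.
#'
#' @return character vector of class names.
#' @export
nucleus_classes <- function() c("hepatocyte", non_hep_classes)

#' Generate a labelled instance mask mimicking segmenter output
#'
#' Produces the input format the quantification pipeline consumes: an integer
#' label image (background 0, one positive label per nucleus) plus a class
#' table mapping each label to a nucleus class. A stated fraction of nuclei
#' (deterministic quota, seeded choice) is relabelled with non-hepatocyte
#' classes; their truth ploidy is blanked, since ploidy is only defined for
#' hepatocyte nuclei here.
#'
#' @param spec a [synthetic_patch_spec()].
#' @param non_hepatocyte_fraction fraction of nuclei to assign to
#'   non-hepatocyte classes (default 0).
#' @return list with `labels` (integer matrix), `classes` (data frame:
#'   `label`, `class`), and `truth` as in [generate_if_patch()].
#' @export
generate_labelled_mask <- function(spec, non_hepatocyte_fraction = 0) {
  stopifnot(inherits(spec, "synthetic_patch_spec"),
            non_hepatocyte_fraction >= 0, non_hepatocyte_fraction <= 1)
  withr::with_seed(spec$seed, {
    geom <- sample_geometry(spec)
    nuclei <- geom$nuclei
    n <- nrow(nuclei)
    n_other <- round(non_hepatocyte_fraction * n)
    if (n_other > 0) {
      idx <- sample(n, n_other)
      nuclei$class[idx] <- sample(non_hep_classes, n_other, replace = TRUE)
      nuclei$ploidy[idx] <- NA_character_
    }
    lab <- rasterize_nuclei(nuclei, spec$height, spec$width)
    classes <- data.frame(label = nuclei$nucleus_id, class = nuclei$class)
    list(labels = lab, classes = classes, truth = truth_from_nuclei(nuclei))
  })
}

#' Write ground truth tables to CSV
#'
#' @param truth the `truth` element of a generated patch.
#' @param path output CSV path for the nucleus table; the cell table is
#'   written next to it with suffix `_cells.csv`.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth$nuclei, path, row.names = FALSE)
  utils::write.csv(truth$cells, sub("\\.csv$", "_cells.csv", path),
                   row.names = FALSE)
  invisible(path)
}
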