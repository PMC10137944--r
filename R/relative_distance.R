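#' Nuclear relative distance
#'
#' The relative distance between two nuclei is the Euclidean distance between
#' their centroids minus both nuclear radii: `d - r1 - r2`. It is zero for
#' touching circular footprints, negative for overlapping ones, and grows with
#' the clear gap between nuclei. Two nuclei of the same hepatocyte sit much
#' closer (small relative distance) than nuclei of neighbouring cells, which
#' makes a simple threshold on this quantity an effective binucleation
#' classifier when cell membranes are not visible.
#'
#' @param d absolute centroid distance in pixels (non-negative).
#' @param r1,r2 nuclear radii in pixels (positive). All arguments are
#'   vectorized and recycled.
#' @return numeric vector of relative distances in pixels (may be negative).
#' @examples
#' relative_distance(20, 5, 5)  # 10
#' relative_distance(10, 6, 4)  # 0, touching
#' relative_distance(8, 5, 5)   # -2, overlapping
#' @export
relative_distance <- function(d, r1, r2) {
  if (any(!is.finite(d)) || any(!is.finite(r1)) || any(!is.finite(r2)))
    stop("relative_distance: non-finite input")
  if (any(d < 0)) stop("relative_distance: absolute distance must be >= 0")
  if (any(r1 <= 0) || any(r2 <= 0))
    stop("relative_distance: radii must be positive")
  d - r1 - r2
}

#' Convert a relative-distance threshold between image resolutions
#'
#' A threshold calibrated in pixel units at one spatial resolution is carried
#' to another resolution by the ratio of the resolutions:
#' `threshold_target = threshold_source * resolution_source / resolution_target`
#' (both resolutions in micrometers per pixel). The canonical use is carrying
#' the immunofluorescence-calibrated threshold (0.65 um/px) to H&E scale
#' (0.23 um/px): 5.5 px becomes 15.54 px.
#'
#' @param threshold_if source threshold in pixels (positive).
#' @param resolution_if source resolution in micrometers per pixel.
#' @param resolution_he target resolution in micrometers per pixel.
#' @param digits decimal places for the reported value (default 2, matching
#'   conventional reporting); use `NULL` for full precision.
#' @return converted threshold in target pixels.
#' @examples
#' convert_threshold(5.5, 0.65, 0.23)  # 15.54
#' @export
convert_threshold <- function(threshold_if, resolution_if, resolution_he,
                              digits = 2) {
  if (threshold_if <= 0) stop("convert_threshold: threshold must be positive")
  if (resolution_if <= 0 || resolution_he <= 0)
    stop("convert_threshold: resolutions must be positive")
  out <- threshold_if * resolution_if / resolution_he
  if (!is.null(digits)) out <- round(out, digits)
  out
}

# Pairwise relative-distance matrix from nucleus records.
# Rows/cols ordered as the input; diagonal set to Inf so self-pairs never
# qualify as nearest neighbours or grouping edges.
rd_matrix <- function(nuclei) {
  n <- nrow(nuclei)
  dm <- as.matrix(stats::dist(cbind(nuclei$centroid_row, nuclei$centroid_col)))
  rd <- dm - outer(nuclei$equivalent_radius, nuclei$equivalent_radius, `+`)
  diag(rd) <- Inf
  rd
}

#' Collect calibration pairs (RDNSC / RDNDC)
#'
#' Builds the two relative-distance samples used to calibrate the
#' binucleation threshold, using membrane-derived cell assignments as ground
#' truth. For every nucleus, the relative distance to its closest nucleus in a
#' *different* cell is collected (RDNDC, the negative class). For every
#' nucleus of a polynuclear cell, the relative distance to its closest nucleus
#' in the *same* cell is additionally collected (RDNSC, the positive class).
#' Sampling is per nucleus, so an unordered pair may appear twice (once per
#' endpoint); duplicates are retained.
#'
#' "Closest" is measured in relative distance by default, keeping the
#' neighbour definition on the same scale the classifier thresholds;
#' `metric = "absolute"` switches to plain centroid distance.
#'
#' @param nuclei data frame of nucleus records with columns `nucleus_id`,
#'   `centroid_row`, `centroid_col`, `equivalent_radius`.
#' @param membership data frame mapping `nucleus_id` to `cell_id` (e.g. the
#'   `$membership` element of [assign_nuclei_to_cells()]).
#' @param metric nearest-neighbour metric, `"relative"` (default) or
#'   `"absolute"`.
#' @return data frame with one row per collected pair: `nucleus_id_a`,
#'   `nucleus_id_b`, `d`, `r1`, `r2`, `relative_distance`, `same_cell`,
#'   `type` (`"RDNSC"`/`"RDNDC"`).
#' @export
collect_calibration_pairs <- function(nuclei, membership,
                                      metric = c("relative", "absolute")) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(nuclei), is.data.frame(membership))
  nuclei <- nuclei[match(membership$nucleus_id, nuclei$nucleus_id), ,
                   drop = FALSE]
  if (anyNA(nuclei$nucleus_id))
    stop("collect_calibration_pairs: membership references unknown nuclei")
  n <- nrow(nuclei)
  if (n < 2) return(empty_pairs())
  cell <- membership$cell_id
  dm <- as.matrix(stats::dist(cbind(nuclei$centroid_row, nuclei$centroid_col)))
  r <- nuclei$equivalent_radius
  rd <- dm - outer(r, r, `+`)
  nn <- if (metric == "relative") rd else dm
  diag(nn) <- Inf

  if (length(unique(cell)) < 2)
    warning("collect_calibration_pairs: fewer than 2 cells; no RDNDC pairs")

  rows <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    other <- which(cell != cell[i])
    if (length(other)) {
      j <- other[which.min(nn[i, other])]
      k <- k + 1L
      rows[[k]] <- pair_row(nuclei, dm, rd, i, j, same_cell = FALSE)
    }
    sib <- which(cell == cell[i])
    sib <- sib[sib != i]
    if (length(sib)) {
      j <- sib[which.min(nn[i, sib])]
      k <- k + 1L
      rows[[k]] <- pair_row(nuclei, dm, rd, i, j, same_cell = TRUE)
    }
  }
  if (k == 0L) return(empty_pairs())
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

pair_row <- function(nuclei, dm, rd, i, j, same_cell) {
  data.frame(
    nucleus_id_a = nuclei$nucleus_id[i],
    nucleus_id_b = nuclei$nucleus_id[j],
    d = dm[i, j],
    r1 = nuclei$equivalent_radius[i],
    r2 = nuclei$equivalent_radius[j],
    relative_distance = rd[i, j],
    same_cell = same_cell,
    type = if (same_cell) "RDNSC" else "RDNDC"
  )
}

empty_pairs <- function() {
  data.frame(nucleus_id_a = integer(), nucleus_id_b = integer(),
             d = numeric(), r1 = numeric(), r2 = numeric(),
             relative_distance = numeric(), same_cell = logical(),
             type = character())
}

#' Select the F1-maximizing relative-distance threshold
#'
#' Sweeps candidate thresholds over the calibration pairs and returns the one
#' maximizing the F1 score for detecting same-cell pairs. The positive class
#' is "same cell"; a pair is predicted positive iff its relative distance is
#' strictly below the threshold. Candidate thresholds are the midpoints
#' between consecutive sorted distinct relative distances, plus one sentinel
#' below the minimum and one above the maximum, so every achievable confusion
#' table is visited and ties sit between observations. Among candidates with
#' equal maximal F1 the smallest is returned (deterministic). The ROC curve is
#' traced over the same sweep and its area computed by the trapezoidal rule.
#'
#' @param pairs data frame as produced by [collect_calibration_pairs()]
#'   (columns `relative_distance` and `same_cell`); both classes must be
#'   present.
#' @return an object of class `ploidy_calibration`: a list with `threshold`,
#'   `f1`, `precision`, `recall` (at the threshold), `auc`, `n_rdnsc`,
#'   `n_rdndc`, and `curves`, a data frame with one row per candidate
#'   threshold (`threshold`, `tp`, `fp`, `tn`, `fn`, `precision`, `recall`,
#'   `f1`, `tpr`, `fpr`).
#' @export
select_threshold <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  x <- pairs$relative_distance
  y <- pairs$same_cell
  if (!any(y)) stop("select_threshold: no same-cell (RDNSC) pairs")
  if (all(y)) stop("select_threshold: no different-cell (RDNDC) pairs")
  sx <- sort(unique(x))
  cand <- c(sx[1] - 1, if (length(sx) > 1) (sx[-1] + sx[-length(sx)]) / 2,
            sx[length(sx)] + 1)
  P <- sum(y); N <- sum(!y)
  tp <- vapply(cand, function(t) sum(y & x < t), numeric(1))
  fp <- vapply(cand, function(t) sum(!y & x < t), numeric(1))
  fn <- P - tp
  tn <- N - fp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- tp / P
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  tpr <- tp / P
  fpr <- fp / N
  best <- which.max(f1)  # first (= smallest candidate) among ties
  # sweep is monotone in t, so (fpr, tpr) is already sorted ascending
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(
    threshold = cand[best],
    f1 = f1[best],
    precision = precision[best],
    recall = recall[best],
    auc = auc,
    n_rdnsc = P,
    n_rdndc = N,
    curves = data.frame(threshold = cand, tp = tp, fp = fp, tn = tn, fn = fn,
                        precision = precision, recall = recall, f1 = f1,
                        tpr = tpr, fpr = fpr)
  ), class = "ploidy_calibration")
}

#' @export
print.ploidy_calibration <- function(x, ...) {
  cat("Relative-distance calibration\n")
  cat(sprintf("  threshold: %.4g px  (F1 = %.3f, precision = %.3f, recall = %.3f)\n",
              x$threshold, x$f1, x$precision, x$recall))
  cat(sprintf("  AUC: %.3f   samples: %d RDNSC, %d RDNDC\n",
              x$auc, x$n_rdnsc, x$n_rdndc))
  invisible(x)
}

#' Write calibration result to JSON (plus curves CSV)
#'
#' @param x a `ploidy_calibration` object.
#' @param path output JSON path; the sweep curves are written next to it with
#'   suffix `_curves.csv`.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(x, path) {
  stopifnot(inherits(x, "ploidy_calibration"))
  jsonlite::write_json(
    list(threshold = x$threshold, f1 = x$f1, precision = x$precision,
         recall = x$recall, auc = x$auc,
         n_rdnsc = x$n_rdnsc, n_rdndc = x$n_rdndc),
    path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(x$curves, sub("\\.json$", "_curves.csv", path),
                   row.names = FALSE)
  invisible(path)
}
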