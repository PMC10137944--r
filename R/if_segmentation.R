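#' Segment nuclei from a nuclear-marker channel by watershed
#'
#' Recipe: Gaussian smoothing, Otsu foreground threshold, Euclidean distance
#' transform, watershed seeded at distance-transform maxima with a minimum
#' seed separation (splits touching nuclei), then per-region properties.
#' Regions smaller than `min_area` are discarded as noise specks. Nuclei
#' touching the patch border are retained here; edge effects are handled
#' later by the central-region filter on cells. Class is set to
#' `"hepatocyte"`, as fluorescence nuclear-marker channels show hepatocyte
#' nuclei only.
#'
#' The equivalent radius is defined as `sqrt(area / pi)` — the radius of the
#' circle of equal area, the only rotation-invariant radius consistent with
#' using area elsewhere in the pipeline.
#'
#' @param img single-channel numeric matrix with finite values.
#' @param min_area minimum region area in pixels^2 (default 30, far below any
#'   realistic nucleus).
#' @param sigma Gaussian smoothing sd in pixels (default 1.5).
#' @param seed_sep minimum separation of watershed seeds in pixels
#'   (default 5).
#' @param patch_id identifier copied into the records (default `"patch"`).
#' @return data frame of nucleus records: `nucleus_id`, `centroid_row`,
#'   `centroid_col` (0-based, continuous), `area`, `equivalent_radius`,
#'   `class_label`, `patch_id`. Empty (zero rows) for blank or constant
#'   images.
#' @export
segment_nuclei <- function(img, min_area = 30, sigma = 1.5, seed_sep = 5,
                           patch_id = "patch") {
  check_image(img)
  if (diff(range(img)) < 1e-9) return(empty_nuclei(patch_id))
  s <- EBImage::gblur(img, sigma = sigma)
  th <- EBImage::otsu(EBImage::Image(clip01(s)))
  mask <- s > th
  if (!any(mask)) return(empty_nuclei(patch_id))
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  lab <- EBImage::watershed(dm, tolerance = 1, ext = seed_sep)
  props <- region_props(as_label_matrix(lab))
  props <- props[props$area >= min_area, , drop = FALSE]
  if (nrow(props) == 0) return(empty_nuclei(patch_id))
  data.frame(nucleus_id = seq_len(nrow(props)),
             centroid_row = props$centroid_row,
             centroid_col = props$centroid_col,
             area = props$area,
             equivalent_radius = sqrt(props$area / pi),
             class_label = "hepatocyte",
             patch_id = patch_id)
}

empty_nuclei <- function(patch_id = character()) {
  data.frame(nucleus_id = integer(), centroid_row = numeric(),
             centroid_col = numeric(), area = numeric(),
             equivalent_radius = numeric(), class_label = character(),
             patch_id = character())
}

check_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a single-channel 2D numeric image")
  if (any(!is.finite(img))) stop("image contains non-finite values")
  invisible(img)
}

as_label_matrix <- function(x) {
  m <- EBImage::imageData(EBImage::Image(x))
  storage.mode(m) <- "integer"
  matrix(m, nrow = nrow(m))
}

# Per-label centroid (0-based) and pixel-count area of a label matrix.
region_props <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx))
    return(data.frame(label = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), area = numeric()))
  labs <- lab[idx]
  rows <- (idx - 1) %% nrow(lab)        # 0-based row coordinate
  cols <- (idx - 1) %/% nrow(lab)       # 0-based col coordinate
  area <- tapply(rows, labs, length)
  data.frame(label = as.integer(names(area)),
             centroid_row = as.numeric(tapply(rows, labs, mean)),
             centroid_col = as.numeric(tapply(cols, labs, mean)),
             area = as.numeric(area))
}

#' Segment cell regions from a membrane-marker channel
#'
#' The membrane channel is bright along cell boundaries, so cells are the
#' catchment basins of the inverted (smoothed) intensity landscape; watershed
#' with a merging tolerance absorbs noise-induced shallow maxima. A uniform
#' image yields a single region covering the patch. Rare unresolved pixels on
#' watershed lines keep label 0 and are treated as background by
#' [assign_nuclei_to_cells()].
#'
#' @param img single-channel numeric matrix.
#' @param sigma Gaussian smoothing sd in pixels (default 1.5).
#' @param tolerance watershed merging tolerance on the `[0, 1]` intensity
#'   scale (default 0.2, several times the synthetic noise level).
#' @return integer label matrix (cells numbered from 1).
#' @export
segment_membranes <- function(img, sigma = 1.5, tolerance = 0.2) {
  check_image(img)
  if (diff(range(img)) < 1e-9)
    return(matrix(1L, nrow(img), ncol(img)))
  s <- EBImage::gblur(img, sigma = sigma)
  inv <- max(s) - s
  lab <- EBImage::watershed(EBImage::Image(inv), tolerance = tolerance,
                            ext = 1)
  as_label_matrix(lab)
}

#' Assign nuclei to cells by centroid location
#'
#' Each nucleus is assigned to the cell region containing its rounded
#' centroid pixel — the label of that exact pixel, a deterministic rule even
#' on region boundaries. Nuclei whose centroid falls on background (label 0)
#' are left unassigned and reported separately. The cell centroid is the
#' arithmetic mean of its member nucleus centroids.
#'
#' @param nuclei data frame of nucleus records ([segment_nuclei()]).
#' @param cell_labels integer label matrix ([segment_membranes()]).
#' @return list with `cells` (data frame: `cell_id`, `cell_row`, `cell_col`,
#'   `n_nuclei`, list-column `members`), `membership` (data frame:
#'   `nucleus_id`, `cell_id`), and `unassigned` (nucleus ids on background).
#' @export
assign_nuclei_to_cells <- function(nuclei, cell_labels) {
  stopifnot(is.data.frame(nuclei), is.matrix(cell_labels))
  if (nrow(nuclei) == 0)
    return(list(cells = data.frame(cell_id = integer(), cell_row = numeric(),
                                   cell_col = numeric(), n_nuclei = integer(),
                                   members = I(list())),
                membership = data.frame(nucleus_id = integer(),
                                        cell_id = integer()),
                unassigned = integer()))
  ri <- round(nuclei$centroid_row) + 1L
  ci <- round(nuclei$centroid_col) + 1L
  if (any(ri < 1 | ri > nrow(cell_labels) | ci < 1 | ci > ncol(cell_labels)))
    stop("assign_nuclei_to_cells: nucleus centroid outside the label image")
  lab <- cell_labels[cbind(ri, ci)]
  unassigned <- nuclei$nucleus_id[lab == 0]
  keep <- lab > 0
  membership <- data.frame(nucleus_id = nuclei$nucleus_id[keep],
                           cell_id = lab[keep])
  groups <- split(which(keep), lab[keep])
  cells <- do.call(rbind, lapply(groups, function(idx) {
    data.frame(cell_id = lab[idx[1]],
               cell_row = mean(nuclei$centroid_row[idx]),
               cell_col = mean(nuclei$centroid_col[idx]),
               n_nuclei = length(idx))
  }))
  cells$members <- I(unname(lapply(groups,
                                   function(idx) nuclei$nucleus_id[idx])))
  rownames(cells) <- NULL
  list(cells = cells, membership = membership, unassigned = unassigned)
}

#' Keep items whose centroid lies in the central region of a patch
#'
#' Cells near the patch edge carry incomplete information (nuclei may be cut
#' off or lie outside), so only items whose centroid falls in the central
#' region are retained. The rule is half-open on 0-based coordinates:
#' `padding <= coordinate < patch_size - padding` on both axes. A 360-pixel
#' patch with padding 30 keeps a 300x300 central region; a 500-pixel patch
#' with padding 85 keeps 330x330.
#'
#' @param items data frame with centroid columns.
#' @param patch_size patch size in pixels, scalar or `c(height, width)`.
#' @param padding margin width in pixels; `2 * padding` must be smaller than
#'   `patch_size`.
#' @param coord_cols names of the row/col columns; by default detected among
#'   `cell_row`/`cell_col` and `centroid_row`/`centroid_col`.
#' @return the filtered data frame (order preserved); if the input has an
#'   `in_central_region` column it is set to `TRUE` on the survivors.
#' @export
filter_central <- function(items, patch_size, padding, coord_cols = NULL) {
  stopifnot(is.data.frame(items))
  size <- rep(patch_size, length.out = 2)
  if (any(2 * padding >= size))
    stop("filter_central: 2*padding must be smaller than patch_size")
  if (is.null(coord_cols)) {
    coord_cols <- if (all(c("cell_row", "cell_col") %in% names(items)))
      c("cell_row", "cell_col") else c("centroid_row", "centroid_col")
  }
  if (!all(coord_cols %in% names(items)))
    stop("filter_central: coordinate columns not found: ",
         paste(coord_cols, collapse = ", "))
  r <- items[[coord_cols[1]]]
  cc <- items[[coord_cols[2]]]
  keep <- r >= padding & r < size[1] - padding &
    cc >= padding & cc < size[2] - padding
  out <- items[keep, , drop = FALSE]
  if ("in_central_region" %in% names(out) && nrow(out))
    out$in_central_region <- TRUE
  out
}
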