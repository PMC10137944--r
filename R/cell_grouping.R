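#' Group hepatocyte nuclei into cells by thresholded relative distance
#'
#' Without visible membranes, two nuclei are deemed to belong to the same
#' hepatocyte when their relative distance (centroid distance minus both
#' radii) falls strictly below the predetermined threshold. An edge is placed
#' between every qualifying pair and cells are the connected components of
#' that graph — the only partition consistent with the pairwise decisions.
#' Components of more than two nuclei are possible and are flagged in
#' [summarize_cellular_ploidy()]; real hepatocytes are mono- or binuclear, so
#' larger components usually signal a threshold set too high.
#'
#' The cell centroid is the arithmetic mean of member nucleus centroids.
#' Cells are numbered deterministically in raster order of their centroid
#' (row, then column).
#'
#' @param nuclei data frame of hepatocyte nucleus records (columns
#'   `nucleus_id`, `centroid_row`, `centroid_col`, `equivalent_radius`; if a
#'   `class_label` column is present it must be all `"hepatocyte"` — callers
#'   must pre-filter other classes).
#' @param threshold relative-distance threshold in pixels (positive); default
#'   15.54, the H&E-scale value.
#' @return data frame of cell records: `cell_id`, `cell_row`, `cell_col`,
#'   `cellular_ploidy`, list-column `members` (nucleus ids), and
#'   `in_central_region` (NA until [filter_central()] is applied).
#' @export
group_nuclei <- function(nuclei, threshold = 15.54) {
  stopifnot(is.data.frame(nuclei), threshold > 0)
  if (!is.null(nuclei$class_label) && any(nuclei$class_label != "hepatocyte"))
    stop("group_nuclei: non-hepatocyte nuclei present; filter classes first")
  n <- nrow(nuclei)
  if (n == 0) return(empty_cells())
  rd <- rd_matrix(nuclei)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (rd[i, j] < threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  rows <- lapply(groups, function(idx) {
    data.frame(cell_row = mean(nuclei$centroid_row[idx]),
               cell_col = mean(nuclei$centroid_col[idx]),
               cellular_ploidy = length(idx))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$members <- I(unname(lapply(groups, function(idx) nuclei$nucleus_id[idx])))
  ord <- order(out$cell_row, out$cell_col)
  out <- out[ord, , drop = FALSE]
  out <- cbind(cell_id = seq_len(nrow(out)), out)
  out$in_central_region <- NA
  rownames(out) <- NULL
  out
}

empty_cells <- function() {
  data.frame(cell_id = integer(), cell_row = numeric(), cell_col = numeric(),
             cellular_ploidy = integer(), members = I(list()),
             in_central_region = logical())
}

#' Summarize cellular ploidy of a set of cells
#'
#' Counts cells by number of nuclei (1, 2, and 3-or-more reported separately)
#' and computes the polynuclear proportion — cells with at least two nuclei
#' over all cells — the quantity compared between membrane-based and
#' relative-distance-based grouping when validating the threshold.
#'
#' @param cells data frame from [group_nuclei()].
#' @return list with `counts` (data frame: `cellular_ploidy` in
#'   `c("1","2",">=3")`, `n`, `fraction`), `n_cells`, and
#'   `polynuclear_proportion` (`NA` for empty input).
#' @export
summarize_cellular_ploidy <- function(cells) {
  stopifnot(is.data.frame(cells))
  n <- nrow(cells)
  bins <- c("1", "2", ">=3")
  if (n == 0) {
    return(list(counts = data.frame(cellular_ploidy = bins, n = 0L,
                                    fraction = 0),
                n_cells = 0L, polynuclear_proportion = NA_real_))
  }
  b <- cut(cells$cellular_ploidy, c(0, 1, 2, Inf), labels = bins)
  tab <- table(b)
  list(counts = data.frame(cellular_ploidy = bins, n = as.integer(tab),
                           fraction = as.numeric(tab) / n),
       n_cells = n,
       polynuclear_proportion = mean(cells$cellular_ploidy >= 2))
}

#' Write cell records to CSV
#'
#' Member nucleus ids are semicolon-joined into a single column.
#'
#' @param cells data frame from [group_nuclei()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cells <- function(cells, path) {
  flat <- cells
  flat$members <- vapply(cells$members, paste, character(1), collapse = ";")
  names(flat)[names(flat) == "members"] <- "nucleus_ids"
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}
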