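#' Pipeline configuration
#'
#' Bundles the tunables of the per-patch quantification: the H&E-scale
#' relative-distance threshold (default 15.54 px, the immunofluorescence
#' calibration 5.5 px carried across the 0.65/0.23 um-per-pixel resolution
#' ratio) and the edge padding (default 85 px, which on a 500-pixel patch
#' keeps a 330x330 central region).
#'
#' @param threshold_he relative-distance threshold in H&E pixels (> 0).
#' @param padding_he central-region margin in pixels; `2 * padding_he` must be
#'   smaller than `patch_size`.
#' @param patch_size patch size in pixels (scalar or `c(height, width)`).
#' @param resolution_he micrometers per pixel of the input images.
#' @param gmm_model a fitted [fit_gmm()] model, a path to a JSON model file,
#'   or `"fit-from-input"` to fit on the patch's own hepatocyte areas.
#' @param seed integer seed recorded with the run.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold_he = 15.54, padding_he = 85,
                            patch_size = 500, resolution_he = 0.23,
                            gmm_model = "fit-from-input", seed = 1L) {
  stopifnot(threshold_he > 0, resolution_he > 0, padding_he >= 0)
  if (any(2 * padding_he >= rep(patch_size, length.out = 2)))
    stop("pipeline_config: 2*padding_he must be smaller than patch_size")
  structure(list(threshold_he = threshold_he, padding_he = padding_he,
                 patch_size = patch_size, resolution_he = resolution_he,
                 gmm_model = gmm_model, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Build nucleus records from a labelled instance mask and class table
#'
#' Consumes the output format of an upstream instance segmenter: an integer
#' label image (0 = background) and a table assigning each label one of the
#' six nucleus classes. Centroid, area, and equivalent radius are computed
#' from the mask pixels.
#'
#' @param labels integer label matrix or path to a 16-bit PNG label image.
#' @param classes data frame with columns `label` and `class`, or path to a
#'   CSV with those columns.
#' @param patch_id identifier copied into the records.
#' @return data frame of nucleus records as in [segment_nuclei()].
#' @export
load_instances <- function(labels, classes, patch_id = "patch") {
  if (is.character(labels)) labels <- read_label_image(labels)
  if (is.character(classes))
    classes <- utils::read.csv(classes, stringsAsFactors = FALSE)
  stopifnot(is.matrix(labels), is.data.frame(classes),
            all(c("label", "class") %in% names(classes)))
  bad <- setdiff(classes$class, nucleus_classes())
  if (length(bad))
    stop("load_instances: unknown class string(s): ",
         paste(unique(bad), collapse = ", "))
  props <- region_props(labels)
  missing_class <- setdiff(props$label, classes$label)
  if (length(missing_class))
    stop("load_instances: labels without a class row: ",
         paste(missing_class, collapse = ", "))
  missing_px <- setdiff(classes$label, props$label)
  if (length(missing_px))
    stop("load_instances: class rows without mask pixels: ",
         paste(missing_px, collapse = ", "))
  if (nrow(props) == 0) return(empty_nuclei())
  data.frame(nucleus_id = props$label,
             centroid_row = props$centroid_row,
             centroid_col = props$centroid_col,
             area = props$area,
             equivalent_radius = sqrt(props$area / pi),
             class_label = classes$class[match(props$label, classes$label)],
             patch_id = patch_id)
}

report_columns <- c("patch_id", "cell_id", "cell_row", "cell_col",
                    "cellular_ploidy", "nucleus_id", "nuclear_area_px2",
                    "nuclear_ploidy", "p_2n", "p_4n", "p_8n",
                    "cell_total_ploidy")

empty_report <- function() {
  out <- data.frame(patch_id = character(), cell_id = integer(),
                    cell_row = numeric(), cell_col = numeric(),
                    cellular_ploidy = integer(), nucleus_id = integer(),
                    nuclear_area_px2 = numeric(), nuclear_ploidy = character(),
                    p_2n = numeric(), p_4n = numeric(), p_8n = numeric(),
                    cell_total_ploidy = character())
  out
}

#' Quantify hepatic ploidy on one patch
#'
#' The full per-patch pipeline: keep hepatocyte-class nuclei, group them into
#' cells by thresholded relative distance, keep cells whose centroid lies in
#' the central region, classify each member nucleus's ploidy with the
#' Gaussian mixture model, and sum nuclear ploidies into the per-cell total.
#' The report is long format — one row per nucleus with its cell's fields
#' repeated — so per-nucleus posteriors are preserved losslessly.
#'
#' @param config a [pipeline_config()].
#' @param nuclei data frame of nucleus records (e.g. from
#'   [load_instances()]); non-hepatocyte classes are dropped here.
#' @return data frame with columns `patch_id`, `cell_id`, `cell_row`,
#'   `cell_col`, `cellular_ploidy`, `nucleus_id`, `nuclear_area_px2`,
#'   `nuclear_ploidy`, `p_2n`, `p_4n`, `p_8n`, `cell_total_ploidy`, ordered
#'   by cell then nucleus id. Attributes `cells`, `calls`, `total`, and
#'   `stage_counts` carry the intermediate tables.
#' @export
run_patch <- function(config, nuclei) {
  stopifnot(inherits(config, "pipeline_config"), is.data.frame(nuclei))
  hep <- nuclei[nuclei$class_label == "hepatocyte", , drop = FALSE]
  counts <- c(nuclei_in = nrow(nuclei), hepatocyte = nrow(hep))
  if (nrow(hep) == 0) {
    warning("run_patch: no hepatocyte nuclei on this patch")
    out <- empty_report()
    attr(out, "stage_counts") <- c(counts, cells = 0L, cells_central = 0L)
    return(out)
  }
  model <- resolve_gmm(config, hep)
  cells <- group_nuclei(hep, threshold = config$threshold_he)
  counts["cells"] <- nrow(cells)
  cells <- filter_central(cells, config$patch_size, config$padding_he)
  counts["cells_central"] <- nrow(cells)
  if (nrow(cells) == 0) {
    warning("run_patch: no cells inside the central region")
    out <- empty_report()
    attr(out, "stage_counts") <- counts
    return(out)
  }
  member_ids <- unlist(cells$members, use.names = FALSE)
  member_nuc <- hep[match(member_ids, hep$nucleus_id), , drop = FALSE]
  calls <- classify_nuclei(model, member_nuc)
  total <- summarize_total_ploidy(cells, calls)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ids <- sort(cells$members[[i]])
    ci <- match(ids, calls$nucleus_id)
    data.frame(patch_id = member_nuc$patch_id[match(ids, member_nuc$nucleus_id)],
               cell_id = cells$cell_id[i],
               cell_row = cells$cell_row[i],
               cell_col = cells$cell_col[i],
               cellular_ploidy = cells$cellular_ploidy[i],
               nucleus_id = ids,
               nuclear_area_px2 = calls$area[ci],
               nuclear_ploidy = as.character(calls$ploidy[ci]),
               p_2n = calls$p_2n[ci], p_4n = calls$p_4n[ci],
               p_8n = calls$p_8n[ci],
               cell_total_ploidy = total$cells$total_ploidy[
                 match(cells$cell_id[i], total$cells$cell_id)])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cell_id, out$nucleus_id), report_columns]
  rownames(out) <- NULL
  attr(out, "cells") <- cells
  attr(out, "calls") <- calls
  attr(out, "total") <- total
  attr(out, "stage_counts") <- counts
  out
}

resolve_gmm <- function(config, hep) {
  m <- config$gmm_model
  if (inherits(m, "gmm_model")) return(m)
  if (identical(m, "fit-from-input")) {
    if (nrow(hep) < 30)
      stop("run_patch: fit-from-input needs >= 30 hepatocyte nuclei, got ",
           nrow(hep))
    return(fit_gmm(hep$area, training_resolution = config$resolution_he))
  }
  if (is.character(m) && file.exists(m)) return(read_gmm_model(m))
  stop("run_patch: gmm_model must be a gmm_model, an existing JSON path, ",
       "or \"fit-from-input\"")
}

#' Calibrate the relative-distance threshold from fluorescence patches
#'
#' Runs the calibration path end to end on one or more two-channel patches:
#' segment nuclei and membranes by watershed, assign nuclei to membrane-bound
#' cells (the ground truth), keep cells in the central region, pool the
#' RDNSC/RDNDC samples across patches, select the F1-maximizing threshold,
#' and convert it to the target resolution.
#'
#' @param patches list of patches, each a list with elements `nuclear` and
#'   `membrane` (numeric matrices); a single patch may be passed directly.
#' @param padding central-region margin in pixels (default 30: a 360-pixel
#'   patch keeps 300x300).
#' @param resolution_if,resolution_he micrometers per pixel of the
#'   calibration and target images (defaults 0.65 and 0.23).
#' @param min_area minimum nucleus area passed to [segment_nuclei()].
#' @return list with `calibration` (a `ploidy_calibration`), `threshold_if`,
#'   and `threshold_he` (converted, reported to 2 decimals).
#' @export
run_calibration <- function(patches, padding = 30,
                            resolution_if = 0.65, resolution_he = 0.23,
                            min_area = 30) {
  if (!is.null(patches$nuclear)) patches <- list(patches)
  stopifnot(length(patches) >= 1)
  all_pairs <- lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    nuc <- segment_nuclei(p$nuclear, min_area = min_area,
                          patch_id = paste0("patch", i))
    if (nrow(nuc) == 0) return(empty_pairs())
    cl <- segment_membranes(p$membrane)
    asg <- assign_nuclei_to_cells(nuc, cl)
    kept <- filter_central(asg$cells, dim(p$nuclear), padding)
    keep_ids <- unlist(kept$members, use.names = FALSE)
    mem <- asg$membership[asg$membership$nucleus_id %in% keep_ids, ,
                          drop = FALSE]
    if (nrow(mem) < 2) return(empty_pairs())
    collect_calibration_pairs(nuc[nuc$nucleus_id %in% keep_ids, ,
                                  drop = FALSE], mem)
  })
  pairs <- do.call(rbind, all_pairs)
  cal <- select_threshold(pairs)
  list(calibration = cal,
       threshold_if = cal$threshold,
       threshold_he = convert_threshold(cal$threshold, resolution_if,
                                        resolution_he))
}

#' Write the per-nucleus ploidy report to CSV
#'
#' @param report data frame from [run_patch()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
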