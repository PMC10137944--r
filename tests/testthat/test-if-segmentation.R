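# Draw a rasterized disk in a background image (0-based center coords).
add_disk <- function(img, r0, c0, radius, value = 0.8) {
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    if ((i - 1 - r0)^2 + (j - 1 - c0)^2 <= radius^2) img[i, j] <- value
  }
  img
}

test_that("nucleus segmentation recovers isolated synthetic nuclei", {
  spec <- sep_patch_spec(n_cells = 10, binuclear_fraction = 0, seed = 4)
  p <- generate_if_patch(spec)
  nuc <- segment_nuclei(p$nuclear)
  tr <- p$truth$nuclei
  expect_equal(nrow(nuc), 10)
  # match each truth nucleus to the nearest segmented centroid
  for (i in seq_len(nrow(tr))) {
    d <- sqrt((nuc$centroid_row - tr$row[i])^2 +
              (nuc$centroid_col - tr$col[i])^2)
    expect_lt(min(d), 2)
  }
  expect_true(all(nuc$class_label == "hepatocyte"))
  expect_equal(nuc$equivalent_radius, sqrt(nuc$area / pi), tolerance = 1e-9)
})

test_that("blank and degenerate images yield empty results, bad input errors", {
  expect_equal(nrow(segment_nuclei(matrix(0.1, 50, 50))), 0)
  expect_equal(nrow(segment_nuclei(matrix(0, 50, 50))), 0)
  expect_error(segment_nuclei(array(0, c(4, 4, 2))), "2D")
  expect_error(segment_nuclei(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
})

test_that("a rasterized disk reports its equivalent radius", {
  img <- add_disk(matrix(0.1, 80, 80), 40, 40, 10)
  set.seed(2)
  img <- pmin(pmax(img + rnorm(6400, 0, 0.02), 0), 1)
  nuc <- segment_nuclei(img)
  expect_equal(nrow(nuc), 1)
  expect_lt(abs(nuc$equivalent_radius - 10), 0.5)
  expect_lt(abs(nuc$centroid_row - 40), 1)
})

test_that("membrane segmentation separates cells at bright ridges", {
  # constructed fixture: two cells split by one bright vertical line
  img <- matrix(0.1, 60, 60)
  img[, 29:31] <- 0.8
  set.seed(3)
  img <- pmin(pmax(img + rnorm(3600, 0, 0.05), 0), 1)
  lab <- segment_membranes(img)
  regions <- setdiff(unique(as.integer(lab)), 0L)
  expect_equal(length(regions), 2)
  # uniform image: one region covering the patch
  expect_equal(unique(as.integer(segment_membranes(matrix(0.4, 40, 40)))), 1L)
  # synthetic patch: most truth cell centroids land in distinct regions
  spec <- sep_patch_spec(n_cells = 10, seed = 8)
  p <- generate_if_patch(spec)
  lab <- segment_membranes(p$membrane)
  tc <- p$truth$cells
  hit <- lab[cbind(round(tc$row) + 1, round(tc$col) + 1)]
  hit <- hit[hit > 0]
  expect_gte(length(unique(hit)), 9)
})

test_that("nucleus-to-cell assignment partitions assigned nuclei", {
  spec <- sep_patch_spec(n_cells = 12, binuclear_fraction = 0.5, seed = 10)
  p <- generate_if_patch(spec)
  nuc <- segment_nuclei(p$nuclear)
  lab <- segment_membranes(p$membrane)
  asg <- assign_nuclei_to_cells(nuc, lab)
  ids <- unlist(asg$cells$members)
  expect_equal(sort(c(ids, asg$unassigned)), sort(nuc$nucleus_id))
  expect_equal(anyDuplicated(ids), 0)
  expect_equal(asg$cells$n_nuclei,
               vapply(asg$cells$members, length, integer(1)))
  # binuclear truth cells come out with two members
  expect_equal(sum(asg$cells$n_nuclei == 2), 6)
  # cell centroid is the mean of member nucleus centroids
  i <- which(asg$cells$n_nuclei == 2)[1]
  mem <- match(asg$cells$members[[i]], nuc$nucleus_id)
  expect_equal(asg$cells$cell_row[i], mean(nuc$centroid_row[mem]),
               tolerance = 1e-9)
  # empty input
  empty <- assign_nuclei_to_cells(segment_nuclei(matrix(0.1, 30, 30)),
                                  matrix(1L, 30, 30))
  expect_equal(nrow(empty$cells), 0)
})

test_that("segmentation recovers nearly all nuclei without merging pairs", {
  hits <- 0L; total <- 0L
  for (seed in c(1, 2)) {
    spec <- sep_patch_spec(n_cells = 20, binuclear_fraction = 0.5,
                           seed = seed)
    p <- generate_if_patch(spec)
    nuc <- segment_nuclei(p$nuclear)
    tr <- p$truth$nuclei
    total <- total + nrow(tr)
    used <- rep(FALSE, nrow(nuc))
    for (i in seq_len(nrow(tr))) {
      d <- sqrt((nuc$centroid_row - tr$row[i])^2 +
                (nuc$centroid_col - tr$col[i])^2)
      j <- which.min(ifelse(used, Inf, d))
      if (d[j] <= 3) { hits <- hits + 1L; used[j] <- TRUE }
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("central-region filtering applies the half-open rule", {
  items <- data.frame(centroid_row = c(29.9, 30, 200, 329.9, 330),
                      centroid_col = rep(100, 5))
  kept <- filter_central(items, patch_size = 360, padding = 30)
  expect_equal(kept$centroid_row, c(30, 200, 329.9))
  # 500-px patch with padding 85 keeps the 330x330 central region
  items2 <- data.frame(centroid_row = c(84, 85, 414.9, 415),
                       centroid_col = rep(250, 4))
  expect_equal(filter_central(items2, 500, 85)$centroid_row, c(85, 414.9))
  # idempotent and order-preserving
  again <- filter_central(kept, 360, 30)
  expect_identical(again, kept)
  expect_error(filter_central(items, 360, 180), "padding")
})
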