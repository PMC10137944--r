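test_that("relative distance follows d - r1 - r2 and validates input", {
  expect_equal(relative_distance(20, 5, 5), 10)
  expect_equal(relative_distance(10, 6, 4), 0)   # tangent circles
  expect_equal(relative_distance(8, 5, 5), -2)   # overlapping footprints
  # vectorized and symmetric in the radii
  expect_equal(relative_distance(c(20, 10), c(5, 6), c(5, 4)), c(10, 0))
  expect_equal(relative_distance(13, 2, 7), relative_distance(13, 7, 2))
  expect_error(relative_distance(-1, 5, 5), "distance")
  expect_error(relative_distance(10, 0, 5), "radii")
  expect_error(relative_distance(10, 5, -2), "radii")
})

test_that("threshold conversion follows the resolution ratio", {
  expect_equal(convert_threshold(5.5, 0.65, 0.23), 15.54)
  expect_equal(convert_threshold(7, 0.4, 0.4), 7)         # identity
  expect_equal(convert_threshold(1.0, 0.5, 0.25), 2.0)    # doubling
  # linear in the source threshold (full precision)
  a <- convert_threshold(3.1, 0.65, 0.23, digits = NULL)
  b <- convert_threshold(6.2, 0.65, 0.23, digits = NULL)
  expect_equal(b, 2 * a)
  expect_error(convert_threshold(5.5, -0.65, 0.23), "resolution")
  expect_error(convert_threshold(0, 0.65, 0.23), "threshold")
})

test_that("calibration pair counts match per-nucleus sampling on small cases", {
  # two mononuclear cells: each nucleus samples its nearest other-cell
  # neighbour -> 2 RDNDC, no RDNSC
  nuc <- data.frame(nucleus_id = 1:2, centroid_row = c(0, 100),
                    centroid_col = c(0, 0), equivalent_radius = c(5, 5))
  mem <- data.frame(nucleus_id = 1:2, cell_id = c(1, 2))
  p <- collect_calibration_pairs(nuc, mem)
  expect_equal(sum(p$type == "RDNDC"), 2)
  expect_equal(sum(p$type == "RDNSC"), 0)
  # one binuclear + one mononuclear cell: 3 RDNDC (one per nucleus) and
  # 2 RDNSC (one per nucleus of the binuclear cell)
  nuc <- data.frame(nucleus_id = 1:3,
                    centroid_row = c(0, 22, 150),
                    centroid_col = c(0, 0, 0),
                    equivalent_radius = c(9, 9, 9))
  mem <- data.frame(nucleus_id = 1:3, cell_id = c(1, 1, 2))
  p <- collect_calibration_pairs(nuc, mem)
  expect_equal(sum(p$type == "RDNDC"), 3)
  expect_equal(sum(p$type == "RDNSC"), 2)
  expect_equal(p$relative_distance[p$same_cell][1], 22 - 18)
  # single cell: no different-cell neighbours exist
  expect_warning(
    p1 <- collect_calibration_pairs(nuc, data.frame(nucleus_id = 1:3,
                                                    cell_id = c(1, 1, 1))),
    "fewer than 2 cells")
  expect_equal(sum(p1$type == "RDNDC"), 0)
})

test_that("pair collection agrees with an exhaustive O(n^2) oracle", {
  set.seed(42)
  nuc <- random_nuclei(200)
  cell <- sample(1:60, 200, replace = TRUE)
  mem <- data.frame(nucleus_id = nuc$nucleus_id, cell_id = cell)
  got <- collect_calibration_pairs(nuc, mem)
  want <- naive_calibration_pairs(nuc, cell)
  key <- function(a, b, s) paste(a, b, s)
  expect_setequal(key(got$nucleus_id_a, got$nucleus_id_b, got$same_cell),
                  key(want$a, want$b, want$same_cell))
  ord_g <- order(got$nucleus_id_a, got$same_cell)
  ord_w <- order(want$a, want$same_cell)
  expect_equal(got$relative_distance[ord_g], want$rd[ord_w])
})

test_that("threshold selection is exact on separable data", {
  pairs <- data.frame(relative_distance = c(1, 2, 3, 10, 11, 12),
                      same_cell = rep(c(TRUE, FALSE), each = 3))
  cal <- select_threshold(pairs)
  expect_equal(cal$f1, 1.0)
  expect_equal(cal$auc, 1.0)
  expect_gt(cal$threshold, 3)
  expect_lt(cal$threshold, 10)
  expect_equal(cal$n_rdnsc, 3)
  expect_equal(cal$n_rdndc, 3)
  expect_error(select_threshold(pairs[pairs$same_cell, ]), "different-cell")
  expect_error(select_threshold(pairs[!pairs$same_cell, ]), "same-cell")
})

test_that("threshold selection matches the grid-scan oracle on noisy data", {
  set.seed(11)
  x <- c(abs(rnorm(800, 3, 1.5)), rnorm(1200, 14, 4))
  y <- rep(c(TRUE, FALSE), c(800, 1200))
  pairs <- data.frame(relative_distance = x, same_cell = y)
  cal <- select_threshold(pairs)
  oracle <- grid_scan_f1(x, y, step = 0.01)
  expect_equal(cal$f1, oracle$f1)
  # AUC equals the Mann-Whitney statistic
  expect_equal(cal$auc, mann_whitney_auc(x, y), tolerance = 1e-9)
  # invariant to pair order
  perm <- sample(nrow(pairs))
  cal2 <- select_threshold(pairs[perm, ])
  expect_equal(cal2$threshold, cal$threshold)
  expect_equal(cal2$auc, cal$auc)
  # adding a constant shifts the threshold by that constant
  pairs3 <- pairs
  pairs3$relative_distance <- pairs3$relative_distance + 7.5
  cal3 <- select_threshold(pairs3)
  expect_equal(cal3$threshold, cal$threshold + 7.5)
  expect_equal(cal3$f1, cal$f1)
})

test_that("random labels give chance-level AUC", {
  set.seed(99)
  x <- rnorm(2000, 10, 3)
  y <- sample(c(TRUE, FALSE), 2000, replace = TRUE)
  cal <- select_threshold(data.frame(relative_distance = x, same_cell = y))
  expect_lt(abs(cal$auc - 0.5), 0.05)
})
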