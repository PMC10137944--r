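well_separated_areas <- function(n = 3000, seed = 1) {
  set.seed(seed)
  c(rnorm(n * 2 / 3, 200, 20), rnorm(n * 7 / 30, 500, 20),
    rnorm(n * 1 / 10, 900, 20))
}

test_that("EM recovers well-separated components and is monotone", {
  x <- well_separated_areas()
  m <- fit_gmm(x)
  expect_equal(m$means, c(200, 500, 900), tolerance = 0.02)
  expect_true(all(diff(m$loglik_trace) >= -1e-8))
  expect_true(all(abs(sum(m$weights) - 1) < 1e-9))
  expect_true(all(m$variances > 0))
  expect_true(all(diff(m$means) > 0))
  # the stage-1 peak is the pooled mean
  expect_equal(m$k, mean(x))
  expect_error(fit_gmm(x[1:10]), "at least 30")
  expect_error(fit_gmm(c(x, -5)), "positive")
})

test_that("fitted parameters agree with an independent EM implementation", {
  suppressPackageStartupMessages(library(mclust))
  x <- well_separated_areas(seed = 2)
  m <- fit_gmm(x)
  # run mclust's EM from the identical two-stage initialization; both
  # optimizers must converge to the same stationary point
  k <- mean(x)
  v <- mean((x - k)^2)
  par <- list(pro = rep(1 / 3, 3), mean = k * c(1, 1.4, 1.96),
              variance = list(modelName = "V", d = 1, G = 3,
                              sigmasq = rep(v, 3)))
  mc <- em(modelName = "V", data = x, parameters = par)
  expect_equal(m$means, as.numeric(sort(mc$parameters$mean)),
               tolerance = 1e-4)
  expect_equal(m$weights, as.numeric(mc$parameters$pro), tolerance = 1e-4)
  expect_equal(m$loglik, mc$loglik, tolerance = 1e-6)
})

test_that("scaling areas rescales parameters but not hard calls", {
  x <- well_separated_areas(seed = 3)
  m1 <- fit_gmm(x)
  m2 <- fit_gmm(2.5 * x)
  expect_equal(m2$means, 2.5 * m1$means, tolerance = 1e-6)
  expect_equal(m2$variances, 2.5^2 * m1$variances, tolerance = 1e-6)
  expect_equal(classify_nuclei(m2, 2.5 * x)$ploidy,
               classify_nuclei(m1, x)$ploidy)
})

test_that("classification is max-posterior with normalized responsibilities", {
  x <- well_separated_areas(seed = 4)
  m <- fit_gmm(x)
  calls <- classify_nuclei(m, x)
  expect_equal(calls$p_2n + calls$p_4n + calls$p_8n, rep(1, length(x)),
               tolerance = 1e-12)
  # an area at a component mean of a well-separated model is called with
  # near-certain posterior
  at_means <- classify_nuclei(m, m$means)
  expect_equal(as.character(at_means$ploidy), c("2n", "4n", "8n"))
  expect_true(all(pmax(at_means$p_2n, at_means$p_4n, at_means$p_8n) > 0.99))
  # brute-force weighted-density oracle over 100 random areas
  set.seed(5)
  a <- runif(100, 100, 1100)
  oracle <- apply(vapply(1:3, function(j) {
    m$weights[j] * dnorm(a, m$means[j], sqrt(m$variances[j]))
  }, numeric(100)), 1, which.max)
  expect_equal(as.integer(classify_nuclei(m, a)$ploidy), oracle)
})

test_that("refitting data drawn from the fitted family recovers it", {
  x <- well_separated_areas(seed = 6)
  m <- fit_gmm(x)
  set.seed(7)
  comp <- sample(1:3, 5000, replace = TRUE, prob = m$weights)
  y <- rnorm(5000, m$means[comp], sqrt(m$variances[comp]))
  m2 <- fit_gmm(y)
  expect_equal(m2$means, m$means, tolerance = 0.05)
  expect_true(all(abs(m2$weights - m$weights) < 0.05))
})

test_that("component means track the per-class slice-area means", {
  cfg <- area_sim_config(seed = 3)
  s <- censor_areas(simulate_areas(cfg), 200)
  m <- fit_gmm(s$area)
  emp <- as.numeric(tapply(s$area, s$ploidy, mean))
  # classes overlap heavily after slicing, so mixture components only
  # approximate the class structure; they track the per-class means to ~10%
  expect_true(all(abs(m$means - emp) / emp < 0.10))
  expect_true(all(diff(m$means) > 0))
})

test_that("total ploidy sums nuclear ploidies with readable categories", {
  cells <- data.frame(cell_id = 1:3, cell_row = 0, cell_col = 0,
                      cellular_ploidy = c(2, 1, 2))
  cells$members <- I(list(c(1L, 2L), 3L, c(4L, 5L)))
  calls <- data.frame(nucleus_id = 1:5, area = 1,
                      ploidy = factor(c("2n", "2n", "8n", "2n", "4n"),
                                      levels = c("2n", "4n", "8n")))
  tot <- summarize_total_ploidy(cells, calls)
  expect_equal(tot$cells$total_ploidy, c("4n", "8n", "6n"))
  expect_equal(tot$cells$category,
               c("binuclear-2x2n", "mononuclear-8n", "binuclear-2n+4n"))
  expect_error(summarize_total_ploidy(cells, calls[-1, ]), "nucleus 1")
  # distribution table counts categories
  expect_equal(sum(tot$distribution$Freq), 3)
})

test_that("a fitted model survives the JSON round trip", {
  m <- fit_gmm(well_separated_areas(seed = 8), training_resolution = 0.23)
  path <- withr::local_tempfile(fileext = ".json")
  write_gmm_model(m, path)
  m2 <- read_gmm_model(path)
  expect_equal(m2$means, m$means)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$variances, m$variances)
  expect_equal(m2$training_resolution, 0.23)
  # cross-resolution application rescales areas by the squared ratio: the
  # same physical nucleus measured at 0.46 um/px covers 1/4 the pixels
  a <- c(210, 480, 950)
  native <- classify_nuclei(m, a)
  coarse <- classify_nuclei(m2, a * (0.23 / 0.46)^2, resolution = 0.46)
  expect_equal(coarse$ploidy, native$ploidy)
  expect_equal(coarse$p_2n, native$p_2n, tolerance = 1e-9)
})
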