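# Independent oracles and fixture builders shared across test files.
# Oracles are deliberately naive (brute force) and never call the package
# functions they are used to check.

# Connected components by breadth-first search over an explicit edge list.
# Returns a component id per node (1..n), renumbered by first occurrence.
bfs_components <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]])
    }
  }
  comp
}

# Exhaustive F1 scan over a fixed grid of thresholds (rule: positive iff
# distance < threshold, positive class = same cell).
grid_scan_f1 <- function(x, y, step = 0.01) {
  grid <- seq(min(x) - step, max(x) + step, by = step)
  P <- sum(y)
  f1 <- vapply(grid, function(t) {
    tp <- sum(y & x < t); fp <- sum(!y & x < t)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / P
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1))
  list(f1 = max(f1), threshold = grid[which.max(f1)])
}

# Mann-Whitney form of the AUC: P(pos < neg) + 0.5 P(tie), positives being
# the small-distance (same-cell) class.
mann_whitney_auc <- function(x, y) {
  pos <- x[y]; neg <- x[!y]
  mean(outer(pos, neg, "<") + 0.5 * outer(pos, neg, "=="))
}

# Per-nucleus nearest-neighbour pair collection by direct O(n^2) enumeration.
naive_calibration_pairs <- function(nuclei, cell) {
  n <- nrow(nuclei)
  out <- NULL
  for (i in seq_len(n)) {
    best_d <- Inf; best_j <- NA
    best_ds <- Inf; best_js <- NA
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt((nuclei$centroid_row[i] - nuclei$centroid_row[j])^2 +
                (nuclei$centroid_col[i] - nuclei$centroid_col[j])^2)
      rd <- d - nuclei$equivalent_radius[i] - nuclei$equivalent_radius[j]
      if (cell[j] != cell[i] && rd < best_d) { best_d <- rd; best_j <- j }
      if (cell[j] == cell[i] && rd < best_ds) { best_ds <- rd; best_js <- j }
    }
    if (!is.na(best_j))
      out <- rbind(out, data.frame(a = nuclei$nucleus_id[i],
                                   b = nuclei$nucleus_id[best_j],
                                   rd = best_d, same_cell = FALSE))
    if (!is.na(best_js))
      out <- rbind(out, data.frame(a = nuclei$nucleus_id[i],
                                   b = nuclei$nucleus_id[best_js],
                                   rd = best_ds, same_cell = TRUE))
  }
  out
}

# Random nucleus table (no geometry constraints; for pure-math oracles).
random_nuclei <- function(n, extent = 300, r_range = c(4, 12)) {
  data.frame(nucleus_id = seq_len(n),
             centroid_row = runif(n, 0, extent),
             centroid_col = runif(n, 0, extent),
             equivalent_radius = runif(n, r_range[1], r_range[2]))
}

# A small well-separated fluorescence-like patch spec for segmentation tests.
sep_patch_spec <- function(n_cells = 10, binuclear_fraction = 0.4, seed = 1,
                           height = 360, width = 360) {
  synthetic_patch_spec(height = height, width = width, n_cells = n_cells,
                       binuclear_fraction = binuclear_fraction,
                       nucleus_radius_mean = 9, nucleus_radius_sd = 0.9,
                       intra_cell_nucleus_gap = 4, min_inter_cell_gap = 12,
                       seed = seed)
}

# Separable H&E-like regime: sibling gap < 15.54 < inter-cell gap, nuclear
# area classes resolvable by a reference mixture model.
sep_he_spec <- function(seed = 21, n_cells = 32) {
  synthetic_patch_spec(height = 500, width = 500, n_cells = n_cells,
                       binuclear_fraction = 0.4,
                       nucleus_radius_mean = 9, nucleus_radius_sd = 0.5,
                       intra_cell_nucleus_gap = 8, min_inter_cell_gap = 24,
                       ploidy_class_fractions = c(0.5, 0.3, 0.2),
                       area_multiplier = 1.5, seed = seed)
}

# Reference mixture model for the separable H&E regime, fitted on a large
# sample from the same three area classes the generator uses.
reference_gmm <- function(seed = 5) {
  set.seed(seed)
  r <- c(rnorm(1500, 9, 0.5), rnorm(900, 13.5, 0.75), rnorm(600, 20.25, 1.1))
  fit_gmm(pi * r^2)
}

truth_ploidy_n <- c(`2n` = 2L, `4n` = 4L, `8n` = 8L)
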