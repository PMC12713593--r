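# Shared fixtures: random count matrices and independent oracles.

# Random gene x spot count matrix with guaranteed positive spot totals.
random_counts <- function(n_genes, n_spots, lambda = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rpois(n_genes * n_spots, lambda), n_genes, n_spots,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_spots))))
  zero <- which(colSums(m) == 0)
  if (length(zero)) m[1L, zero] <- m[1L, zero] + 1L
  m
}

# Independent oracle: per-gene residual deviance from an iteratively fitted
# binomial GLM (intercept-only or intercept + batch factor).
glm_deviance <- function(counts, totals, groups = NULL) {
  vapply(seq_len(nrow(counts)), function(i) {
    y <- as.numeric(counts[i, ])
    if (!is.null(groups) && length(unique(groups)) < 2L) groups <- NULL
    fit <- if (is.null(groups)) {
      suppressWarnings(stats::glm(cbind(y, totals - y) ~ 1,
                                  family = stats::binomial()))
    } else {
      suppressWarnings(stats::glm(cbind(y, totals - y) ~ factor(groups),
                                  family = stats::binomial()))
    }
    fit$deviance
  }, numeric(1))
}

# Brute-force rank oracle: r_i = 1 + number of strictly larger values,
# plus the number of earlier ties (stable tie-break by index).
rank_oracle <- function(d) {
  vapply(seq_along(d), function(i) {
    1L + sum(d > d[i]) + sum(d[seq_len(i - 1L)] == d[i])
  }, integer(1))
}

# Naive confusion-table oracle for evaluate_detection().
confusion_oracle <- function(flagged, biased, universe) {
  tp <- fp <- fn <- tn <- 0L
  for (g in universe) {
    f <- g %in% flagged
    b <- g %in% biased
    if (f && b) tp <- tp + 1L else if (f) fp <- fp + 1L
    else if (b) fn <- fn + 1L else tn <- tn + 1L
  }
  list(
    sensitivity = if (tp + fn == 0L) 1 else tp / (tp + fn),
    specificity = if (tn + fp == 0L) 1 else tn / (tn + fp),
    fpr = if (tn + fp == 0L) 0 else fp / (fp + tn),
    fdr = if (tp + fp == 0L) 0 else fp / (fp + tp)
  )
}

# Small simulation config for fast tests.
tiny_config <- function(...) {
  defaults <- list(n_genes = 80L, n_spots_per_batch = 40L, n_batches = 2L,
                   n_batch_biased = 8L, batch_effect_fold = 4,
                   n_spatial = 10L, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
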