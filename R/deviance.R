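#' Per-gene binomial residual deviance
#'
#' For each gene, spot counts are modelled as
#' \eqn{y_{ij} \sim Binomial(N_j, \pi)}, with \eqn{N_j} the per-spot total
#' over all genes in the matrix. Without `groups` a single success
#' probability is shared by all spots; with `groups` a separate probability
#' is fitted within each level (the exact MLE of a binomial GLM with a
#' categorical covariate, \eqn{\hat\pi_S = \sum_{j \in S} y_{ij} /
#' \sum_{j \in S} N_j}, so no iterative fitting is needed). The residual
#' deviance is twice the saturated-minus-fitted log-likelihood:
#' \deqn{D_i = 2 \sum_j \left[ y_{ij} \ln\frac{y_{ij}}{N_j \hat\pi_j} +
#'   (N_j - y_{ij}) \ln\frac{N_j - y_{ij}}{N_j (1 - \hat\pi_j)} \right]}
#' with the convention \eqn{0 \ln 0 = 0} (applied by masking, never by
#' pseudo-counts) and a final clamp at zero against floating-point
#' undershoot. Larger deviance means more variation left unexplained by the
#' (stratified) constant-proportion model.
#'
#' @inheritParams validate_counts
#' @param totals per-spot totals, by default [spot_totals()] of `counts`.
#'   Pass totals from the full transcriptome matrix when `counts` has been
#'   subset to a candidate gene list.
#' @param groups optional per-spot categorical labels (character or factor,
#'   length `ncol(counts)`); `NULL` fits the intercept-only model.
#' @return Named numeric vector of per-gene deviances, length `nrow(counts)`.
#' @examples
#' m <- matrix(c(3, 1, 0, 2), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' binomial_deviance(m)
#' @export
binomial_deviance <- function(counts, totals = spot_totals(counts),
                              groups = NULL) {
  validate_counts(counts)
  if (length(totals) != ncol(counts)) {
    stop("`totals` must have one entry per spot", call. = FALSE)
  }
  if (any(!is.finite(totals)) || any(totals <= 0)) {
    stop("`totals` must be positive and finite", call. = FALSE)
  }
  if (!is.null(groups)) {
    if (length(groups) != ncol(counts)) {
      stop("`groups` must have one label per spot", call. = FALSE)
    }
    if (anyNA(groups)) stop("`groups` has missing labels", call. = FALSE)
    groups <- as.character(groups)
  } else {
    groups <- rep("all", ncol(counts))
  }

  dev <- numeric(nrow(counts))
  for (idx in split(seq_len(ncol(counts)), groups)) {
    y <- as.matrix(counts[, idx, drop = FALSE])
    tot <- totals[idx]
    pihat <- rowSums(y) / sum(tot)
    mu <- pihat %o% tot               # fitted counts
    comp <- rep(tot, each = nrow(y)) - y
    mu_c <- (1 - pihat) %o% tot

    t1 <- y * (log(y) - log(mu))
    t1[y == 0] <- 0                   # 0 * ln 0 convention
    t2 <- comp * (log(comp) - log(mu_c))
    t2[comp == 0] <- 0                # covers pi-hat = 1 strata
    dev <- dev + rowSums(t1) + rowSums(t2)
  }
  stats::setNames(pmax(2 * dev, 0), rownames(counts))
}

#' Rank genes by deviance
#'
#' Rank 1 is the gene with the largest deviance (the most "important" under
#' the feature-selection reading). Ties are broken by ascending gene index so
#' that ranks are a deterministic permutation of `1..n` on every platform.
#'
#' @param deviances numeric vector of non-negative, finite per-gene deviances.
#' @return Integer rank vector, a permutation of `seq_along(deviances)`,
#'   carrying names over from `deviances`.
#' @examples
#' rank_genes(c(a = 5, b = 1, c = 3))
#' @export
rank_genes <- function(deviances) {
  if (anyNA(deviances) || any(!is.finite(deviances))) {
    stop("deviances must be finite (upstream contract violation)",
         call. = FALSE)
  }
  if (any(deviances < 0)) {
    stop("deviances must be non-negative", call. = FALSE)
  }
  r <- rank(-deviances, ties.method = "first")
  stats::setNames(as.integer(r), names(deviances))
}

#' Per-gene deviance with and without batch covariates
#'
#' Fits the intercept-only binomial model once and the batch-stratified model
#' for each requested batch variable, recording deviances and deviance ranks.
#' Each batch variable is handled independently; a variable with a single
#' level collapses to the default model (a warning notes that downstream RCD
#' and RD will be identically zero).
#'
#' @inheritParams binomial_deviance
#' @param annotations data frame with a `spot_id` column and one column per
#'   batch variable (categorical labels, no missing values).
#' @param batch_vars character vector of annotation column names to use as
#'   batch covariates.
#' @return A tibble with one row per gene and batch variable: `gene_id`,
#'   `batch_var`, `d_default`, `d_batch`, `r_default`, `r_batch`.
#' @seealso [detect_bias()] which consumes this table.
#' @export
deviance_table <- function(counts, annotations, batch_vars,
                           totals = spot_totals(counts)) {
  stopifnot(is.character(batch_vars), length(batch_vars) >= 1L)
  d_default <- binomial_deviance(counts, totals)
  r_default <- rank_genes(d_default)

  purrr::map_dfr(batch_vars, function(v) {
    labs <- batch_labels(annotations, counts, v)
    if (length(unique(labs)) < 2L) {
      warning("batch variable `", v, "` has a single level; ",
              "RCD and RD will be zero for all genes", call. = FALSE)
    }
    d_batch <- binomial_deviance(counts, totals, groups = labs)
    tibble::tibble(
      gene_id = rownames(counts),
      batch_var = v,
      d_default = unname(d_default),
      d_batch = unname(d_batch),
      r_default = unname(r_default),
      r_batch = unname(rank_genes(d_batch))
    )
  })
}
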