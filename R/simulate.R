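#' Simulation settings for multi-sample spatial count data
#'
#' Bundles and validates the parameters of [simulate_svg_counts()]. Defaults
#' define an equal-power validation testbed emulating a multi-sample
#' Visium-style experiment on a candidate gene panel: 1,000 genes over 2
#' batches of 300 spots, 20 genes carrying a 4-fold batch-specific rate
#' shift, 100 genes with a shared spatial pattern (amplitude 2), spot
#' library sizes log-normal around ~10,000 UMIs, and near-exchangeable
#' baseline proportions (concentration 50) so every injected effect has
#' comparable statistical power. Real panels have far more heterogeneous
#' expression; see the package vignette for what this does and does not
#' emulate.
#'
#' @param n_genes number of genes (>= 10).
#' @param n_spots_per_batch spots per batch level (>= 20), laid on a grid.
#' @param n_batches number of batch levels (>= 1).
#' @param n_batch_biased number of genes given a batch-specific rate shift.
#' @param batch_effect_fold multiplicative rate shift (>= 1) applied to
#'   biased genes in odd-indexed batch levels; 1 disables the effect.
#' @param n_spatial number of genes given a spatial expression pattern,
#'   disjoint from the biased set and identical across batches.
#' @param spatial_amplitude strength of the spatial pattern: rates are
#'   scaled by `1 + spatial_amplitude * g(x, y)` with `g` a unit-range bump.
#' @param libsize_log_mean,libsize_log_sd log-normal parameters of per-spot
#'   library sizes.
#' @param baseline_concentration symmetric Dirichlet concentration for the
#'   baseline gene proportions (smaller = more skewed expression).
#' @param seed integer RNG seed; the simulation is fully reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000L, n_spots_per_batch = 300L,
                       n_batches = 2L, n_batch_biased = 20L,
                       batch_effect_fold = 4, n_spatial = 100L,
                       spatial_amplitude = 2,
                       libsize_log_mean = log(10000), libsize_log_sd = 0.4,
                       baseline_concentration = 50, seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_spots_per_batch = as.integer(n_spots_per_batch),
    n_batches = as.integer(n_batches),
    n_batch_biased = as.integer(n_batch_biased),
    batch_effect_fold = as.numeric(batch_effect_fold),
    n_spatial = as.integer(n_spatial),
    spatial_amplitude = as.numeric(spatial_amplitude),
    libsize_log_mean = as.numeric(libsize_log_mean),
    libsize_log_sd = as.numeric(libsize_log_sd),
    baseline_concentration = as.numeric(baseline_concentration),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_genes >= 10L, cfg$n_spots_per_batch >= 20L, cfg$n_batches >= 1L,
    cfg$n_batch_biased >= 0L, cfg$n_spatial >= 0L,
    cfg$batch_effect_fold >= 1, cfg$spatial_amplitude >= 0,
    cfg$libsize_log_sd >= 0, cfg$baseline_concentration > 0
  )
  if (cfg$n_batch_biased + cfg$n_spatial > cfg$n_genes) {
    stop("n_batch_biased + n_spatial must not exceed n_genes", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulation config from a flat key-value file
#'
#' One `key = value` (or `key: value`) pair per line; keys are the arguments
#' of [sim_config()]; `#` starts a comment. Unknown keys are an error.
#'
#' @param path file path.
#' @return A `sim_config` list.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=:]", fixed = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = ":"), ""))
  known <- names(formals(sim_config))
  if (length(bad <- setdiff(keys, known))) {
    stop("unknown simulation config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, stats::setNames(as.list(as.numeric(vals)), keys))
}

# Unit-range smooth bump over [0, 1]^2 grid coordinates (Gaussian kernel
# centred in the tissue, rescaled to [0, 1]).
spatial_bump <- function(x, y) {
  g <- exp(-((x - 0.5)^2 + (y - 0.5)^2) / (2 * 0.3^2))
  if (diff(range(g)) == 0) return(rep(0, length(g)))
  (g - min(g)) / (max(g) - min(g))
}

#' Simulate multi-sample spatial count data with known batch-biased genes
#'
#' Generates a gene x spot UMI count matrix with ground truth. Baseline gene
#' proportions are drawn once from a symmetric Dirichlet. Spots are laid on a
#' unit-square grid per batch (the same grid in every batch). The relative
#' rate of gene i at spot j is `p_i * m_i(batch_j) * s_i(coord_j)`: `m` is
#' `batch_effect_fold` for biased genes in odd-indexed batch levels and 1
#' otherwise; `s` is `1 + spatial_amplitude * g(coord)` for spatial genes
#' (a fixed smooth bump shared across batches) and 1 otherwise. Library
#' sizes are log-normal and spot counts are multinomial given the library
#' size, so column sums equal the drawn library sizes exactly. The global
#' RNG state is left untouched.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `svg_sim`: `counts` (sparse integer matrix,
#'   genes x spots), `annotations` (tibble: `spot_id`, `batch`, `x`, `y`),
#'   and `truth` (list: `gene_ids`, `biased_gene_ids`, `spatial_gene_ids`,
#'   `multipliers` tibble of realised per-gene per-batch rate multipliers).
#' @examples
#' sim <- simulate_svg_counts(sim_config(n_genes = 50, n_spots_per_batch = 30,
#'                                       seed = 7))
#' dim(sim$counts)
#' @export
simulate_svg_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)

  n <- config$n_genes
  js <- config$n_spots_per_batch
  nb <- config$n_batches
  gene_ids <- sprintf("gene%05d", seq_len(n))
  biased <- gene_ids[seq_len(config$n_batch_biased)]
  spatial <- gene_ids[config$n_batch_biased + seq_len(config$n_spatial)]

  # baseline proportions: symmetric Dirichlet via gamma draws
  p <- stats::rgamma(n, shape = config$baseline_concentration)
  p <- p / sum(p)

  side <- ceiling(sqrt(js))
  grid <- expand.grid(x = seq(0, 1, length.out = side),
                      y = seq(0, 1, length.out = side))[seq_len(js), ]
  bump <- spatial_bump(grid$x, grid$y)

  batches <- sprintf("batch%d", seq_len(nb))
  mult <- matrix(1, n, nb, dimnames = list(gene_ids, batches))
  mult[gene_ids %in% biased, seq(1L, nb, by = 2L)] <- config$batch_effect_fold

  spatial_scale <- matrix(1, n, js)
  spatial_scale[gene_ids %in% spatial, ] <-
    rep(1 + config$spatial_amplitude * bump,
        each = length(spatial))

  counts <- matrix(0L, n, js * nb)
  ann <- vector("list", nb)
  for (b in seq_len(nb)) {
    rate <- p * mult[, b] * spatial_scale          # genes x js
    prob <- sweep(rate, 2L, colSums(rate), "/")
    sizes <- pmax(1, round(stats::rlnorm(js, config$libsize_log_mean,
                                         config$libsize_log_sd)))
    for (j in seq_len(js)) {
      counts[, (b - 1L) * js + j] <- stats::rmultinom(1L, sizes[j], prob[, j])
    }
    ann[[b]] <- tibble::tibble(
      spot_id = sprintf("%s_spot%04d", batches[b], seq_len(js)),
      batch = batches[b], x = grid$x, y = grid$y
    )
  }
  annotations <- dplyr::bind_rows(ann)
  dimnames(counts) <- list(gene_ids, annotations$spot_id)

  structure(
    list(
      counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                           "CsparseMatrix"),
      annotations = annotations,
      truth = list(
        gene_ids = gene_ids,
        biased_gene_ids = biased,
        spatial_gene_ids = spatial,
        multipliers = tibble::as_tibble(as.data.frame.table(
          mult, responseName = "multiplier",
          stringsAsFactors = FALSE)) |>
          stats::setNames(c("gene_id", "batch", "multiplier"))
      )
    ),
    class = "svg_sim"
  )
}

#' @export
print.svg_sim <- function(x, ...) {
  cat(sprintf(
    "<svg_sim> %d genes x %d spots (%d batch level(s)); %d batch-biased, %d spatial genes\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$annotations$batch)),
    length(x$truth$biased_gene_ids), length(x$truth$spatial_gene_ids)))
  invisible(x)
}

#' Score a flagged gene set against simulation ground truth
#'
#' Confusion-table summaries of how well a flagged set recovers the truly
#' batch-biased genes: sensitivity `TP / (TP + FN)` (defined as 1 when no
#' gene is biased), specificity `TN / (TN + FP)`, false positive rate
#' `FP / (FP + TN)`, and false discovery rate `FP / (TP + FP)` (0 for an
#' empty flagged set).
#'
#' @param flagged character vector of flagged gene IDs (or an `svg_bias`
#'   object, in which case the union over batch variables is scored).
#' @param truth the `truth` element of [simulate_svg_counts()] output (or
#'   the `svg_sim` object itself).
#' @return One-row tibble: `sensitivity`, `specificity`, `fpr`, `fdr`,
#'   `n_flagged`, `n_biased`.
#' @export
evaluate_detection <- function(flagged, truth) {
  if (inherits(flagged, "svg_bias")) {
    flagged <- unique(unlist(flagged$flagged, use.names = FALSE))
  }
  if (inherits(truth, "svg_sim")) truth <- truth$truth
  universe <- truth$gene_ids
  biased <- truth$biased_gene_ids
  if (length(bad <- setdiff(flagged, universe))) {
    stop("flagged gene(s) outside the simulated universe: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  tp <- length(intersect(flagged, biased))
  fp <- length(setdiff(flagged, biased))
  fn <- length(setdiff(biased, flagged))
  tn <- length(universe) - tp - fp - fn
  tibble::tibble(
    sensitivity = if (length(biased) == 0L) 1 else tp / (tp + fn),
    specificity = if (tn + fp == 0L) 1 else tn / (tn + fp),
    fpr = if (tn + fp == 0L) 0 else fp / (fp + tn),
    fdr = if (tp + fp == 0L) 0 else fp / (tp + fp),
    n_flagged = length(flagged),
    n_biased = length(biased)
  )
}
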