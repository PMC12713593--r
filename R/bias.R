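#' Relative change in deviance (RCD)
#'
#' \eqn{RCD_i = (d_{i,default} - d_{i,batch}) / d_{i,batch}}: the fraction of
#' a gene's unexplained variation absorbed by the batch covariate, relative
#' to what remains. `0/0` (both deviances zero) is defined as 0; a positive
#' default deviance fully explained by batch (`d_batch = 0`) yields `Inf`,
#' a sentinel that force-flags the gene downstream.
#'
#' @param d_default,d_batch non-negative per-gene deviance vectors of equal
#'   length (from [deviance_table()]).
#' @return Numeric RCD vector.
#' @export
relative_change_in_deviance <- function(d_default, d_batch) {
  if (length(d_default) != length(d_batch)) {
    stop("deviance vectors must have equal length", call. = FALSE)
  }
  if (any(d_default < 0) || any(d_batch < 0)) {
    stop("deviances must be non-negative", call. = FALSE)
  }
  rcd <- (d_default - d_batch) / d_batch
  rcd[d_batch == 0 & d_default == 0] <- 0
  rcd[d_batch == 0 & d_default > 0] <- Inf
  rcd
}

#' Rank deviance (RD)
#'
#' \eqn{RD_i = r_{i,batch} - r_{i,default}}. A positive value means the gene
#' dropped in the deviance ranking once the batch variable was accounted for
#' (e.g. rank 1 to rank 500 gives RD = 499): its importance was inflated by
#' batch. RD values over all genes always sum to zero, being the difference
#' of two permutations of `1..n`.
#'
#' @param r_default,r_batch integer rank vectors, each a permutation of
#'   `1..n` (from [rank_genes()]).
#' @return Integer RD vector.
#' @export
rank_deviance <- function(r_default, r_batch) {
  check_perm <- function(r, what) {
    if (length(r) == 0L || !setequal(r, seq_along(r))) {
      stop("`", what, "` is not a permutation of 1..n", call. = FALSE)
    }
  }
  if (length(r_default) != length(r_batch)) {
    stop("rank vectors must have equal length", call. = FALSE)
  }
  check_perm(r_default, "r_default")
  check_perm(r_batch, "r_batch")
  as.integer(r_batch) - as.integer(r_default)
}

#' Standardise to nSD units
#'
#' Centres and scales a vector by its mean and sample standard deviation
#' (denominator `n - 1`), giving the "number of standard deviations" scale on
#' which flagging cutoffs are set. Infinite sentinel values are excluded from
#' the mean/SD and propagate as `Inf` in the output. A degenerate SD of zero
#' (e.g. a single-level batch variable making every value identical) returns
#' all zeros with a warning, so no gene can be flagged on that statistic.
#'
#' @param values numeric vector, length at least 2.
#' @return Standardised vector of the same length.
#' @examples
#' nsd(c(1, 2, 3))
#' @export
nsd <- function(values) {
  if (length(values) < 2L) {
    stop("need at least 2 values to standardise", call. = FALSE)
  }
  if (anyNA(values)) stop("missing values in `values`", call. = FALSE)
  finite <- is.finite(values)
  x <- values[finite]
  s <- stats::sd(x)
  out <- rep(0, length(values))
  if (length(x) >= 2L && !is.na(s) && s > 0) {
    out[finite] <- (x - mean(x)) / s
  } else {
    warning("standard deviation is zero; nSD set to 0 for all genes ",
            "(no gene can be flagged on this statistic)", call. = FALSE)
  }
  out[!finite] <- values[!finite]   # +/- Inf sentinels pass through
  out
}

#' Flag batch-biased genes
#'
#' Computes RCD, RD and their nSD standardisations per batch variable from a
#' [deviance_table()] and flags genes whose positive deviations exceed the
#' cutoffs. Flagging is one-sided: a negative nSD means the gene *gained*
#' importance under the batch model, which is never evidence of batch bias.
#' Genes with infinite RCD (batch explains all variation) are always flagged.
#'
#' @param dev_table tibble from [deviance_table()].
#' @param nsd_rcd_cutoff,nsd_rd_cutoff positive flagging cutoffs on the nSD
#'   scale; default 3 for both.
#' @param mode how the two statistics combine: `"intersection"` (default;
#'   both must exceed their cutoff), `"union"` (either), `"rcd_only"`,
#'   `"rd_only"`.
#' @param batch_var optional subset of batch variables to process; default
#'   all present in `dev_table`.
#' @return An object of class `svg_bias`: a list with `table` (per-gene,
#'   per-batch-variable tibble adding `rcd`, `rd`, `nsd_rcd`, `nsd_rd`,
#'   `flagged`), `flagged` (named list of flagged gene IDs per batch
#'   variable, sorted by descending `nsd_rcd`), and the cutoffs/mode used.
#'   Supports [tidy()], [glance()], [autoplot()] and `print()`.
#' @examples
#' sim <- simulate_svg_counts(sim_config(n_genes = 50, n_spots_per_batch = 40,
#'                                       n_batch_biased = 5, seed = 1))
#' dt <- deviance_table(sim$counts, sim$annotations, "batch")
#' detect_bias(dt)
#' @export
detect_bias <- function(dev_table, nsd_rcd_cutoff = 3, nsd_rd_cutoff = 3,
                        mode = c("intersection", "union", "rcd_only",
                                 "rd_only"),
                        batch_var = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.finite(nsd_rcd_cutoff), nsd_rcd_cutoff > 0,
            is.finite(nsd_rd_cutoff), nsd_rd_cutoff > 0)
  dev_table <- tibble::as_tibble(dev_table)
  need <- c("gene_id", "batch_var", "d_default", "d_batch",
            "r_default", "r_batch")
  if (!all(need %in% names(dev_table))) {
    stop("`dev_table` must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  vars <- unique(dev_table$batch_var)
  if (!is.null(batch_var)) {
    if (!all(batch_var %in% vars)) {
      stop("batch variable(s) absent from `dev_table`: ",
           paste(setdiff(batch_var, vars), collapse = ", "), call. = FALSE)
    }
    vars <- batch_var
  }

  table <- purrr::map_dfr(vars, function(v) {
    d <- dplyr::filter(dev_table, .data$batch_var == v)
    rcd <- relative_change_in_deviance(d$d_default, d$d_batch)
    rd <- rank_deviance(d$r_default, d$r_batch)
    nsd_rcd <- nsd(rcd)
    nsd_rd <- nsd(as.numeric(rd))
    hit_rcd <- nsd_rcd > nsd_rcd_cutoff
    hit_rd <- nsd_rd > nsd_rd_cutoff
    flagged <- switch(mode,
      rcd_only = hit_rcd,
      rd_only = hit_rd,
      intersection = hit_rcd & hit_rd,
      union = hit_rcd | hit_rd
    )
    flagged <- flagged | is.infinite(rcd)   # batch explains all variation
    dplyr::mutate(d, rcd = rcd, rd = rd, nsd_rcd = nsd_rcd,
                  nsd_rd = nsd_rd, flagged = flagged)
  })

  flagged <- lapply(stats::setNames(vars, vars), function(v) {
    f <- dplyr::filter(table, .data$batch_var == v, .data$flagged)
    f <- dplyr::arrange(f, dplyr::desc(.data$nsd_rcd))
    f$gene_id
  })

  structure(
    list(table = table, flagged = flagged,
         nsd_rcd_cutoff = nsd_rcd_cutoff, nsd_rd_cutoff = nsd_rd_cutoff,
         mode = mode),
    class = "svg_bias"
  )
}

#' @export
print.svg_bias <- function(x, ...) {
  n <- length(unique(x$table$gene_id))
  cat(sprintf(
    "<svg_bias> %d genes, %d batch variable(s); mode = %s, cutoffs nSD(RCD) > %g, nSD(RD) > %g\n",
    n, length(x$flagged), x$mode, x$nsd_rcd_cutoff, x$nsd_rd_cutoff))
  for (v in names(x$flagged)) {
    ids <- x$flagged[[v]]
    cat(sprintf("  %s: %d flagged%s\n", v, length(ids),
                if (length(ids)) paste0(" (", paste(utils::head(ids, 5L),
                                                   collapse = ", "),
                                        if (length(ids) > 5L) ", ..." else "",
                                        ")") else ""))
  }
  invisible(x)
}

#' @describeIn detect_bias per-gene, per-batch-variable results as a tibble.
#' @param x an `svg_bias` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.svg_bias <- function(x, ...) x$table

#' @describeIn detect_bias one-row-per-batch-variable summary: genes tested,
#'   genes flagged, cutoffs and mode.
#' @exportS3Method generics::glance
glance.svg_bias <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$table, .data$batch_var),
    n_genes = dplyr::n(),
    n_flagged = sum(.data$flagged),
    max_nsd_rcd = max(.data$nsd_rcd[is.finite(.data$nsd_rcd)]),
    max_nsd_rd = max(.data$nsd_rd),
    .groups = "drop"
  ) |>
    dplyr::mutate(mode = x$mode, nsd_rcd_cutoff = x$nsd_rcd_cutoff,
                  nsd_rd_cutoff = x$nsd_rd_cutoff)
}

#' Remove flagged genes from a candidate SVG list
#'
#' Set difference preserving the input order. When several batch variables
#' were analysed, the union of their flagged sets is removed. A flagged gene
#' absent from `svg_ids` indicates bookkeeping corruption and is an error.
#'
#' @param svg_ids character vector of candidate SVG gene IDs.
#' @param flagged character vector, list of character vectors, or an
#'   `svg_bias` object.
#' @return Character vector: `svg_ids` minus all flagged genes, order kept.
#' @examples
#' refine_svg_list(c("a", "b", "c", "d"), list(c("a", "b"), c("b", "c")))
#' @export
refine_svg_list <- function(svg_ids, flagged) {
  if (inherits(flagged, "svg_bias")) flagged <- flagged$flagged
  if (is.list(flagged)) flagged <- unique(unlist(flagged, use.names = FALSE))
  flagged <- as.character(flagged %||% character())
  extra <- setdiff(flagged, svg_ids)
  if (length(extra)) {
    stop("flagged gene(s) not in the SVG list (bookkeeping corruption): ",
         paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
  }
  svg_ids[!svg_ids %in% flagged]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
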