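#' Run the full batch-bias refinement workflow
#'
#' End-to-end: subset the count matrix to the candidate SVG list, fit the
#' binomial deviance models per batch variable, flag batch-biased genes, and
#' (optionally) write the per-gene bias table, the refined SVG list and
#' diagnostic plots to `out_dir`.
#'
#' The binomial denominator is the per-spot total count. With
#' `totals_scope = "full"` (the default) totals are computed from the matrix
#' as supplied, *before* subsetting to the SVG list — so passing the full
#' transcriptome matrix plus an SVG list models each gene's share of the
#' whole library. With `"subset"` totals are recomputed after subsetting.
#'
#' @param counts gene x spot count matrix, or a path: a directory with a 10x
#'   MatrixMarket triplet, or a dense TSV/CSV table.
#' @param annotations per-spot annotation data frame with a `spot_id`
#'   column, or a path to a TSV.
#' @param svg_ids candidate SVG gene IDs (character vector or path to a
#'   plain-text list, one ID per line); `NULL` uses every gene in `counts`.
#' @param batch_vars character vector of annotation columns to test.
#' @inheritParams detect_bias
#' @param totals_scope `"full"` or `"subset"` (see Details).
#' @param out_dir optional output directory; when given, writes
#'   `bias_table.tsv`, `refined_svgs.txt` and one PNG per batch variable and
#'   view (plot failures are logged, not fatal).
#' @param plots write diagnostic plots (only relevant with `out_dir`).
#' @return A list of class `svg_pipeline`: `dev_table`, `bias` (an
#'   `svg_bias`), `svg_ids` (the candidate list actually used), `refined`
#'   (the refined SVG ID vector), and `files` (paths written, if any).
#' @examples
#' sim <- simulate_svg_counts(sim_config(n_genes = 60, n_spots_per_batch = 30,
#'                                       n_batch_biased = 6, seed = 3))
#' res <- run_pipeline(sim$counts, sim$annotations, batch_vars = "batch")
#' length(res$refined)
#' @export
run_pipeline <- function(counts, annotations, svg_ids = NULL,
                         batch_vars, nsd_rcd_cutoff = 3, nsd_rd_cutoff = 3,
                         mode = "intersection",
                         totals_scope = c("full", "subset"),
                         out_dir = NULL, plots = TRUE) {
  totals_scope <- match.arg(totals_scope)

  if (is.character(counts) && length(counts) == 1L) {
    counts <- if (dir.exists(counts)) read_counts_10x(counts)
              else read_counts_dense(counts)
  }
  if (is.character(annotations) && length(annotations) == 1L) {
    annotations <- read_spot_annotations(annotations)
  }
  if (is.character(svg_ids) && length(svg_ids) == 1L &&
      file.exists(svg_ids)) {
    svg_ids <- read_gene_list(svg_ids)
  }
  validate_counts(counts)
  totals_full <- spot_totals(counts)

  if (is.null(svg_ids)) {
    svg_ids <- rownames(counts)
  } else {
    missing <- setdiff(svg_ids, rownames(counts))
    if (length(missing) == length(svg_ids)) {
      stop("none of the SVG IDs are present in the count matrix",
           call. = FALSE)
    }
    if (length(missing)) {
      warning(length(missing), " SVG ID(s) absent from the count matrix; ",
              "proceeding with the intersection: ",
              paste(utils::head(missing, 5L), collapse = ", "),
              call. = FALSE)
      svg_ids <- svg_ids[svg_ids %in% rownames(counts)]
    }
  }
  sub <- counts[svg_ids, , drop = FALSE]
  totals <- if (totals_scope == "full") totals_full else spot_totals(sub)

  message(sprintf("svgbias: %d candidate genes x %d spots; batch vars: %s; ",
                  nrow(sub), ncol(sub), paste(batch_vars, collapse = ", ")),
          sprintf("mode=%s, cutoffs nSD(RCD)>%g nSD(RD)>%g, totals=%s",
                  mode, nsd_rcd_cutoff, nsd_rd_cutoff, totals_scope))

  dev_table <- deviance_table(sub, annotations, batch_vars, totals = totals)
  bias <- detect_bias(dev_table, nsd_rcd_cutoff = nsd_rcd_cutoff,
                      nsd_rd_cutoff = nsd_rd_cutoff, mode = mode)
  refined <- refine_svg_list(svg_ids, bias)
  message(sprintf("svgbias: flagged %d gene(s); refined list %d -> %d",
                  length(svg_ids) - length(refined),
                  length(svg_ids), length(refined)))

  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    bt <- file.path(out_dir, "bias_table.tsv")
    write_bias_table(bias$table, bt)
    rl <- file.path(out_dir, "refined_svgs.txt")
    write_gene_list(refined, rl)
    files <- c(bias_table = bt, refined_svgs = rl)
    if (plots) {
      for (v in batch_vars) {
        for (ty in c("deviance", "rank")) {
          f <- file.path(out_dir, sprintf("scatter_%s_%s.png", ty, v))
          ok <- tryCatch({
            ggplot2::ggsave(f, plot_deviance_scatter(bias, v, ty),
                            width = 6, height = 5, dpi = 150)
            TRUE
          }, error = function(e) {
            message("svgbias: plot failed (", conditionMessage(e), ")")
            FALSE
          })
          if (ok) files[paste0("plot_", ty, "_", v)] <- f
        }
      }
    }
  }

  structure(list(dev_table = dev_table, bias = bias, svg_ids = svg_ids,
                 refined = refined, files = files),
            class = "svg_pipeline")
}

#' @export
print.svg_pipeline <- function(x, ...) {
  cat(sprintf("<svg_pipeline> %d candidate SVGs -> %d refined (%d flagged)\n",
              length(x$svg_ids), length(x$refined),
              length(x$svg_ids) - length(x$refined)))
  print(x$bias)
  invisible(x)
}
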