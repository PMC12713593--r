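#' Validate a gene x spot count matrix
#'
#' Checks that `counts` is a non-negative integer-valued matrix (base or
#' [Matrix::Matrix]) with unique, non-missing gene and spot identifiers as
#' dimnames, and returns it unchanged. All downstream functions assume a
#' matrix that passes this check.
#'
#' @param counts matrix-like, genes in rows, spots in columns, with rownames
#'   (gene IDs) and colnames (spot IDs).
#' @return `counts`, invisibly unchanged, after validation.
#' @export
validate_counts <- function(counts) {
  if (!(is.matrix(counts) || methods::is(counts, "Matrix"))) {
    stop("`counts` must be a base matrix or a Matrix object", call. = FALSE)
  }
  if (nrow(counts) < 1L || ncol(counts) < 2L) {
    stop("`counts` needs at least 1 gene (row) and 2 spots (columns)",
         call. = FALSE)
  }
  gid <- rownames(counts)
  sid <- colnames(counts)
  if (is.null(gid) || is.null(sid) || anyNA(gid) || anyNA(sid)) {
    stop("`counts` must carry gene IDs as rownames and spot IDs as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(gid)) {
    dup <- unique(gid[duplicated(gid)])
    stop("duplicate gene IDs in `counts`: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    dup <- unique(sid[duplicated(sid)])
    stop("duplicate spot IDs in `counts`: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  vals <- if (methods::is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (anyNA(vals)) stop("`counts` contains missing values", call. = FALSE)
  if (any(vals < 0)) stop("`counts` contains negative values", call. = FALSE)
  if (any(vals != round(vals))) {
    stop("`counts` contains non-integer values; UMI counts must be integers",
         call. = FALSE)
  }
  invisible(counts)
}

#' Per-spot total counts
#'
#' Column sums of the count matrix: the total UMI count at each spot, used as
#' the binomial denominator by [binomial_deviance()]. A spot with total zero
#' has no valid binomial observation and is an error (it signals an upstream
#' QC failure), with the offending spot IDs named.
#'
#' @inheritParams validate_counts
#' @return Named numeric vector of length `ncol(counts)`.
#' @examples
#' m <- matrix(c(1, 3, 2, 4), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' spot_totals(m)
#' @export
spot_totals <- function(counts) {
  validate_counts(counts)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    stop("spots with zero total counts (undefined binomial denominator): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" ... (%d in total)", length(bad)),
         call. = FALSE)
  }
  stats::setNames(as.numeric(totals), colnames(counts))
}

#' Align spot annotations to a count matrix
#'
#' Matches an annotation tibble (one row per spot, `spot_id` column) to the
#' column order of `counts`, erroring on missing spots.
#'
#' @param annotations data frame with a `spot_id` column.
#' @inheritParams validate_counts
#' @return Tibble with rows ordered as `colnames(counts)`.
#' @keywords internal
align_annotations <- function(annotations, counts) {
  annotations <- tibble::as_tibble(annotations)
  if (!"spot_id" %in% names(annotations)) {
    stop("`annotations` must contain a `spot_id` column", call. = FALSE)
  }
  if (anyDuplicated(annotations$spot_id)) {
    stop("duplicate spot IDs in `annotations`", call. = FALSE)
  }
  idx <- match(colnames(counts), annotations$spot_id)
  if (anyNA(idx)) {
    miss <- colnames(counts)[is.na(idx)]
    stop("spots missing from `annotations`: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  annotations[idx, , drop = FALSE]
}

batch_labels <- function(annotations, counts, batch_var) {
  ann <- align_annotations(annotations, counts)
  if (!batch_var %in% names(ann)) {
    stop("unknown batch variable: `", batch_var, "`", call. = FALSE)
  }
  labs <- ann[[batch_var]]
  if (anyNA(labs)) {
    stop("batch variable `", batch_var, "` has missing labels", call. = FALSE)
  }
  as.character(labs)
}
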