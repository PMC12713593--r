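#' Read a 10x-style MatrixMarket count triplet
#'
#' Reads `matrix.mtx[.gz]`, `features.tsv[.gz]` and `barcodes.tsv[.gz]` (the
#' 10x Genomics dialect: features column 1 is the feature ID, column 2 an
#' optional display symbol; barcodes have one spot ID per line, no header).
#' Gene identity is the feature ID; symbols, if present, are attached as the
#' `"symbols"` attribute of the returned matrix.
#'
#' @param dir directory containing the three files, or `NULL` when all three
#'   paths are given explicitly.
#' @param matrix,features,barcodes explicit file paths (override `dir`).
#' @return A validated sparse gene x spot count matrix.
#' @export
read_counts_10x <- function(dir = NULL, matrix = NULL, features = NULL,
                            barcodes = NULL) {
  locate <- function(given, stem) {
    if (!is.null(given)) return(given)
    for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
    stop("cannot find ", stem, "[.gz] in ", dir, call. = FALSE)
  }
  mtx_path <- locate(matrix, "matrix.mtx")
  feat_path <- locate(features, "features.tsv")
  bc_path <- locate(barcodes, "barcodes.tsv")

  m <- Matrix::readMM(mtx_path)
  feat <- utils::read.table(feat_path, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "")
  bc <- readLines(bc_path, warn = FALSE)
  bc <- bc[nzchar(bc)]
  if (nrow(feat) != nrow(m)) {
    stop(sprintf("features file has %d rows but matrix has %d rows",
                 nrow(feat), nrow(m)), call. = FALSE)
  }
  if (length(bc) != ncol(m)) {
    stop(sprintf("barcodes file has %d entries but matrix has %d columns",
                 length(bc), ncol(m)), call. = FALSE)
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(feat[[1L]], bc)
  if (ncol(feat) >= 2L) {
    attr(m, "symbols") <- stats::setNames(feat[[2L]], feat[[1L]])
  }
  validate_counts(m)
  m
}

#' Write a count matrix as a 10x-style MatrixMarket triplet
#'
#' @inheritParams validate_counts
#' @param dir output directory (created if needed).
#' @param symbols optional display symbols, one per gene (defaults to the
#'   `"symbols"` attribute or the gene IDs themselves).
#' @return `dir`, invisibly.
#' @export
write_counts_10x <- function(counts, dir, symbols = NULL) {
  validate_counts(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  symbols <- symbols %||% attr(counts, "symbols") %||% rownames(counts)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(rownames(counts), unname(symbols), "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a dense gene x spot count table
#'
#' TSV or CSV (by extension) with a header row of spot IDs and gene IDs in
#' the first column. Non-integer entries are rejected with the offending
#' gene and spot named.
#'
#' @param path file path (`.tsv`/`.txt` tab-separated, `.csv` comma).
#' @return A validated sparse gene x spot count matrix.
#' @export
read_counts_dense <- function(path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = c("character"), quote = "")
  if (ncol(df) < 3L) {
    stop("dense count table needs a gene ID column and >= 2 spot columns",
         call. = FALSE)
  }
  gid <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals),
                                 dimnames = list(gid, colnames(df)[-1L])))
  bad <- which(is.na(num) | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-integer count at gene `%s`, spot `%s` (value \"%s\")",
      gid[bad[1L, 1L]], colnames(num)[bad[1L, 2L]],
      vals[bad[1L, 1L], bad[1L, 2L]]), call. = FALSE)
  }
  m <- methods::as(Matrix::Matrix(num, sparse = TRUE), "CsparseMatrix")
  validate_counts(m)
  m
}

#' Write a dense gene x spot count table (TSV)
#'
#' @inheritParams validate_counts
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_dense <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts),
                   as.matrix(counts), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a plain-text gene list (one ID per line, no header)
#'
#' @param path file path.
#' @return Character vector of gene IDs.
#' @export
read_gene_list <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) {
    warning("duplicate IDs in gene list; keeping first occurrences",
            call. = FALSE)
    ids <- ids[!duplicated(ids)]
  }
  ids
}

#' @rdname read_gene_list
#' @param ids character vector of gene IDs.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Read a per-spot annotation table
#'
#' TSV with a header; must contain a `spot_id` column. Remaining columns are
#' batch variables and (optionally) `x`/`y` coordinates.
#'
#' @param path file path.
#' @return Tibble of annotations.
#' @export
read_spot_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"spot_id" %in% names(ann)) {
    stop("annotation table must contain a `spot_id` column", call. = FALSE)
  }
  ann
}

#' @rdname read_spot_annotations
#' @param annotations tibble with a `spot_id` column.
#' @export
write_spot_annotations <- function(annotations, path) {
  readr::write_tsv(tibble::as_tibble(annotations), path, progress = FALSE)
  invisible(path)
}

# Format a bias table for disk: floats at 6 significant digits, logical as
# true/false literals.
format_bias_table <- function(table) {
  dplyr::mutate(
    table,
    dplyr::across(dplyr::where(is.double),
                  ~ formatC(.x, digits = 6L, format = "g")),
    dplyr::across(dplyr::where(is.logical), ~ ifelse(.x, "true", "false"))
  )
}

#' Write / read a per-gene bias table (TSV)
#'
#' Columns: `gene_id`, `batch_var`, `d_default`, `d_batch`, `r_default`,
#' `r_batch`, `rcd`, `rd`, `nsd_rcd`, `nsd_rd`, `flagged`. Floats are written
#' at 6 significant digits; `flagged` as `true`/`false`.
#'
#' @param table the `table` element of an `svg_bias` object (or [tidy()] of
#'   one).
#' @param path file path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_bias_table <- function(table, path) {
  readr::write_tsv(format_bias_table(tibble::as_tibble(table)), path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_bias_table
#' @export
read_bias_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           gene_id = "c", batch_var = "c"))
  if ("flagged" %in% names(tbl) && is.character(tbl$flagged)) {
    tbl$flagged <- tbl$flagged == "true"
  }
  for (col in c("r_default", "r_batch", "rd")) {
    if (col %in% names(tbl)) tbl[[col]] <- as.integer(tbl[[col]])
  }
  tbl
}
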