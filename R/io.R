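# Delimited-text readers and writers for every pipeline object, plus a
# compact binary container for the GRM. All tabular formats are
# tab-separated with a header row.

#' Read / write genotype tables
#'
#' Tab-separated, accessions as rows: an `accession` column, an optional
#' `group` column (subpopulation labels), then one column per marker with
#' dosages 0/1/2 and `NA` for missing.
#'
#' @param path file path.
#' @rdname genotype_io
#' @return `read_genotypes` returns a [new_genotypes()] object.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"accession" %in% names(df)) stop_genpred("missing 'accession' column")
  groups <- if ("group" %in% names(df)) df$group else NULL
  mk <- setdiff(names(df), c("accession", "group"))
  new_genotypes(as.matrix(df[, mk, drop = FALSE]),
                accession_ids = df$accession, marker_ids = mk,
                group_labels = groups)
}

#' @param geno a [new_genotypes()] object.
#' @rdname genotype_io
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "genotypes"))
  df <- data.frame(accession = geno$accession_ids, stringsAsFactors = FALSE)
  if (!is.null(geno$group_labels)) df$group <- geno$group_labels
  df <- cbind(df, as.data.frame(geno$dosage, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write long-format trait tables
#'
#' Tab-separated with columns `accession`, `environment`, `value`.
#'
#' @param path file path.
#' @rdname trait_io
#' @export
read_trait <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "environment", "value")
  if (!all(need %in% names(df)))
    stop_genpred("trait table must have columns %s", paste(need, collapse = ", "))
  df$accession <- as.character(df$accession)
  df$environment <- as.character(df$environment)
  df[, need]
}

#' @param trait trait data.frame.
#' @rdname trait_io
#' @export
write_trait <- function(trait, path) {
  utils::write.table(trait[, c("accession", "environment", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write field-trial layouts
#'
#' Tab-separated with columns `row`, `col`, `entry`, `is_check`, `value`
#' (1-based grid coordinates).
#'
#' @param path file path.
#' @param environment environment label to attach (reading only).
#' @rdname trial_io
#' @export
read_trial <- function(path, environment = "OPT") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("row", "col", "entry", "is_check", "value")
  if (!all(need %in% names(df)))
    stop_genpred("trial table must have columns %s", paste(need, collapse = ", "))
  df$is_check <- as.logical(df$is_check)
  attr(df, "environment") <- environment
  class(df) <- c("field_trial", "data.frame")
  df
}

#' @param trial field-trial data.frame.
#' @rdname trial_io
#' @export
write_trial <- function(trial, path) {
  utils::write.table(as.data.frame(trial)[, c("row", "col", "entry", "is_check", "value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the genomic relationship matrix
#'
#' Text format: tab-separated square matrix with an `id` column and one
#' column per accession. Binary format (`format = "bin"`): magic bytes
#' "GRMB1", the dimension as a 4-byte integer, the newline-joined accession
#' identifiers, then `n^2` doubles (column-major) followed by the per-marker
#' frequencies' length and values. Both round-trip losslessly.
#'
#' @param path file path.
#' @param format `"tsv"` or `"bin"`.
#' @rdname grm_io
#' @export
read_grm <- function(path, format = c("tsv", "bin")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df$id)
    M <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
    dimnames(M) <- list(ids, ids)
    return(structure(list(matrix = M, accession_ids = ids,
                          freqs = attr(df, "freqs"), n_markers_used = NA_integer_),
                     class = "grm"))
  }
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, 5, useBytes = TRUE)
  if (!identical(magic, "GRMB1")) stop_genpred("not a GRMB1 container")
  n <- readBin(con, "integer", 1)
  id_len <- readBin(con, "integer", 1)
  ids <- strsplit(readChar(con, id_len, useBytes = TRUE), "\n", fixed = TRUE)[[1]]
  M <- matrix(readBin(con, "double", n * n), n, n, dimnames = list(ids, ids))
  nf <- readBin(con, "integer", 1)
  freqs <- if (nf > 0) readBin(con, "double", nf) else NULL
  nm <- readBin(con, "integer", 1)
  structure(list(matrix = M, accession_ids = ids, freqs = freqs,
                 n_markers_used = nm), class = "grm")
}

#' @param grm a [compute_grm()] object.
#' @rdname grm_io
#' @export
write_grm <- function(grm, path, format = c("tsv", "bin")) {
  format <- match.arg(format)
  stopifnot(inherits(grm, "grm"))
  if (format == "tsv") {
    df <- data.frame(id = grm$accession_ids, grm$matrix, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c("id", grm$accession_ids)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("GRMB1", con, eos = NULL, useBytes = TRUE)
  n <- nrow(grm$matrix)
  writeBin(as.integer(n), con)
  ids <- paste(grm$accession_ids, collapse = "\n")
  writeBin(as.integer(nchar(ids, type = "bytes")), con)
  writeChar(ids, con, eos = NULL, useBytes = TRUE)
  writeBin(as.vector(grm$matrix), con)
  writeBin(as.integer(length(grm$freqs %||% numeric(0))), con)
  if (length(grm$freqs)) writeBin(as.numeric(grm$freqs), con)
  writeBin(as.integer(grm$n_markers_used %||% NA_integer_), con)
  invisible(path)
}
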