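#' Read a fluorescence transient from a two-column TSV
#'
#' Expected dialect: header `time_s<TAB>fluorescence`, UTF-8, '.' decimal.
#' Times must be strictly increasing; fluorescence finite and positive.
#'
#' @param path TSV path.
#' @param label Trace label; defaults to the file stem.
#' @return A `FluorescenceTransient`.
#' @export
read_transient <- function(path, label = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "fluorescence") %in% names(df)))
    .stopf("%s: expected columns time_s and fluorescence", path)
  if (anyNA(df$time_s) || anyNA(df$fluorescence))
    .stopf("%s: non-numeric values in transient table", path)
  new_transient(df$time_s, df$fluorescence,
                label = label %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a fluorescence transient as a two-column TSV
#' @param transient A `FluorescenceTransient`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transient <- function(transient, path) {
  write_tsv(data.frame(time_s = transient$time,
                       fluorescence = transient$fluorescence), path)
}

#' Read promoter sequences from FASTA
#'
#' Record ids are taken as target gene ids; lowercase bases are uppercased
#' on read (attribute `had_lowercase` records whether any were present).
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet], names = record ids.
#' @export
read_promoters <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  chr <- as.character(raw)
  had_lower <- any(grepl("[acgtn]", chr))
  out <- Biostrings::DNAStringSet(toupper(chr))
  names(out) <- sub("\\s.*$", "", names(raw))
  attr(out, "had_lowercase") <- had_lower
  out
}

#' Write sequences as FASTA wrapped at 60 columns
#' @param sequences Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  nms <- names(sequences)
  out <- Biostrings::DNAStringSet(as.character(sequences))
  names(out) <- nms
  Biostrings::writeXStringSet(out, path, width = 60L)
  invisible(path)
}

#' Read a counts (or intensity) matrix with its design table
#'
#' @param counts_path TSV with gene ids in the first column and one column
#'   per sample.
#' @param design_path Two-column TSV `sample<TAB>group`.
#' @param mode `"rnaseq"` or `"microarray"`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(counts_path, design_path,
                            mode = c("rnaseq", "microarray")) {
  mode <- match.arg(mode)
  df <- read.delim(counts_path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  des <- read.delim(design_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(des)))
    .stopf("%s: expected columns sample and group", design_path)
  expression_matrix(mat, setNames(des$group, des$sample), mode = mode)
}

#' Write a data frame as TSV (UTF-8, '.' decimal, no quoting)
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a two-column annotation table (gene to term / pathway / TF)
#' @param path TSV path with a header of exactly two columns.
#' @param col_names Names to assign to the two columns.
#' @return Data frame with the requested column names.
#' @export
read_annotation <- function(path, col_names = c("gene", "term")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) .stopf("%s: expected two columns", path)
  df <- df[, 1:2]
  names(df) <- col_names
  df
}
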