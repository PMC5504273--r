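#' Read a tabular read-alignment table
#'
#' Reads the simple 4-column TSV alignment dialect (`read_id`, `genome_id`,
#' `sample_id`, optional `n_alignments`), one row per (read, candidate
#' genome) alignment. Ambiguity is defined by multiplicity, so the
#' `n_alignments` column, when present, is validated against the actual row
#' counts.
#'
#' @param path Path to a TSV file with a header row.
#' @return Data frame suitable for [assign_reads()].
#' @export
read_alignment_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  req <- c("read_id", "genome_id", "sample_id")
  if (!all(req %in% names(df)))
    stop("alignment table needs columns: ", paste(req, collapse = ", "))
  if ("n_alignments" %in% names(df)) {
    n <- stats::ave(seq_len(nrow(df)),
                    df$sample_id, df$read_id, FUN = length)
    if (any(n != df$n_alignments))
      warning("`n_alignments` column disagrees with row multiplicity; ",
              "multiplicity is authoritative")
  }
  df[req]
}

#' Read alignments from a SAM/BAM file
#'
#' Extracts (read, genome) alignment pairs from a SAM or BAM file; a read
#' aligned to several reference sequences (identical query name on several
#' records) is thereby ambiguous. Requires the Rsamtools package; SAM input
#' is converted to BAM on the fly.
#'
#' @param path Path to a SAM or BAM file.
#' @param sample_id Sample label to attach to every read.
#' @return Data frame `read_id`, `genome_id`, `sample_id` (unique rows,
#'   unmapped records dropped).
#' @export
read_sam_alignments <- function(path, sample_id) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading SAM/BAM requires the Rsamtools package")
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  rec <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = c("qname", "rname")))[[1L]]
  keep <- !is.na(rec$rname)
  unique(data.frame(read_id = rec$qname[keep],
                    genome_id = as.character(rec$rname[keep]),
                    sample_id = sample_id, stringsAsFactors = FALSE))
}

#' Read and write abundance matrices as TSV
#'
#' The on-disk form is a TSV with a `genome_id` first column and one column
#' per sample.
#'
#' @param path File path.
#' @param matrix An [abundance_matrix()] (for writing).
#' @param mode Abundance mode to stamp on a matrix being read.
#' @return `read_abundance_matrix()` returns an [abundance_matrix()];
#'   `write_abundance_matrix()` returns `path` invisibly.
#' @export
read_abundance_matrix <- function(path, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  abundance_matrix(m, mode = mode)
}

#' @rdname read_abundance_matrix
#' @export
write_abundance_matrix <- function(matrix, path) {
  df <- data.frame(genome_id = rownames(matrix), unclass(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tabular alignment hit table (BLAST outfmt-6 dialect)
#'
#' Reads the standard 12-column tabular alignment format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bitscore), headerless, with
#' optional extra columns appended after the standard twelve (for example a
#' coverage column).
#'
#' @param path File path.
#' @param extra_columns Names for columns beyond the standard 12 (for
#'   example `"subject_coverage"`).
#' @return Data frame with the package's column names (`query_id`,
#'   `subject_id`, `percent_identity`, `alignment_length`, `mismatches`,
#'   `gaps`, `q_start`, `q_end`, `s_start`, `s_end`, `e_value`,
#'   `bitscore`, ...).
#' @export
read_blast_table <- function(path, extra_columns = character(0)) {
  cols <- c("query_id", "subject_id", "percent_identity",
            "alignment_length", "mismatches", "gaps", "q_start", "q_end",
            "s_start", "s_end", "e_value", "bitscore", extra_columns)
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 12L)
    stop("expected at least 12 tab-separated columns, found ", ncol(df))
  if (ncol(df) != length(cols))
    stop("file has ", ncol(df), " columns but ", length(cols),
         " names were supplied")
  names(df) <- cols
  df
}

#' Read a host taxonomy table
#'
#' TSV with a header: `genome_id` plus any contiguous prefix of the rank
#' columns ([taxonomic_ranks()]). Empty strings are read as missing.
#'
#' @param path File path.
#' @return Validated host taxonomy data frame.
#' @export
read_host_taxonomy <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_host_table(df)
}

#' Write a correlation network
#'
#' Writes both long form (`genome_a`, `genome_b`, `rho`; upper triangle
#' only) and, optionally, the square matrix as TSV.
#'
#' @param network A `"sparcc_network"`.
#' @param path Output TSV path for the long form.
#' @param matrix_path Optional output path for the square matrix.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, matrix_path = NULL) {
  rho <- network$rho
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  long <- data.frame(genome_a = rownames(rho)[idx[, 1L]],
                     genome_b = colnames(rho)[idx[, 2L]],
                     rho = rho[idx], stringsAsFactors = FALSE)
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(matrix_path)) {
    df <- data.frame(genome_id = rownames(rho), rho, check.names = FALSE)
    write.table(df, matrix_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a square correlation matrix written by [write_network()]
#'
#' @param path TSV path of the square matrix (first column `genome_id`).
#' @return A `"sparcc_network"`-shaped list (`rho`, `genome_ids`).
#' @export
read_network_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  rho <- as.matrix(df[, -1L, drop = FALSE])
  rownames(rho) <- df[[1L]]
  structure(list(rho = rho, genome_ids = rownames(rho)),
            class = "sparcc_network")
}
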