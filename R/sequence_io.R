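#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases the input and maps T to U, so DNA-style input (e.g. cDNA
#' sequences) becomes RNA. Any character outside `{A, U, G, C}` after that
#' mapping is an error: the one-hot encoding is defined over exactly four
#' bases, so ambiguity codes (N, R, Y, ...) and gaps are rejected rather than
#' silently encoded.
#'
#' @param raw non-empty character scalar.
#' @return a string over `{A, U, G, C}`.
#' @examples
#' normalize_sequence("acgt")  # "ACGU"
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  s <- chartr("t", "u", toupper(raw))
  s <- chartr("T", "U", s)
  bad <- regexpr("[^AUGC]", s)
  if (bad > 0L) {
    stop(errorCondition(
      sprintf("invalid base '%s' at position %d (alphabet is A, U, G, C)",
              substr(s, bad, bad), bad),
      class = c("mircnn_alphabet_error", "error", "condition")
    ))
  }
  s
}

#' Read sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file and returns one record per
#' header. Record ids are the first whitespace-delimited token of the header;
#' sequences are normalized to RNA via [normalize_sequence()]. An empty file
#' yields a zero-row frame.
#'
#' @param path path to a FASTA file.
#' @return a `data.frame` with columns `id` and `seq`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(errorCondition(
      sprintf("malformed FASTA: line %d does not start a '>' header",
              nonblank[1]),
      class = c("mircnn_parse_error", "error", "condition")
    ))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- vapply(as.character(set), normalize_sequence, character(1),
                 USE.NAMES = FALSE)
  data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records `data.frame` with columns `id` and `seq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(stats::setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Validate a chimera dataset table
#'
#' A dataset table has one 110-nt chimera sequence and a binary label per
#' row. Rows violating either constraint are reported by index.
#'
#' @param table `data.frame` with columns `chimera_seq` and `label`.
#' @return `table`, invisibly, with `label` coerced to integer.
#' @export
validate_dataset_table <- function(table) {
  if (!is.data.frame(table) ||
      !all(c("chimera_seq", "label") %in% names(table))) {
    stop("dataset table needs columns 'chimera_seq' and 'label'",
         call. = FALSE)
  }
  table$chimera_seq <- as.character(table$chimera_seq)
  table$label <- suppressWarnings(as.integer(table$label))
  bad_len <- which(nchar(table$chimera_seq) != CHIMERA_LENGTH)
  bad_lab <- which(is.na(table$label) | !(table$label %in% c(0L, 1L)))
  bad_alpha <- which(grepl("[^AUGC]", table$chimera_seq))
  bad <- sort(unique(c(bad_len, bad_lab, bad_alpha)))
  if (length(bad)) {
    stop(errorCondition(
      sprintf(
        "invalid dataset rows (need %d-nt AUGC sequence, label 0/1): %s",
        CHIMERA_LENGTH,
        paste(utils::head(bad, 10L), collapse = ", ")),
      class = c("mircnn_validation_error", "error", "condition")
    ))
  }
  invisible(table)
}

#' Read a chimera dataset table (TSV)
#'
#' The canonical on-disk format is tab-separated text with columns
#' `chimera_seq` (110-nt RNA string) and `label` (0 or 1). Every row is
#' validated on read.
#'
#' @param path path to a TSV file.
#' @return validated `data.frame` with columns `chimera_seq`, `label`.
#' @seealso [write_dataset_table()]
#' @export
read_dataset_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chimera_seq = "character"))
  validate_dataset_table(tab)
  tab$label <- as.integer(tab$label)
  tab[, c("chimera_seq", "label")]
}

#' Write a chimera dataset table (TSV)
#'
#' @param table validated dataset table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset_table <- function(table, path) {
  validate_dataset_table(table)
  utils::write.table(table[, c("chimera_seq", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse complement of an RNA string
#'
#' @param seq RNA string over `{A, U, G, C}`.
#' @return the reverse complement (A-U, G-C).
#' @export
revcomp_rna <- function(seq) {
  s <- chartr("AUGC", "UACG", seq)
  vapply(s, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
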