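## Sequence and table I/O. All sequences are normalized to the DNA alphabet
## internally (U -> T, upper case); writers can re-emit RNA.

DNA_OK <- "ACGTN"

#' Normalize nucleotide sequences to the internal DNA alphabet
#'
#' Upper-cases and converts U to T. Fails on symbols outside `A,C,G,T,U,N`.
#'
#' @param x character vector of sequences.
#' @return character vector over `{A,C,G,T,N}`.
#' @export
norm_dna <- function(x) {
  x <- chartr("u", "U", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  bad <- grepl(sprintf("[^%s]", DNA_OK), x)
  if (any(bad)) {
    stop("unknown nucleotide symbols in record(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  x
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences (T-normalized).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  # plain base implementation: called per window in the seed scanner and
  # folding paths, where Biostrings object overhead dominates
  out <- vapply(chartr("ACGTUNacgtun", "TGCANNTGCANN", x),
                function(s) intToUtf8(rev(utf8ToInt(s))),
                character(1), USE.NAMES = FALSE)
  stats::setNames(out, names(x))
}

#' Convert internal DNA representation to RNA (T -> U)
#' @param x character vector.
#' @return character vector over the RNA alphabet.
#' @export
to_rna <- function(x) chartr("T", "U", toupper(x))

#' Read a FASTA file into a named character vector
#'
#' @param path file path.
#' @param normalize normalize to the internal DNA alphabet (default TRUE).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, normalize = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  out <- as.character(ss)
  # keep only the first whitespace-delimited token of the header, miRBase-style
  names(out) <- sub("\\s.*$", "", names(ss))
  if (normalize) out <- stats::setNames(norm_dna(out), names(out))
  out
}

#' Write a named character vector as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param rna emit RNA alphabet (U instead of T).
#' @export
write_fasta <- function(seqs, path, rna = FALSE) {
  if (rna) seqs <- to_rna(seqs)
  out <- character(2L * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  out[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path file path.
#' @return list with `id` (character), `seq` (character, T-normalized) and
#'   `qual` (list of integer Phred vectors).
#' @export
read_fastq <- function(path) {
  qs <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path,
      quality.scoring = "phred")),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  sw <- Biostrings::width(qs)
  qw <- Biostrings::width(Biostrings::quality(qs))
  if (any(sw != qw)) {
    stop("malformed FASTQ record ", which(sw != qw)[1L],
         ": sequence/quality length mismatch")
  }
  list(id   = unname(sub("\\s.*$", "", names(qs))),
       seq  = unname(as.character(qs)),
       qual = unname(as.list(methods::as(Biostrings::quality(qs),
                                         "IntegerList"))))
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param id,seq,qual read identifiers, sequences and quality strings
#'   (character vectors of equal length; `qual` already ASCII-encoded).
#' @param path output path.
#' @export
write_fastq <- function(id, seq, qual, path) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  out <- character(4L * length(id))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", id)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- seq
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Read / write tab-separated tables with headers
#'
#' Thin wrappers fixing the conventions used by every pipeline stage
#' (header, no quoting, no row names).
#'
#' @param path file path.
#' @return `read_tsv`: a data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv
#' @param df data.frame to write.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
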