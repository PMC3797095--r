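## Read cleaning, tag collapsing and length distributions.
##
## Cleaning applies the filters in a fixed order so that every read is
## discarded for exactly one reason:
##   contains_N -> low_quality -> adapter5_pollution -> no_adapter3
##   -> no_insert -> polyA -> too_short -> too_long

CLEAN_REASONS <- c("contains_N", "low_quality", "adapter5_pollution",
                   "no_adapter3", "no_insert", "polyA",
                   "too_short", "too_long")

#' Default read-cleaning parameters
#'
#' "Poor quality" and "poly(A) stretch" are operationalized as: more than
#' `max_lowq_frac` of bases below Phred `min_phred`, and an insert that is at
#' least `polya_frac` adenosine or contains a run of `polya_run` consecutive
#' A's. Adapters are located by the leftmost exact match of their first
#' `adapter_key` bases.
#'
#' @param min_len,max_len insert length window in nt (gel selection window).
#' @param min_phred,max_lowq_frac quality filter thresholds.
#' @param polya_frac,polya_run poly(A) artifact thresholds.
#' @param adapter_key number of adapter bases used as exact-match key.
#' @return a list of cleaning parameters.
#' @export
clean_params <- function(min_len = 18L, max_len = 30L,
                         min_phred = 20L, max_lowq_frac = 0.10,
                         polya_frac = 0.80, polya_run = 10L,
                         adapter_key = 8L) {
  stopifnot(min_len >= 1L, max_len >= min_len, adapter_key >= 1L,
            polya_frac > 0, polya_frac <= 1, polya_run >= 1L)
  list(min_len = as.integer(min_len), max_len = as.integer(max_len),
       min_phred = as.integer(min_phred), max_lowq_frac = max_lowq_frac,
       polya_frac = polya_frac, polya_run = as.integer(polya_run),
       adapter_key = as.integer(adapter_key))
}

#' Clean raw small-RNA reads
#'
#' Removes poor-quality reads, 5' adapter pollution, reads without a 3'
#' adapter, reads without an insert, poly(A) artifacts, and inserts outside
#' the length window; the surviving 3'-adapter-trimmed inserts are returned.
#'
#' Pass `adapter3 = ""` for input that is already adapter-trimmed (the
#' adapter-related filters are then skipped and the read itself is the
#' insert); cleaning clean inserts this way is a no-op.
#'
#' @param seqs character vector of read sequences (may contain U; normalized
#'   internally).
#' @param quals optional list of integer Phred vectors, parallel to `seqs`
#'   (omit for FASTA input; the quality filter is then skipped).
#' @param adapter3 3' adapter sequence ("" to skip adapter trimming).
#' @param adapter5 5' adapter sequence ("" to skip the pollution filter).
#' @param params parameters from [clean_params()].
#' @return list with `inserts` (character vector of clean insert sequences)
#'   and `stats` (list: `input_reads`, `removed_by_reason` named integer
#'   vector, `clean_reads`).
#' @export
clean_reads <- function(seqs, quals = NULL, adapter3 = "", adapter5 = "",
                        params = clean_params()) {
  n <- length(seqs)
  stats_zero <- stats::setNames(integer(length(CLEAN_REASONS)), CLEAN_REASONS)
  if (n == 0L) {
    return(list(inserts = character(0),
                stats = list(input_reads = 0L,
                             removed_by_reason = stats_zero,
                             clean_reads = 0L)))
  }
  if (!is.null(quals)) {
    if (length(quals) != n) stop("quals must be parallel to seqs")
    ql <- lengths(quals)
    sl <- nchar(seqs)
    if (any(ql != sl)) {
      stop("malformed FASTQ record ", which(ql != sl)[1L],
           ": sequence/quality length mismatch")
    }
  }
  seqs <- norm_dna(seqs)
  adapter3 <- if (nzchar(adapter3)) norm_dna(adapter3) else ""
  adapter5 <- if (nzchar(adapter5)) norm_dna(adapter5) else ""

  reason <- rep(NA_character_, n)
  insert <- seqs

  ## 1. quality: N content, then Phred
  has_n <- grepl("N", seqs, fixed = TRUE)
  reason[has_n] <- "contains_N"
  if (!is.null(quals)) {
    lowq <- vapply(quals, function(q) mean(q < params$min_phred), numeric(1))
    sel <- is.na(reason) & lowq > params$max_lowq_frac
    reason[sel] <- "low_quality"
  }

  ## 2. 5' adapter pollution (adapter key anywhere in the read)
  if (nzchar(adapter5)) {
    key5 <- substr(adapter5, 1L, min(params$adapter_key, nchar(adapter5)))
    sel <- is.na(reason) & grepl(key5, seqs, fixed = TRUE)
    reason[sel] <- "adapter5_pollution"
  }

  ## 3. locate and trim the 3' adapter (leftmost exact key match)
  if (nzchar(adapter3)) {
    key3 <- substr(adapter3, 1L, min(params$adapter_key, nchar(adapter3)))
    pos <- regexpr(key3, seqs, fixed = TRUE)
    sel <- is.na(reason) & pos < 0L
    reason[sel] <- "no_adapter3"
    trim <- is.na(reason) & pos > 0L
    insert[trim] <- substr(seqs[trim], 1L, pos[trim] - 1L)
    sel <- is.na(reason) & pos == 1L
    reason[sel] <- "no_insert"
  }

  ## 4. poly(A) artifacts
  live <- is.na(reason)
  if (any(live)) {
    len <- nchar(insert)
    a_frac <- ifelse(len > 0L,
                     nchar(gsub("[^A]", "", insert)) / pmax(len, 1L), 0)
    run <- grepl(strrep("A", params$polya_run), insert, fixed = TRUE)
    sel <- live & len > 0L & (a_frac >= params$polya_frac | run)
    reason[sel] <- "polyA"
  }

  ## 5. length window
  len <- nchar(insert)
  reason[is.na(reason) & len < params$min_len] <- "too_short"
  reason[is.na(reason) & len > params$max_len] <- "too_long"

  keep <- is.na(reason)
  removed <- table(factor(reason[!keep], levels = CLEAN_REASONS))
  removed <- stats::setNames(as.integer(removed), CLEAN_REASONS)
  stopifnot(sum(keep) + sum(removed) == n)
  list(inserts = insert[keep],
       stats = list(input_reads = n,
                    removed_by_reason = removed,
                    clean_reads = sum(keep)))
}

#' Collapse clean inserts from the two libraries into unique tags
#'
#' @param inserts_na,inserts_da character vectors of clean insert sequences
#'   from the NA (non-aestivation) and DA (deep-aestivation) libraries.
#' @return data.frame with columns `sequence`, `count_na` (x), `count_da`
#'   (y), sorted by total count descending, ties lexicographic.
#' @export
collapse_unique <- function(inserts_na, inserts_da = character(0)) {
  seqs <- union(inserts_na, inserts_da)
  if (length(seqs) == 0L) {
    return(data.frame(sequence = character(0), count_na = integer(0),
                      count_da = integer(0), stringsAsFactors = FALSE))
  }
  cnt <- function(v) {
    t <- table(factor(v, levels = seqs))
    as.integer(t)
  }
  out <- data.frame(sequence = seqs, count_na = cnt(inserts_na),
                    count_da = cnt(inserts_da), stringsAsFactors = FALSE)
  ord <- order(-(out$count_na + out$count_da), out$sequence)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand counted tags back into individual reads
#'
#' Inverse of [collapse_unique()] for one library; useful for round-trip
#' checks and resampling.
#'
#' @param tags data.frame from [collapse_unique()].
#' @param library `"na"` or `"da"`.
#' @return character vector of reads.
#' @export
expand_tags <- function(tags, library = c("na", "da")) {
  library <- match.arg(library)
  cnt <- if (library == "na") tags$count_na else tags$count_da
  rep(tags$sequence, cnt)
}

#' Read-length distribution of a library
#'
#' Percentages are computed on read counts (not unique tags).
#'
#' @param tags data.frame from [collapse_unique()].
#' @param library `"na"` or `"da"`.
#' @return named numeric vector mapping length (nt) to percentage of reads;
#'   sums to 100.
#' @export
length_distribution <- function(tags, library = c("na", "da")) {
  library <- match.arg(library)
  cnt <- if (library == "na") tags$count_na else tags$count_da
  total <- sum(cnt)
  if (total == 0L) stop("no reads in library '", library, "'")
  len <- nchar(tags$sequence)
  reads <- tapply(cnt, len, sum)
  pct <- 100 * reads / total
  stats::setNames(as.numeric(pct), names(reads))
}
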