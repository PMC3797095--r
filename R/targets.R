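## TargetScan-style seed-site prediction. The seed is miRNA positions 2-8;
## a site is an 8-nt 3'UTR window classified (in order of precedence) as
##   8mer:    window[1..7] = revcomp(seed) and window[8] = A
##   7mer-m8: window[1..7] = revcomp(seed)
##   7mer-1a: window[2..7] = revcomp(positions 2-7) and window[8] = A
## The target-position-1 A is required as a literal A in the UTR, not as a
## pairing partner for miRNA position 1.

#' Seed region of a mature miRNA (positions 2-8)
#'
#' @param sequence mature miRNA sequence, length >= 8 (RNA or DNA alphabet).
#' @return the 7-nt seed in the internal DNA alphabet.
#' @export
seed_of <- function(sequence) {
  sequence <- norm_dna(sequence)
  if (any(nchar(sequence) < 8L)) stop("mature miRNA must be at least 8 nt")
  substr(sequence, 2L, 8L)
}

#' Classify one 8-nt UTR window against a miRNA seed
#'
#' @param mirna mature miRNA sequence (length >= 8).
#' @param window 8-nt UTR window, 5' to 3'.
#' @return `"8mer"`, `"7mer-m8"`, `"7mer-1a"`, or `NA` for no site.
#' @export
classify_site <- function(mirna, window) {
  window <- norm_dna(window)
  if (nchar(window) != 8L) stop("window must be 8 nt")
  m <- norm_dna(mirna)
  rc7 <- revcomp(substr(m, 2L, 8L))
  rc6 <- revcomp(substr(m, 2L, 7L))
  w7 <- substr(window, 1L, 7L)
  w8 <- substr(window, 8L, 8L)
  w26 <- substr(window, 2L, 7L)
  if (w7 == rc7 && w8 == "A") return("8mer")
  if (w7 == rc7) return("7mer-m8")
  if (w26 == rc6 && w8 == "A") return("7mer-1a")
  NA_character_
}

#' Scan 3'UTRs for seed sites
#'
#' Every window position of every UTR is tested; overlapping windows are
#' reported independently, each at its strongest class. Site coordinates
#' are 1-based inclusive on the UTR: 8 nt for an 8mer (window positions
#' 1-8), 7 nt for a 7mer-m8 (1-7) and for a 7mer-1a (2-8).
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param utrs named character vector of 3'UTR sequences (5' to 3').
#' @return data.frame with columns `mirna`, `utr`, `start`, `end`,
#'   `type`, sorted by (utr, start, mirna).
#' @export
scan_utr <- function(mirnas, utrs) {
  mirnas <- stats::setNames(norm_dna(mirnas), names(mirnas))
  utrs <- stats::setNames(norm_dna(utrs), names(utrs))
  out <- list()
  for (mid in names(mirnas)) {
    m <- mirnas[[mid]]
    rc7 <- revcomp(substr(m, 2L, 8L))
    rc6 <- revcomp(substr(m, 2L, 7L))
    for (uid in names(utrs)) {
      u <- utrs[[uid]]
      L <- nchar(u)
      if (L < 8L) next
      s <- seq_len(L - 7L)
      w7 <- substring(u, s, s + 6L)
      w8 <- substring(u, s + 7L, s + 7L)
      w26 <- substring(u, s + 1L, s + 6L)
      type <- rep(NA_character_, length(s))
      type[w26 == rc6 & w8 == "A"] <- "7mer-1a"
      type[w7 == rc7] <- "7mer-m8"
      type[w7 == rc7 & w8 == "A"] <- "8mer"
      hit <- which(!is.na(type))
      if (!length(hit)) next
      start <- ifelse(type[hit] == "7mer-1a", s[hit] + 1L, s[hit])
      end <- ifelse(type[hit] == "7mer-m8", s[hit] + 6L, s[hit] + 7L)
      out[[length(out) + 1L]] <- data.frame(
        mirna = mid, utr = uid, start = start, end = end,
        type = type[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(mirna = character(0), utr = character(0),
                      start = integer(0), end = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$utr, res$start, res$mirna), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predicted target genes per miRNA
#'
#' A gene is a predicted target iff it carries at least one site of any
#' class.
#'
#' @param sites data.frame from [scan_utr()].
#' @return named list mapping miRNA id to a character vector of UTR ids.
#' @export
predicted_targets <- function(sites) {
  if (nrow(sites) == 0L) return(stats::setNames(list(), character(0)))
  lapply(split(sites$utr, sites$mirna), function(u) sort(unique(u)))
}
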