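## Novel miRNA discovery: genomic anchoring of unannotated tags, single
## stem-loop folding under a self-contained nearest-neighbor-style energy
## model, and the three-criterion hairpin call (genomic match; mature
## entirely on one arm; minimum free energy at or below the threshold),
## plus read support.

#' Hairpin folding energy model
#'
#' A deliberately small, fully documented model: Watson-Crick and wobble
#' pairs only, a stacking energy for each pair of adjacent base pairs equal
#' to minus the mean of the two pair strengths, and a logarithmic loop
#' penalty `loop_a + loop_b * ln(L/4)` (floored at 0) for internal loops,
#' bulges and the terminal loop. With the defaults a GC/GC stack scores
#' -3.3, AU/AU -1.1 and GU/GU -0.5 kcal/mol.
#'
#' @param gc,au,gu pair strengths (kcal/mol, positive).
#' @param loop_a,loop_b loop penalty coefficients.
#' @param min_loop minimum terminal loop size (nt, >= 3).
#' @param max_bulge maximum total unpaired bases in one internal loop or
#'   bulge; pre-miRNA stems carry only small bulges, hence a tight default.
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(gc = 3.3, au = 1.1, gu = 0.5,
                         loop_a = 4.0, loop_b = 1.75,
                         min_loop = 3L, max_bulge = 12L) {
  stopifnot(gc > 0, au > 0, gu > 0, loop_a >= 0, min_loop >= 3L,
            max_bulge >= 0L)
  structure(list(gc = gc, au = au, gu = gu, loop_a = loop_a,
                 loop_b = loop_b, min_loop = as.integer(min_loop),
                 max_bulge = as.integer(max_bulge)),
            class = "energy_model")
}

#' Fold a sequence into its minimum-energy single stem-loop
#'
#' @param sequence nucleotide sequence (DNA or RNA alphabet).
#' @param model an [energy_model()].
#' @return list with `mfe` (kcal/mol, <= 0; 0 means unpaired) and
#'   `structure` (dot-bracket string with exactly one terminal loop).
#' @export
fold_hairpin <- function(sequence, model = energy_model()) {
  sequence <- norm_dna(sequence)
  stopifnot(length(sequence) == 1L)
  fold_hairpin_cpp(sequence, model$gc, model$au, model$gu,
                   model$loop_a, model$loop_b, model$min_loop,
                   model$max_bulge)
}

loop_penalty <- function(L, model) {
  pmax(0, model$loop_a + model$loop_b * log(L / 4))
}

pair_strength_r <- function(a, b, model) {
  key <- paste0(pmin(a, b), pmax(a, b))
  strengths <- c(CG = model$gc, AT = model$au, GT = model$gu)
  out <- strengths[key]
  out[is.na(out)] <- 0
  unname(out)
}

#' Re-score a dot-bracket structure under an energy model
#'
#' Independent of the folding dynamic program: parses the pairing, verifies
#' it is a single nested stem-loop, and sums stack energies and loop
#' penalties directly. Used as the self-consistency oracle for
#' [fold_hairpin()].
#'
#' @param sequence nucleotide sequence.
#' @param structure dot-bracket string of the same length.
#' @return energy in kcal/mol (0 for a fully unpaired structure).
#' @export
rescore_structure <- function(sequence, structure, model = energy_model()) {
  sequence <- norm_dna(sequence)
  s <- strsplit(sequence, "")[[1]]
  db <- strsplit(structure, "")[[1]]
  if (length(s) != length(db)) stop("sequence/structure length mismatch")
  opens <- integer(0)
  pairs <- NULL
  for (k in seq_along(db)) {
    if (db[k] == "(") opens <- c(opens, k)
    else if (db[k] == ")") {
      if (!length(opens)) stop("unbalanced structure")
      i <- opens[length(opens)]
      opens <- opens[-length(opens)]
      pairs <- rbind(pairs, c(i, k))
    }
  }
  if (length(opens)) stop("unbalanced structure")
  if (is.null(pairs)) return(0.0)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  ## single stem-loop: consecutive pairs must be strictly nested
  if (nrow(pairs) > 1L) {
    ok <- all(diff(pairs[, 1]) > 0) && all(diff(pairs[, 2]) < 0)
    if (!ok) stop("structure is not a single stem-loop")
  }
  e <- 0.0
  for (t in seq_len(nrow(pairs) - 1L)) {
    i <- pairs[t, 1]; j <- pairs[t, 2]
    p <- pairs[t + 1L, 1]; q <- pairs[t + 1L, 2]
    if (p <= i || q >= j) stop("structure is not a single stem-loop")
    if (p == i + 1L && q == j - 1L) {
      e <- e - 0.5 * (pair_strength_r(s[i], s[j], model) +
                      pair_strength_r(s[p], s[q], model))
    } else {
      e <- e + loop_penalty((p - i - 1L) + (j - q - 1L), model)
    }
  }
  last <- pairs[nrow(pairs), ]
  e + loop_penalty(last[2] - last[1] - 1L, model)
}

#' Extract candidate precursor windows for a tag
#'
#' For each exact occurrence of the tag (or its reverse complement) in a
#' reference contig, two windows are emitted: long upstream flank / short
#' downstream flank and vice versa (a mature miRNA may sit on either arm of
#' its hairpin). Minus-strand windows are emitted in folding orientation.
#'
#' @param tag tag sequence.
#' @param contigs named character vector of genome/transcriptome contigs.
#' @param flank_long,flank_short flank sizes in nt (defaults 70/20).
#' @return data.frame with columns `contig`, `strand`, `occ_start`,
#'   `occ_end` (forward-strand tag coordinates), `window_start`,
#'   `window_end` (forward-strand), `sequence` (folding orientation),
#'   `mature_start`, `mature_end` (1-based within `sequence`). Empty if the
#'   tag does not occur.
#' @export
extract_candidate_precursors <- function(tag, contigs, flank_long = 70L,
                                         flank_short = 20L) {
  tag <- norm_dna(tag)
  contigs <- stats::setNames(norm_dna(contigs), names(contigs))
  out <- list()
  emit <- function(contig_id, strand, cs, ce, L, contig_seq) {
    ## cs, ce: occurrence in folding-orientation coordinates
    for (fl in list(c(flank_long, flank_short),
                    c(flank_short, flank_long))) {
      ws <- max(1L, cs - fl[1L])
      we <- min(L, ce + fl[2L])
      seq_fold <- substr(contig_seq, ws, we)
      if (strand == "+") {
        fs <- ws; fe <- we; os <- cs; oe <- ce
      } else {
        fs <- L - we + 1L; fe <- L - ws + 1L
        os <- L - ce + 1L; oe <- L - cs + 1L
      }
      out[[length(out) + 1L]] <<- data.frame(
        contig = contig_id, strand = strand,
        occ_start = os, occ_end = oe,
        window_start = fs, window_end = fe,
        sequence = seq_fold,
        mature_start = cs - ws + 1L, mature_end = ce - ws + 1L,
        stringsAsFactors = FALSE)
    }
  }
  for (cid in names(contigs)) {
    fwd <- contigs[[cid]]
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      cseq <- if (strand == "+") fwd else revcomp(fwd)
      hits <- gregexpr(tag, cseq, fixed = TRUE)[[1]]
      if (hits[1L] < 0L) next
      for (h in as.integer(hits)) {
        emit(cid, strand, h, h + nchar(tag) - 1L, L, cseq)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), strand = character(0),
                      occ_start = integer(0), occ_end = integer(0),
                      window_start = integer(0), window_end = integer(0),
                      sequence = character(0), mature_start = integer(0),
                      mature_end = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

## which arm of the folded hairpin carries [m1, m2]? A mature "present in
## one arm" must lie entirely within the stem span on one side; the
## terminal loop is the open interval between the innermost pair, and
## sequence outside the hairpin is no arm at all.
mature_arm <- function(structure, m1, m2) {
  db <- strsplit(structure, "")[[1]]
  op <- which(db == "(")
  cl <- which(db == ")")
  if (!length(op)) return("unpaired")
  i1 <- min(op); ik <- max(op)   # outermost/innermost pair, 5' side
  jk <- min(cl); j1 <- max(cl)   # innermost/outermost pair, 3' side
  if (m1 > ik && m2 < jk) return("loop-overlap")
  if (m2 > ik && m1 < jk) return("loop-overlap")
  if (m1 >= i1 && m2 <= ik) return("5p")
  if (m1 >= jk && m2 <= j1) return("3p")
  "outside"
}

#' Call a novel miRNA from candidate precursor windows
#'
#' Accepts the best-energy window that satisfies all of: a genomic match
#' exists; the window folds into a single stem-loop with the mature interval
#' entirely on one arm; the minimum free energy is at or below `mfe_max`;
#' and the tag has at least `min_reads` supporting reads. One call per tag
#' (ties broken by smallest window coordinate).
#'
#' @param windows data.frame from [extract_candidate_precursors()].
#' @param tag tag sequence (for bookkeeping).
#' @param reads supporting read count for the tag.
#' @param model an [energy_model()].
#' @param mfe_max MFE acceptance threshold in kcal/mol (default -18).
#' @param min_reads minimum supporting reads (default 5).
#' @param mature_pair_min minimum fraction of mature bases paired within
#'   the stem (default 0.6, the miRNA-prediction convention of about 14 of
#'   22 nt in duplex); part of the "mature on one arm" criterion.
#' @return list with `accepted` (logical), and either `candidate` (one-row
#'   data.frame: `tag`, `contig`, `strand`, `window_start`, `window_end`,
#'   `mfe`, `arm`, `structure`, `sequence`, `reads`) or `reason` (one of
#'   `no_genomic_match`, `loop-overlap`, `outside_hairpin`,
#'   `mature_unpaired`, `no_hairpin`, `mfe_above_threshold`,
#'   `insufficient_reads`).
#' @export
call_novel_mirna <- function(windows, tag, reads, model = energy_model(),
                             mfe_max = -18.0, min_reads = 5L,
                             mature_pair_min = 0.6) {
  if (nrow(windows) == 0L) {
    return(list(accepted = FALSE, reason = "no_genomic_match"))
  }
  folds <- lapply(windows$sequence, fold_hairpin, model = model)
  mfe <- vapply(folds, `[[`, numeric(1), "mfe")
  arm <- vapply(seq_len(nrow(windows)), function(i) {
    if (mfe[i] >= 0) return("unpaired")
    a <- mature_arm(folds[[i]]$structure, windows$mature_start[i],
                    windows$mature_end[i])
    if (a %in% c("5p", "3p")) {
      db <- strsplit(folds[[i]]$structure, "")[[1]]
      span <- windows$mature_start[i]:windows$mature_end[i]
      if (mean(db[span] != ".") < mature_pair_min) a <- "mature_unpaired"
    }
    a
  }, character(1))
  on_arm <- arm %in% c("5p", "3p")
  if (!any(on_arm)) {
    reason <- if (any(arm == "loop-overlap")) "loop-overlap"
              else if (any(arm == "outside")) "outside_hairpin"
              else if (any(arm == "mature_unpaired")) "mature_unpaired"
              else "no_hairpin"
    return(list(accepted = FALSE, reason = reason))
  }
  cand <- which(on_arm)
  best <- cand[order(mfe[cand], windows$window_start[cand],
                     windows$contig[cand])][1L]
  if (mfe[best] > mfe_max) {
    return(list(accepted = FALSE, reason = "mfe_above_threshold"))
  }
  if (reads < min_reads) {
    return(list(accepted = FALSE, reason = "insufficient_reads"))
  }
  list(accepted = TRUE, candidate = data.frame(
    tag = tag, contig = windows$contig[best],
    strand = windows$strand[best],
    window_start = windows$window_start[best],
    window_end = windows$window_end[best],
    mfe = mfe[best], arm = arm[best],
    structure = folds[[best]]$structure,
    sequence = windows$sequence[best],
    reads = reads, stringsAsFactors = FALSE))
}

#' Scan unannotated tags for novel miRNA hairpins
#'
#' Convenience driver: anchors each tag, folds its candidate windows and
#' applies [call_novel_mirna()].
#'
#' @param tags data.frame from [collapse_unique()] restricted to
#'   unannotated tags.
#' @param contigs named character vector of reference contigs.
#' @inheritParams call_novel_mirna
#' @param flank_long,flank_short window flank sizes in nt.
#' @return data.frame of accepted candidates (possibly empty) with the
#'   per-tag rejection reasons as attribute `"rejections"`.
#' @export
discover_novel_mirnas <- function(tags, contigs, model = energy_model(),
                                  mfe_max = -18.0, min_reads = 5L,
                                  flank_long = 70L, flank_short = 20L) {
  acc <- list()
  rej <- character(0)
  for (i in seq_len(nrow(tags))) {
    tag <- tags$sequence[i]
    reads <- tags$count_na[i] + tags$count_da[i]
    w <- extract_candidate_precursors(tag, contigs, flank_long, flank_short)
    res <- call_novel_mirna(w, tag, reads, model, mfe_max, min_reads)
    if (res$accepted) {
      acc[[length(acc) + 1L]] <- res$candidate
    } else {
      rej[tag] <- res$reason
    }
  }
  out <- if (length(acc)) do.call(rbind, acc) else
    data.frame(tag = character(0), contig = character(0),
               strand = character(0), window_start = integer(0),
               window_end = integer(0), mfe = numeric(0), arm = character(0),
               structure = character(0), sequence = character(0),
               reads = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rejections") <- rej
  out
}
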