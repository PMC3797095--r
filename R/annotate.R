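## Tag annotation: contaminant ncRNA classification, exact matching against
## known mature/precursor miRNAs, the per-family "temporary miRNA database",
## and quantification against it. All matching is exact (substring identity);
## the source study's miRNA matching is explicitly mismatch-free, and the
## same strict rule is adopted for the contaminant classes.

NCRNA_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA")

is_substring_of_any <- function(tag, refs) {
  any(grepl(tag, refs, fixed = TRUE))
}

#' Classify tags against contaminant ncRNA reference sets
#'
#' A tag is assigned to the first class in the priority order
#' rRNA > tRNA > snRNA > snoRNA for which it occurs as an exact substring of
#' any reference record. Assigned tags are excluded from miRNA matching.
#'
#' @param tags data.frame from [collapse_unique()] (column `sequence`).
#' @param ref_sets named list of named character vectors; recognized names
#'   are `rRNA`, `tRNA`, `snRNA`, `snoRNA`. Missing classes are skipped,
#'   empty ones yield a warning and no assignments.
#' @return data.frame with columns `sequence`, `category` (class or NA) and
#'   `ref_id` (first matching reference id or NA).
#' @export
classify_ncrna <- function(tags, ref_sets) {
  seqs <- tags$sequence
  category <- rep(NA_character_, length(seqs))
  ref_id <- rep(NA_character_, length(seqs))
  for (cls in NCRNA_CLASSES) {
    refs <- ref_sets[[cls]]
    if (is.null(refs)) next
    if (length(refs) == 0L) {
      warning("empty reference set for class ", cls)
      next
    }
    refs <- stats::setNames(norm_dna(refs), names(refs))
    todo <- which(is.na(category))
    for (i in todo) {
      hit <- which(vapply(refs, function(r)
        grepl(seqs[i], r, fixed = TRUE), logical(1)))
      if (length(hit)) {
        category[i] <- cls
        ref_id[i] <- names(refs)[hit[1L]]
      }
    }
  }
  data.frame(sequence = seqs, category = category, ref_id = ref_id,
             stringsAsFactors = FALSE)
}

## derive a family name from a miRBase-style mature id:
## strip the species prefix ("hsa-", "mmu-", ...) and a trailing -5p/-3p
family_root <- function(id) {
  fam <- sub("^[A-Za-z]{2,4}-", "", id)
  sub("-(5p|3p)$", "", fam)
}

#' Match tags against known mature and precursor miRNAs
#'
#' A tag hits a mature reference iff it is identical to the mature sequence,
#' or it is an exact substring of an associated precursor starting within
#' `offset_tol` nt of the annotated mature start (isomiR 5' variation).
#'
#' @param tags data.frame with a `sequence` column (tags not consumed by
#'   [classify_ncrna()]).
#' @param mature named character vector of mature miRNA sequences.
#' @param precursors optional named character vector of precursor sequences.
#' @param family_of optional named character vector mapping mature id ->
#'   family; ids missing from the map fall back to the id root with a
#'   warning.
#' @param offset_tol allowed offset (nt) of the tag start from the annotated
#'   mature start within the precursor (default 2).
#' @return data.frame of hits with columns `sequence`, `mature_id`, `family`.
#' @export
match_known_mirnas <- function(tags, mature, precursors = NULL,
                               family_of = NULL, offset_tol = 2L) {
  mature <- stats::setNames(norm_dna(mature), names(mature))
  if (!is.null(precursors)) {
    precursors <- stats::setNames(norm_dna(precursors), names(precursors))
  }
  ## annotated mature start: first occurrence of each mature in each
  ## precursor that contains it
  prec_anchor <- NULL
  if (!is.null(precursors) && length(precursors)) {
    anchors <- lapply(names(mature), function(mid) {
      pos <- vapply(precursors, function(p)
        as.integer(regexpr(mature[[mid]], p, fixed = TRUE)), integer(1))
      hit <- which(pos > 0L)
      if (!length(hit)) return(NULL)
      data.frame(mature_id = mid, prec_id = names(precursors)[hit],
                 mature_start = pos[hit], stringsAsFactors = FALSE)
    })
    prec_anchor <- do.call(rbind, anchors)
  }

  fam_for <- function(mid) {
    if (!is.null(family_of) && mid %in% names(family_of)) {
      return(unname(family_of[[mid]]))
    }
    if (!is.null(family_of)) {
      warning("mature id '", mid, "' missing from family map; using id root")
    }
    family_root(mid)
  }

  rows <- list()
  for (i in seq_len(nrow(tags))) {
    tag <- tags$sequence[i]
    hit_ids <- names(mature)[mature == tag]
    if (!is.null(prec_anchor) && nrow(prec_anchor)) {
      for (j in seq_len(nrow(prec_anchor))) {
        p <- precursors[[prec_anchor$prec_id[j]]]
        pos <- as.integer(regexpr(tag, p, fixed = TRUE))
        if (pos > 0L &&
            abs(pos - prec_anchor$mature_start[j]) <= offset_tol) {
          hit_ids <- c(hit_ids, prec_anchor$mature_id[j])
        }
      }
    }
    hit_ids <- sort(unique(hit_ids))
    if (length(hit_ids)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = tag, mature_id = hit_ids,
        family = vapply(hit_ids, fam_for, character(1)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(sequence = character(0), mature_id = character(0),
                      family = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the temporary miRNA database
#'
#' For each mature miRNA family the highest-expressed member (summed NA+DA
#' reads over its hitting tags) is chosen as the family representative; ties
#' go to the lexicographically smallest mature id.
#'
#' @param hits data.frame from [match_known_mirnas()].
#' @param tags data.frame from [collapse_unique()] (for the counts).
#' @param mature named character vector of mature sequences (for the
#'   representative sequences).
#' @return data.frame with columns `family`, `mature_id`, `sequence`,
#'   `total_reads`, one row per family.
#' @export
build_temporary_db <- function(hits, tags, mature) {
  if (nrow(hits) == 0L) stop("no miRNA hits; cannot build temporary database")
  mature <- stats::setNames(norm_dna(mature), names(mature))
  m <- merge(hits, tags[, c("sequence", "count_na", "count_da")],
             by = "sequence")
  m$reads <- m$count_na + m$count_da
  per_mature <- aggregate(reads ~ mature_id + family, data = m, FUN = sum)
  pick <- lapply(split(per_mature, per_mature$family), function(d) {
    d <- d[order(-d$reads, d$mature_id), , drop = FALSE]
    d[1L, ]
  })
  out <- do.call(rbind, pick)
  out <- data.frame(family = out$family, mature_id = out$mature_id,
                    sequence = unname(mature[out$mature_id]),
                    total_reads = out$reads, stringsAsFactors = FALSE)
  out <- out[order(out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quantify miRNA expression against the temporary database
#'
#' A tag contributes to a representative iff it is an exact substring of the
#' representative sequence (zero mismatches). A tag matching several
#' representatives is assigned once, to the representative with the longest
#' match (always the full tag here), ties broken by smallest mature id.
#'
#' @param tags data.frame from [collapse_unique()].
#' @param tempdb data.frame from [build_temporary_db()].
#' @return data.frame with columns `mature_id`, `family`, `x` (NA reads),
#'   `y` (DA reads); representatives with no matching tag report (0, 0).
#'   The per-tag assignment is available as attribute `"assignment"`.
#' @export
quantify_mirnas <- function(tags, tempdb) {
  reps <- tempdb[order(tempdb$mature_id), , drop = FALSE]
  x <- stats::setNames(numeric(nrow(reps)), reps$mature_id)
  y <- x
  assigned <- rep(NA_character_, nrow(tags))
  for (i in seq_len(nrow(tags))) {
    tag <- tags$sequence[i]
    hit <- which(vapply(reps$sequence, function(r)
      grepl(tag, r, fixed = TRUE), logical(1)))
    if (!length(hit)) next
    id <- reps$mature_id[hit[1L]]   # reps sorted by id: smallest id wins
    assigned[i] <- id
    x[id] <- x[id] + tags$count_na[i]
    y[id] <- y[id] + tags$count_da[i]
  }
  out <- data.frame(mature_id = reps$mature_id, family = reps$family,
                    x = as.numeric(x), y = as.numeric(y),
                    stringsAsFactors = FALSE)
  ord <- match(tempdb$mature_id, out$mature_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "assignment") <- data.frame(sequence = tags$sequence,
                                        mature_id = assigned,
                                        stringsAsFactors = FALSE)
  out
}

#' Per-category annotation summary of a tag table
#'
#' @param tags data.frame from [collapse_unique()].
#' @param categories character vector parallel to `tags` rows, with values
#'   in `miRNA`, `rRNA`, `tRNA`, `snRNA`, `snoRNA` or NA (unannotated).
#' @return data.frame with one row per category plus a `total` row:
#'   `unique_na`, `unique_da`, `reads_na`, `reads_da`.
#' @export
summarize_annotation <- function(tags, categories) {
  stopifnot(length(categories) == nrow(tags))
  cat <- ifelse(is.na(categories), "unann", categories)
  lv <- c("miRNA", NCRNA_CLASSES, "unann")
  cat <- factor(cat, levels = lv)
  in_na <- tags$count_na > 0
  in_da <- tags$count_da > 0
  row_for <- function(sel) {
    c(unique_na = sum(sel & in_na), unique_da = sum(sel & in_da),
      reads_na = sum(tags$count_na[sel]), reads_da = sum(tags$count_da[sel]))
  }
  m <- t(vapply(lv, function(l) row_for(cat == l), numeric(4)))
  m <- rbind(m, colSums(m))
  storage.mode(m) <- "integer"
  out <- data.frame(category = c(lv, "total"), m, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mapping statistics with percentages
#'
#' Adds per-library unique-tag and read percentages (100 x count / total,
#' rounded to 2 decimals) to an annotation summary.
#'
#' @param summary data.frame as produced by [summarize_annotation()] (a row
#'   with `category == "total"` supplies the denominators; if absent, column
#'   sums over the category rows are used).
#' @return the summary with columns `pct_unique_na`, `pct_unique_da`,
#'   `pct_reads_na`, `pct_reads_da` appended.
#' @export
mapping_stats <- function(summary) {
  cols <- c("unique_na", "unique_da", "reads_na", "reads_da")
  stopifnot(all(cols %in% names(summary)))
  tot_row <- summary$category == "total"
  totals <- if (any(tot_row)) {
    unlist(summary[which(tot_row)[1L], cols])
  } else {
    colSums(summary[, cols, drop = FALSE])
  }
  for (cl in cols) {
    pc <- round(100 * summary[[cl]] / totals[[cl]], 2)
    summary[[sub("^", "pct_", cl)]] <- pc
  }
  summary
}
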