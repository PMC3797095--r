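## Synthetic two-library small-RNA world with ground truth. The generator
## emulates the statistical structure the analysis assumes: two pooled
## libraries (no replicates), a dominant miRNA family, a 22-nt length mode
## within an 18-30 nt window, planted log2 fold changes across known
## families, ncRNA contamination, adapter/poly(A)/quality junk, planted
## genomic hairpin precursors with strongly negative designed MFE, UTRs
## with planted seed sites, and a gene-to-GO map with one planted enriched
## term.

#' Simulation configuration
#'
#' Defaults state the simulated world once: per-library depth 1e6 raw
#' reads, ~62% of clean reads from miRNA with one dominant family, planted
#' log2 fold changes cycling through 0/±1/±1.5/±2, a 22-nt read-length
#' mode, and small contaminant/junk fractions. Tests run the same world at
#' reduced depth for speed.
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical outputs.
#' @param n_families number of known miRNA families.
#' @param lib_size_na,lib_size_da raw reads per library.
#' @param sdlog log-normal sd of per-miRNA base abundance.
#' @param dominant_share share of miRNA reads given to family 1.
#' @param planted_fc vector of planted log2 fold changes, recycled over
#'   families.
#' @param mirna_frac,rrna_frac,trna_frac,snrna_frac,snorna_frac fractions
#'   of raw reads per clean category (the remainder of clean reads is
#'   unannotated background).
#' @param polya_frac,adapter5_frac,lowq_frac,short_frac,noad3_frac,n_frac
#'   junk fractions removed by cleaning.
#' @param len_mode,len_sd discrete read-length model over 18-30 nt.
#' @param adapter3,adapter5 adapter sequences.
#' @param read_len raw read length (insert + adapter + pad).
#' @param n_novel planted novel hairpin loci.
#' @param novel_mean_reads expected supporting reads per novel tag per
#'   library.
#' @param n_utr,utr_len,n_target_mirnas,n_target_genes,sites_per_class
#'   UTR/seed-site planting parameters.
#' @param n_bg_genes,n_go_terms,go_enrich_factor GO map parameters; one
#'   term is planted at `go_enrich_factor` times its base frequency among
#'   the target genes.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 30L,
                       lib_size_na = 1e6, lib_size_da = 1e6,
                       sdlog = 1.5, dominant_share = 0.45,
                       planted_fc = c(0, 1, 1.5, 2, 0, -1, -1.5, -2),
                       mirna_frac = 0.62, rrna_frac = 0.015,
                       trna_frac = 0.007, snrna_frac = 5e-4,
                       snorna_frac = 2e-4,
                       polya_frac = 0.010, adapter5_frac = 0.005,
                       lowq_frac = 0.005, short_frac = 0.005,
                       noad3_frac = 0.005, n_frac = 0.002,
                       len_mode = 22, len_sd = 1.3,
                       adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                       read_len = 44L,
                       n_novel = 5L, novel_mean_reads = 60,
                       n_utr = 40L, utr_len = 300L,
                       n_target_mirnas = 3L, n_target_genes = 15L,
                       sites_per_class = 1L,
                       n_bg_genes = 500L, n_go_terms = 40L,
                       go_enrich_factor = 5) {
  cfg <- as.list(environment())
  fr <- with(cfg, mirna_frac + rrna_frac + trna_frac + snrna_frac +
               snorna_frac + polya_frac + adapter5_frac + lowq_frac +
               short_frac + noad3_frac + n_frac)
  if (fr > 1) stop("category fractions sum above 1")
  stopifnot(cfg$seed == as.integer(cfg$seed), cfg$n_families >= 2L,
            cfg$n_target_genes <= cfg$n_utr)
  class(cfg) <- "sim_config"
  cfg
}

rand_seq <- function(n, len, prob = c(0.25, 0.25, 0.25, 0.25)) {
  vapply(rep(len, length.out = n), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = prob),
          collapse = ""), character(1))
}

## discrete length model over 18..30 nt
sample_lengths <- function(n, cfg) {
  lens <- 18:30
  w <- exp(-0.5 * ((lens - cfg$len_mode) / cfg$len_sd)^2)
  sample(lens, n, replace = TRUE, prob = w / sum(w))
}

## mutate accidental seed matches for the given miRNAs out of a UTR
scrub_utr <- function(utr, mirnas) {
  repeat {
    hits <- scan_utr(mirnas, c(u = utr))
    if (nrow(hits) == 0L) return(utr)
    s <- hits$start[1L]
    mid <- s + 3L
    old <- substr(utr, mid, mid)
    new <- setdiff(c("A", "C", "G", "T"), old)[sample.int(3L, 1L)]
    substr(utr, mid, mid) <- new
  }
}

## build the 8-nt window that realizes a site class for a mature miRNA
site_window <- function(mature, type) {
  rc7 <- revcomp(substr(mature, 2L, 8L))
  rc6 <- revcomp(substr(mature, 2L, 7L))
  m8c <- substr(rc7, 1L, 1L)   # complement of mature position 8
  switch(type,
         "8mer" = paste0(rc7, "A"),
         "7mer-m8" = paste0(rc7, sample(c("C", "G", "T"), 1L)),
         "7mer-1a" = paste0(sample(setdiff(c("A", "C", "G", "T"), m8c), 1L),
                            rc6, "A"))
}

#' Generate reference sets and ground truth
#'
#' Emits the full reference side of the simulated world: mature/precursor
#' miRNA sets with family structure and planted fold changes, contaminant
#' ncRNA sets, genome contigs containing designed hairpin precursors whose
#' perfect GC-biased stems guarantee MFE well below -25 kcal/mol under the
#' default energy model, UTRs carrying exactly the planted seed sites for
#' the target miRNAs, and a gene-to-GO map with one planted enriched term.
#'
#' @param cfg a [sim_config()].
#' @return list with `refs` (mature, precursors, family_of, rRNA, tRNA,
#'   snRNA, snoRNA, contigs, utrs, go_map, term_names) and `truth` (mirna,
#'   novel, sites, go).
#' @export
gen_references <- function(cfg = sim_config()) {
  set.seed(cfg$seed)

  ## --- known miRNA families -------------------------------------------
  mature <- character(0)
  family_of <- character(0)
  fam_id <- integer(0)
  for (i in seq_len(cfg$n_families)) {
    L <- sample_lengths(1L, cfg)
    base <- rand_seq(1L, L)
    ids <- sprintf("syn-miR-%d", i)
    seqs <- base
    if (runif(1) < 0.4) {
      v <- base
      substr(v, L - 2L, L) <- rand_seq(1L, 3L)
      if (v != base) {
        ids <- c(ids, sprintf("syn-miR-%d-3p", i))
        seqs <- c(seqs, v)
      }
    }
    mature[ids] <- seqs
    family_of[ids] <- sprintf("miR-%d", i)
    fam_id <- c(fam_id, rep(i, length(ids)))
  }
  stopifnot(!anyDuplicated(mature))

  precursors <- stats::setNames(
    paste0(rand_seq(length(mature), 20L), mature, rand_seq(length(mature), 15L),
           revcomp(mature), rand_seq(length(mature), 20L)),
    paste0(names(mature), "-prec"))

  ## per-miRNA abundance weights; family 1 dominates
  w <- rlnorm(length(mature), meanlog = 0, sdlog = cfg$sdlog)
  is_dom <- fam_id == 1L
  w[is_dom] <- w[is_dom] * (cfg$dominant_share / (1 - cfg$dominant_share)) *
    sum(w[!is_dom]) / sum(w[is_dom])
  w <- w / sum(w)
  fc <- cfg$planted_fc[(fam_id - 1L) %% length(cfg$planted_fc) + 1L]
  truth_mirna <- data.frame(mature_id = names(mature),
                            family = unname(family_of),
                            sequence = unname(mature),
                            weight = w, fc = fc, stringsAsFactors = FALSE)

  ## --- contaminant ncRNA sets -----------------------------------------
  refs_nc <- list(
    rRNA = stats::setNames(rand_seq(3L, 600L), sprintf("rRNA_%d", 1:3)),
    tRNA = stats::setNames(rand_seq(8L, 75L), sprintf("tRNA_%d", 1:8)),
    snRNA = stats::setNames(rand_seq(5L, 150L), sprintf("snRNA_%d", 1:5)),
    snoRNA = stats::setNames(rand_seq(5L, 120L), sprintf("snoRNA_%d", 1:5)))

  ## --- planted novel hairpin loci -------------------------------------
  contigs <- character(0)
  novel_rows <- list()
  gc_bias <- c(0.15, 0.35, 0.35, 0.15)   # A, C, G, T
  for (i in seq_len(cfg$n_novel)) {
    arm <- rand_seq(1L, 30L, prob = gc_bias)
    loop <- rand_seq(1L, 8L)
    hairpin <- paste0(arm, loop, revcomp(arm))
    tag <- substr(arm, 4L, 25L)
    up <- rand_seq(1L, 60L)
    dn <- rand_seq(1L, 60L)
    contig <- paste0(up, hairpin, dn)
    cid <- sprintf("contig_%d", i)
    contigs[cid] <- contig
    novel_rows[[i]] <- data.frame(
      tag = tag, contig = cid,
      tag_start = 60L + 4L, tag_end = 60L + 25L,
      hairpin_start = 61L, hairpin_end = 60L + nchar(hairpin),
      stringsAsFactors = FALSE)
  }
  truth_novel <- do.call(rbind, novel_rows)
  ## plus decoy contigs with no planted structure
  for (i in seq_len(3L)) {
    contigs[sprintf("decoy_%d", i)] <- rand_seq(1L, 300L)
  }

  ## --- UTRs with planted seed sites -----------------------------------
  ## targets are planted for up-regulated miRNAs (the downstream target
  ## stage predicts targets of the up-called set); background UTR sequence
  ## is scrubbed of accidental seed matches for every known miRNA
  up_fams <- unique(truth_mirna$family[truth_mirna$fc >= 1])
  if (!length(up_fams)) up_fams <- unique(truth_mirna$family)
  rep_ids <- vapply(up_fams[seq_len(min(cfg$n_target_mirnas,
                                        length(up_fams)))],
                    function(f) truth_mirna$mature_id[
                      truth_mirna$family == f][1L], character(1))
  target_mirnas <- mature[rep_ids]
  utrs <- character(0)
  site_rows <- list()
  classes <- c("8mer", "7mer-m8", "7mer-1a")
  for (g in seq_len(cfg$n_utr)) {
    gid <- sprintf("gene%03d", g)
    u <- scrub_utr(rand_seq(1L, cfg$utr_len), mature)
    if (g <= cfg$n_target_genes) {
      mi <- (g - 1L) %% length(target_mirnas) + 1L
      cls <- classes[(g - 1L) %% 3L + 1L]
      m <- target_mirnas[[mi]]
      for (k in seq_len(cfg$sites_per_class)) {
        pos <- 20L + (k - 1L) * 40L
        win <- site_window(m, cls)
        substr(u, pos, pos + 7L) <- win
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          mirna = names(target_mirnas)[mi], utr = gid,
          window_start = pos, type = cls, stringsAsFactors = FALSE)
      }
      ## planting may have broken or created sites; verify exact recovery,
      ## otherwise re-draw the background (rare)
      found <- scan_utr(target_mirnas, stats::setNames(u, gid))
      if (nrow(found) != cfg$sites_per_class ||
          !all(found$type == cls)) {
        u <- scrub_utr(rand_seq(1L, cfg$utr_len), mature)
        for (k in seq_len(cfg$sites_per_class)) {
          pos <- 20L + (k - 1L) * 40L
          substr(u, pos, pos + 7L) <- site_window(m, cls)
        }
      }
    }
    utrs[gid] <- u
  }
  truth_sites <- do.call(rbind, site_rows)

  ## --- gene-to-GO map with one planted enriched term ------------------
  genes <- sprintf("gene%03d", seq_len(cfg$n_bg_genes))
  target_genes <- sprintf("gene%03d", seq_len(cfg$n_target_genes))
  terms <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  planted_term <- terms[1L]
  base_freq <- c(0.10, runif(cfg$n_go_terms - 1L, 0.02, 0.10))
  map_rows <- list()
  for (t in seq_along(terms)) {
    pr <- rep(base_freq[t], cfg$n_bg_genes)
    if (terms[t] == planted_term) {
      pr[seq_len(cfg$n_target_genes)] <-
        pmin(1, cfg$go_enrich_factor * base_freq[t])
    }
    hit <- genes[runif(cfg$n_bg_genes) < pr]
    if (length(hit)) {
      map_rows[[t]] <- data.frame(gene = hit, term = terms[t],
                                  stringsAsFactors = FALSE)
    }
  }
  go_map <- do.call(rbind, map_rows)
  term_names <- stats::setNames(sprintf("synthetic term %d",
                                        seq_along(terms)), terms)

  list(refs = list(mature = mature, precursors = precursors,
                   family_of = family_of, rRNA = refs_nc$rRNA,
                   tRNA = refs_nc$tRNA, snRNA = refs_nc$snRNA,
                   snoRNA = refs_nc$snoRNA, contigs = contigs,
                   utrs = utrs, go_map = go_map, term_names = term_names),
       truth = list(mirna = truth_mirna, novel = truth_novel,
                    sites = truth_sites,
                    go = list(planted_term = planted_term,
                              target_genes = target_genes,
                              background = genes)))
}

## sample contaminant inserts: windows of reference records
contaminant_inserts <- function(n, refs, cfg) {
  if (n == 0L) return(character(0))
  lens <- nchar(refs)
  rec <- sample(seq_along(refs), n, replace = TRUE, prob = lens)
  ins_len <- pmin(sample_lengths(n, cfg), lens[rec])
  start <- vapply(seq_len(n), function(i)
    sample.int(lens[rec[i]] - ins_len[i] + 1L, 1L), integer(1))
  substr(refs[rec], start, start + ins_len - 1L)
}

#' Generate the two raw read libraries
#'
#' Per-miRNA read counts are Poisson with means `C * w * 2^(+-fc/2)` scaled
#' per library, so the planted fold change is exact in RPM space; novel
#' tags, contaminant windows, random unannotated background and the junk
#' classes (poly(A), 5'-adapter pollution, low quality, N-containing,
#' short inserts, adapter-free reads) are layered on top at the configured
#' fractions. Reads carry the 3' adapter and are padded to `read_len`.
#'
#' @param cfg a [sim_config()].
#' @param world output of [gen_references()].
#' @return list with `na` and `da` (each `id`, `seq`, `qual` character
#'   vectors) and `counts` (truth table with drawn per-species counts and
#'   their Poisson means).
#' @export
gen_libraries <- function(cfg, world) {
  set.seed(cfg$seed + 1L)
  refs <- world$refs
  tm <- world$truth$mirna
  novel <- world$truth$novel

  C <- cfg$mirna_frac / sum(tm$weight * 2^(-tm$fc / 2))
  mean_na <- C * cfg$lib_size_na * tm$weight * 2^(-tm$fc / 2)
  mean_da <- C * cfg$lib_size_da * tm$weight * 2^(+tm$fc / 2)

  build_lib <- function(lib_size, means, label) {
    k_mirna <- rpois(length(means), means)
    k_novel <- rpois(nrow(novel), cfg$novel_mean_reads)
    ins <- c(rep(tm$sequence, k_mirna), rep(novel$tag, k_novel))
    for (cls in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
      frac <- cfg[[paste0(tolower(sub("RNA", "", cls)), "rna_frac")]]
      n <- round(frac * lib_size)
      ins <- c(ins, contaminant_inserts(n, refs[[cls]], cfg))
    }
    junk_total <- cfg$polya_frac + cfg$adapter5_frac + cfg$lowq_frac +
      cfg$short_frac + cfg$noad3_frac + cfg$n_frac
    n_unann <- max(0L, round(lib_size * (1 - junk_total)) - length(ins))
    ins <- c(ins, rand_seq(n_unann, sample_lengths(n_unann, cfg)))
    qual_hi <- strrep("I", cfg$read_len)
    mk_read <- function(insert) {
      substr(paste0(insert, cfg$adapter3, strrep("A", cfg$read_len)),
             1L, cfg$read_len)
    }
    seqs <- mk_read(ins)
    quals <- rep(qual_hi, length(seqs))

    ## junk classes (removed by cleaning)
    n_of <- function(f) round(f * lib_size)
    j_polya <- mk_read(strrep("A", sample(20:28, n_of(cfg$polya_frac),
                                          replace = TRUE)))
    j_ad5 <- substr(paste0(cfg$adapter5,
                           rand_seq(n_of(cfg$adapter5_frac), 22L),
                           cfg$adapter3, strrep("A", cfg$read_len)),
                    1L, cfg$read_len)
    j_short <- mk_read(rand_seq(n_of(cfg$short_frac), 12L))
    j_noad3 <- rand_seq(n_of(cfg$noad3_frac), cfg$read_len)
    j_lowq <- mk_read(rand_seq(n_of(cfg$lowq_frac), 22L))
    lowq_qual <- vapply(seq_len(length(j_lowq)), function(i)
      paste(sample(c("I", "#"), cfg$read_len, replace = TRUE,
                   prob = c(0.6, 0.4)), collapse = ""), character(1))
    j_n <- mk_read(vapply(rand_seq(n_of(cfg$n_frac), 22L), function(s) {
      substr(s, 11L, 11L) <- "N"; s
    }, character(1), USE.NAMES = FALSE))

    seqs <- c(seqs, j_polya, j_ad5, j_short, j_noad3, j_lowq, j_n)
    quals <- c(quals, rep(qual_hi, length(j_polya) + length(j_ad5) +
                            length(j_short) + length(j_noad3)),
               lowq_qual, rep(qual_hi, length(j_n)))
    ord <- sample.int(length(seqs))
    list(id = sprintf("%s_%07d", label, seq_along(seqs)),
         seq = seqs[ord], qual = quals[ord],
         k_mirna = k_mirna, k_novel = k_novel)
  }

  na <- build_lib(cfg$lib_size_na, mean_na, "NA")
  da <- build_lib(cfg$lib_size_da, mean_da, "DA")

  counts <- rbind(
    data.frame(id = tm$mature_id, sequence = tm$sequence, kind = "mirna",
               fc = tm$fc, mean_na = mean_na, mean_da = mean_da,
               count_na = na$k_mirna, count_da = da$k_mirna,
               stringsAsFactors = FALSE),
    data.frame(id = paste0("novel_", seq_len(nrow(novel))),
               sequence = novel$tag, kind = "novel", fc = 0,
               mean_na = cfg$novel_mean_reads,
               mean_da = cfg$novel_mean_reads,
               count_na = na$k_novel, count_da = da$k_novel,
               stringsAsFactors = FALSE))
  list(na = na[c("id", "seq", "qual")], da = da[c("id", "seq", "qual")],
       counts = counts)
}

#' Generate and optionally write a complete synthetic dataset
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, FASTQ libraries, all
#'   reference FASTA files, the family and GO maps and the truth tables
#'   are written there as plain text.
#' @return (invisibly) list with `refs`, `truth`, `libs` and, when
#'   written, `paths`.
#' @export
simulate_dataset <- function(cfg = sim_config(), out_dir = NULL) {
  world <- gen_references(cfg)
  libs <- gen_libraries(cfg, world)
  out <- list(refs = world$refs, truth = world$truth, libs = libs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    pth <- function(f) file.path(out_dir, f)
    refs <- world$refs
    write_fastq(libs$na$id, libs$na$seq, libs$na$qual, pth("reads_na.fastq"))
    write_fastq(libs$da$id, libs$da$seq, libs$da$qual, pth("reads_da.fastq"))
    write_fasta(refs$mature, pth("mature.fa"))
    write_fasta(refs$precursors, pth("precursor.fa"))
    for (cls in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
      write_fasta(refs[[cls]], pth(paste0(tolower(cls), ".fa")))
    }
    write_fasta(refs$contigs, pth("genome.fa"))
    write_fasta(refs$utrs, pth("utr.fa"))
    write_tsv(data.frame(mature_id = names(refs$family_of),
                         family = unname(refs$family_of)),
              pth("family_map.tsv"))
    write_tsv(refs$go_map, pth("go_map.tsv"))
    write_tsv(data.frame(term = names(refs$term_names),
                         name = unname(refs$term_names)),
              pth("go_terms.tsv"))
    write_tsv(world$truth$mirna, pth("truth_mirna.tsv"))
    write_tsv(world$truth$novel, pth("truth_novel.tsv"))
    write_tsv(world$truth$sites, pth("truth_sites.tsv"))
    write_tsv(libs$counts, pth("truth_counts.tsv"))
    jsonlite::write_json(list(planted_term = world$truth$go$planted_term,
                              target_genes = world$truth$go$target_genes),
                         pth("truth_go.json"), auto_unbox = TRUE)
    out$paths <- stats::setNames(
      file.path(out_dir, list.files(out_dir)), NULL)
  }
  invisible(out)
}
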