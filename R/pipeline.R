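## Pipeline orchestration: clean -> annotate -> novel -> diffexp ->
## targets -> enrich, driven by a validated configuration, with every
## stage output written as headered TSV (no binary intermediates) and a
## machine-readable JSON summary.

#' Pipeline configuration
#'
#' Collects input paths and analysis thresholds. All paths are checked at
#' validation time, before any compute.
#'
#' @param reads_na,reads_da FASTQ paths for the two libraries.
#' @param mature,precursor,rrna,trna,snrna,snorna FASTA reference paths
#'   (contaminant sets optional, NULL to skip a class).
#' @param family_map optional TSV (mature_id, family).
#' @param genome FASTA of contigs for novel-miRNA anchoring (optional).
#' @param utr 3'UTR FASTA (optional; enables the targets stage).
#' @param go_map gene-to-GO TSV (optional; enables enrichment).
#' @param out_dir output directory.
#' @param adapter3,adapter5 adapter sequences.
#' @param min_len,max_len insert length window.
#' @param rpm_min,fc_min,fdr_max differential expression thresholds.
#' @param mfe_max,min_reads novel-miRNA thresholds.
#' @param go_fdr GO enrichment FDR cutoff.
#' @param max_novel_tags cap on unannotated tags examined for hairpins
#'   (most-abundant first), bounding runtime.
#' @param seed RNG seed recorded in the summary.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(reads_na, reads_da, mature,
                            precursor = NULL, rrna = NULL, trna = NULL,
                            snrna = NULL, snorna = NULL, family_map = NULL,
                            genome = NULL, utr = NULL, go_map = NULL,
                            out_dir = tempfile("aestimir_run_"),
                            adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                            adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                            min_len = 18L, max_len = 30L,
                            rpm_min = 10, fc_min = 1, fdr_max = 0.01,
                            mfe_max = -18, min_reads = 5L, go_fdr = 0.05,
                            max_novel_tags = 200L, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
validate_config <- function(cfg) {
  files <- c(reads_na = cfg$reads_na, reads_da = cfg$reads_da,
             mature = cfg$mature)
  opt <- c("precursor", "rrna", "trna", "snrna", "snorna", "family_map",
           "genome", "utr", "go_map")
  for (o in opt) if (!is.null(cfg[[o]])) files[o] <- cfg[[o]]
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("config error: missing input file(s): ",
         paste(sprintf("%s (%s)", names(missing), missing), collapse = ", "))
  }
  with(cfg, stopifnot(min_len >= 1, max_len >= min_len, rpm_min >= 0,
                      fc_min >= 0, fdr_max > 0, fdr_max <= 1,
                      mfe_max <= 0, min_reads >= 1, go_fdr > 0,
                      go_fdr <= 1))
  invisible(cfg)
}

#' Run the full small-RNA analysis pipeline
#'
#' Executes clean, annotate, novel discovery, differential expression,
#' target prediction and GO enrichment in order (optional stages are
#' skipped when their inputs are absent from the configuration). Every
#' stage's table is written under `out_dir` and is re-loadable; a summary
#' with per-stage counts is written as JSON.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) list of stage results; the `summary` element holds
#'   the per-stage counts.
#' @export
run_pipeline <- function(cfg) {
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(cfg$out_dir, f)
  set.seed(cfg$seed)
  summary <- list(seed = cfg$seed)
  res <- list()

  ## --- clean -----------------------------------------------------------
  prm <- clean_params(min_len = cfg$min_len, max_len = cfg$max_len)
  cl <- lapply(c(na = cfg$reads_na, da = cfg$reads_da), function(f) {
    fq <- read_fastq(f)
    clean_reads(fq$seq, fq$qual, cfg$adapter3, cfg$adapter5, prm)
  })
  tags <- collapse_unique(cl$na$inserts, cl$da$inserts)
  n1 <- cl$na$stats$clean_reads
  n2 <- cl$da$stats$clean_reads
  write_tsv(tags, pth("tags.tsv"))
  summary$clean <- list(
    input_na = cl$na$stats$input_reads, input_da = cl$da$stats$input_reads,
    clean_na = n1, clean_da = n2, unique_tags = nrow(tags),
    removed_na = as.list(cl$na$stats$removed_by_reason),
    removed_da = as.list(cl$da$stats$removed_by_reason))
  res$tags <- tags

  ## --- annotate --------------------------------------------------------
  ref_sets <- list()
  for (cls in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
    f <- cfg[[c(rRNA = "rrna", tRNA = "trna", snRNA = "snrna",
                snoRNA = "snorna")[cls]]]
    if (!is.null(f)) ref_sets[[cls]] <- read_fasta(f)
  }
  nc <- classify_ncrna(tags, ref_sets)
  mature <- read_fasta(cfg$mature)
  precursors <- if (!is.null(cfg$precursor)) read_fasta(cfg$precursor)
  family_of <- NULL
  if (!is.null(cfg$family_map)) {
    fm <- read_tsv(cfg$family_map)
    family_of <- stats::setNames(fm$family, fm$mature_id)
  }
  free <- is.na(nc$category)
  hits <- match_known_mirnas(tags[free, , drop = FALSE], mature,
                             precursors, family_of)
  tempdb <- build_temporary_db(hits, tags, mature)
  quant <- quantify_mirnas(tags[free, , drop = FALSE], tempdb)
  category <- nc$category
  category[free & tags$sequence %in% hits$sequence] <- "miRNA"
  ann <- mapping_stats(summarize_annotation(tags, category))
  write_tsv(ann, pth("annotation_summary.tsv"))
  write_tsv(tempdb, pth("temporary_mirna_db.tsv"))
  write_tsv(quant, pth("mirna_counts.tsv"))
  summary$annotate <- list(families = nrow(tempdb),
                           mirna_tags = sum(category == "miRNA",
                                            na.rm = TRUE))
  res$annotation <- ann; res$tempdb <- tempdb; res$quant <- quant

  ## --- novel discovery -------------------------------------------------
  if (!is.null(cfg$genome)) {
    contigs <- read_fasta(cfg$genome)
    unann <- tags[is.na(category), , drop = FALSE]
    unann <- unann[unann$count_na + unann$count_da >= cfg$min_reads, ,
                   drop = FALSE]
    unann <- utils::head(unann, cfg$max_novel_tags)
    novel <- discover_novel_mirnas(unann, contigs, mfe_max = cfg$mfe_max,
                                   min_reads = cfg$min_reads)
    write_tsv(novel[, setdiff(names(novel), "structure")],
              pth("novel_mirnas.tsv"))
    write_fasta(stats::setNames(novel$sequence,
                                paste0("novel_", seq_len(nrow(novel)))),
                pth("novel_precursors.fa"))
    summary$novel <- list(tags_examined = nrow(unann),
                          accepted = nrow(novel))
    res$novel <- novel
  }

  ## --- differential expression ----------------------------------------
  de <- score_expression(quant$mature_id, quant$x, quant$y, n1, n2)
  de <- call_differential(de, expr_min = cfg$rpm_min, fc_min = cfg$fc_min,
                          fdr_max = cfg$fdr_max)
  write_tsv(de, pth("diffexpr.tsv"))
  de_sum <- attr(de, "summary")
  summary$diffexpr <- as.list(de_sum)
  res$diffexpr <- de

  ## --- targets (of the up-regulated miRNAs) ---------------------------
  if (!is.null(cfg$utr)) {
    utrs <- read_fasta(cfg$utr)
    sig <- de$id[de$call == "up"]
    mseq <- stats::setNames(tempdb$sequence, tempdb$mature_id)
    mseq <- mseq[names(mseq) %in% sig & nchar(mseq) >= 8]
    sites <- scan_utr(mseq, utrs)
    write_tsv(sites, pth("target_sites.tsv"))
    summary$targets <- list(mirnas = length(mseq), sites = nrow(sites),
                            target_genes = length(unique(sites$utr)))
    res$sites <- sites

    ## --- enrichment ----------------------------------------------------
    if (!is.null(cfg$go_map) && nrow(sites)) {
      gm <- read_tsv(cfg$go_map)
      background <- unique(gm$gene)
      targets <- intersect(unique(sites$utr), background)
      enr <- enrich(targets, background, gm, fdr_max = cfg$go_fdr,
                    all = TRUE)
      write_tsv(enr, pth("go_enrichment.tsv"))
      summary$enrich <- list(tested = nrow(enr),
                             significant = sum(enr$significant))
      res$enrichment <- enr
    }
  }

  summary$config_hash <- substr(
    digest_config(cfg[setdiff(names(cfg), "out_dir")]), 1, 12)
  jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  res$summary <- summary
  invisible(res)
}

## tiny stable config fingerprint (no extra dependency)
digest_config <- function(cfg) {
  s <- paste(vapply(cfg, function(v) paste(format(v), collapse = ","),
                    character(1)), collapse = ";")
  sprintf("%08x%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max,
          nchar(s))
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset), `all` (run the
#' full pipeline), `diffexp` (score a count TSV), `qpcr` (2^-ddCt on a Ct
#' TSV). Typical use from a shell:
#' `Rscript -e 'aestimir::aestimir_cli()' simulate --out-dir sim`
#'
#' @param args character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return invisibly, the result of the dispatched stage.
#' @export
aestimir_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    stop("usage: aestimir <simulate|all|diffexp|qpcr> [--key value ...]")
  }
  cmd <- args[1L]
  opt <- parse_cli_args(args[-1L])
  num <- function(k, d) if (!is.null(opt[[k]])) as.numeric(opt[[k]]) else d
  chr <- function(k, d = NULL) if (!is.null(opt[[k]])) opt[[k]] else d
  res <- switch(
    cmd,
    simulate = {
      cfg <- sim_config(seed = as.integer(num("seed", 1)),
                        lib_size_na = num("lib-size", 1e6),
                        lib_size_da = num("lib-size", 1e6))
      simulate_dataset(cfg, chr("out-dir", "sim_out"))
    },
    all = {
      d <- chr("in-dir")
      if (is.null(d)) stop("config error: --in-dir is required")
      cfg <- pipeline_config(
        reads_na = file.path(d, "reads_na.fastq"),
        reads_da = file.path(d, "reads_da.fastq"),
        mature = file.path(d, "mature.fa"),
        precursor = file.path(d, "precursor.fa"),
        rrna = file.path(d, "rrna.fa"), trna = file.path(d, "trna.fa"),
        snrna = file.path(d, "snrna.fa"),
        snorna = file.path(d, "snorna.fa"),
        family_map = file.path(d, "family_map.tsv"),
        genome = file.path(d, "genome.fa"), utr = file.path(d, "utr.fa"),
        go_map = file.path(d, "go_map.tsv"),
        out_dir = chr("out-dir", "aestimir_out"),
        rpm_min = num("rpm-min", 10), fc_min = num("fc-min", 1),
        fdr_max = num("fdr-max", 0.01), mfe_max = num("mfe-max", -18),
        min_reads = as.integer(num("min-reads", 5)),
        seed = as.integer(num("seed", 1)))
      run_pipeline(cfg)
    },
    diffexp = {
      counts <- read_tsv(chr("counts"))
      de <- score_expression(counts[[1]], counts[[2]], counts[[3]],
                             num("n1", NA), num("n2", NA))
      de <- call_differential(de, expr_min = num("rpm-min", 10),
                              fc_min = num("fc-min", 1),
                              fdr_max = num("fdr-max", 0.01))
      write_tsv(de, chr("out", "diffexpr.tsv"))
      de
    },
    qpcr = {
      ct <- read_tsv(chr("ct"))
      rel <- delta_delta_ct(ct, chr("calibrator", "NA"))
      write_tsv(rel, chr("out", "qpcr.tsv"))
      rel
    },
    stop("unknown subcommand: ", cmd))
  invisible(res)
}
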