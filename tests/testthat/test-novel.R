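test_that("unpairable sequences fold to zero energy", {
  f <- fold_hairpin(strrep("A", 40))
  expect_identical(f$mfe, 0)
  expect_false(grepl("[()]", f$structure))
})

test_that("perfect GC stem energy equals the hand-summed value", {
  # 20 GC pairs = 19 GC/GC stacks at -3.3 plus terminal loop penalty
  # 4.0 + 1.75*ln(4/4) = 4.0
  f <- fold_hairpin(paste0(strrep("G", 20), "AAAA", strrep("C", 20)))
  expect_equal(f$mfe, 19 * -3.3 + 4.0, tolerance = 1e-9)
  expect_identical(f$structure,
                   paste0(strrep("(", 20), "....", strrep(")", 20)))
})

test_that("energy is additive in extra GC stacks", {
  mfe_k <- function(k) {
    fold_hairpin(paste0(strrep("G", 20 + k), "AAAA",
                        strrep("C", 20 + k)))$mfe
  }
  base <- mfe_k(0)
  for (k in 1:3) expect_equal(mfe_k(k), base - k * 3.3, tolerance = 1e-9)
})

test_that("returned mfe equals the re-scored energy of the structure", {
  set.seed(77)
  for (i in 1:60) {
    len <- sample(40:90, 1)
    gc <- runif(1, 0.3, 0.7)
    s <- rdna(len, prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    f <- fold_hairpin(s)
    if (f$mfe == 0) {
      expect_false(grepl("[()]", f$structure))
    } else {
      expect_equal(rescore_structure(s, f$structure), f$mfe,
                   tolerance = 1e-9)
    }
  }
})

test_that("candidate windows follow the flank arithmetic", {
  contig <- rdna_fixed("ctg", 300L)
  tag <- substr(contig, 101, 122)
  w <- extract_candidate_precursors(tag, c(c1 = contig))
  fwd <- w[w$strand == "+", ]
  expect_identical(sort(fwd$window_start), c(31L, 81L))
  expect_identical(sort(fwd$window_end), c(142L, 192L))
  expect_identical(fwd$mature_start, fwd$occ_start - fwd$window_start + 1L)
  # edge truncation
  tag5 <- substr(contig, 5, 26)
  w5 <- extract_candidate_precursors(tag5, c(c1 = contig))
  expect_identical(min(w5$window_start[w5$strand == "+"]), 1L)
  # no occurrence -> empty
  expect_identical(nrow(extract_candidate_precursors(rdna_fixed("absent"),
                                                     c(c1 = contig))), 0L)
})

test_that("minus-strand windows are emitted in folding orientation", {
  contig <- rdna_fixed("ctgrc", 200L)
  tag <- rc_oracle(substr(contig, 80, 101))
  w <- extract_candidate_precursors(tag, c(c1 = contig))
  w <- w[w$strand == "-", ]
  expect_gt(nrow(w), 0L)
  for (i in seq_len(nrow(w))) {
    expect_identical(substr(w$sequence[i], w$mature_start[i],
                            w$mature_end[i]), tag)
  }
})

test_that("the three-criterion hairpin call is applied in order", {
  # designed hairpin: tag on the 5' arm of a strong stem
  arm <- rdna_fixed("armA", 30L)
  hp <- paste0(arm, "CAACAACA", rc_oracle(arm))
  contig <- paste0(rdna_fixed("upA", 50L), hp, rdna_fixed("dnA", 50L))
  tag <- substr(arm, 4, 25)
  w <- extract_candidate_precursors(tag, c(c1 = contig))
  ok <- call_novel_mirna(w, tag, reads = 10)
  expect_true(ok$accepted)
  expect_true(ok$candidate$mfe <= -18)
  expect_true(ok$candidate$arm %in% c("5p", "3p"))
  # threshold is inclusive: accepted exactly at its own mfe, rejected just
  # below it
  at <- call_novel_mirna(w, tag, reads = 10, mfe_max = ok$candidate$mfe)
  expect_true(at$accepted)
  below <- call_novel_mirna(w, tag, reads = 10,
                            mfe_max = ok$candidate$mfe - 0.01)
  expect_identical(below$reason, "mfe_above_threshold")
  # read support comes after the energy criterion
  few <- call_novel_mirna(w, tag, reads = 2)
  expect_identical(few$reason, "insufficient_reads")
  # no genomic anchoring
  none <- call_novel_mirna(w[0, ], tag, reads = 10)
  expect_identical(none$reason, "no_genomic_match")
})

test_that("a mature interval spanning the terminal loop is rejected", {
  arm <- rdna_fixed("armB", 30L)
  hp <- paste0(arm, "CAACAACA", rc_oracle(arm))
  # window = exact hairpin; pretend the tag sits across the loop
  w <- data.frame(contig = "c1", strand = "+", occ_start = 20L,
                  occ_end = 45L, window_start = 1L,
                  window_end = nchar(hp), sequence = hp,
                  mature_start = 20L, mature_end = 45L,
                  stringsAsFactors = FALSE)
  res <- call_novel_mirna(w, substr(hp, 20, 45), reads = 10)
  expect_false(res$accepted)
  expect_identical(res$reason, "loop-overlap")
})

test_that("relaxing the MFE threshold never shrinks the accepted set", {
  sim <- small_sim()
  truth <- sim$world$truth$novel
  tags <- data.frame(sequence = truth$tag, count_na = 10L, count_da = 10L,
                     stringsAsFactors = FALSE)
  strict <- discover_novel_mirnas(tags, sim$world$refs$contigs,
                                  mfe_max = -18)
  loose <- discover_novel_mirnas(tags, sim$world$refs$contigs,
                                 mfe_max = -15)
  expect_true(all(strict$tag %in% loose$tag))
})

test_that("all planted precursors are recovered", {
  sim <- small_sim()
  truth <- sim$world$truth$novel
  tags <- data.frame(sequence = truth$tag, count_na = 10L, count_da = 10L,
                     stringsAsFactors = FALSE)
  got <- discover_novel_mirnas(tags, sim$world$refs$contigs)
  expect_setequal(got$tag, truth$tag)
  expect_true(all(got$mfe <= -25))
  expect_identical(got$contig, truth$contig[match(got$tag, truth$tag)])
})
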