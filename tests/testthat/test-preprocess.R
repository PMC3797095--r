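AD3 <- "TCGTATGCCGTCTTCTGCTTG"
AD5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

test_that("empty input yields empty output and zero stats", {
  res <- clean_reads(character(0), adapter3 = AD3)
  expect_identical(res$inserts, character(0))
  expect_identical(res$stats$input_reads, 0L)
  expect_true(all(res$stats$removed_by_reason == 0L))
})

test_that("each filter removes exactly its constructed violator", {
  ins22 <- rdna_fixed("ins22")
  reads <- c(
    clean      = paste0(ins22, AD3),
    no_ad3     = "ACGTACGTACGTACGTACGTACGTACGTAC",
    ad5_inside = paste0(substr(AD5, 1, 8), ins22, AD3),
    no_insert  = AD3,
    polyA      = paste0(strrep("A", 26), AD3),
    too_short  = paste0(substr(ins22, 1, 17), AD3),
    too_long   = paste0(ins22, rdna_fixed("extra9", 9L), AD3),
    with_N     = paste0(sub("G", "N", ins22), AD3))
  res <- clean_reads(unname(reads), adapter3 = AD3, adapter5 = AD5)
  expect_identical(res$inserts, ins22)
  r <- res$stats$removed_by_reason
  expect_identical(r[["no_adapter3"]], 1L)
  expect_identical(r[["adapter5_pollution"]], 1L)
  expect_identical(r[["no_insert"]], 1L)
  expect_identical(r[["polyA"]], 1L)
  expect_identical(r[["too_short"]], 1L)
  expect_identical(r[["too_long"]], 1L)
  expect_identical(r[["contains_N"]], 1L)
  expect_identical(res$stats$clean_reads + sum(r), res$stats$input_reads)
})

test_that("length window boundaries: 17 nt removed, 18 nt kept", {
  mk <- function(n) paste0(substr(rdna_fixed("lenwin"), 1, n), AD3)
  res <- clean_reads(c(mk(17), mk(18)), adapter3 = AD3)
  expect_identical(res$stats$removed_by_reason[["too_short"]], 1L)
  expect_identical(res$stats$clean_reads, 1L)
  expect_identical(nchar(res$inserts), 18L)
})

test_that("quality filter uses the >10% below Phred 20 rule", {
  seqs <- rep(paste0(rdna_fixed("q22"), AD3), 2)
  L <- nchar(seqs[1])
  good <- rep(38L, L)
  bad <- good
  bad[seq_len(ceiling(0.15 * L))] <- 5L
  res <- clean_reads(seqs, quals = list(good, bad), adapter3 = AD3)
  expect_identical(res$stats$removed_by_reason[["low_quality"]], 1L)
  expect_identical(res$stats$clean_reads, 1L)
})

test_that("conservation holds and cleaning clean inserts is a no-op", {
  set.seed(11)
  for (rep in 1:10) {
    reads <- vapply(sample(15:35, 30, replace = TRUE), function(L) {
      core <- rdna(L)
      if (runif(1) < 0.7) paste0(core, AD3) else core
    }, character(1))
    res <- clean_reads(reads, adapter3 = AD3, adapter5 = AD5)
    expect_identical(res$stats$clean_reads +
                       sum(res$stats$removed_by_reason),
                     res$stats$input_reads)
    again <- clean_reads(res$inserts, adapter3 = "", adapter5 = AD5)
    expect_identical(again$inserts, res$inserts)
    expect_identical(sum(again$stats$removed_by_reason), 0L)
  }
})

test_that("unknown symbols and malformed records fail loudly", {
  expect_error(clean_reads("ACGTXACGT", adapter3 = AD3), "unknown")
  expect_error(clean_reads("ACGT", quals = list(c(30L, 30L)),
                           adapter3 = AD3), "record 1")
})

test_that("collapse_unique counts, orders and round-trips", {
  # single read in NA only
  one <- collapse_unique("ACGTACGTACGTACGTACGT")
  expect_identical(one$count_na, 1L)
  expect_identical(one$count_da, 0L)
  # multiplicity and ordering
  s1 <- strrep("AC", 10); s2 <- strrep("GT", 10)
  tags <- collapse_unique(c(rep(s1, 3), rep(s2, 2)))
  expect_identical(tags$sequence, c(s1, s2))
  expect_identical(tags$count_na, c(3L, 2L))
  # shared sequence across libraries
  both <- collapse_unique(rep(s1, 2), rep(s1, 5))
  expect_identical(nrow(both), 1L)
  expect_identical(c(both$count_na, both$count_da), c(2L, 5L))
  # expand/collapse round trip
  set.seed(5)
  rt <- collapse_unique(replicate(40, rdna(sample(18:30, 1))),
                        replicate(25, rdna(sample(18:30, 1))))
  back <- collapse_unique(expand_tags(rt, "na"), expand_tags(rt, "da"))
  expect_identical(back, rt)
})

test_that("length_distribution is read-weighted and sums to 100", {
  t22 <- collapse_unique(rep(rdna(22), 4))
  expect_equal(length_distribution(t22, "na"), c("22" = 100))
  mix <- collapse_unique(c(rep(substr(rdna(30), 1, 21), 3),
                           substr(rdna(30), 1, 24)))
  d <- length_distribution(mix, "na")
  expect_equal(d[["21"]], 75)
  expect_equal(d[["24"]], 25)
  expect_equal(sum(d), 100, tolerance = 1e-9)
  expect_error(length_distribution(collapse_unique(rdna(22)), "da"),
               "no reads")
})

test_that("synthetic default library has a 22-nt mode", {
  sim <- small_sim()
  cl <- clean_reads(sim$libs$na$seq, adapter3 = sim$cfg$adapter3,
                    adapter5 = sim$cfg$adapter5)
  tags <- collapse_unique(cl$inserts)
  d <- length_distribution(tags, "na")
  expect_identical(names(d)[which.max(d)], "22")
})

test_that("FASTQ round trip preserves reads and qualities", {
  f <- tempfile(fileext = ".fastq")
  write_fastq(c("r1", "r2"), c("ACGTACGT", "GGGTTTAA"),
              c("IIIIIIII", "IIII####"), f)
  fq <- read_fastq(f)
  expect_identical(fq$id, c("r1", "r2"))
  expect_identical(fq$seq, c("ACGTACGT", "GGGTTTAA"))
  expect_identical(fq$qual[[2]], c(40L, 40L, 40L, 40L, 2L, 2L, 2L, 2L))
})
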