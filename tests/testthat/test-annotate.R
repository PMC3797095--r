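mk_tags <- function(seqs, na = 1L, da = 0L) {
  data.frame(sequence = seqs,
             count_na = rep(na, length.out = length(seqs)),
             count_da = rep(da, length.out = length(seqs)),
             stringsAsFactors = FALSE)
}

test_that("ncRNA classification is exact-substring with class priority", {
  rr <- rdna_fixed("rrna_ref", 120L)
  tag_rr <- substr(rr, 31, 52)               # 22-nt window of the rRNA
  shared <- rdna_fixed("shared", 20L)
  refs <- list(rRNA = c(r1 = rr),
               tRNA = c(t1 = paste0("AAAA", shared, "CCCC")),
               snRNA = c(s1 = paste0("GGGG", shared, "TTTT")))
  tags <- mk_tags(c(tag_rr, shared, rdna_fixed("nohit", 22L)))
  cls <- classify_ncrna(tags, refs)
  expect_identical(cls$category, c("rRNA", "tRNA", NA))
  expect_identical(cls$ref_id[1:2], c("r1", "t1"))
  expect_warning(classify_ncrna(tags, list(rRNA = character(0))), "empty")
})

test_that("known-miRNA matching: identity, precursor offset rule, fallback", {
  mat <- c("xxx-miR-1" = rdna_fixed("m1", 22L))
  prec <- c("xxx-mir-1-prec" = paste0(rdna_fixed("flank5", 20L), mat,
                                      rdna_fixed("flank3", 30L)))
  off1 <- substr(prec, 20, 41)   # starts 1 nt before the mature
  off3 <- substr(prec, 24, 45)   # starts 3 nt after: outside tolerance
  tags <- mk_tags(c(unname(mat), off1, off3, rdna_fixed("miss", 22L)))
  hits <- match_known_mirnas(tags, mat, prec)
  expect_setequal(hits$sequence, c(unname(mat), off1))
  expect_true(all(hits$mature_id == "xxx-miR-1"))
  # family map fallback strips species prefix and arm suffix
  expect_warning(
    h2 <- match_known_mirnas(mk_tags(unname(mat)),
                             c("xxx-miR-9-5p" = unname(mat)),
                             family_of = c(other = "x")),
    "missing from family map")
  expect_identical(h2$family, "miR-9")
})

test_that("temporary database picks highest expression, ties by id", {
  mat <- c(b_mir = rdna_fixed("fa", 22L), a_mir = rdna_fixed("fb", 22L),
           c_mir = rdna_fixed("fc", 22L))
  fam <- c(b_mir = "famA", a_mir = "famA", c_mir = "famB")
  tags <- mk_tags(unname(mat), na = c(120L, 80L, 50L), da = 0L)
  hits <- match_known_mirnas(tags, mat, family_of = fam)
  db <- build_temporary_db(hits, tags, mat)
  expect_identical(db$mature_id[db$family == "famA"], "b_mir")
  expect_identical(db$total_reads[db$family == "famA"], 120L)
  # tie: equal counts -> lexicographically smaller id
  tags2 <- mk_tags(unname(mat), na = c(50L, 50L, 7L), da = 0L)
  db2 <- build_temporary_db(match_known_mirnas(tags2, mat,
                                               family_of = fam),
                            tags2, mat)
  expect_identical(db2$mature_id[db2$family == "famA"], "a_mir")
  # single-member family
  expect_identical(db2$mature_id[db2$family == "famB"], "c_mir")
})

test_that("quantification sums assigned tags and breaks ties by id", {
  rep_seq <- rdna_fixed("repq", 24L)
  db <- data.frame(family = c("f1", "f2"),
                   mature_id = c("a_rep", "b_rep"),
                   sequence = c(rep_seq, rdna_fixed("repq2", 24L)),
                   total_reads = c(10L, 10L), stringsAsFactors = FALSE)
  t1 <- substr(rep_seq, 1, 22)
  t2 <- substr(rep_seq, 2, 23)
  tags <- mk_tags(c(t1, t2), na = c(3L, 2L), da = c(5L, 0L))
  q <- quantify_mirnas(tags, db)
  expect_identical(q$x[q$mature_id == "a_rep"], 5)
  expect_identical(q$y[q$mature_id == "a_rep"], 5)
  # unmatched representative reports zeros
  expect_identical(q$x[q$mature_id == "b_rep"], 0)
  # tag matching two representatives equally goes to the smaller id
  db$sequence[2] <- rep_seq
  q2 <- quantify_mirnas(mk_tags(t1, na = 4L), db)
  expect_identical(q2$x, c(4, 0))
})

test_that("annotation summary partitions tags and is order-invariant", {
  sim <- small_sim()
  cl_na <- clean_reads(sim$libs$na$seq, adapter3 = sim$cfg$adapter3,
                       adapter5 = sim$cfg$adapter5)
  tags <- collapse_unique(cl_na$inserts)
  tags <- utils::head(tags, 400L)
  refs <- sim$world$refs[c("rRNA", "tRNA", "snRNA", "snoRNA")]
  cls <- classify_ncrna(tags, refs)
  hits <- match_known_mirnas(tags[is.na(cls$category), , drop = FALSE],
                             sim$world$refs$mature,
                             family_of = sim$world$refs$family_of)
  category <- cls$category
  category[is.na(category) & tags$sequence %in% hits$sequence] <- "miRNA"
  s1 <- summarize_annotation(tags, category)
  # partition: category rows sum to the totals row
  cat_rows <- s1$category %in% c("miRNA", "rRNA", "tRNA", "snRNA",
                                 "snoRNA", "unann")
  for (cl in c("unique_na", "reads_na", "reads_da")) {
    expect_identical(sum(s1[[cl]][cat_rows]),
                     s1[[cl]][s1$category == "total"])
  }
  expect_identical(s1$reads_na[s1$category == "total"], sum(tags$count_na))
  # order invariance
  perm <- sample(nrow(tags))
  s2 <- summarize_annotation(tags[perm, ], category[perm])
  expect_identical(s1, s2)
})

test_that("mapping percentages reproduce the published table arithmetic", {
  t1 <- mapping_stats(table1())
  mirna <- t1[t1$category == "miRNA", ]
  expect_identical(mirna$pct_unique_na, 2.62)
  expect_identical(mirna$pct_unique_da, 2.91)
  expect_identical(mirna$pct_reads_na, 62.36)
  expect_identical(mirna$pct_reads_da, 59.99)
  expect_identical(t1$pct_reads_na[t1$category == "snoRNA"], 0)
})

test_that("substring matching agrees with a Biostrings oracle", {
  set.seed(31)
  refs <- list(rRNA = stats::setNames(replicate(4, rdna(300)),
                                      paste0("r", 1:4)))
  tags <- mk_tags(c(vapply(1:10, function(i) {
    r <- refs$rRNA[[sample(4, 1)]]
    s <- sample(270, 1)
    substr(r, s, s + 21)
  }, character(1)), replicate(10, rdna(22))))
  got <- classify_ncrna(tags, refs)
  oracle <- vapply(tags$sequence, function(tg) {
    any(vapply(refs$rRNA, function(r) {
      length(Biostrings::matchPattern(tg, Biostrings::DNAString(r))) > 0
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  expect_identical(!is.na(got$category), oracle)
})
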