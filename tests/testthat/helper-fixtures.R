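# Shared fixtures, all built in code. The synthetic world is generated once
# per test session at reduced depth (the generator's stated default is 1e6
# reads per library; tests use 2e4 for speed) and cached.

.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    cfg <- sim_config(seed = 42L, lib_size_na = 2e4, lib_size_da = 2e4)
    .fixture_cache$sim <- list(cfg = cfg, world = gen_references(cfg))
    .fixture_cache$sim$libs <- gen_libraries(cfg, .fixture_cache$sim$world)
  }
  .fixture_cache$sim
}

sim_dir <- function() {
  if (is.null(.fixture_cache$dir)) {
    d <- file.path(tempdir(), "aestimir_sim_fixture")
    simulate_dataset(small_sim()$cfg, d)
    .fixture_cache$dir <- d
  }
  .fixture_cache$dir
}

# independent reverse complement (no Biostrings), used by test oracles
rc_oracle <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTU", "TGCAA", toupper(s)), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# random DNA for fixtures
rdna <- function(len, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
        collapse = "")
}

# deterministic pseudo-random DNA keyed by a label (stable across runs)
rdna_fixed <- function(tag, len = 22L) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(sum(utf8ToInt(tag)) * 7L)
  rdna(len)
}

# published library totals (clean reads, NA and DA)
N1_PUB <- 10876248
N2_PUB <- 11194928

table2 <- function() {
  read_tsv(system.file("extdata", "table2_diffexpr.tsv",
                       package = "aestimir"))
}

table1 <- function() {
  read_tsv(system.file("extdata", "table1_mapping.tsv",
                       package = "aestimir"))
}
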