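## GO term over-representation of predicted target genes: one-sided
## hypergeometric test per term, BH FDR across tested terms. The term map
## is flat (no DAG ancestor propagation).

#' One-sided hypergeometric over-representation p-value
#'
#' Probability of observing `k` or more annotated genes in a draw of `n`
#' from a background of `N` genes of which `K` carry the term.
#'
#' @param k annotated genes among the targets.
#' @param n number of target genes tested.
#' @param K background genes carrying the term.
#' @param N background size.
#' @return p-value in (0, 1]; exactly 1 for `k = 0`.
#' @export
hypergeom_p <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0)) stop("counts must be non-negative")
  if (any(k > n) || any(n > N) || any(K > N) || any(k > K)) {
    stop("impossible configuration: need k <= min(n, K), n <= N, K <= N")
  }
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' GO term over-representation of a target gene set
#'
#' @param targets character vector of target gene ids (must be a subset of
#'   `background`).
#' @param background character vector of background gene ids (the universe;
#'   by convention all genes in the GO map).
#' @param go_map data.frame with columns `gene`, `term`.
#' @param term_names optional named character vector mapping term id to a
#'   human-readable name.
#' @param fdr_max FDR cutoff (default 0.05).
#' @param min_K minimum background genes per tested term (default 2;
#'   smaller terms are skipped).
#' @param all return all tested terms rather than only the significant
#'   ones.
#' @return data.frame with columns `term`, `name` (if supplied), `k`, `n`,
#'   `K`, `N`, `p`, `q`, `significant`, sorted by (q, p); only rows with
#'   `q < fdr_max` unless `all = TRUE`. Empty target set gives an empty
#'   result.
#' @export
enrich <- function(targets, background, go_map, term_names = NULL,
                   fdr_max = 0.05, min_K = 2L, all = FALSE) {
  targets <- unique(targets)
  background <- unique(background)
  if (!all(targets %in% background)) {
    stop("targets must be a subset of the background universe")
  }
  empty <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
  if (!length(targets)) return(empty)
  go_map <- go_map[go_map$gene %in% background, , drop = FALSE]
  go_map <- unique(go_map[, c("gene", "term")])
  N <- length(background)
  n <- length(targets)
  Kt <- table(go_map$term)
  terms <- names(Kt)[Kt >= min_K]
  if (!length(terms)) return(empty)
  kt <- table(factor(go_map$term[go_map$gene %in% targets], levels = terms))
  out <- data.frame(term = terms,
                    k = as.integer(kt[terms]),
                    n = n,
                    K = as.integer(Kt[terms]),
                    N = N, stringsAsFactors = FALSE)
  out$p <- hypergeom_p(out$k, out$n, out$K, out$N)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < fdr_max
  if (!is.null(term_names)) {
    out$name <- unname(term_names[out$term])
    out <- out[, c("term", "name", "k", "n", "K", "N", "p", "q",
                   "significant")]
  }
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  if (all) out else out[out$significant, , drop = FALSE]
}
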