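## Two-library digital differential expression: reads-per-million
## normalization, log2 fold change with the zero-substitution rule, the
## Audic-Claverie conditional count test on (x, y, N1, N2), BH FDR,
## threshold calling, and the dual-platform (sequencing vs microarray)
## intersection.

#' Reads-per-million normalization
#'
#' @param count read count(s), >= 0.
#' @param total library total clean reads, > 0.
#' @return `count / total * 1e6`.
#' @export
rpm <- function(count, total) {
  if (any(total <= 0)) stop("library total must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  count / total * 1e6
}

#' Log2 fold change (DA over NA) on RPM-normalized counts
#'
#' A zero RPM on either side is replaced by `zero_sub` (0.01 by
#' convention) before the ratio is taken.
#'
#' @param x,y read counts in the NA and DA libraries.
#' @param n1,n2 total clean reads of the NA and DA libraries.
#' @param zero_sub substitute for a zero normalized expression.
#' @return log2 fold change(s), vectorized over `x`, `y`.
#' @export
log2_fold_change <- function(x, y, n1, n2, zero_sub = 0.01) {
  if (any(x == 0 & y == 0)) stop("x and y must not both be zero")
  ra <- rpm(x, n1)
  rb <- rpm(y, n2)
  ra[ra == 0] <- zero_sub
  rb[rb == 0] <- zero_sub
  log2(rb / ra)
}

## log point mass of the Audic-Claverie conditional: given x in a library
## of total n1, the count y' in a library of total n2 follows
##   p(y'|x) = r^y' (x+y')! / (x! y'! (1+r)^(x+y'+1)),  r = n2/n1,
## i.e. a negative binomial with size x+1 and success probability n1/(n1+n2).
ac_log_pmf <- function(yp, x, logr, log1pr) {
  yp * logr + lgamma(x + yp + 1) - lgamma(x + 1) - lgamma(yp + 1) -
    (x + yp + 1) * log1pr
}

log_sum_exp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

ac_pvalue_scalar <- function(x, y, n1, n2, sided, rel_tol) {
  r <- n2 / n1
  logr <- log(n2) - log(n1)
  log1pr <- log1p(r)
  mean_y <- (x + 1) * r
  lower_side <- y <= mean_y
  if (lower_side) {
    lo <- exp(log_sum_exp(ac_log_pmf(0:y, x, logr, log1pr)))
    lo <- min(lo, 1)
    up <- 1 - lo
  } else {
    ## strict upper tail from y+1, summed in chunks until terms are
    ## negligible relative to the accumulated sum
    chunk <- 2048L
    from <- y + 1
    acc <- -Inf
    repeat {
      yp <- from:(from + chunk - 1L)
      lt <- ac_log_pmf(yp, x, logr, log1pr)
      acc <- log_sum_exp(c(acc, log_sum_exp(lt)))
      if (max(lt) < acc + log(rel_tol)) break
      from <- from + chunk
    }
    up <- min(exp(acc), 1)
    lo <- 1 - up
  }
  p <- switch(sided,
              two = 2 * min(lo, up),
              one = if (y / n2 > x / n1) up else lo)
  max(min(p, 1), .Machine$double.xmin)
}

#' Audic-Claverie two-library count test
#'
#' Exact conditional test of equal relative abundance of one tag between
#' two libraries with totals `n1` (NA) and `n2` (DA). Conditional on `x`,
#' the DA count follows `p(y'|x) = r^y' (x+y')! / (x! y'! (1+r)^(x+y'+1))`
#' with `r = n2/n1`. The default is the two-sided value
#' `2 * min(P(Y <= y), P(Y > y))` (capped at 1), which reproduces the
#' published two-library miRNA P-values; `sided = "one"` returns the single
#' tail away from the null expectation. Computed in log space; the upper
#' tail sum is truncated when terms fall below `rel_tol` relative to the
#' accumulated sum.
#'
#' @param x,y tag counts in the NA and DA libraries (vectorized).
#' @param n1,n2 library totals.
#' @param sided `"two"` (default) or `"one"`.
#' @param rel_tol relative truncation tolerance for the tail sum.
#' @return p-value(s) in (0, 1].
#' @export
ac_pvalue <- function(x, y, n1, n2, sided = c("two", "one"),
                      rel_tol = 1e-16) {
  sided <- match.arg(sided)
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (n1 <= 0 || n2 <= 0) stop("library totals must be positive")
  stopifnot(length(x) == length(y))
  vapply(seq_along(x), function(i)
    ac_pvalue_scalar(x[i], y[i], n1, n2, sided, rel_tol), numeric(1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, `q(i) = min_{j >= i} p(j) m / j` on the ranked
#' p-values, capped at 1 and order-preserving. `method = "BY"` applies the
#' Benjamini-Yekutieli variant.
#'
#' @param p p-values in (0, 1].
#' @param method `"BH"` (default) or `"BY"`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = method)
}

#' Score a two-library count table
#'
#' Computes RPM, log2 fold change, Audic-Claverie p and BH q for every row.
#'
#' @param ids row identifiers.
#' @param x,y counts in NA and DA.
#' @param n1,n2 library totals.
#' @param sided passed to [ac_pvalue()].
#' @return data.frame with columns `id`, `x`, `y`, `rpm_na`, `rpm_da`,
#'   `fc`, `p`, `q`.
#' @export
score_expression <- function(ids, x, y, n1, n2, sided = "two") {
  data.frame(id = ids, x = x, y = y,
             rpm_na = rpm(x, n1), rpm_da = rpm(y, n2),
             fc = log2_fold_change(x, y, n1, n2),
             p = ac_pvalue(x, y, n1, n2, sided = sided),
             q = bh_fdr(ac_pvalue(x, y, n1, n2, sided = sided)),
             stringsAsFactors = FALSE)
}

#' Call differential expression
#'
#' Rows with RPM below `exclude_below` in both libraries are excluded from
#' the analysis. A row is called up if its expression exceeds `expr_min` (in
#' at least one library, or in both with `require_both`), `fc >= fc_min`
#' and `q < fdr_max`; down symmetrically. The expression gate is applied to
#' RPM by default; `expr_on = "count"` applies it to the raw counts instead
#' (the convention evidently used for the published table, whose expression
#' columns are raw counts).
#'
#' @param rows data.frame from [score_expression()].
#' @param expr_min expression gate (default 10).
#' @param fc_min absolute log2 fold-change gate (default 1).
#' @param fdr_max FDR gate (default 0.01).
#' @param expr_on `"rpm"` or `"count"`.
#' @param require_both require the expression gate in both libraries.
#' @param exclude_below exclude rows with RPM below this in both libraries
#'   (default 1).
#' @return `rows` with a `call` column (`up`, `down`, `ns`, `excluded`);
#'   summary counts as attribute `"summary"`.
#' @export
call_differential <- function(rows, expr_min = 10, fc_min = 1,
                              fdr_max = 0.01,
                              expr_on = c("rpm", "count"),
                              require_both = FALSE, exclude_below = 1) {
  expr_on <- match.arg(expr_on)
  ea <- if (expr_on == "rpm") rows$rpm_na else rows$x
  eb <- if (expr_on == "rpm") rows$rpm_da else rows$y
  gate <- if (require_both) ea > expr_min & eb > expr_min else
    ea > expr_min | eb > expr_min
  excluded <- rows$rpm_na < exclude_below & rows$rpm_da < exclude_below
  call <- rep("ns", nrow(rows))
  call[gate & rows$fc >= fc_min & rows$q < fdr_max] <- "up"
  call[gate & rows$fc <= -fc_min & rows$q < fdr_max] <- "down"
  call[excluded] <- "excluded"
  rows$call <- call
  attr(rows, "summary") <- c(up = sum(call == "up"),
                             down = sum(call == "down"),
                             ns = sum(call == "ns"),
                             excluded = sum(call == "excluded"))
  rows
}

#' Intersect sequencing and microarray significance
#'
#' Microarray significance requires mean signal above `signal_min` in at
#' least one condition, `|fc| >= fc_min` and `q < fdr_max`. The
#' intersection keeps ids significant on both platforms with the same
#' fold-change sign; an id present on only one platform is not significant
#' on the other.
#'
#' @param seq_rows data.frame from [call_differential()] (columns `id`,
#'   `fc`, `call`).
#' @param array_rows data.frame with columns `id`, `signal_na`,
#'   `signal_da`, `fc`, `q`.
#' @param signal_min,fc_min,fdr_max microarray significance thresholds
#'   (defaults 500, 1, 0.01).
#' @return data.frame with columns `id`, `seq_fc`, `array_fc`,
#'   `direction`, one row per concordant id.
#' @export
intersect_platforms <- function(seq_rows, array_rows, signal_min = 500,
                                fc_min = 1, fdr_max = 0.01) {
  empty <- data.frame(id = character(0), seq_fc = numeric(0),
                      array_fc = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(array_rows) == 0L || nrow(seq_rows) == 0L) return(empty)
  seq_sig <- seq_rows[seq_rows$call %in% c("up", "down"), , drop = FALSE]
  a_sig <- array_rows[
    (array_rows$signal_na > signal_min | array_rows$signal_da > signal_min) &
      abs(array_rows$fc) >= fc_min & array_rows$q < fdr_max, , drop = FALSE]
  common <- intersect(unique(seq_sig$id), unique(a_sig$id))
  if (!length(common)) return(empty)
  sfc <- seq_sig$fc[match(common, seq_sig$id)]
  afc <- a_sig$fc[match(common, a_sig$id)]
  keep <- sign(sfc) == sign(afc)
  out <- data.frame(id = common[keep], seq_fc = sfc[keep],
                    array_fc = afc[keep],
                    direction = ifelse(sfc[keep] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
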