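## Stem-loop RT-qPCR relative quantification (2^-ddCt) with reference-gene
## normalization (5.8S rRNA in the source assay) and a one-way ANOVA group
## test. Amplification efficiency is fixed at exact doubling.

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged on the Ct scale per sample, then
#' `dCt = Ct_target - Ct_reference`, `ddCt = dCt - mean dCt of the
#' calibrator group`, and relative expression `2^-ddCt`. The geometric mean
#' of the calibrator group is 1 by construction.
#'
#' @param ct data.frame with columns `sample`, `group`, `target_ct`,
#'   `ref_ct` and optionally `rep` (technical replicate index).
#' @param calibrator name of the calibrator group.
#' @return data.frame with one row per sample: `sample`, `group`, `dct`,
#'   `ddct`, `rel_expr`.
#' @export
delta_delta_ct <- function(ct, calibrator) {
  need <- c("sample", "group", "target_ct", "ref_ct")
  stopifnot(all(need %in% names(ct)))
  if (any(is.na(ct$ref_ct))) {
    stop("missing reference Ct for sample(s): ",
         paste(unique(ct$sample[is.na(ct$ref_ct)]), collapse = ", "))
  }
  if (!calibrator %in% ct$group) stop("calibrator group not found")
  agg <- aggregate(cbind(target_ct, ref_ct) ~ sample + group, data = ct,
                   FUN = mean)
  agg$dct <- agg$target_ct - agg$ref_ct
  cal_mean <- mean(agg$dct[agg$group == calibrator])
  agg$ddct <- agg$dct - cal_mean
  agg$rel_expr <- 2^(-agg$ddct)
  out <- agg[order(agg$group, agg$sample),
             c("sample", "group", "dct", "ddct", "rel_expr")]
  rownames(out) <- NULL
  out
}

#' One-way ANOVA on relative expressions
#'
#' Standard between/within sum-of-squares decomposition; with two groups
#' the F statistic equals the square of the pooled-variance t statistic.
#'
#' @param values numeric vector of relative expressions.
#' @param groups group labels, parallel to `values` (>= 2 groups, >= 2
#'   samples per group).
#' @return list with `f`, `p`, `df` (between, within) and `stars`
#'   (`"**"` p < 0.01, `"*"` p < 0.05, `""` otherwise).
#' @export
group_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("need at least 2 samples per group")
  gm <- tapply(values, groups, mean)
  n_g <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(n_g * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  dfb <- nlevels(groups) - 1L
  dfw <- length(values) - nlevels(groups)
  if (ssb == 0) {
    f <- 0; p <- 1
  } else if (ssw == 0) {
    warning("zero within-group variance; p reported as 0")
    f <- Inf; p <- 0
  } else {
    f <- (ssb / dfb) / (ssw / dfw)
    p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  }
  stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(f = f, p = p, df = c(between = dfb, within = dfw), stars = stars)
}

#' Group summary of a 2^-ddCt analysis
#'
#' @param rel data.frame from [delta_delta_ct()].
#' @return data.frame with per-group mean and sd of relative expression;
#'   the ANOVA result is attached as attribute `"test"`.
#' @export
qpcr_summary <- function(rel) {
  sm <- aggregate(rel_expr ~ group, data = rel,
                  FUN = function(v) c(mean = mean(v), sd = sd(v)))
  out <- data.frame(group = sm$group,
                    mean = sm$rel_expr[, "mean"],
                    sd = sm$rel_expr[, "sd"], stringsAsFactors = FALSE)
  attr(out, "test") <- group_test(rel$rel_expr, rel$group)
  out
}
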