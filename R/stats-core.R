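#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom, as
#' used to compare synonymous divergence between a candidate stratum and the
#' remaining genes. Degenerate inputs (zero variance in both samples) are
#' flagged rather than erroring, so that exhaustive span scans never abort.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A list with `t`, `df`, `p` (two-sided), `p_less`, `p_greater`
#'   (one-sided, alternative mean(x) < / > mean(y)), and `degenerate`
#'   (TRUE when both samples have zero variance).
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    # no within-sample variance: the test statistic is undefined
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (equal) 0 else sign(mean(x) - mean(y)) * Inf,
                df = NA_real_,
                p = if (equal) 1 else 0,
                p_less = if (equal) 1 else if (mean(x) < mean(y)) 0 else 1,
                p_greater = if (equal) 1 else if (mean(x) > mean(y)) 0 else 1,
                degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       p_less = stats::pt(unname(ht$statistic), unname(ht$parameter)),
       p_greater = stats::pt(unname(ht$statistic), unname(ht$parameter),
                             lower.tail = FALSE),
       degenerate = FALSE)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact for small tie-free samples, normal approximation with tie
#' correction otherwise; reports the W statistic alongside the p-value.
#'
#' @param x,y Numeric vectors.
#' @param side One of `"two.sided"`, `"less"` (x tends below y), `"greater"`.
#' @return List with `W` and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y, side = c("two.sided", "less", "greater")) {
  side <- match.arg(side)
  exact <- min(length(x), length(y)) <= 10 && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = side, exact = exact, correct = !exact))
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' @param table 2x2 matrix of counts.
#' @param continuity Apply the Yates continuity correction (default TRUE).
#' @return A `contingency_result` list: `statistic`, `df`, `p`, `corrected`.
#' @examples
#' chi2_2x2(matrix(c(374, 209, 417, 490), nrow = 2))
#' @export
chi2_2x2 <- function(table, continuity = TRUE) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  ht <- suppressWarnings(stats::chisq.test(table, correct = continuity))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = ht$p.value,
                 corrected = continuity),
            class = "contingency_result")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-values follow the probability-mass rule: the sum over tables
#' whose hypergeometric probability does not exceed that of the observed
#' table.
#'
#' @param table 2x2 matrix of counts.
#' @param side `"two.sided"`, `"less"` or `"greater"` (odds ratio).
#' @return The p-value.
#' @export
fisher_exact_2x2 <- function(table, side = c("two.sided", "less", "greater")) {
  side <- match.arg(side)
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  stats::fisher.test(table, alternative = side)$p.value
}

#' McDonald-Kreitman test
#'
#' Contrasts the nonsynonymous:synonymous ratio of fixed differences between
#' groups with that of polymorphisms within a group. An excess of
#' nonsynonymous fixed differences (neutrality index < 1) is the signature
#' of relaxed purifying selection on the non-recombining haplotype.
#'
#' @param fixed_n,fixed_s Counts of nonsynonymous / synonymous fixed
#'   differences.
#' @param poly_n,poly_s Counts of nonsynonymous / synonymous polymorphisms.
#' @param continuity Yates correction flag passed to [chi2_2x2()].
#' @return A `contingency_result` with an extra `neutrality_index` element,
#'   NI = (poly_n/poly_s) / (fixed_n/fixed_s).
#' @examples
#' mk_test(374, 417, 209, 490)
#' @export
mk_test <- function(fixed_n, fixed_s, poly_n, poly_s, continuity = TRUE) {
  res <- chi2_2x2(matrix(c(fixed_n, poly_n, fixed_s, poly_s), nrow = 2),
                  continuity = continuity)
  ni <- if (fixed_n > 0 && fixed_s > 0 && poly_s > 0)
    (poly_n / poly_s) / (fixed_n / fixed_s) else NA_real_
  res$neutrality_index <- ni
  res$table <- matrix(c(fixed_n, poly_n, fixed_s, poly_s), nrow = 2,
                      dimnames = list(c("fixed", "polymorphic"),
                                      c("nonsynonymous", "synonymous")))
  res
}

#' Chi-squared test of count enrichment in a genomic region
#'
#' Goodness-of-fit of observed counts inside/outside a region against
#' expectations proportional to the region sizes, df = 1. Used to test
#' whether fixed differences are enriched in the supergene region given the
#' fraction of the mapped assembly it occupies.
#'
#' @param count_in,count_out Observed counts inside and outside the region.
#' @param size_in,size_out Sizes (bp) of the region and its complement.
#' @return A `contingency_result`.
#' @export
density_enrichment_chi2 <- function(count_in, count_out, size_in, size_out) {
  stopifnot(count_in >= 0, count_out >= 0, size_in > 0, size_out > 0)
  ht <- suppressWarnings(stats::chisq.test(
    c(count_in, count_out),
    p = c(size_in, size_out) / (size_in + size_out)))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = ht$p.value,
                 corrected = FALSE),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("chi-squared = %.4g, df = %d, p = %.4g%s\n",
              x$statistic, as.integer(x$df), x$p,
              if (isTRUE(x$corrected)) " (continuity-corrected)" else ""))
  if (!is.null(x$neutrality_index))
    cat(sprintf("neutrality index = %.4g\n", x$neutrality_index))
  invisible(x)
}
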