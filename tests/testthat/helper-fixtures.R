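# Small in-code fixtures shared across test files.

# Variant table from a genotype matrix (rows = sites, cols = samples);
# quality annotations all passing unless overridden.
make_test_vt <- function(gt, scaffold = "s1", pos = NULL, class = "snp",
                         ref = "A", alt = "T", site_conf = 99,
                         gt_conf = 99, cov = 10) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  sites <- data.frame(scaffold = rep_len(scaffold, n), pos = pos,
                      ref = rep_len(ref, n), alt = rep_len(alt, n),
                      class = rep_len(class, n),
                      site_conf = rep_len(site_conf, n),
                      stringsAsFactors = FALSE)
  cf <- matrix(rep_len(gt_conf, n * ncol(gt)), n)
  cv <- matrix(rep_len(cov, n * ncol(gt)), n)
  default_names <- if (ncol(gt) %% 2 == 0)
    c(paste0("SB", seq_len(ncol(gt) / 2)), paste0("Sb", seq_len(ncol(gt) / 2)))
  else paste0("smp", seq_len(ncol(gt)))
  variant_table(sites, gt, cf, cv, samples = colnames(gt) %||% default_names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standard 8 + 8 sample sheet (first sample of each group high-coverage).
make_test_ss <- function(m = 8) {
  sample_set(c(paste0("SB", 1:m), paste0("Sb", 1:m)),
             group = rep(c("SB", "Sb"), each = m),
             coverage = rep(c("high", rep("low", m - 1)), 2),
             pair = rep(1:m, 2))
}

# Independent FST oracle: per-site, per-allele one-way ANOVA via lm(),
# variance components assembled from the printed ANOVA table.
oracle_fst <- function(gt, groups) {
  num <- 0; den <- 0
  g <- factor(groups)
  n_i <- table(g); n <- sum(n_i)
  nc <- (n - sum(n_i^2) / n) / (length(n_i) - 1)
  for (s in seq_len(nrow(gt))) {
    row <- gt[s, ]
    for (al in unique(row)) {
      y <- as.numeric(row == al)
      tab <- suppressWarnings(stats::anova(stats::lm(y ~ g)))
      msb <- tab$`Mean Sq`[1]; msw <- tab$`Mean Sq`[2]
      a <- (msb - msw) / nc
      num <- num + a
      den <- den + a + msw
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Enumeration oracle for Fisher's exact two-sided p (probability-mass rule).
oracle_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  k_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(k_range, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Direct-arithmetic Pearson chi-squared on a 2x2 table.
oracle_chi2 <- function(tab, yates = FALSE) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  d <- abs(tab - e)
  if (yates) d <- pmax(d - 0.5, 0)
  sum(d^2 / e)
}
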