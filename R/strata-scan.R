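#' Scan for a contiguous low-divergence gene span
#'
#' Evaluates every contiguous span of at least `min_span` genes (and at
#' most G-2, so the complement keeps a variance) with a two-sided Welch
#' t-test of the span's per-gene divergence against all other genes, and
#' returns the span minimising the p-value among spans whose mean is lower
#' than their complement's — the candidate "young stratum". Spans with
#' zero variance on both sides and equal means score p = 1; when no span
#' has a lower mean than its complement the result is flagged `none` with
#' observed p = 1.
#'
#' @param values Per-gene divergence in map order (e.g. dS, or fixed
#'   differences per coding bp).
#' @param min_span Minimum number of neighbouring genes (default 30).
#' @param max_span Maximum span length; the default leaves at least
#'   `min_span` genes in the complement (never more than G - 2), so the
#'   complement variance is estimated from a reasonable number of genes —
#'   unbounded spans let near-degenerate two-gene complements produce
#'   astronomically small p-values that drown any genuine stratum.
#' @param return_table Also return the per-span p table.
#' @return List with `best` (`start`, `length`, `span_mean`, `comp_mean`,
#'   `t`, `df`, `p`; NULL when none qualifies), `min_p` (observed minimum,
#'   1 when none qualifies), and optionally `table`.
#' @export
scan_min_p <- function(values, min_span = 30, max_span = NULL,
                       return_table = FALSE) {
  g <- length(values)
  if (g < min_span + 2)
    stop("need at least min_span + 2 genes, got ", g)
  if (is.null(max_span)) max_span <- max(min_span, g - min_span)
  max_span <- min(max_span, g - 2)
  geom <- span_geometry(g, min_span, max_span)
  out <- scan_core(values, geom)
  if (return_table) {
    sp <- scan_core(values, geom, full = TRUE)
    out$table <- data.frame(start = geom$st, length = geom$ll,
                            span_mean = sp$m1, comp_mean = sp$m2,
                            t = sp$t, df = sp$df, p = sp$p)
  }
  out
}

# Enumeration of all contiguous spans of length min_span..max_span
# (cached: the same geometry is reused across thousands of null scans).
span_geometry <- local({
  cache <- new.env(parent = emptyenv())
  function(g, min_span, max_span) {
    key <- paste(g, min_span, max_span)
    if (!is.null(cache[[key]])) return(cache[[key]])
    lens <- min_span:max_span
    ll <- rep(lens, times = g - lens + 1L)
    st <- unlist(lapply(lens, function(L) seq_len(g - L + 1L)))
    cache[[key]] <- list(g = g, st = st, ll = ll)
    cache[[key]]
  }
})

# Vectorised Welch t over the enumerated spans; the expensive p-value
# transform is applied only to qualifying spans (span mean below the
# complement mean) unless the full table is requested.
scan_core <- function(x, geom, full = FALSE) {
  g <- geom$g; st <- geom$st; ll <- geom$ll
  s1 <- cumsum(c(0, x)); s2 <- cumsum(c(0, x^2))
  sum_in <- s1[st + ll] - s1[st]
  ssq_in <- s2[st + ll] - s2[st]
  n1 <- ll; n2 <- g - ll
  sum_out <- s1[g + 1] - sum_in
  ssq_out <- s2[g + 1] - ssq_in
  m1 <- sum_in / n1; m2 <- sum_out / n2
  welch_p <- function(idx) {
    v1 <- pmax(0, (ssq_in[idx] - sum_in[idx]^2 / n1[idx]) / (n1[idx] - 1))
    v2 <- pmax(0, (ssq_out[idx] - sum_out[idx]^2 / n2[idx]) / (n2[idx] - 1))
    se2 <- v1 / n1[idx] + v2 / n2[idx]
    t <- ifelse(se2 > 0, (m1[idx] - m2[idx]) / sqrt(se2), NA_real_)
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1[idx])^2 / (n1[idx] - 1) +
                            (v2 / n2[idx])^2 / (n2[idx] - 1)),
                 NA_real_)
    p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t), df),
                ifelse(abs(m1[idx] - m2[idx]) < .Machine$double.eps^0.5,
                       1, 0))
    list(t = t, df = df, p = p)
  }
  if (full) {
    w <- welch_p(seq_along(st))
    return(list(m1 = m1, m2 = m2, t = w$t, df = w$df, p = w$p))
  }
  qual <- which(m1 < m2)
  out <- list(best = NULL, min_p = 1)
  if (length(qual)) {
    w <- welch_p(qual)
    i <- which.min(w$p)
    k <- qual[i]
    out$best <- list(start = st[k], length = ll[k], span_mean = m1[k],
                     comp_mean = m2[k], t = w$t[i], df = w$df[i], p = w$p[i])
    out$min_p <- w$p[i]
  }
  out
}

#' Poisson null substitution counts
#'
#' Simulates per-gene substitution counts under uniform random
#' differentiation: counts[g] ~ Poisson(rate * length[g]), independent
#' across genes and simulations. The default rate of one substitution per
#' 3000 coding bp matches the observed genome-wide level in the motivating
#' system.
#'
#' @param lengths Per-gene coding lengths (bp) in map order.
#' @param rate Substitutions per coding bp (default 1/3000).
#' @param n_sims Number of simulated data sets (default 10000).
#' @param seed Optional seed for reproducibility.
#' @return Integer matrix (`n_sims` x genes) of substitution counts.
#' @export
simulate_null <- function(lengths, rate = 1 / 3000, n_sims = 10000,
                          seed = NULL) {
  stopifnot(rate >= 0, n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rpois(n_sims * length(lengths), lambda = rate * lengths),
         nrow = n_sims, byrow = TRUE)
}

#' Empirical p-value of the observed scan statistic
#'
#' Fraction of null simulations whose minimum scan p-value is at least as
#' strong as (smaller than or equal to, ties inclusive) the observed one.
#'
#' @param observed_min_p Observed minimum Welch p from [scan_min_p()].
#' @param null_min_ps Vector of per-simulation minimum p-values.
#' @return Fraction in \[0, 1\].
#' @export
empirical_p <- function(observed_min_p, null_min_ps) {
  mean(null_min_ps <= observed_min_p)
}

#' Full evolutionary-strata test
#'
#' Runs the span scan on the observed per-gene substitution rates, then
#' repeats it on Poisson-simulated data sets at the global substitution
#' rate, and reports how often the simulated scan statistic is at least as
#' strong as the observed one. Observed data and null are scanned on the
#' same per-bp rate scale (count / coding length).
#'
#' @param counts Observed per-gene substitution (fixed-difference) counts
#'   in map order; alternatively supply `values` directly.
#' @param lengths Per-gene coding lengths (bp).
#' @param values Optional per-gene rates to scan instead of
#'   `counts / lengths` (e.g. dS).
#' @param rate Null substitution rate per coding bp (default 1/3000).
#' @param min_span Minimum span (default 30).
#' @param max_span Maximum span (default as in [scan_min_p()]).
#' @param n_sims Number of null simulations (default 10000).
#' @param seed Seed for the null simulations.
#' @return List of class `strata_scan_result`: `best`, `observed_p`
#'   (minimum Welch p), `empirical_p`, `null_min_ps`, `n_sims`, `seed`.
#' @export
strata_test <- function(counts = NULL, lengths, values = NULL,
                        rate = 1 / 3000, min_span = 30, max_span = NULL,
                        n_sims = 10000, seed = NULL) {
  if (is.null(values)) {
    stopifnot(length(counts) == length(lengths))
    values <- counts / lengths
  }
  obs <- scan_min_p(values, min_span = min_span, max_span = max_span)
  null_counts <- simulate_null(lengths, rate = rate, n_sims = n_sims,
                               seed = seed)
  null_rates <- sweep(null_counts, 2L, lengths, "/")
  null_min_ps <- apply(null_rates, 1L, function(v)
    scan_min_p(v, min_span = min_span, max_span = max_span)$min_p)
  structure(list(best = obs$best, observed_p = obs$min_p,
                 empirical_p = empirical_p(obs$min_p, null_min_ps),
                 null_min_ps = null_min_ps, n_sims = n_sims, seed = seed),
            class = "strata_scan_result")
}

#' @export
print.strata_scan_result <- function(x, ...) {
  if (is.null(x$best)) {
    cat("strata scan: no span with mean below its complement\n")
  } else {
    cat(sprintf(
      "strata scan: best span genes %d-%d (mean %.3g vs %.3g), Welch p = %.3g\n",
      x$best$start, x$best$start + x$best$length - 1L,
      x$best$span_mean, x$best$comp_mean, x$best$p))
  }
  cat(sprintf("empirical p = %.4g (%d of %d simulations as strong)\n",
              x$empirical_p, round(x$empirical_p * x$n_sims), x$n_sims))
  invisible(x)
}

#' Ranked non-overlap inspection of candidate strata
#'
#' Sorts per-gene (or per-window) divergence values and checks whether
#' the value ranges of candidate groups are disjoint — true strata should
#' occupy non-overlapping ranges of divergence when ranked.
#'
#' @param values Numeric divergence values.
#' @param groups Group label per value (e.g. candidate stratum membership).
#' @return List with `table` (values sorted with labels), `ranges`
#'   (per-group min/max) and `nonoverlapping` (TRUE when all group ranges
#'   are pairwise disjoint; FALSE with fewer than two groups).
#' @export
rank_strata_check <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  ord <- order(values)
  tab <- data.frame(rank = seq_along(values), value = values[ord],
                    group = groups[ord])
  gl <- unique(groups)
  rng <- do.call(rbind, lapply(gl, function(g) data.frame(
    group = g, min = min(values[groups == g]), max = max(values[groups == g]))))
  nonov <- FALSE
  if (length(gl) >= 2) {
    nonov <- TRUE
    for (i in seq_along(gl)) for (j in seq_along(gl)) if (j > i) {
      if (rng$min[j] <= rng$max[i] && rng$min[i] <= rng$max[j])
        nonov <- FALSE
    }
  }
  list(table = tab, ranges = rng, nonoverlapping = nonov)
}
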