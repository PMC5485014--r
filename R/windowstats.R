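#' Sliding windows over non-N sequence
#'
#' Windows are defined in the space of assembled (non-N) positions: each
#' window spans exactly `size` non-N bases and successive windows start
#' `step` non-N bases apart, so a window overlapping an assembly gap
#' stretches further in physical coordinates. A terminal window covering
#' fewer than `size` non-N bases is flagged `partial`.
#'
#' @param seqs Named character vector or `Biostrings::DNAStringSet` of
#'   reference sequences.
#' @param size,step Window size and step in non-N bp; `size >= step >= 1`.
#' @return data.frame with columns `scaffold`, `start`, `end` (1-based
#'   physical coordinates), `accessible` (non-N bases covered), `partial`.
#' @examples
#' make_windows(c(s = strrep("A", 100)), size = 30, step = 10)
#' @export
make_windows <- function(seqs, size, step) {
  stopifnot(size >= step, step >= 1)
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  stopifnot(!is.null(names(seqs)))
  res <- lapply(names(seqs), function(sc) {
    chars <- strsplit(seqs[[sc]], "", fixed = TRUE)[[1]]
    nn <- which(chars != "N" & chars != "n")
    k <- length(nn)
    if (k == 0L) return(NULL)
    starts <- seq.int(1L, k, by = step)
    full <- starts + size - 1L <= k
    # keep all full windows plus, when they do not reach the sequence end,
    # the first trailing start as a flagged terminal partial
    covered <- any(full) && max(starts[full]) + size - 1L == k
    if (any(!full) && !covered) starts <- c(starts[full], starts[!full][1])
    else starts <- starts[full]
    ends <- pmin(starts + size - 1L, k)
    acc <- ends - starts + 1L
    data.frame(scaffold = sc, start = nn[starts], end = nn[ends],
               accessible = acc, partial = acc < size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), accessible = integer(),
                      partial = logical())
  rownames(out) <- NULL
  out
}

# Per-site haploid variance components (two groups).
# Returns a data.frame with columns a (among-group) and b (within-group),
# summed over alleles at each site; NA rows mark skipped sites (a group
# with fewer than two called samples).
fst_site_components <- function(gt, group_a_idx, group_b_idx) {
  ga <- gt[, group_a_idx, drop = FALSE]
  gb <- gt[, group_b_idx, drop = FALSE]
  n1 <- rowSums(!is.na(ga)); n2 <- rowSums(!is.na(gb))
  n <- n1 + n2
  ok <- n1 >= 2 & n2 >= 2
  nsite <- nrow(gt)
  a <- rep(NA_real_, nsite); b <- rep(NA_real_, nsite)
  if (!any(ok)) return(data.frame(a = a, b = b))
  nc <- (n - (n1^2 + n2^2) / n)            # r - 1 = 1
  max_allele <- suppressWarnings(max(gt, na.rm = TRUE))
  ssb <- numeric(nsite); ssw <- numeric(nsite)
  for (al in 0:max_allele) {
    c1 <- rowSums(ga == al, na.rm = TRUE)
    c2 <- rowSums(gb == al, na.rm = TRUE)
    p1 <- ifelse(n1 > 0, c1 / n1, 0)
    p2 <- ifelse(n2 > 0, c2 / n2, 0)
    pbar <- (c1 + c2) / n
    ssb <- ssb + n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
    ssw <- ssw + n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)
  }
  msb <- ssb                               # / (r - 1)
  msw <- ssw / (n - 2)
  a[ok] <- ((msb - msw) / nc)[ok]
  b[ok] <- msw[ok]
  data.frame(a = a, b = b)
}

#' Multilocus FST between two groups of haploids
#'
#' Two-level variance-components estimator (Weir-Cockerham style) on
#' haploid allele indicators, combined across sites as a ratio of sums:
#' FST = sum(a) / sum(a + b), where a and b are the among-group and
#' within-group components. Sites monomorphic across all called samples
#' contribute nothing; the estimate is undefined (NA) when the denominator
#' is zero, and may be negative when within-group differentiation exceeds
#' between-group differentiation (as with paired full brothers split
#' across groups).
#'
#' @param vt A [variant_table()]; pass a windowed subset for window scans.
#' @param ss A [sample_set()].
#' @param window Optional `list(scaffold=, start=, end=)` or single-row
#'   window data.frame restricting the sites used.
#' @return FST (scalar; NA when undefined).
#' @export
multilocus_fst <- function(vt, ss, window = NULL) {
  if (!is.null(window)) vt <- vt_window_subset(vt, window)
  if (nrow(vt$sites) == 0L) return(NA_real_)
  gl <- group_levels(ss)
  comp <- fst_site_components(vt$gt,
                              match(group_samples(ss, gl[1]), vt$samples),
                              match(group_samples(ss, gl[2]), vt$samples))
  num <- sum(comp$a, na.rm = TRUE)
  den <- sum(comp$a + comp$b, na.rm = TRUE)
  if (all(is.na(comp$a)) || den == 0) return(NA_real_)
  num / den
}

vt_window_subset <- function(vt, window) {
  w <- as.list(window)
  keep <- vt$sites$scaffold == w$scaffold &
    vt$sites$pos >= w$start & vt$sites$pos <= w$end
  vt_subset(vt, keep)
}

#' Nucleotide diversity (Nei's pi) within a group
#'
#' Per-site heterozygosity with the small-sample correction,
#' `(n/(n-1)) * (1 - sum(p_i^2))`, summed over variant sites and divided
#' by the number of accessible (non-N) bases, which equals the mean
#' per-base pairwise difference between sequences in the group. Sites with
#' fewer than two called samples in the group are skipped.
#'
#' @param vt A [variant_table()] (already filtered per-group if desired).
#' @param ss A [sample_set()].
#' @param group Group label to compute within.
#' @param accessible Number of non-N bases the sites were drawn from.
#' @param window Optional window restriction as in [multilocus_fst()].
#' @return Diversity per accessible bp.
#' @export
nucleotide_diversity <- function(vt, ss, group, accessible, window = NULL) {
  stopifnot(accessible > 0)
  if (!is.null(window)) vt <- vt_window_subset(vt, window)
  sum(site_heterozygosity(vt, ss, group)) / accessible
}

site_heterozygosity <- function(vt, ss, group) {
  idx <- match(group_samples(ss, group), vt$samples)
  g <- vt$gt[, idx, drop = FALSE]
  n <- rowSums(!is.na(g))
  if (nrow(g) == 0L) return(numeric(0))
  max_allele <- suppressWarnings(max(g, na.rm = TRUE))
  if (!is.finite(max_allele)) return(numeric(0))
  sump2 <- numeric(nrow(g))
  for (al in 0:max_allele) {
    p <- ifelse(n > 0, rowSums(g == al, na.rm = TRUE) / n, 0)
    sump2 <- sump2 + p^2
  }
  h <- ifelse(n >= 2, n / (n - 1) * (1 - sump2), 0)
  h
}

#' Fixed differences between the two groups
#'
#' A site is a fixed difference when every called sample of one group
#' carries one allele, every called sample of the other group carries a
#' different allele, and both groups are fully called (the filtering
#' contract guarantees complete calls for retained sites).
#'
#' @inheritParams multilocus_fst
#' @return List with `snp` and `indel` counts and `sites` (row indices of
#'   the input table).
#' @export
fixed_differences <- function(vt, ss, window = NULL) {
  if (!is.null(window)) vt <- vt_window_subset(vt, window)
  gl <- group_levels(ss)
  ia <- match(group_samples(ss, gl[1]), vt$samples)
  ib <- match(group_samples(ss, gl[2]), vt$samples)
  ga <- vt$gt[, ia, drop = FALSE]; gb <- vt$gt[, ib, drop = FALSE]
  mono_a <- rowSums(!is.na(ga)) == length(ia) &
    apply(ga, 1L, function(x) length(unique(x)) == 1L)
  mono_b <- rowSums(!is.na(gb)) == length(ib) &
    apply(gb, 1L, function(x) length(unique(x)) == 1L)
  fixed <- mono_a & mono_b & ga[, 1L] != gb[, 1L]
  fixed[is.na(fixed)] <- FALSE
  list(snp = sum(fixed & vt$sites$class == "snp"),
       indel = sum(fixed & vt$sites$class == "indel"),
       sites = which(fixed))
}

#' Fixed differences at STR loci
#'
#' The fixed-difference rule applied to repeat-unit genotypes: a locus
#' counts when all samples of one group share one unit count, all samples
#' of the other group share a different one. Reports the absolute
#' difference in repeat units per qualifying locus.
#'
#' @param st An [str_table()].
#' @param ss A [sample_set()].
#' @return data.frame of qualifying loci with `unit_diff`.
#' @export
str_fixed_differences <- function(st, ss) {
  gl <- group_levels(ss)
  ia <- match(group_samples(ss, gl[1]), st$samples)
  ib <- match(group_samples(ss, gl[2]), st$samples)
  ua <- st$units[, ia, drop = FALSE]; ub <- st$units[, ib, drop = FALSE]
  mono <- function(m) rowSums(!is.na(m)) == ncol(m) &
    apply(m, 1L, function(x) length(unique(x)) == 1L)
  fixed <- mono(ua) & mono(ub) & ua[, 1L] != ub[, 1L]
  fixed[is.na(fixed)] <- FALSE
  out <- st$loci[fixed, c("locus_id", "scaffold", "pos"), drop = FALSE]
  out$unit_diff <- abs(ua[fixed, 1L] - ub[fixed, 1L])
  rownames(out) <- NULL
  out
}

#' Euclidean genotype distances and clustering
#'
#' Pairwise distances between haploid genotype vectors (sqrt of the number
#' of differing sites, i.e. the Euclidean norm over allele codes at
#' biallelic sites) and an average-linkage dendrogram, as used to display
#' relationships among samples at sites variable within a group.
#'
#' @param vt A [variant_table()].
#' @param samples Samples to include (default all).
#' @return List with `dist` (a `dist` object) and `hclust` (average
#'   linkage; NULL when fewer than 2 samples).
#' @export
genotype_distance_matrix <- function(vt, samples = vt$samples) {
  g <- vt$gt[, match(samples, vt$samples), drop = FALSE]
  ns <- ncol(g)
  d <- matrix(0, ns, ns, dimnames = list(samples, samples))
  for (i in seq_len(ns)) for (j in seq_len(ns)) if (j > i) {
    k <- sum(g[, i] != g[, j], na.rm = TRUE)
    d[i, j] <- d[j, i] <- sqrt(k)
  }
  dd <- stats::as.dist(d)
  list(dist = dd,
       hclust = if (ns >= 2) stats::hclust(dd, method = "average") else NULL)
}

#' Per-window differentiation and diversity statistics
#'
#' Computes, for each window, multilocus FST and fixed-difference counts
#' from the whole-set-filtered table and per-group nucleotide diversity
#' from the per-group-filtered tables (quality filters are applied
#' separately per group so one group's call quality does not affect the
#' other's diversity estimate).
#'
#' @param windows Output of [make_windows()].
#' @param vt Whole-set-filtered [variant_table()].
#' @param ss A [sample_set()].
#' @param vt_a,vt_b Per-group-filtered tables for the first and second
#'   group level (default: `vt`).
#' @return `windows` with columns `fst`, `pi_a`, `pi_b`, `fixed_snps`,
#'   `fixed_indels`, `n_var_a`, `n_var_b` appended.
#' @export
window_stats <- function(windows, vt, ss, vt_a = vt, vt_b = vt) {
  gl <- group_levels(ss)
  n <- nrow(windows)
  fst <- pi_a <- pi_b <- rep(NA_real_, n)
  fx_s <- fx_i <- nv_a <- nv_b <- integer(n)
  for (i in seq_len(n)) {
    w <- windows[i, ]
    wvt <- vt_window_subset(vt, w)
    fst[i] <- multilocus_fst(wvt, ss)
    fd <- fixed_differences(wvt, ss)
    fx_s[i] <- fd$snp; fx_i[i] <- fd$indel
    wa <- vt_window_subset(vt_a, w); wb <- vt_window_subset(vt_b, w)
    ha <- site_heterozygosity(wa, ss, gl[1])
    hb <- site_heterozygosity(wb, ss, gl[2])
    pi_a[i] <- sum(ha) / w$accessible
    pi_b[i] <- sum(hb) / w$accessible
    nv_a[i] <- sum(ha > 0); nv_b[i] <- sum(hb > 0)
  }
  cbind(windows,
        data.frame(fst = fst, pi_a = pi_a, pi_b = pi_b,
                   fixed_snps = fx_s, fixed_indels = fx_i,
                   n_var_a = nv_a, n_var_b = nv_b))
}
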