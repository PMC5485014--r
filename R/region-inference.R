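#' Call candidate supergene region(s) from window statistics
#'
#' Finds maximal runs of at least `min_run` consecutive windows whose FST
#' exceeds the threshold; windows with undefined FST break runs. Pass a
#' non-overlapping tiling (window size equal to step) so "consecutive"
#' windows are also non-overlapping. Runs are returned ranked by physical
#' span.
#'
#' @param ws Window-statistics data.frame from [window_stats()], sorted by
#'   coordinate within each scaffold or linkage group.
#' @param fst_threshold FST cutoff (exclusive; default 0.25, the level
#'   exceeded by consecutive windows only inside the region in the
#'   motivating analysis).
#' @param min_run Minimum number of consecutive qualifying windows
#'   (default 2).
#' @return data.frame of regions: `scaffold`, `start`, `end`, `n_windows`,
#'   `mean_fst`, `fixed_snps`.
#' @export
call_region <- function(ws, fst_threshold = 0.25, min_run = 2) {
  empty <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      mean_fst = numeric(), fixed_snps = integer())
  if (nrow(ws) == 0L) return(empty)
  out <- list()
  for (sc in unique(ws$scaffold)) {
    w <- ws[ws$scaffold == sc, , drop = FALSE]
    hit <- !is.na(w$fst) & w$fst > fst_threshold
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      idx <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, start = w$start[starts[k]], end = w$end[ends[k]],
        n_windows = length(idx), mean_fst = mean(w$fst[idx]),
        fixed_snps = sum(w$fixed_snps[idx]))
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$end - res$start, decreasing = TRUE), , drop = FALSE]
}

#' Assign unmapped scaffolds to the supergene region
#'
#' An unmapped scaffold qualifies when at least `min_qualifying_windows`
#' of its windows simultaneously show high FST and a high density of
#' fixed-difference SNPs.
#'
#' @param ws Per-scaffold window statistics.
#' @param fst_min FST threshold (exclusive; default 0.75).
#' @param fixed_min Fixed-difference SNPs per window threshold (exclusive;
#'   default 25, calibrated to 30 kb windows).
#' @param min_qualifying_windows Windows required per scaffold (default 1).
#' @return Character vector of qualifying scaffold ids.
#' @export
assign_unmapped_scaffolds <- function(ws, fst_min = 0.75, fixed_min = 25,
                                      min_qualifying_windows = 1) {
  qual <- !is.na(ws$fst) & ws$fst > fst_min & ws$fixed_snps > fixed_min
  counts <- tapply(qual, ws$scaffold, sum)
  sort(names(counts)[counts >= min_qualifying_windows])
}

#' Permutation test of group assignment
#'
#' Reallocates samples to two groups of the original sizes at random and
#' recomputes the differentiation statistic, to check that observed
#' differentiation is not an artefact of how individuals were grouped.
#' With `stratified = TRUE`, permuted groups are constrained to mix the
#' two true genotypes equally (each permuted group draws half its members
#' from each original group) — under a genuine supergene signal this
#' mixing collapses the fixed-difference count to near zero.
#'
#' @param vt A [variant_table()].
#' @param ss A [sample_set()].
#' @param statistic `"fixed"` (fixed-difference SNP count) or `"fst"`
#'   (multilocus FST).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional seed.
#' @param stratified Constrain permutations to mix genotypes (default
#'   FALSE: unconstrained reallocation).
#' @return List: `observed`, `null` (length `n_perm`), `p` with the
#'   add-one Monte-Carlo convention (1 + #(null >= observed)) / (n_perm + 1).
#' @export
permutation_test <- function(vt, ss, statistic = c("fixed", "fst"),
                             n_perm = 999, seed = NULL, stratified = FALSE) {
  statistic <- match.arg(statistic)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  stat_fun <- function(ss_perm) {
    if (statistic == "fixed") fixed_differences(vt, ss_perm)$snp
    else multilocus_fst(vt, ss_perm)
  }
  observed <- stat_fun(ss)
  gl <- group_levels(ss)
  a_samples <- group_samples(ss, gl[1])
  b_samples <- group_samples(ss, gl[2])
  n_a <- length(a_samples)
  null <- vapply(seq_len(n_perm), function(i) {
    if (stratified) {
      pick_a <- c(sample(a_samples, n_a %/% 2),
                  sample(b_samples, n_a - n_a %/% 2))
    } else {
      pick_a <- sample(ss$sample, n_a)
    }
    grp <- ifelse(ss$sample %in% pick_a, gl[1], gl[2])
    ss2 <- ss; ss2$group <- grp
    stat_fun(ss2)
  }, numeric(1))
  p <- (1 + sum(null >= observed, na.rm = TRUE)) / (n_perm + 1)
  list(observed = observed, null = null, p = p)
}

#' Extrapolate the region size to the full genome
#'
#' Assuming the non-assembled and unanalysed fractions of the genome carry
#' the region in the same proportion as the analysed fraction, scales the
#' observed region length by each genome-size bound.
#'
#' @param region_bp Region length within the analysed assembly.
#' @param analysed_bp Total analysed assembly length.
#' @param genome_bp_low,genome_bp_high Genome size bounds.
#' @return Named numeric vector `c(low =, high =)`.
#' @export
extrapolate_region_size <- function(region_bp, analysed_bp,
                                    genome_bp_low, genome_bp_high) {
  stopifnot(analysed_bp > 0)
  c(low = region_bp * genome_bp_low / analysed_bp,
    high = region_bp * genome_bp_high / analysed_bp)
}
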