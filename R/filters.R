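#' Apply variant-call quality filters
#'
#' Retains sites that pass the site-confidence threshold and, for every
#' sample in scope, the genotype-confidence and called-allele coverage
#' thresholds. Low-coverage samples are held to a stricter
#' genotype-confidence cutoff than high-coverage samples. In per-group mode
#' only the named group's samples are evaluated, so the call quality of one
#' group cannot affect diversity estimates in the other; retained sites are
#' guaranteed fully called across the in-scope samples.
#'
#' @param vt A [variant_table()].
#' @param ss A [sample_set()].
#' @param mode `"all"` (whole-set) or a group label for per-group filtering.
#' @param site_conf_min Minimum site confidence (exclusive; default 15).
#' @param gt_conf_min_low,gt_conf_min_high Genotype-confidence thresholds
#'   (exclusive) for low- and high-coverage samples (defaults 10 and 2).
#' @param cov_min Minimum called-allele coverage (inclusive; default 1).
#' @return The filtered `variant_table`.
#' @export
apply_variant_filters <- function(vt, ss, mode = "all",
                                  site_conf_min = 15,
                                  gt_conf_min_low = 10,
                                  gt_conf_min_high = 2,
                                  cov_min = 1) {
  scope <- if (identical(mode, "all")) ss$sample else {
    if (!mode %in% ss$group)
      stop("mode must be 'all' or one of: ",
           paste(unique(ss$group), collapse = ", "))
    ss$sample[ss$group == mode]
  }
  idx <- match(scope, vt$samples)
  if (anyNA(idx))
    stop("samples absent from variant table: ",
         paste(scope[is.na(idx)], collapse = ", "))
  if (anyNA(vt$sites$site_conf))
    stop("missing SITE_CONF annotation at site row(s) ",
         paste(utils::head(which(is.na(vt$sites$site_conf))), collapse = ", "))
  gconf <- vt$gt_conf[, idx, drop = FALSE]
  gcov <- vt$cov[, idx, drop = FALSE]
  gcall <- vt$gt[, idx, drop = FALSE]
  called <- !is.na(gcall)
  if (any(called & is.na(gconf)))
    stop("missing GT_CONF annotation for called genotypes")
  if (any(called & is.na(gcov)))
    stop("missing COV annotation for called genotypes")
  thr <- ifelse(ss$coverage[match(scope, ss$sample)] == "low",
                gt_conf_min_low, gt_conf_min_high)
  conf_ok <- sweep(gconf, 2L, thr, ">")
  keep <- vt$sites$site_conf > site_conf_min &
    rowSums(called) == length(idx) &
    rowSums(conf_ok, na.rm = TRUE) == length(idx) &
    rowSums(gcov >= cov_min, na.rm = TRUE) == length(idx)
  keep[is.na(keep)] <- FALSE
  vt_subset(vt, keep)
}

#' Filter STR loci by reference repeat-unit number
#'
#' Loci are kept when the reference repeat-unit count exceeds a
#' period-dependent threshold: 9 for mononucleotide repeats, 5 for
#' dinucleotide repeats, 4 for longer repeat units. The comparison is
#' strict by default (`inclusive = FALSE` keeps units > threshold);
#' `inclusive = TRUE` switches to >=. Loci with period outside 1-6 are
#' dropped with a warning.
#'
#' @param st An [str_table()].
#' @param inclusive Use >= instead of > against the thresholds.
#' @return The filtered `str_table`.
#' @export
filter_str_loci <- function(st, inclusive = FALSE) {
  per <- st$loci$period
  bad <- is.na(per) | per < 1 | per > 6
  if (any(bad)) {
    warning(sum(bad), " locus/loci with period outside 1-6 dropped")
  }
  thr <- ifelse(per == 1, 9, ifelse(per == 2, 5, 4))
  keep <- !bad &
    (if (inclusive) st$loci$ref_units >= thr else st$loci$ref_units > thr)
  st_subset(st, keep)
}

#' Filter STR genotype calls
#'
#' Keeps loci where every in-scope sample has a call with quality
#' Q >= 0.25, at least two supporting reads, and total coverage of at most
#' 25 reads. Per-group mode restricts the scope to one group's samples, as
#' for variants.
#'
#' @param st An [str_table()].
#' @param ss A [sample_set()].
#' @param mode `"all"` or a group label.
#' @param q_min,support_min,coverage_max Call thresholds (defaults 0.25,
#'   2, 25; Q and support inclusive minima, coverage an inclusive maximum).
#' @return The filtered `str_table`.
#' @export
filter_str_calls <- function(st, ss, mode = "all",
                             q_min = 0.25, support_min = 2,
                             coverage_max = 25) {
  scope <- if (identical(mode, "all")) ss$sample else {
    if (!mode %in% ss$group)
      stop("mode must be 'all' or one of: ",
           paste(unique(ss$group), collapse = ", "))
    ss$sample[ss$group == mode]
  }
  idx <- match(scope, st$samples)
  if (anyNA(idx))
    stop("samples absent from STR table: ",
         paste(scope[is.na(idx)], collapse = ", "))
  u <- st$units[, idx, drop = FALSE]
  q <- st$q[, idx, drop = FALSE]
  sup <- st$support[, idx, drop = FALSE]
  cov <- st$coverage[, idx, drop = FALSE]
  ok <- !is.na(u) & !is.na(q) & q >= q_min &
    !is.na(sup) & sup >= support_min &
    !is.na(cov) & cov <= coverage_max
  st_subset(st, rowSums(ok) == length(idx))
}
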