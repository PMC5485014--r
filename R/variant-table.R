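#' Haploid variant table
#'
#' The central container of the package: one row per variant site, one
#' column per haploid sample. Genotypes are allele indices (0 = reference,
#' 1 = first alternate, ...) with NA for missing calls, so each sample
#' carries exactly one allele per site. Per-site `SITE_CONF` and per-sample
#' `GT_CONF` and called-allele coverage annotations mirror the confidence
#' scores emitted by de Bruijn graph genotypers.
#'
#' @param sites data.frame with columns `scaffold`, `pos` (1-based),
#'   `ref`, `alt` (comma-separated for multiallelic sites), `class`
#'   (`"snp"` or `"indel"`), `site_conf`.
#' @param gt Integer matrix (sites x samples) of haploid allele indices.
#' @param gt_conf,cov Numeric/integer matrices of the same shape: genotype
#'   confidence and read coverage supporting the called allele.
#' @param samples Character vector of sample names (column order of `gt`).
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, gt, gt_conf, cov, samples = colnames(gt)) {
  sites <- as.data.frame(sites)
  needed <- c("scaffold", "pos", "ref", "alt", "class", "site_conf")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols))
    stop("sites is missing column(s): ", paste(missing_cols, collapse = ", "))
  gt <- as.matrix(gt); storage.mode(gt) <- "integer"
  if (is.null(samples)) stop("sample names required")
  stopifnot(nrow(gt) == nrow(sites),
            identical(dim(gt), dim(as.matrix(gt_conf))),
            identical(dim(gt), dim(as.matrix(cov))),
            ncol(gt) == length(samples))
  ord_ok <- !unlist(tapply(sites$pos, sites$scaffold,
                           function(p) is.unsorted(p, strictly = TRUE),
                           default = FALSE))
  if (!all(ord_ok))
    stop("positions must be strictly increasing within scaffold: ",
         paste(names(ord_ok)[!ord_ok], collapse = ", "))
  gt_conf <- as.matrix(gt_conf); cov <- as.matrix(cov)
  dimnames(gt) <- dimnames(gt_conf) <- dimnames(cov) <- list(NULL, samples)
  rownames(sites) <- NULL
  obj <- list(sites = sites, gt = gt, gt_conf = gt_conf, cov = cov,
              samples = samples)
  class(obj) <- "variant_table"
  obj
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites (%d SNPs, %d indels) x %d samples\n",
              nrow(x$sites), sum(x$sites$class == "snp"),
              sum(x$sites$class == "indel"), length(x$samples)))
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$sites), length(x$samples))

#' Subset a variant table by site index
#'
#' @param vt A [variant_table()].
#' @param i Logical or integer site index.
#' @return A `variant_table` with the selected sites.
#' @export
vt_subset <- function(vt, i) {
  variant_table(vt$sites[i, , drop = FALSE],
                vt$gt[i, , drop = FALSE],
                vt$gt_conf[i, , drop = FALSE],
                vt$cov[i, , drop = FALSE],
                vt$samples)
}

#' Sample sheet with group labels
#'
#' @param sample Character sample ids.
#' @param group Group label per sample; exactly two distinct labels
#'   (conventionally `"SB"` and `"Sb"`).
#' @param coverage `"high"` or `"low"` per sample; low-coverage samples are
#'   held to a stricter genotype-confidence threshold.
#' @param pair Optional sibling-pair id (one member in each group).
#' @return data.frame of class `sample_set`.
#' @export
sample_set <- function(sample, group, coverage = "low", pair = NA) {
  stopifnot(length(sample) == length(group), !anyDuplicated(sample))
  groups <- unique(group)
  if (length(groups) != 2L)
    stop("exactly two non-empty groups required, got: ",
         paste(groups, collapse = ", "))
  stopifnot(all(coverage %in% c("high", "low")))
  ss <- data.frame(sample = as.character(sample), group = as.character(group),
                   coverage = rep_len(coverage, length(sample)),
                   pair = rep_len(pair, length(sample)),
                   stringsAsFactors = FALSE)
  class(ss) <- c("sample_set", "data.frame")
  ss
}

group_samples <- function(ss, group) ss$sample[ss$group == group]

group_levels <- function(ss) unique(ss$group)

#' Short tandem repeat genotype table
#'
#' @param loci data.frame with columns `locus_id`, `scaffold`, `pos`,
#'   `period` (repeat unit length, 1-6), `ref_units`, `score`.
#' @param units Numeric matrix (loci x samples) of called repeat-unit
#'   counts (NA = no call).
#' @param q,support,coverage Matrices of per-call quality, supporting reads
#'   and total coverage.
#' @param samples Sample names.
#' @return An object of class `str_table`.
#' @export
str_table <- function(loci, units, q, support, coverage,
                      samples = colnames(units)) {
  loci <- as.data.frame(loci)
  needed <- c("locus_id", "scaffold", "pos", "period", "ref_units", "score")
  missing_cols <- setdiff(needed, names(loci))
  if (length(missing_cols))
    stop("loci is missing column(s): ", paste(missing_cols, collapse = ", "))
  units <- as.matrix(units)
  stopifnot(nrow(units) == nrow(loci), ncol(units) == length(samples))
  q <- as.matrix(q); support <- as.matrix(support)
  coverage <- as.matrix(coverage)
  dimnames(units) <- dimnames(q) <- dimnames(support) <-
    dimnames(coverage) <- list(NULL, samples)
  rownames(loci) <- NULL
  obj <- list(loci = loci, units = units, q = q, support = support,
              coverage = coverage, samples = samples)
  class(obj) <- "str_table"
  obj
}

#' @export
print.str_table <- function(x, ...) {
  cat(sprintf("str_table: %d loci x %d samples\n",
              nrow(x$loci), length(x$samples)))
  invisible(x)
}

st_subset <- function(st, i) {
  str_table(st$loci[i, , drop = FALSE], st$units[i, , drop = FALSE],
            st$q[i, , drop = FALSE], st$support[i, , drop = FALSE],
            st$coverage[i, , drop = FALSE], st$samples)
}
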