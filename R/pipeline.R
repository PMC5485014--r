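#' Pipeline configuration
#'
#' Collects input paths (or in-memory objects from [simulate_dataset()]),
#' window geometry, thresholds and seeds for the end-to-end analysis.
#'
#' @param vcf,genome,gff,markers,str,samples File paths, or NULL when the
#'   corresponding `data` object is supplied.
#' @param data Optional list as returned by [simulate_dataset()]; takes
#'   precedence over file paths.
#' @param window_size,window_step Scan window geometry in non-N bp
#'   (defaults 30 kb / 10 kb).
#' @param summary_window Non-overlapping window size used for region
#'   calling and genome-wide means (default 10 kb).
#' @param fst_threshold,min_run Region-calling parameters (defaults 0.25, 2).
#' @param strata_min_span,strata_rate,strata_sims Strata-scan parameters
#'   (defaults 30 genes, 1/3000 per bp, 1000 simulations).
#' @param n_perm Label permutations for the grouping check (default 99).
#' @param seed Seed used for all stochastic stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, genome = NULL, gff = NULL,
                            markers = NULL, str = NULL, samples = NULL,
                            data = NULL,
                            window_size = 30000, window_step = 10000,
                            summary_window = 10000,
                            fst_threshold = 0.25, min_run = 2,
                            strata_min_span = 30, strata_rate = 1 / 3000,
                            strata_sims = 1000, n_perm = 99, seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(data)) {
    paths <- c(vcf = vcf, genome = genome, gff = gff, markers = markers,
               str = str, samples = samples)
    missing_files <- paths[!vapply(paths, file.exists, logical(1))]
    if (length(missing_files))
      stop("input file(s) not found: ",
           paste(missing_files, collapse = ", "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full supergene analysis
#'
#' Orchestrates the stages end to end: quality filtering (whole-set and
#' per-group), linkage-map scaffold placement, sliding-window FST /
#' diversity / fixed-difference scans, region calling on a non-overlapping
#' tiling, per-gene consensus divergence with a McDonald-Kreitman
#' contrast, the evolutionary-strata scan against its Poisson null, and a
#' permutation check of the group labels. Deterministic for a fixed
#' config.
#'
#' @param cfg A [pipeline_config()].
#' @return List of class `supergene_report` with elements `summary`
#'   (Table-1-style differentiation/diversity summary), `windows`,
#'   `region`, `anchored_scaffolds`, `divergence` (per-gene records),
#'   `mk`, `strata`, `permutation`, `str_fixed`, and `seed`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  set.seed(cfg$seed)
  d <- cfg$data
  genome <- if (!is.null(d)) d$genome else read_genome(cfg$genome)
  vt_raw <- if (!is.null(d)) d$vt else read_vcf(cfg$vcf)
  ss <- if (!is.null(d)) d$ss else read_sample_set(cfg$samples)
  genes_raw <- if (!is.null(d)) d$genes else read_gene_models(cfg$gff)
  markers <- if (!is.null(d)) d$markers else read_markers(cfg$markers)
  st_raw <- if (!is.null(d)) d$st else read_str_table(cfg$str)
  gl <- group_levels(ss)

  ## stage 1: filters
  vt <- apply_variant_filters(vt_raw, ss, mode = "all")
  vt_a <- apply_variant_filters(vt_raw, ss, mode = gl[1])
  vt_b <- apply_variant_filters(vt_raw, ss, mode = gl[2])
  st <- filter_str_calls(filter_str_loci(st_raw), ss, mode = "all")

  ## stage 2: genome map
  mk <- filter_low_confidence_scaffolds(markers)
  map <- build_map(mk, vapply(genome, nchar, numeric(1)))
  anchored <- anchor_markers(mk)

  ## stage 3: windows
  scan_w <- make_windows(genome, cfg$window_size, cfg$window_step)
  scan_stats <- window_stats(scan_w, vt, ss, vt_a, vt_b)
  tile_w <- make_windows(genome, cfg$summary_window, cfg$summary_window)
  tile_stats <- window_stats(tile_w, vt, ss, vt_a, vt_b)

  ## stage 4: region call on the non-overlapping tiling
  region <- call_region(tile_stats, fst_threshold = cfg$fst_threshold,
                        min_run = cfg$min_run)
  in_region <- rep(FALSE, nrow(tile_stats))
  if (nrow(region) > 0) {
    r <- region[1, ]
    in_region <- tile_stats$scaffold == r$scaffold &
      tile_stats$start >= r$start & tile_stats$end <= r$end
  }
  full <- !tile_stats$partial
  summ <- list(
    region = if (nrow(region)) region[1, ] else NULL,
    fst_region_mean = mean(tile_stats$fst[in_region & full], na.rm = TRUE),
    fst_region_sd = stats::sd(tile_stats$fst[in_region & full], na.rm = TRUE),
    fst_background_mean = mean(tile_stats$fst[!in_region & full],
                               na.rm = TRUE),
    fixed_snps_region = sum(tile_stats$fixed_snps[in_region]),
    fixed_snps_background = sum(tile_stats$fixed_snps[!in_region]),
    pi_a_region = mean(tile_stats$pi_a[in_region & full], na.rm = TRUE),
    pi_a_background = mean(tile_stats$pi_a[!in_region & full], na.rm = TRUE),
    pi_b_region = mean(tile_stats$pi_b[in_region & full], na.rm = TRUE),
    pi_b_background = mean(tile_stats$pi_b[!in_region & full], na.rm = TRUE))
  summ$pi_a_ratio <- summ$pi_a_region / summ$pi_a_background
  summ$pi_b_ratio <- summ$pi_b_region / summ$pi_b_background

  ## stage 5: coding divergence in the called region
  genes <- filter_genes(genes_raw, genome, vt)
  div <- NULL; mk_res <- NULL; strata <- NULL
  if (nrow(region) > 0 && nrow(genes) > 0) {
    r <- region[1, ]
    gsel <- unique(genes$gene_id[genes$scaffold == r$scaffold &
                                   genes$start >= r$start &
                                   genes$end <= r$end])
    if (length(gsel) > 0) {
      div <- do.call(rbind, lapply(gsel, function(id) {
        pair <- build_consensus_pair(genes, id, genome, vt, ss)
        rec <- ng86_divergence(pair)
        rec$n_fixed <- nrow(pair$applied)
        g <- genes[genes$gene_id == id, ]
        rec$scaffold <- g$scaffold[1]; rec$start <- min(g$start)
        rec$length <- sum(g$end - g$start + 1)
        rec
      }))
      mk_counts <- mk_region_counts(genes, gsel, genome, vt, vt_a, ss)
      if (all(unlist(mk_counts) >= 0) &&
          (mk_counts$fixed_n + mk_counts$fixed_s) > 0 &&
          (mk_counts$poly_n + mk_counts$poly_s) > 0)
        mk_res <- mk_test(mk_counts$fixed_n, mk_counts$fixed_s,
                          mk_counts$poly_n, mk_counts$poly_s)
      div <- div[order(div$start), ]
      if (nrow(div) >= cfg$strata_min_span + 2)
        strata <- strata_test(counts = div$n_fixed, lengths = div$length,
                              rate = cfg$strata_rate,
                              min_span = cfg$strata_min_span,
                              n_sims = cfg$strata_sims, seed = cfg$seed)
    }
  }

  ## stage 6: permutation check of the grouping
  perm <- permutation_test(vt, ss, statistic = "fixed", n_perm = cfg$n_perm,
                           seed = cfg$seed)

  structure(list(summary = summ, windows = scan_stats, tiles = tile_stats,
                 region = region, map = map, anchored_scaffolds = anchored,
                 divergence = div, mk = mk_res, strata = strata,
                 permutation = perm,
                 str_fixed = str_fixed_differences(st, ss),
                 seed = cfg$seed),
            class = "supergene_report")
}

# Region-gene McDonald-Kreitman counts: fixed differences between groups
# vs polymorphisms within the first group, classified syn/nonsyn.
mk_region_counts <- function(genes, gene_ids, genome, vt, vt_a, ss) {
  gl <- group_levels(ss)
  counts <- list(fixed_n = 0L, fixed_s = 0L, poly_n = 0L, poly_s = 0L)
  fd <- fixed_differences(vt, ss)
  fixed_vt <- vt_subset(vt, fd$sites)
  ia <- match(group_samples(ss, gl[1]), vt_a$samples)
  het_a <- site_heterozygosity(vt_a, ss, gl[1])
  for (id in gene_ids) {
    g <- genes[genes$gene_id == id, ]
    lay <- cds_layout(genes, id, genome)
    fsel <- which(fixed_vt$sites$class == "snp" &
                    fixed_vt$sites$scaffold == g$scaffold[1] &
                    fixed_vt$sites$pos %in% lay$pos)
    for (k in fsel) {
      alleles <- c(fixed_vt$sites$ref[k],
                   strsplit(fixed_vt$sites$alt[k], ",", fixed = TRUE)[[1]])
      ib <- match(group_samples(ss, gl[2])[1], fixed_vt$samples)
      alt <- alleles[fixed_vt$gt[k, ib] + 1L]
      ref <- substr(fixed_vt$sites$ref[k], 1, 1)
      eff <- classify_snp_effect(genes, id, genome, fixed_vt$sites$pos[k],
                                 ref, alt)
      if (eff == "nonsynonymous") counts$fixed_n <- counts$fixed_n + 1L
      if (eff == "synonymous") counts$fixed_s <- counts$fixed_s + 1L
    }
    psel <- which(vt_a$sites$class == "snp" &
                    vt_a$sites$scaffold == g$scaffold[1] &
                    vt_a$sites$pos %in% lay$pos & het_a > 0)
    for (k in psel) {
      alleles <- c(vt_a$sites$ref[k],
                   strsplit(vt_a$sites$alt[k], ",", fixed = TRUE)[[1]])
      seen <- unique(vt_a$gt[k, ia])
      seen <- seen[!is.na(seen) & seen > 0]
      for (al in seen) {
        eff <- classify_snp_effect(genes, id, genome, vt_a$sites$pos[k],
                                   vt_a$sites$ref[k], alleles[al + 1L])
        if (eff == "nonsynonymous") counts$poly_n <- counts$poly_n + 1L
        if (eff == "synonymous") counts$poly_s <- counts$poly_s + 1L
      }
    }
  }
  counts
}

#' @export
print.supergene_report <- function(x, ...) {
  cat("supergene analysis report\n")
  if (!is.null(x$summary$region)) {
    r <- x$summary$region
    cat(sprintf("  region: %s:%d-%d (%.2f Mb, %d windows)\n", r$scaffold,
                r$start, r$end, (r$end - r$start + 1) / 1e6, r$n_windows))
  } else cat("  region: none called\n")
  cat(sprintf("  FST (region) %.3f +/- %.3f; background %.3f\n",
              x$summary$fst_region_mean, x$summary$fst_region_sd,
              x$summary$fst_background_mean))
  cat(sprintf("  fixed SNPs: %d in region, %d outside\n",
              x$summary$fixed_snps_region, x$summary$fixed_snps_background))
  cat(sprintf("  pi ratios (region/background): %.3g (group A), %.3g (group B)\n",
              x$summary$pi_a_ratio, x$summary$pi_b_ratio))
  if (!is.null(x$mk))
    cat(sprintf("  MK test: chi2 = %.2f, p = %.3g, NI = %.3g\n",
                x$mk$statistic, x$mk$p, x$mk$neutrality_index))
  if (!is.null(x$strata))
    cat(sprintf("  strata scan: empirical p = %.3g\n", x$strata$empirical_p))
  cat(sprintf("  permutation p (fixed differences) = %.3g\n",
              x$permutation$p))
  invisible(x)
}
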