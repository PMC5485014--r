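#' Parameters for the synthetic study-design generator
#'
#' Encodes the statistical structure the downstream analysis assumes: two
#' groups of haploid brothers (default 8 + 8, one pair per colony), a
#' megabase-scale planted region where the groups are fixed for
#' alternative alleles at high density and the second group has almost no
#' diversity, embedded in a diverse background shared by both groups.
#' Default densities follow the magnitudes observed in the motivating
#' system: 1.4 fixed differences per kb inside the region, background
#' diversity of 8.2e-4 per bp, within-region diversity of 6.7e-4 (first
#' group) and 1.3e-6 (second group).
#'
#' @param seed Integer seed; identical seed and parameters give
#'   byte-identical output files.
#' @param n_per_group Haploid samples per group (default 8).
#' @param scaffold_lengths Named vector of scaffold lengths (bp).
#' @param n_gap_fraction Fraction of each scaffold set to N, in contiguous
#'   blocks (default 0.02).
#' @param region_span `list(scaffold=, start=, end=)` of the planted
#'   region, or NULL for no region.
#' @param fixed_diff_density Fixed differences per non-N bp in the region
#'   (default 1.4e-3).
#' @param pi_background Target per-bp diversity outside the region, per
#'   group (default 8.2e-4).
#' @param pi_SB_region,pi_Sb_region Target per-bp diversity inside the
#'   region for group A / group B (defaults 6.7e-4, 1.3e-6).
#' @param paired_siblings Add pair-private variants shared by exactly one
#'   sample of each group (full brothers), which push background FST
#'   slightly negative.
#' @param pair_private_fraction Fraction of background polymorphic sites
#'   that are pair-private when `paired_siblings` (default 0.2).
#' @param indel_fraction Fraction of polymorphic non-coding sites emitted
#'   as short indels rather than SNPs (default 0.1).
#' @param gene_count,gene_length Number and CDS length (bp, multiple of 3)
#'   of single-exon genes; half are placed inside the region.
#' @param frac_nonsyn_fixed Target fraction of planted fixed coding
#'   differences that are nonsynonymous (default 374/791, the observed
#'   proportion in the motivating system).
#' @param str_locus_count,str_period_range STR locus count and repeat-unit
#'   period range.
#' @param site_conf_fail,gt_conf_fail,cov_fail Fractions of sites (or
#'   sample-calls) drawn below each quality-filter threshold.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_per_group = 8L,
                       scaffold_lengths = c(scaffold_1 = 3e6, scaffold_2 = 2e6,
                                            scaffold_3 = 2e6, scaffold_4 = 1e6),
                       n_gap_fraction = 0.02,
                       region_span = list(scaffold = "scaffold_1",
                                          start = 1000001, end = 2000000),
                       fixed_diff_density = 1.4e-3,
                       pi_background = 8.2e-4,
                       pi_SB_region = 6.7e-4,
                       pi_Sb_region = 1.3e-6,
                       paired_siblings = TRUE,
                       pair_private_fraction = 0.2,
                       indel_fraction = 0.1,
                       gene_count = 60L,
                       gene_length = 900L,
                       frac_nonsyn_fixed = 374 / 791,
                       str_locus_count = 120L,
                       str_period_range = c(1L, 6L),
                       site_conf_fail = 0.005,
                       gt_conf_fail = 0.001,
                       cov_fail = 2e-4) {
  p <- as.list(environment())
  dens <- c(fixed_diff_density, pi_background, pi_SB_region, pi_Sb_region)
  if (any(dens < 0 | dens >= 1))
    stop("densities and diversities must lie in [0, 1)")
  if (!is.null(region_span)) {
    len <- scaffold_lengths[[region_span$scaffold]]
    if (is.null(len) || region_span$start < 1 || region_span$end > len ||
        region_span$start >= region_span$end)
      stop("region_span must lie within its scaffold")
  }
  if (gene_length %% 3L != 0L) stop("gene_length must be a multiple of 3")
  if (n_per_group < 2L) stop("need at least 2 samples per group")
  class(p) <- "sim_params"
  p
}

# Expected per-site heterozygosity of a group-private polymorphism under
# the 1/i minor-count weighting (i = 1..n/2): h_i = 2 i (n-i) / (n (n-1)).
expected_het_private <- function(n) {
  i <- seq_len(n %/% 2)
  w <- 1 / i
  h <- 2 * i * (n - i) / (n * (n - 1))
  sum(w * h) / sum(w)
}

# Expected within-group heterozygosity of a shared-pool polymorphism:
# minor count i among 2m samples (1/i weighting), carriers split into the
# group of m hypergeometrically.
expected_het_shared <- function(m) {
  n <- 2L * m
  i_vals <- seq_len(m)
  w <- 1 / i_vals
  eh <- vapply(i_vals, function(i) {
    j <- 0:min(i, m)
    sum(stats::dhyper(j, i, n - i, m) * 2 * j * (m - j) / (m * (m - 1)))
  }, numeric(1))
  sum(w * eh) / sum(w)
}

draw_minor_count <- function(k, n) {
  i <- seq_len(n %/% 2)
  sample(i, k, replace = TRUE, prob = 1 / i)
}

#' Generate a complete synthetic data set
#'
#' Draws a reference genome with contiguous N gaps, plants variant sites
#' by independent per-site Bernoulli draws in four truth classes (fixed
#' difference, group-A-private, group-B-private, shared background
#' polymorphism — optionally pair-private for sibling pairs), lays out
#' single-exon genes (half inside the region) with codon-aware allele
#' choice at fixed coding sites, simulates STR loci and linkage-map
#' markers, and attaches quality annotations of which a configurable
#' fraction fails each downstream filter. Site densities are calibrated
#' analytically so that within-group diversity matches the pi targets in
#' expectation.
#'
#' @param params A [sim_params()].
#' @param dir Optional directory: writes `genome.fasta`, `variants.vcf`,
#'   `genes.gff3`, `markers.tsv`, `str.tsv`, `samples.tsv`, `truth.json`.
#' @return Invisible list with `params`, `genome`, `vt` ([variant_table()]),
#'   `ss`, `genes`, `st` ([str_table()]), `markers`, `truth`, and `files`
#'   (paths, when `dir` given).
#' @export
simulate_dataset <- function(params, dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  m <- p$n_per_group
  samples <- c(paste0("SB", seq_len(m)), paste0("Sb", seq_len(m)))
  ss <- sample_set(samples,
                   group = rep(c("SB", "Sb"), each = m),
                   coverage = rep(c("high", rep("low", m - 1)), 2),
                   pair = rep(seq_len(m), 2))

  genome <- make_genome(p)
  genes <- place_genes(p, genome)
  pieces <- place_variants(p, genome, genes, ss)
  vt <- pieces$vt
  truth_sites <- pieces$truth_sites
  st <- make_strs(p, genome, ss)
  markers <- make_markers(p, genome)

  gene_counts <- planted_gene_counts(pieces$coding, genes)
  truth <- list(
    region = p$region_span,
    params = p[c("seed", "n_per_group", "n_gap_fraction",
                 "fixed_diff_density", "pi_background", "pi_SB_region",
                 "pi_Sb_region", "paired_siblings", "pair_private_fraction",
                 "indel_fraction", "frac_nonsyn_fixed")],
    scaffold_lengths = as.list(p$scaffold_lengths),
    sites = truth_sites,
    genes = gene_counts,
    str = st$truth)

  out <- list(params = p, genome = genome$seqs, vt = vt, ss = ss,
              genes = genes, st = st$table, markers = markers, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(
      genome = file.path(dir, "genome.fasta"),
      vcf = file.path(dir, "variants.vcf"),
      gff = file.path(dir, "genes.gff3"),
      markers = file.path(dir, "markers.tsv"),
      str = file.path(dir, "str.tsv"),
      samples = file.path(dir, "samples.tsv"),
      truth = file.path(dir, "truth.json"))
    write_genome(genome$seqs, files$genome)
    write_vcf(vt, files$vcf)
    write_gene_models(genes, files$gff)
    write_markers(markers, files$markers)
    write_str_table(st$table, files$str)
    write_sample_set(ss, files$samples)
    jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA)
    out$files <- files
  }
  invisible(out)
}

make_genome <- function(p) {
  seqs <- list(); nmask <- list()
  for (sc in names(p$scaffold_lengths)) {
    len <- as.integer(p$scaffold_lengths[[sc]])
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    is_n <- rep(FALSE, len)
    n_total <- round(p$n_gap_fraction * len)
    while (n_total > 0) {
      block <- min(n_total, sample(2000:20000, 1))
      start <- sample.int(len - block + 1L, 1)
      chars[start:(start + block - 1L)] <- "N"
      is_n[start:(start + block - 1L)] <- TRUE
      n_total <- n_total - block
    }
    seqs[[sc]] <- chars
    nmask[[sc]] <- is_n
  }
  list(seqs = vapply(seqs, paste, character(1), collapse = ""),
       chars = seqs, nmask = nmask)
}

place_genes <- function(p, genome) {
  if (p$gene_count == 0L)
    return(data.frame(gene_id = character(), scaffold = character(),
                      start = integer(), end = integer(), strand = character(),
                      partial = logical(), transl_table = integer()))
  n_in <- if (is.null(p$region_span)) 0L else p$gene_count %/% 2L
  n_out <- p$gene_count - n_in
  gl <- p$gene_length
  slots <- function(sc, lo, hi, n) {
    if (n == 0L) return(NULL)
    starts <- round(seq(lo, hi - gl, length.out = n + 2L))[2:(n + 1L)]
    ok <- vapply(starts, function(s)
      !any(genome$nmask[[sc]][s:(s + gl - 1L)]), logical(1))
    data.frame(scaffold = sc, start = as.integer(starts[ok]),
               stringsAsFactors = FALSE)
  }
  rows <- NULL
  if (n_in > 0L) {
    rs <- p$region_span
    rows <- rbind(rows, slots(rs$scaffold, rs$start, rs$end, n_in))
  }
  # background genes on the last scaffold (outside any region)
  bg_sc <- names(p$scaffold_lengths)[length(p$scaffold_lengths)]
  rows <- rbind(rows, slots(bg_sc, 1L, p$scaffold_lengths[[bg_sc]], n_out))
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(nrow(rows))),
    scaffold = rows$scaffold, start = rows$start,
    end = rows$start + gl - 1L,
    strand = rep_len(c("+", "-"), nrow(rows)),
    partial = FALSE, transl_table = 1L, stringsAsFactors = FALSE)
  # decoy models exercising the gene filters
  decoy_start <- p$scaffold_lengths[[bg_sc]] - 10L * gl
  decoys <- data.frame(
    gene_id = c("decoy_partial", "decoy_mito", "decoy_frame"),
    scaffold = bg_sc,
    start = as.integer(decoy_start + c(0L, 2L, 4L) * gl),
    end = as.integer(decoy_start + c(1L, 3L, 5L) * gl) - 1L +
      c(0L, 0L, 1L),
    strand = "+", partial = c(TRUE, FALSE, FALSE),
    transl_table = c(1L, 5L, 1L), stringsAsFactors = FALSE)
  rbind(genes, decoys)
}

# choose an alternate allele at a coding position aiming for the target
# synonymous/nonsynonymous class; returns the allele actually achieving it
coding_alt_allele <- function(lay, pos, want_nonsyn, code) {
  ci <- match(pos, lay$pos)
  codon_i <- (ci - 1L) %/% 3L
  frame <- (ci - 1L) %% 3L + 1L
  codon <- lay$bases[codon_i * 3L + 1:3]
  aa <- code[[paste(codon, collapse = "")]]
  cands <- setdiff(c("A", "C", "G", "T"), codon[frame])
  cls <- vapply(cands, function(b) {
    mut <- codon; mut[frame] <- b
    !identical(code[[paste(mut, collapse = "")]], aa)
  }, logical(1))
  pick_from <- if (want_nonsyn) cands[cls] else cands[!cls]
  if (!length(pick_from)) pick_from <- cands
  alt_cds <- if (length(pick_from) == 1L) pick_from else sample(pick_from, 1)
  mut <- codon; mut[frame] <- alt_cds
  is_nonsyn <- !identical(code[[paste(mut, collapse = "")]], aa)
  alt_gen <- if (lay$minus) unname(COMPLEMENT[alt_cds]) else alt_cds
  list(alt = alt_gen, nonsyn = is_nonsyn)
}

place_variants <- function(p, genome, genes, ss) {
  m <- p$n_per_group
  n <- 2L * m
  code <- Biostrings::GENETIC_CODE
  eh_priv <- expected_het_private(m)
  eh_shared <- expected_het_shared(m)
  h_pair <- 2 / m
  f <- if (p$paired_siblings) p$pair_private_fraction else 0
  bg_rate <- p$pi_background / ((1 - f) * eh_shared + f * h_pair)
  sb_rate <- p$pi_SB_region / eh_priv
  sbb_rate <- p$pi_Sb_region / eh_priv
  if (p$fixed_diff_density + sb_rate + sbb_rate > 1 || bg_rate > 1)
    stop("requested densities imply more than one variant per bp")

  real_genes <- genes[!grepl("^decoy", genes$gene_id), , drop = FALSE]
  layouts <- lapply(unique(real_genes$gene_id), function(id)
    cds_layout(real_genes, id, genome$seqs))
  names(layouts) <- unique(real_genes$gene_id)
  # O(log n) position -> gene lookup over the non-overlapping gene intervals
  gene_idx <- lapply(split(real_genes, real_genes$scaffold), function(g) {
    g <- g[order(g$start), ]
    list(start = g$start, end = g$end, id = g$gene_id)
  })
  gene_of_pos <- function(sc, pos) {
    gi <- gene_idx[[sc]]
    if (is.null(gi)) return(NA_character_)
    k <- findInterval(pos, gi$start)
    if (k >= 1L && pos <= gi$end[k]) gi$id[k] else NA_character_
  }

  rows <- list(); coding <- list()
  add_site <- function(sc, pos, class, gt, truth_class, pair_private = FALSE) {
    ref <- genome$chars[[sc]][pos]
    gid <- gene_of_pos(sc, pos)
    in_cds <- !is.na(gid)
    if (class == "indel" && !in_cds) {
      if (stats::runif(1) < 0.5) {            # insertion
        alt <- paste0(ref, sample(c("A", "C", "G", "T"), 1))
      } else {                                 # deletion
        if (pos >= length(genome$chars[[sc]])) return(invisible(NULL))
        nxt <- genome$chars[[sc]][pos + 1L]
        if (nxt == "N") return(invisible(NULL))
        ref <- paste0(ref, nxt)
        alt <- substr(ref, 1L, 1L)
      }
      effect <- NA
    } else {
      class <- "snp"
      if (in_cds && truth_class == "fixed") {
        ch <- coding_alt_allele(layouts[[gid]], pos,
                                stats::runif(1) < p$frac_nonsyn_fixed, code)
        alt <- ch$alt
        effect <- if (ch$nonsyn) "nonsynonymous" else "synonymous"
        coding[[length(coding) + 1L]] <<- data.frame(
          gene_id = gid, scaffold = sc, pos = pos, truth_class = truth_class,
          effect = effect, stringsAsFactors = FALSE)
      } else {
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        effect <- NA
        if (in_cds)
          coding[[length(coding) + 1L]] <<- data.frame(
            gene_id = gid, scaffold = sc, pos = pos, truth_class = truth_class,
            effect = NA_character_, stringsAsFactors = FALSE)
      }
    }
    rows[[length(rows) + 1L]] <<- list(
      scaffold = sc, pos = pos, ref = ref, alt = alt, class = class,
      gt = gt, truth_class = truth_class, pair_private = pair_private)
    invisible(NULL)
  }

  region <- p$region_span
  for (sc in names(p$scaffold_lengths)) {
    nn <- which(!genome$nmask[[sc]])
    in_region <- if (!is.null(region) && region$scaffold == sc)
      nn >= region$start & nn <= region$end else rep(FALSE, length(nn))
    reg_pos <- nn[in_region]; bg_pos <- nn[!in_region]

    if (length(reg_pos)) {
      u <- stats::runif(length(reg_pos))
      fixed_at <- reg_pos[u < p$fixed_diff_density]
      sb_at <- reg_pos[u >= p$fixed_diff_density &
                         u < p$fixed_diff_density + sb_rate]
      sbb_at <- reg_pos[u >= p$fixed_diff_density + sb_rate &
                          u < p$fixed_diff_density + sb_rate + sbb_rate]
      for (pos in fixed_at)
        add_site(sc, pos, "snp", c(rep(0L, m), rep(1L, m)), "fixed")
      for (pos in sb_at) {
        k <- draw_minor_count(1L, m)
        carriers <- sample.int(m, k)
        gt <- rep(0L, n); gt[carriers] <- 1L
        cls <- if (stats::runif(1) < p$indel_fraction &&
                     is.na(gene_of_pos(sc, pos))) "indel" else "snp"
        add_site(sc, pos, cls, gt, "SB-poly")
      }
      for (pos in sbb_at) {
        k <- draw_minor_count(1L, m)
        carriers <- m + sample.int(m, k)
        gt <- rep(0L, n); gt[carriers] <- 1L
        add_site(sc, pos, "snp", gt, "Sb-poly")
      }
    }
    if (length(bg_pos)) {
      u <- stats::runif(length(bg_pos))
      poly_at <- bg_pos[u < bg_rate]
      pair_flag <- stats::runif(length(poly_at)) < f
      for (j in seq_along(poly_at)) {
        pos <- poly_at[j]
        if (pair_flag[j]) {
          pair <- sample.int(m, 1)
          gt <- rep(0L, n); gt[c(pair, m + pair)] <- 1L
          add_site(sc, pos, "snp", gt, "shared-poly", pair_private = TRUE)
        } else {
          k <- draw_minor_count(1L, n)
          carriers <- sample.int(n, k)
          gt <- rep(0L, n); gt[carriers] <- 1L
          cls <- if (stats::runif(1) < p$indel_fraction &&
                       is.na(gene_of_pos(sc, pos))) "indel" else "snp"
          add_site(sc, pos, cls, gt, "shared-poly")
        }
      }
    }
  }

  sc_order <- names(p$scaffold_lengths)
  ord <- order(match(vapply(rows, `[[`, character(1), "scaffold"), sc_order),
               vapply(rows, `[[`, numeric(1), "pos"))
  rows <- rows[ord]
  nsite <- length(rows)
  if (nsite == 0L) {
    empty <- matrix(integer(0), 0, n, dimnames = list(NULL, ss$sample))
    vt <- variant_table(
      data.frame(scaffold = character(), pos = integer(), ref = character(),
                 alt = character(), class = character(),
                 site_conf = numeric()),
      empty, empty, empty, ss$sample)
    return(list(vt = vt,
                truth_sites = data.frame(scaffold = character(),
                                         pos = integer(), class = character(),
                                         truth_class = character(),
                                         pair_private = logical()),
                coding = data.frame(gene_id = character(),
                                    scaffold = character(), pos = integer(),
                                    truth_class = character(),
                                    effect = character())))
  }
  sites <- data.frame(
    scaffold = vapply(rows, `[[`, character(1), "scaffold"),
    pos = vapply(rows, function(r) as.integer(r$pos), integer(1)),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"),
    class = vapply(rows, `[[`, character(1), "class"),
    site_conf = numeric(nsite), stringsAsFactors = FALSE)
  gt <- do.call(rbind, lapply(rows, `[[`, "gt"))
  colnames(gt) <- ss$sample

  # quality annotations: a small fraction fails each filter
  sites$site_conf <- ifelse(stats::runif(nsite) < p$site_conf_fail,
                            stats::runif(nsite, 0, 15),
                            stats::runif(nsite, 15.5, 60))
  low <- ss$coverage == "low"
  conf_pass <- matrix(stats::runif(nsite * n, 10.5, 40), nsite, n)
  conf_pass[, !low] <- stats::runif(nsite * sum(!low), 2.5, 60)
  conf_fail <- matrix(stats::runif(nsite * n, 0, 2), nsite, n)
  fail_mask <- matrix(stats::runif(nsite * n) < p$gt_conf_fail, nsite, n)
  gt_conf <- ifelse(fail_mask, conf_fail, conf_pass)
  cov <- matrix(stats::rpois(nsite * n, 7) + 1L, nsite, n)
  cov[matrix(stats::runif(nsite * n) < p$cov_fail, nsite, n)] <- 0L
  dimnames(gt_conf) <- dimnames(cov) <- dimnames(gt)

  vt <- variant_table(sites, gt, gt_conf, cov, ss$sample)
  truth_sites <- data.frame(
    scaffold = sites$scaffold, pos = sites$pos, class = sites$class,
    truth_class = vapply(rows, `[[`, character(1), "truth_class"),
    pair_private = vapply(rows, `[[`, logical(1), "pair_private"),
    stringsAsFactors = FALSE)
  coding <- if (length(coding)) do.call(rbind, coding) else
    data.frame(gene_id = character(), scaffold = character(), pos = integer(),
               truth_class = character(), effect = character())
  list(vt = vt, truth_sites = truth_sites, coding = coding)
}

planted_gene_counts <- function(coding, genes) {
  ids <- unique(genes$gene_id[!grepl("^decoy", genes$gene_id)])
  do.call(rbind, lapply(ids, function(id) {
    cc <- coding[coding$gene_id == id & coding$truth_class == "fixed", ]
    data.frame(gene_id = id,
               fixed_syn = sum(cc$effect == "synonymous", na.rm = TRUE),
               fixed_nonsyn = sum(cc$effect == "nonsynonymous", na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
}

make_strs <- function(p, genome, ss) {
  n_loci <- p$str_locus_count
  m <- p$n_per_group; n <- 2L * m
  scs <- names(p$scaffold_lengths)
  sc <- sample(scs, n_loci, replace = TRUE,
               prob = p$scaffold_lengths / sum(p$scaffold_lengths))
  pos <- vapply(sc, function(s) {
    nn <- which(!genome$nmask[[s]])
    nn[sample.int(length(nn), 1)]
  }, integer(1))
  period <- sample(seq(p$str_period_range[1], p$str_period_range[2]),
                   n_loci, replace = TRUE)
  thr <- ifelse(period == 1, 9, ifelse(period == 2, 5, 4))
  # ~20% of loci fall at/below the reference-unit threshold
  pass_units <- thr + sample.int(8, n_loci, replace = TRUE)
  fail_units <- pmax(1L, thr - sample.int(2, n_loci, replace = TRUE) + 1L)
  ref_units <- ifelse(stats::runif(n_loci) < 0.2, fail_units, pass_units)
  in_region <- if (is.null(p$region_span)) rep(FALSE, n_loci) else
    sc == p$region_span$scaffold &
      pos >= p$region_span$start & pos <= p$region_span$end
  units <- matrix(rep(ref_units, n), n_loci, n)
  truth_class <- rep("monomorphic", n_loci)
  for (i in seq_len(n_loci)) {
    r <- stats::runif(1)
    if (in_region[i] && r < 0.5) {           # fixed difference between groups
      diffu <- sample.int(3, 1)
      units[i, (m + 1):n] <- ref_units[i] + diffu
      truth_class[i] <- "fixed"
    } else if (!in_region[i] && r < 0.3) {   # background polymorphism
      k <- draw_minor_count(1L, n)
      carriers <- sample.int(n, k)
      units[i, carriers] <- ref_units[i] + sample(c(-1L, 1L), 1)
      truth_class[i] <- "polymorphic"
    }
  }
  q <- matrix(stats::runif(n_loci * n, 0.25, 1), n_loci, n)
  support <- matrix(2L + stats::rpois(n_loci * n, 4), n_loci, n)
  coverage <- matrix(pmin(25L, 4L + stats::rpois(n_loci * n, 8)), n_loci, n)
  # a few failing calls per filter
  q[matrix(stats::runif(n_loci * n) < 0.01, n_loci, n)] <- 0.1
  support[matrix(stats::runif(n_loci * n) < 0.01, n_loci, n)] <- 1L
  coverage[matrix(stats::runif(n_loci * n) < 0.01, n_loci, n)] <- 30L
  dimnames(units) <- dimnames(q) <- dimnames(support) <-
    dimnames(coverage) <- list(NULL, ss$sample)
  loci <- data.frame(locus_id = sprintf("str%04d", seq_len(n_loci)),
                     scaffold = sc, pos = pos, period = period,
                     ref_units = ref_units,
                     score = 20 + round(stats::runif(n_loci, 0, 80)),
                     stringsAsFactors = FALSE)
  ord <- order(match(loci$scaffold, scs), loci$pos)
  list(table = str_table(loci[ord, ], units[ord, , drop = FALSE],
                         q[ord, , drop = FALSE],
                         support[ord, , drop = FALSE],
                         coverage[ord, , drop = FALSE], ss$sample),
       truth = data.frame(locus_id = loci$locus_id[ord],
                          truth_class = truth_class[ord],
                          stringsAsFactors = FALSE))
}

make_markers <- function(p, genome) {
  scs <- names(p$scaffold_lengths)
  lg <- ifelse(seq_along(scs) <= ceiling(length(scs) / 2), "lg16", "lg1")
  rows <- list()
  fams <- data.frame(family_id = c("sq1", "sq2", "sq3",
                                   "mq1", "mq2", "mq3", "mq4"),
                     family_type = c(rep("single-queen", 3),
                                     rep("multiple-queen", 4)),
                     stringsAsFactors = FALSE)
  for (k in seq_along(scs)) {
    sc <- scs[k]
    fam_pick <- fams[sample.int(nrow(fams), 2), ]
    nn <- which(!genome$nmask[[sc]])
    pos <- sort(nn[round(seq(1, length(nn), length.out = 8))])
    fam <- rep(fam_pick$family_id, each = 4)
    ftype <- rep(fam_pick$family_type, each = 4)
    coseg <- if (is.null(p$region_span) || p$region_span$scaffold != sc)
      rep(0L, length(pos))
    else as.integer(ftype == "multiple-queen" &
                      pos >= p$region_span$start &
                      pos <= p$region_span$end)
    rows[[k]] <- data.frame(
      marker_id = sprintf("%s_m%d", sc, seq_along(pos)),
      scaffold = sc, pos = pos, linkage_group = lg[k],
      cM = round((k * 50 + pos / 1e6 * 5), 3),
      family_id = fam, family_type = ftype,
      cosegregates_gp9 = coseg, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plant a low-divergence stratum in simulated gene counts
#'
#' Generates per-gene substitution counts with a contiguous span of genes
#' at a reduced rate and the rest at the global rate — the ground truth
#' for testing the strata scan.
#'
#' @param lengths Per-gene coding lengths (bp) in map order.
#' @param span Integer range (e.g. `11:40`) of genes forming the stratum.
#' @param rate_global Substitutions per bp outside the span.
#' @param rate_low Substitutions per bp inside the span (>= 0).
#' @param seed Optional seed.
#' @return List: `counts`, `truth` (`span`, `rate_low`, `rate_global`,
#'   `is_stratum` — FALSE when the rates are equal).
#' @export
plant_stratum <- function(lengths, span, rate_global, rate_low, seed = NULL) {
  if (rate_low < 0 || rate_global < 0) stop("rates must be non-negative")
  if (min(span) < 1 || max(span) > length(lengths))
    stop("span must lie within the gene list")
  if (!is.null(seed)) set.seed(seed)
  rates <- rep(rate_global, length(lengths))
  rates[span] <- rate_low
  counts <- stats::rpois(length(lengths), rates * lengths)
  list(counts = counts,
       truth = list(span = range(span), rate_low = rate_low,
                    rate_global = rate_global,
                    is_stratum = rate_low != rate_global))
}
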