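COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chars <- function(x) rev(unname(COMPLEMENT[x]))

# Genomic positions of a gene's CDS in translation order (5'->3' of the
# mRNA), plus the corresponding reference bases in CDS orientation.
cds_layout <- function(genes, gene_id, seqs) {
  g <- genes[genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0L) stop("unknown gene: ", gene_id)
  sc <- g$scaffold[1]
  chars <- strsplit(seqs[[sc]], "", fixed = TRUE)[[1]]
  if (any(g$start < 1 | g$end > length(chars)))
    stop("CDS outside scaffold bounds for gene ", gene_id)
  g <- g[order(g$start), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(g)),
                       function(i) seq.int(g$start[i], g$end[i])))
  minus <- g$strand[1] == "-"
  if (minus) {
    bases <- unname(COMPLEMENT[chars[rev(pos)]])
    pos <- rev(pos)
  } else {
    bases <- chars[pos]
  }
  list(gene_id = gene_id, scaffold = sc, strand = g$strand[1],
       pos = pos, bases = bases, minus = minus)
}

#' Filter gene models for divergence analysis
#'
#' A gene survives when it is not flagged partial, does not use the
#' mitochondrial code (transl_table 5), has a CDS length that is a
#' multiple of three, contains no N in its reference coding sequence, and
#' has no retained insertion/deletion variant overlapping its CDS in any
#' sample (indels would break the gap-free consensus construction).
#'
#' @param genes Gene-model data.frame (see [read_gene_models()]).
#' @param seqs Named reference sequences.
#' @param vt Optional [variant_table()] whose indel records veto genes.
#' @return The surviving subset of `genes`.
#' @export
filter_genes <- function(genes, seqs, vt = NULL) {
  ids <- unique(genes$gene_id)
  indels <- if (!is.null(vt))
    vt$sites[vt$sites$class == "indel", , drop = FALSE] else NULL
  keep <- vapply(ids, function(id) {
    g <- genes[genes$gene_id == id, , drop = FALSE]
    if (any(g$partial) || any(g$transl_table == 5L)) return(FALSE)
    len <- sum(g$end - g$start + 1L)
    if (len %% 3L != 0L) return(FALSE)
    lay <- cds_layout(genes, id, seqs)
    if (any(lay$bases == "N")) return(FALSE)
    if (!is.null(indels) && nrow(indels) > 0) {
      sc_ind <- indels[indels$scaffold == g$scaffold[1], , drop = FALSE]
      if (nrow(sc_ind) > 0) {
        span_end <- sc_ind$pos + nchar(sc_ind$ref) - 1L
        for (i in seq_len(nrow(g)))
          if (any(sc_ind$pos <= g$end[i] & span_end >= g$start[i]))
            return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  genes[genes$gene_id %in% ids[keep], , drop = FALSE]
}

#' Classify the coding effect of a SNP
#'
#' Looks up the affected codon under the standard nuclear genetic code
#' (strand-aware: alleles of minus-strand genes are complemented into CDS
#' orientation) and reports whether the substitution changes the encoded
#' amino acid. SNPs outside the CDS are `"noncoding"`.
#'
#' @param genes Gene-model data.frame.
#' @param gene_id Gene to evaluate against.
#' @param seqs Named reference sequences.
#' @param pos 1-based genomic position of the SNP.
#' @param ref,alt Reference and alternate alleles (A/C/G/T, genome strand).
#' @return `"synonymous"`, `"nonsynonymous"` or `"noncoding"`.
#' @export
classify_snp_effect <- function(genes, gene_id, seqs, pos, ref, alt) {
  if (!all(c(ref, alt) %in% c("A", "C", "G", "T")))
    stop("alleles must be A/C/G/T, got ", ref, "/", alt)
  lay <- cds_layout(genes, gene_id, seqs)
  ci <- match(pos, lay$pos)
  if (is.na(ci)) return("noncoding")
  alt_cds <- if (lay$minus) unname(COMPLEMENT[alt]) else alt
  codon_i <- (ci - 1L) %/% 3L
  frame <- (ci - 1L) %% 3L + 1L
  codon <- lay$bases[codon_i * 3L + 1:3]
  codon_alt <- codon
  codon_alt[frame] <- alt_cds
  code <- Biostrings::GENETIC_CODE
  aa_ref <- code[[paste(codon, collapse = "")]]
  aa_alt <- code[[paste(codon_alt, collapse = "")]]
  if (identical(aa_ref, aa_alt)) "synonymous" else "nonsynonymous"
}

#' Build group consensus coding sequences
#'
#' Produces one representative CDS per group from the fixed differences
#' between the two groups: the first group's consensus is the reference
#' CDS with that group's alleles substituted at fixed-difference SNPs
#' (identity when the reference individual belongs to this group), the
#' second group's substitutes its alleles. Minus-strand genes are
#' represented in CDS orientation. Indel fixed differences never reach
#' this step because [filter_genes()] removes affected genes.
#'
#' @param genes Gene-model data.frame.
#' @param gene_id Gene of interest.
#' @param seqs Named reference sequences.
#' @param vt Whole-set-filtered [variant_table()].
#' @param ss A [sample_set()].
#' @return List of class `consensus_pair`: `gene_id`, `seq_a`, `seq_b`
#'   (character vectors of bases), `applied` (data.frame of substituted
#'   sites), `groups`.
#' @export
build_consensus_pair <- function(genes, gene_id, seqs, vt, ss) {
  lay <- cds_layout(genes, gene_id, seqs)
  gl <- group_levels(ss)
  fd <- fixed_differences(vt, ss)
  seq_a <- lay$bases
  seq_b <- lay$bases
  applied <- data.frame(pos = integer(), cds_index = integer(),
                        allele_a = character(), allele_b = character())
  if (length(fd$sites)) {
    sub_vt <- vt_subset(vt, fd$sites)
    snp <- sub_vt$sites$class == "snp" &
      sub_vt$sites$scaffold == lay$scaffold &
      sub_vt$sites$pos %in% lay$pos
    if (any(snp)) {
      sub_vt <- vt_subset(sub_vt, snp)
      ia <- match(group_samples(ss, gl[1])[1], sub_vt$samples)
      ib <- match(group_samples(ss, gl[2])[1], sub_vt$samples)
      for (k in seq_len(nrow(sub_vt$sites))) {
        alleles <- c(sub_vt$sites$ref[k],
                     strsplit(sub_vt$sites$alt[k], ",", fixed = TRUE)[[1]])
        aa <- alleles[sub_vt$gt[k, ia] + 1L]
        ab <- alleles[sub_vt$gt[k, ib] + 1L]
        ci <- match(sub_vt$sites$pos[k], lay$pos)
        if (lay$minus) {
          aa <- unname(COMPLEMENT[aa]); ab <- unname(COMPLEMENT[ab])
        }
        seq_a[ci] <- aa
        seq_b[ci] <- ab
        applied <- rbind(applied, data.frame(
          pos = sub_vt$sites$pos[k], cds_index = ci,
          allele_a = aa, allele_b = ab))
      }
    }
  }
  structure(list(gene_id = gene_id, seq_a = seq_a, seq_b = seq_b,
                 applied = applied, groups = gl),
            class = "consensus_pair")
}

# Synonymous site count of one codon: for each position, the fraction of
# the three possible changes that preserve the encoded amino acid (stop
# codons participate as their own identity class, keeping N + S equal to
# the sequence length).
codon_syn_sites <- function(codon, code) {
  s <- 0
  aa <- code[[paste(codon, collapse = "")]]
  for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), codon[p])) {
    mut <- codon; mut[p] <- b
    if (identical(code[[paste(mut, collapse = "")]], aa)) s <- s + 1 / 3
  }
  s
}

# Count synonymous/nonsynonymous differences between two codons, averaging
# over all minimal mutation paths; paths passing through stop codons are
# excluded (unless every path does).
codon_diff_counts <- function(c1, c2, code) {
  diff_pos <- which(c1 != c2)
  nd <- length(diff_pos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- combinat_permutations(diff_pos)
  tally <- matrix(NA_real_, nrow = nrow(paths), ncol = 2)
  for (pi in seq_len(nrow(paths))) {
    cur <- c1
    s <- n <- 0
    blocked <- FALSE
    for (p in paths[pi, ]) {
      nxt <- cur; nxt[p] <- c2[p]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && !identical(nxt, c2)) blocked <- TRUE
      if (identical(aa1, aa2)) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (!blocked) tally[pi, ] <- c(s, n)
  }
  if (all(is.na(tally[, 1]))) tally <- matrix(c(0, nd), ncol = 2)  # all blocked
  c(syn = mean(tally[, 1], na.rm = TRUE),
    nonsyn = mean(tally[, 2], na.rm = TRUE))
}

combinat_permutations <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], combinat_permutations(x[-i])))
  out
}

#' Nei-Gojobori (1986) divergence between two coding sequences
#'
#' Counts synonymous and nonsynonymous sites per codon (averaged over the
#' two sequences), resolves observed codon differences with equal
#' weighting of minimal mutation paths (paths through stop codons
#' excluded), and applies the Jukes-Cantor correction
#' d = -(3/4) log(1 - 4p/3) to the proportions pN = ND/N and pS = SD/S.
#'
#' @param pair A `consensus_pair` from [build_consensus_pair()], or a list
#'   with `seq_a`/`seq_b` character vectors of equal, in-frame length.
#' @return A one-row data.frame (`divergence_record`): `gene_id`, `n_sites`,
#'   `s_sites`, `nd`, `sd`, `pn`, `ps`, `dn`, `ds`, `dnds` (NA when dS = 0),
#'   `saturated` (TRUE when a proportion reaches 3/4 and the correction is
#'   undefined).
#' @examples
#' ng86_divergence(list(gene_id = "g", seq_a = strsplit("GGTGGTGGT", "")[[1]],
#'                      seq_b = strsplit("GGAGGTGGT", "")[[1]]))
#' @export
ng86_divergence <- function(pair) {
  s1 <- pair$seq_a; s2 <- pair$seq_b
  if (length(s1) != length(s2)) stop("sequences must have equal length")
  if (length(s1) %% 3L != 0L) stop("sequence length must be a multiple of 3")
  code <- Biostrings::GENETIC_CODE
  ncod <- length(s1) %/% 3L
  s_sites <- 0; sd_count <- 0; nd_count <- 0
  for (i in seq_len(ncod)) {
    idx <- (i - 1L) * 3L + 1:3
    c1 <- s1[idx]; c2 <- s2[idx]
    s_sites <- s_sites +
      (codon_syn_sites(c1, code) + codon_syn_sites(c2, code)) / 2
    d <- codon_diff_counts(c1, c2, code)
    sd_count <- sd_count + d[["syn"]]
    nd_count <- nd_count + d[["nonsyn"]]
  }
  n_sites <- 3 * ncod - s_sites
  ps <- if (s_sites > 0) sd_count / s_sites else 0
  pn <- if (n_sites > 0) nd_count / n_sites else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  ds <- jc(ps); dn <- jc(pn)
  data.frame(gene_id = if (!is.null(pair$gene_id)) pair$gene_id else NA,
             n_sites = n_sites, s_sites = s_sites,
             nd = nd_count, sd = sd_count, pn = pn, ps = ps,
             dn = dn, ds = ds,
             dnds = if (!is.na(ds) && ds > 0 && !is.na(dn)) dn / ds
                    else NA_real_,
             saturated = ps >= 3 / 4 || pn >= 3 / 4,
             stringsAsFactors = FALSE)
}

#' Compare gene dN/dS values against a background distribution
#'
#' Tests whether supergene-region dN/dS values exceed a genome-wide
#' background distribution (e.g. from a between-species ortholog
#' comparison supplied as a plain numbers file). The primary test is a
#' Wilcoxon signed-rank of the gene values against the background median;
#' an unpaired rank-sum against the full background is reported alongside.
#'
#' @param dnds Numeric vector of per-gene dN/dS (NA dropped).
#' @param background Numeric vector of background dN/dS values.
#' @param side Alternative for the signed-rank test (default
#'   `"greater"`: genes exceed the background median).
#' @return List with `signed_rank` (V, p), `rank_sum` (W, p) and
#'   `background_median`.
#' @export
dnds_background_comparison <- function(dnds, background,
                                       side = c("greater", "less",
                                                "two.sided")) {
  side <- match.arg(side)
  x <- dnds[!is.na(dnds)]
  med <- stats::median(background, na.rm = TRUE)
  sr <- suppressWarnings(
    stats::wilcox.test(x, mu = med, alternative = side,
                       exact = length(x) < 25))
  rs <- suppressWarnings(
    stats::wilcox.test(x, background, alternative = side, exact = FALSE))
  list(signed_rank = list(V = unname(sr$statistic), p = sr$p.value),
       rank_sum = list(W = unname(rs$statistic), p = rs$p.value),
       background_median = med)
}
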