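# One-gene toy genome: plus-strand CDS ATG AAA GGT TAA at positions 11-22.
toy_genome <- function() {
  pad5 <- "CCCCCCCCCC"; cds <- "ATGAAAGGTTAA"; pad3 <- "GGGGGGGGGG"
  c(s1 = paste0(pad5, cds, pad3))
}
toy_genes <- function(strand = "+", partial = FALSE, transl_table = 1L,
                      end = 22L) {
  data.frame(gene_id = "g1", scaffold = "s1", start = 11L, end = end,
             strand = strand, partial = partial,
             transl_table = transl_table, stringsAsFactors = FALSE)
}

test_that("gene filters remove partial, frame-shifted, mitochondrial, N and indel genes", {
  g <- toy_genome()
  expect_equal(nrow(filter_genes(toy_genes(), g)), 1)
  expect_equal(nrow(filter_genes(toy_genes(partial = TRUE), g)), 0)
  expect_equal(nrow(filter_genes(toy_genes(transl_table = 5L), g)), 0)
  expect_equal(nrow(filter_genes(toy_genes(end = 20L), g)), 0)  # length 10

  with_n <- c(s1 = sub("AAA", "ANA", g[["s1"]]))
  expect_equal(nrow(filter_genes(toy_genes(), with_n)), 0)

  # indel overlapping the CDS in one sample vetoes the gene
  ss <- make_test_ss(2)
  gt <- matrix(c(0L, 0L, 0L, 1L), 1)
  indel_vt <- make_test_vt(gt, pos = 15L, ref = "AA", alt = "A",
                           class = "indel")
  expect_equal(nrow(filter_genes(toy_genes(), g, indel_vt)), 0)
  away_vt <- make_test_vt(gt, pos = 2L, ref = "CC", alt = "C",
                          class = "indel")
  expect_equal(nrow(filter_genes(toy_genes(), g, away_vt)), 1)

  expect_error(filter_genes(toy_genes(end = 40L), g), "bounds")
})

test_that("SNP effects follow the standard code, strand-aware", {
  g <- toy_genome()
  genes <- toy_genes()
  # codon AAA third position A->G = AAG (Lys): synonymous
  expect_equal(classify_snp_effect(genes, "g1", g, pos = 16L, "A", "G"),
               "synonymous")
  # codon AAA first position A->G = GAA (Glu): nonsynonymous
  expect_equal(classify_snp_effect(genes, "g1", g, pos = 14L, "A", "G"),
               "nonsynonymous")
  expect_equal(classify_snp_effect(genes, "g1", g, pos = 5L, "C", "T"),
               "noncoding")
  expect_error(classify_snp_effect(genes, "g1", g, pos = 16L, "A", "X"),
               "A/C/G/T")

  # minus strand: CDS = revcomp of the genomic span TTACCCTTTCAT, i.e.
  # ATGAAAGGGTAA; CDS index i sits at genomic position 23 - i, so the third
  # position of the AAA codon (CDS index 6) is genomic position 17.
  # Genomic T->C complements to CDS A->G: AAA -> AAG, both Lys.
  rc <- paste0("CCCCCCCCCC", "TTACCCTTTCAT", "GGGGGGGGGG")
  genes_m <- toy_genes(strand = "-")
  gm <- c(s1 = rc)
  expect_equal(classify_snp_effect(genes_m, "g1", gm, pos = 17L, "T", "C"),
               "synonymous")
  # first position of the same codon (CDS index 4, genomic 19): A->C is
  # AAA -> CAA, Lys -> Gln
  expect_equal(classify_snp_effect(genes_m, "g1", gm, pos = 19L, "T", "G"),
               "nonsynonymous")
})

test_that("consensus pairs substitute group alleles at fixed differences", {
  g <- c(s1 = "ATGAAA")
  genes <- data.frame(gene_id = "g1", scaffold = "s1", start = 1L, end = 6L,
                      strand = "+", partial = FALSE, transl_table = 1L)
  ss <- make_test_ss(2)
  # no fixed differences: both equal reference
  vt0 <- make_test_vt(matrix(c(0L, 1L, 0L, 1L), 1), pos = 4L, ref = "A",
                      alt = "G")
  p0 <- build_consensus_pair(genes, "g1", g, vt0, ss)
  expect_equal(paste(p0$seq_a, collapse = ""), "ATGAAA")
  expect_equal(paste(p0$seq_b, collapse = ""), "ATGAAA")

  # fixed SNP at CDS position 4, ref A alt G
  vt1 <- make_test_vt(matrix(c(0L, 0L, 1L, 1L), 1), pos = 4L, ref = "A",
                      alt = "G")
  p1 <- build_consensus_pair(genes, "g1", g, vt1, ss)
  expect_equal(paste(p1$seq_a, collapse = ""), "ATGAAA")
  expect_equal(paste(p1$seq_b, collapse = ""), "ATGGAA")

  # minus strand: genome TTTCAT, CDS = revcomp = ATGAAA; the fixed SNP at
  # genomic pos 4 (ref C, alt G) lands at CDS index 3 as G -> C
  # (oracle: manual reverse complement)
  gm <- c(s1 = "TTTCAT")
  genes_m <- genes; genes_m$strand <- "-"
  vt1m <- make_test_vt(matrix(c(0L, 0L, 1L, 1L), 1), pos = 4L, ref = "C",
                       alt = "G")
  pm <- build_consensus_pair(genes_m, "g1", gm, vt1m, ss)
  expect_equal(paste(pm$seq_a, collapse = ""), "ATGAAA")
  expect_equal(paste(pm$seq_b, collapse = ""), "ATCAAA")
})

test_that("NG86 reproduces hand-computed glycine-codon examples", {
  gly3 <- strsplit("GGTGGTGGT", "")[[1]]
  ident <- ng86_divergence(list(seq_a = gly3, seq_b = gly3))
  expect_equal(ident$dn, 0)
  expect_equal(ident$ds, 0)

  syn1 <- ng86_divergence(list(seq_a = gly3,
                               seq_b = strsplit("GGAGGTGGT", "")[[1]]))
  expect_equal(syn1$s_sites, 3)
  expect_equal(syn1$n_sites, 6)
  expect_equal(syn1$ps, 1 / 3)
  expect_equal(syn1$ds, -0.75 * log(1 - 4 / 9), tolerance = 1e-6)  # 0.4408
  expect_equal(syn1$dn, 0)

  # Gly -> Ser first-position change; site counts averaged over both
  # sequences: GGT contributes 1 synonymous site per codon, AGT only 1/3,
  # so S = (3 + 7/3)/2 = 8/3, N = 19/3 and pN = 1/(19/3) = 3/19
  non1 <- ng86_divergence(list(seq_a = gly3,
                               seq_b = strsplit("GGTAGTGGT", "")[[1]]))
  expect_equal(non1$s_sites, 8 / 3, tolerance = 1e-9)
  expect_equal(non1$pn, 3 / 19, tolerance = 1e-9)
  expect_equal(non1$dn, -0.75 * log(15 / 19), tolerance = 1e-6)     # 0.1773
  expect_equal(non1$ds, 0)
  expect_true(is.na(non1$dnds))
})

test_that("NG86 is symmetric and conserves N + S = CDS length", {
  set.seed(17)
  codons <- setdiff(names(Biostrings::GENETIC_CODE),
                    c("TAA", "TAG", "TGA"))
  for (i in 1:10) {
    a <- strsplit(paste(sample(codons, 8, TRUE), collapse = ""), "")[[1]]
    b <- a
    mut <- sample(24, 4)
    b[mut] <- sample(c("A", "C", "G", "T"), 4, TRUE)
    ra <- ng86_divergence(list(seq_a = a, seq_b = b))
    rb <- ng86_divergence(list(seq_a = b, seq_b = a))
    expect_equal(ra$n_sites + ra$s_sites, 24, tolerance = 1e-9)
    expect_equal(ra$nd, rb$nd, tolerance = 1e-9)
    expect_equal(ra$sd, rb$sd, tolerance = 1e-9)
    expect_equal(ra$ds, rb$ds, tolerance = 1e-9)
  }
})

test_that("planted fixed differences are recovered exactly when codons carry one change", {
  set.seed(33)
  ss <- make_test_ss(2)
  g <- c(s1 = paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""))
  genes <- data.frame(gene_id = "g1", scaffold = "s1", start = 1L, end = 120L,
                      strand = "+", partial = FALSE, transl_table = 1L)
  chars <- strsplit(g[["s1"]], "")[[1]]
  # plant fixed SNPs in distinct codons
  pos <- c(5L, 31L, 62L, 100L)
  alt <- vapply(pos, function(p)
    sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1), character(1))
  planted <- vapply(seq_along(pos), function(i)
    classify_snp_effect(genes, "g1", g, pos[i], chars[pos[i]], alt[i]),
    character(1))
  vt <- make_test_vt(matrix(rep(c(0L, 0L, 1L, 1L), each = 1), 4, 4,
                            byrow = TRUE),
                     pos = pos, ref = chars[pos], alt = alt)
  pair <- build_consensus_pair(genes, "g1", g, vt, ss)
  rec <- ng86_divergence(pair)
  expect_equal(rec$nd, sum(planted == "nonsynonymous"))
  expect_equal(rec$sd, sum(planted == "synonymous"))
})

test_that("dN/dS background comparison behaves at its fixed points", {
  bg <- c(0.05, 0.1, 0.13, 0.2, 0.4)
  at_median <- dnds_background_comparison(rep(0.13, 10), bg)
  expect_equal(at_median$signed_rank$p, 1)
  above <- dnds_background_comparison(seq(0.5, 0.9, length.out = 8), bg,
                                      side = "greater")
  expect_equal(above$signed_rank$p, 1 / 2^8, tolerance = 1e-9)
  # simulation: shifted genes are detected
  set.seed(4)
  bg2 <- rexp(500, 10)
  genes_up <- rexp(40, 10) + 0.2
  expect_lt(dnds_background_comparison(genes_up, bg2)$signed_rank$p, 1e-4)
})
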