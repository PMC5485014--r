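test_that("windows tile non-N positions and stretch over gaps", {
  plain <- make_windows(c(s = strrep("A", 100000)), size = 30000, step = 10000)
  expect_equal(plain$start, seq(1, 70001, by = 10000))
  expect_equal(plain$end[1], 30000)
  expect_true(all(plain$accessible[!plain$partial] == 30000))

  # a 5 kb N block inside the first window pushes its end 5 kb further;
  # oracle: explicit scan of non-N positions
  gapped_seq <- paste0(strrep("A", 10000), strrep("N", 5000),
                       strrep("A", 85000))
  gapped <- make_windows(c(s = gapped_seq), size = 30000, step = 30000)
  nn <- which(strsplit(gapped_seq, "")[[1]] != "N")
  expect_equal(gapped$start[1], nn[1])
  expect_equal(gapped$end[1], nn[30000])
  expect_equal(gapped$end[1], 35000)

  tiling <- make_windows(c(s = strrep("A", 50000)), size = 10000, step = 10000)
  expect_equal(tiling$start, c(1, 10001, 20001, 30001, 40001))
  expect_false(any(tiling$partial))

  expect_equal(nrow(make_windows(c(s = strrep("N", 5000)), 1000, 1000)), 0)
})

test_that("multilocus FST is 1 at a fixed difference and 0 without among-group variance", {
  ss <- make_test_ss()
  fixed <- make_test_vt(matrix(c(rep(0L, 8), rep(1L, 8)), nrow = 1))
  expect_equal(multilocus_fst(fixed, ss), 1.0)

  # groups of 2: {A,A} vs {A,T}; brute-force ANOVA gives a = 0
  ss2 <- sample_set(c("SB1", "SB2", "Sb1", "Sb2"), rep(c("SB", "Sb"), each = 2))
  vt2 <- make_test_vt(matrix(c(0L, 0L, 0L, 1L), nrow = 1))
  expect_equal(multilocus_fst(vt2, ss2), 0.0)
  expect_equal(oracle_fst(vt2$gt, rep(c("SB", "Sb"), each = 2)), 0.0)

  mono <- make_test_vt(matrix(0L, nrow = 3, ncol = 16))
  expect_true(is.na(multilocus_fst(mono, ss)))
  empty <- vt_subset(mono, integer(0))
  expect_true(is.na(multilocus_fst(empty, ss)))
})

test_that("multilocus FST agrees with the lm-based variance-components oracle", {
  ss <- make_test_ss()
  groups <- rep(c("SB", "Sb"), each = 8)
  set.seed(99)
  for (rep_i in 1:40) {
    n_sites <- sample(1:20, 1)
    gt <- matrix(sample(0:1, n_sites * 16, replace = TRUE,
                        prob = c(0.7, 0.3)), n_sites, 16)
    got <- multilocus_fst(make_test_vt(gt), ss)
    want <- oracle_fst(gt, groups)
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-12)
  }
  # multiallelic sites
  gt3 <- matrix(sample(0:2, 5 * 16, replace = TRUE), 5, 16)
  expect_equal(multilocus_fst(make_test_vt(gt3, alt = "T,G"), ss),
               oracle_fst(gt3, groups), tolerance = 1e-12)
})

test_that("nucleotide diversity equals the mean pairwise difference rate", {
  ss <- make_test_ss()
  mono <- make_test_vt(matrix(0L, 2, 16))
  expect_equal(nucleotide_diversity(mono, ss, "SB", accessible = 1e4), 0)

  # one SNP at 4/4 within SB: 16 of 28 pairs differ -> 16/28 per site
  split44 <- make_test_vt(matrix(c(rep(0L, 4), rep(1L, 4), rep(0L, 8)),
                                 nrow = 1))
  expect_equal(nucleotide_diversity(split44, ss, "SB", accessible = 1e4),
               (16 / 28) / 1e4, tolerance = 1e-12)

  # two singletons among 8: each site 7/28 = 0.25
  g <- matrix(0L, 2, 16); g[1, 1] <- 1L; g[2, 5] <- 1L
  expect_equal(nucleotide_diversity(make_test_vt(g), ss, "SB",
                                    accessible = 1e4),
               5.0e-5, tolerance = 1e-12)

  # invariance to relabelling within the group
  set.seed(5)
  gt <- matrix(sample(0:1, 6 * 16, replace = TRUE), 6, 16)
  vt <- make_test_vt(gt)
  perm <- c(sample(1:8), 9:16)
  vt_perm <- make_test_vt(gt[, perm])
  expect_equal(nucleotide_diversity(vt, ss, "SB", 1e4),
               nucleotide_diversity(vt_perm, ss, "SB", 1e4))
})

test_that("fixed differences require within-group monomorphism in both groups", {
  ss <- make_test_ss()
  yes <- matrix(c(rep(0L, 8), rep(1L, 8)), nrow = 1)
  near <- matrix(c(rep(0L, 8), rep(1L, 7), 0L), nrow = 1)
  gt <- rbind(yes, near)
  fd <- fixed_differences(make_test_vt(gt), ss)
  expect_equal(fd$snp, 1)
  expect_equal(fd$sites, 1L)
  # every fixed-difference site has single-site FST 1
  expect_equal(multilocus_fst(vt_subset(make_test_vt(gt), fd$sites), ss), 1.0)
})

test_that("STR fixed differences report repeat-unit distances", {
  ss <- make_test_ss()
  mk_st <- function(units) {
    n <- nrow(units)
    str_table(data.frame(locus_id = paste0("L", 1:n), scaffold = "s1",
                         pos = 1:n * 1000, period = 2, ref_units = 8,
                         score = 50),
              units, matrix(1, n, 16), matrix(5, n, 16), matrix(10, n, 16),
              samples = ss$sample)
  }
  units <- rbind(rep(10, 16),                       # monomorphic
                 c(rep(10, 8), rep(12, 8)),          # fixed, diff 2
                 c(10, rep(11, 7), rep(13, 8)))      # within-group variation
  out <- str_fixed_differences(mk_st(units), ss)
  expect_equal(nrow(out), 1)
  expect_equal(out$locus_id, "L2")
  expect_equal(out$unit_diff, 2)
})

test_that("genotype distances are sqrt(differing sites) and recover planted clusters", {
  gt <- cbind(a = c(0L, 0L, 0L), b = c(0L, 0L, 0L), c = c(1L, 1L, 0L))
  d <- genotype_distance_matrix(make_test_vt(gt))
  m <- as.matrix(d$dist)
  expect_equal(m["a", "b"], 0)
  expect_equal(m["a", "c"], sqrt(2))

  set.seed(21)
  block <- cbind(matrix(0L, 20, 8), matrix(1L, 20, 8))
  noise <- matrix(sample(0:1, 20 * 16, TRUE, prob = c(0.95, 0.05)), 20, 16)
  gt2 <- (block + noise) %% 2L
  colnames(gt2) <- c(paste0("SB", 1:8), paste0("Sb", 1:8))
  res <- genotype_distance_matrix(make_test_vt(gt2))
  cl <- cutree(res$hclust, k = 2)
  expect_equal(length(unique(cl[1:8])), 1)
  expect_equal(length(unique(cl[9:16])), 1)
  expect_true(cl[1] != cl[9])
})

test_that("window_stats assembles per-window FST, diversity and fixed counts", {
  ss <- make_test_ss()
  gt <- rbind(c(rep(0L, 8), rep(1L, 8)),   # fixed, pos 500
              c(1L, rep(0L, 15)),          # SB singleton, pos 1500
              c(rep(0L, 8), rep(1L, 8)))   # fixed, pos 2500
  vt <- make_test_vt(gt, pos = c(500L, 1500L, 2500L))
  w <- make_windows(c(s1 = strrep("A", 3000)), size = 1000, step = 1000)
  wsu <- window_stats(w, vt, ss)
  expect_equal(wsu$fixed_snps, c(1, 0, 1))
  expect_equal(wsu$fst[1], 1.0)
  expect_equal(wsu$pi_a[2], (7 / 28) / 1000)
  expect_equal(wsu$pi_b[2], 0)
})
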