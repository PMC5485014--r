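small_params <- function(seed = 1, ...) {
  sim_params(seed = seed,
             scaffold_lengths = c(scaffold_1 = 4e5, scaffold_2 = 2e5),
             region_span = list(scaffold = "scaffold_1",
                                start = 100001, end = 250000),
             gene_count = 10L, str_locus_count = 30L, ...)
}

test_that("parameter validation rejects impossible designs", {
  expect_error(sim_params(fixed_diff_density = 1.2), "densities")
  expect_error(sim_params(region_span = list(scaffold = "scaffold_1",
                                             start = 1, end = 9e7)),
               "region_span")
  expect_error(sim_params(gene_length = 100), "multiple of 3")
  expect_error(simulate_dataset(
    small_params(fixed_diff_density = 0.5, pi_SB_region = 0.4,
                 pi_Sb_region = 0.3)),
    "more than one variant per bp")
})

test_that("zero densities yield an empty variant table", {
  p <- small_params(fixed_diff_density = 0, pi_background = 0,
                    pi_SB_region = 0, pi_Sb_region = 0,
                    paired_siblings = FALSE, indel_fraction = 0)
  d <- simulate_dataset(p)
  expect_equal(nrow(d$vt$sites), 0)
})

test_that("identical seeds give byte-identical files, different seeds differ", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  simulate_dataset(small_params(seed = 7), dir = d1)
  simulate_dataset(small_params(seed = 7), dir = d2)
  simulate_dataset(small_params(seed = 8), dir = d3)
  for (f in c("genome.fasta", "variants.vcf", "genes.gff3", "markers.tsv",
              "str.tsv", "samples.tsv", "truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("determinism of", f))
  }
  expect_false(identical(unname(tools::md5sum(file.path(d1, "variants.vcf"))),
                         unname(tools::md5sum(file.path(d3, "variants.vcf")))))
})

test_that("every emitted variant belongs to exactly one truth class", {
  d <- simulate_dataset(small_params(seed = 3))
  expect_equal(nrow(d$truth$sites), nrow(d$vt$sites))
  expect_true(all(d$truth$sites$truth_class %in%
                    c("fixed", "SB-poly", "Sb-poly", "shared-poly")))
  key_vt <- paste(d$vt$sites$scaffold, d$vt$sites$pos)
  key_tr <- paste(d$truth$sites$scaffold, d$truth$sites$pos)
  expect_identical(key_vt, key_tr)
  expect_false(anyDuplicated(key_vt) > 0)
})

test_that("planted truth-class densities match requests within 4 binomial SDs", {
  p <- small_params(seed = 11)
  d <- simulate_dataset(p)
  region_nn <- sum(strsplit(d$genome[["scaffold_1"]], "")[[1]][
    p$region_span$start:p$region_span$end] != "N")
  n_fixed <- sum(d$truth$sites$truth_class == "fixed")
  exp_fixed <- p$fixed_diff_density * region_nn
  expect_lt(abs(n_fixed - exp_fixed), 4 * sqrt(exp_fixed))

  # truth genotypes honour the class definitions
  sb <- 1:8; sbb <- 9:16
  cls <- d$truth$sites$truth_class
  gt <- d$vt$gt
  fx <- which(cls == "fixed")
  expect_true(all(gt[fx, sb] == 0L) && all(gt[fx, sbb] == 1L))
  sbp <- which(cls == "SB-poly")
  expect_true(all(gt[sbp, sbb] == 0L))
  expect_true(all(rowSums(gt[sbp, sb, drop = FALSE]) > 0))
})

test_that("pair-private variants land on exactly one sibling pair", {
  d <- simulate_dataset(small_params(seed = 5))
  pp <- which(d$truth$sites$pair_private)
  expect_gt(length(pp), 0)
  for (i in pp[seq_len(min(20, length(pp)))]) {
    carriers <- which(d$vt$gt[i, ] == 1L)
    expect_equal(length(carriers), 2)
    expect_equal(d$ss$pair[carriers[1]], d$ss$pair[carriers[2]])
    expect_setequal(d$ss$group[carriers], c("SB", "Sb"))
  }
})

test_that("generated files are readable through the package readers", {
  dir <- tempfile()
  d <- simulate_dataset(small_params(seed = 2), dir = dir)
  vt <- read_vcf(d$files$vcf)
  expect_equal(vt$gt, d$vt$gt)
  expect_equal(read_genome(d$files$genome), d$genome)
  genes_back <- read_gene_models(d$files$gff)
  expect_setequal(unique(genes_back$gene_id), unique(d$genes$gene_id))
  st_back <- read_str_table(d$files$str)
  expect_equal(st_back$units, d$st$units)
  expect_equal(read_markers(d$files$markers), d$markers)
})

test_that("plant_stratum generates Poisson counts at the planted rates", {
  lens <- rep(1500, 50)
  zero <- plant_stratum(lens, 11:40, rate_global = 1 / 3000, rate_low = 0,
                        seed = 1)
  expect_true(all(zero$counts[11:40] == 0))
  expect_true(zero$truth$is_stratum)

  same <- plant_stratum(lens, 11:40, rate_global = 1 / 3000,
                        rate_low = 1 / 3000, seed = 1)
  expect_false(same$truth$is_stratum)

  expect_error(plant_stratum(lens, 11:40, 1 / 3000, -1), "non-negative")
  expect_error(plant_stratum(lens, 45:60, 1 / 3000, 0), "within")

  # Poisson mean at rate/10 over many genes
  big <- plant_stratum(rep(3000, 10000), 1:10000, rate_global = 1 / 3000,
                       rate_low = 1 / 30000, seed = 2)
  expect_equal(mean(big$counts), 0.1, tolerance = 0.1)
})
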