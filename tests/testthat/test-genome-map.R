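mk_markers <- function(scaffold, pos, lg = "lg1", cM = seq_along(pos),
                       fam = "sq1", ftype = "single-queen") {
  data.frame(marker_id = paste0(scaffold, "_", seq_along(pos)),
             scaffold = scaffold, pos = pos, linkage_group = lg, cM = cM,
             family_id = fam, family_type = ftype,
             cosegregates_gp9 = 0L, stringsAsFactors = FALSE)
}

test_that("low-confidence scaffolds are removed only under the single single-queen-map rule", {
  three_sq <- mk_markers("scA", c(10, 20, 30))
  expect_equal(nrow(filter_low_confidence_scaffolds(three_sq)), 0)

  three_mq <- mk_markers("scB", c(10, 20, 30), fam = "mq1",
                         ftype = "multiple-queen")
  expect_equal(nrow(filter_low_confidence_scaffolds(three_mq)), 3)

  four_sq <- mk_markers("scC", c(10, 20, 30, 40))
  expect_equal(nrow(filter_low_confidence_scaffolds(four_sq)), 4)

  # two maps, few markers each: kept
  two_maps <- rbind(mk_markers("scD", c(10, 20)),
                    mk_markers("scD", c(30, 40), fam = "sq2"))
  two_maps$marker_id <- paste0("scD_", 1:4)
  expect_equal(nrow(filter_low_confidence_scaffolds(two_maps)), 4)
})

test_that("chimeric scaffolds split into per-linkage-group segments", {
  chim <- rbind(mk_markers("scX", c(100e3, 150e3, 200e3), lg = "lg3"),
                mk_markers("scX", c(300e3, 350e3, 400e3), lg = "lg7"))
  out <- split_chimeric_scaffolds(chim)
  expect_equal(nrow(out$segments), 2)
  expect_equal(out$segments$seg_start, c(100e3, 300e3))
  expect_equal(out$segments$seg_end, c(200e3, 400e3))
  expect_equal(out$segments$linkage_group, c("lg3", "lg7"))

  single <- mk_markers("scY", c(10, 20))
  expect_equal(nrow(split_chimeric_scaffolds(single)$segments), 0)

  interleaved <- rbind(mk_markers("scZ", c(100, 300), lg = "lg1"),
                       mk_markers("scZ", c(200, 400), lg = "lg2"))
  expect_error(split_chimeric_scaffolds(interleaved), "chimera")
})

test_that("map building orders by mean cM and orients by cM-bp correlation", {
  mk <- rbind(mk_markers("sc1", c(100, 200, 300), cM = c(10, 11, 12)),
              mk_markers("sc2", c(100, 200, 300), cM = c(7, 6, 5)),
              mk_markers("sc3", 100, cM = 20))
  map <- build_map(mk, c(sc1 = 1000, sc2 = 1000, sc3 = 500))
  expect_equal(map$scaffold, c("sc2", "sc1", "sc3"))  # mean cM 6 < 11 < 20
  expect_equal(map$orientation, c("-", "+", "unknown"))
  expect_equal(map$pseudo_start, c(1, 1001, 2001))
  expect_equal(map$pseudo_end, c(1000, 2000, 2500))
  # total placed length equals sum of segment lengths
  expect_equal(sum(map$seg_end - map$seg_start + 1),
               max(map$pseudo_end))
})

test_that("marker conservation holds through filter + split", {
  set.seed(8)
  mk <- rbind(mk_markers("a", sort(sample(1e5, 6)), lg = "lg1"),
              mk_markers("b", sort(sample(1e5, 2))),  # dropped: 2 sq markers
              rbind(mk_markers("c", c(1e4, 2e4), lg = "lg1", fam = "mq1",
                               ftype = "multiple-queen"),
                    mk_markers("c", c(6e4, 8e4), lg = "lg2", fam = "mq1",
                               ftype = "multiple-queen")))
  filt <- filter_low_confidence_scaffolds(mk)
  out <- split_chimeric_scaffolds(filt)
  expect_lte(nrow(out$markers), nrow(mk))
  expect_identical(out$markers$linkage_group, filt$linkage_group)
  # planted chimera recovered exactly
  expect_equal(out$segments$seg_start, c(1e4, 6e4))
  expect_equal(out$segments$seg_end, c(2e4, 8e4))
})

test_that("anchored scaffolds are those with cosegregating markers", {
  mk <- rbind(mk_markers("a", c(10, 20)), mk_markers("b", c(10, 20)))
  expect_equal(anchor_markers(mk), character(0))
  mk$cosegregates_gp9[1] <- 1L
  mk$cosegregates_gp9[3] <- 1L
  expect_equal(anchor_markers(mk), c("a", "b"))
})

test_that("pseudo-coordinate conversion respects orientation", {
  mk <- rbind(mk_markers("sc1", c(100, 900), cM = c(1, 2)),
              mk_markers("sc2", c(100, 900), cM = c(9, 8)))
  map <- build_map(mk, c(sc1 = 1000, sc2 = 1000))
  fwd <- scaffold_to_pseudo(map, "sc1", 1)
  expect_equal(fwd$pseudo_pos, 1)
  rev_first <- scaffold_to_pseudo(map, "sc2", 1000)
  expect_equal(rev_first$pseudo_pos, 1001)  # "-" segment reversed
  expect_true(is.na(scaffold_to_pseudo(map, "sc9", 5)$pseudo_pos))
})
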