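test_that("re-windowing tiles tracks and averages depths exactly", {
  tr <- tibble::tibble(chrom = "chrI", start = 0L, end = 1000L, depth = 30)
  w <- window_depth(tr, 200L)
  expect_equal(nrow(w), 5L)
  expect_true(all(w$depth == 30))
  expect_equal(w$start, seq(0L, 800L, by = 200L))

  # a 77 kb mtDNA in 1 kb windows gives exactly 77 windows
  mt <- tibble::tibble(chrom = "chrM", start = 0L, end = 77000L, depth = 12)
  expect_equal(nrow(window_depth(mt, 1000L)), 77L)

  # a depth step at a window boundary stays exact on both sides
  step <- tibble::tibble(chrom = "chrI", start = c(0L, 400L),
                         end = c(400L, 800L), depth = c(10, 20))
  ws <- window_depth(step, 200L)
  expect_equal(ws$depth, c(10, 10, 20, 20))

  # trailing remnants: short ones merge left, long ones stand alone
  short_tail <- tibble::tibble(chrom = "c", start = 0L, end = 1100L,
                               depth = 7)
  wst <- window_depth(short_tail, 500L)
  expect_equal(wst$end, c(500L, 1100L))
  long_tail <- tibble::tibble(chrom = "c", start = 0L, end = 1400L,
                              depth = 7)
  wlt <- window_depth(long_tail, 500L)
  expect_equal(wlt$end, c(500L, 1000L, 1400L))
  expect_error(window_depth(tr[0, ], 200L), "empty")
})

test_that("mtDNA copy number is the euploid-median-normalized median ratio", {
  lens <- c(chrI = 20000L, chrII = 20000L, chrM = 5000L)
  cov <- gen_coverage(synth_coverage_config(
    chrom_lengths = lens, mt_copy_number = 20, mean_depth = 30,
    noise = "none", window_bp = 1000L, seed = 1L))
  prof <- mtdna_copy_number(cov$windows)
  expect_equal(prof$mt_copy_number, 20)
  expect_true(all(prof$windows$log2_ratio[prof$windows$chrom != "chrM"] == 0))

  # mtDNA identical to the nuclear background: copy number 1
  cov1 <- gen_coverage(synth_coverage_config(
    chrom_lengths = lens, mt_copy_number = 1, mean_depth = 30,
    noise = "none", window_bp = 1000L, seed = 1L))
  expect_equal(mtdna_copy_number(cov1$windows)$mt_copy_number, 1)
})

test_that("the median copy estimate is robust to sub-majority deletions", {
  # 30 of 77 mtDNA windows deleted: median unmoved, lost windows floored
  cov <- gen_coverage(synth_coverage_config(
    mt_copy_number = 20, mean_depth = 30, noise = "none",
    mt_deleted_intervals = list(c(14000L, 44000L)), window_bp = 1000L,
    seed = 1L))
  w1k <- window_depth(cov$windows, 1000L)
  prof <- mtdna_copy_number(w1k)
  expect_equal(prof$mt_copy_number, 20, tolerance = 1e-9)
  mt <- prof$windows[prof$windows$chrom == "chrM", ]
  inside <- mt$start >= 14000 & mt$end <= 44000
  expect_true(all(mt$log2_ratio[inside] == -10))
  expect_error(mtdna_copy_number(cov$windows[cov$windows$chrom == "chrM", ]),
               "euploid")
})

test_that("founder-normalized aneuploidy calls cancel library size", {
  lens <- c(chrI = 40000L, chrII = 30000L, chrIII = 30000L, chrM = 5000L)
  founder <- gen_coverage(synth_coverage_config(
    chrom_lengths = lens, mean_depth = 30, noise = "none", seed = 1L))
  same <- call_aneuploidies(founder$windows, founder$windows)
  expect_equal(same$kappa, 1)
  expect_true(all(same$calls$median_log2 == 0))
  expect_true(all(same$calls$call == "euploid"))
  expect_false("chrM" %in% same$calls$chrom)

  dup <- gen_coverage(synth_coverage_config(
    chrom_lengths = lens, duplicated_chroms = "chrII", mean_depth = 30,
    noise = "none", seed = 1L))
  ca <- call_aneuploidies(dup$windows, founder$windows)
  # closed-form kappa from chromosome lengths (mtDNA carries 20 copies in
  # both samples, so it contributes 20x its length to each depth total)
  G_nuc <- sum(lens) - lens[["chrM"]]
  L2 <- lens[["chrII"]]; LM <- lens[["chrM"]]
  kappa_expected <- (G_nuc + 20 * LM) / (G_nuc + L2 + 20 * LM)
  expect_equal(ca$kappa, kappa_expected, tolerance = 1e-12)
  m2 <- ca$calls$median_log2[ca$calls$chrom == "chrII"]
  expect_equal(m2, 1 + log2(kappa_expected), tolerance = 1e-12)
  expect_identical(ca$calls$call[ca$calls$chrom == "chrII"], "duplicated")
  expect_true(all(ca$calls$call[ca$calls$chrom != "chrII"] == "euploid"))

  # a global depth rescaling (library size) changes no call
  scaled <- dup$windows
  scaled$depth <- scaled$depth * 3.7
  ca2 <- call_aneuploidies(scaled, founder$windows)
  expect_equal(ca2$calls$median_log2, ca$calls$median_log2,
               tolerance = 1e-12)
  expect_error(call_aneuploidies(dup$windows[-1, ], founder$windows),
               "identical")
})

test_that("mtDNA segmentation recovers deletions with exact boundaries", {
  mk_profile <- function(log2s) {
    tibble::tibble(chrom = "chrM",
                   start = seq(0L, by = 1000L, length.out = length(log2s)),
                   end = seq(1000L, by = 1000L, length.out = length(log2s)),
                   log2_ratio = log2s)
  }
  # uniform retained molecule: one segment spanning everything
  seg <- segment_mtdna(mk_profile(rep(log2(20), 77)))
  expect_equal(nrow(seg), 1L)
  expect_identical(seg$state, "retained")
  expect_equal(c(seg$start, seg$end), c(0L, 77000L))

  # block deletion [14 kb, 44 kb): exact boundaries
  lr <- rep(log2(20), 77); lr[15:44] <- -10
  seg2 <- segment_mtdna(mk_profile(lr))
  lost <- seg2[seg2$state == "lost", ]
  expect_equal(c(lost$start, lost$end), c(14000L, 44000L))
  # segments tile the molecule and alternate in state
  expect_equal(sum(seg2$end - seg2$start), 77000L)
  expect_true(all(seg2$state[-1] != seg2$state[-nrow(seg2)]))

  # an isolated low window is absorbed at min_windows = 2
  lr3 <- rep(log2(20), 77); lr3[30] <- -10
  seg3 <- segment_mtdna(mk_profile(lr3), min_windows = 2L)
  expect_equal(nrow(seg3), 1L)
  expect_identical(seg3$state, "retained")
})

test_that("rho classification follows the retained-span thresholds", {
  seg <- function(retained_kb, total_kb = 77) {
    tibble::tibble(start = c(0L, retained_kb * 1000L),
                   end = c(retained_kb * 1000L, total_kb * 1000L),
                   state = c("retained", "lost"))
  }
  expect_identical(
    classify_rho(tibble::tibble(start = 0L, end = 77000L,
                                state = "retained"))$label, "rho_plus")
  expect_identical(classify_rho(seg(20))$label, "rho_minus")
  expect_identical(classify_rho(seg(0.8))$label, "rho_minus_minus")
  expect_identical(
    classify_rho(tibble::tibble(start = 0L, end = 77000L,
                                state = "lost"))$label, "rho_zero")
})

test_that("gene-level loss reports follow the overlap-fraction rule", {
  segs <- tibble::tibble(start = c(0L, 30000L), end = c(30000L, 77000L),
                         state = c("lost", "retained"))
  genes <- tibble::tibble(chrom = "chrM",
                          start = c(5000L, 50000L, 27000L),
                          end = c(8000L, 55000L, 32000L),
                          name = c("inside_lost", "inside_retained",
                                   "straddle_60_40"))
  rep50 <- map_segments_to_genes(segs, genes)
  expect_identical(rep50$state,
                   c("lost", "retained", "lost"))   # 60% lost >= 50%
  expect_equal(rep50$lost_fraction[3], 0.6)
  rep70 <- map_segments_to_genes(segs, genes, loss_fraction = 0.7)
  expect_identical(rep70$state[3], "retained")
  bad <- tibble::tibble(chrom = "chrM", start = 10L, end = 5L, name = "x")
  expect_error(map_segments_to_genes(segs, bad), "malformed")
})

test_that("the full CNV pipeline round-trips generated ground truth", {
  cfg <- synth_coverage_config(
    mt_copy_number = 20, mean_depth = 30, noise = "poisson",
    mt_deleted_intervals = list(c(14000L, 44000L)),
    duplicated_chroms = "chrII", window_bp = 200L, seed = 33L)
  cov <- gen_coverage(cfg)
  founder <- gen_coverage(synth_coverage_config(
    mean_depth = 30, noise = "poisson", window_bp = 200L, seed = 34L))

  an <- call_aneuploidies(cov$windows, founder$windows)
  dup <- an$calls$chrom[an$calls$call == "duplicated"]
  expect_identical(dup, "chrII")

  w1k <- window_depth(cov$windows, 1000L)
  prof <- mtdna_copy_number(w1k, aneuploid_chroms = dup)
  expect_equal(prof$mt_copy_number, 20, tolerance = 0.05 * 20)

  seg <- segment_mtdna(prof)
  lost <- seg[seg$state == "lost", ]
  expect_equal(nrow(lost), 1L)
  expect_lte(abs(lost$start - 14000), 1000)
  expect_lte(abs(lost$end - 44000), 1000)

  genes <- map_segments_to_genes(seg, mtdna_gene_annotation())
  expect_identical(genes$state[genes$gene == "COX1"], "lost")
  expect_identical(genes$state[genes$gene == "COX3"], "retained")
})
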