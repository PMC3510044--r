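test_that("spot log ratios are oriented mutant-over-reference", {
  expect_equal(spot_log_ratio(2000, 1000, "forward"), 1.0)
  expect_equal(spot_log_ratio(1000, 2000, "flipped"), 1.0)
  expect_true(is.na(spot_log_ratio(0, 1000, "forward")))
  expect_true(is.na(spot_log_ratio(1000, 0, "flipped")))
})

test_that("technical replicates combine by median with a survivor threshold", {
  mk <- function(flags) data.frame(
    gene_id = "g1", feature = "intron", block = 1:6,
    i_ch1 = 2000, i_ch2 = 1000, flag = flags, stringsAsFactors = FALSE)

  # symmetric array: add a mirrored gene so the array median is 0
  spots <- rbind(mk(rep(0L, 6)),
                 within(mk(rep(0L, 6)), {
                   gene_id <- "g2"; i_ch1 <- 1000; i_ch2 <- 2000
                 }))
  out <- combine_replicates(spots, "forward")
  expect_equal(out$log2_ratio[out$gene_id == "g1"], 1.0)
  expect_identical(out$n_spots_used[out$gene_id == "g1"], 6L)

  # 4 of 6 flagged with min_spots = 3 -> missing
  out2 <- combine_replicates(mk(c(-100L, -100L, -100L, -100L, 0L, 0L)),
                             "forward", pipeline_config(normalization = "none"))
  expect_true(is.na(out2$log2_ratio))
  expect_identical(out2$n_spots_used, 2L)
})

test_that("median centering removes a global dye-bias offset", {
  set.seed(42)
  base <- data.frame(
    gene_id = rep(sprintf("g%02d", 1:20), each = 6),
    feature = "intron", block = rep(1:6, 20),
    i_ch1 = 1000 * 2^rnorm(120, 0, 0.2), i_ch2 = 1000,
    flag = 0L, stringsAsFactors = FALSE)
  shifted <- base
  shifted$i_ch1 <- shifted$i_ch1 * 2^0.5   # +0.5 log2 everywhere
  expect_equal(combine_replicates(base, "forward")$log2_ratio,
               combine_replicates(shifted, "forward")$log2_ratio,
               tolerance = 1e-12)
})

test_that("an array with zero usable spots returns empty with a warning", {
  spots <- data.frame(gene_id = "g1", feature = "exon", block = 1L,
                      i_ch1 = 100, i_ch2 = 100, flag = -50L,
                      stringsAsFactors = FALSE)
  expect_warning(out <- combine_replicates(spots, "forward"), "zero usable")
  expect_identical(nrow(out), 0L)
})

test_that("biological averaging is an unweighted mean over non-missing arrays", {
  tabs <- list(
    data.frame(gene_id = "g1", feature = "intron", log2_ratio = 0.8,
               n_spots_used = 6L, stringsAsFactors = FALSE),
    data.frame(gene_id = "g1", feature = "intron", log2_ratio = NA_real_,
               n_spots_used = 0L, stringsAsFactors = FALSE),
    data.frame(gene_id = "g1", feature = "intron", log2_ratio = 1.2,
               n_spots_used = 6L, stringsAsFactors = FALSE))
  out <- average_biological(tabs)
  expect_equal(out$log2_ratio, 1.0)
  expect_identical(out$n_arrays_used, 2L)
  expect_warning(average_biological(tabs[1]), "single replicate")
})

test_that("IAI is the intron minus exon log ratio, shift invariant", {
  expect_equal(compute_iai(exon_lr = 0.2, intron_lr = 1.0), 0.8)
  x <- rnorm(20)
  expect_equal(compute_iai(x, x), rep(0, 20))
  c0 <- 1.7
  expect_equal(compute_iai(x + c0, x + 0.5 + c0), compute_iai(x, x + 0.5))
})

test_that("defect calls use a strict cutoff and the max over introns", {
  profiles <- data.frame(
    gene_id = c("gA", "gB", "gC", "gC_2", "gD"),
    exon_lr = 0, intron_lr = c(0.31, 0.30, 0.1, 0.9, NA),
    junction_lr = 0,
    iai = c(0.31, 0.30, 0.1, 0.9, NA),
    stringsAsFactors = FALSE)
  res <- classify_defects(profiles)
  calls <- setNames(res$calls$defect_class, res$calls$gene)
  expect_identical(calls[["gA"]], "defective")   # 0.31 > 0.3
  expect_identical(calls[["gB"]], "none")        # boundary is strict
  expect_identical(calls[["gC"]], "defective")   # any-intron rule
  expect_identical(calls[["gD"]], "missing")
  expect_equal(res$calls$max_iai[res$calls$gene == "gC"], 0.9)
  expect_identical(res$n_missing, 1L)
  # gC lands in the (0.6, 1] severity bin by its worse intron
  expect_identical(unname(res$histogram), c(1L, 1L, 0L))
})

test_that("raising the cutoff never increases the defective count", {
  set.seed(7)
  profiles <- data.frame(
    gene_id = sprintf("g%03d", 1:200), exon_lr = 0,
    intron_lr = rnorm(200, 0.2, 0.4), junction_lr = 0,
    iai = rnorm(200, 0.2, 0.4), stringsAsFactors = FALSE)
  cuts <- seq(0.1, 1.2, by = 0.1)
  counts <- vapply(cuts, function(ct)
    classify_defects(profiles, pipeline_config(iai_cutoff = ct))$n_defective,
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("uncentered Pearson matches its closed form", {
  x <- c(1, 2, 3)
  expect_equal(uncentered_pearson(x, x), 1.0)
  expect_equal(uncentered_pearson(c(1, 0), c(0, 1)), 0.0)
  expect_equal(uncentered_pearson(c(1, 1), c(1, -1)), 0.0)
  # pairwise NA exclusion
  expect_equal(uncentered_pearson(c(1, NA, 2), c(1, 5, 2)),
               uncentered_pearson(c(1, 2), c(1, 2)))
  expect_warning(z <- uncentered_pearson(c(0, 0), c(1, 2)), "all-zero")
  expect_equal(z, 0)
})

test_that("clustering merges identical rows first and handles degenerate input", {
  mat <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, -2, 0.5))
  hc <- cluster_profiles(mat)
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_setequal(hc$merge[1, ], c(-1L, -2L))
  expect_identical(cluster_profiles(mat[1, , drop = FALSE])$order, 1L)
})

test_that("cluster merge heights match the naive O(n^3) oracle", {
  set.seed(13)
  for (n in c(4, 7, 12)) {
    mat <- matrix(rnorm(n * 5), n)
    d <- uncentered_pearson_dist(mat)
    hc <- cluster_profiles(mat)
    expect_equal(hc$height, naive_average_linkage(d), tolerance = 1e-12)
  }
})

test_that("pipeline is dye-flip invariant at zero noise", {
  cfg <- small_array_cfg(noise_sd = 0, flag_rate = 0, dye_bias = 0.3,
                         defect_genes = c(YSN0005C = 0.9),
                         exon_effect_genes = c(YSN0005C = 0.4))
  exp1 <- generate_array_experiment(cfg)
  fwd <- Filter(function(a) a$sample$orientation == "forward", exp1$arrays)
  flp <- Filter(function(a) a$sample$orientation == "flipped", exp1$arrays)
  run <- function(arrs) process_experiment(list(arrays = arrs))$profiles
  expect_equal(run(fwd), run(flp), tolerance = 1e-12)
  # and the planted IAI is recovered exactly, independent of the exon effect
  prof <- run(fwd)
  expect_equal(prof$iai[prof$gene_id == "YSN0005C"], 0.9, tolerance = 1e-9)
  expect_equal(prof$exon_lr[prof$gene_id == "YSN0005C"], 0.4, tolerance = 1e-9)
})
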