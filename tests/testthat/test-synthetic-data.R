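test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(noise_sd = -0.1), "noise_sd")
  expect_error(sim_config(flag_rate = 1.5), "fraction")
  expect_error(sim_config(n_tech_reps = 0), "n_tech_reps")
  expect_error(sim_config(defect_genes = c(1, 2)), "named")
})

test_that("generated catalog honors the construction contract", {
  cfg <- small_array_cfg(n_sets = 10)
  cat1 <- generate_catalog(cfg)
  expect_length(cat1, 11L)  # 10 requested + the fixed trio
  expect_true("RAD6_complex" %in% names(cat1$sets))
  expect_length(cat1$sets$RAD6_complex, 3L)
  expect_true(all(unlist(cat1$sets) %in% cat1$universe))
  expect_true(all(lengths(cat1$sets) >= 2L))
})

test_that("catalog generation is deterministic and rejects infeasible sizes", {
  cfg <- small_array_cfg()
  expect_identical(generate_catalog(cfg), generate_catalog(cfg))
  expect_error(
    generate_catalog(sim_config(n_genes = 20, set_size_range = c(50, 50))),
    "exceeds")
})

test_that("interaction generator plants complexes into the E-MAP scores", {
  cfg <- small_array_cfg(planted_complexes = c(RAD6_complex = -4))
  cat1 <- generate_catalog(cfg)
  ia <- generate_interaction_data(cfg, cat1)
  members <- cat1$sets$RAD6_complex
  sc <- setNames(ia$emap$score, ia$emap$gene)
  expect_gt(mean(sc[members] <= -2.5), 0.5)
  expect_setequal(ia$truth$true_negative_genes, members)
  expect_identical(ia$truth$enriched_sets, "RAD6_complex")
  expect_error(
    generate_interaction_data(
      small_array_cfg(planted_complexes = c(NOPE = -4)), cat1),
    "NOPE")
})

test_that("background E-MAP tail matches the normal closed form", {
  cfg <- sim_config(seed = 5, n_genes = 20000, n_sets = 2)
  ia <- generate_interaction_data(cfg, generate_catalog(cfg))
  frac <- mean(ia$emap$score <= -2.5)
  expected <- pnorm(-2.5, sd = cfg$emap_sd)
  se <- sqrt(expected * (1 - expected) / cfg$n_genes)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("interaction generator is reproducible under a fixed seed", {
  cfg <- small_array_cfg(planted_complexes = c(RAD6_complex = -4))
  cat1 <- generate_catalog(cfg)
  expect_identical(generate_interaction_data(cfg, cat1),
                   generate_interaction_data(cfg, cat1))
})

test_that("array spots average to the planted effects", {
  cfg <- small_array_cfg(
    defect_genes = c(YSN0001C = 1.0),
    exon_effect_genes = c(YSN0002C = 0.7),
    noise_sd = 0.15, flag_rate = 0, dye_bias = 0)
  exp1 <- generate_array_experiment(cfg)
  lr_all <- do.call(rbind, lapply(exp1$arrays, function(a) {
    cbind(a$spots[c("gene_id", "feature")],
          lr = spot_log_ratio(a$spots$i_ch1, a$spots$i_ch2,
                              a$sample$orientation))
  }))
  # per-channel noise => spot log-ratio sd is noise_sd * sqrt(2)
  pick <- function(g, f) lr_all$lr[lr_all$gene_id == g & lr_all$feature == f]
  tol <- 3 * cfg$noise_sd * sqrt(2) / sqrt(6 * cfg$n_tech_reps)
  expect_lt(abs(mean(pick("YSN0001C", "intron")) - 1.0), tol)
  expect_lt(abs(mean(pick("YSN0001C", "exon")) - 0.0), tol)
  expect_lt(abs(mean(pick("YSN0002C", "intron")) - 0.7), tol)
  expect_lt(abs(mean(pick("YSN0002C", "exon")) - 0.7), tol)
})

test_that("dye-flipped arrays mirror forward arrays spot-for-spot at zero noise", {
  cfg <- small_array_cfg(noise_sd = 0, flag_rate = 0, dye_bias = 0,
                         defect_genes = c(YSN0003C = 0.8))
  exp1 <- generate_array_experiment(cfg)
  fwd <- exp1$arrays$mutant_b1_forward
  flp <- exp1$arrays$mutant_b1_flipped
  lr_f <- log2(fwd$spots$i_ch1 / fwd$spots$i_ch2)
  lr_r <- log2(flp$spots$i_ch1 / flp$spots$i_ch2)
  expect_equal(lr_f, -lr_r, tolerance = 1e-12)
})

test_that("array generator enforces ground-truth linkage and the universe", {
  cfg <- small_array_cfg(defect_genes = c(YSN0004C = 1.2))
  exp1 <- generate_array_experiment(cfg)
  planted <- names(exp1$truth$true_iai)[exp1$truth$true_iai != 0]
  expect_identical(planted, "YSN0004C")
  expect_false("YSN0004C" %in% exp1$truth$true_negative_genes)
  genes <- unique(sub("_2$", "", exp1$arrays[[1]]$spots$gene_id))
  expect_true(all(genes %in% sim_universe(cfg)))
  expect_error(generate_array_experiment(
    small_array_cfg(defect_genes = c(YSN9999C = 1))), "intron-gene list")
})

test_that("second introns appear as _2 rows with their own planted effects", {
  cfg <- small_array_cfg(frac_two_intron = 0.5)
  exp1 <- generate_array_experiment(cfg)
  ids <- unique(exp1$arrays[[1]]$spots$gene_id)
  two <- grep("_2$", ids, value = TRUE)
  expect_gt(length(two), 0)
  feats <- unique(exp1$arrays[[1]]$spots$feature[
    exp1$arrays[[1]]$spots$gene_id == two[1]])
  expect_setequal(feats, c("intron", "junction"))
})

test_that("identical configs give byte-identical array experiments", {
  cfg <- small_array_cfg(defect_genes = c(YSN0001C = 1))
  expect_identical(generate_array_experiment(cfg),
                   generate_array_experiment(cfg))
})

test_that("null-model defect rate matches a direct simulation of the noise chain", {
  # informative tail: large noise, single biological replicate (2 arrays)
  cfg <- small_array_cfg(seed = 21, n_genes = 400, n_intron_genes = 300,
                         frac_two_intron = 0, noise_sd = 0.5,
                         n_bio_reps = 1, flag_rate = 0)
  exp1 <- generate_array_experiment(cfg)
  res <- suppressWarnings(process_experiment(exp1))
  observed <- mean(res$defects$calls$max_iai > 0.3)

  # oracle: same combine chain (median of 6 spot ratios per array, mean of
  # 2 arrays, intron - exon), simulated directly from the noise model
  set.seed(99)
  nsim <- 20000
  sim_feature <- function() {
    rowMeans(cbind(
      apply(matrix(rnorm(6 * nsim, 0, cfg$noise_sd * sqrt(2)), nsim), 1, median),
      apply(matrix(rnorm(6 * nsim, 0, cfg$noise_sd * sqrt(2)), nsim), 1, median)))
  }
  iai_null <- sim_feature() - sim_feature()
  expected <- mean(iai_null > 0.3)
  tol <- 2 * sqrt(expected * (1 - expected) / cfg$n_intron_genes) +
    2 * sqrt(expected * (1 - expected) / nsim)
  expect_lt(abs(observed - expected), tol)
})
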