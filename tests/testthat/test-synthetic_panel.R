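test_that("configuration errors name the offending field", {
  expect_error(panel_config(n_accessions = 3), "n_accessions")
  expect_error(panel_config(frac_tolerant = 0), "frac_tolerant")
  expect_error(panel_config(frac_tolerant = 1), "frac_tolerant")
  bad <- default_index_defs(); bad$sd[2] <- 0
  expect_error(panel_config(index_defs = bad), "SD")
  bad2 <- default_locus_defs()
  bad2[[2]]$freq_tolerant <- c(1, 0, 0)
  expect_error(panel_config(locus_defs = bad2), "OsHAK21")
})

test_that("same config and seed give identical panels; seeds differ", {
  p1 <- generate_panel(panel_config(seed = 5))
  p2 <- generate_panel(panel_config(seed = 5))
  expect_identical(p1, p2)
  p3 <- generate_panel(panel_config(seed = 6))
  expect_false(identical(p1$observations$value, p3$observations$value))
})

test_that("every accession has observations for every (index, treatment, timepoint)", {
  p <- generate_panel(panel_config(seed = 2))
  counts <- table(p$observations$accession_id, p$observations$index,
                  p$observations$treatment, p$observations$timepoint_d)
  expect_true(all(counts == 3))
  expect_true(all(p$observations$value[p$observations$index == "STS"] %in% 1:9))
  expect_setequal(p$truth$accession_id, p$accessions$accession_id)
})

test_that("substreams are independent: adding Ct records leaves traits untouched", {
  cfg_a <- panel_config(seed = 11, ct_timepoints = c(0, 6))
  cfg_b <- panel_config(seed = 11, ct_timepoints = c(0, 3, 6, 12, 24, 48))
  pa <- generate_panel(cfg_a); pb <- generate_panel(cfg_b)
  expect_identical(pa$observations, pb$observations)
  expect_identical(pa$genotypes, pb$genotypes)
})

test_that("marginal means calibrate to the configured cell means", {
  cfg <- panel_config(n_accessions = 500, seed = 77, locus_defs = list(),
                      ct_targets = NULL, timepoints = 6)
  p <- generate_panel(cfg)
  idx <- cfg$index_defs
  lat <- setNames(p$truth$latent, p$truth$accession_id)
  for (i in which(idx$index != "STS")) {
    for (trt in c("CK", "SST")) {
      sl <- p$observations[p$observations$index == idx$index[i] &
                             p$observations$treatment == trt, ]
      eff <- if (trt == "SST") {
        mean((1 - lat[sl$accession_id]) * idx$effect_sensitive[i] +
               lat[sl$accession_id] * idx$effect_tolerant[i])
      } else 0
      sdv <- if (trt == "SST") idx$sd_stress[i] else idx$sd[i]
      se <- sdv / sqrt(nrow(sl))
      expect_lt(abs(mean(sl$value) - (idx$baseline[i] + eff)), 3 * se + 1e-12)
    }
  }
})

test_that("under the null the class contrast rejects at the nominal rate", {
  # scaled-down check; the full 1000-panel calibration runs in the
  # acceptance suite
  rejections <- 0L
  n_rep <- 200L
  for (s in seq_len(n_rep)) {
    p <- generate_panel(small_panel_config(seed = 20000 + s, null_effects = TRUE))
    sl <- p$observations[p$observations$treatment == "SST", ]
    mu <- tapply(sl$value, sl$accession_id, mean)
    cls <- setNames(p$accessions$class, p$accessions$accession_id)
    tt <- independent_t(mu[cls[names(mu)] == "tolerant"],
                        mu[cls[names(mu)] == "sensitive"])
    if (tt$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_lt(abs(rejections / n_rep - 0.05), 0.04)
})

test_that("OLS on STS recovers the configured SSR repeat effect", {
  idx <- default_index_defs()
  # remove the class contrast on STS so the locus effect is unconfounded
  idx$effect_sensitive[1] <- idx$effect_tolerant[1] <- -3
  ssr <- default_locus_defs(ssr_effect_per_repeat = -0.5)[[2]]
  ssr$freq_tolerant <- ssr$freq_sensitive <- rep(0.25, 4)
  cfg <- panel_config(n_accessions = 200, index_defs = idx,
                      locus_defs = list(ssr), ct_targets = NULL,
                      timepoints = 6, seed = 31)
  p <- generate_panel(cfg)
  reps <- setNames(as.integer(p$genotypes$allele), p$genotypes$accession_id)
  fit <- lm(p$accessions$sts ~ reps[p$accessions$accession_id])
  est <- summary(fit)$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - (-0.5)), 2 * est["Std. Error"])
})

test_that("panel tables round-trip losslessly through the TSV writers", {
  p <- generate_panel(panel_config(seed = 3))
  dir <- tempfile("panel")
  paths <- panel_to_tables(p, dir)
  expect_true(all(file.exists(paths)))
  back <- read_panel_tables(dir)
  expect_identical(back$observations, p$observations)
  expect_identical(back$genotypes, p$genotypes)
  expect_identical(back$ct_records, p$ct_records)

  empty <- p; empty$observations <- p$observations[0, ]
  expect_error(panel_to_tables(empty, tempfile()), "empty")
})

test_that("a strongly separated panel ranks all tolerant accessions on top", {
  p <- generate_panel(panel_config(seed = 14))
  m <- build_index_matrix(p$observations, "SST", 6)
  ev <- suppressWarnings(evaluate_panel(m))
  cls <- setNames(p$accessions$class, p$accessions$accession_id)
  top6 <- ev$membership$accession_id[order(ev$membership$rank)][1:6]
  expect_true(all(cls[top6] == "tolerant"))
})
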