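wells_fixture <- function(ct = c(25.0, 25.2, 24.8)) {
  tibble::tibble(sample_id = "s1", gene = "g", region = "promoter",
                 treatment = "AAG+APE1", replicate = seq_along(ct), ct = ct)
}

test_that("aggregate_ct averages replicates on the Ct scale", {
  expect_equal(aggregate_ct(wells_fixture())$ct_mean, 25.0)
  expect_equal(aggregate_ct(wells_fixture(26.1))$ct_mean, 26.1)
  expect_equal(aggregate_ct(wells_fixture())$n_replicates, 3L)
  expect_error(aggregate_ct(wells_fixture()[0, ]),
               class = "bertx_missing_data")
  expect_error(aggregate_ct(wells_fixture(c(25, NA, 26))),
               class = "bertx_validation_error")
})

test_that("lesion delta-Ct and lesion frequency follow the digestion model", {
  expect_equal(lesion_delta_ct(26.0, 25.0), 1.0)
  expect_equal(lesion_delta_ct(25.0, 25.0), 0.0)
  expect_error(lesion_delta_ct(NaN, 25), class = "bertx_validation_error")

  expect_equal(as.numeric(lesion_frequency(0)), 0)
  expect_equal(as.numeric(lesion_frequency(1, efficiency = 2)), log(2))
  clamped <- lesion_frequency(-0.2)
  expect_equal(as.numeric(clamped), 0)
  expect_true(attr(clamped, "clamped"))
  expect_error(lesion_frequency(1, efficiency = 1),
               class = "bertx_invalid_parameter")

  # monotone in delta-Ct; zero at identical arms for any Ct
  dct <- seq(-1, 3, by = 0.25)
  expect_true(!is.unsorted(as.numeric(lesion_frequency(dct))))
  for (x in c(18, 25, 33)) {
    expect_equal(as.numeric(lesion_frequency(lesion_delta_ct(x, x))), 0)
  }
})

test_that("relative lesion levels are promoter-anchored in both modes", {
  est <- tibble::tibble(gene = "g",
                        region = c("promoter", "middle", "end"),
                        delta_ct = c(0.2, 0.5, 1.0),
                        lambda_hat = c(0.2, 0.5, 1.0) * log(2))
  ratio <- relative_lesions(est)
  expect_equal(ratio$rel_to_promoter[ratio$region == "promoter"], 1.0)
  expect_equal(ratio$rel_to_promoter[ratio$region == "end"], 5.0)
  ddct <- relative_lesions(est, mode = "ddct")
  expect_equal(ddct$rel_to_promoter, c(0, 0.3, 0.8))

  flat <- dplyr::mutate(est, delta_ct = 0.4, lambda_hat = 0.4 * log(2))
  expect_equal(relative_lesions(flat)$rel_to_promoter, rep(1, 3))

  zero <- dplyr::mutate(est, lambda_hat = c(0, 0.5, 1.0))
  expect_warning(out <- relative_lesions(zero), "pseudocount")
  expect_true(all(out$promoter_pseudocount))
  expect_error(relative_lesions(est[-1, ]), class = "bertx_missing_data")
})

test_that("noiseless pipeline recovers planted ratios to 6 significant digits", {
  for (base in c(0.05, 0.4)) {
    land <- lesion_landscape("g", base_lambda = base, end_enrichment = 5)
    sim <- simulate_damage_qpcr(land, ct_noise_sd = 0, seed = 1)
    prof <- lesion_profile(sim$wells)
    expect_equal(prof$rel_to_promoter[prof$region == "end"], 5,
                 tolerance = 1e-7)
    expect_equal(prof$rel_to_promoter[prof$region == "middle"], sqrt(5),
                 tolerance = 1e-7)
  }
})

test_that("noisy lesion-gradient recovery is unbiased", {
  # planted promoter 0.1, end 0.5; 60 noisy experiments. A per-experiment
  # end/promoter ratio is heavy-tailed (noisy near-zero denominator), so
  # recovery is assessed on the ratio of mean delta-Ct across experiments.
  land <- lesion_landscape("g", base_lambda = 0.1, end_enrichment = 5)
  dct <- t(vapply(seq_len(60), function(i) {
    sim <- simulate_damage_qpcr(land, n_replicates = 3, ct_noise_sd = 0.15,
                                seed = 1000 + i)
    prof <- suppressWarnings(lesion_profile(sim$wells))
    c(end = prof$delta_ct[prof$region == "end"],
      prom = prof$delta_ct[prof$region == "promoter"])
  }, numeric(2)))
  ratio <- mean(dct[, "end"]) / mean(dct[, "prom"])
  se <- ratio * sqrt((sd(dct[, "end"]) / mean(dct[, "end"]))^2 +
                       (sd(dct[, "prom"]) / mean(dct[, "prom"]))^2) /
    sqrt(nrow(dct))
  expect_lt(abs(ratio - 5), 3 * se)
})

test_that("percent input satisfies its algebraic identities", {
  expect_equal(percent_input(24, 24, input_fraction = 0.01), 1.0)
  expect_equal(percent_input(24 - log2(100), 24, input_fraction = 0.01), 100)
  # one extra IP cycle halves the percentage at E = 2
  expect_equal(percent_input(25, 24, 0.01), percent_input(24, 24, 0.01) / 2)
  # invariant to a common Ct shift
  expect_equal(percent_input(26.3, 23.1, 0.05),
               percent_input(26.3 + 4, 23.1 + 4, 0.05))
  expect_error(percent_input(24, 24, input_fraction = 1.2),
               class = "bertx_invalid_parameter")
})

test_that("relative occupancy is promoter-anchored and guarded", {
  occ <- tibble::tibble(gene = "g",
                        region = c("promoter", "end"),
                        percent_input = c(0.5, 1.0))
  out <- relative_occupancy(occ)
  expect_equal(out$relative_occupancy, c(1, 2))
  expect_error(relative_occupancy(dplyr::mutate(occ, percent_input = c(0, 1))),
               class = "bertx_division_guard")
  expect_error(relative_occupancy(occ[-1, ]), class = "bertx_missing_data")
})

test_that("planted ChIP gradients are recovered under noise", {
  occ <- tibble::tibble(gene = "g",
                        region = c("promoter", "middle", "end"),
                        occupancy = c(1, 2, 4))
  est <- vapply(seq_len(60), function(i) {
    sim <- simulate_chip_qpcr(occ, input_fraction = 0.01, ct_noise_sd = 0.15,
                              seed = 2000 + i)
    prof <- chip_occupancy(sim$wells, input_fraction = 0.01)
    prof$relative_occupancy[prof$region == "end"]
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 4), 3 * se)
})

test_that("delta-delta-Ct expression behaves as expected", {
  expect_equal(relative_expression(24, 20, 24, 20), 1.0)
  expect_equal(relative_expression(23, 20, 24, 20), 2.0)
  expect_error(relative_expression(Inf, 20, 24, 20),
               class = "bertx_validation_error")

  # planted 3-fold induction via the table interface
  wells <- tibble::tibble(
    sample_id = rep(c("wt", "ko"), each = 4),
    gene = rep(c("GAPDH", "GAPDH", "tgt", "tgt"), 2),
    replicate = rep(1:2, 4),
    ct = c(20, 20, 26, 26,                       # wt
           20, 20, 26 - log2(3), 26 - log2(3))   # ko: 3-fold up
  )
  fc <- expression_fold_change(wells, calibrator = "wt")
  expect_equal(fc$fold_change[fc$sample_id == "wt"], 1.0)
  expect_equal(fc$fold_change[fc$sample_id == "ko"], 3.0, tolerance = 1e-9)
})
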