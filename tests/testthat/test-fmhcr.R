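test_that("reporter signal reproduces hand-computed values", {
  ev <- manual_events(n_live = 10000, n_pos = 50, pos_intensity = 1000.5)
  # override MFI to exactly 1000 by using intensity 1000 above a 999 threshold
  cfg <- gate_config(positivity = c(ch_reporter = 999, ch_egfp = 999))
  ev$ch_reporter[seq_len(50)] <- 1000
  rs <- reporter_signal(ev, "ch_reporter", cfg)
  expect_identical(rs$n_positive, 50L)
  expect_equal(rs$mfi, 1000)
  expect_equal(rs$signal, 50 * 1000 / 10000)  # F = N x MFI / S = 5

  # no positive events: F = 0, MFI reported as 0
  none <- manual_events(n_live = 100, n_pos = 0)
  rs0 <- reporter_signal(none, "ch_reporter", gate_config())
  expect_equal(rs0$signal, 0)
  expect_equal(rs0$mfi, 0)

  # linearity: doubling every positive intensity doubles F
  ev2 <- ev
  ev2$ch_reporter <- ifelse(ev2$ch_reporter > 999, ev2$ch_reporter * 2,
                            ev2$ch_reporter)
  expect_equal(reporter_signal(ev2, "ch_reporter", cfg)$signal,
               2 * rs$signal)

  expect_error(reporter_signal(ev[0, ], "ch_reporter", cfg),
               class = "bertx_empty_sample")
})

test_that("normalization and percent reporter expression are exact", {
  expect_equal(normalize_to_transfection(5, 2), 2.5)
  expect_equal(normalize_to_transfection(3, 3), 1)
  expect_error(normalize_to_transfection(5, 0, sample = "ctrl_sample"),
               class = "bertx_transfection_control_error")

  expect_equal(percent_reporter_expression(1, 1), 100)
  expect_equal(percent_reporter_expression(0, 1), 0)
  expect_error(percent_reporter_expression(1, 0),
               class = "bertx_undamaged_control_error")
})

test_that("gating drops the planted contaminants and is idempotent", {
  cfg <- gate_config()
  ev <- manual_events(n_live = 50)
  dead <- dplyr::mutate(ev[1, ], viability = cfg$viability_max + 1)
  doublet <- dplyr::mutate(ev[1, ], fsc_h = fsc_a * 0.5)
  debris <- dplyr::mutate(ev[1, ], fsc_a = 10, fsc_h = 10)
  all_ev <- dplyr::bind_rows(ev, dead, doublet, debris)
  gated <- gate_live_singlets(all_ev, cfg)
  expect_equal(nrow(gated), 50L)
  expect_identical(gate_live_singlets(gated, cfg), gated)
  expect_warning(gate_live_singlets(dead, cfg), "every event")
})

test_that("relaxing any gate bound never decreases the gated count", {
  sim <- simulate_flow_experiment(flow_sim_config(n_events = 3000, seed = 21))
  ev <- dplyr::filter(sim$events, grepl("_dam$", sample_id))
  base_cfg <- gate_config()
  n_base <- nrow(gate_live_singlets(ev, base_cfg))
  relaxed <- list(
    gate_config(fsc_bounds = c(0, 1e9)),
    gate_config(ssc_bounds = c(0, 1e9)),
    gate_config(singlet_ratio_band = c(0, 10)),
    gate_config(viability_max = 1e9)
  )
  for (cfg in relaxed) {
    expect_gte(nrow(gate_live_singlets(ev, cfg)), n_base)
  }
})

test_that("an undamaged sample scored against itself gives exactly 100", {
  sim <- simulate_flow_experiment(flow_sim_config(n_events = 2000, seed = 8))
  un <- dplyr::filter(sim$events, grepl("_un$", sample_id))
  ev <- dplyr::bind_rows(dplyr::mutate(un, sample_id = "x_dam"),
                         dplyr::mutate(un, sample_id = "x_un"))
  sheet <- tibble::tibble(sample_id = c("x_dam", "x_un"), condition = "x",
                          damaged = c(TRUE, FALSE), replicate = 1L)
  res <- analyze_fmhcr(ev, sheet)
  expect_identical(res$per_replicate$percent_re, 100)
})

test_that("experiment analysis pairs samples and summarises replicates", {
  sims <- lapply(1:3, function(rep) {
    simulate_flow_experiment(
      flow_sim_config(n_events = 3000, repair_prob = 0.5, seed = 30 + rep),
      condition = "wt", replicate = rep)
  })
  events <- dplyr::bind_rows(lapply(sims, `[[`, "events"))
  samples <- dplyr::bind_rows(lapply(sims, `[[`, "samples"))
  res <- analyze_fmhcr(events, samples)
  expect_equal(nrow(res$per_replicate), 3L)
  g <- glance(res)
  expect_equal(g$n, 3L)
  expect_equal(g$sem, sd(res$per_replicate$percent_re) / sqrt(3))
  expect_lt(abs(g$mean_percent_re - 50), 5)

  # identical event tables under two conditions give identical %R.E.
  ev2 <- dplyr::bind_rows(
    events,
    dplyr::mutate(events, sample_id = paste0("c2_", sample_id)))
  sh2 <- dplyr::bind_rows(
    samples,
    dplyr::mutate(samples, sample_id = paste0("c2_", sample_id),
                  condition = "wt2"))
  res2 <- analyze_fmhcr(ev2, sh2)
  cond_means <- glance(res2)
  expect_equal(cond_means$mean_percent_re[1], cond_means$mean_percent_re[2])

  # missing undamaged counterpart
  expect_error(
    analyze_fmhcr(dplyr::filter(events, grepl("_dam$", sample_id)),
                  dplyr::filter(samples, damaged)),
    class = "bertx_pairing_error")
})

test_that("repair capacity is recovered across the repair-probability range", {
  for (r in c(0, 0.5, 1)) {
    means <- vapply(1:10, function(i) {
      sim <- simulate_flow_experiment(
        flow_sim_config(n_events = 4000, repair_prob = r, seed = 100 * r + i))
      glance(analyze_fmhcr(sim$events, sim$samples))$mean_percent_re
    }, numeric(1))
    expect_lt(abs(mean(means) - 100 * r), 2)
  }
})
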