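test_that("zero noise reproduces the model truth exactly, seeded runs repeat", {
  des <- synth_design("AVL_S", congeners = default_congeners()["PCB4"],
                      noise_cv = c(PUF = 0, SPME = 0), seed = 12)
  tab <- generate_experiment(des, tol = 1e-6)
  truth <- attr(tab, "truth")
  for (grp in c("control", "treatment")) {
    means <- truth[[grp]]$means$PCB4
    for (m in c("PUF", "SPME")) for (j in seq_along(des$sampling_days)) {
      reps <- tab$mass_ng[tab$group == grp & tab$matrix == m &
                            tab$day == des$sampling_days[j]]
      expect_equal(reps, rep(means[[m]][j], 3), tolerance = 1e-12)
    }
  }
  # bit-identical reproducibility with noise on
  des2 <- synth_design("AVL_S", congeners = default_congeners()["PCB4"],
                       seed = 99)
  t1 <- generate_experiment(des2, tol = 1e-6)
  t2 <- generate_experiment(des2, tol = 1e-6)
  expect_identical(t1$mass_ng, t2$mass_ng)
  des3 <- des2; des3$seed <- 100L
  t3 <- generate_experiment(des3, tol = 1e-6)
  expect_false(identical(t1$mass_ng, t3$mass_ng))
})

test_that("scenario presets carry the experimental design", {
  ds <- synth_design("AVL_S")
  expect_equal(ds$sampling_days, c(3, 11, 16, 35))
  expect_equal(ds$config$regime, "shaken")
  expect_equal(ds$n_replicates, 3)
  dn <- synth_design("NBH_NS")
  expect_equal(dn$sampling_days, c(16, 35, 75))
  expect_equal(dn$config$regime, "nonshaken")
  # sediment inventory split: LC share of the NBH-like total
  lc_ids <- names(dn$congeners)[vapply(dn$congeners, is_lc, logical(1))]
  expect_equal(sum(dn$sed_conc[lc_ids]), 59000 * 0.44)
  expect_equal(sum(dn$sed_conc), 59000)
})

test_that("day-35 LC airborne decrease grows with the treatment rate", {
  pds <- vapply(c(0.5, 2, 17), function(kb) {
    des <- synth_design("AVL_S", congeners = default_congeners()["PCB4"],
                        control_params = rtm_params(k_bio = 0),
                        treatment_params = rtm_params(k_bio = kb),
                        noise_cv = c(PUF = 0, SPME = 0), seed = 1)
    tab <- generate_experiment(des, tol = 1e-6)
    agg <- aggregate_sums(tab, des$congeners)
    d <- agg[agg$day == 35 & agg$matrix == "PUF" & agg$replicate == 1, ]
    percent_difference(d$lc[d$group == "control"],
                       d$lc[d$group == "treatment"])
  }, numeric(1))
  expect_true(all(pds > 0))
  expect_true(all(diff(pds) > 0))
})

test_that("generated blanks are seeded, level-true, and LOQ-consistent", {
  b0 <- generate_blanks("PUF", n = 19, level = 2, cv = 0, seed = 4)
  expect_true(all(unlist(b0$masses) == 2))
  expect_equal(unname(b0$n), rep(19L, 3))
  b1 <- generate_blanks("PUF", n = 19, level = 2, cv = 0.3, seed = 4)
  b2 <- generate_blanks("PUF", n = 19, level = 2, cv = 0.3, seed = 4)
  expect_identical(b1$masses, b2$masses)
  expect_error(generate_blanks("PUF", n = 1), ">= 2")
  # delta-method check: at small cv, LOQ ~= level * (1 + 1.96 cv)
  loqs <- replicate(200, {
    s <- sample.int(1e6, 1)
    mean(compute_loq(generate_blanks("PUF", n = 50, level = 10, cv = 0.05,
                                     seed = s)))
  })
  expect_equal(mean(loqs), 10 * (1 + 1.96 * 0.05), tolerance = 0.01)
})

test_that("generated recoveries respect their means and truncation", {
  r0 <- generate_recoveries(c(2, 3, 5), mean_by_homologue = 0.8, sd = 0,
                            seed = 1)
  expect_equal(r0$recovery, c(0.8, 0.8, 0.8))
  expect_equal(r0$homologue, c(2L, 3L, 5L))
  rr <- generate_recoveries(rep(2, 500), mean_by_homologue = 0.9, sd = 0.15,
                            seed = 2)
  expect_true(all(rr$recovery > 0 & rr$recovery <= 1.5))
  # Monte-Carlo mean within 3 standard errors of the target
  big <- generate_recoveries(rep(3, 10000), mean_by_homologue = 0.8,
                             sd = 0.14, seed = 3)
  expect_lt(abs(mean(big$recovery) - 0.8), 3 * 0.14 / sqrt(10000) + 0.002)
  expect_error(generate_recoveries(2, mean_by_homologue = 1.6), "0, 1.5")
  expect_error(generate_recoveries(2, sd = -0.1), "sd")
})

test_that("bioaugmentation yields a significant day-35 LC decrease across seeds", {
  # strong treatment vs quiet control, replicate noise at the default level:
  # the reduction and paired test should flag the decrease in nearly all runs
  hits <- 0; n_seeds <- 30
  for (s in seq_len(n_seeds)) {
    des <- synth_design("AVL_S", congeners = default_congeners()["PCB4"],
                        control_params = rtm_params(k_bio = 0.2),
                        treatment_params = rtm_params(k_bio = 17, k_cell = 8),
                        seed = s)
    tab <- generate_experiment(des, tol = 1e-6)
    cmp <- compare_time_point(tab, 35, "PUF", des$congeners, aggregate = "lc")
    if (isTRUE(cmp$p_value < 0.05) && cmp$percent_difference > 0)
      hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("noiseless truth-record round trip recovers k_bio within 1%", {
  des <- synth_design("AVL_NS", congeners = default_congeners()["PCB4"],
                      treatment_params = fx_ns_params(k_bio = 0.4),
                      x_cells_treatment = 0,
                      noise_cv = c(PUF = 0, SPME = 0), seed = 21)
  tab <- generate_experiment(des, tol = 1e-6)
  truth <- attr(tab, "truth")
  expect_equal(truth$treatment$params$k_bio, 0.4)
  y0 <- initial_state(des$config, des$treatment_params,
                      sed_conc = des$sed_conc[["PCB4"]])
  fit <- rtm_fit(tab, des$config, des$treatment_params, fx_congener(), y0,
                 free = list(k_bio = c(0, 20)), group = "treatment",
                 n_starts = 8, seed = 5, tol = 1e-6)
  expect_lt(abs(coef(fit)[["k_bio"]] - 0.4) / 0.4, 0.01)
})
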