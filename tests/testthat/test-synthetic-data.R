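test_that("design profiles honor the SOA schedule and repetition bounds", {
  d <- toj_design("paper_like")
  expect_equal(nrow(d), 11L)
  expect_true(all(d$n_trials >= 8 & d$n_trials <= 24))
  expect_true(setequal(d$soa_ms, c(0, -14, 14, -28, 28, -42, 42, -63, 63,
                                   -83, 83)))
  # denser sampling near simultaneity
  expect_true(all(d$n_trials[abs(d$soa_ms) <= 14] >=
                    max(d$n_trials[abs(d$soa_ms) >= 63])))

  u <- toj_design("uniform", reps = 10)
  expect_true(all(u$n_trials == 10L))
  expect_equal(sum(u$n_trials), 110L)

  expect_error(toj_design("nope"), "arg")
  expect_error(toj_design("custom", soa_levels_ms = c(-10, -10, 10),
                          reps = c(5, 5, 5)), "unique")
  expect_error(toj_design("custom", soa_levels_ms = c(-10, 10),
                          reps = c(5, 5, 5)), "match")
  expect_error(toj_design("custom", soa_levels_ms = c(-10, 10),
                          reps = c(0, 5)), "positive")
})

test_that("population sampling is deterministic and respects the spec", {
  spec <- population_spec(effects = list(salience = list(dw = 0.06)))
  a <- sample_population(spec, 8, seed = 3)
  b <- sample_population(spec, 8, seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$C > 0))
  expect_true(all(a$w_p > 0 & a$w_p < 1))

  # zero spread: every participant carries exactly the group parameters
  s0 <- population_spec(C_mean = 0.055, C_sd = 0, w_p_mean = 0.45,
                        w_sd = 0, effects = list(salience = list(dw = 0.1)))
  p0 <- sample_population(s0, 5, seed = 1)
  base <- p0[p0$condition == "baseline", ]
  expect_equal(base$C, rep(0.055, 5))
  expect_equal(base$w_p, rep(0.45, 5))
  expect_equal(p0$w_p[p0$condition == "salience"], rep(0.55, 5))

  # positive injected weight effect raises every participant's weight
  sw <- population_spec(effects = list(salience = list(dw = 0.06,
                                                       dw_sd = 0)))
  pw <- sample_population(sw, 30, seed = 9)
  wide <- merge(pw[pw$condition == "baseline", c("participant_id", "w_p")],
                pw[pw$condition == "salience", c("participant_id", "w_p")],
                by = "participant_id")
  expect_true(all(wide$w_p.y > wide$w_p.x))
})

test_that("impossible population specifications are rejected", {
  expect_error(population_spec(C_mean = -0.01), "C_mean")
  expect_error(population_spec(effects = list(salience = list(dC = -0.08))),
               "non-positive")
  expect_error(population_spec(effects = list(salience = list(dw = 0.6))),
               "outside")
  expect_error(population_spec(effects = list(baseline = list(dw = 0.1))),
               "baseline")
})

test_that("TOJ simulation is deterministic, bounded, and degenerate-safe", {
  spec <- population_spec()
  pop <- sample_population(spec, 4, seed = 5)
  d <- toj_design("paper_like")
  a <- simulate_toj(pop, d, seed = 6)
  b <- simulate_toj(pop, d, seed = 6)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$n_probe_first >= 0 & a$n_probe_first <= a$n_trials))
  expect_equal(nrow(a), nrow(pop) * nrow(d))

  # v_r = 0 and non-negative SOAs: the probe wins every trial
  degen <- data.frame(participant_id = 1, condition = "baseline",
                      C = 0.06, w_p = 1)
  dd <- toj_design("custom", soa_levels_ms = c(0, 14, 42), reps = c(9, 9, 9))
  tab <- simulate_toj(degen, dd, seed = 1)
  expect_true(all(tab$n_probe_first == tab$n_trials))

  expect_error(simulate_toj(pop, d[0, ], seed = 1), "empty design")
})

test_that("simulated proportions concentrate on the generating curve", {
  pop <- data.frame(participant_id = 1, condition = "baseline",
                    C = 0.06, w_p = 0.55)
  d <- toj_design("uniform", reps = 1e5)
  tab <- simulate_toj(pop, d, seed = 8)
  p_true <- p_probe_first(0.55 * 0.06, 0.45 * 0.06, tab$soa_ms)
  se <- sqrt(p_true * (1 - p_true) / tab$n_trials)
  expect_true(all(abs(tab$n_probe_first / tab$n_trials - p_true) <= 3 * se))
})

test_that("matching simulation reproduces the injected accuracy structure", {
  spec <- population_spec(acc_self = 0.95, acc_other = 0.80, acc_sd = 0)
  m <- simulate_matching(spec, 150, n_trials_per_cell = 100, seed = 4)
  m2 <- simulate_matching(spec, 150, n_trials_per_cell = 100, seed = 4)
  expect_identical(as.data.frame(m), as.data.frame(m2))
  spe <- compute_spe(m)
  se <- sqrt((0.95 * 0.05 + 0.80 * 0.20) / 100 / 150)
  expect_lt(abs(spe$group$mean - 0.15), 3 * se)

  # no injected gap: SPE near zero
  s_eq <- population_spec(acc_self = 0.85, acc_other = 0.85, acc_sd = 0)
  spe0 <- compute_spe(simulate_matching(s_eq, 150, 100, seed = 5))
  se0 <- sqrt(2 * 0.85 * 0.15 / 100 / 150)
  expect_lt(abs(spe0$group$mean), 3 * se0)
})
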