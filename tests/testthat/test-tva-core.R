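test_that("psychometric function matches its defining cases", {
  # symmetric race at simultaneity: share of capacity
  expect_identical(p_probe_first(0.03, 0.03, 0), 0.5)
  # reference can never be encoded: probe always first
  expect_identical(p_probe_first(0.05, 0, 40), 1)
  expect_identical(p_probe_first(0.001, 0, 1000), 1)
  # frozen values confirmed against the Monte-Carlo race oracle
  expect_equal(p_probe_first(0.03, 0.03, -83), 0.958545, tolerance = 1e-5)
  expect_equal(p_probe_first(0.04, 0.02, 50), 0.245253, tolerance = 1e-5)
})

test_that("psychometric function agrees with the race oracle", {
  cases <- expand.grid(v_p = c(0.02, 0.06), v_r = c(0.03, 0.05),
                       soa = c(-63, -14, 28))
  for (i in seq_len(nrow(cases))) {
    p_cf <- p_probe_first(cases$v_p[i], cases$v_r[i], cases$soa[i])
    p_mc <- race_oracle(cases$v_p[i], cases$v_r[i], cases$soa[i],
                        reps = 2e5, seed = 100 + i)
    expect_lt(abs(p_cf - p_mc), oracle_tol(p_cf, 2e5))
  }
})

test_that("psychometric function is continuous at SOA zero with correct limits", {
  for (w in c(0.3, 0.5, 0.7)) {
    v <- rates_from_params(tva_params(0.06, w))
    expect_equal(p_probe_first(v[1], v[2], -1e-9),
                 p_probe_first(v[1], v[2], 0), tolerance = 1e-6)
    # at soa = 0 the report probability is exactly the attentional weight
    expect_identical(p_probe_first(v[1], v[2], 0), w)
  }
  expect_equal(p_probe_first(0.03, 0.05, -1e6), 1)
  expect_equal(p_probe_first(0.03, 0.05, 1e6), 0)
})

test_that("psychometric function is monotone in SOA and in each rate", {
  soas <- seq(-120, 120, by = 5)
  rates <- seq(0.01, 0.12, by = 0.01)
  for (v_p in c(0.02, 0.06)) {
    for (v_r in c(0.03, 0.08)) {
      p <- p_probe_first(v_p, v_r, soas)
      expect_true(all(diff(p) <= 1e-12))          # non-increasing in SOA
      expect_true(all(p >= 0 & p <= 1))
    }
  }
  for (soa in c(-42, 0, 42)) {
    expect_true(all(diff(p_probe_first(rates, 0.05, soa)) >= -1e-12))
    expect_true(all(diff(p_probe_first(0.05, rates, soa)) <= 1e-12))
  }
})

test_that("degenerate races and bad rates are rejected", {
  expect_error(p_probe_first(0, 0, 10), "both encoding rates are zero")
  expect_error(p_probe_first(-0.01, 0.03, 10), "non-negative")
  expect_error(p_probe_first(0.03, 0.03, NA), "finite")
})

test_that("TVA parameters validate and map to rates exactly", {
  expect_error(tva_params(0, 0.5), "strictly positive")
  expect_error(tva_params(-1, 0.5), "strictly positive")
  expect_error(tva_params(0.06, 0), "open interval")
  expect_error(tva_params(0.06, 1), "open interval")
  expect_equal(rates_from_params(tva_params(0.06, 0.5)),
               c(v_p = 0.03, v_r = 0.03))
  expect_equal(rates_from_params(tva_params(0.06, 0.75)),
               c(v_p = 0.045, v_r = 0.015))
  # capacity partition holds to machine precision over a parameter sweep
  for (C in c(0.013, 0.06, 0.11)) {
    for (w in c(0.07, 0.41, 0.93)) {
      v <- rates_from_params(tva_params(C, w))
      expect_equal(unname(v[1] + v[2]), C, tolerance = 1e-15)
    }
  }
})

test_that("change scores obey their defining identities", {
  b <- tva_params(0.06, 0.5)
  expect_true(all(as.matrix(change_scores(b, b)) == 0))

  # pure weight shift: capacity unchanged, rates trade off one for one
  e <- change_scores(tva_params(0.06, 0.5), tva_params(0.06, 0.6))
  expect_equal(e$C_effect, 0)
  expect_equal(e$dv_p, 0.006)
  expect_equal(e$dv_r, -0.006)
  expect_equal(e$dv_rel, 0.012)

  # group-mean arithmetic: 53 -> 54 Hz capacity, weight 0.50 -> 0.488
  e2 <- change_scores(tva_params(0.053, 0.50), tva_params(0.054, 0.488))
  expect_equal(e2$dv_p, -0.000148, tolerance = 1e-9)
  expect_equal(e2$dv_r, 0.001148, tolerance = 1e-9)

  # identities at machine precision across random parameter pairs
  set.seed(11)
  for (i in 1:25) {
    pb <- tva_params(runif(1, 0.02, 0.1), runif(1, 0.1, 0.9))
    pc <- tva_params(runif(1, 0.02, 0.1), runif(1, 0.1, 0.9))
    e <- change_scores(pb, pc)
    expect_equal(e$dv_rel, e$dv_p - e$dv_r, tolerance = 1e-15)
    expect_equal(e$dv_p + e$dv_r, e$C_effect, tolerance = 1e-15)
  }
})
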