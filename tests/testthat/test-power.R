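test_that("the power posterior follows Beta(1 + s, 1 + f)", {
  # 184 successes in 200 simulations: posterior mean 185/202
  expect_equal(185 / 202, 0.9158, tolerance = 1e-4)
  h <- tvatoj:::beta_hdi(185, 17, 0.95)
  mass <- pbeta(h[["upper"]], 185, 17) - pbeta(h[["lower"]], 185, 17)
  expect_equal(mass, 0.95, tolerance = 1e-6)
  # HDI is no wider than the central interval
  central <- qbeta(c(0.025, 0.975), 185, 17)
  expect_lte(h[["upper"]] - h[["lower"]], central[2] - central[1] + 1e-9)
  expect_true(h[["lower"]] >= 0 && h[["upper"]] <= 1)
})

test_that("power run bookkeeping: successes, failures, determinism", {
  spec <- population_spec(effects = list(salience = list(dw = 0.06)))
  expect_error(run_power(spec, n_grid = 10, n_sims = 0), "at least 1")
  expect_error(run_power(spec, n_grid = integer(0), n_sims = 5), "n_grid")
  expect_error(run_power(spec, n_grid = 10, n_sims = 5,
                         condition = "nope"), "condition")

  d <- toj_design("uniform", reps = 6)
  # a success rule that always fires: power posterior is Beta(1+m, 1)
  res <- run_power(spec, design = d, n_grid = 4, n_sims = 3,
                   success_rule = function(eff) TRUE, seed = 2)
  expect_s3_class(res, "power_result")
  expect_equal(res$n_successes, 3L)
  expect_equal(res$n_failed, 0L)
  expect_equal(res$power_mean, 4 / 5)
  expect_true(res$power_mean >= res$hdi_lower &&
                res$power_mean <= res$hdi_upper)

  # identical seeds reproduce identical rows
  r1 <- run_power(spec, design = d, n_grid = 4, n_sims = 2, seed = 3)
  r2 <- run_power(spec, design = d, n_grid = 4, n_sims = 2, seed = 3)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  # failing inner pipelines are counted, never silently dropped
  rf <- run_power(spec, design = d, n_grid = 4, n_sims = 2,
                  success_rule = function(eff) stop("boom"), seed = 4)
  expect_equal(rf$n_failed, 2L)
  expect_equal(rf$n_successes, 0L)
  expect_equal(rf$power_mean, 0.5)    # Beta(1, 1) with no completed sims
})

test_that("power curve table mirrors the result", {
  spec <- population_spec(effects = list(salience = list(dw = 0.06)))
  res <- run_power(spec, design = toj_design("uniform", reps = 6),
                   n_grid = 4, n_sims = 2,
                   success_rule = function(eff) TRUE, seed = 5)
  pc <- power_curve(res)
  expect_equal(nrow(pc), 1L)
  expect_true(all(pc$power_mean >= pc$hdi_lower &
                    pc$power_mean <= pc$hdi_upper))
  expect_lte(max(pc$power_mean), 1)
  expect_error(power_curve(res[0, ]), "power_result|empty")
})

test_that("power configs read identically from JSON and YAML", {
  cfg <- list(C_mean = 0.055, dw = 0.08, n_grid = c(10, 20), n_sims = 7,
              seed = 3, profile = "cheap")
  jf <- tempfile(fileext = ".json")
  yf <- tempfile(fileext = ".yaml")
  jsonlite::write_json(cfg, jf, auto_unbox = TRUE)
  yaml::write_yaml(cfg, yf)
  a <- read_power_config(jf)
  b <- read_power_config(yf)
  expect_equal(a$spec$C_mean, 0.055)
  expect_equal(a$spec$effects$salience$dw, 0.08)
  expect_equal(a$n_grid, c(10, 20))
  expect_equal(a$n_sims, 7)
  expect_equal(a[-1], b[-1])
  expect_equal(unclass(a$spec), unclass(b$spec))
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(nonsense_key = 1), bad, auto_unbox = TRUE)
  expect_error(read_power_config(bad), "unknown config key")
})
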