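test_that("model building indexes conditions and capacities correctly", {
  tab <- tiny_toj_table()
  shared <- build_toj_model(tab, variant = "shared_C")
  expect_equal(shared$jags_data$K, 2L)
  expect_equal(shared$jags_data$KC, 1L)        # one C node per participant
  expect_true(all(shared$jags_data$ccol == 1L))

  bycond <- build_toj_model(tab, variant = "condition_C")
  expect_equal(bycond$jags_data$KC, 2L)        # one C per condition
  expect_equal(bycond$jags_data$ccol, bycond$jags_data$cond)
  # baseline is always condition index 1
  expect_equal(bycond$conditions[1], "baseline")

  expect_error(build_toj_model(tab[0, ]), "empty")
  expect_error(build_toj_model(tab, baseline = "neutral"), "not found")
  one_soa <- tab[tab$soa_ms == 0, ]
  expect_error(build_toj_model(one_soa), "2 SOA levels")
})

test_that("fitting attaches aligned log-likelihood and diagnostics", {
  fit <- fixture_fit("shared_C")
  expect_s3_class(fit, "toj_fit")
  # pointwise log-likelihood aligned 1:1 with data cells
  expect_equal(ncol(fit$log_lik), nrow(fit$model$cells))
  expect_equal(nrow(fit$log_lik), nrow(fit$draws))
  expect_true(all(is.finite(fit$log_lik)))
  # R-hat and ESS reported for every monitored parameter
  expect_equal(sort(fit$diagnostics$parameter), sort(colnames(fit$draws)))
  expect_true(all(is.finite(fit$diagnostics$rhat)))

  # log-likelihood recomputes from draws: spot-check one cell
  cell <- fit$model$cells[17, ]
  w <- fit$draws[, sprintf("w[%d,%d]", cell$pid, cell$cond)]
  C <- fit$draws[, sprintf("C[%d,%d]", cell$pid, cell$ccol)]
  p <- pmin(pmax(p_probe_first(w * C, (1 - w) * C, cell$soa_ms), 1e-12),
            1 - 1e-12)
  expect_equal(fit$log_lik[, 17],
               dbinom(cell$n_probe_first, cell$n_trials, p, log = TRUE))
})

test_that("fits are reproducible given the seed", {
  tab <- fixture_study()$toj
  tab <- tab[tab$participant_id <= 4, ]
  mod <- build_toj_model(tab)
  f1 <- suppressWarnings(fit_toj_model(mod, draws = 300, tune = 200,
                                       chains = 2, seed = 99))
  f2 <- suppressWarnings(fit_toj_model(mod, draws = 300, tune = 200,
                                       chains = 2, seed = 99))
  expect_identical(f1$draws, f2$draws)
  expect_identical(posterior_summary(f1), posterior_summary(f2))
  f3 <- suppressWarnings(fit_toj_model(mod, draws = 300, tune = 200,
                                       chains = 2, seed = 100))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior summaries match their sampling-theory oracles", {
  # degenerate draws: the HDI collapses to a point
  s <- posterior_summary(rep(1.5, 500))
  expect_equal(s$hdi_lower, 1.5)
  expect_equal(s$hdi_upper, 1.5)
  expect_equal(s$p_gt_0, 1)

  # symmetric draws around zero
  set.seed(2)
  z <- rnorm(2e5)
  s2 <- posterior_summary(z)
  expect_equal(s2$p_gt_0, 0.5, tolerance = 0.01)
  # standard normal 95% HDI matches the quantile oracle (-1.96, 1.96)
  expect_equal(s2$hdi_lower, qnorm(0.025), tolerance = 0.05)
  expect_equal(s2$hdi_upper, qnorm(0.975), tolerance = 0.05)

  expect_error(posterior_summary(z, prob = 1.2), "prob")
  expect_error(posterior_summary(numeric(0)), "draws|finite")
})

test_that("draw-wise effect scores preserve the change-score identities", {
  fit <- fixture_fit("shared_C")
  eff <- derive_effects(fit, "salience")
  gd <- eff$group_draws
  # definitional identity holds draw-wise, not mean-wise
  expect_equal(gd$dv_rel, gd$dv_p - gd$dv_r, tolerance = 1e-14)
  expect_equal(gd$dv_p + gd$dv_r, gd$C_effect, tolerance = 1e-14)
  # shared-capacity variant: capacity change identically zero
  expect_true(all(gd$C_effect == 0))
  # summary rows summarize the draw-wise quantities
  expect_equal(eff$group_summary$mean[eff$group_summary$parameter == "dv_rel"],
               mean(gd$dv_p) - mean(gd$dv_r), tolerance = 1e-12)
  # contrasting a condition with itself is exactly null
  null_eff <- derive_effects(fit, "baseline")
  expect_true(all(as.matrix(null_eff$group_draws) == 0))
  expect_error(derive_effects(fit, "unknown_condition"), "unknown")
  # participant table covers every participant
  expect_equal(nrow(eff$participant), 12L)
})

test_that("with no data the group weight posterior tracks its prior", {
  dat <- expand.grid(participant_id = 1:4,
                     condition = c("baseline", "salience"),
                     soa_ms = c(-40, 40), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  dat$n_trials <- 0L
  dat$n_probe_first <- 0L
  mod <- build_toj_model(dat, variant = "shared_C")
  fit <- suppressWarnings(fit_toj_model(mod, draws = 3000, tune = 500,
                                        chains = 2, seed = 31))
  s <- posterior_summary(fit)
  mu_w <- s[grepl("^mu_w", s$parameter), ]
  # prior location 0.5, sd 0.2: posterior mean near 0.5, spread wide
  expect_true(all(abs(mu_w$mean - 0.5) < 0.06))
  expect_true(all(mu_w$sd > 0.1))
})
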