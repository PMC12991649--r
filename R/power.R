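#' Simulation-based Bayesian power analysis for TOJ designs
#'
#' Estimates the probability of obtaining a "successful result" -- by
#' default, a group attentional-weight effect whose 95% highest-density
#' interval excludes zero -- as a function of sample size. For each
#' participant count in `n_grid` it repeats: sample a population from
#' `spec`, simulate TOJ data under `design`, fit the hierarchical model,
#' derive effect scores, and apply the success rule. Power is the
#' posterior of the success proportion under a uniform Beta(1, 1) prior:
#' after s successes in m completed simulations, Beta(1 + s, 1 + m - s),
#' reported as its mean and HDI. Simulation seeds derive deterministically
#' from the master seed. Fits that fail are counted and reported, never
#' silently dropped.
#'
#' @param spec A [population_spec()] carrying the assumed effect sizes.
#' @param design A [toj_design()].
#' @param n_grid Integer vector of participant counts to evaluate.
#' @param n_sims Simulated experiments per grid point (>= 1).
#' @param condition Condition whose effect defines success; defaults to
#'   the first effect condition in `spec`.
#' @param success_rule Function of a `toj_effect_draws` returning a
#'   single logical; the default tests whether the `prob` HDI of the
#'   group `w_peffect` excludes zero.
#' @param variant Model variant used for the inner fits; the default
#'   `"shared_C"` matches a weight-shift target effect.
#' @param profile [sampler_profile()] name for the inner fits
#'   (default `"cheap"`; 200 full-fidelity fits is not an interactive
#'   workload).
#' @param prob HDI probability for both the success rule and the power
#'   posterior.
#' @param seed Master seed.
#' @return A `power_result`: data frame with one row per sample size and
#'   columns `n`, `n_sims`, `n_failed`, `n_successes`, `power_mean`,
#'   `hdi_lower`, `hdi_upper`.
#' @export
run_power <- function(spec, design = toj_design("paper_like"), n_grid,
                      n_sims, condition = NULL, success_rule = NULL,
                      variant = "shared_C", profile = "cheap",
                      prob = 0.95, seed = 1) {
  stopifnot(inherits(spec, "population_spec"))
  if (length(n_grid) < 1L || any(n_grid < 1L)) {
    stop("`n_grid` must contain positive participant counts", call. = FALSE)
  }
  if (!is.numeric(n_sims) || n_sims < 1L) {
    stop("`n_sims` must be at least 1", call. = FALSE)
  }
  condition <- condition %||% names(spec$effects)[1]
  if (!condition %in% names(spec$effects)) {
    stop("`condition` must name an effect condition in `spec`",
         call. = FALSE)
  }
  success_rule <- success_rule %||% function(eff) {
    h <- hdi(eff$group_draws$w_peffect, prob)
    h[["lower"]] > 0 || h[["upper"]] < 0
  }
  n_sims <- as.integer(n_sims)
  seeds <- matrix(derive_seeds(seed, length(n_grid) * n_sims),
                  nrow = length(n_grid))
  rows <- lapply(seq_along(n_grid), function(gi) {
    n <- as.integer(n_grid[gi])
    ok <- 0L; fail <- 0L
    for (si in seq_len(n_sims)) {
      s3 <- derive_seeds(seeds[gi, si], 3L)
      res <- tryCatch({
        pop <- sample_population(spec, n, seed = s3[1])
        dat <- simulate_toj(pop, design, seed = s3[2])
        mod <- build_toj_model(dat, variant = variant,
                               baseline = spec$baseline)
        fit <- suppressWarnings(
          fit_toj_model(mod, profile = profile, seed = s3[3]))
        eff <- derive_effects(fit, condition = condition, prob = prob)
        isTRUE(success_rule(eff))
      }, error = function(e) NA)
      if (is.na(res)) fail <- fail + 1L else if (res) ok <- ok + 1L
    }
    m <- n_sims - fail
    a <- 1 + ok
    b <- 1 + max(m - ok, 0L)
    h <- beta_hdi(a, b, prob)
    data.frame(n = n, n_sims = n_sims, n_failed = fail, n_successes = ok,
               power_mean = a / (a + b),
               hdi_lower = h[["lower"]], hdi_upper = h[["upper"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "condition") <- condition
  attr(out, "prob") <- prob
  attr(out, "variant") <- variant
  class(out) <- c("power_result", class(out))
  out
}

#' Power curve table
#'
#' One row per sample size with the raw power estimates and HDI band, for
#' plotting power against n. No monotone smoothing is applied; individual
#' estimates may invert within Monte-Carlo error.
#'
#' @param result A `power_result` from [run_power()].
#' @return Data frame with columns `n`, `power_mean`, `hdi_lower`,
#'   `hdi_upper`, `n_sims`, `n_successes`, `n_failed`.
#' @export
power_curve <- function(result) {
  stopifnot(inherits(result, "power_result"))
  if (nrow(result) == 0L) stop("empty power result", call. = FALSE)
  result[, c("n", "power_mean", "hdi_lower", "hdi_upper", "n_sims",
             "n_successes", "n_failed")]
}

#' @export
plot.power_result <- function(x, ...) {
  pc <- power_curve(x)
  graphics::plot(pc$n, pc$power_mean, type = "b", ylim = c(0, 1),
                 xlab = "participants", ylab = "power",
                 main = sprintf("HDI-exclusion power (%s)",
                                attr(x, "condition")), ...)
  graphics::arrows(pc$n, pc$hdi_lower, pc$n, pc$hdi_upper, angle = 90,
                   code = 3, length = 0.04)
  invisible(x)
}

#' Read a power-analysis configuration file
#'
#' JSON or YAML (chosen by file extension) key-value configuration for
#' [run_power()]. Recognized keys: the [population_spec()] arguments
#' (`C_mean`, `C_sd`, `w_p_mean`, `w_sd`, `acc_self`, `acc_other`,
#' `acc_sd`), effect sizes `dw`, `dw_sd`, `dC`, `dC_sd` (applied to a
#' single `"salience"` condition), `design_profile`, `n_grid`, `n_sims`,
#' `variant`, `profile`, `prob` and `seed`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return List with components `spec`, `design` and the remaining
#'   [run_power()] arguments.
#' @export
read_power_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format: .", ext, " (use JSON or YAML)",
         call. = FALSE))
  known <- c("C_mean", "C_sd", "w_p_mean", "w_sd", "acc_self", "acc_other",
             "acc_sd", "dw", "dw_sd", "dC", "dC_sd", "design_profile",
             "n_grid", "n_sims", "variant", "profile", "prob", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  spec_args <- cfg[intersect(names(cfg), c("C_mean", "C_sd", "w_p_mean",
                                           "w_sd", "acc_self", "acc_other",
                                           "acc_sd"))]
  eff <- cfg[intersect(names(cfg), c("dw", "dw_sd", "dC", "dC_sd"))]
  spec_args$effects <- list(salience = eff)
  list(spec = do.call(population_spec, spec_args),
       design = toj_design(cfg$design_profile %||% "paper_like"),
       n_grid = cfg$n_grid %||% c(20, 40, 60),
       n_sims = cfg$n_sims %||% 20,
       variant = cfg$variant %||% "shared_C",
       profile = cfg$profile %||% "cheap",
       prob = cfg$prob %||% 0.95,
       seed = cfg$seed %||% 1)
}
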