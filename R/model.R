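#' Hyperprior constants for the hierarchical TVA-TOJ model
#'
#' Group-level prior locations and scales. The defaults place the group
#' probe weight at 0.5 (sd 0.2) -- a neutral attentional split -- and the
#' group capacity at 0.08 items/ms (sd 0.05), vague enough for the data to
#' dominate. `sigma_w_scale` and `sigma_C_scale` are the half-t(3) scales
#' of the between-participant spreads (logit scale for w, items/ms for C).
#'
#' @param w_p_mean,w_p_sd Normal prior on the group probe weight
#'   (truncated to (0, 1)).
#' @param C_mean,C_sd Normal prior on the group capacity, items/ms
#'   (truncated to positive values).
#' @param sigma_w_scale,sigma_C_scale Half-t(3) scales for the
#'   participant-level standard deviations.
#' @return A `tva_hyperpriors` list.
#' @export
tva_hyperpriors <- function(w_p_mean = 0.5, w_p_sd = 0.2,
                            C_mean = 0.08, C_sd = 0.05,
                            sigma_w_scale = 1, sigma_C_scale = 0.05) {
  stopifnot(w_p_mean > 0, w_p_mean < 1, w_p_sd > 0, C_mean > 0, C_sd > 0,
            sigma_w_scale > 0, sigma_C_scale > 0)
  structure(list(w_p_mean = w_p_mean, w_p_sd = w_p_sd, C_mean = C_mean,
                 C_sd = C_sd, sigma_w_scale = sigma_w_scale,
                 sigma_C_scale = sigma_C_scale),
            class = "tva_hyperpriors")
}

# JAGS model code for a given number of capacity columns (1 = shared).
.toj_model_code <- function() {
"model {
  for (i in 1:N) {
    vp[i] <- w[pid[i], cond[i]] * C[pid[i], ccol[i]]
    vr[i] <- (1 - w[pid[i], cond[i]]) * C[pid[i], ccol[i]]
    pr[i] <- ifelse(neg[i] > 0.5,
      1 - exp(-vp[i] * asoa[i]) + exp(-vp[i] * asoa[i]) * vp[i] / (vp[i] + vr[i]),
      exp(-vr[i] * asoa[i]) * vp[i] / (vp[i] + vr[i]))
    pc[i] <- max(1.0E-12, min(1 - 1.0E-12, pr[i]))
    k[i] ~ dbin(pc[i], n[i])
  }
  for (j in 1:P) {
    for (c in 1:K) {
      lw[j, c] ~ dnorm(logit(mu_w[c]), tau_lw[c])
      w[j, c] <- ilogit(lw[j, c])
    }
    for (c in 1:KC) {
      C[j, c] ~ dnorm(mu_C[c], tau_C[c]) T(0,)
    }
  }
  for (c in 1:K) {
    mu_w[c] ~ dnorm(hp_w_mu, hp_w_tau) T(0.001, 0.999)
    sigma_lw[c] ~ dt(0, hp_sw_tau, 3) T(0,)
    tau_lw[c] <- 1 / (sigma_lw[c] * sigma_lw[c])
  }
  for (c in 1:KC) {
    mu_C[c] ~ dnorm(hp_C_mu, hp_C_tau) T(0,)
    sigma_C[c] ~ dt(0, hp_sC_tau, 3) T(0,)
    tau_C[c] <- 1 / (sigma_C[c] * sigma_C[c])
  }
}"
}

#' Build a hierarchical TVA-TOJ model specification
#'
#' Binds an SOA-aggregated TOJ trial table to one of the two model
#' variants: `"shared_C"` ties each participant's processing capacity
#' across conditions (attentional selection acts only through the
#' weights), `"condition_C"` frees capacity per condition (selection may
#' also change the total encoding rate). In both, the per-cell likelihood
#' is Binomial(n, P) with P from [p_probe_first()] (clipped to
#' \[1e-12, 1-1e-12\] inside the likelihood only), participant weights are
#' logit-normal around a condition-level group weight, and participant
#' capacities are positive-truncated normal around the group capacity.
#'
#' @param data A `toj_trial_table` (from [simulate_toj()] or
#'   [read_toj()]): columns `participant_id`, `condition`, `soa_ms`,
#'   `n_trials`, `n_probe_first`, unique per key. SOA is negative when
#'   the probe leads; which stimulus is the probe is a property of the
#'   ingested coding, never inferred here.
#' @param variant `"shared_C"` or `"condition_C"`.
#' @param baseline Label of the baseline condition (must be present).
#' @param hyperpriors A [tva_hyperpriors()].
#' @return A `toj_model_spec`.
#' @export
build_toj_model <- function(data, variant = c("shared_C", "condition_C"),
                            baseline = "baseline",
                            hyperpriors = tva_hyperpriors()) {
  variant <- match.arg(variant)
  stopifnot(inherits(hyperpriors, "tva_hyperpriors"))
  data <- validate_toj_table(data)
  if (nrow(data) == 0L) stop("empty TOJ table", call. = FALSE)
  conds <- unique(as.character(data$condition))
  if (!baseline %in% conds) {
    stop("baseline condition \"", baseline, "\" not found in data (have: ",
         paste(conds, collapse = ", "), ")", call. = FALSE)
  }
  if (length(unique(data$soa_ms)) < 2L) {
    stop("need at least 2 SOA levels to constrain the race model",
         call. = FALSE)
  }
  conds <- c(baseline, setdiff(conds, baseline))
  parts <- unique(data$participant_id)
  K <- length(conds)
  KC <- if (variant == "shared_C") 1L else K

  cells <- data
  cells$pid <- match(data$participant_id, parts)
  cells$cond <- match(as.character(data$condition), conds)
  cells$ccol <- if (variant == "shared_C") 1L else cells$cond

  structure(list(
    variant = variant, baseline = baseline, conditions = conds,
    participants = parts, hyperpriors = hyperpriors, cells = cells,
    code = .toj_model_code(),
    jags_data = list(
      N = nrow(cells), P = length(parts), K = K, KC = KC,
      pid = cells$pid, cond = cells$cond, ccol = cells$ccol,
      asoa = abs(cells$soa_ms), neg = as.numeric(cells$soa_ms < 0),
      n = cells$n_trials, k = cells$n_probe_first,
      hp_w_mu = hyperpriors$w_p_mean, hp_w_tau = 1 / hyperpriors$w_p_sd^2,
      hp_C_mu = hyperpriors$C_mean, hp_C_tau = 1 / hyperpriors$C_sd^2,
      hp_sw_tau = 1 / hyperpriors$sigma_w_scale^2,
      hp_sC_tau = 1 / hyperpriors$sigma_C_scale^2)),
    class = "toj_model_spec")
}

#' @export
print.toj_model_spec <- function(x, ...) {
  cat(sprintf(
    "Hierarchical TVA-TOJ model (%s): %d participants, %d conditions, %d cells\n",
    x$variant, length(x$participants), length(x$conditions),
    nrow(x$cells)))
  cat("  conditions:", paste(x$conditions, collapse = ", "),
      sprintf("(baseline: %s)\n", x$baseline))
  invisible(x)
}

#' Sampler profiles
#'
#' Named shortcut settings for [fit_toj_model()]: `"cheap"` (600 draws,
#' 300 adaptation, 2 chains) for simulation loops such as power analysis,
#' `"default"` (2000/1000/4) for interactive fits, and `"full"`
#' (30000/1000/4) for full-fidelity posteriors.
#'
#' @param profile Profile name.
#' @return List with `draws`, `tune`, `chains`.
#' @export
sampler_profile <- function(profile = c("default", "cheap", "full")) {
  switch(match.arg(profile),
         cheap = list(draws = 600, tune = 300, chains = 2),
         default = list(draws = 2000, tune = 1000, chains = 4),
         full = list(draws = 30000, tune = 1000, chains = 4))
}

#' Fit a hierarchical TVA-TOJ model with MCMC
#'
#' Samples the posterior with JAGS (adaptive slice/Gibbs sampling). The
#' total number of retained draws is split evenly across chains; `tune`
#' iterations of adaptation plus the same number of burn-in are discarded.
#' The per-cell pointwise log-likelihood is computed from the retained
#' draws and stored for PSIS-LOO model comparison. Chain seeds derive
#' deterministically from `seed`, so repeated fits with identical
#' settings reproduce identical draws.
#'
#' @param model A [build_toj_model()] specification.
#' @param draws Total retained posterior draws across chains.
#' @param tune Adaptation iterations (the same number again is used as
#'   burn-in).
#' @param chains Number of chains.
#' @param seed Integer master seed.
#' @param profile Optional [sampler_profile()] name overriding
#'   `draws`/`tune`/`chains`.
#' @param quiet Suppress JAGS progress output.
#' @return A `toj_fit` with elements `draws` (matrix, one column per
#'   parameter), `chain` (chain index per draw), `log_lik` (draws x cells
#'   matrix), `diagnostics` (split R-hat and effective sample size per
#'   parameter) and the model specification. A warning (never silence) is
#'   raised if any R-hat exceeds 1.01.
#' @export
fit_toj_model <- function(model, draws = 2000, tune = 1000, chains = 4,
                          seed = 1, profile = NULL, quiet = TRUE) {
  stopifnot(inherits(model, "toj_model_spec"))
  if (!is.null(profile)) {
    p <- sampler_profile(profile)
    draws <- p$draws; tune <- p$tune; chains <- p$chains
  }
  stopifnot(draws >= 1, tune >= 1, chains >= 1)
  chain_seeds <- derive_seeds(seed, chains)
  inits <- lapply(seq_len(chains), function(ch) {
    jd <- model$jags_data
    list(lw = matrix(0, jd$P, jd$K),
         C = matrix(model$hyperpriors$C_mean, jd$P, jd$KC),
         mu_w = rep(model$hyperpriors$w_p_mean, jd$K),
         mu_C = rep(model$hyperpriors$C_mean, jd$KC),
         sigma_lw = rep(0.2, jd$K),
         sigma_C = rep(model$hyperpriors$sigma_C_scale / 2, jd$KC),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = chain_seeds[ch])
  })
  per_chain <- ceiling(draws / chains)
  run <- function() {
    jm <- rjags::jags.model(textConnection(model$code),
                            data = model$jags_data, inits = inits,
                            n.chains = chains, n.adapt = tune,
                            quiet = quiet)
    stats::update(jm, n.iter = tune, progress.bar = "none")
    rjags::coda.samples(jm, c("mu_w", "sigma_lw", "mu_C", "sigma_C",
                              "w", "C"),
                        n.iter = per_chain, progress.bar = "none")
  }
  mc <- if (quiet) suppressWarnings(run()) else run()

  draw_mat <- do.call(rbind, lapply(mc, as.matrix))
  colnames(draw_mat) <- .normalize_parnames(colnames(draw_mat))
  for (ch in seq_along(mc)) {
    colnames(mc[[ch]]) <- colnames(draw_mat)
  }
  chain_idx <- rep(seq_len(chains), each = per_chain)

  fit <- structure(list(
    model = model, draws = draw_mat, chain = chain_idx,
    settings = list(draws = nrow(draw_mat), tune = tune, chains = chains,
                    seed = seed)),
    class = "toj_fit")
  fit$log_lik <- .pointwise_loglik(fit)
  fit$diagnostics <- .fit_diagnostics(mc)
  bad <- fit$diagnostics$rhat > 1.01
  if (any(bad, na.rm = TRUE)) {
    warning(sprintf(
      "possible non-convergence: %d parameter(s) with split R-hat > 1.01 (max %.3f)",
      sum(bad, na.rm = TRUE), max(fit$diagnostics$rhat, na.rm = TRUE)),
      call. = FALSE)
  }
  fit
}

# JAGS drops the "[1]" index on length-one monitored vectors; restore it
# so parameter addressing is uniform across variants.
.normalize_parnames <- function(nm) {
  bare <- nm %in% c("mu_w", "sigma_lw", "mu_C", "sigma_C")
  nm[bare] <- paste0(nm[bare], "[1]")
  nm
}

# Pointwise log-likelihood at the binomial-cell granularity
# (participant x condition x SOA), the unit over which PSIS-LOO
# cross-validates.
.pointwise_loglik <- function(fit) {
  cells <- fit$model$cells
  dm <- fit$draws
  S <- nrow(dm)
  ll <- matrix(NA_real_, S, nrow(cells))
  wcol <- sprintf("w[%d,%d]", cells$pid, cells$cond)
  Ccol <- sprintf("C[%d,%d]", cells$pid, cells$ccol)
  for (i in seq_len(nrow(cells))) {
    w <- dm[, wcol[i]]
    C <- dm[, Ccol[i]]
    p <- .p_probe_first_clipped(w * C, (1 - w) * C, cells$soa_ms[i])
    ll[, i] <- stats::dbinom(cells$n_probe_first[i], cells$n_trials[i], p,
                             log = TRUE)
  }
  ll
}

# Split R-hat and effective sample size per monitored parameter. Each
# chain is split in half so within-chain drift also registers.
.fit_diagnostics <- function(mc) {
  mats <- lapply(mc, as.matrix)
  pars <- colnames(mats[[1]])
  half <- floor(nrow(mats[[1]]) / 2)
  rhat <- vapply(pars, function(p) {
    chains <- unlist(lapply(mats, function(m) {
      if (half < 2) return(list(m[, p]))
      list(m[seq_len(half), p], m[(half + 1):(2 * half), p])
    }), recursive = FALSE)
    .split_rhat(chains)
  }, numeric(1))
  ess <- tryCatch(
    as.numeric(coda::effectiveSize(mc))[seq_along(pars)],
    error = function(e) rep(NA_real_, length(pars)))
  data.frame(parameter = pars, rhat = rhat, ess = ess,
             row.names = NULL)
}

.split_rhat <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1]])
  if (m < 2 || n < 2) return(NA_real_)
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.toj_fit <- function(x, ...) {
  cat(sprintf("TVA-TOJ fit (%s): %d draws x %d chains\n",
              x$model$variant, x$settings$draws, x$settings$chains))
  cat(sprintf("  max split R-hat: %.3f; min ESS: %.0f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  print(posterior_summary(x))
  invisible(x)
}
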