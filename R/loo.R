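# Generalized Pareto fit to tail exceedances, profile-likelihood method
# (Zhang & Stephens 2009) with the standard weak prior regularization of
# the shape estimate. Returns the shape xi ("khat") and scale sigma.
.gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5L || x[n] <= 0 || stats::sd(x) == 0) {
    return(list(k = NA_real_, sigma = NA_real_))
  }
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  kzs <- -vapply(b, function(bi) mean(log1p(-bi * x)), numeric(1))
  l <- n * (log(b / kzs) + kzs - 1)
  w <- 1 / vapply(jj, function(j) sum(exp(l - l[j])), numeric(1))
  bhat <- sum(b * w)
  k <- mean(log1p(-bhat * x))        # GPD shape xi
  sigma <- -k / bhat
  # weakly informative prior on the shape: shrink towards 0.5
  k_reg <- (n * k + 10 * 0.5) / (n + 10)
  list(k = k_reg, sigma = sigma)
}

.gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# Pareto-smoothed importance sampling for one observation's log ratios.
# Returns smoothed log weights (shifted so max = 0) and the tail shape.
.psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  tail_len <- as.integer(ceiling(min(0.2 * S, 3 * sqrt(S))))
  if (tail_len < 5L) {
    return(list(lw = lw, k = NA_real_))
  }
  ord <- order(lw)
  tail_idx <- ord[(S - tail_len + 1L):S]
  cutoff <- exp(lw[ord[S - tail_len]])
  exc <- exp(lw[tail_idx]) - cutoff
  fit <- .gpd_fit(exc)
  if (!is.finite(fit$k)) {
    return(list(lw = lw, k = fit$k))
  }
  # expected order statistics of the fitted tail
  pj <- (seq_len(tail_len) - 0.5) / tail_len
  qj <- cutoff + vapply(pj, .gpd_quantile, numeric(1),
                        k = fit$k, sigma = fit$sigma)
  lw[tail_idx[order(lw[tail_idx])]] <- pmin(log(qj), 0)
  list(lw = lw - max(lw), k = fit$k)
}

#' PSIS-LOO: approximate leave-one-out cross-validation
#'
#' Pareto-smoothed importance-sampling estimate of the expected log
#' pointwise predictive density under leave-one-out cross-validation.
#' For a fitted TVA-TOJ model the held-out unit is the binomial cell
#' (participant x condition x SOA); responses within a cell are
#' exchangeable under the model, so the cell is the natural
#' cross-validation granularity, and changing it would change the elpd
#' scale.
#'
#' @param x A `toj_fit`, or a draws-by-observations matrix of pointwise
#'   log-likelihood values.
#' @param k_threshold Pareto shape above which an observation's
#'   importance-sampling estimate is flagged as unreliable (default 0.7,
#'   the standard PSIS practice); flagged fractions are reported, and a
#'   warning is raised when any occur.
#' @param ... Unused.
#' @return A `tva_loo` with `elpd` (and its standard error), `p_loo`,
#'   and `pointwise` (per-observation `elpd_i` and Pareto `k`).
#' @export
psis_loo <- function(x, ...) UseMethod("psis_loo")

#' @rdname psis_loo
#' @export
psis_loo.matrix <- function(x, k_threshold = 0.7, ...) {
  stopifnot(is.numeric(x), nrow(x) >= 10L, ncol(x) >= 1L)
  S <- nrow(x)
  res <- vapply(seq_len(ncol(x)), function(i) {
    ll <- x[, i]
    sm <- .psis_smooth(-ll)
    elpd_i <- logsumexp(sm$lw + ll) - logsumexp(sm$lw)
    lpd_i <- logsumexp(ll) - log(S)
    c(elpd_i, sm$k, lpd_i)
  }, numeric(3))
  pointwise <- data.frame(elpd_i = res[1, ], k = res[2, ])
  n_bad <- sum(pointwise$k > k_threshold, na.rm = TRUE) +
    sum(!is.finite(pointwise$k))
  if (n_bad > 0) {
    warning(sprintf(
      "%d of %d observations with Pareto k > %.2f (or unestimable); elpd may be unreliable",
      n_bad, ncol(x), k_threshold), call. = FALSE)
  }
  structure(list(
    elpd = sum(pointwise$elpd_i),
    se = stats::sd(pointwise$elpd_i) * sqrt(ncol(x)),
    p_loo = sum(res[3, ]) - sum(pointwise$elpd_i),
    pointwise = pointwise,
    n_obs = ncol(x), k_threshold = k_threshold,
    bad_k_fraction = n_bad / ncol(x)),
    class = "tva_loo")
}

#' @rdname psis_loo
#' @export
psis_loo.toj_fit <- function(x, k_threshold = 0.7, ...) {
  out <- psis_loo.matrix(x$log_lik, k_threshold = k_threshold)
  out$data_digest <- .cell_digest(x$model$cells)
  out$model_name <- x$model$variant
  out
}

#' @export
print.tva_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO over %d observations: elpd = %.2f (se %.2f), p_loo = %.2f\n",
              x$n_obs, x$elpd, x$se, x$p_loo))
  cat(sprintf("  Pareto k > %.2f: %.1f%% of observations\n",
              x$k_threshold, 100 * x$bad_k_fraction))
  invisible(x)
}

.cell_digest <- function(cells) {
  paste(cells$participant_id, cells$condition, cells$soa_ms,
        cells$n_trials, cells$n_probe_first, collapse = ";")
}

#' Compare two models by PSIS-LOO
#'
#' Arbitrates between two fitted models of the same data (e.g. the
#' shared-capacity and condition-specific-capacity TVA-TOJ variants):
#' computes each model's PSIS-LOO elpd, the difference `d_elpd`
#' (best minus other, so >= 0 for the winner) with its standard error
#' from the pointwise differences, and per-model weights. The default
#' pseudo-BMA+ weights (Bayesian-bootstrap-regularized) sum to 1 and can
#' loosely be read as the probability of each model against the other;
#' stacking weights are available as an alternative.
#'
#' @param a,b `toj_fit` objects (or `tva_loo` objects from
#'   [psis_loo()]). Fits must carry pointwise log-likelihoods over the
#'   identical data cells; mismatched data is a hard error.
#' @param method Weighting scheme: `"pseudobma"` (default) or
#'   `"stacking"`.
#' @param n_boot Bayesian-bootstrap replicates for pseudo-BMA+.
#' @param seed Seed for the bootstrap.
#' @param model_names Optional length-2 character labels.
#' @return A `tva_loo_compare`: data frame with columns `model`, `elpd`,
#'   `se`, `p_loo`, `d_elpd`, `d_se`, `weight`, `bad_k_fraction`, best
#'   model first.
#' @export
loo_compare <- function(a, b, method = c("pseudobma", "stacking"),
                        n_boot = 1000, seed = 1, model_names = NULL) {
  method <- match.arg(method)
  as_loo <- function(x) if (inherits(x, "toj_fit")) psis_loo(x) else x
  la <- as_loo(a); lb <- as_loo(b)
  stopifnot(inherits(la, "tva_loo"), inherits(lb, "tva_loo"))
  if (la$n_obs != lb$n_obs) {
    stop("models were fit to different numbers of observations",
         call. = FALSE)
  }
  if (!is.null(la$data_digest) && !is.null(lb$data_digest) &&
      !identical(la$data_digest, lb$data_digest)) {
    stop("models were fit to different data; PSIS-LOO comparison requires identical cells",
         call. = FALSE)
  }
  if (is.null(model_names)) {
    model_names <- c(la$model_name %||% "model_a",
                     lb$model_name %||% "model_b")
    if (model_names[1] == model_names[2]) {
      model_names <- paste0(model_names, c("_a", "_b"))
    }
  }
  ew <- cbind(la$pointwise$elpd_i, lb$pointwise$elpd_i)
  elpd <- colSums(ew)
  diff_i <- ew[, 1] - ew[, 2]
  d_se <- stats::sd(diff_i) * sqrt(nrow(ew))

  weights <- switch(method,
    pseudobma = .pseudobma_weights(ew, n_boot = n_boot, seed = seed),
    stacking = .stacking_weights(ew))

  ord <- order(elpd, decreasing = TRUE)
  out <- data.frame(
    model = model_names[ord],
    elpd = elpd[ord],
    se = c(la$se, lb$se)[ord],
    p_loo = c(la$p_loo, lb$p_loo)[ord],
    d_elpd = c(0, elpd[ord][1] - elpd[ord][2]),
    d_se = c(0, d_se),
    weight = weights[ord],
    bad_k_fraction = c(la$bad_k_fraction, lb$bad_k_fraction)[ord])
  attr(out, "method") <- method
  class(out) <- c("tva_loo_compare", class(out))
  out
}

# Pseudo-BMA+ weights: softmax of total elpd under Bayesian-bootstrap
# resampling of the pointwise contributions, averaged over replicates.
.pseudobma_weights <- function(ew, n_boot = 1000, seed = 1) {
  n <- nrow(ew)
  if (n == 1L) {
    z <- ew[1, ] - max(ew[1, ])
    return(exp(z) / sum(exp(z)))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  acc <- rep(0, ncol(ew))
  for (b in seq_len(n_boot)) {
    g <- stats::rexp(n)
    wts <- g / sum(g)
    z <- n * colSums(wts * ew)
    z <- z - max(z)
    acc <- acc + exp(z) / sum(exp(z))
  }
  acc / n_boot
}

# Stacking of predictive distributions: maximize the summed log of the
# weighted pointwise predictive densities over the simplex.
.stacking_weights <- function(ew) {
  K <- ncol(ew)
  ref <- apply(ew, 1, max)
  dens <- exp(ew - ref)
  obj <- function(theta) {
    w <- exp(c(theta, 0))
    w <- w / sum(w)
    -sum(log(dens %*% w))
  }
  opt <- stats::optim(rep(0, K - 1), obj, method = "BFGS")
  w <- exp(c(opt$par, 0))
  w / sum(w)
}

#' @export
print.tva_loo_compare <- function(x, ...) {
  cat(sprintf("PSIS-LOO model comparison (%s weights):\n",
              attr(x, "method")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
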