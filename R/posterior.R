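#' Summarize posterior draws
#'
#' Posterior mean, shortest (highest-density) interval and the posterior
#' mass above zero, per parameter.
#'
#' @param x A `toj_fit`, a draws matrix (one column per parameter) or a
#'   numeric vector of draws.
#' @param pars For a `toj_fit`: parameters to summarize; defaults to the
#'   group-level parameters, with group weights and capacities labelled
#'   by condition.
#' @param prob HDI probability mass, in (0, 1).
#' @param ... Unused.
#' @return Data frame with columns `parameter`, `mean`, `sd`,
#'   `hdi_lower`, `hdi_upper`, `p_gt_0` (and, for fits, `rhat`, `ess`).
#' @examples
#' posterior_summary(rnorm(4000))
#' @export
posterior_summary <- function(x, ...) UseMethod("posterior_summary")

#' @rdname posterior_summary
#' @export
posterior_summary.default <- function(x, prob = 0.95, ...) {
  if (is.numeric(x) && is.null(dim(x))) {
    x <- matrix(x, ncol = 1, dimnames = list(NULL, "theta"))
  }
  stopifnot(is.matrix(x) || is.data.frame(x))
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("no draws to summarize", call. = FALSE)
  if (!is.numeric(prob) || length(prob) != 1L || prob <= 0 || prob >= 1) {
    stop("`prob` must be in (0, 1)", call. = FALSE)
  }
  nm <- colnames(x) %||% paste0("par", seq_len(ncol(x)))
  rows <- lapply(seq_len(ncol(x)), function(j) {
    d <- x[, j]
    h <- hdi(d, prob)
    data.frame(parameter = nm[j], mean = mean(d), sd = stats::sd(d),
               hdi_lower = h[["lower"]], hdi_upper = h[["upper"]],
               p_gt_0 = mean(d > 0))
  })
  out <- do.call(rbind, rows)
  attr(out, "prob") <- prob
  out
}

#' @rdname posterior_summary
#' @export
posterior_summary.toj_fit <- function(x, pars = NULL, prob = 0.95, ...) {
  conds <- x$model$conditions
  KC <- x$model$jags_data$KC
  if (is.null(pars)) {
    pars <- c(sprintf("mu_w[%d]", seq_along(conds)),
              sprintf("mu_C[%d]", seq_len(KC)),
              sprintf("sigma_lw[%d]", seq_along(conds)),
              sprintf("sigma_C[%d]", seq_len(KC)))
  }
  missing <- setdiff(pars, colnames(x$draws))
  if (length(missing)) {
    stop("unknown parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- posterior_summary.default(x$draws[, pars, drop = FALSE],
                                   prob = prob)
  # label group nodes by condition for readability
  relabel <- c(
    stats::setNames(sprintf("mu_w[%s]", conds),
                    sprintf("mu_w[%d]", seq_along(conds))),
    stats::setNames(sprintf("sigma_lw[%s]", conds),
                    sprintf("sigma_lw[%d]", seq_along(conds))),
    stats::setNames(
      if (KC == 1L) "mu_C" else sprintf("mu_C[%s]", conds),
      sprintf("mu_C[%d]", seq_len(KC))),
    stats::setNames(
      if (KC == 1L) "sigma_C" else sprintf("sigma_C[%s]", conds),
      sprintf("sigma_C[%d]", seq_len(KC))))
  hit <- out$parameter %in% names(relabel)
  out$parameter[hit] <- unname(relabel[out$parameter[hit]])
  diag <- x$diagnostics
  m <- match(pars, diag$parameter)
  out$rhat <- diag$rhat[m]
  out$ess <- diag$ess[m]
  out
}

#' Draw-wise social/perceptual salience effect scores
#'
#' Applies the change-score arithmetic of [change_scores()] to every
#' posterior draw, at the group level (group weight and capacity nodes)
#' and at the participant level, preserving posterior correlations. Under
#' the `shared_C` variant the capacity change is identically zero and all
#' rate changes are pure weight shifts.
#'
#' @param fit A `toj_fit`.
#' @param condition Condition label to contrast against baseline.
#' @param baseline Baseline label; defaults to the fit's baseline.
#' @param prob HDI probability for the summaries.
#' @return A `toj_effect_draws` list: `group_draws` (data frame of
#'   per-draw `C_effect`, `w_peffect`, `dv_p`, `dv_r`, `dv_rel`),
#'   `group_summary` (via [posterior_summary()]), and `participant`
#'   (per-participant posterior means of the same effect scores).
#' @export
derive_effects <- function(fit, condition, baseline = NULL, prob = 0.95) {
  stopifnot(inherits(fit, "toj_fit"))
  baseline <- baseline %||% fit$model$baseline
  conds <- fit$model$conditions
  for (lab in c(baseline, condition)) {
    if (!lab %in% conds) {
      stop("unknown condition label \"", lab, "\"", call. = FALSE)
    }
  }
  ib <- match(baseline, conds)
  ic <- match(condition, conds)
  shared <- fit$model$variant == "shared_C"
  dm <- fit$draws

  Cb <- dm[, sprintf("mu_C[%d]", if (shared) 1L else ib)]
  Cc <- dm[, sprintf("mu_C[%d]", if (shared) 1L else ic)]
  wb <- dm[, sprintf("mu_w[%d]", ib)]
  wc <- dm[, sprintf("mu_w[%d]", ic)]
  group_draws <- .change_scores_num(Cb, wb, Cc, wc)

  P <- fit$model$jags_data$P
  part_rows <- lapply(seq_len(P), function(j) {
    Cjb <- dm[, sprintf("C[%d,%d]", j, if (shared) 1L else ib)]
    Cjc <- dm[, sprintf("C[%d,%d]", j, if (shared) 1L else ic)]
    wjb <- dm[, sprintf("w[%d,%d]", j, ib)]
    wjc <- dm[, sprintf("w[%d,%d]", j, ic)]
    colMeans(.change_scores_num(Cjb, wjb, Cjc, wjc))
  })
  participant <- cbind(
    data.frame(participant_id = fit$model$participants),
    as.data.frame(do.call(rbind, part_rows)))

  structure(list(
    group_draws = group_draws,
    group_summary = posterior_summary(as.matrix(group_draws), prob = prob),
    participant = participant,
    baseline = baseline, condition = condition, prob = prob),
    class = "toj_effect_draws")
}

#' @export
print.toj_effect_draws <- function(x, ...) {
  cat(sprintf("Effect scores: %s vs %s (baseline)\n", x$condition,
              x$baseline))
  print(x$group_summary, row.names = FALSE)
  invisible(x)
}
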