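#' TOJ design: SOA schedule and repetitions
#'
#' The stimulus onset asynchrony (SOA) schedule of a temporal order
#' judgement block, with the number of trial repetitions per SOA level.
#' The `"paper_like"` profile follows the common TVA-TOJ layout: 11 levels
#' at 0, +/-14, +/-28, +/-42, +/-63, +/-83 ms, with more repetitions at
#' small SOAs (24 at |SOA| <= 14, 16 at 28-42 ms, 8 at 63-83 ms), all
#' within the 8-24 range. Small SOAs carry the most information about the
#' race parameters, hence the denser sampling there.
#'
#' @param profile One of `"paper_like"`, `"uniform"`, `"custom"`.
#' @param soa_levels_ms For `"custom"` (or to override `"uniform"`'s
#'   default levels): signed SOA levels in ms, negative when the probe
#'   leads. Must be unique.
#' @param reps Repetitions per level. For `"uniform"` a single count
#'   (default 10) recycled over all levels; for `"custom"` a vector
#'   matching `soa_levels_ms`.
#' @return A `toj_design`: data frame with columns `soa_ms`, `n_trials`.
#' @examples
#' toj_design("paper_like")
#' toj_design("uniform", reps = 10)
#' @export
toj_design <- function(profile = c("paper_like", "uniform", "custom"),
                       soa_levels_ms = NULL, reps = NULL) {
  profile <- match.arg(profile)
  paper_levels <- c(-83, -63, -42, -28, -14, 0, 14, 28, 42, 63, 83)
  if (profile == "paper_like") {
    if (!is.null(soa_levels_ms) || !is.null(reps)) {
      stop("`paper_like` takes no custom levels or reps; use profile = \"custom\"",
           call. = FALSE)
    }
    soa_levels_ms <- paper_levels
    reps <- c(8, 8, 16, 16, 24, 24, 24, 16, 16, 8, 8)
  } else if (profile == "uniform") {
    soa_levels_ms <- soa_levels_ms %||% paper_levels
    reps <- rep_len(reps %||% 10L, length(soa_levels_ms))
  } else {
    if (is.null(soa_levels_ms) || is.null(reps)) {
      stop("`custom` requires both `soa_levels_ms` and `reps`", call. = FALSE)
    }
    if (length(reps) != length(soa_levels_ms)) {
      stop("`reps` must match `soa_levels_ms` in length", call. = FALSE)
    }
  }
  if (anyDuplicated(soa_levels_ms)) {
    stop("SOA levels must be unique", call. = FALSE)
  }
  if (any(!is.finite(soa_levels_ms))) {
    stop("SOA levels must be finite", call. = FALSE)
  }
  reps <- as.integer(reps)
  if (any(is.na(reps) | reps < 1L)) {
    stop("every repetition count must be a positive integer", call. = FALSE)
  }
  ord <- order(soa_levels_ms)
  out <- data.frame(soa_ms = soa_levels_ms[ord], n_trials = reps[ord])
  class(out) <- c("toj_design", class(out))
  out
}

#' Population specification for synthetic TVA-TOJ studies
#'
#' Describes the generating population for synthetic experiments:
#' between-participant distributions of baseline capacity and probe
#' weight, condition-level injected effects, and matching-task accuracy.
#' Participant heterogeneity lives on unconstrained scales -- log C and
#' logit w_p -- so every sampled participant satisfies C > 0 and
#' 0 < w_p < 1. `C_mean`/`C_sd` are the population mean and SD in items/ms
#' (moment-matched to a log-normal); `w_p_mean` is the probability-scale
#' group weight, with `w_sd` the logit-scale spread.
#'
#' Injected effects are given per condition: `dw` shifts the group weight
#' from `w_p_mean` to `w_p_mean + dw` (applied as the corresponding logit
#' shift), `dC` shifts capacity from `C_mean` to `C_mean + dC` (applied as
#' the corresponding log shift); `dw_sd` (logit scale) and `dC_sd`
#' (items/ms, delta-method-converted to the log scale) add
#' between-participant variability in the effects.
#'
#' @param C_mean,C_sd Baseline capacity mean and SD, items/ms.
#' @param w_p_mean Baseline group probe weight in (0, 1).
#' @param w_sd Between-participant SD of logit(w_p).
#' @param effects Named list of conditions beyond baseline, each a list
#'   with any of `dw`, `dw_sd`, `dC`, `dC_sd` (missing entries default
#'   to 0). Default: one `"salience"` condition with no injected effect.
#' @param baseline Label of the baseline condition.
#' @param acc_self,acc_other Matching-task accuracy means in (0, 1) for
#'   self-match and other-match trials.
#' @param acc_sd Between-participant SD of matching accuracy on the
#'   log-odds scale.
#' @return A `population_spec` object.
#' @examples
#' population_spec(effects = list(salience = list(dw = 0.06)))
#' @export
population_spec <- function(C_mean = 0.06, C_sd = 0.01,
                            w_p_mean = 0.5, w_sd = 0.3,
                            effects = list(salience = list()),
                            baseline = "baseline",
                            acc_self = 0.95, acc_other = 0.80,
                            acc_sd = 0.5) {
  stopifnot(is.numeric(C_mean), C_mean > 0, is.numeric(C_sd), C_sd >= 0,
            is.numeric(w_p_mean), w_p_mean > 0, w_p_mean < 1,
            is.numeric(w_sd), w_sd >= 0,
            acc_self > 0, acc_self < 1, acc_other > 0, acc_other < 1,
            acc_sd >= 0)
  if (!is.list(effects) || is.null(names(effects)) ||
      any(!nzchar(names(effects)))) {
    stop("`effects` must be a named list of condition effect lists",
         call. = FALSE)
  }
  if (baseline %in% names(effects)) {
    stop("the baseline condition cannot carry an injected effect",
         call. = FALSE)
  }
  effects <- lapply(effects, function(e) {
    e <- utils::modifyList(list(dw = 0, dw_sd = 0, dC = 0, dC_sd = 0), e)
    stopifnot(e$dw_sd >= 0, e$dC_sd >= 0)
    if (w_p_mean + e$dw <= 0 || w_p_mean + e$dw >= 1) {
      stop("injected `dw` pushes the group weight outside (0, 1)",
           call. = FALSE)
    }
    if (C_mean + e$dC <= 0) {
      stop("injected `dC` implies non-positive processing capacity",
           call. = FALSE)
    }
    e
  })
  structure(list(C_mean = C_mean, C_sd = C_sd, w_p_mean = w_p_mean,
                 w_sd = w_sd, effects = effects, baseline = baseline,
                 acc_self = acc_self, acc_other = acc_other,
                 acc_sd = acc_sd),
            class = "population_spec")
}

#' Sample per-participant TVA parameters from a population
#'
#' Draws baseline parameters on the unconstrained scales (log C, logit
#' w_p) and adds the per-condition injected shifts, so each participant's
#' condition parameters are their own baseline plus an effect. With all
#' SDs zero every participant carries exactly the group parameters.
#'
#' @param spec A [population_spec()].
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A `tva_population`: data frame with columns `participant_id`,
#'   `condition`, `C`, `w_p`, one row per participant x condition.
#' @export
sample_population <- function(spec, n_participants, seed) {
  stopifnot(inherits(spec, "population_spec"),
            n_participants >= 1L, is.finite(seed))
  n <- as.integer(n_participants)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  # moment-matched log-normal for baseline C
  s2 <- log(1 + (spec$C_sd / spec$C_mean)^2)
  lC <- stats::rnorm(n, log(spec$C_mean) - s2 / 2, sqrt(s2))
  lw <- stats::rnorm(n, logit(spec$w_p_mean), spec$w_sd)

  conds <- c(spec$baseline, names(spec$effects))
  rows <- vector("list", length(conds))
  rows[[1L]] <- data.frame(participant_id = seq_len(n),
                           condition = spec$baseline,
                           C = exp(lC), w_p = ilogit(lw))
  for (i in seq_along(spec$effects)) {
    e <- spec$effects[[i]]
    dlw <- stats::rnorm(n, logit(spec$w_p_mean + e$dw) - logit(spec$w_p_mean),
                        e$dw_sd)
    dlC <- stats::rnorm(n, log((spec$C_mean + e$dC) / spec$C_mean),
                        e$dC_sd / spec$C_mean)
    rows[[i + 1L]] <- data.frame(participant_id = seq_len(n),
                                 condition = names(spec$effects)[i],
                                 C = exp(lC + dlC), w_p = ilogit(lw + dlw))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  class(out) <- c("tva_population", class(out))
  out
}
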