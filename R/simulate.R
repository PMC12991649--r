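#' Simulate temporal order judgement responses
#'
#' Generates SOA-aggregated binomial TOJ data: for every participant x
#' condition x SOA cell the number of "probe first" reports is drawn as
#' Binomial(n_trials, P) with P from the closed-form race model
#' [p_probe_first()].
#'
#' @param population A `tva_population` from [sample_population()], or any
#'   data frame with columns `participant_id`, `condition`, `C`, `w_p`
#'   (`C > 0`, `0 <= w_p <= 1`; the boundary weights are allowed so
#'   degenerate races can be simulated).
#' @param design A [toj_design()].
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A `toj_trial_table`: data frame with columns `participant_id`,
#'   `condition`, `soa_ms`, `n_trials`, `n_probe_first`.
#' @examples
#' pop <- sample_population(population_spec(), 3, seed = 1)
#' simulate_toj(pop, toj_design("uniform", reps = 8), seed = 2)
#' @export
simulate_toj <- function(population, design, seed) {
  stopifnot(is.data.frame(population), is.data.frame(design))
  need <- c("participant_id", "condition", "C", "w_p")
  if (!all(need %in% names(population))) {
    stop("`population` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(design) == 0L) stop("empty design", call. = FALSE)
  if (any(population$C <= 0) || any(population$w_p < 0) ||
      any(population$w_p > 1)) {
    stop("invalid population parameters: need C > 0 and w_p in [0, 1]",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  idx <- rep(seq_len(nrow(population)), each = nrow(design))
  out <- data.frame(
    participant_id = population$participant_id[idx],
    condition = population$condition[idx],
    soa_ms = rep(design$soa_ms, nrow(population)),
    n_trials = rep(as.integer(design$n_trials), nrow(population))
  )
  v_p <- population$w_p[idx] * population$C[idx]
  v_r <- (1 - population$w_p[idx]) * population$C[idx]
  p <- p_probe_first(v_p, v_r, out$soa_ms)
  out$n_probe_first <- stats::rbinom(nrow(out), out$n_trials, p)
  class(out) <- c("toj_trial_table", class(out))
  out
}

#' Simulate shape-label matching responses
#'
#' Generates the 2 x 2 matching-task table (identity self/other x pairing
#' match/mismatch) with binomial correctness per cell. Per-participant
#' accuracies vary around the specified self-match and other-match means
#' on the log-odds scale; mismatch cells use the average of the two match
#' accuracies (they are not analysed for the self-prioritization effect
#' but keep the table complete).
#'
#' @param spec A [population_spec()] (its `acc_self`, `acc_other`,
#'   `acc_sd` fields are used).
#' @param n_participants Number of participants.
#' @param n_trials_per_cell Trials per identity x pairing cell.
#' @param seed Integer seed.
#' @return A `matching_table`: data frame with columns `participant_id`,
#'   `identity` ("self"/"other"), `pairing` ("match"/"mismatch"),
#'   `n_trials`, `n_correct`.
#' @export
simulate_matching <- function(spec, n_participants, n_trials_per_cell = 24,
                              seed = 1) {
  stopifnot(inherits(spec, "population_spec"), n_participants >= 1L,
            n_trials_per_cell >= 1L)
  n <- as.integer(n_participants)
  m <- as.integer(n_trials_per_cell)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  acc_self <- ilogit(stats::rnorm(n, logit(spec$acc_self), spec$acc_sd))
  acc_other <- ilogit(stats::rnorm(n, logit(spec$acc_other), spec$acc_sd))
  acc_mis <- ilogit((logit(acc_self) + logit(acc_other)) / 2)

  grid <- expand.grid(identity = c("self", "other"),
                      pairing = c("match", "mismatch"),
                      participant_id = seq_len(n),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  acc <- ifelse(grid$pairing == "match",
                ifelse(grid$identity == "self",
                       acc_self[grid$participant_id],
                       acc_other[grid$participant_id]),
                acc_mis[grid$participant_id])
  out <- data.frame(participant_id = grid$participant_id,
                    identity = grid$identity, pairing = grid$pairing,
                    n_trials = m,
                    n_correct = stats::rbinom(nrow(grid), m, acc))
  out <- out[order(out$participant_id, out$identity, out$pairing), ]
  rownames(out) <- NULL
  class(out) <- c("matching_table", class(out))
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper producing everything a downstream analysis needs:
#' the sampled population, the TOJ trial table and the matching table,
#' with all randomness driven from one master seed via a deterministic
#' seed ladder.
#'
#' @inheritParams sample_population
#' @param design A [toj_design()]; default `"paper_like"`.
#' @param n_matching_trials Trials per matching cell.
#' @return List with elements `population`, `toj`, `matching`.
#' @examples
#' study <- simulate_study(population_spec(), 12, seed = 7)
#' head(study$toj)
#' @export
simulate_study <- function(spec, n_participants,
                           design = toj_design("paper_like"),
                           n_matching_trials = 24, seed = 1) {
  seeds <- derive_seeds(seed, 3L)
  pop <- sample_population(spec, n_participants, seed = seeds[1])
  list(population = pop,
       toj = simulate_toj(pop, design, seed = seeds[2]),
       matching = simulate_matching(spec, n_participants,
                                    n_matching_trials, seed = seeds[3]))
}
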