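#' Self-prioritization effect from matching-task data
#'
#' The self-prioritization effect (SPE) is the accuracy advantage for
#' self-associated over other-associated stimuli on match trials of the
#' shape-label matching task; only match trials enter the score. Each
#' participant contributes `spe = acc_self_match - acc_other_match`;
#' participants missing either match cell are excluded with a warning.
#'
#' @param table A `matching_table` (from [simulate_matching()] or
#'   [read_matching()]).
#' @param conf Confidence level of the group-mean interval (t-based).
#' @return An `spe_result`: list with `participant` (data frame of
#'   per-participant `acc_self`, `acc_other`, `spe`) and `group` (mean,
#'   confidence bounds, n).
#' @examples
#' m <- simulate_matching(population_spec(), 20, seed = 1)
#' compute_spe(m)
#' @export
compute_spe <- function(table, conf = 0.95) {
  table <- validate_matching_table(table)
  match_rows <- table[table$pairing == "match", , drop = FALSE]
  ids <- unique(table$participant_id)
  rows <- lapply(ids, function(id) {
    self <- match_rows[match_rows$participant_id == id &
                         match_rows$identity == "self", , drop = FALSE]
    other <- match_rows[match_rows$participant_id == id &
                          match_rows$identity == "other", , drop = FALSE]
    if (nrow(self) == 0L || nrow(other) == 0L ||
        sum(self$n_trials) == 0L || sum(other$n_trials) == 0L) {
      return(NULL)
    }
    a_s <- sum(self$n_correct) / sum(self$n_trials)
    a_o <- sum(other$n_correct) / sum(other$n_trials)
    data.frame(participant_id = id, acc_self = a_s, acc_other = a_o,
               spe = a_s - a_o)
  })
  dropped <- ids[vapply(rows, is.null, logical(1))]
  if (length(dropped) == length(ids)) {
    stop("no participant has both a self-match and an other-match cell; ",
         "cannot compute the SPE", call. = FALSE)
  }
  if (length(dropped)) {
    warning("excluding participant(s) missing a match cell: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  participant <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(participant) <- NULL
  group <- list(mean = mean(participant$spe), n = nrow(participant))
  if (group$n >= 2L && stats::sd(participant$spe) > 0) {
    tt <- stats::t.test(participant$spe, conf.level = conf)
    group$ci_lower <- unname(tt$conf.int[1])
    group$ci_upper <- unname(tt$conf.int[2])
  } else {
    group$ci_lower <- group$ci_upper <- group$mean
  }
  structure(list(participant = participant, group = group, conf = conf),
            class = "spe_result")
}

#' @export
print.spe_result <- function(x, ...) {
  cat(sprintf("SPE over %d participants: mean %+.3f [%.0f%% CI %+.3f, %+.3f]\n",
              x$group$n, x$group$mean, 100 * x$conf, x$group$ci_lower,
              x$group$ci_upper))
  invisible(x)
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Descriptive association between two per-participant quantities, e.g.
#' the SPE and an attentional effect score. Thin wrapper around
#' [stats::cor.test()].
#'
#' @param x,y Paired numeric vectors (>= 4 finite pairs, both with
#'   nonzero variance).
#' @param conf Confidence level.
#' @return List with `r`, `ci_lower`, `ci_upper`, `n`.
#' @examples
#' correlate(1:10, 2 * (1:10) + 1)$r
#' @export
correlate <- function(x, y, conf = 0.95) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) {
    stop("need at least 4 paired finite observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: an input has zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, conf.level = conf)
  list(r = unname(ct$estimate), ci_lower = unname(ct$conf.int[1]),
       ci_upper = unname(ct$conf.int[2]), n = length(x))
}

#' Correlate SPE with participant-level attentional effects
#'
#' Pairs the per-participant SPE with the posterior-mean effect scores of
#' a fitted model (default the relative rate change `dv_rel`, the
#' processing-rate advantage of the probe) by participant id, and returns
#' the Pearson correlation with its confidence interval.
#'
#' @param spe An `spe_result` from [compute_spe()].
#' @param effects A `toj_effect_draws` from [derive_effects()].
#' @param score Effect column to use: one of `"dv_rel"`, `"dv_p"`,
#'   `"dv_r"`, `"w_peffect"`, `"C_effect"`.
#' @param conf Confidence level.
#' @return As [correlate()], plus the merged per-participant table.
#' @export
correlate_spe_effects <- function(spe, effects, score = "dv_rel",
                                  conf = 0.95) {
  stopifnot(inherits(spe, "spe_result"),
            inherits(effects, "toj_effect_draws"))
  score <- match.arg(score, c("dv_rel", "dv_p", "dv_r", "w_peffect",
                              "C_effect"))
  merged <- merge(spe$participant, effects$participant,
                  by = "participant_id")
  if (nrow(merged) < 4L) {
    stop("fewer than 4 participants shared between SPE and effects",
         call. = FALSE)
  }
  out <- correlate(merged$spe, merged[[score]], conf = conf)
  out$score <- score
  out$data <- merged
  out
}
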