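#' TVA parameters: processing capacity and probe weight
#'
#' Bundle the two parameters of the TVA account of two-stimulus temporal
#' order judgements: the total processing capacity `C` (items/ms) and the
#' relative attentional weight `w_p` of the probe stimulus. The probe and
#' reference encoding rates follow as `v_p = w_p * C` and
#' `v_r = (1 - w_p) * C`, so `v_p + v_r = C` by construction.
#'
#' @param C Processing capacity in items/ms; strictly positive. 0.06
#'   items/ms corresponds to the 60 Hz typically observed with dense
#'   shape displays.
#' @param w_p Relative attentional weight of the probe, in the open
#'   interval (0, 1). 0.5 means both stimuli receive equal resources.
#' @return An object of class `tva_params`.
#' @examples
#' p <- tva_params(C = 0.06, w_p = 0.5)
#' rates_from_params(p)
#' @export
tva_params <- function(C, w_p) {
  stopifnot(is.numeric(C), length(C) == 1L, is.finite(C),
            is.numeric(w_p), length(w_p) == 1L, is.finite(w_p))
  if (C <= 0) {
    stop("`C` must be strictly positive (items/ms), got ", C, call. = FALSE)
  }
  if (w_p <= 0 || w_p >= 1) {
    stop("`w_p` must lie in the open interval (0, 1), got ", w_p,
         call. = FALSE)
  }
  structure(list(C = C, w_p = w_p), class = "tva_params")
}

#' @export
print.tva_params <- function(x, ...) {
  v <- rates_from_params(x)
  cat(sprintf(
    "TVA parameters: C = %.4g items/ms (%.3g Hz), w_p = %.4g\n", x$C,
    1000 * x$C, x$w_p))
  cat(sprintf("  rates: v_p = %.4g, v_r = %.4g items/ms\n",
              v[["v_p"]], v[["v_r"]]))
  invisible(x)
}

#' Encoding rates implied by TVA parameters
#'
#' @param p A [tva_params()] object.
#' @return Named numeric vector `c(v_p = , v_r = )` in items/ms. The two
#'   rates sum to `C` exactly.
#' @export
rates_from_params <- function(p) {
  stopifnot(inherits(p, "tva_params"))
  v_p <- p$w_p * p$C
  # complement form keeps v_p + v_r = C exact in floating point
  c(v_p = v_p, v_r = p$C - v_p)
}

#' Probability of reporting the probe first in a TVA race
#'
#' Closed-form psychometric function of the two-stimulus exponential race:
#' encoding completion times are exponential with rates `v_p` (probe) and
#' `v_r` (reference), the reference onset is delayed relative to the probe
#' by the stimulus onset asynchrony, and the stimulus encoded first is
#' reported first. With the convention that `soa < 0` means the probe
#' leads,
#' \deqn{P = 1 - e^{-v_p|SOA|} + e^{-v_p|SOA|} \frac{v_p}{v_p+v_r}
#'       \quad (SOA < 0)}
#' \deqn{P = e^{-v_r|SOA|} \frac{v_p}{v_p+v_r} \quad (SOA \ge 0).}
#' Both branches agree at `soa = 0`, where `P = v_p / (v_p + v_r) = w_p`.
#'
#' @param v_p,v_r Non-negative encoding rates in items/ms (not both zero).
#' @param soa Stimulus onset asynchrony in ms; negative if the probe leads.
#' @return Probability in \[0, 1\]. Vectorized over all arguments with the
#'   usual recycling.
#' @examples
#' p_probe_first(0.03, 0.03, 0)     # symmetric race: 0.5
#' p_probe_first(0.03, 0.03, -83)   # probe leads by 83 ms
#' @export
p_probe_first <- function(v_p, v_r, soa) {
  n <- max(length(v_p), length(v_r), length(soa))
  v_p <- rep_len(v_p, n)
  v_r <- rep_len(v_r, n)
  soa <- rep_len(soa, n)
  if (any(!is.finite(v_p)) || any(!is.finite(v_r)) || any(!is.finite(soa))) {
    stop("rates and SOA must be finite", call. = FALSE)
  }
  if (any(v_p < 0) || any(v_r < 0)) {
    stop("encoding rates must be non-negative", call. = FALSE)
  }
  if (any(v_p + v_r == 0)) {
    stop("undefined race: both encoding rates are zero", call. = FALSE)
  }
  a <- abs(soa)
  share <- v_p / (v_p + v_r)
  ifelse(soa < 0,
         1 - exp(-v_p * a) + exp(-v_p * a) * share,
         exp(-v_r * a) * share)
}

# Internal: clipped probability for likelihood evaluation only. The public
# psychometric function is never clipped.
.p_probe_first_clipped <- function(v_p, v_r, soa, eps = 1e-12) {
  pmin(pmax(p_probe_first(v_p, v_r, soa), eps), 1 - eps)
}

# Internal vectorized change-score arithmetic shared by change_scores()
# and the draw-wise effect derivation.
.change_scores_num <- function(C_base, w_base, C_cond, w_cond) {
  C_effect <- C_cond - C_base
  dv_p <- w_cond * C_cond - w_base * C_base
  # v_r = C - v_p within each condition, so dv_r = C_effect - dv_p; the
  # complement form keeps both effect identities exact in floating point
  dv_r <- C_effect - dv_p
  data.frame(
    C_effect = C_effect,
    w_peffect = w_cond - w_base,
    dv_p = dv_p,
    dv_r = dv_r,
    dv_rel = dv_p - dv_r
  )
}

#' Baseline-corrected TVA change scores
#'
#' Condition-minus-baseline differences in capacity, probe weight and the
#' implied encoding rates: `C_effect = C_cond - C_base`,
#' `w_peffect = w_cond - w_base`, `dv_p` and `dv_r` the probe/reference
#' rate changes, and `dv_rel = dv_p - dv_r`, the relative processing-rate
#' advantage gained by the probe. Because `v_p + v_r = C` within each
#' condition, `dv_p + dv_r = C_effect` identically.
#'
#' @param baseline,condition [tva_params()] objects.
#' @return An object of class `tva_effects`: a one-row data frame with
#'   columns `C_effect`, `w_peffect`, `dv_p`, `dv_r`, `dv_rel` (rates in
#'   items/ms).
#' @examples
#' change_scores(tva_params(0.06, 0.5), tva_params(0.06, 0.6))
#' @export
change_scores <- function(baseline, condition) {
  stopifnot(inherits(baseline, "tva_params"), inherits(condition, "tva_params"))
  out <- .change_scores_num(baseline$C, baseline$w_p,
                            condition$C, condition$w_p)
  class(out) <- c("tva_effects", class(out))
  out
}

#' @export
print.tva_effects <- function(x, ...) {
  cat("TVA change scores (condition - baseline):\n")
  cat(sprintf("  C_effect  = %+.5g items/ms (%+.3g Hz)\n",
              x$C_effect, 1000 * x$C_effect))
  cat(sprintf("  w_peffect = %+.5g\n", x$w_peffect))
  cat(sprintf("  dv_p      = %+.5g items/ms (%+.3g Hz)\n",
              x$dv_p, 1000 * x$dv_p))
  cat(sprintf("  dv_r      = %+.5g items/ms (%+.3g Hz)\n",
              x$dv_r, 1000 * x$dv_r))
  cat(sprintf("  dv_rel    = %+.5g items/ms (%+.3g Hz)\n",
              x$dv_rel, 1000 * x$dv_rel))
  invisible(x)
}
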