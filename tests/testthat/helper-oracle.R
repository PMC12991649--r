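# Monte-Carlo oracle for the two-stimulus exponential race: the probe's
# encoding time is Exponential(v_p) from probe onset, the reference's is
# Exponential(v_r) from reference onset, the onsets are separated by the
# SOA (negative = probe leads), and the stimulus finishing first is
# reported first. Independent of the closed form it checks.
race_oracle <- function(v_p, v_r, soa, reps = 1e6, seed = 1) {
  set.seed(seed)
  t_p <- if (v_p > 0) rexp(reps, v_p) else rep(Inf, reps)
  t_r <- if (v_r > 0) rexp(reps, v_r) else rep(Inf, reps)
  if (soa < 0) {
    mean(t_p < abs(soa) + t_r)
  } else {
    mean(soa + t_p < t_r)
  }
}

# binomial 3*SE tolerance for an oracle estimate of probability p
oracle_tol <- function(p, reps = 1e6) {
  pmax(3 * sqrt(p * (1 - p) / reps), 1e-6)
}
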