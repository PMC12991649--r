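logit <- function(p) log(p / (1 - p))
ilogit <- function(x) 1 / (1 + exp(-x))

# Deterministic seed ladder: one master seed fans out to n child seeds so
# that individual simulations are reproducible and reorderable. Children
# stay below .Machine$integer.max.
derive_seeds <- function(master, n) {
  stopifnot(length(master) == 1L, is.finite(master), n >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Highest density interval of a sample
#'
#' Shortest interval containing a given probability mass, computed from
#' sorted draws (the standard sample-based HDI estimator for unimodal
#' posteriors).
#'
#' @param x Numeric vector of posterior draws.
#' @param prob Probability mass of the interval, in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower = , upper = )`.
#' @examples
#' hdi(rnorm(10000), prob = 0.95)
#' @export
hdi <- function(x, prob = 0.95) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  if (!is.numeric(prob) || length(prob) != 1L || prob <= 0 || prob >= 1) {
    stop("`prob` must be a single value in (0, 1)", call. = FALSE)
  }
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0L) stop("no finite draws", call. = FALSE)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = x[1L], upper = x[n]))
  widths <- x[(m + 1L):n] - x[1L:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

# Exact HDI of a Beta(a, b) distribution, used for the power posterior.
beta_hdi <- function(a, b, prob = 0.95) {
  stopifnot(a > 0, b > 0, prob > 0, prob < 1)
  # Degenerate/monotone density cases: fall back to one-sided intervals.
  if (a <= 1 && b > 1) return(c(lower = 0, upper = stats::qbeta(prob, a, b)))
  if (b <= 1 && a > 1) return(c(lower = stats::qbeta(1 - prob, a, b), upper = 1))
  if (a <= 1 && b <= 1) return(c(lower = 0, upper = 1))
  width <- function(lo_mass) {
    stats::qbeta(lo_mass + prob, a, b) - stats::qbeta(lo_mass, a, b)
  }
  opt <- stats::optimize(width, interval = c(0, 1 - prob))
  c(lower = stats::qbeta(opt$minimum, a, b),
    upper = stats::qbeta(opt$minimum + prob, a, b))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
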