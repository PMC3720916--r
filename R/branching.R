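#' Abortive colony size distribution for a constant death probability
#'
#' Closed-form probability that a single plated cell produces a fully
#' extinct (abortive) colony of exactly `n` cells when every cell, at every
#' generation, dies with probability `p` or divides with probability
#' `1 - p`. A final size of `n` corresponds to a binary lineage tree with
#' `n` dead leaves and `n - 1` divisions, and the number of such trees is
#' the Catalan number \eqn{C_{n-1}}, so
#' \deqn{f_n = C_{n-1}\, p^n (1-p)^{n-1}.}
#' Summed over all `n` this gives the extinction probability
#' \eqn{\min(1, p/(1-p))}.
#'
#' @param p Death probability in `[0, 1]`.
#' @param n_max Largest colony size to return.
#' @return Numeric vector of length `n_max`; element `n` is the probability
#'   of an abortive colony of exactly `n` cells.
#' @examples
#' pmf_constant(0.5, 3)  # 0.5, 0.125, 0.0625
#' sum(pmf_constant(0.4, 2000))  # ~ 2/3, the extinction probability
#' @export
pmf_constant <- function(p, n_max) {
  if (is.na(p) || p < 0 || p > 1) stop("death probability `p` must lie in [0, 1]")
  n_max <- as.integer(n_max)
  if (n_max < 1L) stop("`n_max` must be >= 1")
  if (p == 0) return(numeric(n_max))
  if (p == 1) return(c(1, numeric(n_max - 1L)))
  n <- seq_len(n_max)
  # Catalan(n-1) = choose(2(n-1), n-1) / n, in log space to avoid overflow
  exp(lchoose(2 * (n - 1), n - 1) - log(n) + n * log(p) + (n - 1) * log1p(-p))
}

# self-convolution over colony sizes: out[n] = sum_{k=1}^{n-1} q[k] q[n-k]
branch_selfconv <- function(q) {
  n_max <- length(q)
  if (n_max == 1L) return(0)
  full <- convolve(q, rev(q), type = "open")
  c(0, pmax(full[seq_len(n_max - 1L)], 0))
}

#' Abortive colony size distribution under a generation-dependent schedule
#'
#' Generalizes [pmf_constant()] to a death probability that changes with
#' generation. Writing \eqn{q_g(n)} for the probability that a single
#' generation-`g` cell founds an abortive colony of `n` cells,
#' \deqn{q_g(n) = P_1(g)\,[n = 1] + (1 - P_1(g)) \sum_{k=1}^{n-1}
#'   q_{g+1}(k)\, q_{g+1}(n-k),}
#' and the returned distribution is \eqn{q_0}. Beyond the schedule horizon
#' the tail is handled in one of two ways:
#' \describe{
#'   \item{`"constant"` (default)}{\eqn{P_1(g) = P_1(g_{max})} for all
#'     \eqn{g > g_{max}}; the tail level is then the exact Catalan closed
#'     form and the recursion is exact at every size, so for a constant
#'     schedule the result equals [pmf_constant()] exactly.}
#'   \item{`"truncate"`}{lineages still proliferative after generation
#'     `g_max` are scored as non-abortive and contribute no mass,
#'     mimicking colonies fixed and scored at a finite assay time.}
#' }
#'
#' @param schedule A [p1_schedule].
#' @param n_max Largest colony size to return.
#' @param tail `"constant"` or `"truncate"` (see Details).
#' @return Numeric vector of length `n_max` of abortive-colony size
#'   probabilities \eqn{q_0(1..n_{max})}.
#' @examples
#' pmf_schedule(p1_schedule(c(0.2, 0.4, 0.5), g_max = 2), 3)
#' @export
pmf_schedule <- function(schedule, n_max, tail = c("constant", "truncate")) {
  stopifnot(inherits(schedule, "p1_schedule"))
  tail <- match.arg(tail)
  n_max <- as.integer(n_max)
  if (n_max < 1L) stop("`n_max` must be >= 1")
  probs <- schedule$probs
  e1 <- c(1, numeric(n_max - 1L))
  if (tail == "constant") {
    # all generations >= g_max share the closed-form constant-p distribution
    if (all(probs == probs[1L])) return(pmf_constant(probs[1L], n_max))
    q <- pmf_constant(probs[length(probs)], n_max)
    gens <- rev(seq_len(length(probs) - 1L))  # g_max-1 .. 0 (1-based offsets)
  } else {
    # generation-g_max cells that divide push daughters past the horizon
    q <- probs[length(probs)] * e1
    gens <- rev(seq_len(length(probs) - 1L))
  }
  for (g in gens) {
    p1 <- probs[g]
    q <- p1 * e1 + (1 - p1) * branch_selfconv(q)
  }
  q
}

#' Probability that a plated cell escapes extinction
#'
#' Complement of the total abortive-colony mass: the probability that the
#' lineage of a single plated cell never goes fully extinct (under the
#' constant continuation of the schedule tail). Computed from the exact
#' extinction fixed point \eqn{x_g = P_1(g) + (1 - P_1(g))\, x_{g+1}^2}
#' anchored at the closed-form constant-tail extinction probability
#' \eqn{\min(1, p/(1-p))}.
#'
#' @param schedule A [p1_schedule].
#' @return Probability in `[0, 1]` that the colony survives indefinitely.
#' @examples
#' survivor_mass(p1_schedule(0.6))  # 0: subcritical proliferation
#' survivor_mass(p1_schedule(0.25)) # 1 - 1/3
#' @export
survivor_mass <- function(schedule) {
  stopifnot(inherits(schedule, "p1_schedule"))
  probs <- schedule$probs
  p_tail <- probs[length(probs)]
  x <- if (p_tail >= 0.5) 1 else p_tail / (1 - p_tail)
  for (g in rev(seq_len(length(probs) - 1L))) {
    x <- probs[g] + (1 - probs[g]) * x^2
  }
  max(0, min(1, 1 - x))
}

#' Estimate the unobserved 1-cell colony frequency from the 2-cell class
#'
#' Single cells are not scored in the assay, so the 1-cell frequency is
#' inferred from the 2-cell frequency by assuming the same death
#' probability applies at the first two branch points: under the branching
#' model \eqn{f_2 = (1-p)\,p^2} and \eqn{f_1 = p}, so `p` is recovered as a
#' root of the cubic \eqn{(1-p)p^2 = f_2}. The cubic has two roots in
#' `[0, 1]` (they merge at `p = 2/3` where \eqn{f_2} attains its maximum
#' `4/27`); both are reported and one is selected.
#'
#' @param f2 Observed 2-cell colony frequency, as a probability in
#'   `[0, 4/27]`.
#' @param hint Which root to select when two exist: `"smaller"` (default;
#'   consistent with observed sub-50% 1-cell frequencies) or `"larger"`.
#' @return A list with `f1` (the selected 1-cell frequency, equal to `p`),
#'   `p`, and `roots` (both roots, ascending).
#' @examples
#' estimate_f1_from_f2(0.125)  # p = 0.5
#' @export
estimate_f1_from_f2 <- function(f2, hint = c("smaller", "larger")) {
  hint <- match.arg(hint)
  if (is.na(f2) || f2 < 0) stop("`f2` must be a non-negative frequency")
  fmax <- 4 / 27
  if (f2 > fmax + 1e-12)
    stop("no root: `f2` exceeds the model maximum 4/27 = ", signif(fmax, 6))
  g <- function(p) (1 - p) * p^2 - f2
  if (f2 == 0) {
    roots <- c(0, 1)
  } else if (abs(f2 - fmax) <= 1e-12) {
    roots <- c(2 / 3, 2 / 3)
  } else {
    lo <- uniroot(g, c(0, 2 / 3), tol = 1e-12)$root
    hi <- uniroot(g, c(2 / 3, 1), tol = 1e-12)$root
    roots <- c(lo, hi)
  }
  p <- if (hint == "smaller") roots[1L] else roots[2L]
  list(f1 = p, p = p, roots = roots)
}
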