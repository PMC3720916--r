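#' Generation-indexed schedule of reproductive cell death probabilities
#'
#' A `p1_schedule` holds the per-generation probability of reproductive cell
#' death (RCD), \eqn{P_1(g)} for \eqn{g = 0, \dots, g_{max}}. A cell of
#' generation \eqn{g} either dies with probability \eqn{P_1(g)} or divides
#' with probability \eqn{1 - P_1(g)}, producing two generation-\eqn{g+1}
#' daughters.
#'
#' @param probs Numeric vector of death probabilities indexed by generation
#'   `0:g_max`, each in `[0, 1]`. A single value is recycled (constant
#'   schedule).
#' @param g_max Integer generation horizon (default 16, or inferred from
#'   `probs` when it has more than one element).
#' @param c_tail Optional tail-slope parameter `c` in `[0, 1]` recorded with
#'   the schedule; when a schedule is built with [build_schedule()] the
#'   probabilities for generations `6:g_max` lie on the straight line from
#'   `P1(5)` down to `(1 - c) * P1(5)` at `g_max`.
#' @return An object of class `p1_schedule`: a list with elements `probs`,
#'   `g_max` and `c_tail`.
#' @examples
#' p1_schedule(0.5)                      # constant P1 = 0.5
#' p1_schedule(seq(0.1, 0.4, length.out = 17))
#' @export
p1_schedule <- function(probs, g_max = if (length(probs) > 1L) length(probs) - 1L else 16L,
                        c_tail = NULL) {
  if (length(probs) == 0L) stop("empty schedule: `probs` must have length >= 1")
  g_max <- as.integer(g_max)
  if (g_max < 0L) stop("`g_max` must be >= 0")
  if (length(probs) == 1L) probs <- rep(probs, g_max + 1L)
  if (length(probs) != g_max + 1L)
    stop("`probs` must have length g_max + 1 (one entry per generation 0..g_max)")
  if (anyNA(probs) || any(probs < 0) || any(probs > 1))
    stop("all death probabilities must lie in [0, 1]")
  if (!is.null(c_tail) && (c_tail < 0 || c_tail > 1))
    stop("tail slope `c_tail` must lie in [0, 1]")
  structure(list(probs = as.numeric(probs), g_max = g_max, c_tail = c_tail),
            class = "p1_schedule")
}

#' @export
print.p1_schedule <- function(x, ...) {
  cat("P1 schedule, generations 0..", x$g_max, "\n", sep = "")
  cat("  P1(g): ", paste(formatC(x$probs, digits = 3, format = "fg"),
                         collapse = " "), "\n", sep = "")
  if (!is.null(x$c_tail))
    cat("  tail slope c = ", x$c_tail, " (P1(", x$g_max, ") = (1 - c) * P1(5))\n",
        sep = "")
  invisible(x)
}

#' @export
length.p1_schedule <- function(x) length(x$probs)

#' Build a full schedule from an estimated head and a linear tail
#'
#' Extends the six estimated probabilities \eqn{P_1(0), \dots, P_1(5)} to a
#' full generation horizon with the one-parameter linear tail model: the
#' terminal probability is \eqn{P_1(g_{max}) = (1 - c)\,P_1(5)} and the
#' generations between 5 and `g_max` are linearly interpolated. `c = 0`
#' keeps RCD constant beyond generation 5; `c = 1` lets it decay to zero.
#'
#' @param head Numeric vector of six probabilities `P1(0..5)`, each in
#'   `[0, 1]`.
#' @param c_tail Tail slope `c` in `[0, 1]`.
#' @param g_max Integer horizon, at least 6 (default 16).
#' @return A [p1_schedule] of length `g_max + 1` with the `c_tail` recorded.
#' @examples
#' sch <- build_schedule(c(0.10, 0.22, 0.29, 0.34, 0.34, 0.41), c_tail = 0.4)
#' sch$probs[17]  # (1 - 0.4) * 0.41
#' @export
build_schedule <- function(head, c_tail, g_max = 16L) {
  if (length(head) != 6L) stop("`head` must contain the six probabilities P1(0..5)")
  if (anyNA(head) || any(head < 0) || any(head > 1))
    stop("head probabilities must lie in [0, 1]")
  if (c_tail < 0 || c_tail > 1) stop("tail slope `c_tail` must lie in [0, 1]")
  g_max <- as.integer(g_max)
  if (g_max < 6L) stop("`g_max` must be >= 6")
  p5 <- head[6L]
  p_end <- (1 - c_tail) * p5
  tail_g <- seq.int(6L, g_max)
  tail_p <- p5 + (p_end - p5) * (tail_g - 5) / (g_max - 5)
  p1_schedule(c(head, tail_p), g_max = g_max, c_tail = c_tail)
}
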