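# forward model used by the inversion: head = P1(0..5), constant tail P1(5)
pmf_head <- function(head, n_max) {
  q <- pmf_constant(head[6L], n_max)
  e1 <- c(1, numeric(n_max - 1L))
  for (g in 5:1) q <- head[g] * e1 + (1 - head[g]) * branch_selfconv(q)
  q
}

#' Estimate P1(g) for generations 0..5 from a smoothed size distribution
#'
#' Inverts the branching model against the regression-smoothed colony-size
#' frequencies: finds the six death probabilities \eqn{P_1(0), \dots,
#' P_1(5)} whose model size distribution (with the tail held constant at
#' \eqn{P_1(5)} during inversion) best matches the fitted frequencies over
#' `n_range` on the log10 scale. Under the lineage-tree model the 1-cell
#' frequency pins \eqn{P_1(0)} exactly (\eqn{f_1 = P_1(0)}); deeper
#' generations are informed by progressively larger and sparser colonies,
#' so \eqn{P_1(5)} carries the most uncertainty and is flagged as such.
#'
#' Two inversion modes are available. `"least_squares"` (default) solves
#' the over-determined system (15 sizes, 6 unknowns) by box-constrained
#' weighted least squares on log-frequencies. `"sequential"` solves sizes
#' one at a time: for each `g`, \eqn{P_1(g)} is the root matching
#' \eqn{f_{g+1}} with earlier generations fixed and later ones held at the
#' same value.
#'
#' 95% limits are propagated by re-running the inversion on the lower and
#' upper 95% confidence-limit curves of the regression fit.
#'
#' @param fit A `regression_fit` from [fit_size_distribution()], or a bare
#'   numeric vector of frequencies over `n_range` (no limits available in
#'   that case).
#' @param n_range Colony sizes over which to match (default `1:15`).
#' @param mode `"least_squares"` or `"sequential"`.
#' @param normalize `"percent"` (default: fitted frequencies are percent of
#'   all colonies and are divided by 100) or `"none"` (already
#'   probabilities).
#' @param weights Optional per-size weights for the log-scale residuals
#'   (default uniform).
#' @param limits Propagate 95% limits from the regression band?
#' @return An object of class `p1_estimate`: list with `dose`, `probs`
#'   (named `g0..g5`), `lo`, `hi`, `p5_uncertain = TRUE`, `mode`,
#'   `objective`, `convergence` and `source_fit`.
#' @examples
#' d <- colony_size_distribution("0", 1:15,
#'        frequency = 10^(1.02 - 1.28 * log10(1:15)), f1_estimated = TRUE)
#' est <- invert_p1(fit_size_distribution(d, "log_log"), limits = FALSE)
#' round(est$probs, 2)
#' @export
invert_p1 <- function(fit, n_range = 1:15,
                      mode = c("least_squares", "sequential"),
                      normalize = c("percent", "none"), weights = NULL,
                      limits = TRUE) {
  mode <- match.arg(mode)
  normalize <- match.arg(normalize)
  n_range <- as.integer(n_range)
  if (is.numeric(fit)) {
    if (length(fit) != length(n_range))
      stop("frequency vector must match `n_range` in length")
    fhat <- fit
    limits <- FALSE
  } else {
    stopifnot(inherits(fit, "regression_fit"))
    fhat <- predict(fit, n_range)
  }
  if (normalize == "percent") fhat <- fhat / 100
  if (any(fhat <= 0)) stop("fit predicts non-positive frequencies on `n_range`")
  if (fhat[1L] > 1) stop("infeasible frequencies: f(1) exceeds 1")
  probs <- solve_head(fhat, n_range, mode, weights)
  lo <- hi <- NULL
  if (limits) {
    band <- confidence_band(fit, n_range)
    scale <- if (normalize == "percent") 100 else 1
    p_lo <- solve_head(pmin(band$lower / scale, 1 - 1e-9), n_range, mode, weights)
    p_hi <- solve_head(pmin(band$upper / scale, 1 - 1e-9), n_range, mode, weights)
    lo <- pmax(0, pmin(probs$par, p_lo$par, p_hi$par))
    hi <- pmin(1, pmax(probs$par, p_lo$par, p_hi$par))
  }
  dose <- if (inherits(fit, "regression_fit")) fit$dose else NA_character_
  structure(list(dose = dose, probs = setNames(probs$par, paste0("g", 0:5)),
                 lo = lo, hi = hi, p5_uncertain = TRUE, mode = mode,
                 objective = probs$value, convergence = probs$convergence,
                 source_fit = fit),
            class = "p1_estimate")
}

solve_head <- function(fhat, n_range, mode, weights) {
  n_max <- max(n_range)
  if (is.null(weights)) weights <- rep(1, length(n_range))
  if (mode == "sequential") {
    head <- numeric(6L)
    for (g in 0:5) {
      target <- g + 1L
      if (!(target %in% n_range)) stop("sequential mode needs sizes 1..6 in `n_range`")
      h <- function(x) {
        hd <- head
        hd[(g + 1L):6L] <- x
        pmf_head(hd, target)[target] - fhat[match(target, n_range)]
      }
      sol <- tryCatch(uniroot(h, c(1e-6, 1 - 1e-6), tol = 1e-10)$root,
                      error = function(e)
                        stop("sequential inversion failed at generation ", g,
                             ": ", conditionMessage(e)))
      head[g + 1L] <- sol
    }
    return(list(par = head, value = NA_real_, convergence = 0L))
  }
  # optimize on the logit scale so the [0, 1] box is enforced smoothly
  obj <- function(theta) {
    par <- stats::plogis(theta)
    q <- pmf_head(par, n_max)[n_range]
    if (any(q <= 0)) return(1e10)
    sum(weights * (log10(q) - log10(fhat))^2)
  }
  init <- stats::qlogis(pmin(pmax(c(fhat[1L], rep(0.3, 5)), 1e-3), 0.99))
  o <- optim(init, obj, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-14))
  o2 <- optim(o$par, obj, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-14))
  if (o2$value < o$value) o <- o2
  if (!is.finite(o$value) || o$value >= 1e10)
    stop("P1 inversion did not converge: objective did not reach a feasible value")
  list(par = stats::plogis(o$par), value = o$value, convergence = 0L)
}

#' @export
print.p1_estimate <- function(x, ...) {
  cat("P1(g) estimate, dose ", x$dose, " Gy (", x$mode, " inversion)\n", sep = "")
  m <- rbind(P1 = x$probs)
  if (!is.null(x$lo)) m <- rbind(lo = x$lo, P1 = x$probs, hi = x$hi)
  print(round(m, 4))
  cat("  note: P1(5) is informed only by the largest, sparsest size classes\n")
  invisible(x)
}

#' Radiation-induced excess probability of reproductive cell death
#'
#' Per-generation difference between the RCD probability estimated at a
#' dose and the unirradiated baseline, `excess(g) = P1_dose(g) -
#' P1_control(g)` (positive when irradiation increases RCD). 95% limits
#' are combined conservatively by interval arithmetic:
#' `[lo_d - hi_c, hi_d - lo_c]`.
#'
#' @param p_dose,p_control `p1_estimate` objects over the same
#'   generations.
#' @return A data frame of class `p1_excess` with columns `g`, `excess`,
#'   `lo`, `hi` and attribute `doses`.
#' @export
excess_p1 <- function(p_dose, p_control) {
  stopifnot(inherits(p_dose, "p1_estimate"), inherits(p_control, "p1_estimate"))
  if (length(p_dose$probs) != length(p_control$probs) ||
      !identical(names(p_dose$probs), names(p_control$probs)))
    stop("estimates cover different generation ranges")
  out <- data.frame(g = seq_along(p_dose$probs) - 1L,
                    excess = unname(p_dose$probs - p_control$probs))
  if (!is.null(p_dose$lo) && !is.null(p_control$lo)) {
    out$lo <- unname(p_dose$lo - p_control$hi)
    out$hi <- unname(p_dose$hi - p_control$lo)
  }
  attr(out, "doses") <- c(dose = p_dose$dose, control = p_control$dose)
  class(out) <- c("p1_excess", "data.frame")
  out
}
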