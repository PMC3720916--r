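#' Colony-size frequency distribution at one dose
#'
#' Container for the scored colony-size distribution of one irradiation
#' condition: for each colony size `n` (cells), the frequency as a percent
#' of scored colonies, optionally backed by raw colony counts. The 1-cell
#' class is not scored experimentally; when it has been inferred with
#' [estimate_f1_from_f2()] the `f1_estimated` flag marks it so that fits
#' can include it while information criteria exclude it.
#'
#' @param dose Dose label (e.g. `"0"`, `"8"`; treated as opaque text).
#' @param n Integer colony sizes (cells), distinct and >= 1.
#' @param frequency Frequencies in percent, non-negative, same length as
#'   `n`.
#' @param counts Optional raw colony counts consistent with `frequency`.
#' @param f1_estimated Logical: is the `n = 1` entry inferred rather than
#'   observed?
#' @return An object of class `colony_dist`.
#' @examples
#' colony_size_distribution("0", n = 2:5, frequency = c(8.6, 5.1, 3.5, 2.6))
#' @export
colony_size_distribution <- function(dose, n, frequency, counts = NULL,
                                     f1_estimated = FALSE) {
  n <- as.integer(n)
  if (length(n) == 0L) stop("empty distribution")
  if (any(n < 1L)) stop("colony sizes must be positive integers")
  if (anyDuplicated(n)) stop("colony sizes must be distinct")
  if (length(frequency) != length(n)) stop("`n` and `frequency` lengths differ")
  if (anyNA(frequency) || any(frequency < 0)) stop("frequencies must be >= 0")
  if (!is.null(counts)) {
    if (length(counts) != length(n)) stop("`counts` length differs from `n`")
    if (any(counts < 0)) stop("counts must be >= 0")
    total <- sum(counts)
    if (total > 0) {
      implied <- 100 * counts / total
      ok <- is.na(frequency) | abs(implied - frequency) < 1e-6 * pmax(1, frequency)
      if (!all(ok))
        warning("frequencies are not consistent with counts under the total-count denominator")
    }
  }
  ord <- order(n)
  structure(list(dose = as.character(dose), n = n[ord],
                 frequency = as.numeric(frequency)[ord],
                 counts = if (is.null(counts)) NULL else counts[ord],
                 f1_estimated = isTRUE(f1_estimated)),
            class = "colony_dist")
}

#' @export
print.colony_dist <- function(x, ...) {
  cat("Colony size distribution, dose ", x$dose, " Gy (", length(x$n),
      " size classes)\n", sep = "")
  if (x$f1_estimated) cat("  n = 1 class estimated from the 2-cell frequency\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.colony_dist <- function(x, ...) {
  d <- data.frame(dose = x$dose, n = x$n, frequency = x$frequency,
                  stringsAsFactors = FALSE)
  if (!is.null(x$counts)) d$count <- x$counts
  d
}

#' Add the inferred 1-cell class to a distribution
#'
#' Infers the unscored 1-cell frequency from the 2-cell class via the
#' branching-model cubic (see [estimate_f1_from_f2()]) and prepends it,
#' flagged as estimated.
#'
#' @param dist A [colony_size_distribution()] containing an `n = 2` entry
#'   and no `n = 1` entry.
#' @param hint Root selection passed to [estimate_f1_from_f2()].
#' @return A new `colony_dist` with the `n = 1` class added and
#'   `f1_estimated = TRUE`.
#' @export
add_estimated_f1 <- function(dist, hint = "smaller") {
  stopifnot(inherits(dist, "colony_dist"))
  if (1L %in% dist$n) stop("distribution already contains an n = 1 entry")
  if (!(2L %in% dist$n)) stop("an n = 2 entry is required to estimate f1")
  f2 <- dist$frequency[dist$n == 2L] / 100
  est <- estimate_f1_from_f2(f2, hint = hint)
  colony_size_distribution(dist$dose, c(1L, dist$n),
                           c(100 * est$f1, dist$frequency),
                           counts = NULL, f1_estimated = TRUE)
}
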