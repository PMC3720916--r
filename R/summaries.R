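#' Classify colonies by final size
#'
#' Standard colony-formation-assay scoring: 1-cell "colonies" are single
#' unscored cells, colonies of 2-49 cells are abortive (growth stopped
#' before reaching the survivor threshold) and colonies of 50 or more
#' cells are clonogenic survivors.
#'
#' @param n Integer colony sizes, all >= 1.
#' @return Factor with levels `single`, `abortive`, `clonogenic`.
#' @examples
#' classify_colony(c(1, 2, 49, 50))
#' @export
classify_colony <- function(n) {
  if (any(is.na(n)) || any(n < 1)) stop("colony sizes must be integers >= 1")
  cut(n, breaks = c(0, 1, 49, Inf),
      labels = c("single", "abortive", "clonogenic"))
}

colony_bin_breaks <- c(2, 8, 16, 50, Inf)
colony_bin_labels <- c("2-7", "8-15", "16-49", ">=50")

#' Binned colony-size frequencies
#'
#' Percentages of scored colonies (>= 2 cells; singles are not scored)
#' falling in the fixed size bins 2-7, 8-15, 16-49 and >= 50 cells.
#'
#' @param final_sizes Integer colony sizes.
#' @return Named numeric vector of class `binned_frequencies` summing to
#'   100, over bins `2-7`, `8-15`, `16-49`, `>=50`.
#' @examples
#' bin_frequencies(c(2, 3, 8, 50))  # 50, 25, 0, 25
#' @export
bin_frequencies <- function(final_sizes) {
  if (any(is.na(final_sizes)) || any(final_sizes < 1))
    stop("colony sizes must be integers >= 1")
  scored <- final_sizes[final_sizes >= 2]
  if (length(scored) == 0L)
    stop("no scored colonies: all sizes are 1 (empty denominator)")
  counts <- table(cut(scored, breaks = colony_bin_breaks, right = FALSE,
                      labels = colony_bin_labels))
  out <- 100 * as.numeric(counts) / length(scored)
  structure(setNames(out, colony_bin_labels), class = "binned_frequencies")
}

#' @export
print.binned_frequencies <- function(x, ...) {
  cat("Colony-size bin frequencies (% of colonies with >= 2 cells):\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Squared relative discrepancy (SQD) between binned distributions
#'
#' Discrepancy metric between simulated and experimental binned
#' frequencies,
#' \deqn{\mathrm{SQD} = \sum_{\mathrm{bins}} \left( \frac{f_{sim} -
#'   f_{obs}}{f_{obs}} \times 100 \right)^2,}
#' in arbitrary units. Note the metric is not symmetric: the observed
#' frequencies are the denominator.
#'
#' @param sim,obs Binned frequencies on the same bins ([bin_frequencies()]
#'   output or plain named vectors).
#' @param skip_zero_obs Drop bins where `obs` is 0 instead of erroring?
#' @return The scalar SQD.
#' @examples
#' sqd(c(55, 20, 15, 10), c(50, 20, 15, 15))
#' @export
sqd <- function(sim, obs, skip_zero_obs = FALSE) {
  if (length(sim) != length(obs)) stop("bin sets differ in length")
  if (!is.null(names(sim)) && !is.null(names(obs)) &&
      !identical(names(sim), names(obs)))
    stop("bin labels do not match")
  sim <- as.numeric(sim); obs <- as.numeric(obs)
  if (any(obs <= 0)) {
    if (!skip_zero_obs)
      stop("observed bin frequency is 0: relative deviation undefined ",
           "(set `skip_zero_obs = TRUE` to drop such bins)")
    keep <- obs > 0
    sim <- sim[keep]; obs <- obs[keep]
  }
  sum(((sim - obs) / obs * 100)^2)
}

#' Surviving fraction from simulated batches
#'
#' Ratio of clonogenic (>= 50 cells) colony counts between an irradiated
#' batch and the unirradiated control batch plated at the same density.
#' Per-set fractions are retained so the dispersion across replicate
#' simulation sets can be reported.
#'
#' @param batch_dose,batch_control `simulation_result` objects from
#'   [run_batch()].
#' @return A list with `sf` (overall fraction), `per_set` (per matching
#'   set pair, when both batches have the same number of sets), and the
#'   clonogenic counts.
#' @export
surviving_fraction <- function(batch_dose, batch_control) {
  stopifnot(inherits(batch_dose, "simulation_result"),
            inherits(batch_control, "simulation_result"))
  clono <- function(b) sum(b$final_sizes >= 50)
  n_dose <- clono(batch_dose)
  n_ctrl <- clono(batch_control)
  if (n_ctrl == 0L)
    stop("control batch has no clonogenic colonies: surviving fraction undefined")
  per_set <- NULL
  if (batch_dose$n_sets == batch_control$n_sets) {
    cd <- tapply(batch_dose$final_sizes >= 50, batch_dose$set_id, sum)
    cc <- tapply(batch_control$final_sizes >= 50, batch_control$set_id, sum)
    per_set <- as.numeric(cd) / as.numeric(cc)
  }
  # normalize by inocula in case the two batches differ in plating scale
  scale <- (batch_control$n_inocula * batch_control$n_sets) /
    (batch_dose$n_inocula * batch_dose$n_sets)
  list(sf = (n_dose / n_ctrl) * scale, per_set = per_set,
       clonogenic_dose = n_dose, clonogenic_control = n_ctrl)
}

#' Chi-square comparison of observed counts with simulated proportions
#'
#' Pearson chi-square test of observed per-bin colony counts against the
#' proportions taken from a (much larger) simulation, with Bonferroni
#' correction for a family of `n_tests` comparisons. The simulated
#' proportions are treated as fixed: the simulation totals dwarf the
#' observed ones, so their sampling error is ignored and the statistic has
#' `bins - 1` degrees of freedom.
#'
#' @param obs_counts Observed integer counts per bin.
#' @param sim_proportions Simulated proportions per bin (normalized
#'   internally).
#' @param n_tests Size of the Bonferroni family (default 1).
#' @return A list with `statistic`, `df`, `p_value`,
#'   `p_corrected = min(1, p * n_tests)` and `expected` counts.
#' @examples
#' chi_square_bonferroni(c(10, 10, 10, 70), rep(0.25, 4), n_tests = 4)
#' @export
chi_square_bonferroni <- function(obs_counts, sim_proportions, n_tests = 1L) {
  if (length(obs_counts) != length(sim_proportions)) stop("bin sets differ")
  if (n_tests < 1L) stop("`n_tests` must be >= 1")
  if (any(obs_counts < 0) || any(sim_proportions < 0)) stop("negative input")
  p <- sim_proportions / sum(sim_proportions)
  expected <- sum(obs_counts) * p
  if (any(expected == 0))
    stop("degenerate expectation: a simulated bin proportion is 0")
  stat <- sum((obs_counts - expected)^2 / expected)
  df <- length(obs_counts) - 1L
  p_raw <- pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p_raw,
       p_corrected = min(1, p_raw * n_tests), expected = expected)
}

#' Write a per-dose binned-frequency report
#'
#' @param bins_by_dose Named list of [bin_frequencies()] vectors, one per
#'   dose label.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_binned_report <- function(bins_by_dose, path) {
  rows <- do.call(rbind, lapply(names(bins_by_dose), function(d) {
    b <- bins_by_dose[[d]]
    data.frame(dose = d, bin = names(b), frequency = as.numeric(b))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
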