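#' Configuration of the 2D lattice colony-expansion simulator
#'
#' Colonies grow on a square lattice whose pitch matches the footprint of
#' one fibroblast (31.6 um x 31.6 um, i.e. a cell area of 1,000 um^2). One
#' time step is one population doubling time (20 h), and the assay horizon
#' of about 13 days corresponds to at most 16 divisions; the number of
#' steps is `min(ceiling(horizon_days * 24 / dt_hours), g_max)`.
#'
#' @param pitch Site spacing in micrometres (default 31.6).
#' @param grid_side Number of sites per grid edge; must be odd so a single
#'   inoculum sits at the exact centre (default 201).
#' @param g_max Maximum number of divisions (default 16).
#' @param dt_hours Doubling time in hours; one simulation step (default 20).
#' @param horizon_days Simulated culture duration in days (default 13).
#' @param p_move Per-step probability that a cell with a free neighbour
#'   relocates to one (default 0.25; the biology fixes only that movement
#'   exists, not its rate).
#' @param rcd_when_blocked Logical: may a contact-inhibited cell still
#'   undergo RCD that step? Default `FALSE` (fate deferred: a blocked cell
#'   neither divides nor dies, since fate is drawn per doubling).
#' @param seed Optional integer master seed recorded in the config.
#' @return An object of class `lattice_config`.
#' @export
lattice_config <- function(pitch = 31.6, grid_side = 201L, g_max = 16L,
                           dt_hours = 20, horizon_days = 13, p_move = 0.25,
                           rcd_when_blocked = FALSE, seed = NULL) {
  grid_side <- as.integer(grid_side)
  g_max <- as.integer(g_max)
  if (grid_side < 3L || grid_side %% 2L == 0L)
    stop("`grid_side` must be an odd integer >= 3 (centre inoculation)")
  if (p_move < 0 || p_move > 1) stop("`p_move` must lie in [0, 1]")
  n_steps <- min(as.integer(ceiling(horizon_days * 24 / dt_hours)), g_max)
  structure(list(pitch = pitch, grid_side = grid_side, g_max = g_max,
                 dt_hours = dt_hours, horizon_days = horizon_days,
                 n_steps = n_steps, p_move = p_move,
                 rcd_when_blocked = isTRUE(rcd_when_blocked), seed = seed),
            class = "lattice_config")
}

#' @export
print.lattice_config <- function(x, ...) {
  cat(sprintf(paste0("Lattice config: %d x %d sites (pitch %.1f um), ",
                     "%d steps of %g h (<= %d divisions), p_move = %g\n"),
              x$grid_side, x$grid_side, x$pitch, x$n_steps, x$dt_hours,
              x$g_max, x$p_move))
  invisible(x)
}

check_schedule_covers <- function(schedule, config) {
  if (length(schedule$probs) < config$n_steps)
    stop("schedule must cover at least generations 0..", config$n_steps - 1L)
}

#' Initial lattice state with a single centred inoculum
#'
#' @param config A [lattice_config()].
#' @return A `lattice_state`: list with square integer matrices `status`
#'   (0 empty, 1 proliferative, 2 RCD) and `generation`, plus `step`.
#' @export
lattice_state <- function(config) {
  side <- config$grid_side
  status <- matrix(0L, side, side)
  generation <- matrix(0L, side, side)
  ctr <- (side + 1L) %/% 2L
  status[ctr, ctr] <- 1L
  structure(list(status = status, generation = generation, step = 0L,
                 boundary = FALSE),
            class = "lattice_state")
}

#' Advance the lattice by one doubling step
#'
#' In a uniformly random order, every proliferative cell with at least one
#' free site among its 8 neighbours draws a fate: RCD with probability
#' `P1(g)` (the status flip is permanent) or division, placing a
#' generation-`g+1` daughter on a uniformly random free neighbour (the
#' dividing cell itself also advances to generation `g+1`, matching the
#' lineage-tree view that an internal node is a division). Blocked cells
#' are contact-inhibited and defer their fate. Afterwards every cell with
#' a free neighbour relocates to one with probability `p_move`.
#'
#' @param state A [lattice_state()].
#' @param schedule A [p1_schedule] covering every generation present.
#' @param config A [lattice_config()].
#' @return The advanced `lattice_state` (the input is not modified).
#' @export
lattice_step <- function(state, schedule, config) {
  stopifnot(inherits(state, "lattice_state"), inherits(schedule, "p1_schedule"))
  res <- cpp_lattice_step(state$status, state$generation, schedule$probs,
                          config$p_move, config$rcd_when_blocked)
  structure(list(status = res$status, generation = res$generation,
                 step = state$step + 1L,
                 boundary = state$boundary || res$boundary),
            class = "lattice_state")
}

#' Simulate one colony from a single plated cell
#'
#' Runs lattice steps until the assay horizon is reached or no
#' proliferative cell remains, starting from one generation-0 cell at the
#' grid centre.
#'
#' @param schedule A [p1_schedule].
#' @param config A [lattice_config()].
#' @return A list with `size` (total cells), `n_proliferative`, `n_rcd`,
#'   `boundary` (did the colony ever touch the grid edge?) and `steps`.
#' @export
simulate_colony <- function(schedule, config = lattice_config()) {
  stopifnot(inherits(schedule, "p1_schedule"), inherits(config, "lattice_config"))
  check_schedule_covers(schedule, config)
  res <- cpp_simulate_colony(schedule$probs, config$grid_side, config$n_steps,
                             config$p_move, config$rcd_when_blocked)
  if (res$boundary)
    warning("colony touched the grid boundary; sizes may be clipped")
  res
}

#' Simulate a batch of independently inoculated colonies
#'
#' Repeats the single-colony simulation for `n_inocula` plated cells in
#' each of `n_sets` replicate simulation sets (the defaults, 10,000 x 5 =
#' 50,000 inocula, reproduce a full assay-scale run). Each set uses a seed
#' derived deterministically from the master seed, so results are
#' bit-reproducible.
#'
#' @param schedule A [p1_schedule].
#' @param config A [lattice_config()].
#' @param n_inocula Colonies per set (default 10000).
#' @param n_sets Replicate sets (default 5).
#' @param seed Master seed; defaults to `config$seed`.
#' @return An object of class `simulation_result`: a list with
#'   `final_sizes`, `n_proliferative`, `n_rcd`, `boundary`, `set_id`,
#'   `n_inocula`, `n_sets`, `set_seeds`, `seed` and the `schedule` and
#'   `config` echoes.
#' @export
run_batch <- function(schedule, config = lattice_config(), n_inocula = 10000L,
                      n_sets = 5L, seed = config$seed) {
  stopifnot(inherits(schedule, "p1_schedule"), inherits(config, "lattice_config"))
  check_schedule_covers(schedule, config)
  if (n_inocula < 1L || n_sets < 1L) stop("`n_inocula` and `n_sets` must be >= 1")
  if (is.null(seed)) seed <- 1L
  set.seed(seed)
  set_seeds <- sample.int(.Machine$integer.max, n_sets)
  per_set <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    set.seed(set_seeds[s])
    per_set[[s]] <- cpp_run_inocula(schedule$probs, config$grid_side,
                                    config$n_steps, config$p_move,
                                    config$rcd_when_blocked, as.integer(n_inocula))
  }
  m <- do.call(rbind, per_set)
  structure(list(final_sizes = m[, 1L], n_proliferative = m[, 2L],
                 n_rcd = m[, 3L], boundary = m[, 4L] == 1L,
                 set_id = rep(seq_len(n_sets), each = n_inocula),
                 n_inocula = as.integer(n_inocula), n_sets = as.integer(n_sets),
                 set_seeds = set_seeds, seed = seed,
                 schedule = schedule, config = config),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Lattice simulation: ", x$n_sets, " set(s) x ", x$n_inocula,
      " inocula = ", length(x$final_sizes), " colonies\n", sep = "")
  cls <- table(classify_colony(x$final_sizes))
  cat("  ", paste(names(cls), as.integer(cls), sep = ": ", collapse = ", "),
      "\n", sep = "")
  if (any(x$boundary)) cat("  note:", sum(x$boundary), "colonies touched the grid boundary\n")
  invisible(x)
}

#' Write per-inoculum simulation results as delimited text
#'
#' One row per inoculum: `set_id`, `seed` (the set seed), `final_size`,
#' `n_proliferative`, `n_rcd`, `boundary_flag`.
#'
#' @param result A `simulation_result` from [run_batch()].
#' @param path Output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_simulation_result <- function(result, path) {
  stopifnot(inherits(result, "simulation_result"))
  d <- data.frame(set_id = result$set_id,
                  seed = result$set_seeds[result$set_id],
                  final_size = result$final_sizes,
                  n_proliferative = result$n_proliferative,
                  n_rcd = result$n_rcd,
                  boundary_flag = as.integer(result$boundary))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulated growth curve under contact inhibition
#'
#' Plates cells uniformly at random at a given site-occupancy density and
#' tracks the total cell count over time. Early growth doubles once per
#' step; as free sites are exhausted contact inhibition saturates the
#' culture, which is the behaviour this check is designed to expose.
#'
#' @param config A [lattice_config()].
#' @param initial_density Initial fraction of occupied sites, in `(0, 1]`.
#' @param days Duration in days; must not exceed `g_max` doublings.
#' @param schedule A [p1_schedule]; default no RCD (pure growth).
#' @param seed Optional seed.
#' @return A data frame with columns `step`, `day` and `cells`.
#' @export
simulate_growth_curve <- function(config = lattice_config(), initial_density,
                                  days = 11,
                                  schedule = p1_schedule(0, g_max = config$g_max),
                                  seed = config$seed) {
  stopifnot(inherits(config, "lattice_config"))
  if (initial_density <= 0 || initial_density > 1)
    stop("`initial_density` must lie in (0, 1]")
  n_steps <- as.integer(ceiling(days * 24 / config$dt_hours))
  if (n_steps > config$g_max)
    stop("`days` exceeds the schedule horizon (", config$g_max, " doublings)")
  check_schedule_covers(schedule, config)
  if (!is.null(seed)) set.seed(seed)
  counts <- cpp_growth_curve(schedule$probs, config$grid_side, n_steps,
                             config$p_move, config$rcd_when_blocked,
                             initial_density)
  steps <- 0:n_steps
  data.frame(step = steps, day = steps * config$dt_hours / 24,
             cells = as.integer(counts))
}
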