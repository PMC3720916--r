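small_config <- function(...) lattice_config(grid_side = 41L, ...)

test_that("a lone cell divides or dies according to P1(0)", {
  cfg <- small_config(p_move = 0)
  st <- lattice_state(cfg)
  set.seed(601)
  nxt <- lattice_step(st, p1_schedule(0), cfg)
  expect_equal(sum(nxt$status == 1L), 2L)           # forced division
  expect_equal(unique(nxt$generation[nxt$status == 1L]), 1L)
  expect_equal(nxt$step, 1L)
  nxt2 <- lattice_step(st, p1_schedule(1), cfg)
  expect_equal(sum(nxt2$status == 2L), 1L)          # forced RCD
  expect_equal(sum(nxt2$status != 0L), 1L)
})

test_that("a fully enclosed cell is contact-inhibited and unchanged", {
  cfg <- small_config(p_move = 0)
  st <- lattice_state(cfg)
  ctr <- (cfg$grid_side + 1L) %/% 2L
  st$status[(ctr - 1L):(ctr + 1L), (ctr - 1L):(ctr + 1L)] <- 2L
  st$status[ctr, ctr] <- 1L   # proliferative, ringed by RCD cells
  set.seed(602)
  nxt <- lattice_step(st, p1_schedule(0.9), cfg)
  expect_equal(nxt$status[ctr, ctr], 1L)            # fate deferred
  expect_equal(sum(nxt$status != 0L), 9L)
})

test_that("occupancy invariants hold along a trajectory", {
  cfg <- small_config(p_move = 0)
  sch <- p1_schedule(0.3)
  set.seed(603)
  st <- lattice_state(cfg)
  n_prev <- 1L
  rcd_sites <- NULL
  for (i in 1:10) {
    st <- lattice_step(st, sch, cfg)
    n_now <- sum(st$status != 0L)
    expect_gte(n_now, n_prev)                       # cells never disappear
    n_prev <- n_now
    if (!is.null(rcd_sites)) expect_true(all(st$status[rcd_sites] == 2L))
    rcd_sites <- which(st$status == 2L)             # RCD is absorbing
    expect_true(is_8_connected(st$status))          # no movement: one blob
    expect_true(all(st$generation[st$status != 0L] <= i))
  }
})

test_that("single-colony simulation respects trivial schedules", {
  cfg <- small_config(p_move = 0)
  set.seed(604)
  res <- simulate_colony(p1_schedule(1), cfg)
  expect_equal(res$size, 1L)
  expect_equal(res$n_rcd, 1L)
  # unconstrained doubling for two steps: 4 cells
  cfg2 <- lattice_config(grid_side = 41L, g_max = 2L, horizon_days = 2 * 20 / 24,
                         p_move = 0)
  res2 <- simulate_colony(p1_schedule(0, g_max = 2), cfg2)
  expect_equal(res2$size, 4L)
})

test_that("batches are reproducible bit-exact under a master seed", {
  cfg <- small_config()
  sch <- p1_schedule(0.5)
  r1 <- run_batch(sch, cfg, n_inocula = 100, n_sets = 2, seed = 99)
  r2 <- run_batch(sch, cfg, n_inocula = 100, n_sets = 2, seed = 99)
  expect_identical(r1$final_sizes, r2$final_sizes)
  expect_identical(r1$set_seeds, r2$set_seeds)
  expect_equal(length(r1$final_sizes), 200L)
  expect_true(all(r1$final_sizes >= 1L))
  r3 <- run_batch(p1_schedule(1), cfg, n_inocula = 50, n_sets = 1, seed = 1)
  expect_true(all(r3$final_sizes == 1L))
  expect_equal(sum(r3$final_sizes >= 50), 0L)
})

test_that("small-colony sizes match the analytic pmf (oracle equivalence)", {
  cfg <- small_config()
  n_inocula <- 4000
  res <- run_batch(p1_schedule(0.5), cfg, n_inocula = n_inocula, n_sets = 1,
                   seed = 605)
  emp <- tabulate(res$final_sizes, nbins = 6) / n_inocula
  ana <- pmf_constant(0.5, 6)
  se <- sqrt(ana * (1 - ana) / n_inocula)
  expect_true(all(abs(emp - ana) <= 3 * se))
})

test_that("uniformly deadlier schedules do not grow larger colonies", {
  cfg <- small_config()
  base <- c(0.2, 0.25, 0.3, 0.35, 0.4, 0.45)
  sch_lo <- p1_schedule(c(base, rep(0.45, 11)))
  sch_hi <- p1_schedule(pmin(1, sch_lo$probs + 0.1))
  m_lo <- mean(run_batch(sch_lo, cfg, n_inocula = 1000, n_sets = 1,
                         seed = 606)$final_sizes)
  m_hi <- mean(run_batch(sch_hi, cfg, n_inocula = 1000, n_sets = 1,
                         seed = 606)$final_sizes)
  expect_lte(m_hi, m_lo)
})

test_that("growth saturates by contact inhibition", {
  cfg <- lattice_config(grid_side = 21L, p_move = 0)
  # full confluence: nothing can move or divide
  gc_full <- simulate_growth_curve(cfg, initial_density = 1, days = 3, seed = 607)
  expect_true(all(gc_full$cells == 21L^2))
  # a single-cell-equivalent low density colony doubles, then slows
  gc <- simulate_growth_curve(cfg, initial_density = 1 / 21^2, days = 11,
                              seed = 608)
  ratios <- gc$cells[-1] / gc$cells[-nrow(gc)]
  expect_true(all(ratios <= 2 + 1e-12))
  expect_lt(ratios[length(ratios)], 2)              # interior cells blocked
  # low density: early doublings near 2, later ratio drops (plateau onset)
  gc2 <- simulate_growth_curve(cfg, initial_density = 0.02, days = 11,
                               seed = 609)
  early <- gc2$cells[2] / gc2$cells[1]
  late <- gc2$cells[nrow(gc2)] / gc2$cells[nrow(gc2) - 1]
  expect_gt(early, 1.7)
  expect_lt(late, 1.1)
  expect_error(simulate_growth_curve(cfg, initial_density = 1.5, days = 2),
               "density")
})

test_that("schedules shorter than the horizon are rejected", {
  cfg <- small_config()
  expect_error(run_batch(p1_schedule(0.3, g_max = 4), cfg, n_inocula = 2,
                         n_sets = 1, seed = 1), "cover")
})

test_that("per-inoculum results serialize as delimited text", {
  cfg <- small_config()
  res <- run_batch(p1_schedule(0.6), cfg, n_inocula = 20, n_sets = 2, seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_simulation_result(res, path)
  d <- read.delim(path)
  expect_equal(nrow(d), 40L)
  expect_named(d, c("set_id", "seed", "final_size", "n_proliferative",
                    "n_rcd", "boundary_flag"))
  expect_equal(d$final_size, unname(res$final_sizes))
})
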