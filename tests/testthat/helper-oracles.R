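# Independent oracle: brute-force enumeration of binary lineage trees.
# An abortive colony of n cells is a full binary tree with n leaves (dead
# cells) and n - 1 internal nodes (divisions). The probability of one tree
# rooted at generation g is the product of P1(gen) over leaves and
# (1 - P1(gen)) over internal nodes; q_g(n) sums over all tree shapes.
# Exponential in n, usable for n <= ~8; deliberately shares no code with
# the package's convolution recursion.
oracle_tree_prob <- function(n, g, p1) {
  # p1 is a plain function of generation (0-based), defined for all g needed
  if (n == 1L) return(p1(g))
  total <- 0
  for (k in 1:(n - 1L)) {
    total <- total + oracle_tree_prob(k, g + 1L, p1) *
      oracle_tree_prob(n - k, g + 1L, p1)
  }
  (1 - p1(g)) * total
}

oracle_pmf <- function(n_max, p1_fun) {
  vapply(seq_len(n_max), oracle_tree_prob, numeric(1), g = 0L, p1 = p1_fun)
}

# schedule whose tail continues at the last value, as a generation function
schedule_fun <- function(probs) {
  function(g) if (g + 1L > length(probs)) probs[length(probs)] else probs[g + 1L]
}

# power-law / exponential colony-size fixtures on the percent scale
power_law_dist <- function(a = -1.28, b = 1.02, n = 1:15, dose = "0",
                           f1_estimated = TRUE) {
  colony_size_distribution(dose, n, 10^(b + a * log10(n)),
                           f1_estimated = f1_estimated)
}

exponential_dist <- function(a = -0.089, b = 0.70, n = 1:15, dose = "0",
                             f1_estimated = TRUE) {
  colony_size_distribution(dose, n, 10^(b + a * n), f1_estimated = f1_estimated)
}

# 8-connectivity check on a status matrix (for lattice invariants)
is_8_connected <- function(status) {
  occ <- which(status != 0L, arr.ind = TRUE)
  if (nrow(occ) <= 1L) return(TRUE)
  key <- function(m) paste(m[, 1], m[, 2])
  seen <- rep(FALSE, nrow(occ))
  names(seen) <- key(occ)
  queue <- key(occ)[1L]
  seen[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    xy <- as.integer(strsplit(cur, " ")[[1L]])
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      k <- paste(xy[1] + dx, xy[2] + dy)
      if (!is.na(seen[k]) && !seen[k]) {
        seen[k] <- TRUE
        queue <- c(queue, k)
      }
    }
  }
  all(seen)
}
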