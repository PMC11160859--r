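# Simulator law checks, history densities, and structural invariants.

test_that("zero rates give a jump-free history; seeds give reproducibility", {
  lb <- builtin_model("lbd", list(lambda = 0, mu = 0, psi = 0, x0 = 4))
  h <- simulate_history(lb, 5, seed = 1)
  expect_length(h$times, 0L)
  m <- seirs_small()
  h1 <- simulate_history(m, 2, seed = 7)
  h2 <- simulate_history(m, 2, seed = 7)
  expect_identical(h1$times, h2$times)
  expect_identical(h1$marks, h2$marks)
  h3 <- simulate_history(m, 2, seed = 8)
  expect_false(identical(h1$times, h3$times))
})

test_that("moran jump counts are Poisson and the lbd mean grows as x0 e^{(lambda-mu)t}", {
  mo <- builtin_model("moran", list(n = 5, mu = 1))
  h <- simulate_history(mo, 1000, seed = 3)
  expect_lt(abs(length(h$times) / 1000 - 1), 3 * sqrt(1000) / 1000)

  lb <- builtin_model("lbd", list(lambda = 1, mu = 0.5, psi = 0, x0 = 5, xmax = 500))
  n_rep <- 1500
  xT <- vapply(seq_len(n_rep), function(s) {
    h <- simulate_history(lb, 1, seed = 1000 + s)
    h$states[nrow(h$states), "X"]
  }, numeric(1))
  expect_lt(abs(mean(xT) - 5 * exp(0.5)), 3 * stats::sd(xT) / sqrt(n_rep))
})

test_that("per-deme tip counts track deme occupancy along the path", {
  ## snapshot the same realization at increasing horizons (the Gillespie
  ## draws replay identically under a fixed seed) and compare the tip
  ## counts of G_t with the occupancy n(X_t)
  m <- seirs_small()
  for (t in c(0.75, 1.5, 2.25, 3)) {
    sim <- simulate_genealogy(m, t, seed = 11)
    g <- sim$genealogy
    xT <- stats::setNames(sim$history$states[nrow(sim$history$states), ],
                          m$compartments)
    occ <- m$occupancy(xT)
    tips_per_deme <- vapply(1:2, function(d)
      sum(g$nodes$kind == "tip" & g$nodes$deme == d), integer(1))
    expect_identical(unname(tips_per_deme), unname(as.integer(occ)))
  }
  ## and the full history is a prefix-consistent refinement
  h_long <- simulate_history(m, 3, seed = 11)
  h_short <- simulate_history(m, 1.5, seed = 11)
  k <- length(h_short$times)
  expect_identical(h_short$times, h_long$times[seq_len(k)])
})

test_that("history log densities match hand calculations", {
  ## no-jump history with constant total rate Lambda: -Lambda*T
  mo <- builtin_model("moran", list(n = 3, mu = 2))
  h0 <- simulate_history(mo, 0.05, seed = 6)
  if (length(h0$times) == 0)
    expect_equal(history_log_density(mo, h0), -2 * 0.05)
  ## k jumps on [0,T]: k log(mu) - mu T
  h <- simulate_history(mo, 3, seed = 2)
  k <- length(h$times)
  expect_equal(history_log_density(mo, h), k * log(2) - 2 * 3)
  ## a jump of a zero-rate mark has zero density
  mo0 <- builtin_model("moran", list(n = 3, mu = 0, psi = 0))
  h_bad <- h
  expect_equal(history_log_density(mo0, h_bad), -Inf)
})

test_that("history density integrates to one on an enumerable toy model", {
  ## two-state toy: a single decay jump at rate r; over horizon T the path
  ## has 0 or 1 jumps. Sum over discretized histories of exp(log density)
  ## equals 1 up to discretization error.
  r <- 1.3; T <- 0.4
  toy <- population_model(
    "toy", "pop", "A",
    list(jump_mark("Decay", function(t, x) r * x[["A"]],
                   function(x) c(A = 0L), 1L, deaths = 1L)),
    occupancy = function(x) x[["A"]],
    state0 = c(A = 1),
    enumerate = function() matrix(0:1, ncol = 1, dimnames = list(NULL, "A")))
  ## P(no jump)
  h0 <- genfilter:::new_history(T, numeric(0), character(0),
                                matrix(1, 1, 1, dimnames = list(NULL, "A")))
  total <- exp(history_log_density(toy, h0))
  ## integrate the one-jump density over the jump time
  grid <- seq(0, T, length.out = 2001)[-1] - T / 4000
  for (tj in grid) {
    h1 <- genfilter:::new_history(T, tj, "Decay",
                                  matrix(c(1, 0), 2, 1, byrow = TRUE,
                                         dimnames = list(NULL, "A")))
    total <- total + exp(history_log_density(toy, h1)) * (T / 2000)
  }
  expect_equal(total, 1, tolerance = 1e-5)
})

test_that("moran pairwise coalescence times have mean C(n,2)/mu", {
  ## with two sampled lineages followed back, the waiting time to their
  ## common ancestor is exponential with rate mu/C(n,2)
  n <- 5; mu <- 1
  mo <- builtin_model("moran", list(n = n, mu = mu, n_end = 2))
  horizon <- 60  # long enough that the pair almost surely coalesces
  n_rep <- 2000
  waits <- rep(NA_real_, n_rep)
  for (s in seq_len(n_rep)) {
    z <- obscure(prune(simulate_genealogy(mo, horizon, seed = 30000 + s)$genealogy))
    nch <- genfilter:::n_children(z)
    bt <- z$nodes$time[nch >= 2L]
    if (length(bt) == 1L) waits[s] <- horizon - bt
  }
  waits <- waits[!is.na(waits)]
  expect_gt(length(waits), 1800)
  expect_lt(abs(mean(waits) - choose(n, 2) / mu),
            3 * stats::sd(waits) / sqrt(length(waits)))
})

test_that("simulated genealogies never lose sample nodes in pruning", {
  for (s in 1:5) {
    sim <- simulate_genealogy(seirs_small(), 3, seed = 40 + s)
    g <- sim$genealogy
    p <- prune(g)
    expect_identical(sum(p$nodes$kind == "sample"), sum(g$nodes$kind == "sample"))
  }
})
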