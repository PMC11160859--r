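# Deterministic filter solvers: forward/adjoint duality, reduction to the
# known Moran coefficients, agreement with an independently assembled
# generator, and Monte-Carlo consistency of the colored filter.

test_that("forward and adjoint solutions agree on colored and obscured trees", {
  m <- seirs_small()
  for (s in c(5, 14)) {
    p <- prune(simulate_genealogy(m, 2.5, seed = s)$genealogy)
    lf <- filter_forward(m, p)
    la <- filter_adjoint(m, p)
    expect_lt(abs(lf - la), 1e-6)
    z <- obscure(p)
    expect_lt(abs(filter_forward(m, z) - filter_adjoint(m, z)), 1e-6)
  }
  lb <- lbd_small()
  zl <- obscure(prune(simulate_genealogy(lb, 3, seed = 5)$genealogy))
  expect_lt(abs(filter_forward(lb, zl) - filter_adjoint(lb, zl)), 1e-6)
})

test_that("trivial inputs: empty tree, zero rates, impossible structure", {
  ## zero-rate model, empty pruned genealogy: likelihood 1
  lb0 <- builtin_model("lbd", list(lambda = 0, mu = 0, psi = 0, x0 = 3, xmax = 10))
  empty <- genfilter:::new_genealogy(genfilter:::empty_nodes(), 2, character(0),
                                     "obscured_genealogy")
  expect_equal(filter_forward(lb0, empty), 0)
  expect_equal(filter_adjoint(lb0, empty), 0)
  ## a branch on a tree under a model with no birth mark is impossible
  mo_nobirth <- population_model(
    "deathonly", "pop", "X",
    list(jump_mark("Death", function(t, x) 0.5 * x[["X"]],
                   function(x) x - c(X = 1L), 1L, deaths = 1L),
         jump_mark("Sample", function(t, x) 0.4 * x[["X"]], identity, 1L,
                   sample_deme = 1L, n_samples = 1L)),
    occupancy = function(x) x[["X"]],
    state0 = c(X = 5),
    enumerate = function() matrix(0:5, ncol = 1, dimnames = list(NULL, "X")))
  z <- two_sample_tree(0.5, 1)
  expect_identical(filter_forward(mo_nobirth, z), -Inf)
  ## more samples than the population can hold
  mo2 <- builtin_model("moran", list(n = 2, mu = 1, psi = 0.5))
  z3 <- read_newick("((s1:0.6,(s2:0.3,s3:0.3):0.3):0.4);", horizon = 1)
  expect_identical(filter_obscured(mo2, z3), -Inf)
})

test_that("the obscured generator reduces to the Moran coefficients exactly", {
  ## summing out the hidden coordinate of the assembled generator must give
  ## gain mu(1 - C(l,2)/C(n,2)) off events and mu/C(n,2) at branch events,
  ## exactly in integer arithmetic after scaling by C(n,2)
  for (n in 2:6) {
    mo <- builtin_model("moran", list(n = n, mu = 1))
    tb <- genfilter:::model_tables(mo)
    for (l in 0:n) {
      G <- genfilter:::obscured_generator(mo, tb, genfilter:::assign_enum(1L, l))
      gain <- as.numeric(G[1, 1]) + tb$total_rate[1]
      expect_identical(round(gain * choose(n, 2)),
                       choose(n, 2) - choose(l, 2))
    }
    ## branch update coefficient: one lineage splitting into two
    ev <- list(time = 1, type = "branch", node_ids = 2L, children = c(3L, 4L),
               branch_pre = 1L, pre = 2L, post = c(3L, 4L),
               map = c(NA_integer_, NA_integer_))
    S <- genfilter:::obscured_singular(mo, tb, ev, 1L)
    expect_identical(round(as.numeric(S[1, 1]) * choose(n, 2)), 1)
  }
})

test_that("the obscured generator matches a brute-force assembly", {
  m <- seirs_small(N = 6)
  tb <- genfilter:::model_tables(m)
  for (l in 0:2) {
    Gpkg <- as.matrix(genfilter:::obscured_generator(
      m, tb, genfilter:::assign_enum(2L, l)))
    Gbrute <- brute_obscured_generator(m, l)
    expect_equal(Gpkg, Gbrute, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("uniformization agrees with the dense matrix exponential", {
  m <- seirs_small(N = 6)
  tb <- genfilter:::model_tables(m)
  A <- genfilter:::obscured_generator(m, tb, genfilter:::assign_enum(2L, 2L))
  v <- rep(tb$p0, 4)
  w1 <- genfilter:::unif_expmv(A, v, 0.8)
  w2 <- as.numeric(Matrix::expm(A * 0.8) %*% v)
  expect_equal(w1, w2, tolerance = 1e-9)
})

test_that("the colored filter matches conditional-weight Monte Carlo averaging", {
  m <- seirs_small()
  res <- sim_tree_with_samples(m, 2.5, 2, 4, seed_start = 14)
  p <- res$p
  lf <- filter_forward(m, p)
  mc <- mc_loglik(m, p, n_rep = 8000, seed = 2)
  expect_lt(abs(exp(lf) - exp(mc$logmean)), 3 * mc$se_log * exp(mc$logmean))
})

test_that("loglik_given_history is -Inf off the history's event times", {
  m <- seirs_small()
  sim <- simulate_genealogy(m, 2.5, seed = 14)
  p <- prune(sim$genealogy)
  expect_gt(loglik_given_history(m, p, sim$history), -Inf)
  ## shift one genealogical node off every history jump time
  p_bad <- p
  i <- which(p_bad$nodes$kind == "internal")[1]
  p_bad$nodes$time[i] <- p_bad$nodes$time[i] + 1e-4
  expect_identical(loglik_given_history(m, p_bad, sim$history), -Inf)
})

test_that("the likelihood is invariant to truncation beyond reachable mass", {
  zl <- obscure(prune(simulate_genealogy(lbd_small(xmax = 150), 3, seed = 5)$genealogy))
  lls <- vapply(c(60, 90, 150), function(xm) {
    filter_adjoint(lbd_small(xmax = xm), zl)
  }, numeric(1))
  expect_lt(abs(lls[1] - lls[3]), 1e-8)
  expect_lt(abs(lls[2] - lls[3]), 1e-10)
})

test_that("likelihood is unchanged by relabeling simultaneous samples", {
  mo <- builtin_model("moran", list(n = 8, mu = 1.3, psi = 0, n_end = 5))
  sim <- simulate_genealogy(mo, 4, seed = 11)
  z <- obscure(prune(sim$genealogy))
  ll1 <- filter_obscured(mo, z)
  z2 <- z
  lab <- z2$nodes$kind == "sample"
  z2$nodes$label[lab] <- rev(z2$nodes$label[lab])
  expect_identical(filter_obscured(mo, z2), ll1)
})
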