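# Closed-form likelihoods: hand values, ODE residuals, and agreement with
# the generic filter solvers.

test_that("kingman likelihood matches the hand-evaluated two-sample case", {
  ## n = 2, mu = 1: rate mu/C(2,2)... C(2,2) is C(n,2)=1, one branch, the
  ## pair spends 0.5 at l=2: log(1) - 1*0.5
  z <- two_sample_tree(tb = 0.5, ts = 1)
  expect_equal(kingman_loglik(z, n = 2, mu = 1), -0.5)
  ## single sample: no branch, no pair time
  z1 <- read_newick("(s1:1);", horizon = 1)
  expect_equal(kingman_loglik(z1, n = 5, mu = 3), 0)
  ## serial samples are rejected
  zs <- read_newick("((s1:0.4,s2:0.7):0.3);", horizon = 1)
  expect_error(kingman_loglik(zs, 4, 1), "moran_serial")
})

test_that("kingman and serial moran closed forms equal the obscured filter", {
  set.seed(1)
  n_match <- 0L
  for (s in 1:10) {
    n <- sample(4:10, 1)
    mu <- stats::runif(1, 0.5, 2)
    m_end <- sample(2:min(6, n), 1)
    mo <- builtin_model("moran", list(n = n, mu = mu, n_end = m_end))
    z <- obscure(prune(simulate_genealogy(mo, 3, seed = 100 + s)$genealogy))
    expect_lt(abs(kingman_loglik(z, n, mu) - filter_obscured(mo, z)), 1e-8)

    psi <- stats::runif(1, 0.3, 1)
    mo2 <- builtin_model("moran", list(n = n, mu = mu, psi = psi))
    z2 <- obscure(prune(simulate_genealogy(mo2, 3, seed = 200 + s)$genealogy))
    ns <- sum(z2$nodes$kind == "sample")
    if (ns > 6) next
    expect_lt(abs(moran_serial_loglik(z2, n, mu, psi) - filter_obscured(mo2, z2)),
              1e-8)
    n_match <- n_match + 1L
  }
  expect_gte(n_match, 8L)
})

test_that("the G/H solution satisfies its ODEs and boundary conditions", {
  lam <- 1.4; mu <- 0.7; psi <- 0.5; rho <- 0.6; T <- 3
  times <- seq(0, T, length.out = 101)
  gh <- genfilter:::bd_GH(lam, mu, psi, rho, T, times)
  expect_equal(gh$G(T), 1 - rho, tolerance = 1e-10)
  expect_equal(gh$H(T), 1, tolerance = 1e-10)
  G <- gh$G(times); H <- gh$H(times)
  expect_true(all(G >= 0 & G <= 1))
  expect_true(all(H > 0))
  ## centered finite-difference residual of the backward ODEs
  h <- times[2] - times[1]
  mid <- 2:(length(times) - 1)
  dG <- (G[mid + 1] - G[mid - 1]) / (2 * h)
  dH <- (H[mid + 1] - H[mid - 1]) / (2 * h)
  rG <- dG - (-lam * G[mid]^2 + (lam + mu + psi) * G[mid] - mu)
  rH <- dH - H[mid] * ((lam + mu + psi) - 2 * lam * G[mid])
  expect_lt(max(abs(rG)), 1e-3 * max(abs(dG)))  # O(h^2) differencing error
  expect_lt(max(abs(rH)), 1e-3 * max(abs(dH)))
})

test_that("lbd closed form equals the adjoint filter on random fixtures", {
  set.seed(2)
  n_done <- 0L
  s <- 0L
  while (n_done < 10L && s < 60L) {
    s <- s + 1L
    lam <- stats::runif(1, 0.6, 1.6); mu <- stats::runif(1, 0.1, 0.8)
    psi <- stats::runif(1, 0.2, 0.7); rho <- sample(c(0, 0.5, 1), 1)
    x0 <- sample(1:3, 1)
    lb <- builtin_model("lbd", list(lambda = lam, mu = mu, psi = psi,
                                    rho = rho, x0 = x0, xmax = 170))
    z <- obscure(prune(simulate_genealogy(lb, 2.5, seed = 300 + s)$genealogy))
    ns <- sum(z$nodes$kind == "sample")
    if (ns < 1 || ns > 8) next
    ll_closed <- lbd_loglik(z, lam, mu, psi, rho, x0)
    ll_filter <- filter_adjoint(lb, z)
    expect_lt(abs(ll_closed - ll_filter), 1e-6)
    n_done <- n_done + 1L
  }
  expect_identical(n_done, 10L)
})

test_that("survival-only likelihood decreases in lambda * span", {
  ## rho = 1, psi = 0, mu = 0, one lineage certainly sampled at the
  ## horizon and no branches: every birth would be observed, so the
  ## likelihood reduces to the survival factor exp(-lambda T)
  z1 <- read_newick("(s1:2);", horizon = 2)
  lambdas <- c(0.2, 0.6, 1.2, 2)
  lls <- vapply(lambdas, function(l) lbd_loglik(z1, l, 0, 0, 1, 1), numeric(1))
  expect_true(all(diff(lls) < 0))
  expect_equal(lls, -lambdas * 2, tolerance = 1e-8)
})

test_that("degenerate frozen-lineage case has likelihood one", {
  ## lambda = mu = psi = 0, rho = 1, one lineage sampled at the horizon:
  ## G == 0, H == 1, and the ordered factor rho^1/1! = 1
  z <- read_newick("(s1:2);", horizon = 2)
  expect_equal(lbd_loglik(z, 0, 0, 0, 1, 1), 0)
})

test_that("closed form and filter share the ordered-samples convention", {
  ## on a tree with several simultaneous horizon samples the two routes can
  ## only agree if both carry the same 1/n_T! ordering factor
  lb <- builtin_model("lbd", list(lambda = 1, mu = 0.3, psi = 0.4, rho = 1,
                                  x0 = 2, xmax = 150))
  res <- NULL
  for (s in 1:40) {
    z <- obscure(prune(simulate_genealogy(lb, 2, seed = 500 + s)$genealogy))
    nT <- sum(z$nodes$kind == "sample" & z$nodes$time == 2)
    if (nT >= 3 && sum(z$nodes$kind == "sample") <= 8) { res <- z; break }
  }
  expect_false(is.null(res))
  nT <- sum(res$nodes$kind == "sample" & res$nodes$time == 2)
  expect_gte(nT, 3)
  ll <- lbd_loglik(res, 1, 0.3, 0.4, 1, 2)
  expect_lt(abs(ll - filter_adjoint(lb, res)), 1e-6)
  ## dropping the ordering factor must break the agreement by log nT!
  expect_gt(lgamma(nT + 1), 1)
})
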