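# Shared model and tree builders for the test suite. Everything is
# generated in code under fixed seeds; no files are read.

seirs_small <- function(N = 15, psi = 0.4) {
  builtin_model("seirs", list(N = N, beta = 2, sigma = 1, gamma = 0.8,
                              psi = psi, omega = 0.2, E0 = 1, I0 = 1))
}

moran_serial_model <- function(n = 6, mu = 0.8, psi = 0.5) {
  builtin_model("moran", list(n = n, mu = mu, psi = psi))
}

lbd_small <- function(lambda = 1.2, mu = 0.6, psi = 0.4, rho = 0.5,
                      x0 = 2, xmax = 120) {
  builtin_model("lbd", list(lambda = lambda, mu = mu, psi = psi, rho = rho,
                            x0 = x0, xmax = xmax))
}

## simulate until the pruned genealogy has a sample count in [lo, hi]
sim_tree_with_samples <- function(model, horizon, lo, hi, seed_start = 1,
                                  max_tries = 200) {
  for (s in seed_start + seq_len(max_tries) - 1L) {
    sim <- simulate_genealogy(model, horizon, seed = s)
    p <- prune(sim$genealogy)
    ns <- sum(p$nodes$kind == "sample")
    if (ns >= lo && ns <= hi) return(list(sim = sim, p = p, seed = s, n_samples = ns))
  }
  stop("no simulation with the requested sample count")
}

## two-sample obscured tree: root at 0, branch at tb, both samples at ts
two_sample_tree <- function(tb, ts, horizon = ts) {
  read_newick(sprintf("((s1:%g,s2:%g):%g);", ts - tb, ts - tb, tb),
              horizon = horizon)
}

## deterministic fixture set shared by the acceptance blocks (memoized)
.fixture_env <- new.env(parent = emptyenv())
acceptance_fixture_set <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  set.seed(10)
  fixtures <- list()
  for (s in 1:10) {
    n <- sample(4:10, 1); mu <- stats::runif(1, 0.5, 2)
    m_end <- sample(2:min(6, n), 1)
    mo <- builtin_model("moran", list(n = n, mu = mu, n_end = m_end))
    z <- obscure(prune(simulate_genealogy(mo, 3, seed = 1000 + s)$genealogy))
    fixtures[[length(fixtures) + 1L]] <-
      list(kind = "kingman", model = mo, tree = z, n = n, mu = mu)

    psi <- stats::runif(1, 0.3, 0.8)
    mo2 <- builtin_model("moran", list(n = n, mu = mu, psi = psi))
    z2 <- obscure(prune(simulate_genealogy(mo2, 3, seed = 2000 + s)$genealogy))
    if (sum(z2$nodes$kind == "sample") <= 6)
      fixtures[[length(fixtures) + 1L]] <-
        list(kind = "serial", model = mo2, tree = z2, n = n, mu = mu, psi = psi)
  }
  n_lbd <- 0L; s <- 0L
  while (n_lbd < 10L && s < 60L) {
    s <- s + 1L
    lam <- stats::runif(1, 0.6, 1.6); mu <- stats::runif(1, 0.1, 0.8)
    psi <- stats::runif(1, 0.2, 0.7); rho <- sample(c(0, 0.5, 1), 1)
    lb <- builtin_model("lbd", list(lambda = lam, mu = mu, psi = psi,
                                    rho = rho, x0 = sample(1:3, 1), xmax = 170))
    z <- obscure(prune(simulate_genealogy(lb, 2.5, seed = 3000 + s)$genealogy))
    ns <- sum(z$nodes$kind == "sample")
    if (ns < 1 || ns > 8) next
    fixtures[[length(fixtures) + 1L]] <-
      list(kind = "lbd", model = lb, tree = z, lam = lam, mu = mu,
           psi = psi, rho = rho, x0 = lb$state0[["X"]])
    n_lbd <- n_lbd + 1L
  }
  .fixture_env$fx <- fixtures
  fixtures
}

## brute-force reimplementation of the obscured-mode regular generator:
## straight nested loops over combined (state, assignment) pairs, scalar
## binomial ratios, no shared code with the package's sparse assembly
brute_obscured_generator <- function(model, n_slots) {
  tb <- genfilter:::model_tables(model)
  K <- model$n_demes
  Y <- genfilter:::assign_enum(K, n_slots)
  M <- tb$M; A <- nrow(Y)
  G <- matrix(0, M * A, M * A)
  for (a in seq_len(A)) for (i in seq_len(M)) {
    col <- (a - 1L) * M + i
    y <- Y[a, ]
    for (u in seq_along(model$marks)) {
      m <- model$marks[[u]]
      rate <- tb$rate[i, u]
      if (rate <= 0) next
      G[col, col] <- G[col, col] - rate
      i2 <- tb$to[i, u]
      if (is.na(i2) || m$n_samples > 0L) next
      occ2 <- tb$occ[i2, ]
      ## event misses the genealogy entirely
      row <- (a - 1L) * M + i2
      G[row, col] <- G[row, col] +
        rate * binomial_ratio(occ2, tabulate(y, K), m$production, integer(K))
      ## one genealogy lineage hidden-involved
      for (k in seq_len(n_slots)) {
        cands <- list()
        if (sum(m$offspring) > 0L && y[k] == m$parent_deme)
          cands <- c(cands, lapply(which(m$production >= 1L), identity))
        if (!is.na(m$migr_from) && y[k] == m$migr_from && sum(m$migr_to) == 1L)
          cands <- c(cands, list(which(m$migr_to == 1L)))
        for (d in cands) {
          y2 <- y; y2[k] <- d
          s <- integer(K); s[d] <- 1L
          a2 <- genfilter:::assign_index(y2, K)
          row <- (a2 - 1L) * M + i2
          G[row, col] <- G[row, col] +
            rate * binomial_ratio(occ2, tabulate(y2, K), m$production, s)
        }
      }
    }
  }
  G
}
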