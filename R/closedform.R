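## Closed-form genealogy likelihoods for the two classical special cases:
## the Moran model (Kingman coalescent, with or without serial sampling)
## and the linear birth-death process with Poisson sampling through time
## plus binomial sampling at the horizon. These serve as independent
## oracles for the generic filter solvers.

## ---- adaptive Dormand-Prince RK45 ----------------------------------------

## integrates dy/dt = f(t, y) from t0 through the sorted times `t_out`,
## returning the solution matrix at those times
rk45 <- function(f, y0, t0, t_out, rtol = 1e-10, atol = 1e-12) {
  a <- list(c(1/5),
            c(3/40, 9/40),
            c(44/45, -56/15, 32/9),
            c(19372/6561, -25360/2187, 64448/6561, -212/729),
            c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
            c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84))
  b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
  b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)
  cs <- c(0, 1/5, 3/10, 4/5, 8/9, 1, 1)
  y <- y0; t <- t0
  out <- matrix(NA_real_, length(t_out), length(y0))
  h <- if (length(t_out)) max((t_out[length(t_out)] - t0) / 100, 1e-8) else 0
  oi <- 1L
  while (oi <= length(t_out)) {
    target <- t_out[oi]
    if (target <= t + 1e-14) { out[oi, ] <- y; oi <- oi + 1L; next }
    hh <- min(h, target - t)
    k <- matrix(0, 7, length(y))
    k[1, ] <- f(t, y)
    for (i in 1:5) k[i + 1, ] <- f(t + cs[i + 1] * hh,
                                   y + hh * drop(a[[i]] %*% k[1:i, , drop = FALSE]))
    y5 <- y + hh * drop(b5[1:6] %*% k[1:6, , drop = FALSE])
    k[7, ] <- f(t + hh, y5)
    y4 <- y + hh * drop(b4 %*% k)
    err <- max(abs(y5 - y4) / (atol + rtol * pmax(abs(y), abs(y5))))
    if (is.finite(err) && err <= 1) {
      t <- t + hh; y <- y5
      h <- hh * min(5, max(0.2, 0.9 * (1 / max(err, 1e-10))^0.2))
    } else {
      h <- hh * max(0.1, 0.9 * (1 / max(err, 1e-10))^0.25)
      if (h < 1e-14) stop("rk45 step size underflow")
    }
  }
  out
}

## tree feature extraction shared by the closed forms
tree_features <- function(z) {
  nd <- z$nodes
  nch <- n_children(z)
  T <- z$horizon
  is_sample <- nd$kind == "sample"
  branch <- (nd$kind %in% c("internal", "root")) & nch >= 2L
  list(
    T = T,
    branch_times = nd$time[branch],
    branch_sizes = nch[branch],
    S0 = nd$time[is_sample & nch == 0L & nd$time < T],
    S1 = nd$time[is_sample & nch >= 1L],
    n_T = sum(is_sample & nd$time == T),
    l0 = sum(is.na(nd$parent)),
    inline_nonsample = any(nd$kind == "internal" & nch == 1L)
  )
}

#' Kingman coalescent log-likelihood under the Moran model
#'
#' Classical case: all samples taken simultaneously at the horizon of a
#' Moran population of constant size `n` with event rate `mu`. The
#' log-likelihood is `|B| log(mu/C(n,2)) - mu/C(n,2) * sum_i C(i,2) s_i`
#' with `s_i` the coalescent-interval durations.
#'
#' @param z an obscured genealogy whose samples all sit at one time.
#' @param n Moran population size.
#' @param mu Moran event rate.
#' @return log-likelihood.
#' @export
kingman_loglik <- function(z, n, mu) {
  ft <- tree_features(z)
  st <- z$nodes$time[z$nodes$kind == "sample"]
  if (length(st) > 0 && length(unique(st)) > 1L)
    stop("samples are not simultaneous; use moran_serial_loglik")
  if (any(ft$branch_sizes > 2L)) return(-Inf)
  ci <- coalescent_intervals(z)
  lmax <- if (length(ci)) max(as.integer(names(ci))) else 0L
  if (lmax > n) return(-Inf)
  nb <- length(ft$branch_times)
  rate <- mu / choose(n, 2)
  i <- as.integer(names(ci))
  nb * log(rate) - rate * sum(choose(i, 2) * ci)
}

#' Serially sampled Moran log-likelihood
#'
#' Moran model of size `n`, event rate `mu`, with samples collected by a
#' rate-`psi` Poisson process. Terminal samples (leaves) contribute
#' `log(psi (1 - l(t)/n))` with `l(t)` the post-event lineage count;
#' inline samples contribute `log(psi/n)`; branch points contribute
#' `log(mu/C(n,2))`; the regular part contributes the coalescent-interval
#' decay plus the survival factor `-psi T` for observing no further
#' samples. Samples at the horizon itself (scheduled sampling) are
#' conditioned on and contribute no factor.
#'
#' @param z an obscured genealogy.
#' @param n Moran population size.
#' @param mu Moran event rate.
#' @param psi total sampling rate.
#' @return log-likelihood (possibly `-Inf`).
#' @export
moran_serial_loglik <- function(z, n, mu, psi) {
  ft <- tree_features(z)
  if (any(ft$branch_sizes > 2L)) return(-Inf)
  ci <- coalescent_intervals(z)
  i <- as.integer(names(ci))
  if (length(i) && max(i) > n) return(-Inf)
  rate <- mu / choose(n, 2)
  nS <- length(ft$S0) + length(ft$S1)
  ll <- length(ft$branch_times) * log(rate) - rate * sum(choose(i, 2) * ci) -
    psi * ft$T
  if (nS > 0) ll <- ll + nS * log(psi)
  for (t in ft$S0) {
    l_post <- lineage_count(z, t)
    if (l_post >= n) return(-Inf)
    ll <- ll + log(1 - l_post / n)
  }
  ll <- ll - length(ft$S1) * log(n)
  ll
}

## G/H final-value problem of the linear birth-death ansatz, solved
## backward from the horizon; returns interpolants at requested times
bd_GH <- function(lam, mu, psi, rho, T, times, rtol = 1e-10) {
  f <- function(tau, y) {
    G <- y[1]; H <- y[2]
    c(lam * G^2 - (lam + mu + psi) * G + mu,
      H * (2 * lam * G - (lam + mu + psi)))
  }
  taus <- sort(unique(c(0, T, pmax(T - times, 0))))
  sol <- rk45(f, c(1 - rho, 1), 0, taus, rtol = rtol)
  G <- stats::approxfun(T - taus, sol[, 1], rule = 2)
  H <- stats::approxfun(T - taus, sol[, 2], rule = 2)
  list(G = G, H = H)
}

#' Linear birth-death-sampling log-likelihood (closed form)
#'
#' Likelihood of an obscured genealogy under the linear birth-death
#' process with per-capita birth, death and sampling rates `lam`, `mu`,
#' `psi`, binomial sampling with probability `rho` at the horizon, and
#' initial population size `x0`. The two auxiliary functions G and H
#' solve a final-value problem (`G(T) = 1-rho`, `H(T) = 1`) integrated
#' numerically; the likelihood multiplies their initial values with
#' per-event factors: `2 lam H(e)` at branch times, `psi G(e)/H(e)` at
#' terminal sample times, `psi` at inline sample times, and the ordered
#' bulk-sampling factor `rho^n/n!` for the `n` horizon samples. Samples
#' are treated as ordered, so the value differs from an unordered
#' convention by `log n!`.
#'
#' @param z an obscured genealogy with horizon `T`.
#' @param lam,mu,psi per-capita birth, death, sampling rates.
#' @param rho horizon sampling probability in `[0, 1]`.
#' @param x0 initial population size (must be at least the number of
#'   roots of `z`).
#' @param rtol relative tolerance of the G/H integration.
#' @return log-likelihood (possibly `-Inf`).
#' @export
lbd_loglik <- function(z, lam, mu, psi, rho, x0, rtol = 1e-10) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0,1]")
  ft <- tree_features(z)
  if (any(ft$branch_sizes > 2L)) return(-Inf)
  l0 <- ft$l0
  if (x0 < l0) return(-Inf)
  if (ft$n_T > 0 && rho == 0) return(-Inf)
  ev <- c(ft$branch_times, ft$S0, 0)
  gh <- bd_GH(lam, mu, psi, rho, ft$T, ev, rtol = rtol)
  G0 <- gh$G(0); H0 <- gh$H(0)
  if (H0 <= 0 || G0 < 0) return(-Inf)
  ll <- lgamma(x0 + 1) - lgamma(x0 - l0 + 1) - lgamma(ft$n_T + 1) +
    l0 * log(H0)
  if (length(ft$S1) > 0) ll <- ll + length(ft$S1) * log(psi)
  if (ft$n_T > 0) ll <- ll + ft$n_T * log(rho)
  if (x0 > l0) {
    if (G0 <= 0) return(-Inf)
    ll <- ll + (x0 - l0) * log(G0)
  }
  for (e in ft$branch_times) ll <- ll + log(2 * lam * gh$H(e))
  for (e in ft$S0) ll <- ll + log(psi * gh$G(e) / gh$H(e))
  ll
}
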