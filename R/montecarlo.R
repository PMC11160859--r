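## Likelihood given a history (the per-event product of binomial-ratio
## weights) and a forced-history Monte Carlo estimator of the genealogy
## likelihood built on it. The Monte Carlo route is deliberately
## independent of the deterministic filter code path: it simulates
## population histories forward, forcing a jump at each genealogical event
## time with the appropriate density weight, and averages the resulting
## per-event conditional weights.

#' Log-likelihood of a pruned genealogy given a history
#'
#' Conditional on the full population history `h`, the probability of the
#' colored pruned genealogy `p` is a product over the jumps of `h` of
#' per-event weights (binomial ratio times compatibility), provided every
#' genealogical event time of `p` appears among the jump times of `h`;
#' otherwise the probability is zero. Scheduled horizon events contribute
#' their kernel factor.
#'
#' @param model a `population_model`.
#' @param p a colored `pruned_genealogy` with the same horizon as `h`.
#' @param h a `history` consistent with `model`.
#' @return log-probability (possibly `-Inf`).
#' @export
loglik_given_history <- function(model, p, h) {
  if (!isTRUE(all.equal(p$horizon, h$horizon)))
    stop("genealogy and history horizons differ")
  sched <- resolve_scheduled(model, h$horizon)
  evp <- event_times(p)
  if (length(sched) > 0) evp <- evp[evp < h$horizon]
  if (!all(evp %in% h$times)) return(-Inf)
  ll <- 0
  for (k in seq_along(h$times)) {
    t <- h$times[k]
    m <- model$marks[[h$marks[k]]]
    x <- stats::setNames(as.integer(h$states[k + 1L, ]), model$compartments)
    phi <- event_weight(model, m, x, p, t)
    if (phi <= 0) return(-Inf)
    ll <- ll + log(phi)
  }
  ## scheduled horizon events
  if (length(sched) > 0) {
    xT <- stats::setNames(as.integer(h$states[nrow(h$states), ]), model$compartments)
    occ <- model$occupancy(xT)
    ndT <- p$nodes[p$nodes$time == p$horizon & p$nodes$kind == "sample", , drop = FALSE]
    for (ev in sched) {
      m_nodes <- if (length(p$demes) > 0) sum(ndT$deme == ev$deme, na.rm = TRUE)
                 else nrow(ndT)
      if (!is.null(ev$prob)) {
        f <- choose(occ[ev$deme], m_nodes) * ev$prob^m_nodes *
          (1 - ev$prob)^max(occ[ev$deme] - m_nodes, 0)
        if (occ[ev$deme] < m_nodes) f <- 0
      } else {
        f <- as.numeric(occ[ev$deme] >= ev$count && m_nodes == ev$count)
      }
      if (f <= 0) return(-Inf)
      ll <- ll + log(f)
    }
  }
  ll
}

## per-interval phi matrix (state x mark) for jumps that leave the tree
## unchanged; sampling marks get zero
phi0_table <- function(model, tb, l) {
  U <- length(model$marks)
  out <- matrix(0, tb$M, U)
  for (u in seq_len(U)) {
    m <- model$marks[[u]]
    if (m$n_samples > 0L) next
    out[, u] <- ratio_vec(tb$occ, l, m$production, integer(model$n_demes))
  }
  out
}

#' Monte Carlo likelihood of a colored pruned genealogy
#'
#' Unbiased importance-sampling estimator of the genealogy likelihood that
#' never solves the filter equation: population histories are simulated
#' forward from the model; between genealogical events each realized jump
#' contributes its leave-the-tree-unchanged weight; at each genealogical
#' event a jump is forced, weighted by the summed event density
#' `sum_u alpha_u phi_u` and drawn proportionally. The mean of the
#' replicate weights estimates the likelihood.
#'
#' @param model a `population_model` (time-homogeneous, enumerable).
#' @param p a colored `pruned_genealogy`.
#' @param n_rep number of independent history replicates.
#' @param seed RNG seed.
#' @return list with `logmean` (log of the mean weight), `se_log`
#'   (delta-method standard error of `logmean`), `weights` (the replicate
#'   weights, rescaled by `exp(log_shift)`), and `log_shift`.
#' @export
mc_loglik <- function(model, p, n_rep = 1e4, seed = 1) {
  tb <- model_tables(model)
  T <- p$horizon
  sched <- resolve_scheduled(model, T)
  evs <- event_times(p)
  evs <- evs[evs > 0]
  if (length(sched) > 0) evs <- evs[evs < T]
  brk <- c(0, evs, T)
  n_int <- length(brk) - 1L
  phi0 <- vector("list", n_int)
  for (k in seq_len(n_int))
    phi0[[k]] <- phi0_table(model, tb, lineage_count(p, brk[k]))
  ## per-event singular weight matrices (state x mark): alpha_u(i) * phi_u(to)
  U <- length(model$marks)
  evw <- lapply(evs, function(e) {
    lpost <- lineage_count(p, e)
    s <- saturation(p, e)
    W <- matrix(0, tb$M, U)
    for (u in seq_len(U)) {
      m <- model$marks[[u]]
      if (compatibility(m, p, e) == 0L) next
      ok <- !is.na(tb$to[, u])
      phi <- numeric(tb$M)
      phi[ok] <- ratio_vec(tb$occ[tb$to[ok, u], , drop = FALSE], lpost,
                           m$production, s)
      W[, u] <- tb$rate[, u] * phi
    }
    W
  })
  fsched <- NULL
  if (length(sched) > 0) {
    pc <- prep_colored(model, tb, p)
    fsched <- pc$fsched
  }
  with_local_seed(seed, {
    logw <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      i <- tb$i0
      lw <- 0
      t <- 0
      dead <- FALSE
      for (k in seq_len(n_int)) {
        tend <- brk[k + 1L]
        ph <- phi0[[k]]
        repeat {
          R <- tb$total_rate[i]
          if (R <= 0) { t <- tend; break }
          dt <- stats::rexp(1L, R)
          if (t + dt >= tend) { t <- tend; break }
          t <- t + dt
          u <- sample.int(U, 1L, prob = tb$rate[i, ])
          i2 <- tb$to[i, u]
          if (is.na(i2)) { dead <- TRUE; break }
          f <- ph[i2, u]
          if (f <= 0) { dead <- TRUE; break }
          lw <- lw + log(f)
          i <- i2
        }
        if (dead) break
        if (k <= length(evw)) {
          g <- evw[[k]][i, ]
          ok <- !is.na(tb$to[i, ]) & g > 0
          g[!ok] <- 0
          W <- sum(g)
          if (W <= 0) { dead <- TRUE; break }
          lw <- lw + log(W)
          u <- sample.int(U, 1L, prob = g)
          i <- tb$to[i, u]
        }
      }
      if (!dead && !is.null(fsched)) {
        if (fsched[i] <= 0) dead <- TRUE else lw <- lw + log(fsched[i])
      }
      logw[r] <- if (dead) -Inf else lw
    }
    shift <- max(logw)
    if (!is.finite(shift)) return(list(logmean = -Inf, se_log = NA_real_,
                                       weights = rep(0, n_rep), log_shift = 0))
    w <- exp(logw - shift)
    mw <- mean(w)
    se_nat <- stats::sd(w) / sqrt(n_rep)
    list(logmean = shift + log(mw), se_log = se_nat / mw,
         weights = w, log_shift = shift)
  })
}
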