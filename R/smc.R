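## Sequential Monte Carlo estimation of the obscured-genealogy likelihood.
##
## Particles carry a population state and a hidden deme assignment of the
## current tree lineages. Between genealogical events, population jumps
## are proposed from the model dynamics; at each realized jump a hidden
## involvement option (none; a tree lineage as hidden birth parent/child;
## a tree lineage migrating) is drawn from the uniform kernel and weighted
## by its event factor times the option count. At each genealogical event
## the observed node is forced: the particle weight picks up the summed
## event density over compatible marks and hidden outcomes, and one
## outcome is drawn proportionally. Systematic resampling controls weight
## degeneracy. Particles are partitioned into independent groups so that a
## standard error can be reported from the group-level estimates.

## enumerate hidden involvement options for a jump of mark m given
## assignment y; returns list of (y2, s_deme) -- s_deme 0 means none
hidden_options <- function(m, y, K) {
  opts <- list(list(y2 = y, d = 0L))
  if (sum(m$offspring) > 0L) {
    for (k in which(y == m$parent_deme)) {
      for (d in which(m$production >= 1L)) {
        y2 <- y; y2[k] <- d
        opts[[length(opts) + 1L]] <- list(y2 = y2, d = d)
      }
    }
  }
  if (!is.na(m$migr_from)) {
    d <- which(m$migr_to == 1L)
    if (length(d) == 1L) {
      for (k in which(y == m$migr_from)) {
        y2 <- y; y2[k] <- d
        opts[[length(opts) + 1L]] <- list(y2 = y2, d = d)
      }
    }
  }
  opts
}

smc_core <- function(model, tb, tree, J, seed, ess_threshold) {
  K <- model$n_demes
  T <- tree$horizon
  sched <- resolve_scheduled(model, T)
  sk <- obscured_skeleton(tree)
  events <- sk$events
  final_slots <- sk$final_slots
  sched_nodes <- integer(0)
  if (length(sched) > 0) {
    at_T <- vapply(events, function(e) e$time == T && e$type == "sample", logical(1))
    if (any(at_T)) {
      sched_nodes <- events[[which(at_T)]]$node_ids
      final_slots <- events[[which(at_T)]]$pre
      events <- events[!at_T]
    }
  }
  slots0 <- if (length(events) > 0) events[[1]]$pre else final_slots
  brk <- c(0, vapply(events, `[[`, numeric(1), "time"), T)
  U <- length(model$marks)
  ## initial assignments: uniform over colorings supported by the state
  Y0 <- assign_enum(K, length(slots0))
  occ0 <- tb$occ[tb$i0, ]
  valid0 <- which(apply(Y0, 1L, function(y)
    all(tabulate(y, K) <= occ0)))
  if (length(valid0) == 0) return(list(loglik = -Inf, ess = numeric(0)))
  with_local_seed(seed, {
    xs <- rep(tb$i0, J)
    ys <- Y0[valid0[sample.int(length(valid0), J, replace = TRUE)], , drop = FALSE]
    lw <- rep(log(length(valid0)), J)
    logscale <- 0
    ess_trace <- numeric(0)
    for (kint in seq_along(brk)[-1]) {
      t0 <- brk[kint - 1L]; t1 <- brk[kint]
      for (j in seq_len(J)) {
        if (!is.finite(lw[j])) next
        i <- xs[j]; y <- ys[j, ]
        t <- t0
        repeat {
          R <- tb$total_rate[i]
          if (R <= 0) break
          dt <- stats::rexp(1L, R)
          if (t + dt >= t1) break
          t <- t + dt
          u <- sample.int(U, 1L, prob = tb$rate[i, ])
          m <- model$marks[[u]]
          i2 <- tb$to[i, u]
          if (is.na(i2) || m$n_samples > 0L) { lw[j] <- -Inf; break }
          opts <- hidden_options(m, y, K)
          pick <- opts[[sample.int(length(opts), 1L)]]
          s <- integer(K); if (pick$d > 0L) s[pick$d] <- 1L
          phi <- binomial_ratio(tb$occ[i2, ], tabulate(pick$y2, K),
                                m$production, s)
          if (phi <= 0) { lw[j] <- -Inf; break }
          lw[j] <- lw[j] + log(phi * length(opts))
          i <- i2; y <- pick$y2
        }
        xs[j] <- i; ys[j, ] <- y
      }
      ## singular update at t1 (if it is an event)
      if (kint - 1L <= length(events)) {
        ev <- events[[kint - 1L]]
        n_post <- length(ev$post)
        ys_new <- matrix(0L, J, n_post)
        mapped <- which(!is.na(ev$map))
        for (j in seq_len(J)) {
          if (!is.finite(lw[j])) next
          i <- xs[j]; y <- ys[j, ]
          cand_w <- numeric(0); cand_u <- integer(0); cand_y <- list()
          if (ev$type == "branch") {
            ch_pos <- which(is.na(ev$map))
            tuples <- assign_enum(K, length(ch_pos))
            for (u in seq_len(U)) {
              m <- model$marks[[u]]
              if (sum(m$offspring) == 0L) next
              i2 <- tb$to[i, u]
              if (is.na(i2) || tb$rate[i, u] <= 0) next
              if (length(y) > 0 && y[ev$branch_pre] != m$parent_deme) next
              for (tu in seq_len(nrow(tuples))) {
                dts <- tuples[tu, ]
                s <- tabulate(dts, K)
                if (any(s > m$production)) next
                y2 <- integer(n_post)
                y2[mapped] <- y[ev$map[mapped]]
                y2[ch_pos] <- dts
                phi <- binomial_ratio(tb$occ[i2, ], tabulate(y2, K),
                                      m$production, s)
                if (phi <= 0) next
                cand_w <- c(cand_w, tb$rate[i, u] * phi)
                cand_u <- c(cand_u, u); cand_y[[length(cand_y) + 1L]] <- y2
              }
            }
          } else {
            n_inline <- sum(!ev$terminal)
            for (u in seq_len(U)) {
              m <- model$marks[[u]]
              if (m$n_samples != length(ev$node_ids) || m$n_samples == 0L) next
              if (!m$sample_survives && n_inline > 0L) next
              i2 <- tb$to[i, u]
              if (is.na(i2) || tb$rate[i, u] <= 0) next
              if (any(y[ev$sampled_pre] != m$sample_deme)) next
              s <- integer(K); s[m$sample_deme] <- n_inline
              y2 <- integer(n_post)
              y2[mapped] <- y[ev$map[mapped]]
              phi <- binomial_ratio(tb$occ[i2, ],
                                    if (n_post > 0) tabulate(y2, K) else integer(K),
                                    m$production, s)
              if (phi <= 0) next
              cand_w <- c(cand_w, tb$rate[i, u] * phi)
              cand_u <- c(cand_u, u); cand_y[[length(cand_y) + 1L]] <- y2
            }
          }
          W <- sum(cand_w)
          if (W <= 0) { lw[j] <- -Inf; next }
          lw[j] <- lw[j] + log(W)
          pick <- sample.int(length(cand_w), 1L, prob = cand_w)
          xs[j] <- tb$to[i, cand_u[pick]]
          ys_new[j, ] <- cand_y[[pick]]
        }
        ys <- ys_new
        ## resample on effective sample size
        mx <- max(lw)
        if (!is.finite(mx)) return(list(loglik = -Inf, ess = ess_trace))
        w <- exp(lw - mx)
        ess <- sum(w)^2 / sum(w^2)
        ess_trace <- c(ess_trace, ess)
        if (ess < ess_threshold * J) {
          logscale <- logscale + mx + log(mean(w))
          idx <- systematic_resample(w / sum(w), J)
          xs <- xs[idx]; ys <- ys[idx, , drop = FALSE]
          lw <- rep(0, J)
        }
      }
    }
    ## scheduled horizon factor
    if (length(sched) > 0) {
      lfin <- length(final_slots)
      for (j in seq_len(J)) {
        if (!is.finite(lw[j])) next
        occ <- tb$occ[xs[j], ]
        for (ev in sched) {
          m_nodes <- length(sched_nodes)
          if (lfin != m_nodes || (lfin > 0 && any(ys[j, ] != ev$deme))) {
            lw[j] <- -Inf; break
          }
          f <- if (!is.null(ev$prob)) {
            if (occ[ev$deme] < m_nodes) 0
            else choose(occ[ev$deme], m_nodes) * ev$prob^m_nodes *
              (1 - ev$prob)^(occ[ev$deme] - m_nodes)
          } else {
            as.numeric(occ[ev$deme] >= ev$count && m_nodes == ev$count)
          }
          if (f <= 0) { lw[j] <- -Inf; break }
          lw[j] <- lw[j] + log(f)
        }
      }
    }
    mx <- max(lw)
    if (!is.finite(mx)) return(list(loglik = -Inf, ess = ess_trace))
    list(loglik = logscale + mx + log(mean(exp(lw - mx))), ess = ess_trace)
  })
}

systematic_resample <- function(p, J) {
  u <- (stats::runif(1L) + 0:(J - 1L)) / J
  findInterval(u, cumsum(p)) + 1L
}

#' Sequential Monte Carlo log-likelihood of an obscured genealogy
#'
#' Unbiased particle estimate of the likelihood computed by the
#' deterministic obscured filter, usable when the hidden state space is
#' too large to enumerate. Particles are split into `n_groups` independent
#' sub-filters; the reported estimate is the log of the mean of the group
#' estimates (each unbiased on the natural scale) and the standard error
#' is the delta-method error of that log-mean.
#'
#' @param model a `population_model`.
#' @param z an `obscured_genealogy`.
#' @param n_particles total particle count (at least 2).
#' @param seed RNG seed.
#' @param ess_threshold resampling trigger, as a fraction of the per-group
#'   particle count.
#' @param n_groups number of independent particle groups.
#' @return list with `loglik`, `se_log`, `group_logliks`, `ess`.
#' @export
smc_loglik <- function(model, z, n_particles = 1e4, seed = 1,
                       ess_threshold = 0.5, n_groups = 10L) {
  if (n_particles < 2) stop("n_particles must be at least 2")
  if (!inherits(z, "obscured_genealogy")) z <- obscure(z)
  tb <- model_tables(model)
  n_groups <- max(1L, min(n_groups, n_particles %/% 2L))
  Jg <- ceiling(n_particles / n_groups)
  gl <- numeric(n_groups)
  ess_all <- list()
  for (g in seq_len(n_groups)) {
    res <- smc_core(model, tb, z, Jg, seed = (seed * 131L + g) %% 2147483646L + 1L,
                    ess_threshold = ess_threshold)
    gl[g] <- res$loglik
    ess_all[[g]] <- res$ess
  }
  mx <- max(gl)
  if (!is.finite(mx))
    return(list(loglik = -Inf, se_log = NA_real_, group_logliks = gl,
                ess = ess_all, diagnostic = "all particles extinct"))
  w <- exp(gl - mx)
  mw <- mean(w)
  se <- if (n_groups > 1) stats::sd(w) / (sqrt(n_groups) * mw) else NA_real_
  list(loglik = mx + log(mw), se_log = se, group_logliks = gl, ess = ess_all)
}

#' Replicated SMC estimates
#'
#' Runs `n_reps` independent copies of [smc_loglik()] from split seeds,
#' for variance diagnostics and log-mean-exp combination.
#'
#' @inheritParams smc_loglik
#' @param n_reps number of replicates (at least 2).
#' @return list with `logliks` (vector), `combined` (log-mean-exp of the
#'   replicate likelihoods), `se_log` (replicate spread of the mean).
#' @export
smc_replicates <- function(model, z, n_particles, n_reps, seed = 1,
                           ess_threshold = 0.5) {
  stopifnot(n_reps >= 2)
  seeds <- (seed * 7919L + seq_len(n_reps) * 104729L) %% 2147483646L + 1L
  ll <- vapply(seq_len(n_reps), function(r)
    smc_loglik(model, z, n_particles, seed = seeds[r],
               ess_threshold = ess_threshold)$loglik, numeric(1))
  mx <- max(ll)
  comb <- if (is.finite(mx)) mx + log(mean(exp(ll - mx))) else -Inf
  w <- exp(ll - mx)
  list(logliks = ll, combined = comb,
       se_log = stats::sd(w) / (sqrt(n_reps) * mean(w)))
}
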