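## Gillespie simulation of the population process, its history, and the
## genealogy it induces. All randomness flows through an explicit seed; the
## caller's RNG state is restored on exit.

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

resample <- function(x, k = 1L) x[sample.int(length(x), k)]

new_history <- function(horizon, times, marks, states) {
  structure(list(horizon = horizon, times = times, marks = marks,
                 states = states), class = "history")
}

#' @export
print.history <- function(x, ...) {
  cat(sprintf("<history: horizon %g, %d jumps>\n", x$horizon, length(x$times)))
  invisible(x)
}

## One Gillespie step: returns list(dt, mark index) or NULL when the clock
## outruns the residual horizon. Time-homogeneous rates only; time-varying
## rates would need a thinning envelope, which builtin models do not use.
gillespie_core <- function(model, horizon, record_genealogy, gb = NULL) {
  x <- model$state0
  t <- 0
  times <- numeric(0); marknames <- character(0)
  states <- matrix(x, nrow = 1L, dimnames = list(NULL, model$compartments))
  marks <- model$marks
  repeat {
    rates <- vapply(marks, function(m) m$rate(t, x), numeric(1))
    tot <- sum(rates)
    if (tot <= 0) break
    dt <- stats::rexp(1L, tot)
    if (t + dt > horizon) break
    t <- t + dt
    u <- sample.int(length(marks), 1L, prob = rates)
    m <- marks[[u]]
    x <- m$jump(x)
    if (any(x < 0)) stop(sprintf("mark %s drove the state negative at t=%g", m$name, t))
    if (record_genealogy) gb_apply_event(gb, m, t)
    times <- c(times, t); marknames <- c(marknames, m$name)
    states <- rbind(states, x)
  }
  list(times = times, marks = marknames, states = states)
}

#' Simulate a population-process history
#'
#' Runs the Gillespie algorithm for the model's jump process from its
#' initial state up to `horizon`, recording every jump time, mark, and the
#' embedded state chain.
#'
#' @param model a `population_model` (time-homogeneous rates).
#' @param horizon positive end time.
#' @param seed integer RNG seed; fixed seeds reproduce the history exactly.
#' @return a `history` object with fields `times`, `marks`, `states` (a
#'   matrix whose first row is the initial state).
#' @export
simulate_history <- function(model, horizon, seed) {
  stopifnot(horizon > 0)
  if (!model$time_homogeneous)
    stop("time-varying rates require a thinning envelope, which is not configured")
  with_local_seed(seed, {
    res <- gillespie_core(model, horizon, record_genealogy = FALSE)
    new_history(horizon, res$times, res$marks, res$states)
  })
}

#' Log density of a history under a model
#'
#' The log of the jump-process path density: initial mass, plus the log
#' hazard of each realized jump, minus the integrated total hazard over
#' each inter-jump interval. Returns `-Inf` when any factor vanishes (an
#' impossible initial state, a zero-rate jump, or a state sequence
#' inconsistent with the marks).
#'
#' @param model a `population_model`.
#' @param h a `history`.
#' @return a number (possibly `-Inf`).
#' @export
history_log_density <- function(model, h) {
  x0 <- stats::setNames(as.integer(h$states[1L, ]), model$compartments)
  if (any(x0 != model$state0)) return(-Inf)
  ll <- 0
  tt <- c(0, h$times, h$horizon)
  kj <- length(h$times)
  for (k in seq_len(kj + 1L)) {
    x <- stats::setNames(as.integer(h$states[k, ]), model$compartments)
    ll <- ll - total_rate(model, tt[k], x) * (tt[k + 1L] - tt[k])
    if (k <= kj) {
      m <- model$marks[[h$marks[k]]]
      if (is.null(m)) return(-Inf)
      xnext <- stats::setNames(as.integer(h$states[k + 1L, ]), model$compartments)
      if (any(m$jump(x) != xnext)) stop("history inconsistent with model marks")
      a <- m$rate(h$times[k], x)
      if (a <= 0) return(-Inf)
      ll <- ll + log(a)
    }
  }
  ll
}

## ---- genealogy builder ----------------------------------------------------

gb_new <- function(K, horizon) {
  gb <- new.env(parent = emptyenv())
  n0 <- 256L
  gb$time <- numeric(n0); gb$kind <- character(n0)
  gb$deme <- integer(n0); gb$parent <- integer(n0)
  gb$nchild <- integer(n0); gb$alive <- logical(n0)
  gb$label <- character(n0)
  gb$n <- 0L
  gb$tips <- rep(list(integer(0)), K)
  gb$n_samples <- 0L
  gb$horizon <- horizon
  gb
}

gb_add <- function(gb, time, kind, deme, parent) {
  if (gb$n == length(gb$time)) {
    grow <- function(v) c(v, v)
    gb$time <- grow(gb$time); gb$kind <- grow(gb$kind); gb$deme <- grow(gb$deme)
    gb$parent <- grow(gb$parent); gb$nchild <- grow(gb$nchild)
    gb$alive <- grow(gb$alive); gb$label <- grow(gb$label)
  }
  i <- gb$n + 1L; gb$n <- i
  gb$time[i] <- time; gb$kind[i] <- kind; gb$deme[i] <- deme
  gb$parent[i] <- parent; gb$nchild[i] <- 0L; gb$alive[i] <- TRUE
  gb$label[i] <- NA_character_
  i
}

## insert a new node directly above tip `a`; the new node inherits a's
## incoming-edge deme and takes over a's position in the tree
gb_insert_above <- function(gb, a, kind, time) {
  v <- gb_add(gb, time, kind, gb$deme[a], gb$parent[a])
  gb$parent[a] <- v
  gb$nchild[v] <- 1L
  v
}

gb_kill_tip <- function(gb, a) {
  gb$alive[a] <- FALSE
  w <- gb$parent[a]
  while (!is.na(w)) {
    gb$nchild[w] <- gb$nchild[w] - 1L
    if (gb$kind[w] == "internal" && gb$nchild[w] == 0L) {
      gb$alive[w] <- FALSE
      w <- gb$parent[w]
    } else break
  }
}

gb_apply_event <- function(gb, m, t) {
  protected <- integer(0)
  ## birth component
  if (!is.na(m$parent_deme)) {
    cand <- gb$tips[[m$parent_deme]]
    if (length(cand) == 0)
      stop(sprintf("mark %s requests a parent from an empty deme", m$name))
    a <- resample(cand)
    b <- gb_insert_above(gb, a, "internal", t)
    protected <- c(protected, a)
    for (d in seq_along(m$offspring)) {
      if (m$offspring[d] > 0L) for (j in seq_len(m$offspring[d])) {
        child <- gb_add(gb, NA_real_, "tip", d, b)
        gb$nchild[b] <- gb$nchild[b] + 1L
        gb$tips[[d]] <- c(gb$tips[[d]], child)
        protected <- c(protected, child)
      }
    }
  }
  ## migration component
  if (!is.na(m$migr_from)) {
    n_mig <- sum(m$migr_to)
    cand <- setdiff(gb$tips[[m$migr_from]], protected)
    if (length(cand) < n_mig)
      stop(sprintf("mark %s requests %d migrants but deme holds %d",
                   m$name, n_mig, length(cand)))
    movers <- resample(cand, n_mig)
    dests <- rep(seq_along(m$migr_to), m$migr_to)
    for (j in seq_len(n_mig)) {
      a <- movers[j]; d <- dests[j]
      gb_insert_above(gb, a, "internal", t)
      gb$tips[[m$migr_from]] <- setdiff(gb$tips[[m$migr_from]], a)
      gb$deme[a] <- d
      gb$tips[[d]] <- c(gb$tips[[d]], a)
      protected <- c(protected, a)
    }
  }
  ## sampling component (demes in index order when several are sampled)
  for (d in which(m$samples > 0L)) {
    cand <- setdiff(gb$tips[[d]], protected)
    if (length(cand) < m$samples[d])
      stop(sprintf("mark %s samples %d lineages but deme %d holds %d",
                   m$name, m$samples[d], d, length(cand)))
    chosen <- resample(cand, m$samples[d])
    for (a in chosen) {
      s <- gb_insert_above(gb, a, "sample", t)
      gb$n_samples <- gb$n_samples + 1L
      gb$label[s] <- paste0("s", gb$n_samples)
      if (!m$sample_survives) {
        gb$tips[[d]] <- setdiff(gb$tips[[d]], a)
        gb_kill_tip(gb, a)
      } else protected <- c(protected, a)
    }
  }
  ## death component
  for (d in seq_along(m$deaths)) {
    if (m$deaths[d] > 0L) {
      cand <- setdiff(gb$tips[[d]], protected)
      if (length(cand) < m$deaths[d])
        stop(sprintf("mark %s kills %d lineages but deme %d holds only %d",
                     m$name, m$deaths[d], d, length(cand)))
      doomed <- resample(cand, m$deaths[d])
      for (a in doomed) {
        gb$tips[[d]] <- setdiff(gb$tips[[d]], a)
        gb_kill_tip(gb, a)
      }
    }
  }
  invisible(NULL)
}

gb_finalize <- function(gb, model, horizon) {
  ## scheduled binomial sampling at the horizon
  for (ev in resolve_scheduled(model, horizon)) {
    if (ev$time != horizon)
      stop("scheduled events are supported at the horizon only")
    tips_d <- gb$tips[[ev$deme]]
    chosen <- if (ev$type == "binomial_sample") {
      tips_d[stats::runif(length(tips_d)) < ev$prob]
    } else if (ev$type == "fixed_sample") {
      if (length(tips_d) < ev$count)
        stop("scheduled sampling requests more lineages than are extant")
      resample(tips_d, ev$count)
    } else stop(sprintf("unknown scheduled event type '%s'", ev$type))
    for (a in chosen) {
      s <- gb_insert_above(gb, a, "sample", horizon)
      gb$n_samples <- gb$n_samples + 1L
      gb$label[s] <- paste0("s", gb$n_samples)
    }
  }
  live <- which(gb$alive[seq_len(gb$n)])
  tipsel <- gb$kind[live] == "tip"
  gb$time[live[tipsel]] <- horizon
  nd <- data.frame(id = live, time = gb$time[live], kind = gb$kind[live],
                   deme = gb$deme[live], parent = gb$parent[live],
                   label = gb$label[live], stringsAsFactors = FALSE)
  nd$parent[!is.na(nd$parent) & !(nd$parent %in% nd$id)] <- NA_integer_
  new_genealogy(nd, horizon, model$demes)
}

#' Simulate the population process together with its induced genealogy
#'
#' Runs the Gillespie algorithm and applies, at each jump, the genealogical
#' rule for the mark's event class: births insert a branch node above a
#' uniformly chosen parent tip of the parent deme; deaths delete tips and
#' recursively remove childless non-sample nodes; migrations insert inline
#' nodes and recolor the moved lineage; sampling inserts sample nodes
#' (labelled `s1, s2, ...` in collection order); neutral events leave the
#' genealogy untouched; compound events combine these rules. Lineage
#' selections are uniform within deme and independent across events.
#'
#' @inheritParams simulate_history
#' @return a list with elements `history` and `genealogy`.
#' @export
simulate_genealogy <- function(model, horizon, seed) {
  stopifnot(horizon > 0)
  with_local_seed(seed, {
    gb <- gb_new(model$n_demes, horizon)
    occ0 <- model$occupancy(model$state0)
    for (d in seq_len(model$n_demes)) {
      if (occ0[d] > 0) for (j in seq_len(occ0[d])) {
        r <- gb_add(gb, 0, "root", d, NA_integer_)
        a <- gb_add(gb, NA_real_, "tip", d, r)
        gb$nchild[r] <- 1L
        gb$tips[[d]] <- c(gb$tips[[d]], a)
      }
    }
    res <- gillespie_core(model, horizon, record_genealogy = TRUE, gb = gb)
    g <- gb_finalize(gb, model, horizon)
    list(history = new_history(horizon, res$times, res$marks, res$states),
         genealogy = g)
  })
}
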