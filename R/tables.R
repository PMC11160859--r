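## Precomputed finite-state tables for a population model: the enumerated
## lattice, per-state occupancies, and per-mark hazard and target-index
## vectors. These back the deterministic filters, the sequential Monte
## Carlo proposal, and the fast Gillespie paths. They require the model to
## be time-homogeneous and finitely enumerable.

model_tables <- function(model, max_states = 5e5) {
  cache <- model$cache
  if (!is.null(cache$tables)) return(cache$tables)
  if (is.null(model$enumerate))
    stop(sprintf("model '%s' has no finite state enumeration", model$name))
  if (!model$time_homogeneous)
    stop("state tables require time-homogeneous rates")
  states <- model$enumerate()
  M <- nrow(states)
  if (M > max_states)
    stop(sprintf("state space too large (%d states > %d)", M, max_states))
  keys <- apply(states, 1L, paste, collapse = ",")
  key_index <- stats::setNames(seq_len(M), keys)
  K <- model$n_demes
  occ <- matrix(0L, M, K)
  for (i in seq_len(M)) {
    x <- stats::setNames(as.integer(states[i, ]), model$compartments)
    occ[i, ] <- model$occupancy(x)
  }
  marks <- model$marks
  U <- length(marks)
  rate <- matrix(0, M, U); to <- matrix(NA_integer_, M, U)
  for (u in seq_len(U)) {
    m <- marks[[u]]
    for (i in seq_len(M)) {
      x <- stats::setNames(as.integer(states[i, ]), model$compartments)
      rate[i, u] <- m$rate(0, x)
      if (rate[i, u] > 0) {
        x2 <- m$jump(x)
        j <- key_index[paste(x2, collapse = ",")]
        if (is.na(j)) {
          ## target outside the truncation: treat as boundary leak -- the
          ## mark keeps its hazard (loss term) but transfers no mass
          to[i, u] <- NA_integer_
        } else to[i, u] <- j
      }
    }
  }
  colnames(rate) <- colnames(to) <- names(marks)
  p0 <- numeric(M)
  i0 <- key_index[paste(model$state0, collapse = ",")]
  if (is.na(i0)) stop("initial state lies outside the enumerated state space")
  p0[i0] <- 1
  tb <- list(states = states, keys = keys, key_index = key_index, occ = occ,
             rate = rate, to = to, total_rate = rowSums(rate), p0 = p0,
             i0 = i0, M = M)
  cache$tables <- tb
  tb
}

state_at <- function(model, tb, i) {
  stats::setNames(as.integer(tb$states[i, ]), model$compartments)
}

## Scheduled events with time = NA bind to the horizon.
resolve_scheduled <- function(model, horizon) {
  lapply(model$scheduled, function(ev) {
    if (is.na(ev$time)) ev$time <- horizon
    ev
  })
}
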