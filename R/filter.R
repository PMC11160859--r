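## Deterministic filter solvers for genealogy likelihoods.
##
## The likelihood of a genealogy under a structured population model solves
## a linear filter equation: between genealogical event times the weight
## vector obeys a linear ODE (the regular part), and at each event it is
## hit by a sparse multiplicative update (the singular part). Two modes:
##
##  * colored: the tree is a fully colored pruned genealogy, inline nodes
##    included. The hidden coordinate is absent; between events only jumps
##    that leave the tree untouched contribute gain terms (saturation 0).
##  * obscured: demes and inline nodes are unknown. The weight is indexed
##    by (population state, deme assignment of the current tree lineages),
##    and the regular part also carries "hidden inline" transitions --
##    births off a tree lineage whose other descendants are unobserved, and
##    migrations of a tree lineage -- which leave no visible node.
##
## Both modes admit a forward solution (initial condition p0, terminal
## summation) and an adjoint solution (terminal condition 1, initial
## summation against p0); the two agree to integration tolerance.

## vectorized binomial ratio over rows of an occupancy matrix
ratio_vec <- function(occM, l, r, s) {
  K <- length(l)
  if (any(s < 0L) || any(r < s)) return(numeric(nrow(occM)))
  out <- rep(1, nrow(occM))
  for (i in seq_len(K)) {
    num <- choose(occM[, i] - l[i], r[i] - s[i])
    den <- choose(occM[, i], r[i])
    v <- ifelse(den > 0 & occM[, i] >= l[i] & (occM[, i] - l[i]) >= (r[i] - s[i]),
                num / den, 0)
    out <- out * v
  }
  out
}

## exp(A*dt) %*% v by uniformization. A must have non-negative
## off-diagonal entries (a filter sub-generator). Exact up to the series
## truncation tolerance; intervals with large rate*dt are chunked so the
## Poisson weights stay representable.
unif_expmv <- function(A, v, dt, tol = 1e-14) {
  if (dt == 0 || all(v == 0)) return(v)
  lam <- max(-min(Matrix::diag(A)), max(abs(A)), 1e-12)
  n_chunk <- max(1L, ceiling(lam * dt / 30))
  h <- dt / n_chunk
  P <- A / lam
  Matrix::diag(P) <- Matrix::diag(P) + 1
  a <- lam * h
  for (chunk in seq_len(n_chunk)) {
    term <- v
    acc <- exp(-a) * v
    pk <- exp(-a)
    cum <- pk
    k <- 0L
    while (cum < 1 - tol && k < 100000L) {
      k <- k + 1L
      term <- as.numeric(P %*% term)
      pk <- pk * a / k
      acc <- acc + pk * term
      cum <- cum + pk
    }
    v <- acc
  }
  v
}

## ---- colored mode ---------------------------------------------------------

## regular-part generator for a colored tree with lineage count `l`
colored_generator <- function(model, tb, l) {
  M <- tb$M
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (u in seq_along(model$marks)) {
    m <- model$marks[[u]]
    if (m$n_samples > 0L) next  # a sampling event always deposits a node
    ok <- which(!is.na(tb$to[, u]) & tb$rate[, u] > 0)
    if (length(ok) == 0) next
    to <- tb$to[ok, u]
    w <- tb$rate[ok, u] * ratio_vec(tb$occ[to, , drop = FALSE], l, m$production,
                                    integer(model$n_demes))
    ii <- c(ii, to); jj <- c(jj, ok); xx <- c(xx, w)
  }
  ii <- c(ii, seq_len(M)); jj <- c(jj, seq_len(M)); xx <- c(xx, -tb$total_rate)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(M, M))
}

## singular update operator at event time t of a colored tree
colored_singular <- function(model, tb, tree, t) {
  M <- tb$M
  lpost <- lineage_count(tree, t)
  s <- saturation(tree, t)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (u in seq_along(model$marks)) {
    m <- model$marks[[u]]
    if (compatibility(m, tree, t) == 0L) next
    ok <- which(!is.na(tb$to[, u]) & tb$rate[, u] > 0)
    if (length(ok) == 0) next
    to <- tb$to[ok, u]
    w <- tb$rate[ok, u] * ratio_vec(tb$occ[to, , drop = FALSE], lpost,
                                    m$production, s)
    ii <- c(ii, to); jj <- c(jj, ok); xx <- c(xx, w)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(M, M))
}

## scheduled-event factor at the horizon, as a diagonal weight vector over
## states (colored mode) or over (state, assignment) pairs (obscured mode).
sched_factor_states <- function(model, tb, ev, m_nodes, l_tilde) {
  d <- ev$deme
  occ_d <- tb$occ[, d]
  if (!is.null(ev$prob)) {
    f <- choose(occ_d, m_nodes) * ev$prob^m_nodes * (1 - ev$prob)^(pmax(occ_d - m_nodes, 0))
    f[occ_d < m_nodes] <- 0
  } else {
    f <- as.numeric(occ_d >= ev$count)
    if (m_nodes != ev$count) f[] <- 0
  }
  ## every tree lineage alive just before the horizon must be sampled
  if (any(l_tilde[-d] > 0) || l_tilde[d] != m_nodes) f[] <- 0
  f
}

prep_colored <- function(model, tb, tree) {
  T <- tree$horizon
  sched <- resolve_scheduled(model, T)
  evs <- event_times(tree)
  evs <- evs[evs >= 0 & evs <= T]
  has_sched <- length(sched) > 0
  if (has_sched) evs <- evs[evs < T]
  brk <- c(0, evs, T)
  n_int <- length(brk) - 1L
  lcache <- list()
  Alist <- vector("list", n_int)
  for (k in seq_len(n_int)) {
    l <- lineage_count(tree, brk[k])
    key <- paste(l, collapse = ",")
    if (is.null(lcache[[key]])) lcache[[key]] <- colored_generator(model, tb, l)
    Alist[[k]] <- lcache[[key]]
  }
  Slist <- lapply(evs, function(e) colored_singular(model, tb, tree, e))
  ## initial support: occupancy must cover the pre-event lineage count; if
  ## an event sits at t=0 its own update enforces feasibility
  mask0 <- rep(1, tb$M)
  if (!any(evs == 0)) {
    l0 <- lineage_count(tree, 0)
    mask0 <- as.numeric(apply(tb$occ >= rep(l0, each = tb$M), 1L, all))
  }
  fsched <- NULL
  if (has_sched) {
    nodes_T <- tree$nodes[tree$nodes$time == T & tree$nodes$kind == "sample", , drop = FALSE]
    ltilde <- if (length(evs) > 0) lineage_count(tree, evs[length(evs)])
              else lineage_count(tree, 0)
    fsched <- rep(1, tb$M)
    for (ev in sched) {
      m_nodes <- if (length(tree$demes) > 0)
        sum(nodes_T$deme == ev$deme, na.rm = TRUE) else nrow(nodes_T)
      fsched <- fsched * sched_factor_states(model, tb, ev, m_nodes, ltilde)
    }
  }
  list(brk = brk, Alist = Alist, Slist = Slist, mask0 = mask0,
       fsched = fsched, n_state = tb$M)
}

## ---- obscured mode --------------------------------------------------------

## assignment enumeration: K^l rows, one deme per lineage slot; row `a`
## satisfies assign_index(Y[a, ], K) == a (first slot varies fastest)
assign_enum <- function(K, l) {
  if (l == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  m <- as.matrix(expand.grid(rep(list(seq_len(K)), l), KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

assign_index <- function(y, K) {
  if (length(y) == 0L) return(1L)
  1L + sum((y - 1L) * K^(seq_along(y) - 1L))
}

## slot bookkeeping: walk the obscured tree's events in time order. A slot
## is a current lineage, identified by the id of the node terminating its
## edge (or by the root id for a not-yet-branched root lineage). For each
## event we record the pre- and post-event slot lists and, for every post
## slot, the pre position it descends from (`map`, NA for branch children).
obscured_skeleton <- function(tree) {
  nd <- tree$nodes
  nch <- n_children(tree)
  is_event <- (nd$kind %in% c("internal", "sample")) | (nch >= 2L & nd$kind == "root")
  evs <- sort(unique(nd$time[is_event]))
  kids_of <- function(id) sort(nd$id[!is.na(nd$parent) & nd$parent == id])
  slots <- integer(0)
  for (i in which(nd$kind == "root")) {
    if (is_event[i]) slots <- c(slots, nd$id[i])  # will branch in place
    else slots <- c(slots, kids_of(nd$id[i]))
  }
  slots <- sort(slots)
  events <- list()
  for (e in evs) {
    idx <- which(nd$time == e & is_event)
    kinds <- nd$kind[idx]
    pre <- slots
    if (all(kinds == "sample")) {
      post <- integer(0); map <- integer(0)
      sampled_pre <- match(nd$id[idx], pre)
      if (anyNA(sampled_pre)) stop("sample node is not a current lineage")
      term <- logical(length(idx))
      repl <- stats::setNames(rep(NA_integer_, length(pre)), pre)
      for (j in seq_along(idx)) {
        sid <- nd$id[idx[j]]
        ch <- kids_of(sid)
        if (length(ch) > 1L) stop("sample node with several children")
        if (length(ch) == 0L) term[j] <- TRUE
        else repl[as.character(sid)] <- ch
      }
      for (k in seq_along(pre)) {
        sid <- pre[k]
        if (sid %in% nd$id[idx]) {
          j <- match(sid, nd$id[idx])
          if (term[j]) next
          post <- c(post, repl[as.character(sid)]); map <- c(map, k)
        } else {
          post <- c(post, sid); map <- c(map, k)
        }
      }
      ord <- order(post)
      events[[length(events) + 1L]] <- list(
        time = e, type = "sample", node_ids = nd$id[idx], terminal = term,
        sampled_pre = sampled_pre, pre = pre,
        post = post[ord], map = map[ord])
    } else if (length(idx) == 1L && kinds[1] %in% c("internal", "root")) {
      bid <- nd$id[idx]
      ch <- kids_of(bid)
      if (length(ch) < 2L) stop("obscured tree retains an inline node")
      kpos <- match(bid, pre)
      if (is.na(kpos)) stop("branch node is not a current lineage")
      post <- c(setdiff(pre, bid), ch)
      map <- c(match(setdiff(pre, bid), pre), rep(NA_integer_, length(ch)))
      ord <- order(post)
      events[[length(events) + 1L]] <- list(
        time = e, type = "branch", node_ids = bid, children = ch,
        branch_pre = kpos, pre = pre, post = post[ord], map = map[ord])
    } else stop("unsupported simultaneous event structure in obscured tree")
    slots <- events[[length(events)]]$post
  }
  list(events = events, final_slots = slots,
       slots0 = if (length(events) > 0) events[[1]]$pre else slots)
}

obscured_generator <- function(model, tb, Y) {
  M <- tb$M; K <- model$n_demes
  A <- nrow(Y); l_slots <- ncol(Y)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  off <- function(a) (a - 1L) * M
  for (a in seq_len(A)) {
    y <- Y[a, ]
    ly <- tabulate(y, K)
    for (u in seq_along(model$marks)) {
      m <- model$marks[[u]]
      if (m$n_samples > 0L) next
      ok <- which(!is.na(tb$to[, u]) & tb$rate[, u] > 0)
      if (length(ok) == 0) next
      to <- tb$to[ok, u]
      occ_to <- tb$occ[to, , drop = FALSE]
      ## no tree lineage involved
      w <- tb$rate[ok, u] * ratio_vec(occ_to, ly, m$production, integer(K))
      ii <- c(ii, off(a) + to); jj <- c(jj, off(a) + ok); xx <- c(xx, w)
      ## hidden inline: a birth whose parent is a tree lineage (which then
      ## continues as parent or as one of the offspring)
      if (sum(m$offspring) > 0L && l_slots > 0L) {
        for (k in which(y == m$parent_deme)) {
          for (d in which(m$production >= 1L)) {
            y2 <- y; y2[k] <- d
            ly2 <- tabulate(y2, K)
            s <- integer(K); s[d] <- 1L
            w <- tb$rate[ok, u] * ratio_vec(occ_to, ly2, m$production, s)
            a2 <- assign_index(y2, K)
            ii <- c(ii, off(a2) + to); jj <- c(jj, off(a) + ok); xx <- c(xx, w)
          }
        }
      }
      ## hidden inline: migration of a tree lineage
      if (!is.na(m$migr_from) && l_slots > 0L) {
        if (sum(m$migr_to) > 1L)
          stop("hidden marginalization for multi-lineage migration marks is not supported")
        d <- which(m$migr_to == 1L)
        for (k in which(y == m$migr_from)) {
          y2 <- y; y2[k] <- d
          ly2 <- tabulate(y2, K)
          s <- integer(K); s[d] <- 1L
          w <- tb$rate[ok, u] * ratio_vec(occ_to, ly2, m$production, s)
          a2 <- assign_index(y2, K)
          ii <- c(ii, off(a2) + to); jj <- c(jj, off(a) + ok); xx <- c(xx, w)
        }
      }
    }
  }
  N <- M * A
  ii <- c(ii, seq_len(N)); jj <- c(jj, seq_len(N))
  xx <- c(xx, rep(-tb$total_rate, A))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
}

obscured_singular <- function(model, tb, ev, K) {
  M <- tb$M
  Ypre <- assign_enum(K, length(ev$pre))
  n_post <- length(ev$post)
  Apre <- nrow(Ypre)
  N_pre <- M * Apre; N_post <- M * K^n_post
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  mapped <- which(!is.na(ev$map))
  if (ev$type == "branch") {
    ch_pos <- which(is.na(ev$map))
    c_n <- length(ch_pos)
    tuples <- assign_enum(K, c_n)
    for (u in seq_along(model$marks)) {
      m <- model$marks[[u]]
      if (sum(m$offspring) == 0L) next
      ok <- which(!is.na(tb$to[, u]) & tb$rate[, u] > 0)
      if (length(ok) == 0) next
      to <- tb$to[ok, u]
      occ_to <- tb$occ[to, , drop = FALSE]
      for (a in seq_len(Apre)) {
        y <- Ypre[a, ]
        if (length(y) > 0 && y[ev$branch_pre] != m$parent_deme) next
        for (tu in seq_len(nrow(tuples))) {
          dts <- tuples[tu, ]
          s <- tabulate(dts, K)
          if (any(s > m$production)) next
          y2 <- integer(n_post)
          y2[mapped] <- y[ev$map[mapped]]
          y2[ch_pos] <- dts
          ly2 <- tabulate(y2, K)
          w <- tb$rate[ok, u] * ratio_vec(occ_to, ly2, m$production, s)
          a2 <- assign_index(y2, K)
          ii <- c(ii, (a2 - 1L) * M + to); jj <- c(jj, (a - 1L) * M + ok)
          xx <- c(xx, w)
        }
      }
    }
  } else {  # sample event
    n_inline <- sum(!ev$terminal)
    for (u in seq_along(model$marks)) {
      m <- model$marks[[u]]
      if (m$n_samples != length(ev$node_ids)) next
      if (m$n_samples == 0L) next
      if (!m$sample_survives && n_inline > 0L) next
      ok <- which(!is.na(tb$to[, u]) & tb$rate[, u] > 0)
      if (length(ok) == 0) next
      to <- tb$to[ok, u]
      occ_to <- tb$occ[to, , drop = FALSE]
      s <- integer(K); s[m$sample_deme] <- n_inline
      for (a in seq_len(Apre)) {
        y <- Ypre[a, ]
        if (any(y[ev$sampled_pre] != m$sample_deme)) next
        y2 <- integer(n_post)
        y2[mapped] <- y[ev$map[mapped]]
        ly2 <- if (n_post > 0) tabulate(y2, K) else integer(K)
        w <- tb$rate[ok, u] * ratio_vec(occ_to, ly2, m$production, s)
        a2 <- assign_index(y2, K)
        ii <- c(ii, (a2 - 1L) * M + to); jj <- c(jj, (a - 1L) * M + ok)
        xx <- c(xx, w)
      }
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N_post, N_pre))
}

prep_obscured <- function(model, tb, tree, max_size = 2e6) {
  T <- tree$horizon
  K <- model$n_demes
  sched <- resolve_scheduled(model, T)
  sk <- obscured_skeleton(tree)
  events <- sk$events
  final_slots <- sk$final_slots
  has_sched <- length(sched) > 0
  sched_nodes <- integer(0)
  if (has_sched) {
    at_T <- vapply(events, function(e) e$time == T && e$type == "sample", logical(1))
    if (any(at_T)) {
      sched_nodes <- events[[which(at_T)]]$node_ids
      final_slots <- events[[which(at_T)]]$pre
      events <- events[!at_T]
    }
  }
  max_l <- max(0L, vapply(events, function(e) length(e$pre), integer(1)),
               length(final_slots))
  if (tb$M * K^max_l > max_size)
    stop(sprintf("hidden-coloring space too large: %d states x %d^%d assignments",
                 tb$M, K, max_l))
  slots0 <- if (length(events) > 0) events[[1]]$pre else final_slots
  brk <- c(0, vapply(events, `[[`, numeric(1), "time"), T)
  n_int <- length(brk) - 1L
  slot_seq <- vector("list", n_int)
  slot_seq[[1]] <- slots0
  if (n_int > 1) for (k in 2:n_int) slot_seq[[k]] <- events[[k - 1L]]$post
  gcache <- list()
  Alist <- vector("list", n_int)
  for (k in seq_len(n_int)) {
    l <- length(slot_seq[[k]])
    key <- as.character(l)
    if (is.null(gcache[[key]]))
      gcache[[key]] <- obscured_generator(model, tb, assign_enum(K, l))
    Alist[[k]] <- gcache[[key]]
  }
  Slist <- lapply(events, function(e) obscured_singular(model, tb, e, K))
  ## initial mask over (state, assignment)
  Y0 <- assign_enum(K, length(slots0))
  mask0 <- numeric(tb$M * nrow(Y0))
  for (a in seq_len(nrow(Y0))) {
    ly <- tabulate(Y0[a, ], K)
    okst <- apply(tb$occ >= rep(ly, each = tb$M), 1L, all)
    mask0[(a - 1L) * tb$M + which(okst)] <- 1
  }
  fsched <- NULL
  if (has_sched) {
    lfin <- length(final_slots)
    Yfin <- assign_enum(K, lfin)
    fsched <- numeric(tb$M * nrow(Yfin))
    for (a in seq_len(nrow(Yfin))) {
      y <- Yfin[a, ]
      f <- rep(1, tb$M)
      for (ev in sched) {
        ltilde <- integer(K)
        if (lfin > 0) ltilde <- tabulate(y, K)
        f <- f * sched_factor_states(model, tb, ev, length(sched_nodes), ltilde)
      }
      fsched[(a - 1L) * tb$M + seq_len(tb$M)] <- f
    }
    if (length(sched_nodes) != lfin)
      fsched[] <- 0  # unsampled tree lineages cannot reach the horizon
  }
  list(brk = brk, Alist = Alist, Slist = Slist, mask0 = mask0,
       fsched = fsched, n_state = tb$M)
}

## ---- drivers --------------------------------------------------------------

run_forward <- function(prep, p0rep, tol = 1e-14) {
  w <- p0rep * prep$mask0
  logscale <- 0
  if (sum(w) == 0) return(-Inf)
  brk <- prep$brk
  for (k in seq_along(prep$Alist)) {
    w <- unif_expmv(prep$Alist[[k]], w, brk[k + 1L] - brk[k], tol = tol)
    if (k <= length(prep$Slist)) w <- as.numeric(prep$Slist[[k]] %*% w)
    sw <- sum(w)
    if (sw <= 0 || !is.finite(sw)) return(-Inf)
    logscale <- logscale + log(sw)
    w <- w / sw
  }
  if (!is.null(prep$fsched)) {
    w <- w * prep$fsched
    sw <- sum(w)
    if (sw <= 0) return(-Inf)
    logscale <- logscale + log(sw)
  }
  logscale
}

run_adjoint <- function(prep, p0rep, tol = 1e-14) {
  F <- rep(1, nrow(prep$Alist[[length(prep$Alist)]]))
  if (!is.null(prep$fsched)) F <- F * prep$fsched
  logscale <- 0
  brk <- prep$brk
  for (k in rev(seq_along(prep$Alist))) {
    F <- unif_expmv(Matrix::t(prep$Alist[[k]]), F, brk[k + 1L] - brk[k], tol = tol)
    if (k > 1L) F <- as.numeric(Matrix::t(prep$Slist[[k - 1L]]) %*% F)
    sF <- max(F)
    if (sF <= 0 || !is.finite(sF)) return(-Inf)
    logscale <- logscale + log(sF)
    F <- F / sF
  }
  val <- sum(p0rep * prep$mask0 * F)
  if (val <= 0) return(-Inf)
  logscale + log(val)
}

filter_prep <- function(model, tree, max_size = 2e6) {
  for (m in model$marks)
    if (m$n_samples > 0L && is.na(m$sample_deme))
      stop("filters support sampling marks confined to a single deme")
  tb <- model_tables(model)
  if (inherits(tree, "obscured_genealogy")) {
    prep <- prep_obscured(model, tb, tree, max_size = max_size)
    A <- length(prep$mask0) / tb$M
    p0rep <- rep(tb$p0, A)
  } else {
    if (length(tree$demes) > 0 && !identical(tree$demes, model$demes))
      stop("tree and model deme sets differ")
    prep <- prep_colored(model, tb, tree)
    p0rep <- tb$p0
  }
  list(prep = prep, p0rep = p0rep)
}

#' Forward filter log-likelihood of a genealogy
#'
#' Solves the forward filter equation for the given tree under the model:
#' a linear ODE over population states (and, for obscured trees, hidden
#' deme assignments of the current lineages) between genealogical events,
#' with sparse multiplicative updates at them. Returns the log-likelihood
#' `log L`; `-Inf` signals structurally impossible data.
#'
#' @param model a time-homogeneous, finitely enumerable `population_model`.
#' @param tree a colored `pruned_genealogy` (complete with inline nodes, as
#'   produced by [prune()] on simulator output) or an
#'   `obscured_genealogy`.
#' @param max_size guard on `#states x #assignments` for obscured trees.
#' @param tol truncation tolerance of the uniformization series.
#' @return log-likelihood (scalar, possibly `-Inf`).
#' @export
filter_forward <- function(model, tree, max_size = 2e6, tol = 1e-14) {
  fp <- filter_prep(model, tree, max_size)
  run_forward(fp$prep, fp$p0rep, tol = tol)
}

#' Adjoint filter log-likelihood of a genealogy
#'
#' Integrates the adjoint (backward) form of the filter equation from the
#' final condition 1 at the horizon down to time 0 and contracts against
#' the initial distribution. Agrees with [filter_forward()] to integration
#' tolerance on every valid input.
#'
#' @inheritParams filter_forward
#' @return log-likelihood (scalar, possibly `-Inf`).
#' @export
filter_adjoint <- function(model, tree, max_size = 2e6, tol = 1e-14) {
  fp <- filter_prep(model, tree, max_size)
  run_adjoint(fp$prep, fp$p0rep, tol = tol)
}

#' Obscured-genealogy log-likelihood by deterministic filtering
#'
#' Convenience wrapper: the forward filter in obscured mode, marginalizing
#' the hidden deme assignment of every lineage (including events whose
#' only trace would be a hidden inline node).
#'
#' @param model a `population_model`.
#' @param z an `obscured_genealogy`.
#' @param max_size guard on the hidden-space size.
#' @param tol truncation tolerance of the uniformization series.
#' @return log-likelihood (scalar, possibly `-Inf`).
#' @export
filter_obscured <- function(model, z, max_size = 2e6, tol = 1e-14) {
  if (!inherits(z, "obscured_genealogy")) z <- obscure(z)
  filter_forward(model, z, max_size = max_size, tol = tol)
}
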