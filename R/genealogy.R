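## Genealogies as node tables. Each node carries an id, its absolute time,
## its kind (root / internal / sample / tip), the deme of its incoming edge
## (NA when unknown), and its parent id (NA for roots). Edges live on the
## half-open interval [parent time, node time) of the child node's incoming
## branch; values at an event time are post-event (cadlag convention).

new_genealogy <- function(nodes, horizon, demes, subclass = character(0)) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "time", "kind", "deme", "parent", "label") %in% names(nodes)))
  structure(list(nodes = nodes, horizon = horizon, demes = demes),
            class = c(subclass, "genealogy"))
}

empty_nodes <- function() {
  data.frame(id = integer(0), time = numeric(0), kind = character(0),
             deme = integer(0), parent = integer(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.genealogy <- function(x, ...) {
  k <- table(factor(x$nodes$kind, levels = c("root", "internal", "sample", "tip")))
  cat(sprintf("<%s: horizon %g, %d nodes (%s)>\n",
              class(x)[1], x$horizon, nrow(x$nodes),
              paste(sprintf("%d %s", k, names(k)), collapse = ", ")))
  invisible(x)
}

## Number of children of every node, as a vector indexed like g$nodes.
n_children <- function(g) {
  tab <- table(factor(g$nodes$parent, levels = g$nodes$id))
  as.integer(tab)
}

genealogy_samples <- function(g) g$nodes[g$nodes$kind == "sample", , drop = FALSE]

#' Event times of a genealogy
#'
#' The set of internal and sample node times (roots and tips excluded),
#' sorted and unique.
#' @param g a genealogy.
#' @return numeric vector.
#' @export
event_times <- function(g) {
  keep <- g$nodes$kind %in% c("internal", "sample") | n_children(g) >= 2L
  sort(unique(g$nodes$time[keep]))
}

#' Prune a genealogy down to its sample-spanning subtree
#'
#' Drops every tip node, then recursively drops every childless non-sample
#' node. Sample nodes are never removed, and single-child (inline) internal
#' nodes that remain on a surviving path are retained, as is the coloring.
#' The result may be an empty forest when the genealogy carries no samples.
#'
#' @param g a genealogy.
#' @return a `pruned_genealogy`.
#' @export
prune <- function(g) {
  nd <- g$nodes
  keep <- nd$kind != "tip"
  nd <- nd[keep, , drop = FALSE]
  repeat {
    has_child <- nd$id %in% nd$parent
    drop <- !has_child & nd$kind != "sample"
    if (!any(drop)) break
    nd <- nd[!drop, , drop = FALSE]
  }
  new_genealogy(nd, g$horizon, g$demes, "pruned_genealogy")
}

#' Obscure a pruned genealogy
#'
#' Erases all deme information and splices out every non-sample inline
#' (single-child internal) node, leaving only the tree shape: root, branch
#' point, and sample nodes with their times.
#'
#' @param p a `pruned_genealogy` (an already-obscured genealogy passes
#'   through unchanged).
#' @return an `obscured_genealogy`.
#' @export
obscure <- function(p) {
  nd <- p$nodes
  if (nrow(nd) > 0) {
    repeat {
      nch <- as.integer(table(factor(nd$parent, levels = nd$id)))
      splice <- nd$kind == "internal" & nch == 1L
      if (!any(splice)) break
      victim <- which(splice)[1]
      vid <- nd$id[victim]
      nd$parent[!is.na(nd$parent) & nd$parent == vid] <- nd$parent[victim]
      nd <- nd[-victim, , drop = FALSE]
    }
    nd$deme <- NA_integer_
  }
  new_genealogy(nd, p$horizon, character(0), "obscured_genealogy")
}

## Edge table: one row per non-root node; the incoming edge spans
## [parent_time, time) and carries deme `deme` (NA when obscured).
edge_table <- function(g) {
  nd <- g$nodes
  has_par <- !is.na(nd$parent)
  pid <- match(nd$parent[has_par], nd$id)
  data.frame(child = nd$id[has_par], start = nd$time[pid], end = nd$time[has_par],
             deme = nd$deme[has_par], child_kind = nd$kind[has_par],
             stringsAsFactors = FALSE)
}

#' Per-deme lineage count of a pruned genealogy
#'
#' Number of branches, per deme, crossing time `t`, with the right-continuous
#' convention that an edge starting at `t` counts at `t` while an edge ending
#' at `t` does not. For obscured genealogies the total count is returned as a
#' single number.
#'
#' @param p a pruned or obscured genealogy.
#' @param t a time in `[0, horizon]`.
#' @return integer vector over demes (length 1 for obscured genealogies).
#' @export
lineage_count <- function(p, t) {
  if (t < 0 || t > p$horizon) stop("t outside [0, horizon]")
  ed <- edge_table(p)
  live <- ed$start <= t & t < ed$end
  if (inherits(p, "obscured_genealogy") || length(p$demes) == 0)
    return(sum(live))
  K <- length(p$demes)
  out <- integer(K)
  if (any(live)) {
    tb <- table(factor(ed$deme[live], levels = seq_len(K)))
    out <- as.integer(tb)
  }
  out
}

#' Per-deme saturation of a pruned genealogy at a time
#'
#' The number of lineages, per deme, emerging from nodes with time exactly
#' `t`: edges whose parent node sits at `t`. Zero in all demes when no node
#' has time `t`; a terminal sample contributes nothing while an inline
#' sample contributes one lineage in its deme.
#'
#' @inheritParams lineage_count
#' @return integer vector over demes (total count for obscured genealogies).
#' @export
saturation <- function(p, t) {
  nd <- p$nodes
  at_t <- nd$id[nd$time == t & nd$kind != "root"]
  has_par <- !is.na(nd$parent)
  emerg <- which(has_par & nd$parent %in% at_t)
  if (inherits(p, "obscured_genealogy") || length(p$demes) == 0)
    return(length(emerg))
  K <- length(p$demes)
  if (length(emerg) == 0) return(integer(K))
  as.integer(table(factor(nd$deme[emerg], levels = seq_len(K))))
}

## Local structure of a pruned genealogy at time t: the nodes with time t
## (roots excluded) together with their vanishing-edge demes and the demes
## of their emerging edges. Used by the compatibility indicator and by the
## filters' singular updates.
local_structure <- function(p, t) {
  nd <- p$nodes
  nch <- n_children(p)
  idx <- which(nd$time == t & (nd$kind != "root" | nch >= 2L))
  if (length(idx) == 0) return(NULL)
  kids <- split(seq_len(nrow(nd)), match(nd$parent, nd$id))
  lapply(idx, function(i) {
    ch <- kids[[as.character(i)]]
    list(id = nd$id[i], kind = nd$kind[i], deme = nd$deme[i],
         child_demes = if (is.null(ch)) integer(0) else nd$deme[ch],
         n_child = if (is.null(ch)) 0L else length(ch))
  })
}

#' Compatibility of a jump mark with the local genealogy structure
#'
#' Indicator: can an event of mark `u` generate the local structure of the
#' colored pruned genealogy `p` at time `t`? Branch nodes require a
#' birth-type mark whose parent deme matches the vanishing edge and whose
#' production covers the emerging demes; sample nodes require a sampling
#' mark of the right deme and multiplicity; an inline deme change requires
#' a matching migration or a birth whose offspring can continue the
#' lineage; when no node sits at `t`, only marks whose events can leave the
#' pruned genealogy unchanged (anything without a sampling component) are
#' compatible.
#'
#' @param u a [jump_mark()].
#' @param p a colored `pruned_genealogy`.
#' @param t a time in `[0, horizon]`.
#' @return 0 or 1.
#' @export
compatibility <- function(u, p, t) {
  ls <- local_structure(p, t)
  if (is.null(ls)) {
    ## no node: the event must be able to leave p unchanged; a sampling
    ## component always deposits a sample node, so it is incompatible
    return(as.integer(u$n_samples == 0L))
  }
  kinds <- vapply(ls, `[[`, character(1), "kind")
  if (any(kinds == "sample")) {
    if (!all(kinds == "sample")) return(0L)
    if (u$n_samples != length(ls)) return(0L)
    for (nod in ls) {
      if (!is.na(nod$deme) && !is.na(u$sample_deme) && nod$deme != u$sample_deme)
        return(0L)
      if (nod$n_child > 1L) return(0L)
      if (nod$n_child == 1L) {
        if (!u$sample_survives) return(0L)
        if (!is.na(nod$child_demes[1]) && !is.na(u$sample_deme) &&
            nod$child_demes[1] != u$sample_deme) return(0L)
      }
    }
    return(1L)
  }
  if (length(ls) != 1L) return(0L)  # simultaneous non-sample nodes not generated
  nod <- ls[[1]]
  if (nod$n_child >= 2L) {
    ## branch point: birth-type only, matching parent deme, s <= r
    if (sum(u$offspring) == 0L) return(0L)
    if (!is.na(nod$deme) && nod$deme != u$parent_deme) return(0L)
    s <- as.integer(table(factor(nod$child_demes, levels = seq_len(u$n_demes))))
    if (any(s > u$production)) return(0L)
    return(1L)
  }
  if (nod$n_child == 1L) {
    ## inline node: a migration, or a birth whose parent or offspring
    ## continues the lineage
    d_old <- nod$deme; d_new <- nod$child_demes[1]
    ok_mig <- !is.na(u$migr_from) &&
      (is.na(d_old) || u$migr_from == d_old) &&
      (is.na(d_new) || u$migr_to[d_new] > 0L)
    ok_birth <- sum(u$offspring) > 0L &&
      (is.na(d_old) || u$parent_deme == d_old) &&
      (is.na(d_new) || u$production[d_new] > 0L)
    return(as.integer(ok_mig || ok_birth))
  }
  ## childless non-sample node cannot occur in a pruned genealogy
  0L
}

#' Per-event conditional weight of a population jump
#'
#' The factor contributed by one population-process jump of mark `u` to the
#' likelihood of the pruned genealogy `p` given the history: the binomial
#' ratio of occupancy, lineage count, production and saturation, times the
#' compatibility indicator.
#'
#' @param model a `population_model`.
#' @param u a [jump_mark()] of the model.
#' @param x the post-jump population state (named vector).
#' @param p a colored `pruned_genealogy`.
#' @param t the jump time.
#' @return a number in [0, 1].
#' @export
event_weight <- function(model, u, x, p, t) {
  q <- compatibility(u, p, t)
  if (q == 0L) return(0)
  n <- model$occupancy(x)
  l <- lineage_count(p, t)
  s <- saturation(p, t)
  binomial_ratio(n, l, u$production, s)
}

#' Coalescent-interval durations of an obscured genealogy
#'
#' For each lineage count `i`, the total time during which the genealogy
#' has exactly `i` lineages.
#'
#' @param z an obscured (or single-deme pruned) genealogy.
#' @return named numeric vector mapping lineage count to duration.
#' @export
coalescent_intervals <- function(z) {
  ed <- edge_table(z)
  if (nrow(ed) == 0) return(stats::setNames(numeric(0), character(0)))
  brk <- sort(unique(c(ed$start, ed$end)))
  out <- numeric(0)
  for (k in seq_len(length(brk) - 1L)) {
    t0 <- brk[k]; t1 <- brk[k + 1L]
    cnt <- sum(ed$start <= t0 & t0 < ed$end)
    key <- as.character(cnt)
    out[key] <- (if (is.na(out[key])) 0 else out[key]) + (t1 - t0)
  }
  out[order(as.integer(names(out)))]
}
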