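# Genealogy data structures: pruning, obscuring, lineage counts,
# saturation, compatibility, the binomial ratio, coalescent intervals.

hand_tree <- function() {
  ## 3 extant tips, 1 sample: root -> b1(t=1) branches; left child subtree
  ## has a birth b2(t=2) whose one branch ends in a sample (t=3), the rest
  ## are tips at the horizon 4; single deme
  nd <- data.frame(
    id     = 1:8,
    time   = c(0, 1, 2, 3, 4, 4, 4, 3.5),
    kind   = c("root", "internal", "internal", "sample", "tip", "tip", "tip", "internal"),
    deme   = c(NA, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    parent = c(NA, 1L, 2L, 3L, 3L, 8L, 2L, NA),
    label  = c(NA, NA, NA, "s1", NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  ## node 8: a second root-lineage... keep a single root: re-parent 8
  nd$parent[8] <- 2L; nd$kind[8] <- "internal"
  genfilter:::new_genealogy(nd, 4, "pop")
}

test_that("prune keeps exactly the sample-spanning subtree and is idempotent", {
  g <- hand_tree()
  p <- prune(g)
  expect_s3_class(p, "pruned_genealogy")
  ## only root -> b1 -> b2 -> s1 path survives; b1 and b2 become inline
  expect_setequal(p$nodes$id, c(1L, 2L, 3L, 4L))
  expect_true(all(p$nodes$kind != "tip"))
  leaves <- p$nodes$id[!(p$nodes$id %in% p$nodes$parent)]
  expect_true(all(p$nodes$kind[match(leaves, p$nodes$id)] == "sample"))
  p2 <- prune(p)
  expect_identical(p2$nodes, p$nodes)

  ## no samples -> empty pruned genealogy
  g0 <- g; g0$nodes$kind[g0$nodes$kind == "sample"] <- "tip"
  expect_identical(nrow(prune(g0)$nodes), 0L)
})

test_that("obscure erases demes and splices every non-sample unifurcation", {
  m <- seirs_small()
  sim <- simulate_genealogy(m, 3, seed = 5)
  p <- prune(sim$genealogy)
  z <- obscure(p)
  expect_true(all(is.na(z$nodes$deme)))
  nch <- genfilter:::n_children(z)
  expect_false(any(z$nodes$kind == "internal" & nch == 1L))
  ## node count = samples + branch points + roots
  expect_identical(nrow(z$nodes),
                   sum(z$nodes$kind == "sample") + sum(nch >= 2L & z$nodes$kind != "sample") +
                     sum(is.na(z$nodes$parent) & nch < 2L))
  ## obscuring is invariant to recoloring
  p_recolored <- p
  p_recolored$nodes$deme <- rev(p_recolored$nodes$deme)
  z2 <- obscure(p_recolored)
  expect_identical(z$nodes[c("id", "time", "kind", "parent")],
                   z2$nodes[c("id", "time", "kind", "parent")])
})

test_that("lineage count follows the right-continuous edge convention", {
  p <- genfilter:::worked_example_tree()
  ## branch at 1 (blue), migration inline at 1.5 (blue->yellow),
  ## samples at 2.2 (yellow) and 2.5 (blue)
  expect_identical(lineage_count(p, 0.5), c(1L, 0L))
  expect_identical(lineage_count(p, 1), c(2L, 0L))      # post-branch
  expect_identical(lineage_count(p, 1.5), c(1L, 1L))    # post-migration
  expect_identical(lineage_count(p, 2.2), c(1L, 0L))    # sample vanished
  expect_identical(lineage_count(p, 2.5), c(0L, 0L))
  expect_error(lineage_count(p, 5), "outside")

  ## interval-stabbing brute force on a simulated two-deme tree
  sim <- simulate_genealogy(seirs_small(), 3, seed = 8)
  ps <- prune(sim$genealogy)
  ed <- genfilter:::edge_table(ps)
  for (t in c(0.3, 0.9, 1.7, 2.6)) {
    brute <- vapply(1:2, function(d)
      sum(ed$deme == d & ed$start <= t & t < ed$end), integer(1))
    expect_identical(lineage_count(ps, t), brute)
  }
})

test_that("saturation counts emergent lineages per deme", {
  p <- genfilter:::worked_example_tree()
  expect_identical(saturation(p, 1), c(2L, 0L))    # binary branch, both blue
  expect_identical(saturation(p, 1.5), c(0L, 1L))  # migration inline, yellow out
  expect_identical(saturation(p, 2.2), c(0L, 0L))  # terminal sample
  expect_identical(saturation(p, 0.77), c(0L, 0L)) # not a node time
})

test_that("compatibility implements the local-structure rule table", {
  m <- seirs_small()
  sim <- simulate_genealogy(m, 3, seed = 5)
  p <- prune(sim$genealogy)
  nd <- p$nodes
  nch <- genfilter:::n_children(p)
  branch_t <- nd$time[nd$kind == "internal" & nch >= 2L][1]
  sample_t <- nd$time[nd$kind == "sample"][1]
  expect_false(is.na(branch_t))
  ## a branch point is compatible only with birth-type marks
  expect_identical(compatibility(m$marks$Trans, p, branch_t), 1L)
  expect_identical(compatibility(m$marks$Recov, p, branch_t), 0L)
  expect_identical(compatibility(m$marks$Prog, p, branch_t), 0L)
  ## samples are in deme I; the sampling mark matches, others do not
  expect_identical(compatibility(m$marks$Sample, p, sample_t), 1L)
  expect_identical(compatibility(m$marks$Recov, p, sample_t), 0L)
  ## between events, marks without a sampling component are compatible
  t_free <- branch_t + min(diff(sort(unique(nd$time)))) / 2
  expect_identical(compatibility(m$marks$Recov, p, t_free), 1L)
  expect_identical(compatibility(m$marks$Wane, p, t_free), 1L)
  expect_identical(compatibility(m$marks$Sample, p, t_free), 0L)
  ## an E->I color change matches the progression mark
  wt <- genfilter:::worked_example_tree()
  mig <- jump_mark("Prog", function(t, x) 1, identity, 2,
                   migr_from = 1L, migr_to = c(0L, 1L))
  expect_identical(compatibility(mig, wt, 1.5), 1L)
  mig_back <- jump_mark("Back", function(t, x) 1, identity, 2,
                        migr_from = 2L, migr_to = c(1L, 0L))
  expect_identical(compatibility(mig_back, wt, 1.5), 0L)
})

test_that("binomial ratio matches hand values and degenerate branches", {
  expect_equal(binomial_ratio(5, 2, 2, 2), 0.1)        # C(3,0)/C(5,2)
  expect_equal(binomial_ratio(c(4, 7), c(1, 2), c(0, 0), c(0, 0)), 1)
  expect_equal(binomial_ratio(4, 2, 1, 2), 0)          # s > r
  expect_equal(binomial_ratio(3, 4, 1, 0), 0)          # l > n
  expect_equal(binomial_ratio(4, 2, 2, 2), 1 / 6)
  ## large-occupancy log-space path agrees with direct computation
  expect_equal(binomial_ratio(50, 3, 2, 1),
               choose(47, 1) / choose(50, 2))
})

test_that("Chu-Vandermonde normalization holds exactly", {
  ## sum_s ratio(n,l,r,s) * prod_i C(l_i, s_i) == 1, in integer arithmetic
  set.seed(42)
  for (rep in 1:100) {
    K <- sample(1:3, 1)
    n <- sample(2:12, K, replace = TRUE)
    l <- vapply(n, function(ni) sample(0:ni, 1), integer(1))
    r <- vapply(n, function(ni) sample(0:ni, 1), integer(1))
    svals <- genfilter:::lattice_box(pmin(r, l))
    total_num <- 0
    den <- prod(choose(n, r))
    for (row in seq_len(nrow(svals))) {
      s <- svals[row, ]
      total_num <- total_num +
        prod(choose(n - l, r - s)) * prod(choose(l, s))
    }
    expect_identical(total_num, den)
  }
})

test_that("event weights reproduce the Moran per-event factors", {
  mo <- builtin_model("moran", list(n = 4, mu = 1))
  z <- two_sample_tree(tb = 0.5, ts = 1)
  x <- mo$state0
  ## branch point with l = 2, production 2: 1/C(4,2)
  expect_equal(event_weight(mo, mo$marks$Event, x, z, 0.5), 1 / 6)
  ## saturation-0 weight away from nodes: C(2,2)/C(4,2)
  expect_equal(event_weight(mo, mo$marks$Event, x, z, 0.75), 1 / 6)
  ## incompatible event
  lb <- builtin_model("lbd", list(lambda = 1, mu = 1, psi = 0, x0 = 2))
  expect_equal(event_weight(lb, lb$marks$Death, c(X = 5), z, 0.5), 0)
})

test_that("coalescent intervals partition the tree span", {
  z <- two_sample_tree(tb = 0.5, ts = 1)
  ci <- coalescent_intervals(z)
  expect_equal(ci, c("1" = 0.5, "2" = 0.5))
  ## single lineage, no branch
  z1 <- read_newick("(s1:2);", horizon = 2)
  expect_equal(coalescent_intervals(z1), c("1" = 2))
  ## durations sum to the span on a simulated tree
  zz <- obscure(prune(simulate_genealogy(moran_serial_model(), 5, seed = 9)$genealogy))
  ci2 <- coalescent_intervals(zz)
  expect_equal(sum(ci2), max(zz$nodes$time) - min(zz$nodes$time))
})
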