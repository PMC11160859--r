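## Deterministic fixture corpus: simulated genealogies from the builtin
## model families plus hand-built worked-example trees, written as Newick
## plus event logs with a checksum manifest. Everything regenerates
## byte-identically from the same seed.

## hand-built two-deme pruned genealogy: a birth event at t=1 where a blue
## parent sires a yellow child (both branches sampled later), plus an
## inline migration; exercises branch, inline, and sample local structures
worked_example_tree <- function() {
  nd <- data.frame(
    id     = 1:5,
    time   = c(0, 1.0, 1.5, 2.2, 2.5),
    kind   = c("root", "internal", "internal", "sample", "sample"),
    deme   = c(NA, 1L, 1L, 2L, 1L),
    parent = c(NA, 1L, 2L, 3L, 2L),
    label  = c(NA, NA, NA, "s1", "s2"),
    stringsAsFactors = FALSE
  )
  new_genealogy(nd, 2.5, c("blue", "yellow"), "pruned_genealogy")
}

#' Generate the deterministic fixture corpus
#'
#' Writes, under `out_dir`: Moran genealogies with simultaneous and serial
#' sampling, linear birth-death genealogies at several parameter settings,
#' SEIRS colored and obscured genealogies at population sizes 10, 20, 30,
#' and a hand-built worked-example tree; each with a Newick file, an event
#' log (for simulated fixtures), and an md5 manifest.
#'
#' @param out_dir writable output directory (created if absent).
#' @param seed integer seed; the corpus is a deterministic function of it.
#' @return the manifest as a data frame (file, family, md5), invisibly
#'   written to `manifest.json`.
#' @export
generate_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  put <- function(fname, family, text) {
    path <- file.path(out_dir, fname)
    writeLines(text, path)
    entries[[length(entries) + 1L]] <<- data.frame(
      file = fname, family = family, md5 = unname(tools::md5sum(path)),
      stringsAsFactors = FALSE)
    path
  }
  sim_and_put <- function(model, horizon, s, stem, family) {
    sim <- simulate_genealogy(model, horizon, seed = s)
    p <- prune(sim$genealogy)
    put(paste0(stem, ".nwk"), family, write_newick(p))
    put(paste0(stem, "_obscured.nwk"), family, write_newick(obscure(p)))
    logpath <- file.path(out_dir, paste0(stem, "_events.tsv"))
    write_event_log(sim$history, logpath)
    entries[[length(entries) + 1L]] <<- data.frame(
      file = basename(logpath), family = family,
      md5 = unname(tools::md5sum(logpath)), stringsAsFactors = FALSE)
  }
  sim_and_put(builtin_model("moran", list(n = 10, mu = 1, psi = 0, n_end = 6)),
              3, seed + 1L, "moran_kingman", "moran")
  sim_and_put(builtin_model("moran", list(n = 10, mu = 1, psi = 0.5)),
              4, seed + 2L, "moran_serial", "moran")
  lbd_pars <- list(c(1, 0.5, 0.3, 0), c(1.5, 1, 0.5, 1), c(0.8, 0.2, 0.4, 0.5))
  for (i in seq_along(lbd_pars)) {
    pp <- lbd_pars[[i]]
    sim_and_put(builtin_model("lbd", list(lambda = pp[1], mu = pp[2], psi = pp[3],
                                          rho = pp[4], x0 = 3, xmax = 150)),
                3, seed + 10L + i, sprintf("lbd_%d", i), "lbd")
  }
  for (N in c(10, 20, 30)) {
    sim_and_put(builtin_model("seirs", list(N = N, beta = 2, sigma = 1,
                                            gamma = 0.7, psi = 0.3, omega = 0.1,
                                            E0 = 1, I0 = 1)),
                3, seed + 20L + N, sprintf("seirs_N%d", N), "seirs")
  }
  put("worked_example.nwk", "hand_built", write_newick(worked_example_tree()))
  manifest <- do.call(rbind, entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
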