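## Population models: a structured Markov jump process on a finite integer
## lattice, specified by a set of jump marks, a deme-occupancy function, and
## an initial state. Built-in compartmental examples cover the standard
## epidemic motifs (SIRS, SEIRS, two-strain competition, complex infection
## progression, superspreading) plus the Moran and linear birth-death
## processes that anchor the classical phylodynamic likelihoods.

#' Construct a population model
#'
#' @param name model label.
#' @param demes character vector of deme names.
#' @param compartments character vector naming the coordinates of the state
#'   vector.
#' @param marks list of [jump_mark()] objects.
#' @param occupancy function mapping a named state vector to the integer
#'   vector of per-deme lineage counts.
#' @param state0 named integer vector, the initial state (the initial
#'   distribution is a point mass at `state0`).
#' @param enumerate function of no arguments returning the full state-space
#'   matrix (one row per state, columns named as `compartments`), or `NULL`
#'   if the state space is not finitely enumerable. Filters require it.
#' @param scheduled optional list of scheduled deterministic-time events;
#'   each element is `list(time=, type="binomial_sample", deme=, prob=)`.
#'   `time = NA` means "at the horizon" (resolved when a horizon is known).
#' @param time_homogeneous logical; `TRUE` if no mark rate depends on time.
#'
#' @return an object of class `population_model`.
#' @export
population_model <- function(name, demes, compartments, marks, occupancy,
                             state0, enumerate = NULL, scheduled = list(),
                             time_homogeneous = TRUE) {
  stopifnot(is.character(demes), length(demes) >= 1L,
            all(vapply(marks, inherits, logical(1), "jump_mark")))
  names(marks) <- vapply(marks, `[[`, character(1), "name")
  state0 <- stats::setNames(as.integer(state0), compartments)
  structure(
    list(name = name, demes = demes, n_demes = length(demes),
         compartments = compartments, marks = marks, occupancy = occupancy,
         state0 = state0, enumerate = enumerate, scheduled = scheduled,
         time_homogeneous = time_homogeneous,
         cache = new.env(parent = emptyenv())),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population model '%s': %d demes (%s), %d marks (%s)>\n",
              x$name, x$n_demes, paste(x$demes, collapse = ","),
              length(x$marks), paste(names(x$marks), collapse = ",")))
  invisible(x)
}

#' Total jump rate of a model at a state
#'
#' Sum of all per-mark hazards at `(t, x)`.
#'
#' @param model a `population_model`.
#' @param t time.
#' @param x named state vector; defaults to the model's initial state.
#' @return a non-negative number.
#' @export
total_rate <- function(model, t = 0, x = model$state0) {
  sum(vapply(model$marks, function(m) m$rate(t, x), numeric(1)))
}

param_get <- function(params, nm, default = NULL, nonneg = TRUE) {
  if (!is.null(params[[nm]])) {
    v <- params[[nm]]
  } else if (!is.null(default)) {
    v <- default
  } else {
    stop(sprintf("missing parameter '%s'", nm))
  }
  if (nonneg && v < 0) stop(sprintf("parameter '%s' must be non-negative", nm))
  v
}

## All states reachable for a closed population of size N distributed over
## d compartments: compositions of N.
enumerate_closed <- function(N, compartments) {
  m <- compositions(N, length(compartments))
  colnames(m) <- compartments
  m
}

#' Built-in example models
#'
#' Constructs one of the package's example models. Available names:
#' \describe{
#'   \item{sirs}{single deme I; params `N, beta, gamma, psi, omega, I0`.}
#'   \item{seirs}{demes E, I; params `N, beta, sigma, gamma, psi, omega,
#'     E0, I0`. Five marks: transmission (birth), progression (migration),
#'     recovery (death), sampling (sample), waning (neutral).}
#'   \item{two_strain}{demes E1, E2, I1, I2; two pathogen strains competing
#'     for susceptibles; per-strain `beta, sigma, gamma, psi, omega`
#'     (suffix 1/2) plus `N, E1_0, E2_0, I1_0, I2_0`.}
#'   \item{progression}{demes E, IA, IS; asymptomatic (unobserved) and
#'     symptomatic infections, hospitalization (lineage leaves the demes)
#'     and hospital death; params `N, beta_a, beta_s, sigma_a, sigma_s,
#'     gamma_a, gamma_s, eta, delta_h, psi, E0`.}
#'   \item{superspreading}{demes E, IL, IH; low/high-transmission behavior
#'     with switching; params `N, beta_l, beta_h, sigma, f_h, eta_lh,
#'     eta_hl, gamma, psi, omega, E0`.}
#'   \item{moran}{single deme, constant population `n`; a rate-`mu` Poisson
#'     clock of compound birth/death events (one lineage dies, another
#'     sires one child, so the production is 2), plus optional serial
#'     sampling at total rate `psi`.}
#'   \item{lbd}{linear birth-death-sampling: per-capita rates `lambda, mu,
#'     psi`, binomial sampling with probability `rho` at the horizon,
#'     initial size `x0`, truncation bound `xmax`. An optional
#'     sample/death compound mark is enabled by `psi_fatal > 0`.}
#' }
#'
#' @param name model name (see above).
#' @param params named list of parameters.
#' @return a [population_model()].
#' @export
builtin_model <- function(name = c("sirs", "seirs", "two_strain", "progression",
                                   "superspreading", "moran", "lbd"),
                          params = list()) {
  name <- match.arg(name)
  switch(name,
    sirs = {
      N <- param_get(params, "N"); beta <- param_get(params, "beta")
      gamma <- param_get(params, "gamma"); psi <- param_get(params, "psi")
      omega <- param_get(params, "omega", 0); I0 <- param_get(params, "I0", 1)
      K <- 1L
      marks <- list(
        jump_mark("Trans", function(t, x) beta * x[["S"]] * x[["I"]] / N,
                  function(x) x + c(S = -1L, I = 1L, R = 0L), K,
                  parent_deme = 1L, offspring = 1L),
        jump_mark("Recov", function(t, x) gamma * x[["I"]],
                  function(x) x + c(S = 0L, I = -1L, R = 1L), K, deaths = 1L),
        jump_mark("Sample", function(t, x) psi * x[["I"]], identity, K,
                  sample_deme = 1L, n_samples = 1L),
        jump_mark("Wane", function(t, x) omega * x[["R"]],
                  function(x) x + c(S = 1L, I = 0L, R = -1L), K)
      )
      population_model("sirs", "I", c("S", "I", "R"), marks,
                       occupancy = function(x) x[["I"]],
                       state0 = c(S = N - I0, I = I0, R = 0),
                       enumerate = function() enumerate_closed(N, c("S", "I", "R")))
    },
    seirs = {
      N <- param_get(params, "N"); beta <- param_get(params, "beta")
      sigma <- param_get(params, "sigma"); gamma <- param_get(params, "gamma")
      psi <- param_get(params, "psi"); omega <- param_get(params, "omega", 0)
      E0 <- param_get(params, "E0", 0); I0 <- param_get(params, "I0", 1)
      K <- 2L
      marks <- list(
        jump_mark("Trans", function(t, x) beta * x[["S"]] * x[["I"]] / N,
                  function(x) x + c(S = -1L, E = 1L, I = 0L, R = 0L), K,
                  parent_deme = 2L, offspring = c(1L, 0L)),
        jump_mark("Prog", function(t, x) sigma * x[["E"]],
                  function(x) x + c(S = 0L, E = -1L, I = 1L, R = 0L), K,
                  migr_from = 1L, migr_to = c(0L, 1L)),
        jump_mark("Recov", function(t, x) gamma * x[["I"]],
                  function(x) x + c(S = 0L, E = 0L, I = -1L, R = 1L), K,
                  deaths = c(0L, 1L)),
        jump_mark("Sample", function(t, x) psi * x[["I"]], identity, K,
                  sample_deme = 2L, n_samples = 1L),
        jump_mark("Wane", function(t, x) omega * x[["R"]],
                  function(x) x + c(S = 1L, E = 0L, I = 0L, R = -1L), K)
      )
      population_model("seirs", c("E", "I"), c("S", "E", "I", "R"), marks,
                       occupancy = function(x) c(x[["E"]], x[["I"]]),
                       state0 = c(S = N - E0 - I0, E = E0, I = I0, R = 0),
                       enumerate = function() enumerate_closed(N, c("S", "E", "I", "R")))
    },
    two_strain = {
      N <- param_get(params, "N")
      p <- function(nm, d = NULL) param_get(params, nm, d)
      cmp <- c("S", "E1", "E2", "I1", "I2", "R1", "R2")
      K <- 4L  # demes E1 E2 I1 I2
      mk_strain <- function(i) {
        Ei <- paste0("E", i); Ii <- paste0("I", i); Ri <- paste0("R", i)
        ed <- i; id <- 2L + i
        beta <- p(paste0("beta", i)); sigma <- p(paste0("sigma", i))
        gamma <- p(paste0("gamma", i)); psi <- p(paste0("psi", i))
        omega <- p(paste0("omega", i), 0)
        shift <- function(from, to) {
          force(from); force(to)
          function(x) { x[from] <- x[from] - 1L; x[to] <- x[to] + 1L; x }
        }
        list(
          jump_mark(paste0("Trans", i),
                    local({ b <- beta; ii <- Ii; function(t, x) b * x[["S"]] * x[[ii]] / N }),
                    shift("S", Ei), K, parent_deme = id,
                    offspring = as.integer(seq_len(K) == ed)),
          jump_mark(paste0("Prog", i),
                    local({ s <- sigma; ee <- Ei; function(t, x) s * x[[ee]] }),
                    shift(Ei, Ii), K, migr_from = ed,
                    migr_to = as.integer(seq_len(K) == id)),
          jump_mark(paste0("Recov", i),
                    local({ g <- gamma; ii <- Ii; function(t, x) g * x[[ii]] }),
                    shift(Ii, Ri), K, deaths = as.integer(seq_len(K) == id)),
          jump_mark(paste0("Sample", i),
                    local({ ps <- psi; ii <- Ii; function(t, x) ps * x[[ii]] }),
                    identity, K, sample_deme = id, n_samples = 1L),
          jump_mark(paste0("Wane", i),
                    local({ o <- omega; rr <- Ri; function(t, x) o * x[[rr]] }),
                    shift(Ri, "S"), K)
        )
      }
      marks <- c(mk_strain(1L), mk_strain(2L))
      st0 <- c(S = N, E1 = p("E1_0", 0), E2 = p("E2_0", 0),
               I1 = p("I1_0", 1), I2 = p("I2_0", 1), R1 = 0, R2 = 0)
      st0[["S"]] <- N - sum(st0[-1L])
      population_model("two_strain", c("E1", "E2", "I1", "I2"), cmp, marks,
                       occupancy = function(x) c(x[["E1"]], x[["E2"]], x[["I1"]], x[["I2"]]),
                       state0 = st0,
                       enumerate = function() enumerate_closed(N, cmp))
    },
    progression = {
      N <- param_get(params, "N")
      p <- function(nm, d = NULL) param_get(params, nm, d)
      cmp <- c("S", "E", "IA", "IS", "H", "R", "D")
      K <- 3L  # demes E IA IS
      shift <- function(from, to) {
        force(from); force(to)
        function(x) { x[from] <- x[from] - 1L; x[to] <- x[to] + 1L; x }
      }
      marks <- list(
        jump_mark("TransA", function(t, x) p("beta_a") * x[["S"]] * x[["IA"]] / N,
                  shift("S", "E"), K, parent_deme = 2L, offspring = c(1L, 0L, 0L)),
        jump_mark("TransS", function(t, x) p("beta_s") * x[["S"]] * x[["IS"]] / N,
                  shift("S", "E"), K, parent_deme = 3L, offspring = c(1L, 0L, 0L)),
        jump_mark("ProgA", function(t, x) p("sigma_a") * x[["E"]],
                  shift("E", "IA"), K, migr_from = 1L, migr_to = c(0L, 1L, 0L)),
        jump_mark("ProgS", function(t, x) p("sigma_s") * x[["E"]],
                  shift("E", "IS"), K, migr_from = 1L, migr_to = c(0L, 0L, 1L)),
        jump_mark("RecovA", function(t, x) p("gamma_a") * x[["IA"]],
                  shift("IA", "R"), K, deaths = c(0L, 1L, 0L)),
        jump_mark("RecovS", function(t, x) p("gamma_s") * x[["IS"]],
                  shift("IS", "R"), K, deaths = c(0L, 0L, 1L)),
        jump_mark("Hosp", function(t, x) p("eta") * x[["IS"]],
                  shift("IS", "H"), K, deaths = c(0L, 0L, 1L)),
        jump_mark("DeathH", function(t, x) p("delta_h") * x[["H"]],
                  shift("H", "D"), K),
        jump_mark("SampleS", function(t, x) p("psi") * x[["IS"]],
                  identity, K, sample_deme = 3L, n_samples = 1L)
      )
      E0 <- p("E0", 1)
      population_model("progression", c("E", "IA", "IS"), cmp, marks,
                       occupancy = function(x) c(x[["E"]], x[["IA"]], x[["IS"]]),
                       state0 = c(S = N - E0, E = E0, IA = 0, IS = 0, H = 0, R = 0, D = 0),
                       enumerate = function() enumerate_closed(N, cmp))
    },
    superspreading = {
      N <- param_get(params, "N")
      p <- function(nm, d = NULL) param_get(params, nm, d)
      cmp <- c("S", "E", "IL", "IH", "R")
      K <- 3L  # demes E IL IH
      shift <- function(from, to) {
        force(from); force(to)
        function(x) { x[from] <- x[from] - 1L; x[to] <- x[to] + 1L; x }
      }
      fh <- p("f_h", 0.5); if (fh > 1) stop("f_h must lie in [0,1]")
      marks <- list(
        jump_mark("TransL", function(t, x) p("beta_l") * x[["S"]] * x[["IL"]] / N,
                  shift("S", "E"), K, parent_deme = 2L, offspring = c(1L, 0L, 0L)),
        jump_mark("TransH", function(t, x) p("beta_h") * x[["S"]] * x[["IH"]] / N,
                  shift("S", "E"), K, parent_deme = 3L, offspring = c(1L, 0L, 0L)),
        jump_mark("ProgL", function(t, x) p("sigma") * (1 - fh) * x[["E"]],
                  shift("E", "IL"), K, migr_from = 1L, migr_to = c(0L, 1L, 0L)),
        jump_mark("ProgH", function(t, x) p("sigma") * fh * x[["E"]],
                  shift("E", "IH"), K, migr_from = 1L, migr_to = c(0L, 0L, 1L)),
        jump_mark("SwitchLH", function(t, x) p("eta_lh") * x[["IL"]],
                  shift("IL", "IH"), K, migr_from = 2L, migr_to = c(0L, 0L, 1L)),
        jump_mark("SwitchHL", function(t, x) p("eta_hl") * x[["IH"]],
                  shift("IH", "IL"), K, migr_from = 3L, migr_to = c(0L, 1L, 0L)),
        jump_mark("RecovL", function(t, x) p("gamma") * x[["IL"]],
                  shift("IL", "R"), K, deaths = c(0L, 1L, 0L)),
        jump_mark("RecovH", function(t, x) p("gamma") * x[["IH"]],
                  shift("IH", "R"), K, deaths = c(0L, 0L, 1L)),
        jump_mark("SampleL", function(t, x) p("psi") * x[["IL"]],
                  identity, K, sample_deme = 2L, n_samples = 1L),
        jump_mark("SampleH", function(t, x) p("psi") * x[["IH"]],
                  identity, K, sample_deme = 3L, n_samples = 1L),
        jump_mark("Wane", function(t, x) p("omega", 0) * x[["R"]],
                  shift("R", "S"), K)
      )
      E0 <- p("E0", 1)
      population_model("superspreading", c("E", "IL", "IH"), cmp, marks,
                       occupancy = function(x) c(x[["E"]], x[["IL"]], x[["IH"]]),
                       state0 = c(S = N - E0, E = E0, IL = 0, IH = 0, R = 0),
                       enumerate = function() enumerate_closed(N, cmp))
    },
    moran = {
      n <- param_get(params, "n"); mu <- param_get(params, "mu")
      psi <- param_get(params, "psi", 0)
      n_end <- param_get(params, "n_end", 0)
      if (n < 1) stop("moran population size n must be positive")
      if (n_end > n) stop("cannot sample more lineages at the horizon than exist")
      K <- 1L
      marks <- list(
        jump_mark("Event", function(t, x) mu, identity, K,
                  parent_deme = 1L, offspring = 1L, deaths = 1L),
        jump_mark("Sample", function(t, x) psi, identity, K,
                  sample_deme = 1L, n_samples = 1L)
      )
      sched <- if (n_end > 0)
        list(list(time = NA_real_, type = "fixed_sample", deme = 1L,
                  count = as.integer(n_end)))
      else list()
      population_model("moran", "pop", "dummy", marks,
                       occupancy = function(x) n,
                       state0 = c(dummy = 0),
                       enumerate = function() matrix(0L, 1L, 1L,
                         dimnames = list(NULL, "dummy")),
                       scheduled = sched)
    },
    lbd = {
      lambda <- param_get(params, "lambda"); mu <- param_get(params, "mu")
      psi <- param_get(params, "psi"); rho <- param_get(params, "rho", 0)
      psi_fatal <- param_get(params, "psi_fatal", 0)
      x0 <- param_get(params, "x0", 1); xmax <- param_get(params, "xmax", 200)
      if (rho < 0 || rho > 1) stop("rho must lie in [0,1]")
      K <- 1L
      marks <- list(
        jump_mark("Birth", function(t, x) lambda * x[["X"]],
                  function(x) x + c(X = 1L), K, parent_deme = 1L, offspring = 1L),
        jump_mark("Death", function(t, x) mu * x[["X"]],
                  function(x) x + c(X = -1L), K, deaths = 1L),
        jump_mark("Sample", function(t, x) psi * x[["X"]], identity, K,
                  sample_deme = 1L, n_samples = 1L)
      )
      if (psi_fatal > 0)
        marks <- c(marks, list(
          jump_mark("SampleDeath", function(t, x) psi_fatal * x[["X"]],
                    function(x) x + c(X = -1L), K,
                    sample_deme = 1L, n_samples = 1L, sample_survives = FALSE)))
      sched <- if (rho > 0)
        list(list(time = NA_real_, type = "binomial_sample", deme = 1L, prob = rho))
      else list()
      population_model("lbd", "pop", "X", marks,
                       occupancy = function(x) x[["X"]],
                       state0 = c(X = x0),
                       enumerate = function() matrix(0:xmax, ncol = 1L,
                         dimnames = list(NULL, "X")),
                       scheduled = sched)
    }
  )
}

#' Validate the internal consistency of a population model
#'
#' Checks the mark and model invariants on a sampled grid of states: rates
#' are finite and non-negative, occupancy is non-negative, the occupancy
#' change across each mark's state update matches the participants implied
#' by the mark (offspring added, deaths and migrations moved), and no mark
#' with positive rate drives a compartment negative.
#'
#' @param model a `population_model`.
#' @param times time points at which to evaluate rates.
#' @param n_states maximum number of states to probe (sampled
#'   deterministically from the enumeration when available).
#' @return a character vector of violations; empty if all checks pass.
#' @export
validate_model <- function(model, times = c(0, 1), n_states = 200L) {
  bad <- character(0)
  states <- if (is.null(model$enumerate)) {
    matrix(model$state0, nrow = 1L, dimnames = list(NULL, model$compartments))
  } else model$enumerate()
  if (nrow(states) > n_states)
    states <- states[round(seq(1L, nrow(states), length.out = n_states)), , drop = FALSE]
  K <- model$n_demes
  for (i in seq_len(nrow(states))) {
    x <- stats::setNames(as.integer(states[i, ]), model$compartments)
    occ <- model$occupancy(x)
    if (length(occ) != K || any(occ < 0)) {
      bad <- c(bad, sprintf("occupancy invalid at state (%s)", paste(x, collapse = ",")))
      next
    }
    for (m in model$marks) {
      for (t in times) {
        rt <- m$rate(t, x)
        if (!is.finite(rt) || rt < 0) {
          bad <- c(bad, sprintf("mark %s has invalid rate at t=%g, state (%s)",
                                m$name, t, paste(x, collapse = ",")))
        }
      }
      x2 <- m$jump(x)
      rt0 <- m$rate(times[1], x)
      if (any(x2 < 0) && rt0 > 0) {
        bad <- c(bad, sprintf("mark %s drives a compartment negative at state (%s)",
                              m$name, paste(x, collapse = ",")))
        next
      }
      occ2 <- model$occupancy(x2)
      expected <- m$offspring + m$migr_to - m$deaths
      if (!is.na(m$migr_from))
        expected[m$migr_from] <- expected[m$migr_from] - sum(m$migr_to)
      if (!m$sample_survives) expected <- expected - m$samples
      if (rt0 > 0 && all(x2 >= 0) && any(occ2 - occ != expected)) {
        bad <- c(bad, sprintf(
          "mark %s: occupancy change (%s) inconsistent with participants (%s) at state (%s)",
          m$name, paste(occ2 - occ, collapse = ","),
          paste(expected, collapse = ","), paste(x, collapse = ",")))
      }
    }
  }
  unique(bad)
}
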