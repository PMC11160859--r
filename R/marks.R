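## Jump marks: the labeled jump categories of a structured population model.
##
## A mark bundles (i) a hazard function on (time, state), (ii) the
## deterministic effect of one jump on the population state, and (iii) a
## genealogical action descriptor: which lineages take part as parent,
## offspring, migrants, samples, or deaths. The per-deme production (the
## number of lineages emerging from a node inserted at an event of this
## mark) is computed once from the descriptor and is constant by
## construction, as the theory requires.

#' Construct a jump mark
#'
#' @param name mark label.
#' @param rate function of `(t, x)` returning the non-negative hazard of
#'   this mark when the population is in state `x` (a named integer vector)
#'   at time `t`.
#' @param jump function of `x` returning the post-jump state. Defaults to
#'   the identity (state-preserving events such as pure sampling).
#' @param n_demes number of demes in the host model.
#' @param parent_deme deme index of the parent lineage for birth-type
#'   events, or `NA` if the mark has no birth component. All offspring of
#'   one event share this single parent, which survives the event.
#' @param offspring integer vector (length `n_demes`): number of new
#'   lineages created in each deme at one event.
#' @param migr_from source deme index for migration-type events (`NA` if
#'   none). All migrating lineages at one event leave this deme.
#' @param migr_to integer vector (length `n_demes`): number of migrating
#'   lineages arriving in each deme.
#' @param sample_deme deme index in which lineages are sampled (`NA` if the
#'   mark has no sampling component); all lineages sampled at one event
#'   share this deme.
#' @param n_samples number of lineages sampled at one event.
#' @param samples alternative to `sample_deme`/`n_samples`: a per-deme
#'   integer vector of simultaneous sample counts. The emergent-lineage
#'   production rule handles several demes; the simulator and filters
#'   support sampling in a single deme per mark.
#' @param sample_survives logical; if `FALSE` the sampled lineages are
#'   removed at the event (sample/death compound), so they do not emerge.
#' @param deaths integer vector (length `n_demes`): number of lineages
#'   (other than unsampled-killed ones) extinguished at one event.
#'
#' @return an object of class `jump_mark` with fields `production` (the
#'   per-deme emergent-lineage count) and `event_class` (one of `birth`,
#'   `death`, `migration`, `sample`, `neutral`, `compound`).
#' @export
jump_mark <- function(name, rate, jump = identity, n_demes,
                      parent_deme = NA_integer_,
                      offspring = integer(n_demes),
                      migr_from = NA_integer_,
                      migr_to = integer(n_demes),
                      sample_deme = NA_integer_,
                      n_samples = 0L,
                      samples = NULL,
                      sample_survives = TRUE,
                      deaths = integer(n_demes)) {
  stopifnot(is.function(rate), is.function(jump), n_demes >= 1L)
  offspring <- as.integer(offspring); migr_to <- as.integer(migr_to)
  deaths <- as.integer(deaths)
  if (is.null(samples)) {
    samples <- integer(n_demes)
    if (n_samples > 0L) {
      if (is.na(sample_deme)) stop("sample-type marks need a sampling deme")
      samples[sample_deme] <- as.integer(n_samples)
    }
  }
  samples <- as.integer(samples)
  stopifnot(length(offspring) == n_demes, length(migr_to) == n_demes,
            length(deaths) == n_demes, length(samples) == n_demes)
  if (any(offspring < 0L) || any(migr_to < 0L) || any(deaths < 0L) || any(samples < 0L))
    stop("participant counts must be non-negative")
  if (sum(offspring) > 0L && is.na(parent_deme))
    stop("birth-type marks need exactly one parent deme")
  if (!is.na(parent_deme) && sum(offspring) == 0L)
    stop("a parent deme was given but there are no offspring")
  if (sum(migr_to) > 0L && is.na(migr_from))
    stop("migration-type marks need a source deme")
  n_samples <- sum(samples)
  sample_deme <- if (sum(samples > 0L) == 1L) which(samples > 0L) else NA_integer_

  ## emergent lineages: offspring, migrants at their destinations, the
  ## surviving parent, surviving sampled lineages; dying lineages never count
  production <- offspring + migr_to
  if (!is.na(parent_deme)) production[parent_deme] <- production[parent_deme] + 1L
  if (sample_survives) production <- production + samples

  comps <- c(
    birth     = !is.na(parent_deme),
    death     = sum(deaths) > 0L || (n_samples > 0L && !sample_survives),
    migration = !is.na(migr_from),
    sample    = n_samples > 0L
  )
  event_class <- if (!any(comps)) "neutral"
    else if (sum(comps) > 1L) "compound"
    else names(comps)[comps]

  structure(
    list(name = name, rate = rate, jump = jump, n_demes = n_demes,
         parent_deme = parent_deme, offspring = offspring,
         migr_from = migr_from, migr_to = migr_to,
         sample_deme = sample_deme, n_samples = n_samples, samples = samples,
         sample_survives = sample_survives, deaths = deaths,
         production = as.integer(production), event_class = event_class),
    class = "jump_mark"
  )
}

#' @export
print.jump_mark <- function(x, ...) {
  cat(sprintf("<jump mark '%s' (%s), production (%s)>\n",
              x$name, x$event_class, paste(x$production, collapse = ",")))
  invisible(x)
}

#' Per-deme production of a jump mark
#'
#' The production of a mark is the number of lineages, per deme, that
#' emerge from (descend from a node inserted at) one event of that mark:
#' all offspring, all migrants in their destination demes, surviving
#' sampled lineages, and the surviving parent. Dying lineages do not count.
#'
#' @param mark a `jump_mark`.
#' @return integer vector, one entry per deme.
#' @export
production <- function(mark) {
  stopifnot(inherits(mark, "jump_mark"))
  mark$production
}
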