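## Newick I/O for (pruned and obscured) genealogies. Dialect: one tree per
## line, forests as multiple lines; node times are absolute, anchored by
## giving every root branch length equal to its time (0); demes, when
## known, are carried as `[&deme=NAME]` annotations; inline nodes appear as
## unifurcations. Sample nodes are the labelled nodes (`s1`, `s2`, ...).

fmt_num <- function(x) sprintf("%.12g", x)

#' Serialize a genealogy to Newick
#'
#' @param g a genealogy (pruned, obscured, or unpruned). Tips are written
#'   with `tip_`-prefixed labels; sample labels are written verbatim; demes
#'   (when present) as `[&deme=NAME]` annotations.
#' @return a single string, one tree per line (empty string for an empty
#'   forest).
#' @export
write_newick <- function(g) {
  nd <- g$nodes
  if (nrow(nd) == 0) return("")
  kids <- split(seq_len(nrow(nd)), factor(nd$parent, levels = nd$id))
  demes <- g$demes
  rec <- function(i) {
    ch <- kids[[as.character(nd$id[i])]]
    lab <- nd$label[i]
    if (is.na(lab) || lab == "")
      lab <- if (nd$kind[i] == "tip") paste0("tip_", nd$id[i]) else ""
    ann <- if (!is.na(nd$deme[i]) && length(demes) > 0)
      sprintf("[&deme=%s]", demes[nd$deme[i]]) else ""
    ptime <- if (is.na(nd$parent[i])) 0 else nd$time[match(nd$parent[i], nd$id)]
    blen <- fmt_num(nd$time[i] - ptime)
    core <- if (is.null(ch) || length(ch) == 0) lab
      else paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")", lab)
    paste0(core, ann, ":", blen)
  }
  roots <- which(is.na(nd$parent))
  paste(vapply(roots, function(i) paste0(rec(i), ";"), character(1)),
        collapse = "\n")
}

#' Parse a Newick forest into a genealogy
#'
#' Reads the package's dialect (see [write_newick()]): absolute times
#' reconstructed from cumulative branch lengths with roots at time 0,
#' optional `[&deme=NAME]` annotations, unifurcations allowed. Leaves and
#' labelled nodes are classified as samples (labels starting `tip_` as
#' tips); the topmost node of each line is a root.
#'
#' @param text Newick string (possibly multi-line) or path handled by the
#'   caller.
#' @param demes optional character vector fixing the deme index order; by
#'   default the sorted set of deme names seen in the annotations.
#' @param horizon optional genealogy horizon; defaults to the latest node
#'   time.
#' @return a `pruned_genealogy` when deme annotations are present, an
#'   `obscured_genealogy` otherwise.
#' @export
read_newick <- function(text, demes = NULL, horizon = NULL) {
  lines <- trimws(strsplit(text, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines)]
  acc <- new.env(parent = emptyenv())
  acc$id <- integer(0); acc$blen <- numeric(0); acc$label <- character(0)
  acc$deme_nm <- character(0); acc$parent <- integer(0); acc$nkid <- integer(0)
  acc$n <- 0L
  parse_tree <- function(s) {
    pos <- 1L
    nc <- nchar(s)
    peek <- function() substr(s, pos, pos)
    node <- function(parent) {
      acc$n <- acc$n + 1L
      me <- acc$n
      acc$id[me] <- me; acc$parent[me] <- parent
      acc$blen[me] <- 0; acc$label[me] <- ""
      acc$deme_nm[me] <- NA_character_; acc$nkid[me] <- 0L
      if (peek() == "(") {
        pos <<- pos + 1L
        repeat {
          node(me)
          acc$nkid[me] <- acc$nkid[me] + 1L
          if (peek() == ",") { pos <<- pos + 1L; next }
          if (peek() == ")") { pos <<- pos + 1L; break }
          stop("malformed Newick: expected ',' or ')'")
        }
      }
      ## label
      st <- pos
      while (pos <= nc && !(peek() %in% c(":", ",", ")", ";", "[")))
        pos <<- pos + 1L
      acc$label[me] <- substr(s, st, pos - 1L)
      ## annotation
      if (pos <= nc && peek() == "[") {
        close <- regexpr("]", substr(s, pos, nc), fixed = TRUE)
        if (close < 0) stop("malformed Newick: unterminated annotation")
        ann <- substr(s, pos, pos + close - 1L)
        m <- regmatches(ann, regexec("deme=([^],]+)", ann))[[1]]
        if (length(m) == 2L) acc$deme_nm[me] <- m[2]
        pos <<- pos + close
      }
      ## branch length
      if (pos <= nc && peek() == ":") {
        pos <<- pos + 1L
        st <- pos
        while (pos <= nc && grepl("[-0-9.eE+]", peek())) pos <<- pos + 1L
        acc$blen[me] <- as.numeric(substr(s, st, pos - 1L))
        if (is.na(acc$blen[me])) stop("malformed Newick: bad branch length")
        if (acc$blen[me] < 0) stop("negative branch length")
      }
      me
    }
    root <- node(NA_integer_)
    if (peek() != ";") stop("malformed Newick: expected ';'")
    root
  }
  for (ln in lines) parse_tree(ln)
  n <- acc$n
  if (n == 0L) {
    g <- new_genealogy(empty_nodes(), horizon %||% 0,
                       demes %||% character(0), "obscured_genealogy")
    return(g)
  }
  ## absolute times by cumulative branch lengths
  time <- numeric(n)
  for (i in seq_len(n)) {
    time[i] <- acc$blen[i] + if (is.na(acc$parent[i])) 0 else time[acc$parent[i]]
  }
  seen <- unique(acc$deme_nm[!is.na(acc$deme_nm)])
  colored <- length(seen) > 0
  if (colored) {
    if (is.null(demes)) demes <- sort(seen)
    if (!all(seen %in% demes)) stop("unknown deme name in annotations")
    deme <- match(acc$deme_nm, demes)
  } else {
    demes <- demes %||% character(0)
    deme <- rep(NA_integer_, n)
  }
  label <- acc$label
  kind <- ifelse(is.na(acc$parent), "root",
          ifelse(startsWith(label, "tip_"), "tip",
          ifelse(nzchar(label), "sample", "internal")))
  hz <- horizon %||% max(time)
  if (any(kind != "root" & time > hz)) stop("node time beyond the horizon")
  nd <- data.frame(id = seq_len(n), time = time, kind = kind, deme = deme,
                   parent = acc$parent, label = ifelse(nzchar(label), label, NA),
                   stringsAsFactors = FALSE)
  new_genealogy(nd, hz, demes,
                if (colored) "pruned_genealogy" else "obscured_genealogy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
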