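# Phase 4a: subsumption taxonomy over resilience indicators.
#
# Indicator x subsumes indicator y when the posts annotated with y are
# (approximately) contained in the posts annotated with x. Strict mode
# demands a proper subset; thresholded mode relaxes containment to a
# fraction t, the classical co-occurrence subsumption rule.

#' Invert annotations into per-indicator post sets
#'
#' @param annotated An `annotated_posts` data.frame (see [annotate()]).
#' @param indicators Indicator universe; indicators never assigned get an
#'   empty set.
#' @return Named list `indicator -> character vector of post ids`.
#' @export
collect_post_sets <- function(annotated, indicators = RESILIENCE_INDICATORS) {
  sets <- stats::setNames(vector("list", length(indicators)), indicators)
  for (ind in indicators) {
    hit <- vapply(annotated$indicators, function(s) ind %in% s, logical(1))
    sets[[ind]] <- annotated$post_id[hit]
  }
  sets
}

#' Infer the subsumption taxonomy
#'
#' For an ordered pair (x broader, y narrower), let `containment(y in x) =
#' |posts(y) & posts(x)| / |posts(y)|`. x is an ancestor candidate of y when
#' that containment reaches the threshold `t` and strictly exceeds the
#' reverse containment (ruling out equal sets, which produce no edge and are
#' logged). Each node's parent is its most specific subsumer — the candidate
#' with the smallest post set — and candidate-free nodes are roots. Strict
#' mode (`t = 1`) is the default: a proper-subset partial order, so the
#' result is always a forest; thresholded mode checks for cycles and errors
#' on the offending pair.
#'
#' @param sets Per-indicator post sets from [collect_post_sets()].
#' @param mode `"strict"` (subset, `t = 1`) or `"thresholded"`.
#' @param threshold Containment threshold `t` in (0, 1]; only used in
#'   thresholded mode (default 0.8 there).
#' @return `resilience_taxonomy`: `nodes`, `parent` (named character, `NA`
#'   for roots), `roots`, `containment` matrix (`containment[x, y]` =
#'   containment of y in x), `mode`, `threshold`.
#' @export
infer_taxonomy <- function(sets, mode = c("strict", "thresholded"),
                           threshold = if (mode[1] == "strict") 1 else 0.8) {
  mode <- match.arg(mode)
  t <- if (mode == "strict") 1 else threshold
  stopifnot(t > 0, t <= 1)
  nodes <- names(sets)
  nonempty <- nodes[lengths(sets) > 0L]
  if (length(nonempty) == 0L) stop("all indicator post sets are empty")

  # containment[x, y]: fraction of y's posts also in x
  cont <- matrix(NA_real_, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  for (x in nodes) for (y in nodes) {
    if (length(sets[[y]]) > 0L) {
      cont[x, y] <- length(intersect(sets[[x]], sets[[y]])) / length(sets[[y]])
    }
  }

  parent <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  for (y in nonempty) {
    cands <- character(0)
    for (x in setdiff(nonempty, y)) {
      fwd <- cont[x, y]   # y in x
      rev <- cont[y, x]   # x in y
      if (fwd >= t && rev < fwd) cands <- c(cands, x)
      if (x < y && !is.na(fwd) && !is.na(rev) && fwd >= t && rev >= t && fwd == rev) {
        message("indicators with identical post sets, no edge: ", x, " / ", y)
      }
    }
    if (length(cands)) {
      sizes <- lengths(sets[cands])
      parent[y] <- cands[order(sizes, cands)][1]
    }
  }

  # cycle check (relevant only under thresholded containment)
  for (start in nodes) {
    seen <- character(0); cur <- start
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) {
        stop("cycle in subsumption relation involving: ",
             paste(seen, collapse = " -> "))
      }
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }

  structure(list(nodes = nodes, parent = parent,
                 roots = nodes[is.na(parent)],
                 containment = cont, mode = mode, threshold = t),
            class = "resilience_taxonomy")
}

#' Indicator coverage for treemap export
#'
#' Relative size of each indicator's post set against the union of all
#' annotated posts; overlapping indicators can sum above one.
#'
#' @param sets Per-indicator post sets.
#' @return Named numeric vector of coverage fractions.
#' @export
coverage <- function(sets) {
  u <- unique(unlist(sets, use.names = FALSE))
  if (length(u) == 0L) stop("empty union: no annotated posts")
  vapply(sets, function(s) length(unique(s)) / length(u), numeric(1))
}

#' Export a taxonomy as JSON
#'
#' @param taxonomy A `resilience_taxonomy`.
#' @param path Output file.
#' @export
write_taxonomy_json <- function(taxonomy, path) {
  jsonlite::write_json(
    list(nodes = taxonomy$nodes,
         parent = as.list(taxonomy$parent),
         roots = taxonomy$roots,
         mode = taxonomy$mode,
         threshold = taxonomy$threshold,
         containment = as.data.frame(taxonomy$containment)),
    path, auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}

#' Export a taxonomy as Graphviz DOT
#'
#' @param taxonomy A `resilience_taxonomy`.
#' @param path Output file.
#' @export
write_taxonomy_dot <- function(taxonomy, path) {
  lines <- c("digraph resilience_taxonomy {")
  for (n in taxonomy$nodes) lines <- c(lines, sprintf('  "%s";', n))
  for (n in taxonomy$nodes) {
    p <- taxonomy$parent[[n]]
    if (!is.na(p)) lines <- c(lines, sprintf('  "%s" -> "%s";', p, n))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.resilience_taxonomy <- function(x, ...) {
  cat("Resilience taxonomy (", x$mode, " mode)\n", sep = "")
  for (r in x$roots) .print_tree(x, r, 0L)
  invisible(x)
}

.print_tree <- function(x, node, depth) {
  cat(strrep("  ", depth), "- ", node, "\n", sep = "")
  for (ch in x$nodes[!is.na(x$parent) & x$parent == node]) {
    .print_tree(x, ch, depth + 1L)
  }
}
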