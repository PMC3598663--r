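## Reaction-pathway DAG enumeration under a dechlorination rule set.

.emptyEdges <- function() {
  data.frame(substrate = character(0), product = character(0),
             ringIndex = integer(0), substrateRing = character(0),
             removed = integer(0), tag = character(0), weight = numeric(0))
}

#' Enumerate the dechlorination pathway graph
#'
#' Breadth-first closure of a start congener under single-step rule
#' application. Every edge removes exactly one chlorine, so the graph is a
#' DAG; nodes with no applicable rules are terminals. Node ordering is
#' deterministic: chlorine count descending, then name.
#'
#' @param start a \code{Congener} or congener name.
#' @param ruleset a \code{\linkS4class{ProcessRuleSet}}.
#' @param maxDepth maximum number of steps from the start (default
#'   unlimited; pathway graphs are bounded by the sub-patterns of the
#'   start's chlorines, at most 2^10 nodes).
#' @return a \code{\linkS4class{PathwayGraph}}.
#' @examples
#' pg <- enumeratePathways("2345-245-CB", builtinProcess("H"))
#' pathwayTerminals(pg)  # "235-25-CB" "25-25-CB"
#' @export
enumeratePathways <- function(start, ruleset, maxDepth = Inf) {
  cg <- .asCongener(start)
  cache_key <- if (is.infinite(maxDepth))
    paste0("pg|", cg@name, "|", .rulesetKey(ruleset)) else NULL
  if (!is.null(cache_key)) {
    hit <- .cacheGet(cache_key)
    if (!is.null(hit)) return(hit)
  }
  edges <- list()
  seen <- cg@name
  frontier <- list(cg)
  depth <- 0
  while (length(frontier) && depth < maxDepth) {
    nxt <- list()
    for (node in frontier) {
      apps <- applicableRules(node, ruleset)
      if (!nrow(apps)) next
      prods <- character(nrow(apps))
      for (i in seq_len(nrow(apps))) {
        prod <- applyRule(node, apps$ringIndex[i], apps$removed[i])
        prods[i] <- prod@name
        if (!prod@name %in% seen) {
          seen <- c(seen, prod@name)
          nxt[[length(nxt) + 1L]] <- prod
        }
      }
      apps$substrate <- NULL
      edges[[length(edges) + 1L]] <- cbind(
        data.frame(substrate = node@name, product = prods),
        data.frame(ringIndex = apps$ringIndex,
                   substrateRing = vapply(apps$ringIndex, function(ri)
                     .ringString(if (ri == 1) node@ringA else node@ringB),
                     character(1)),
                   removed = apps$removed, tag = apps$tag,
                   weight = apps$weight))
    }
    frontier <- nxt
    depth <- depth + 1
  }
  edf <- if (length(edges)) do.call(rbind, edges) else .emptyEdges()
  rownames(edf) <- NULL
  ncl <- vapply(seen, function(n) nChlorines(n), integer(1))
  nodes <- seen[order(-ncl, seen)]
  terminals <- setdiff(nodes, unique(edf$substrate))
  pg <- methods::new("PathwayGraph", start = cg@name, process = ruleset@name,
                     nodes = nodes, edges = edf, terminals = terminals)
  if (!is.null(cache_key)) .cacheSet(cache_key, pg)
  pg
}

#' @rdname enumeratePathways
#' @param x a \code{PathwayGraph}.
#' @export
pathwayNodes <- function(x) x@nodes

#' @rdname enumeratePathways
#' @export
pathwayEdges <- function(x) x@edges

#' @rdname enumeratePathways
#' @export
pathwayTerminals <- function(x) x@terminals

#' Terminal dechlorination products
#'
#' @param start start congener (object or name).
#' @param ruleset a \code{ProcessRuleSet}.
#' @return character vector of terminal congener names (the start itself if
#'   no rule applies).
#' @examples
#' terminalProducts("2345-245-CB", builtinProcess("N"))  # "24-24-CB"
#' @export
terminalProducts <- function(start, ruleset) {
  pathwayTerminals(enumeratePathways(start, ruleset))
}

.pathwayIgraph <- function(pg) {
  if (!nrow(pg@edges))
    return(igraph::make_empty_graph(n = 1) |>
             igraph::set_vertex_attr("name", value = pg@start))
  el <- unique(pg@edges[, c("substrate", "product")])
  igraph::graph_from_data_frame(el, directed = TRUE,
                                vertices = data.frame(name = pg@nodes))
}

#' Reachability with witness path
#'
#' Tests whether one congener can be converted to another under a rule set,
#' and if so returns one shortest sequence of intermediates. Path length is
#' exactly the chlorine-count difference (every step removes one chlorine),
#' which also caps the search depth automatically.
#'
#' @param from,to congeners (objects or names).
#' @param ruleset a \code{ProcessRuleSet}.
#' @param maxDepth optional step cap (defaults to the chlorine-count
#'   difference).
#' @return list with \code{reachable} (logical) and \code{path} (character
#'   vector from \code{from} to \code{to}; empty when unreachable).
#' @examples
#' reachable("245-245-CB", "25-25-CB", builtinProcess("H"))
#' @export
reachable <- function(from, to, ruleset, maxDepth = NULL) {
  f <- .asCongener(from); t_ <- .asCongener(to)
  if (f@name == t_@name)
    return(list(reachable = TRUE, path = f@name))
  dCl <- f@nChlorines - t_@nChlorines
  if (dCl <= 0) return(list(reachable = FALSE, path = character(0)))
  ## Depth in the pathway DAG equals chlorines removed, so the target, if
  ## reachable at all, sits at depth exactly dCl; the full (cached) closure
  ## answers any capped query at or beyond that depth.
  pg <- if (is.null(maxDepth) || maxDepth >= dCl)
    enumeratePathways(f, ruleset)
  else return(list(reachable = FALSE, path = character(0)))
  if (!t_@name %in% pg@nodes)
    return(list(reachable = FALSE, path = character(0)))
  g <- .pathwayIgraph(pg)
  sp <- igraph::shortest_paths(g, from = f@name, to = t_@name,
                               mode = "out")$vpath[[1]]
  list(reachable = TRUE, path = names(sp))
}

#' Export a pathway graph in DOT format
#'
#' @param pg a \code{PathwayGraph}.
#' @return character vector of DOT lines, suitable for
#'   \code{writeLines()} and Graphviz rendering.
#' @export
pathwayToDot <- function(pg) {
  e <- pg@edges
  c(sprintf("digraph \"%s under %s\" {", pg@start, pg@process),
    sprintf("  \"%s\" [shape=box];", pg@terminals),
    if (nrow(e)) sprintf("  \"%s\" -> \"%s\" [label=\"-%d (%s)\"];",
                         e$substrate, e$product, e$removed, e$tag),
    "}")
}

setMethod("show", "PathwayGraph", function(object) {
  cat(sprintf("Dechlorination pathway of %s under process %s\n",
              object@start, object@process))
  cat(sprintf("  %d congeners, %d rule applications\n",
              length(object@nodes), nrow(object@edges)))
  cat("  terminals:", paste(object@terminals, collapse = ", "), "\n")
})
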