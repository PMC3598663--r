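## Declarative dechlorination rule sets and single-step rule application.

.makeRules <- function(substrate, removed, tag, weight = 1) {
  product <- mapply(function(s, p) {
    .ringString(canonicalizeRing(setdiff(.ringFromString(s), p)))
  }, substrate, removed, USE.NAMES = FALSE)
  data.frame(substrate = substrate, removed = as.integer(removed),
             product = product, tag = tag,
             weight = rep_len(weight, length(substrate)),
             stringsAsFactors = FALSE)
}

#' Built-in dechlorination process rule sets
#'
#' Returns the evidenced rule set for one of the dechlorination patterns
#' observed in sediment-free Aroclor 1260 cultures:
#' \describe{
#'   \item{H}{removes flanked para- and doubly flanked meta-chlorines from
#'     34-, 234-, 245- and 2345-chlorophenyl rings.}
#'   \item{N}{removes flanked meta-chlorines (any meta chlorine with at
#'     least one chlorinated neighbour); available in strict form (the
#'     evidenced transformations on 234/235/236/245/2345 rings) or generic
#'     form (the structural predicate itself).}
#'   \item{T}{removes only the doubly flanked meta-chlorine of
#'     2345-chlorophenyl rings.}
#'   \item{CG1}{doubly flanked meta removal from 234- and 2345-rings, plus
#'     partial para (2345 -> 235) and partial ortho (234 -> 34) removal;
#'     the partial rules carry weight 0.2 so kinetic simulation treats them
#'     as minor routes.}
#' }
#'
#' @param name one of \code{"H"}, \code{"N"}, \code{"T"}, \code{"CG1"}.
#' @param mode \code{"strict"} (default; only the evidenced, listed
#'   transformations) or \code{"generic"} (structural predicate; currently
#'   defined only for N). Strict is the default because generic predicates
#'   over-generate: the H evidence never shows 234 -> 23, which a generic
#'   flanked-para predicate would allow.
#' @return a \code{\linkS4class{ProcessRuleSet}}.
#' @examples
#' builtinProcess("H")
#' builtinProcess("N", mode = "generic")
#' @export
builtinProcess <- function(name, mode = c("strict", "generic")) {
  mode <- match.arg(mode)
  name <- match.arg(name, c("H", "N", "T", "CG1"))
  rules <- switch(name,
    H = .makeRules(
      substrate = c("34", "234", "245", "2345", "2345"),
      removed   = c(4L,   3L,    4L,    4L,     3L),
      tag = c("flanked para", "doubly flanked meta", "flanked para",
              "doubly flanked para", "doubly flanked meta")),
    N = .makeRules(
      substrate = c("234", "236", "235", "245", "2345", "2345"),
      removed   = c(3L,    3L,    3L,    5L,    3L,     5L),
      tag = "flanked meta"),
    T = .makeRules("2345", 3L, "doubly flanked meta"),
    CG1 = .makeRules(
      substrate = c("234", "2345", "2345", "234"),
      removed   = c(3L,    3L,     4L,     2L),
      tag = c("doubly flanked meta", "doubly flanked meta",
              "partial para", "partial ortho"),
      weight = c(1, 1, 0.2, 0.2))
  )
  if (mode == "generic") {
    if (name != "N")
      stop("generic mode is defined only for process N (flanked-meta predicate)")
    return(methods::new("ProcessRuleSet", name = name, rules = rules[0, ],
                        mode = "generic", predicate = "flanked_meta"))
  }
  methods::new("ProcessRuleSet", name = name, rules = rules,
               mode = "strict", predicate = NA_character_)
}

#' @rdname builtinProcess
#' @param x a \code{ProcessRuleSet}.
#' @return \code{processName} returns the rule-set name; \code{processRules}
#'   the rule table.
#' @export
processName <- function(x) x@name

#' @rdname builtinProcess
#' @export
processRules <- function(x) x@rules

## Generic-mode rule derivation. flanked_meta: remove any meta chlorine
## (position 3 or 5) having at least one chlorinated ring neighbour.
.genericRingRules <- function(ring, predicate) {
  if (predicate != "flanked_meta")
    stop("unknown generic predicate: ", predicate)
  metas <- intersect(ring, c(3L, 5L))
  hits <- metas[vapply(metas, function(p) {
    any(intersect(c(p - 1L, p + 1L), 2:6) %in% ring)
  }, logical(1))]
  if (!length(hits)) return(.makeRules(character(0), integer(0), character(0)))
  s <- .ringString(ring)
  .makeRules(rep(s, length(hits)), hits, "flanked meta (generic)")
}

#' Applicable rule applications for a congener
#'
#' Lists every (ring, rule) pair of a rule set that matches either ring of
#' the congener. An empty result means the congener is terminal under the
#' rule set. Symmetric congeners yield one application per ring (the two
#' removable chlorines are distinct sites, which kinetics must count twice).
#'
#' @param x a \code{\linkS4class{Congener}} or name string.
#' @param ruleset a \code{\linkS4class{ProcessRuleSet}}.
#' @return data.frame with columns \code{ringIndex}, \code{substrate},
#'   \code{removed}, \code{product}, \code{tag}, \code{weight}; zero rows if
#'   terminal.
#' @examples
#' applicableRules("2345-245-CB", builtinProcess("H"))  # 3 applications
#' applicableRules("25-25-CB", builtinProcess("H"))     # terminal
#' @export
applicableRules <- function(x, ruleset) {
  cg <- .asCongener(x)
  out <- list()
  for (idx in 1:2) {
    ring <- if (idx == 1) cg@ringA else cg@ringB
    if (!length(ring)) next
    s <- .ringString(ring)
    hits <- if (ruleset@mode == "generic")
      .genericRingRules(ring, ruleset@predicate)
    else ruleset@rules[ruleset@rules$substrate == s, , drop = FALSE]
    if (nrow(hits))
      out[[length(out) + 1L]] <- cbind(ringIndex = idx, hits)
  }
  if (!length(out))
    return(data.frame(ringIndex = integer(0), substrate = character(0),
                      removed = integer(0), product = character(0),
                      tag = character(0), weight = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply one dechlorination step
#'
#' Removes a single chlorine from one ring of a congener and returns the
#' canonicalized product, one homolog class down.
#'
#' @param x substrate \code{Congener} or name string.
#' @param ringIndex 1 (first-named ring) or 2.
#' @param removed position to remove; must be chlorinated on that ring.
#' @return the product \code{\linkS4class{Congener}}.
#' @examples
#' applyRule("2345-245-CB", 1, 4)  # "235-245-CB"
#' @export
applyRule <- function(x, ringIndex, removed) {
  cg <- .asCongener(x)
  if (!ringIndex %in% 1:2) stop("ringIndex must be 1 or 2")
  ring <- if (ringIndex == 1) cg@ringA else cg@ringB
  other <- if (ringIndex == 1) cg@ringB else cg@ringA
  removed <- as.integer(removed)
  if (!removed %in% ring)
    stop(sprintf("rule not applicable: no chlorine at position %d of ring %s in %s",
                 removed, .ringString(ring), cg@name))
  .newCongener(setdiff(ring, removed), other)
}

#' Read / write rule-set configuration files
#'
#' Tab-separated text, one rule per line:
#' \code{substrate_ring<TAB>removed_position<TAB>tag<TAB>weight}. The
#' product ring is derived on read, never stored. Lines starting with
#' \code{#} are comments. Built-in rule sets round-trip through this format.
#'
#' @param path file path.
#' @param name rule-set name to attach on read.
#' @return \code{readRuleSet} returns a \code{ProcessRuleSet} (strict mode).
#' @export
readRuleSet <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("rule-set file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed rule line(s) ", paste(bad, collapse = ", "), " in ", path)
  rules <- .makeRules(
    substrate = vapply(parts, `[`, character(1), 1L),
    removed = as.integer(vapply(parts, `[`, character(1), 2L)),
    tag = vapply(parts, `[`, character(1), 3L),
    weight = vapply(parts, function(p)
      if (length(p) >= 4L) as.numeric(p[4L]) else 1, numeric(1)))
  methods::new("ProcessRuleSet", name = name, rules = rules,
               mode = "strict", predicate = NA_character_)
}

#' @rdname readRuleSet
#' @param ruleset a \code{ProcessRuleSet} to write (strict rules only).
#' @export
writeRuleSet <- function(ruleset, path) {
  if (ruleset@mode != "strict")
    stop("only strict rule sets have a listable rule table")
  r <- ruleset@rules
  writeLines(c(sprintf("# process %s", ruleset@name),
               sprintf("%s\t%d\t%s\t%g", r$substrate, r$removed, r$tag,
                       r$weight)), path)
  invisible(path)
}

setMethod("show", "ProcessRuleSet", function(object) {
  cat(sprintf("Dechlorination process %s (%s mode)\n", object@name, object@mode))
  if (object@mode == "generic") {
    cat("  predicate:", object@predicate, "\n")
  } else {
    r <- object@rules
    cat(sprintf("  %d rules:\n", nrow(r)))
    for (i in seq_len(nrow(r)))
      cat(sprintf("    %s -> %s (remove %d, %s%s)\n", r$substrate[i],
                  r$product[i], r$removed[i], r$tag[i],
                  if (r$weight[i] != 1) sprintf(", weight %g", r$weight[i]) else ""))
  }
})
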