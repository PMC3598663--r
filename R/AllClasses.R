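## Central S4 classes. Congener names in the per-ring positional dialect
## (e.g. "2345-245-CB") are the universal identifier across all classes.

#' PCB congener
#'
#' One of the 209 polychlorinated biphenyl congeners, stored as an unordered
#' pair of canonical ring substitution patterns. Positions are IUPAC biphenyl
#' numbers restricted to one ring's 2--6 set; carbon 1 carries the biphenyl
#' bond and is never chlorinated. Objects are created with
#' \code{\link{parseCongener}}, never with \code{new()}.
#'
#' @slot ringA integer vector, chlorine positions on the first-named ring
#'   (canonical form; the ring with more chlorines, ties broken by the
#'   smaller position string).
#' @slot ringB integer vector, positions on the other ring (may be empty).
#' @slot name canonical name string, e.g. \code{"2345-245-CB"}.
#' @slot nChlorines total chlorine count, 1--10.
#' @slot homolog homolog class, one of \code{"mono"} ... \code{"deca"}.
#' @export
setClass("Congener", representation(
  ringA = "integer",
  ringB = "integer",
  name = "character",
  nChlorines = "integer",
  homolog = "character"
))

setValidity("Congener", function(object) {
  msg <- character()
  if (!all(object@ringA %in% 2:6) || !all(object@ringB %in% 2:6))
    msg <- c(msg, "chlorine positions must lie in 2..6")
  if (anyDuplicated(object@ringA) || anyDuplicated(object@ringB))
    msg <- c(msg, "duplicate position within a ring")
  n <- length(object@ringA) + length(object@ringB)
  if (n < 1L || n > 10L)
    msg <- c(msg, "total chlorine count must be 1..10")
  if (object@nChlorines != n)
    msg <- c(msg, "nChlorines inconsistent with ring patterns")
  if (length(msg)) msg else TRUE
})

#' Dechlorination process rule set
#'
#' A named collection of ring-level dechlorination transformations. Each rule
#' removes exactly one chlorine from a specific canonical ring pattern, so
#' applying any rule moves a congener down exactly one homolog class. Strict
#' mode applies only the listed, evidenced transformations; generic mode
#' derives applicable removals from a structural predicate (e.g. "any meta
#' chlorine with a chlorinated neighbour") at application time.
#'
#' @slot name process name, e.g. \code{"H"}, \code{"N"}, \code{"T"},
#'   \code{"CG1"} or a user-defined label.
#' @slot rules data.frame with columns \code{substrate} (canonical ring
#'   string), \code{removed} (position), \code{product} (derived canonical
#'   ring string), \code{tag} (structural motif provenance) and \code{weight}
#'   (relative rate multiplier used by kinetic simulation; 1 for full rules,
#'   less for rules the evidence calls partial).
#' @slot mode \code{"strict"} or \code{"generic"}.
#' @slot predicate predicate identifier for generic mode (currently
#'   \code{"flanked_meta"}), \code{NA} otherwise.
#' @export
setClass("ProcessRuleSet", representation(
  name = "character",
  rules = "data.frame",
  mode = "character",
  predicate = "character"
))

setValidity("ProcessRuleSet", function(object) {
  msg <- character()
  r <- object@rules
  need <- c("substrate", "removed", "product", "tag", "weight")
  if (!all(need %in% names(r)))
    return(sprintf("rules must have columns %s", paste(need, collapse = ", ")))
  if (!object@mode %in% c("strict", "generic"))
    msg <- c(msg, "mode must be 'strict' or 'generic'")
  if (nrow(r)) {
    for (i in seq_len(nrow(r))) {
      sub <- .ringFromString(r$substrate[i])
      if (!r$removed[i] %in% sub) {
        msg <- c(msg, sprintf("rule %d: removed position %d not in substrate %s",
                              i, r$removed[i], r$substrate[i]))
        next
      }
      prod <- .ringString(canonicalizeRing(setdiff(sub, r$removed[i])))
      if (!identical(prod, r$product[i]))
        msg <- c(msg, sprintf("rule %d: product %s is not canonical removal result (%s)",
                              i, r$product[i], prod))
    }
    if (any(r$weight < 0)) msg <- c(msg, "rule weights must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Congener mixture profile
#'
#' A mixture composition: mapping from congener name to percentage of total
#' PCBs, in mole or weight percent. Homolog-level profiles (as in published
#' homolog tables) are carried by pseudo-congener entries such as
#' \code{"hexa-CB"}; operations that need ring structure (pathways,
#' classification) reject those.
#'
#' @slot entries named numeric, percentages summing to 100 (within 0.5, the
#'   drift of rounded published tables). Names are canonical congener names
#'   or homolog pseudo-names.
#' @slot unit \code{"mol_percent"} or \code{"weight_percent"}.
#' @slot totalConc total PCB concentration in µM (1 µM = 1 nmol/mL);
#'   \code{NA} when unknown.
#' @slot label free-text sample label.
#' @export
setClass("CongenerProfile", representation(
  entries = "numeric",
  unit = "character",
  totalConc = "numeric",
  label = "character"
))

setValidity("CongenerProfile", function(object) {
  msg <- character()
  e <- object@entries
  if (is.null(names(e)) || any(!nzchar(names(e))))
    msg <- c(msg, "entries must be a named numeric vector")
  if (any(e < 0)) msg <- c(msg, "entries must be non-negative")
  if (anyDuplicated(names(e)))
    msg <- c(msg, "duplicate congener entries")
  if (length(e) && abs(sum(e) - 100) > 0.5)
    msg <- c(msg, sprintf("entries sum to %.3f, outside 100 +/- 0.5", sum(e)))
  if (!object@unit %in% c("mol_percent", "weight_percent"))
    msg <- c(msg, "unit must be 'mol_percent' or 'weight_percent'")
  if (length(msg)) msg else TRUE
})

#' Homolog distribution
#'
#' Mole percent of total PCBs per homolog class plus the mean number of
#' chlorines per biphenyl (the weighted average used for chlorine-release
#' bookkeeping).
#'
#' @slot molPercent named numeric over \code{mono} ... \code{deca}.
#' @slot meanChlorines mean chlorines per biphenyl.
#' @export
setClass("HomologDistribution", representation(
  molPercent = "numeric",
  meanChlorines = "numeric"
))

#' Profile change (after - before)
#'
#' @slot delta named numeric, signed per-congener mol\% change.
#' @slot homologDelta named numeric, signed per-homolog change.
#' @slot threshold mol\% magnitude a change must exceed to count as a loss
#'   or gain (2 by convention of published congener-change tables).
#' @slot decreased,increased,unchanged congener names partitioned by the
#'   threshold.
#' @export
setClass("DeltaProfile", representation(
  delta = "numeric",
  homologDelta = "numeric",
  threshold = "numeric",
  decreased = "character",
  increased = "character",
  unchanged = "character"
))

#' Dechlorination pathway graph
#'
#' The DAG of congeners reachable from a start congener under a rule set.
#' Every edge removes exactly one chlorine, so the graph is acyclic by
#' construction; terminals have no applicable rules.
#'
#' @slot start canonical name of the start congener.
#' @slot process name of the rule set used.
#' @slot nodes canonical names, ordered by chlorine count (descending) then
#'   name.
#' @slot edges data.frame with columns \code{substrate}, \code{product},
#'   \code{ringIndex}, \code{substrateRing}, \code{removed}, \code{tag},
#'   \code{weight}; two distinct rule applications yielding the same product
#'   are kept as separate edges (kinetics needs the multiplicity).
#' @slot terminals nodes with out-degree zero.
#' @export
setClass("PathwayGraph", representation(
  start = "character",
  process = "character",
  nodes = "character",
  edges = "data.frame",
  terminals = "character"
))

#' Rate assignment for kinetic simulation
#'
#' First-order rate constants (per month) for rule applications. The rate of
#' an edge is \code{base * weight}, where \code{weight} is the rule's
#' multiplier from the rule set (e.g. 0.2 for rules the evidence calls
#' partial) and \code{base} is, in order of precedence, a congener-context
#' override, a per-rule override, or the default.
#'
#' @slot default default base rate, per month.
#' @slot ruleRates named numeric, keys \code{"<substrate>:<removed>"}.
#' @slot contextRates named numeric, keys
#'   \code{"<congener>|<substrate>:<removed>"}.
#' @export
setClass("RateAssignment", representation(
  default = "numeric",
  ruleRates = "numeric",
  contextRates = "numeric"
))

setValidity("RateAssignment", function(object) {
  if (object@default < 0 || any(object@ruleRates < 0) ||
      any(object@contextRates < 0)) "rates must be >= 0" else TRUE
})

#' Kinetic simulation result
#'
#' @slot times time grid in months.
#' @slot profiles matrix, congeners (rows) by time points (columns), mol\%.
#' @slot meanChlorines mean chlorines per biphenyl at each time point.
#' @slot chlorineReleased cumulative chlorine released at each time point,
#'   nmol/mL (\code{NA} when the initial profile has no concentration).
#' @slot totalConc total PCB concentration, µM.
#' @slot process rule-set name.
#' @export
setClass("SimulationResult", representation(
  times = "numeric",
  profiles = "matrix",
  meanChlorines = "numeric",
  chlorineReleased = "numeric",
  totalConc = "numeric",
  process = "character"
))

#' Process classification result
#'
#' Ranking of candidate dechlorination processes by how much of an observed
#' loss/gain pattern each explains, with per-congener witness records so the
#' verdict can be audited congener by congener.
#'
#' @slot scores data.frame with columns \code{process},
#'   \code{explainedLossFraction}, \code{explainedGainFraction},
#'   \code{combined}, ranked by \code{combined} descending (ties broken by
#'   process name).
#' @slot winners process name(s) attaining the top combined score.
#' @slot tie \code{TRUE} when more than one process attains the top score.
#' @slot threshold,weighting parameters used.
#' @slot explanations per-process list: for each process, \code{losses}
#'   (data.frame of decreased congeners and whether/why a rule applies) and
#'   \code{gains} (list of witness paths per increased congener).
#' @slot noClassification \code{TRUE} when nothing changed beyond the
#'   threshold, in which case scores are empty.
#' @export
setClass("ClassificationResult", representation(
  scores = "data.frame",
  winners = "character",
  tie = "logical",
  threshold = "numeric",
  weighting = "character",
  explanations = "list",
  noClassification = "logical"
))

#' Synthetic Aroclor-like mixture specification
#'
#' Target homolog marginals, named dominant congeners, and allocation
#' parameters for \code{\link{generateMixture}}. Defaults emulate the
#' uninoculated-control homolog distribution of Aroclor 1260 at 81 µM
#' (hexa-CB 47.75 mol\%, hepta-CB 36.26 mol\%, ...), with the dominant
#' hepta- and hexa-chlorobiphenyl congeners reported for that mixture.
#'
#' @slot homologTargets named numeric, mol\% per homolog, summing to 100.
#' @slot dominants named list: homolog -> character vector of dominant
#'   congener names within that homolog.
#' @slot dominantShare fraction of each homolog's mol\% given to its
#'   dominant congeners (split evenly among them).
#' @slot congenersPerHomolog number of non-dominant congeners per homolog to
#'   receive the remainder (seeded random choice; Dirichlet allocation).
#' @slot totalConc total PCB concentration, µM.
#' @export
setClass("MixtureSpec", representation(
  homologTargets = "numeric",
  dominants = "list",
  dominantShare = "numeric",
  congenersPerHomolog = "integer",
  totalConc = "numeric"
))

#' Replicate noise specification
#'
#' Per-homolog replicate standard deviations (mol\%) for synthetic
#' dechlorinated replicates, defaulting to the SD scale of triplicate
#' homolog measurements in the emulated experiment (0.01--2.10 mol\%).
#'
#' @slot sd named numeric over homolog classes, mol\%.
#' @slot replicates number of replicates to generate.
#' @export
setClass("NoiseSpec", representation(
  sd = "numeric",
  replicates = "integer"
))
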