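## Attribution of an observed profile change to the best-matching
## dechlorination process.
##
## The scoring formalizes the pattern matching by which congener loss/gain
## tables are compared with literature process definitions: a decreased
## congener is explained by a process if at least one of its rules applies
## to it; an increased congener is explained if it is reachable (multi-step)
## from some decreased congener. Each verdict carries per-congener witness
## records so it can be audited against the underlying chemistry.

#' Explain a gained congener from a loss set
#'
#' Finds every decreased congener from which the gained congener is
#' reachable under the rule set, with all shortest witness paths for each
#' (path length is fixed at the chlorine-count difference, which also caps
#' the search). Witnesses are ordered by path length.
#'
#' @param gained the increased congener (object or name).
#' @param losses character vector (or list) of decreased congener names.
#' @param ruleset a \code{\linkS4class{ProcessRuleSet}}.
#' @return list of witnesses, each \code{list(loss=, path=)}; empty if the
#'   gain is unexplained by this process.
#' @examples
#' explainCongener("24-25-CB", "234-245-CB", builtinProcess("H"))
#' @export
explainCongener <- function(gained, losses, ruleset) {
  g <- .asCongener(gained)
  wits <- list()
  for (loss in vapply(losses, congenerName, character(1))) {
    f <- parseCongener(loss)
    dCl <- f@nChlorines - g@nChlorines
    if (dCl < 0) next
    if (dCl == 0) {
      if (f@name == g@name) wits[[length(wits) + 1L]] <-
          list(loss = loss, path = loss)
      next
    }
    pg <- enumeratePathways(f, ruleset)
    if (!g@name %in% pg@nodes) next
    ig <- .pathwayIgraph(pg)
    paths <- igraph::all_shortest_paths(ig, from = f@name, to = g@name,
                                        mode = "out")$vpaths
    for (p in paths)
      wits[[length(wits) + 1L]] <- list(loss = loss, path = names(p))
  }
  if (length(wits))
    wits <- wits[order(vapply(wits, function(w) length(w$path), integer(1)))]
  wits
}

.resolveCandidates <- function(candidates) {
  if (methods::is(candidates, "ProcessRuleSet")) candidates <- list(candidates)
  lapply(candidates, function(p) {
    if (methods::is(p, "ProcessRuleSet")) p else builtinProcess(p)
  })
}

#' Classify a profile change against candidate processes
#'
#' Scores each candidate dechlorination process by the fraction of observed
#' losses and gains it explains. Losses and gains can be derived from
#' before/after profiles (changes beyond the threshold) or supplied
#' directly as congener lists, reproducing published loss/gain table rows.
#' Fractions are weighted by change magnitude (\code{"mole"} weighting,
#' requires profiles) or by congener counts (\code{"unit"} weighting, for
#' list input). The combined score is by default the unweighted mean of the
#' two fractions; ranking is by combined score descending with a
#' deterministic tie-break on process name.
#'
#' @param before,after \code{CongenerProfile}s (same unit), or \code{NULL}
#'   when \code{losses}/\code{gains} are given.
#' @param candidates list of \code{ProcessRuleSet}s or builtin process
#'   names (default all four built-ins).
#' @param losses,gains character vectors of congener names, alternative to
#'   profiles.
#' @param threshold change magnitude (mol\%) that must be exceeded, default
#'   2 as in published congener-change tables.
#' @param weighting \code{"mole"} (|delta mol\%| weights) or \code{"unit"}
#'   (each congener counts once).
#' @param combine \code{"mean"} (default), \code{"harmonic"} or
#'   \code{"gain_only"} combination of the loss/gain fractions. With no
#'   gains beyond the threshold the combined score falls back to the loss
#'   fraction.
#' @return a \code{\linkS4class{ClassificationResult}}; when nothing
#'   changed beyond the threshold the result has
#'   \code{noClassification = TRUE} rather than raising an error.
#' @examples
#' res <- classifyProfileChange(
#'   losses = c("245-245-CB", "234-245-CB", "2345-245-CB"),
#'   gains = c("25-25-CB", "24-25-CB"),
#'   candidates = c("H", "N", "T", "CG1"), weighting = "unit")
#' classificationWinners(res)
#' @export
classifyProfileChange <- function(before = NULL, after = NULL,
                                  candidates = c("H", "N", "T", "CG1"),
                                  losses = NULL, gains = NULL,
                                  threshold = 2,
                                  weighting = c("mole", "unit"),
                                  combine = c("mean", "harmonic", "gain_only")) {
  weighting <- match.arg(weighting)
  combine <- match.arg(combine)
  cand <- .resolveCandidates(candidates)
  if (!length(cand)) stop("'candidates' must be non-empty")
  if (is.null(losses) && is.null(gains)) {
    if (is.null(before) || is.null(after))
      stop("supply either before/after profiles or losses/gains lists")
    .requireCongenerLevel(before, "process classification")
    .requireCongenerLevel(after, "process classification")
    d <- deltaProfile(before, after, threshold)
    losses <- d@decreased
    gains <- d@increased
    lw <- abs(d@delta[losses])
    gw <- abs(d@delta[gains])
  } else {
    losses <- unique(vapply(as.character(losses %||% character(0)),
                            congenerName, character(1)))
    gains <- unique(vapply(as.character(gains %||% character(0)),
                           congenerName, character(1)))
    if (weighting == "mole")
      stop("mole weighting needs before/after profiles; use weighting='unit' for lists")
    lw <- setNames(rep(1, length(losses)), losses)
    gw <- setNames(rep(1, length(gains)), gains)
  }
  if (weighting == "unit") {
    lw <- setNames(rep(1, length(losses)), losses)
    gw <- setNames(rep(1, length(gains)), gains)
  }
  if (!length(losses)) {
    return(methods::new("ClassificationResult",
                        scores = data.frame(), winners = character(0),
                        tie = FALSE, threshold = threshold,
                        weighting = weighting, explanations = list(),
                        noClassification = TRUE))
  }
  expl <- list()
  rows <- list()
  for (rs in cand) {
    loss_ok <- vapply(losses, function(l)
      nrow(applicableRules(l, rs)) > 0, logical(1))
    gain_wits <- lapply(gains, explainCongener, losses = losses, ruleset = rs)
    names(gain_wits) <- gains
    gain_ok <- lengths(gain_wits) > 0
    lf <- if (length(losses)) sum(lw[loss_ok]) / sum(lw) else 0
    gf <- if (length(gains)) sum(gw[gain_ok]) / sum(gw) else NA_real_
    comb <- if (is.na(gf)) lf
    else switch(combine,
                mean = (lf + gf) / 2,
                harmonic = if (lf + gf == 0) 0 else 2 * lf * gf / (lf + gf),
                gain_only = gf)
    rows[[rs@name]] <- data.frame(process = rs@name,
                                  explainedLossFraction = lf,
                                  explainedGainFraction = if (is.na(gf)) NA else gf,
                                  combined = comb)
    expl[[rs@name]] <- list(
      losses = data.frame(congener = losses, explained = loss_ok,
                          row.names = NULL),
      gains = gain_wits)
  }
  scores <- do.call(rbind, rows)
  scores <- scores[order(-scores$combined, scores$process), , drop = FALSE]
  rownames(scores) <- NULL
  top <- scores$combined[1]
  winners <- scores$process[scores$combined == top]
  methods::new("ClassificationResult", scores = scores, winners = winners,
               tie = length(winners) > 1, threshold = threshold,
               weighting = weighting, explanations = expl,
               noClassification = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname classifyProfileChange
#' @param x a \code{ClassificationResult}.
#' @export
classificationScores <- function(x) x@scores

#' @rdname classifyProfileChange
#' @export
classificationWinners <- function(x) x@winners

#' @rdname classifyProfileChange
#' @export
classificationExplanations <- function(x) x@explanations

setMethod("show", "ClassificationResult", function(object) {
  if (object@noClassification) {
    cat("No classification: no congener changed beyond the threshold (",
        object@threshold, " mol%)\n", sep = "")
    return(invisible(NULL))
  }
  cat(sprintf("Process classification (%s weighting, threshold %g):\n",
              object@weighting, object@threshold))
  s <- object@scores
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s loss %.3f  gain %s  combined %.3f%s\n",
                s$process[i], s$explainedLossFraction[i],
                if (is.na(s$explainedGainFraction[i])) "  NA "
                else sprintf("%.3f", s$explainedGainFraction[i]),
                s$combined[i],
                if (s$process[i] %in% object@winners) "  <- winner" else ""))
  if (object@tie) cat("  (tie)\n")
})
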