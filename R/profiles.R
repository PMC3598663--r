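## Mixture profile arithmetic: unit conversion, homolog statistics, deltas,
## chlorine release, growth yield.

#' Construct a congener profile
#'
#' @param entries named numeric: congener name (or homolog pseudo-name such
#'   as \code{"hexa-CB"}) to percentage. Names are canonicalized; values
#'   must be non-negative and sum to 100 within 0.5 (the rounding drift of
#'   published tables). Profiles are never renormalized silently; use
#'   \code{renormalize()}.
#' @param unit \code{"mol_percent"} (default) or \code{"weight_percent"}.
#' @param totalConc total PCB concentration in µM (1 µM = 1 nmol/mL);
#'   \code{NA} if unknown. The mixture concentration used in the emulated
#'   experiments is 30 ppm = 81 µM.
#' @param label sample label.
#' @return a \code{\linkS4class{CongenerProfile}}.
#' @examples
#' congenerProfile(c("245-245-CB" = 60, "24-25-CB" = 40), totalConc = 81)
#' @export
congenerProfile <- function(entries, unit = "mol_percent",
                            totalConc = NA_real_, label = "") {
  if (is.null(names(entries)))
    stop("'entries' must be a named numeric vector")
  nm <- vapply(names(entries), .canonicalEntryName, character(1))
  if (anyDuplicated(nm))
    stop("duplicate congener entries after canonicalization: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  e <- as.numeric(entries)
  names(e) <- nm
  methods::new("CongenerProfile", entries = e, unit = unit,
               totalConc = as.numeric(totalConc), label = as.character(label))
}

#' @rdname congenerProfile
#' @param x a \code{CongenerProfile}.
#' @export
profileEntries <- function(x) x@entries

#' @rdname congenerProfile
#' @export
totalConcentration <- function(x) x@totalConc

#' @rdname congenerProfile
#' @export
profileLabel <- function(x) x@label

#' @rdname congenerProfile
#' @export
profileUnit <- function(x) x@unit

#' @rdname congenerProfile
#' @return \code{renormalize} returns the profile rescaled to sum exactly
#'   to 100 (explicit request only).
#' @export
renormalize <- function(x) {
  s <- sum(x@entries)
  if (s <= 0) stop("cannot renormalize an all-zero profile")
  methods::initialize(x, entries = x@entries / s * 100)
}

.isHomologProfile <- function(p) {
  any(vapply(names(p@entries), .isHomologName, logical(1)))
}

.requireCongenerLevel <- function(p, what) {
  if (.isHomologProfile(p))
    stop(what, " requires a congener-level profile; this one has ",
         "homolog pseudo-congener entries")
  invisible(p)
}

#' Convert weight percent to mole percent
#'
#' mol\%_i = (w_i / MW_i) / sum_j (w_j / MW_j) * 100, using the congener
#' molecular weights (154.21 + n * 34.44 g/mol). This is the conversion by
#' which congener quantification from weight-percent distributions yields
#' mole percent values.
#'
#' @param x a \code{CongenerProfile} in \code{weight_percent}, or a named
#'   numeric vector of weight percentages.
#' @return a \code{CongenerProfile} in \code{mol_percent}, summing to 100.
#' @examples
#' weightToMol(c("245-245-CB" = 50, "2345-245-CB" = 50))
#' @export
weightToMol <- function(x) {
  if (!methods::is(x, "CongenerProfile"))
    x <- congenerProfile(x, unit = "weight_percent")
  if (x@unit != "weight_percent")
    stop("profile is not in weight_percent")
  w <- x@entries
  if (any(w < 0)) stop("negative weight percentage")
  mol <- (w / molecularWeight(names(w)))
  mol <- mol / sum(mol) * 100
  methods::initialize(x, entries = mol, unit = "mol_percent")
}

#' @rdname weightToMol
#' @return \code{molToWeight} performs the inverse conversion.
#' @export
molToWeight <- function(x) {
  if (!methods::is(x, "CongenerProfile"))
    x <- congenerProfile(x, unit = "mol_percent")
  if (x@unit != "mol_percent")
    stop("profile is not in mol_percent")
  m <- x@entries
  w <- m * molecularWeight(names(m))
  w <- w / sum(w) * 100
  methods::initialize(x, entries = w, unit = "weight_percent")
}

#' Homolog distribution of a profile
#'
#' Sums mole percent by homolog class and computes the mean number of
#' chlorines per biphenyl, sum_h n_h * mol\%_h / 100.
#'
#' @param p a \code{CongenerProfile} in mole percent (congener- or
#'   homolog-level).
#' @return a \code{\linkS4class{HomologDistribution}}.
#' @examples
#' p <- congenerProfile(c("245-245-CB" = 100))
#' homologDistribution(p)  # hexa 100, mean chlorines 6
#' @export
homologDistribution <- function(p) {
  if (p@unit != "mol_percent")
    stop("homolog distribution is defined on mole-percent profiles; ",
         "convert with weightToMol() first")
  h <- vapply(names(p@entries), .entryHomolog, character(1))
  mp <- setNames(numeric(length(HOMOLOGS)), HOMOLOGS)
  agg <- tapply(p@entries, factor(h, levels = HOMOLOGS), sum)
  mp[names(agg)] <- ifelse(is.na(agg), 0, agg)
  mean_cl <- sum(seq_along(HOMOLOGS) * mp) / 100
  methods::new("HomologDistribution", molPercent = mp, meanChlorines = mean_cl)
}

#' @rdname homologDistribution
#' @param x a \code{HomologDistribution}.
#' @export
homologMolPercent <- function(x) x@molPercent

#' @rdname homologDistribution
#' @export
meanChlorines <- function(x) {
  if (methods::is(x, "CongenerProfile")) x <- homologDistribution(x)
  x@meanChlorines
}

#' Signed profile change
#'
#' Per-congener and per-homolog signed change (after - before), partitioned
#' into decreased / increased / unchanged congeners by whether the change
#' magnitude exceeds the threshold (2 mol\% by the convention of published
#' congener-change tables: listed changes are "above 2 mol\%").
#'
#' @param before,after \code{CongenerProfile}s in the same unit.
#' @param threshold change magnitude that must be exceeded, same unit.
#' @return a \code{\linkS4class{DeltaProfile}}.
#' @export
deltaProfile <- function(before, after, threshold = 2) {
  if (before@unit != after@unit)
    stop("unit mismatch: before is ", before@unit, ", after is ", after@unit)
  all_names <- union(names(before@entries), names(after@entries))
  b <- setNames(numeric(length(all_names)), all_names)
  a <- b
  b[names(before@entries)] <- before@entries
  a[names(after@entries)] <- after@entries
  d <- a - b
  h <- vapply(all_names, .entryHomolog, character(1))
  hd <- setNames(numeric(length(HOMOLOGS)), HOMOLOGS)
  agg <- tapply(d, factor(h, levels = HOMOLOGS), sum)
  hd[names(agg)] <- ifelse(is.na(agg), 0, agg)
  methods::new("DeltaProfile",
               delta = d, homologDelta = hd, threshold = threshold,
               decreased = names(d)[d < -threshold],
               increased = names(d)[d > threshold],
               unchanged = names(d)[abs(d) <= threshold])
}

#' @rdname deltaProfile
#' @param x a \code{DeltaProfile}.
#' @export
profileDelta <- function(x) x@delta

#' @rdname deltaProfile
#' @export
homologDelta <- function(x) x@homologDelta

#' Percent decrease per homolog
#'
#' 100 * (before - after) / before for each homolog present before.
#' Homologs that increased carry no entry (mirroring how published homolog
#' tables print a \% decrease only for homologs that went down); homologs
#' absent before are omitted with a warning if they appear after.
#'
#' @param before,after \code{HomologDistribution}s (or mole-percent
#'   profiles, which are reduced first).
#' @return named numeric, percent decrease per homolog.
#' @examples
#' # hexa 47.75 -> 19.52 gives 59.12 % decrease
#' @export
percentDecreaseByHomolog <- function(before, after) {
  if (methods::is(before, "CongenerProfile")) before <- homologDistribution(before)
  if (methods::is(after, "CongenerProfile")) after <- homologDistribution(after)
  b <- before@molPercent; a <- after@molPercent
  zero_div <- names(b)[b == 0 & a > 0]
  if (length(zero_div))
    warning("homolog(s) absent before but present after, omitted: ",
            paste(zero_div, collapse = ", "))
  keep <- names(b)[b > 0 & a <= b]
  setNames(100 * (b[keep] - a[keep]) / b[keep], keep)
}

#' Chlorine removed between two profiles
#'
#' (mean chlorines before - mean chlorines after) * total concentration.
#' With concentration in µM the result is nmol chlorine per mL (1 µM = 1
#' nmol/mL). Depends only on the homolog marginals, so any within-homolog
#' redistribution of mol\% leaves it unchanged.
#'
#' @param before,after \code{CongenerProfile}s with the same (non-missing)
#'   total concentration.
#' @return chlorine removed, nmol/mL.
#' @export
chlorineRemoval <- function(before, after) {
  cb <- before@totalConc; ca <- after@totalConc
  if (is.na(cb) || is.na(ca))
    stop("both profiles need a total PCB concentration (µM)")
  if (cb != ca)
    stop("total concentrations differ (", cb, " vs ", ca, " µM)")
  (meanChlorines(before) - meanChlorines(after)) * cb
}

#' Growth yield of dechlorinating cells
#'
#' Cells grown per mole of chlorine released:
#' cells/mL divided by chlorine removal converted from nmol/mL to mol/mL.
#'
#' @param cellsGrown cell growth, cells/mL.
#' @param clRemoved total chlorine removal, nmol/mL; must be positive.
#' @return yield in cells per mole chlorine.
#' @examples
#' growthYield(3.3e5, 1)  # 3.3e14 cells per mole Cl
#' @export
growthYield <- function(cellsGrown, clRemoved) {
  if (any(clRemoved <= 0))
    stop("chlorine removal must be positive to define a growth yield")
  cellsGrown / (clRemoved * 1e-9)
}

setMethod("show", "CongenerProfile", function(object) {
  cat(sprintf("CongenerProfile%s: %d entries (%s), sum %.2f",
              if (nzchar(object@label)) paste0(" '", object@label, "'") else "",
              length(object@entries), object@unit, sum(object@entries)))
  if (!is.na(object@totalConc))
    cat(sprintf(", %.0f uM total PCB", object@totalConc))
  cat("\n")
  top <- sort(object@entries, decreasing = TRUE)
  top <- head(top, 5L)
  for (i in seq_along(top))
    cat(sprintf("  %-14s %6.2f\n", names(top)[i], top[i]))
  if (length(object@entries) > 5L) cat("  ...\n")
})

setMethod("show", "HomologDistribution", function(object) {
  cat("Homolog distribution (mol% of total PCBs):\n")
  mp <- object@molPercent
  for (h in names(mp)[mp > 0])
    cat(sprintf("  %-6s %6.2f\n", paste0(h, "-CB"), mp[h]))
  cat(sprintf("  mean chlorines per biphenyl: %.2f\n", object@meanChlorines))
})

setMethod("show", "DeltaProfile", function(object) {
  cat(sprintf("Profile change (threshold %g):\n", object@threshold))
  cat(sprintf("  decreased (%d): %s\n", length(object@decreased),
              paste(object@decreased, collapse = ", ")))
  cat(sprintf("  increased (%d): %s\n", length(object@increased),
              paste(object@increased, collapse = ", ")))
})
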