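## Seeded generator of Aroclor-1260-like mixtures, noisy dechlorinated
## replicates, and growth/chlorine-release series. Every pipeline stage can
## be exercised with these in place of GC-ECD and qPCR measurements.

.defaultHomologTargets <- c(
  tri = 0.07, tetra = 0.21, penta = 9.63, hexa = 47.75,
  hepta = 36.26, octa = 5.51, nona = 0.57)

.defaultDominants <- list(
  hepta = c("2345-245-CB", "2345-236-CB", "2356-234-CB", "2345-234-CB"),
  hexa = c("245-245-CB", "236-245-CB", "234-245-CB", "234-236-CB",
           "2345-25-CB"))

.defaultNoiseSD <- c(
  tri = 0.47, tetra = 1.54, penta = 1.89, hexa = 2.10,
  hepta = 1.33, octa = 0.06, nona = 0.01)

#' Specification of a synthetic Aroclor-1260-like mixture
#'
#' Defaults reproduce the uninoculated-control homolog distribution of
#' Aroclor 1260 (tri 0.07, tetra 0.21, penta 9.63, hexa 47.75, hepta 36.26,
#' octa 5.51, nona 0.57 mol\%; no mono- or di-chlorobiphenyls detected) at
#' 81 µM, with the reported dominant hepta- and hexa-chlorobiphenyls.
#'
#' @param homologTargets named numeric, target mol\% per homolog class,
#'   summing to 100 within 0.5.
#' @param dominants named list mapping a homolog to its dominant congener
#'   names; each dominant must belong to the stated homolog.
#' @param dominantShare fraction (0--1) of each homolog's mol\% assigned to
#'   its dominants, split evenly.
#' @param congenersPerHomolog how many non-dominant congeners per homolog
#'   receive the remaining mass (seeded random subset of the homolog's
#'   canonical congeners).
#' @param totalConc total PCB concentration, µM.
#' @return a \code{\linkS4class{MixtureSpec}}.
#' @export
mixtureSpec <- function(homologTargets = .defaultHomologTargets,
                        dominants = .defaultDominants,
                        dominantShare = 0.70,
                        congenersPerHomolog = 10L,
                        totalConc = 81) {
  if (abs(sum(homologTargets) - 100) > 0.5)
    stop("homolog targets sum to ", sum(homologTargets),
         ", outside 100 +/- 0.5")
  if (!all(names(homologTargets) %in% HOMOLOGS))
    stop("unknown homolog class in targets: ",
         paste(setdiff(names(homologTargets), HOMOLOGS), collapse = ", "))
  for (h in names(dominants)) {
    wrong <- dominants[[h]][vapply(dominants[[h]], homolog,
                                   character(1)) != h]
    if (length(wrong))
      stop("dominant congener(s) not in homolog '", h, "': ",
           paste(wrong, collapse = ", "))
  }
  methods::new("MixtureSpec", homologTargets = homologTargets,
               dominants = dominants, dominantShare = dominantShare,
               congenersPerHomolog = as.integer(congenersPerHomolog),
               totalConc = totalConc)
}

#' Replicate noise specification
#'
#' @param sd named numeric, replicate standard deviation per homolog class
#'   in mol\% (defaults: the SD scale of triplicate homolog measurements,
#'   tri 0.47, tetra 1.54, penta 1.89, hexa 2.10, hepta 1.33, octa 0.06,
#'   nona 0.01).
#' @param replicates number of replicates.
#' @return a \code{\linkS4class{NoiseSpec}}.
#' @export
noiseSpec <- function(sd = .defaultNoiseSD, replicates = 3L) {
  methods::new("NoiseSpec", sd = sd, replicates = as.integer(replicates))
}

.dirichlet <- function(k, alpha = 1) {
  g <- stats::rgamma(k, shape = alpha)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

#' Generate a synthetic Aroclor-like mixture
#'
#' Builds a congener-level profile whose homolog marginals equal the spec
#' exactly (a construction guarantee). Within each homolog the named
#' dominant congeners receive \code{dominantShare} of the homolog's mass,
#' split evenly; the remainder is spread over a seeded random subset of
#' that homolog's other congeners with Dirichlet(1) proportions. The true
#' congener-level composition of the commercial mixture is not published in
#' the emulated study, so the within-homolog allocation is a documented
#' stand-in, not a measurement.
#'
#' @param spec a \code{\link{mixtureSpec}}.
#' @param seed integer seed; identical seeds give identical profiles.
#' @param label profile label.
#' @return a congener-level mole-percent \code{CongenerProfile}.
#' @examples
#' m <- generateMixture(seed = 1)
#' homologMolPercent(homologDistribution(m))["hexa"]  # exactly 47.75
#' @export
generateMixture <- function(spec = mixtureSpec(), seed = 1,
                            label = "synthetic Aroclor 1260") {
  set.seed(as.integer(seed))
  entries <- numeric(0)
  for (h in names(spec@homologTargets)) {
    target <- spec@homologTargets[[h]]
    if (target <= 0) next
    members <- enumerateAllCongeners(homolog = h)
    doms <- intersect(spec@dominants[[h]] %||% character(0), members)
    dom_mass <- if (length(doms)) target * spec@dominantShare else 0
    rest_pool <- setdiff(members, doms)
    k <- min(spec@congenersPerHomolog, length(rest_pool))
    others <- if (k > 0) sample(rest_pool, k) else character(0)
    rest_mass <- target - dom_mass
    vals <- c(if (length(doms)) setNames(rep(dom_mass / length(doms),
                                             length(doms)), doms),
              if (length(others)) setNames(rest_mass * .dirichlet(length(others)),
                                           others)
              else if (rest_mass > 0 && length(doms))
                stop("no congeners available for remainder of homolog ", h))
    entries <- c(entries, vals)
  }
  congenerProfile(entries, totalConc = spec@totalConc, label = label)
}

#' Generate noisy dechlorinated replicates
#'
#' Simulates the mixture forward under a rule set, then emulates replicate
#' measurement noise: seeded zero-mean Gaussian perturbations at the
#' congener level, scaled so that homolog-level standard deviations match
#' the noise spec (each congener of homolog h receives SD
#' \code{sd[h] / sqrt(m_h)} with m_h the congeners of that homolog present
#' in the profile), clipped at zero and renormalized to 100. Noise is
#' applied post-simulation (measurement noise), not to the rates.
#'
#' @param initial congener-level mole-percent \code{CongenerProfile}.
#' @param ruleset a \code{ProcessRuleSet}.
#' @param rates a \code{RateAssignment}.
#' @param t incubation time, months.
#' @param noise a \code{\link{noiseSpec}}.
#' @param seed integer seed.
#' @return list of \code{CongenerProfile}s, one per replicate.
#' @export
generateDechlorinatedReplicates <- function(initial, ruleset,
                                            rates = rateAssignment(),
                                            t = 3, noise = noiseSpec(),
                                            seed = 1) {
  sim <- simulateDechlorination(initial, ruleset, rates, times = t)
  final <- sim@profiles[, 1]
  h <- vapply(names(final), .entryHomolog, character(1))
  m_h <- table(h)
  sd_cong <- vapply(h, function(hh) {
    s <- if (hh %in% names(noise@sd)) noise@sd[[hh]] else 0
    s / sqrt(m_h[[hh]])
  }, numeric(1))
  set.seed(as.integer(seed))
  lapply(seq_len(noise@replicates), function(i) {
    x <- final + stats::rnorm(length(final), 0, sd_cong)
    x[x < 0] <- 0
    x <- x / sum(x) * 100
    congenerProfile(x, totalConc = initial@totalConc,
                    label = sprintf("%s, %s, t=%g mo, replicate %d",
                                    initial@label, ruleset@name, t, i))
  })
}

#' Generate a synthetic growth series
#'
#' Paired (chlorine removed, dechlorinator cell count) observations from a
#' fixed growth yield: cells/mL = yield (cells per mole Cl) x chlorine
#' removed (converted from nmol/mL) x (1 + noise). With zero noise,
#' \code{\link{growthYield}} applied to the output recovers the input yield
#' exactly.
#'
#' @param clRemoved numeric vector of chlorine removals, nmol/mL.
#' @param yield growth yield, cells per mole chlorine; must be positive.
#' @param noiseFraction relative SD of multiplicative Gaussian noise.
#' @param seed integer seed.
#' @return data.frame with columns \code{clRemoved} (nmol/mL) and
#'   \code{cells} (cells/mL).
#' @examples
#' generateGrowthSeries(36.49, yield = 3.30e14, noiseFraction = 0)
#' @export
generateGrowthSeries <- function(clRemoved, yield = 3.30e14,
                                 noiseFraction = 0.1, seed = 1) {
  if (yield <= 0) stop("yield must be positive")
  set.seed(as.integer(seed))
  noise <- if (noiseFraction > 0)
    stats::rnorm(length(clRemoved), 0, noiseFraction) else rep(0, length(clRemoved))
  cells <- yield * (clRemoved * 1e-9) * (1 + noise)
  data.frame(clRemoved = clRemoved, cells = cells)
}
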