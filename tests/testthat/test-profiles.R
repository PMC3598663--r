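test_that("profile construction validates entries and canonicalizes names", {
  p <- congenerProfile(c("24-245-CB" = 60, "25-24-CB" = 40))
  expect_setequal(names(profileEntries(p)), c("245-24-CB", "24-25-CB"))
  expect_error(congenerProfile(c("245-24-CB" = 50, "24-245-CB" = 50)),
               "duplicate")
  expect_error(congenerProfile(c("245-245-CB" = 90)), "outside 100")
  expect_error(congenerProfile(c("245-245-CB" = -1, "24-25-CB" = 101)),
               "non-negative")
  expect_equal(sum(profileEntries(renormalize(
    congenerProfile(c("245-245-CB" = 55.2, "24-25-CB" = 44.9))))), 100)
})

test_that("weight-to-mole conversion follows w/MW normalization", {
  # identity for a single congener
  one <- weightToMol(c("245-245-CB" = 100))
  expect_equal(unname(profileEntries(one)), 100)
  # equal weights: the lighter congener carries more moles
  two <- profileEntries(weightToMol(c("2-CB" = 50, "23456-23456-CB" = 50)))
  expect_gt(two[["2-CB"]], two[["23456-23456-CB"]])
  # closed form for a hexa/hepta 50/50 weight split:
  # mol ratio = MW(hepta)/MW(hexa) = 395.29/360.85
  hh <- profileEntries(weightToMol(c("245-245-CB" = 50, "2345-245-CB" = 50)))
  expect_equal(hh[["245-245-CB"]] / hh[["2345-245-CB"]],
               395.29 / 360.85, tolerance = 1e-9)
  expect_equal(sum(hh), 100, tolerance = 1e-12)
})

test_that("mol->weight->mol round trip recovers the input", {
  m <- generateMixture(seed = 42)
  back <- weightToMol(molToWeight(m))
  expect_equal(profileEntries(back)[names(profileEntries(m))],
               profileEntries(m), tolerance = 1e-6)
  expect_error(weightToMol(m), "not in weight_percent")
})

test_that("homolog distribution reproduces the published mean-chlorine values", {
  before <- homologDistribution(control_homolog_profile())
  after <- homologDistribution(dechlorinated_homolog_profile())
  expect_equal(meanChlorines(before), 6.39, tolerance = 0.005)
  expect_equal(meanChlorines(after), 5.59, tolerance = 0.005)
  expect_equal(sum(homologMolPercent(before)), 100, tolerance = 1e-9)
  single <- homologDistribution(congenerProfile(c("245-245-CB" = 100)))
  expect_equal(unname(homologMolPercent(single)["hexa"]), 100)
  expect_equal(meanChlorines(single), 6)
})

test_that("homolog sums equal the profile total for congener-level profiles", {
  for (s in 1:3) {
    m <- generateMixture(seed = s)
    expect_equal(sum(homologMolPercent(homologDistribution(m))),
                 sum(profileEntries(m)), tolerance = 1e-9)
  }
})

test_that("profile deltas reproduce the published homolog changes", {
  d <- deltaProfile(control_homolog_profile(), dechlorinated_homolog_profile())
  dd <- profileDelta(d)
  expect_equal(unname(dd["tetra-CB"]), 26.72, tolerance = 1e-9)
  expect_equal(unname(dd["hexa-CB"]), -28.23, tolerance = 1e-9)
  expect_equal(unname(dd["penta-CB"]), 11.57, tolerance = 1e-9)
  expect_equal(unname(dd["hepta-CB"]), -11.04, tolerance = 1e-9)
  # unchanged input gives all-zero deltas
  z <- deltaProfile(control_homolog_profile(), control_homolog_profile())
  expect_true(all(profileDelta(z) == 0))
  expect_length(z@decreased, 0)
  # unit mismatch is an error
  w <- molToWeight(generateMixture(seed = 1))
  expect_error(deltaProfile(generateMixture(seed = 1), w), "unit mismatch")
})

test_that("percent decrease by homolog matches the printed table", {
  pd <- percentDecreaseByHomolog(control_homolog_profile(),
                                 dechlorinated_homolog_profile())
  expect_equal(unname(pd["hexa"]), 59.12, tolerance = 0.005)
  expect_equal(unname(pd["hepta"]), 30.44, tolerance = 0.01)
  expect_equal(unname(pd["octa"]), 2.18, tolerance = 0.005)
  # increased homologs carry no entry
  expect_false("tetra" %in% names(pd))
  # x -> x gives zero
  same <- percentDecreaseByHomolog(control_homolog_profile(),
                                   control_homolog_profile())
  expect_true(all(same == 0))
})

test_that("chlorine removal is the mean-chlorine drop times concentration", {
  removed <- chlorineRemoval(control_homolog_profile(),
                             dechlorinated_homolog_profile())
  # (6.3873 - 5.5908) * 81 = 64.52; printed culture value 64.23, within 1%
  expect_equal(removed, (6.3873 - 5.5908) * 81, tolerance = 1e-6)
  expect_equal(removed, 64.23, tolerance = 0.01)
  expect_equal(chlorineRemoval(control_homolog_profile(),
                               control_homolog_profile()), 0)
  # missing concentration is an error
  mono <- congenerProfile(c("2-CB" = 100), totalConc = 81)
  expect_error(chlorineRemoval(mono, congenerProfile(c("2-CB" = 100))),
               "concentration")
})

test_that("chlorine removal depends only on homolog marginals", {
  m <- generateMixture(seed = 9)
  after <- profileAtTime(simulateDechlorination(m, builtinProcess("N"),
                                                times = 3), 3)
  base <- chlorineRemoval(m, after)
  # redistribute mass within each homolog of 'after': removal is unchanged
  e <- profileEntries(after)
  h <- vapply(names(e), homolog, character(1))
  e2 <- e
  for (hh in unique(h)) {
    idx <- which(h == hh)
    if (length(idx) > 1) e2[idx] <- rev(e[idx])
  }
  shuffled <- congenerProfile(e2, totalConc = totalConcentration(after))
  expect_equal(chlorineRemoval(m, shuffled), base, tolerance = 1e-9)
})

test_that("growth yield converts nmol/mL chlorine to cells per mole", {
  expect_equal(growthYield(3.3e5, 1), 3.3e14)
  expect_equal(growthYield(1.1e7, 36.49), 1.1e7 / 36.49e-9)
  expect_equal(growthYield(1.1e7, 36.49), 3.0e14, tolerance = 0.005)
  expect_equal(growthYield(0, 10), 0)
  expect_error(growthYield(1e7, 0), "positive")
  expect_error(growthYield(1e7, -2), "positive")
})

test_that("structure-requiring operations reject homolog-level profiles", {
  hp <- control_homolog_profile()
  expect_error(simulateDechlorination(hp, builtinProcess("N"), times = 1),
               "congener-level")
  expect_error(classifyProfileChange(hp, dechlorinated_homolog_profile()),
               "congener-level")
})
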