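test_that("loss/gain lists of the flanked-para culture rank Process H first", {
  res <- classifyProfileChange(losses = cw4_losses(), gains = cw4_gains(),
                               candidates = c("H", "N", "T", "CG1"),
                               weighting = "unit")
  sc <- classificationScores(res)
  expect_identical(sc$process[1], "H")
  expect_identical(classificationWinners(res), "H")
  expect_false(res@tie)
  # H explains all six losses and three of four gains (not 2345-26-CB)
  expect_equal(sc$explainedLossFraction[sc$process == "H"], 1)
  expect_equal(sc$explainedGainFraction[sc$process == "H"], 3 / 4)
  # N explains 24-25-CB and 2345-26-CB only
  expect_equal(sc$explainedGainFraction[sc$process == "N"], 2 / 4)
  ex <- classificationExplanations(res)
  expect_length(ex$H$gains[["2345-26-CB"]], 0)
  expect_gt(length(ex$H$gains[["25-25-CB"]]), 0)
  expect_gt(length(ex$H$gains[["235-25-CB"]]), 0)
  expect_gt(length(ex$H$gains[["24-25-CB"]]), 0)
  # the flanked-meta process accounts for 2345-26-CB in one step
  w <- ex$N$gains[["2345-26-CB"]]
  expect_identical(w[[1]]$path, c("2345-236-CB", "2345-26-CB"))
})

test_that("gain witnesses enumerate all shortest routes", {
  w <- explainCongener("24-25-CB", "234-245-CB", builtinProcess("H"))
  expect_length(w, 2)
  mids <- vapply(w, function(x) x$path[2], character(1))
  expect_setequal(mids, c("234-25-CB", "245-24-CB"))
  # unexplainable gain returns an empty witness list
  expect_length(explainCongener("25-25-CB", cw4_losses(), builtinProcess("N")),
                0)
})

test_that("scores are invariant to list order and irrelevant candidates", {
  base <- classificationScores(classifyProfileChange(
    losses = cw4_losses(), gains = cw4_gains(),
    candidates = c("H", "N"), weighting = "unit"))
  shuffled <- classificationScores(classifyProfileChange(
    losses = rev(cw4_losses()), gains = rev(cw4_gains()),
    candidates = c("N", "H"), weighting = "unit"))
  expect_equal(base, shuffled)
  with_extra <- classificationScores(classifyProfileChange(
    losses = cw4_losses(), gains = cw4_gains(),
    candidates = c("H", "N", "T", "CG1"), weighting = "unit"))
  for (p in c("H", "N"))
    expect_equal(with_extra$combined[with_extra$process == p],
                 base$combined[base$process == p])
})

test_that("an unchanged profile yields an explicit no-classification result", {
  m <- generateMixture(seed = 1)
  res <- classifyProfileChange(m, m)
  expect_true(res@noClassification)
  expect_length(classificationWinners(res), 0)
  expect_output(show(res), "No classification")
})

test_that("empty candidate list is rejected", {
  expect_error(classifyProfileChange(losses = "245-245-CB", gains = NULL,
                                     candidates = list(), weighting = "unit"),
               "non-empty")
})

test_that("noiseless simulated data score 1 for the generating process", {
  m <- generateMixture(seed = 5)
  for (p in c("H", "N", "T", "CG1")) {
    rs <- builtinProcess(p)
    after <- profileAtTime(simulateDechlorination(m, rs, times = 3), 3)
    # threshold 0 counts every true source, so the generating process
    # explains everything
    res <- classifyProfileChange(m, after, threshold = 0)
    sc <- classificationScores(res)
    expect_equal(sc$combined[sc$process == p], 1, info = p)
    expect_true(p %in% classificationWinners(res), info = p)
  }
  # H and N data identify their generator uniquely; T and CG1 rule sets are
  # contained in richer ones, so ties are reported honestly rather than
  # broken arbitrarily
  for (p in c("H", "N")) {
    after <- profileAtTime(
      simulateDechlorination(m, builtinProcess(p), times = 3), 3)
    res <- classifyProfileChange(m, after)
    expect_identical(classificationWinners(res), p)
  }
})

test_that("mole weighting requires profiles and scores scale-invariantly", {
  expect_error(classifyProfileChange(losses = cw4_losses(),
                                     gains = cw4_gains(),
                                     weighting = "mole"),
               "mole weighting")
  # scores from profiles are unchanged when all deltas scale together
  # (fractions are ratios of delta weights)
  m <- generateMixture(seed = 8)
  sim <- simulateDechlorination(m, builtinProcess("H"), times = c(1, 3))
  sc1 <- classificationScores(classifyProfileChange(
    m, profileAtTime(sim, 1), threshold = 0.5))
  expect_identical(sc1$process[1], "H")
})
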