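test_that("ring canonicalization picks the mirror-minimal form and is idempotent", {
  # brute-force oracle: compare both mirror images as sorted strings
  for (sub in all_position_subsets()) {
    a <- paste0(sort(sub), collapse = "")
    b <- paste0(sort(8 - sub), collapse = "")
    expected <- if (nchar(a) == 0) integer(0)
                else as.integer(strsplit(min(a, b), "")[[1]])
    got <- canonicalizeRing(sub)
    expect_identical(got, expected,
                     info = paste("subset", paste(sub, collapse = "")))
    expect_identical(canonicalizeRing(got), got)
  }
  expect_identical(canonicalizeRing(c(3, 6)), c(2L, 5L))
  expect_identical(canonicalizeRing(4), 4L)
  expect_identical(canonicalizeRing(c(2, 5, 6)), c(2L, 3L, 6L))
  expect_length(allRingPatterns(), 20)
})

test_that("canonicalizeRing rejects invalid positions", {
  expect_error(canonicalizeRing(c(1, 3)), "2\\.\\.6")
  expect_error(canonicalizeRing(c(7)), "2\\.\\.6")
  expect_error(canonicalizeRing(c(3, 3)), "duplicate")
})

test_that("parsing printed congener names round-trips exactly", {
  printed <- c(
    # loss/gain table names
    "245-245-CB", "234-245-CB", "2345-245-CB", "2345-236-CB", "2345-25-CB",
    "235-25-CB", "25-25-CB", "245-24-CB", "235-245-CB", "24-25-CB",
    "2345-234-CB", "2346-245-CB", "2345-26-CB", "245-25-CB", "234-236-CB",
    "235-34-CB", "236-245-CB", "236-24-CB", "2356-245-CB", "24-24-CB",
    "2356-24-CB", "24-26-CB", "24-2-CB", "2356-234-CB", "25-26-CB",
    # single-ring congeners
    "2356-CB", "2345-CB", "23456-CB", "236-34-CB")
  for (nm in printed)
    expect_identical(congenerName(parseCongener(nm)), nm, info = nm)
})

test_that("parsing normalizes non-canonical input and rejects malformed names", {
  # mirror image and swapped ring order normalize to the canonical name
  expect_identical(congenerName("36-CB"), "25-CB")
  expect_identical(congenerName("24-245-CB"), "245-24-CB")
  expect_identical(congenerName("25-24-CB"), "24-25-CB")
  expect_error(parseCongener("2345-245"), "-CB")
  expect_error(parseCongener("1234-CB"), "'1234'")
  expect_error(parseCongener("2347-245-CB"), "'2347'")
  expect_error(parseCongener("2344-25-CB"), "duplicate")
  expect_error(parseCongener("--CB"), "malformed")
  expect_error(parseCongener("234-25-24-CB"), "malformed")
})

test_that("congener accessors report structure", {
  cg <- parseCongener("2345-245-CB")
  expect_equal(nChlorines(cg), 7L)
  expect_equal(homolog(cg), "hepta")
  expect_identical(ringPatterns(cg), list(c(2L, 3L, 4L, 5L), c(2L, 4L, 5L)))
  expect_equal(homolog("24-2-CB"), "tri")
  expect_equal(nChlorines("2345-CB"), 4L)
})

test_that("enumeration yields the 209 congeners with the known homolog counts", {
  congs <- enumerateAllCongeners()
  expect_length(congs, 209)
  expect_false(anyDuplicated(congs) > 0)
  counts <- table(vapply(congs, homolog, character(1)))
  expected <- c(mono = 3, di = 12, tri = 24, tetra = 42, penta = 46,
                hexa = 42, hepta = 24, octa = 12, nona = 3, deca = 1)
  expect_equal(as.vector(counts[names(expected)]), unname(expected))
  expect_identical(enumerateAllCongeners(homolog = "deca"), "23456-23456-CB")
  expect_length(enumerateAllCongeners(homolog = "hexa"), 42)
})

test_that("enumeration agrees with a brute-force all-pairs oracle", {
  # independent oracle: all 32x32 ordered subset pairs, normalized by an
  # 8-variant symmetry key, minus the unchlorinated biphenyl
  subsets <- all_position_subsets()
  keys <- character(0)
  for (a in subsets)
    for (b in subsets) {
      if (length(a) + length(b) == 0) next
      keys <- c(keys, oracle_pair_key(a, b))
    }
  expect_equal(length(unique(keys)), 209)
  # and the package's names map 1:1 onto the oracle keys
  pkg_keys <- vapply(enumerateAllCongeners(), function(nm) {
    r <- ringPatterns(nm)
    oracle_pair_key(r[[1]], r[[2]])
  }, character(1))
  expect_setequal(unique(keys), unname(pkg_keys))
})

test_that("chlorine-site classification matches a brute-force neighbor scan", {
  for (pat in setdiff(allRingPatterns(), "")) {
    ring <- as.integer(strsplit(pat, "")[[1]])
    cg <- parseCongener(paste0(pat, "-CB"))
    sites <- classifyChlorines(cg)
    sites <- sites[sites$ring == 1, ]
    expect_setequal(sites$position, ring)
    for (p in ring) {
      row <- sites[sites$position == p, ]
      expect_equal(row$class,
                   if (p %in% c(2, 6)) "ortho" else if (p == 4) "para" else "meta")
      n_nb <- sum(c(p - 1, p + 1) %in% ring & c(p - 1, p + 1) >= 2 &
                    c(p - 1, p + 1) <= 6)
      expect_equal(row$flanking,
                   c("unflanked", "singly_flanked", "doubly_flanked")[n_nb + 1],
                   info = paste(pat, p))
    }
  }
})

test_that("site classification reproduces the motif examples", {
  s <- classifyChlorines("2345-CB")
  expect_equal(s$flanking[s$position == 3], "doubly_flanked")
  expect_equal(s$flanking[s$position == 4], "doubly_flanked")
  expect_equal(s$flanking[s$position == 2], "singly_flanked")
  expect_equal(s$flanking[s$position == 5], "singly_flanked")
  s2 <- classifyChlorines("25-CB")
  expect_true(all(s2$flanking == "unflanked"))
  s3 <- classifyChlorines("34-CB")
  expect_true(all(s3$flanking == "singly_flanked"))
  # ortho positions can never be doubly flanked
  for (pat in setdiff(allRingPatterns(), "")) {
    s <- classifyChlorines(paste0(pat, "-CB"))
    expect_false(any(s$class == "ortho" & s$flanking == "doubly_flanked"),
                 info = pat)
  }
})

test_that("molecular weight is the biphenyl mass plus 34.44 per chlorine", {
  expect_equal(molecularWeight("2-CB"), 154.21 + 34.44, tolerance = 1e-9)
  expect_equal(molecularWeight("245-245-CB"), 360.85, tolerance = 0.1)
  expect_equal(molecularWeight("23456-23456-CB"), 498.61, tolerance = 0.1)
  expect_equal(molecularWeight("hexa-CB"), molecularWeight("234-245-CB"))
  expect_equal(molecularWeight(c("2-CB", "24-CB")),
               154.21 + c(1, 2) * 34.44, tolerance = 1e-9)
})
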