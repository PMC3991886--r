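tab3 <- ssb_composition()

test_that("residue counting is an exact multiset count", {
  cnt <- count_residues("MAGKK")
  expect_s3_class(cnt, "ssb_counts")
  expect_equal(unname(unclass(cnt)[c("M", "A", "G", "K")]), c(1L, 1L, 1L, 2L))
  expect_equal(sum(cnt), 5L)
  set.seed(41)
  for (len in c(1, 17, 300)) {
    s <- random_sequence(len)
    expect_equal(sum(count_residues(s)), len)
  }
})

test_that("percentages follow the printed one-decimal half-up convention", {
  expect_equal(unname(residue_percentages(count_residues("AGGG"))["A"]), 25.0)
  # 16/142 = 11.267 -> 11.3, the printed value
  seq142 <- paste0(strrep("G", 16), strrep("A", 126))
  expect_equal(unname(residue_percentages(count_residues(seq142))["G"]), 11.3)
  expect_error(residue_percentages(structure(integer(20),
                                            names = canonical_residues(),
                                            class = "ssb_counts")),
               "zero-length")
})

test_that("count reconstruction reproduces hand-verified rows and their sums", {
  dps <- reconstruct_counts(tab3$percent["DpsSSB", ], 142)
  expect_equal(sum(dps), 142L)
  expect_equal(unname(unclass(dps)[c("A", "V", "I", "L", "G", "R", "K", "D", "E", "C")]),
               c(10L, 5L, 9L, 7L, 16L, 10L, 6L, 7L, 11L, 1L))
  # re-rounding the reconstruction reproduces the printed row exactly
  expect_equal(residue_percentages(dps), tab3$percent["DpsSSB", ])

  eco <- suppressWarnings(reconstruct_counts(tab3$percent["EcoSSB", ], 178))
  expect_equal(sum(eco), 178L)
  expect_equal(unname(unclass(eco)[c("A", "V", "I", "L")]), c(13L, 13L, 5L, 8L))

  one <- structure(c(100, rep(0, 19)), names = canonical_residues())
  expect_equal(unname(unclass(reconstruct_counts(one, 50))["A"]), 50L)
})

test_that("rows with unrealizable printed entries are flagged, and only then", {
  # FpsSSB Ser 8.0 at length 140 has no realizing integer count
  expect_warning(reconstruct_counts(tab3$percent["FpsSSB", ], 140), "S")
  expect_error(reconstruct_counts(tab3$percent["FpsSSB", ], 140, check = "error"), "S")
  expect_silent(reconstruct_counts(tab3$percent["DpsSSB", ], 142))
})

test_that("reconstruction inverts percentages for arbitrary sequences", {
  set.seed(99)
  for (len in c(3, 50, 142, 499)) {
    s <- random_sequence(len)
    cnt <- count_residues(s)
    back <- reconstruct_counts(residue_percentages(cnt), len)
    expect_identical(unclass(back), unclass(cnt))
  }
})

test_that("group fractions reproduce the published cold-adaptation figures", {
  expect_equal(unname(group_fractions(tab3$percent["DpsSSB", ], groups = "charged")), 24.5)
  expect_equal(unname(group_fractions(tab3$percent["DpsSSB", ], groups = "polar")), 30.2)
  expect_equal(unname(group_fractions(tab3$percent["FpsSSB", ], groups = "hydrophobic")), 39.9)
  expect_equal(unname(group_fractions(tab3$percent["EcoSSB", ], groups = "aromatic")), 6.6)
  empty_scheme <- group_scheme()
  empty_scheme$nothing <- character(0)
  expect_equal(unname(group_fractions(tab3$percent["DpsSSB", ],
                                      scheme = empty_scheme, groups = "nothing")), 0)
  expect_error(group_fractions(tab3$percent["DpsSSB", ], groups = "bogus"), "bogus")
})

test_that("group fractions from counts agree with a per-character tally", {
  set.seed(7)
  sch <- group_scheme()
  for (i in 1:5) {
    s <- random_sequence(120)
    got <- group_fractions(count_residues(s))
    for (g in names(sch)) {
      expect_equal(unname(got[g]),
                   round(brute_force_group_pct(s, sch[[g]]) + 1e-9, 1),
                   tolerance = 0.051)
    }
  }
})

test_that("a residue-set partition of the alphabet conserves the row total", {
  part <- list(a = canonical_residues()[1:7], b = canonical_residues()[8:15],
               c = canonical_residues()[16:20])
  sch <- group_scheme()
  sch$a <- part$a; sch$b <- part$b; sch$c <- part$c
  row <- tab3$percent["PinSSB", ]
  got <- group_fractions(row, scheme = sch, groups = c("a", "b", "c"))
  expect_lt(abs(sum(got) - sum(row)), 0.2)
})

test_that("Arg/(Arg+Lys) matches the published ratios and handles edge cases", {
  expect_equal(arg_lys_ratio(tab3$percent["DpsSSB", ]), 0.63)
  expect_equal(arg_lys_ratio(tab3$percent["TmaSSB", ]), 0.75)
  expect_equal(arg_lys_ratio("RKRK"), 0.50)
  no_rk <- structure(c(100, rep(0, 19)), names = canonical_residues())
  expect_warning(r <- arg_lys_ratio(no_rk), "undefined")
  expect_true(is.na(r))
})
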