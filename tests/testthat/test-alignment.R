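test_that("residue similarity follows the six-group scheme, overlaps included", {
  expect_true(all(residues_similar(c("V", "W", "E", "K", "Q", "S"),
                                   c("M", "Y", "D", "R", "D", "T"))))
  # D sits in two groups; E and Q are not co-members of any
  expect_true(residues_similar("E", "D"))
  expect_true(residues_similar("Q", "D"))
  expect_false(residues_similar("E", "Q"))
  expect_false(residues_similar("A", "G"))
  expect_true(residues_similar("A", "A"))
})

test_that("self-alignment scores 100/100 and de-gapping returns the inputs", {
  al <- global_align("ACDE", "ACDE")
  expect_equal(al$identity_pct, 100)
  expect_equal(al$similarity_pct, 100)
  al2 <- global_align("MAGKWLL", "MAKWL")
  expect_equal(gsub("-", "", al2$aligned_a), "MAGKWLL")
  expect_equal(gsub("-", "", al2$aligned_b), "MAKWL")
})

test_that("identity and similarity count columns the way the published table does", {
  al <- global_align("KDE", "RDE")
  expect_equal(al$identity_pct, 67)   # 2/3
  expect_equal(al$similarity_pct, 100) # K~R by the basic group
  # forced terminal gaps enter the full-alignment-length denominator
  al3 <- global_align("AAAA", "AA")
  expect_equal(nchar(al3$aligned_b), 4L)
  expect_equal(al3$identity_pct, 50)
  expect_equal(identity_similarity(al3$aligned_a, al3$aligned_b,
                                   denominator = "shorter")[["identity_pct"]], 100)
  expect_error(identity_similarity("A-", "AB-"), "length")
})

test_that("identity/similarity are symmetric under the default denominator", {
  set.seed(13)
  for (i in 1:5) {
    a <- random_sequence(sample(8:20, 1))
    b <- random_sequence(sample(8:20, 1))
    ab <- global_align(a, b); ba <- global_align(b, a)
    expect_equal(ab$identity_pct, ba$identity_pct)
    expect_equal(ab$similarity_pct, ba$similarity_pct)
  }
})

test_that("similarity never decreases when a group is enlarged", {
  set.seed(17)
  bigger <- similarity_scheme()
  bigger$g6 <- c("S", "T", "A", "G")
  for (i in 1:5) {
    a <- random_sequence(12); b <- random_sequence(12)
    base <- global_align(a, b)$similarity_pct
    grown <- global_align(a, b, scheme = bigger)$similarity_pct
    expect_gte(grown, base)
  }
})

test_that("DP alignment score equals exhaustive enumeration on short pairs", {
  # every pair over a two-letter alphabet up to length 3, plus random pairs
  # up to length 7 over a six-letter alphabet
  two <- unlist(lapply(1:3, function(k) {
    apply(expand.grid(rep(list(c("A", "K")), k)), 1, paste, collapse = "")
  }))
  pairs <- expand.grid(a = two, b = two, stringsAsFactors = FALSE)
  set.seed(23)
  extra <- data.frame(
    a = replicate(15, random_sequence(sample(4:7, 1), c("A", "C", "D", "E", "K", "W"))),
    b = replicate(15, random_sequence(sample(4:7, 1), c("A", "C", "D", "E", "K", "W"))))
  pairs <- rbind(pairs, extra)
  for (i in seq_len(nrow(pairs))) {
    got <- global_align(pairs$a[i], pairs$b[i])$score
    want <- brute_force_align_score(pairs$a[i], pairs$b[i], blosum62)
    expect_equal(got, want, info = paste(pairs$a[i], pairs$b[i]))
  }
})

test_that("alignment rejects empty input and non-default matrices are honored", {
  expect_error(global_align("", "ACD"), "empty")
  # PAM250 is more permissive than BLOSUM62; the score must differ for a
  # mismatch-rich pair, while percentages remain well-defined
  al_b <- global_align("WWWW", "AAAA")
  al_p <- global_align("WWWW", "AAAA", matrix = "PAM250")
  expect_false(isTRUE(all.equal(al_b$score, al_p$score)))
})

test_that("MSA conservation shading classes follow the cluster fractions", {
  msa <- c("WAC-A", "WACDA", "WACDG", "FLCDA", "LVCDA")
  sh <- shade_msa(msa)
  # col 1: W,W,W,F,L -> W/F co-group gives 4/5
  expect_equal(sh$class[1], ">=80%")
  expect_equal(sh$max_fraction[1], 0.8)
  # col 3: all C
  expect_equal(sh$class[3], "100%")
  # col 4: gap breaks full conservation: 4/5
  expect_equal(sh$class[4], ">=80%")
  # col 5: A,A,G,A,A -> 4/5 (A and G are not similar)
  expect_equal(sh$class[5], ">=80%")
  # five mutually dissimilar residues
  sh2 <- shade_msa(c("A", "G", "C", "P", "H"))
  expect_equal(sh2$class, "none")
  expect_error(shade_msa(c("AC", "A")), "ragged")
})

test_that("column two of the toy MSA is graded >=60%", {
  # A,A,A,L,V -> {A,A,A} vs {L,V(,A? no)}: best cluster 3/5
  sh <- shade_msa(c("WAC", "WAC", "WAC", "FLC", "LVC"))
  expect_equal(sh$class[2], ">=60%")
})
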