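test_that("affix candidates obey the two strict thresholds on both sides", {
  p <- colexParams("affix")
  aff <- enumerateAffixes(c("h", "a", "n", "t", "ʃ", "uː"), p)
  expect_equal(nrow(aff), 2L)
  expect_equal(aff$affix[aff$side == "prefix"][[1]], c("h", "a", "n"))
  expect_equal(aff$affix[aff$side == "suffix"][[1]], c("t", "ʃ", "uː"))

  # a 3-token affix plus a 3-token remainder need at least 6 tokens
  for (n in 1:5) {
    expect_equal(nrow(enumerateAffixes(letters[seq_len(n)], p)), 0L)
  }

  # 9-character word: prefixes and suffixes of lengths 3-6, 8 candidates
  hs <- strsplit("handschuh", "")[[1]]
  aff9 <- enumerateAffixes(hs, p)
  expect_equal(nrow(aff9), 8L)
  expect_equal(sort(aff9$length[aff9$side == "prefix"]), 3:6)
  expect_equal(sort(aff9$length[aff9$side == "suffix"]), 3:6)
  expect_true("h a n d" %in% aff9$key)
  expect_true("s c h u h" %in% aff9$key)
  # a word is never indexed under its own full form
  expect_false("h a n d s c h u h" %in% aff9$key)

  # sides restriction
  pp <- colexParams("affix", sides = "prefix")
  expect_equal(unique(enumerateAffixes(hs, pp)$side), "prefix")
})

test_that("full colexifications: identical forms link distinct concepts", {
  f <- languageForms(toy_wordlist(earth_world_table()), "German")
  inst <- fullColexifications(f)
  expect_equal(nrow(inst), 1L)
  expect_equal(inst$concept_a, "EARTH")
  expect_equal(inst$concept_b, "WORLD")
  expect_equal(inst$shared, "E r d e")

  # all forms distinct -> nothing
  f2 <- lang_forms(c("abc", "def", "ghi"), c("A", "B", "C"))
  expect_equal(nrow(fullColexifications(f2)), 0L)

  # one form expressing {X, Y, Z}: all pairs, checked against brute force
  f3 <- lang_forms(rep("tolo", 3), c("X", "Y", "Z"))
  inst3 <- fullColexifications(f3)
  cps <- c("X", "Y", "Z")
  brute <- t(combn(cps, 2))
  expect_equal(nrow(inst3), nrow(brute))
  expect_equal(paste(inst3$concept_a, inst3$concept_b),
               paste(brute[, 1], brute[, 2]))
  expect_equal(nrow(fullColexifications(f3[0, ])), 0L)
})

test_that("affix colexifications recover the glove example with direction", {
  f <- languageForms(toy_wordlist(hand_glove_table(), lowercase = TRUE), "German")
  inst <- affixColexifications(f)
  expect_equal(nrow(inst), 2L)
  expect_equal(sort(paste(inst$concept_a, "->", inst$concept_b)),
               c("HAND -> GLOVE", "SHOE -> GLOVE"))
  expect_equal(inst$side_b[inst$concept_a == "HAND"], "prefix")
  expect_equal(inst$side_b[inst$concept_a == "SHOE"], "suffix")

  # direction: the reused word points at the compound, never the reverse
  f2 <- lang_forms(c("finger", "fingernagel"), c("FINGER", "FINGERNAIL"))
  inst2 <- affixColexifications(f2)
  expect_equal(nrow(inst2), 1L)
  expect_equal(inst2$concept_a, "FINGER")
  expect_equal(inst2$concept_b, "FINGERNAIL")

  # identical forms: remainder would be 0, so no affix relation
  f3 <- lang_forms(c("atolo", "atolo"), c("X", "Y"))
  expect_equal(nrow(affixColexifications(f3)), 0L)
  expect_equal(nrow(fullColexifications(f3)), 1L)
})

test_that("overlap colexifications share a peripheral substring without part-of", {
  f <- lang_forms(c("waterfall", "watermelon"), c("WATERFALL", "WATERMELON"))
  inst <- overlapColexifications(f)
  expect_equal(nrow(inst), 1L)
  expect_equal(inst$shared, "w a t e r")
  expect_equal(c(inst$side_a, inst$side_b), c("prefix", "prefix"))

  # part-of relations are affix, not overlap
  f2 <- lang_forms(c("hand", "handschuh"), c("HAND", "GLOVE"))
  expect_equal(nrow(overlapColexifications(f2)), 0L)
  expect_equal(nrow(affixColexifications(f2)), 1L)

  # a shared peripheral substring of exactly 4 tokens fails the strict threshold
  f3 <- lang_forms(c("abcdwxyz", "abcdmnop"), c("A", "B"))
  expect_equal(nrow(overlapColexifications(f3)), 0L)
  # ... 5 tokens passes
  f4 <- lang_forms(c("abcdewxyz", "abcdemnop"), c("A", "B"))
  expect_equal(nrow(overlapColexifications(f4)), 1L)
  expect_equal(f4$segments[[1]][1:5], strsplit("abcde", "")[[1]])
})

test_that("each overlap pair is reported once, at its longest shared substring", {
  # forms share prefixes of length 6; nested shorter keys must not duplicate
  f <- lang_forms(c("abcdefxxxx", "abcdefyyyy"), c("A", "B"))
  inst <- overlapColexifications(f)
  expect_equal(nrow(inst), 1L)
  expect_equal(inst$shared, "a b c d e f")
})

test_that("side mixing is admitted by default and rejected with sameSideOnly", {
  # "abcde" is a prefix of the first form and a suffix of the second
  f <- lang_forms(c("abcdewxyz", "mnopabcde"), c("A", "B"))
  inst <- overlapColexifications(f)
  expect_equal(nrow(inst), 1L)
  expect_equal(sort(c(inst$side_a, inst$side_b)), c("prefix", "suffix"))
  strict <- overlapColexifications(f, colexParams("overlap", sameSideOnly = TRUE))
  expect_equal(nrow(strict), 0L)
})

test_that("efficient and naive inference produce identical instance sets", {
  for (seed in 1:10) {
    wl <- random_wordlist(n_forms = 50, n_languages = 5, seed = seed)
    for (lg in languageIds(wl)) {
      f <- languageForms(wl, lg)
      for (kind in c("affix", "overlap")) {
        p <- colexParams(kind)
        eff <- switch(kind, affix = affixColexifications(f, p),
                      overlap = overlapColexifications(f, p))
        naive <- naivePartialColexifications(f, p, kind)
        expect_equal(instance_set(eff), instance_set(naive),
                     info = paste("seed", seed, lg, kind))
      }
    }
  }
})

test_that("oracle equivalence also holds under non-default thresholds and sides", {
  wl <- random_wordlist(n_forms = 40, n_languages = 2, seed = 99, max_len = 12)
  grid <- expand.grid(a = c(1, 3), r = c(0, 2), s = c("both", "prefix", "suffix"),
                      stringsAsFactors = FALSE)
  for (lg in languageIds(wl)) {
    f <- languageForms(wl, lg)
    for (i in seq_len(nrow(grid))) {
      for (kind in c("affix", "overlap")) {
        p <- colexParams(kind, affixMin = grid$a[i], residueMin = grid$r[i],
                         sides = grid$s[i])
        eff <- switch(kind, affix = affixColexifications(f, p),
                      overlap = overlapColexifications(f, p))
        naive <- naivePartialColexifications(f, p, kind)
        expect_equal(instance_set(eff), instance_set(naive),
                     info = paste(lg, kind, grid$a[i], grid$r[i], grid$s[i]))
      }
    }
  }
})

test_that("raising either threshold never adds an instance", {
  wl <- random_wordlist(n_forms = 45, n_languages = 3, seed = 7)
  # pair-level identity: the witnessing substring and sides may legitimately
  # change when thresholds exclude the longest shared substring
  key_of <- function(x) paste(x$language_id, x$concept_a, x$concept_b,
                              x$form_a, x$form_b)
  for (kind in c("affix", "overlap")) {
    for (lg in languageIds(wl)) {
      f <- languageForms(wl, lg)
      base <- colexParams(kind, affixMin = 1, residueMin = 0)
      loose <- switch(kind, affix = affixColexifications(f, base),
                      overlap = overlapColexifications(f, base))
      for (a in 1:3) for (r in 0:2) {
        p <- colexParams(kind, affixMin = a, residueMin = r)
        tight <- switch(kind, affix = affixColexifications(f, p),
                        overlap = overlapColexifications(f, p))
        expect_true(all(key_of(tight) %in% key_of(loose)),
                    info = paste(kind, lg, a, r))
      }
    }
  }
})

test_that("affix witnesses always show the source form as a peripheral part of the host", {
  wl <- random_wordlist(n_forms = 50, n_languages = 4, seed = 13)
  for (lg in languageIds(wl)) {
    inst <- affixColexifications(languageForms(wl, lg))
    if (!nrow(inst)) next
    for (i in seq_len(nrow(inst))) {
      a <- strsplit(inst$form_a[i], " ", fixed = TRUE)[[1]]
      b <- strsplit(inst$form_b[i], " ", fixed = TRUE)[[1]]
      expect_true(length(a) < length(b))
      expect_equal(inst$shared[i], inst$form_a[i])
      if (inst$side_b[i] == "prefix") {
        expect_equal(a, b[seq_along(a)])
      } else {
        expect_equal(a, b[(length(b) - length(a) + 1):length(b)])
      }
    }
  }
})

test_that("canonicalization orders undirected endpoints and rows deterministically", {
  f <- lang_forms(c("abcdewxyz", "abcdemnop"), c("B", "A"))
  inst <- overlapColexifications(f)
  expect_equal(inst$concept_a, "A")
  expect_equal(inst$concept_b, "B")
  shuffled <- inst[sample(nrow(inst)), ]
  expect_equal(canonicalizeInstances(shuffled, directed = FALSE), inst)
})
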