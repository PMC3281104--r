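test_that("pattern parsing handles the family motifs and round-trips", {
  p <- parse_pattern("C-x-x-[CU]-x-x>")
  expect_true(p$anchored)
  expect_length(p$elements, 6)
  expect_identical(vapply(p$elements, `[[`, character(1), "type"),
                   c("FIXED", "WILDCARD", "WILDCARD", "FIXED", "WILDCARD", "WILDCARD"))
  expect_identical(p$elements[[1]]$residues, "C")
  expect_identical(p$elements[[4]]$residues, c("C", "U"))

  # canonical render re-parses to an equal pattern, for a spread of shapes
  for (txt in c("C-x-x-[CU]-x-x>", "x>", "CxxCxx>", "C-x(3,10)-C-x-x>",
                "[UC]x(2)[AG]", "u-x-x>")) {
    canon <- render_pattern(parse_pattern(txt))
    expect_identical(parse_pattern(canon), parse_pattern(txt), info = txt)
    expect_identical(render_pattern(parse_pattern(canon)), canon, info = txt)
  }

  # single anchored wildcard matches any non-empty sequence
  expect_true(matches("x>", "M"))
  expect_true(matches("x>", "ACDEFGHIKLMNPQ"))
})

test_that("malformed patterns fail with informative errors", {
  expect_error(parse_pattern("C-x(5,3)>"), "range")
  expect_error(parse_pattern("C-J-x>"), "unknown character 'J'")
  expect_error(parse_pattern("[]x>"), "empty residue class")
  expect_error(parse_pattern(""), "empty pattern")
  expect_error(parse_pattern("C-[AB"), "unterminated")
})

test_that("anchored matching follows the terminus and distinguishes C from U", {
  # the human-style terminus CVTUSS> carries the Cxx[CU]xx> motif
  expect_true(matches("C-x-x-[CU]-x-x>", "MKAPLLECVTUSS"))
  expect_false(matches("Cxx>", "AAAAAA"))
  # bare C never matches selenocysteine
  expect_false(matches("C-x-x>", "AAAUGG"))
  expect_true(matches("[CU]-x-x>", "AAAUGG"))
  # anchoring: motif present internally but not at the terminus
  expect_false(matches("C-x-x-C-x-x>", "CAACAAW"))
  expect_true(matches("C-x-x-C-x-x", "CAACAAW"))
  expect_error(matches("Cxx>", "AB1C"), "alphabet")
})

test_that("matching agrees with the exhaustive RANGE-assignment oracle", {
  withr::local_seed(421)
  for (rep in 1:250) {
    pat <- random_pattern(15)
    s <- random_protein(sample(1:15, 1))
    expect_identical(matches(pat, s), oracle_matches(pat, s),
                     info = paste(pat, s))
  }
})

test_that("terminal classification reproduces the ring categories", {
  # inner ring from the -3 residue, outer ring by gap precedence
  got <- classify_terminus(c(hs = "MEPLAARFENELPALAACVTUSS"))
  expect_identical(got$inner, "U_TERM")
  expect_identical(got$outer, "CXXC")

  expect_identical(classify_terminus("AAAAAAAAAAAAAAAADEFG")[, c("inner", "outer")],
                   data.frame(inner = "NONE", outer = "NONE"))

  # upstream C with gap 4: the bounded-range category
  s <- paste0("MAAAAAAA", "C", "AAAA", "CTS")
  got <- classify_terminus(s)
  expect_identical(got$inner, "C_TERM")
  expect_identical(got$outer, "CX_RANGE_C")
  expect_true(matches("C-x(3,10)-[CU]-x-x>", s))

  # precedence: the smallest gap wins (here CXC over the bounded range)
  got <- classify_terminus("MAAAAACAAACACTS")   # C at -9, -5 and -3
  expect_identical(got$outer, "CXC")
  got2 <- classify_terminus("MAAAAACAACAACTS")  # C at -9, -6 and -3
  expect_identical(got2$outer, "CXXC")

  expect_error(classify_terminus("ACDEF"), "shorter")
})

test_that("classification is local: inner depends on the last 3 residues, outer on the last 14", {
  withr::local_seed(99)
  for (rep in 1:60) {
    s <- random_protein(sample(20:40, 1))
    base <- classify_terminus(s)
    # mutate everything before the final 14 residues
    n <- nchar(s)
    prefix <- random_protein(n - 14)
    mutated <- paste0(prefix, substr(s, n - 13, n))
    got <- classify_terminus(mutated)
    expect_identical(got$inner, base$inner)
    expect_identical(got$outer, base$outer)
    # inner: only final 3 matter
    inner_only <- paste0(random_protein(n - 3), substr(s, n - 2, n))
    expect_identical(classify_terminus(inner_only)$inner, base$inner)
  }
})

test_that("census counts match per-pattern matching and is additive", {
  pl <- gen_proteome(10, length_min = 50, length_max = 80,
                     terminal_spec = c("Cxx>" = 1.0), seed = 11)
  cen <- census(pl$seqs)
  expect_identical(as.integer(cen$class_counts[["C_TERM"]]), 10L)
  expect_identical(cen$pattern_counts$k[cen$pattern_counts$pattern == "C-x-x>"], 10L)

  empty <- census(character(0))
  expect_identical(empty$n, 0L)
  expect_true(all(empty$pattern_counts$k == 0L))

  # permutation invariance and additivity over disjoint sets
  mix <- gen_proteome(40, length_min = 40, length_max = 60,
                      terminal_spec = c("Cxx>" = 0.3, "CxxUxx>" = 0.2), seed = 5)
  s <- mix$seqs
  a <- census(s[1:15]); b <- census(s[16:40])
  whole <- census(s)
  shuffled <- census(s[sample(seq_along(s))])
  expect_identical(whole$pattern_counts$k, a$pattern_counts$k + b$pattern_counts$k)
  expect_identical(whole$pattern_counts$k, shuffled$pattern_counts$k)
})

test_that("kinase fingerprint slots are found in order, greedily", {
  spacer <- function(n) paste(rep("A", n), collapse = "")
  s <- paste0(spacer(6), "GTTGAG", spacer(5), "K", spacer(4), "E", spacer(6),
              "HGV", spacer(5), "N", spacer(4), "DYG", spacer(10))
  fp <- annotate_kinase_fingerprint(s)
  expect_true(all(fp$present))
  expect_true(all(diff(fp$start) > 0))
  expect_identical(fp$hit[fp$slot == "G_LOOP"], "GTTGAG")
  expect_identical(fp$hit[fp$slot == "DFG"], "DYG")

  # no D[YF]G anywhere: that slot is absent
  s2 <- paste0(spacer(6), "GTTGAG", spacer(5), "K", spacer(4), "E", spacer(6),
               "HGV", spacer(5), "N", spacer(20))
  fp2 <- annotate_kinase_fingerprint(s2)
  expect_false(fp2$present[fp2$slot == "DFG"])
  expect_true(all(fp2$present[fp2$slot != "DFG"]))

  # scrambled order: a G-loop sitting after the DYG motif cannot be placed
  s3 <- paste0(spacer(10), "DYG", spacer(10), "GTTGAG", spacer(30))
  fp3 <- annotate_kinase_fingerprint(s3)
  expect_true(fp3$present[fp3$slot == "G_LOOP"])   # earliest slot claims it
  expect_false(fp3$present[fp3$slot == "DFG"])     # nothing left downstream
})

test_that("column conservation matches closed-form information content", {
  aln <- c(a = "CAAA", b = "CACA", c = "CACA", d = "CACA")
  # invariant column: IC = log2(20)
  prof <- column_conservation(aln)
  expect_equal(prof$ic[1], log2(20), tolerance = 1e-12)

  # uniform column over the 20 residues: IC = 0
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  aln20 <- setNames(paste0(aa20, "A"), paste0("s", 1:20))
  expect_equal(column_conservation(aln20)$ic[1], 0, tolerance = 1e-12)

  # 50/50 two-residue column: IC = log2(20) - 1
  half <- setNames(c(rep("CA", 5), rep("SA", 5)), paste0("s", 1:10))
  expect_equal(column_conservation(half)$ic[1], log2(20) - 1, tolerance = 1e-12)

  # gap handling: >50% gaps flagged, distribution over non-gap residues
  gappy <- c(a = "C-", b = "C-", c = "CA", d = "C.")
  prof <- column_conservation(gappy)
  expect_true(prof$flagged[2])
  expect_false(prof$flagged[1])
  expect_equal(sum(prof$freqs[[2]]), 1)

  expect_error(column_conservation(c(a = "CA", b = "CAA")), "ragged")
})
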