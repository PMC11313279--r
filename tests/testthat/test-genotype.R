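# alleles, genotype enumeration, expected patterns, informative positions

test_that("allele sequences have length 2m + n", {
  expect_identical(nchar(allele_sequence(allele(12, 5))), 29L)
  expect_identical(nchar(allele_sequence(allele(11, 9))), 31L)
  expect_identical(allele_sequence(allele(1, 1)), "TGT")
  expect_identical(allele_sequence(allele(2, 3)), "TGTGTTT")
})

test_that("genotypes are unordered pairs with a canonical label", {
  a <- allele(12, 5); b <- allele(11, 9)
  expect_identical(genotype(a, b)$label, genotype(b, a)$label)
  expect_identical(genotype(a, b)$label, "(TG)12T5/(TG)11T9")
  expect_identical(parse_genotype("(TG)11T9/(TG)12T5")$label,
                   "(TG)12T5/(TG)11T9")
  expect_identical(parse_genotype("(TG)11T7")$label, "(TG)11T7/(TG)11T7")
})

test_that("enumeration covers all unordered pairs with replacement", {
  expect_length(enumerate_genotypes(search_space()), 3321L)  # 81 * 82 / 2
  expect_length(enumerate_genotypes(search_space(5, 5, 11, 11)), 1L)
  expect_length(enumerate_genotypes(search_space(5, 5, 11, 12)), 3L)
  labels <- vapply(enumerate_genotypes(search_space()),
                   function(g) g$label, "")
  expect_identical(anyDuplicated(labels), 0L)
  expect_error(search_space(5, 4, 8, 16), class = "polytg_empty_space")
})

test_that("forward pattern of (TG)12T5/(TG)11T9 has its only T/G position at index 23", {
  p <- expected_pattern(parse_genotype("(TG)12T5/(TG)11T9"), "forward")
  expect_identical(p$length, 31L)
  expect_identical(which(p$sets == "TG") - 1L, 23L)
  expect_equal(p$et[24], 0.5)
  expect_equal(p$eg[24], 0.5)
  # dosage dilution past the shorter allele (positions 29, 30)
  expect_equal(p$et[30:31], c(0.5, 0.5))
  expect_equal(p$eg[30:31], c(0, 0))
})

test_that("reverse pattern of (TG)12T5/(TG)11T9 has T/G at the 6th and 8th position from the 3' end", {
  p <- expected_pattern(parse_genotype("(TG)12T5/(TG)11T9"), "reverse")
  expect_identical(p$length, 31L)
  from3p <- rev(p$sets)
  expect_identical(which(from3p == "TG"), c(6L, 8L))
})

test_that("homozygous patterns are single-base with unit dosage everywhere", {
  for (dir in c("forward", "reverse")) {
    p <- expected_pattern(parse_genotype("(TG)11T7"), dir)
    expect_false(any(p$sets == "TG"))
    expect_true(all(p$et + p$eg == 1))
    expect_true(all(p$et %in% c(0, 1)))
  }
})

test_that("expected sets equal the union of the aligned allele strings", {
  set.seed(42)
  for (rep in 1:25) {
    m <- sample(8:16, 2, TRUE); n <- sample(3:11, 2, TRUE)
    g <- genotype(allele(m[1], n[1]), allele(m[2], n[2]))
    for (dir in c("forward", "reverse")) {
      p <- expected_pattern(g, dir)
      align <- if (dir == "forward") "left" else "right"
      o <- oracle_pattern(oracle_allele_string(g$allele_a$m, g$allele_a$n),
                          oracle_allele_string(g$allele_b$m, g$allele_b$n),
                          align)
      expect_equal(p$et, o$et)
      expect_equal(p$eg, o$eg)
      expect_identical(p$length, max(g$allele_a$tract_length,
                                     g$allele_b$tract_length))
    }
    # both directions share the expected length
    expect_identical(expected_pattern(g, "forward")$length,
                     expected_pattern(g, "reverse")$length)
  }
})

test_that("right alignment is left alignment of the reversed allele sequences", {
  set.seed(7)
  for (rep in 1:10) {
    m <- sample(8:16, 2, TRUE); n <- sample(3:11, 2, TRUE)
    g <- genotype(allele(m[1], n[1]), allele(m[2], n[2]))
    p_rev <- expected_pattern(g, "reverse")
    rev_str <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
    o <- oracle_pattern(rev_str(allele_sequence(g$allele_a)),
                        rev_str(allele_sequence(g$allele_b)), "left")
    expect_equal(rev(p_rev$et), o$et)
    expect_equal(rev(p_rev$eg), o$eg)
  }
})

test_that("informative positions are where surviving patterns disagree", {
  g1 <- parse_genotype("(TG)11T7")
  expect_identical(
    informative_positions(list(expected_pattern(g1, "forward"),
                               expected_pattern(g1, "forward")), "forward"),
    integer(0))
  expect_identical(informative_positions(list(), "forward"), integer(0))

  # single difference: a T/G position versus a pure T position
  g2 <- parse_genotype("(TG)12T5/(TG)11T7")  # lengths 29/29, one TG site
  p1 <- expected_pattern(g1, "forward")
  p2 <- expected_pattern(g2, "forward")
  diff <- informative_positions(list(p1, p2), "forward")
  expect_identical(diff, which(p1$sets != p2$sets) - 1L)
  expect_gt(length(diff), 0L)

  # unequal lengths: the no-base marker makes trailing positions informative
  p3 <- expected_pattern(parse_genotype("(TG)11T9"), "forward")  # length 31
  tail2 <- informative_positions(list(p1, p3), "forward")
  expect_true(all(c(29L, 30L) %in% tail2))

  # reverse frame pads at the 5' side instead
  q1 <- expected_pattern(g1, "reverse")
  q3 <- expected_pattern(parse_genotype("(TG)11T9"), "reverse")
  rev_diff <- informative_positions(list(q1, q3), "reverse")
  expect_true(all(c(0L, 1L) %in% rev_diff))
})
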