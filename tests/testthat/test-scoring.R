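# elimination, the normalized difference score, and ranking

hom_obs <- function(m, n) {
  # noiseless observation of a homozygote, both directions
  s <- strsplit(allele_sequence(allele(m, n)), "")[[1]]
  ot <- as.numeric(s == "T"); og <- as.numeric(s == "G")
  list(forward = obs_tract(ot, og, "forward"),
       reverse = obs_tract(ot, og, "reverse"))
}

test_that("an expected single base with absent signal eliminates", {
  g <- parse_genotype("(TG)11T7")
  o <- hom_obs(11, 7)
  expect_true(is_compatible(o$forward, o$reverse, g))
  # kill the thymine signal at one informative poly-T position
  bad <- o
  bad$forward$ot[25] <- 0
  expect_false(is_compatible(bad$forward, bad$reverse, g))
  # but if that position is uninformative it cannot eliminate
  masked <- bad
  masked$forward$informative_mask[25] <- FALSE
  expect_true(is_compatible(masked$forward, masked$reverse, g))
})

test_that("T/G positions accept either base and never eliminate", {
  g <- parse_genotype("(TG)12T5/(TG)11T9")  # forward T/G at 0-based 23
  o <- hom_obs(11, 9)  # length 31 observation
  o$forward$ot[24] <- 0; o$forward$og[24] <- 1
  expect_true(is_compatible(o$forward, o$reverse, g))
  o$forward$ot[24] <- 1; o$forward$og[24] <- 0
  expect_true(is_compatible(o$forward, o$reverse, g))
})

test_that("observed signal beyond the expected length never eliminates", {
  g <- parse_genotype("(TG)11T7")          # expected length 29
  o <- hom_obs(11, 7)
  # a spurious extra thymine peak past the expected tract end
  o$forward$ot <- c(o$forward$ot, 1); o$forward$og <- c(o$forward$og, 0)
  o$forward$informative_mask <- c(o$forward$informative_mask, TRUE)
  o$forward$length <- 30L
  expect_true(is_compatible(o$forward, o$reverse, g))
})

test_that("an expected tract longer than the observed one is incompatible", {
  g <- parse_genotype("(TG)11T9")          # expected length 31
  o <- hom_obs(11, 7)                      # observed length 29
  expect_false(is_compatible(o$forward, o$reverse, g))
})

test_that("a perfect match scores the closed form (100 - 2L) / 1e5", {
  o <- hom_obs(11, 7)
  g <- parse_genotype("(TG)11T7")
  d <- difference_score(o$forward, o$reverse,
                        expected_pattern(g, "forward"),
                        expected_pattern(g, "reverse"))
  expect_equal(d, 4.2e-4, tolerance = 1e-12)
})

test_that("one unexpected unit peak adds 1 / (2 (nF + nR)) to the score", {
  # observation one position longer than the expected pattern, pure T there
  g <- parse_genotype("(TG)11T7")                   # expected length 29
  o <- hom_obs(11, 7)
  o$forward$ot <- c(o$forward$ot, 1); o$forward$og <- c(o$forward$og, 0)
  o$forward$informative_mask <- c(o$forward$informative_mask, TRUE)
  o$forward$length <- 30L
  d <- difference_score(o$forward, o$reverse,
                        expected_pattern(g, "forward"),
                        expected_pattern(g, "reverse"))
  expect_equal(d, 1 / (2 * 59) + 4.2e-4, tolerance = 1e-12)
})

test_that("uninformative positions drop out of the sum but stay in the denominator", {
  o <- hom_obs(11, 7)
  g <- parse_genotype("(TG)11T7")
  o$forward$ot[10] <- 0.3; o$forward$og[10] <- 0.2  # would-be mismatch
  o$forward$informative_mask[10] <- FALSE
  d <- difference_score(o$forward, o$reverse,
                        expected_pattern(g, "forward"),
                        expected_pattern(g, "reverse"))
  expect_equal(d, 4.2e-4, tolerance = 1e-12)
})

test_that("injecting positional error never decreases the score", {
  g <- parse_genotype("(TG)12T5/(TG)11T9")
  eF <- expected_pattern(g, "forward"); eR <- expected_pattern(g, "reverse")
  obs <- pipeline_obs(g, seed = 3)
  d0 <- difference_score(obs$forward, obs$reverse, eF, eR)
  set.seed(41)
  for (rep in 1:20) {
    pert <- obs
    i <- sample(pert$forward$length, 1L)
    pert$forward$og[i] <- min(1, pert$forward$og[i] + runif(1, 0.05, 0.5))
    d1 <- difference_score(pert$forward, pert$reverse, eF, eR)
    expect_gte(d1, d0)
  }
})

test_that("degenerate empty observations are refused", {
  empty <- obs_tract(numeric(0), numeric(0))
  expect_error(difference_score(empty, empty,
                                expected_pattern(parse_genotype("(TG)11T7"),
                                                 "forward"),
                                expected_pattern(parse_genotype("(TG)11T7"),
                                                 "reverse")),
               class = "polytg_degenerate_observation")
  expect_error(rank_genotypes(empty, empty),
               class = "polytg_degenerate_observation")
})

test_that("ranking is deterministic with ties broken by label", {
  obs <- pipeline_obs("(TG)11T7", seed = 12)
  r1 <- rank_genotypes(obs$forward, obs$reverse)
  r2 <- rank_genotypes(obs$forward, obs$reverse)
  expect_identical(r1, r2)
  surv <- r1[!r1$eliminated, ]
  expect_identical(surv$rank, seq_len(nrow(surv)))
  expect_true(!is.unsorted(surv$d))
  ties <- split(surv$label, surv$d)
  for (grp in ties) expect_identical(grp, sort(grp))
})

test_that("an observation matching nothing raises no_matching_genotype", {
  # informative window with neither T nor G anywhere: every genotype
  # expects tract signal at position 1
  o <- obs_tract(rep(0, 20), rep(0, 20))
  expect_error(rank_genotypes(o, o), class = "polytg_no_matching_genotype")
})

test_that("the ranking engine agrees with the reference score on survivors", {
  obs <- pipeline_obs("(TG)12T5/(TG)11T9", seed = 31, noise_sd = 25)
  rk <- rank_genotypes(obs$forward, obs$reverse)
  surv <- rk[!rk$eliminated, ][1:10, ]
  for (i in seq_len(nrow(surv))) {
    g <- genotype(allele(surv$m1[i], surv$n1[i]),
                  allele(surv$m2[i], surv$n2[i]))
    d <- difference_score(obs$forward, obs$reverse,
                          expected_pattern(g, "forward"),
                          expected_pattern(g, "reverse"))
    expect_equal(surv$d[i], d, tolerance = 1e-12)
  }
})

test_that("per-position diagnostics classify matches, mismatches and masked positions", {
  g <- parse_genotype("(TG)11T7")
  o <- hom_obs(11, 7)
  o$forward$og[3] <- 0.4                   # unexpected guanine shoulder
  o$forward$informative_mask[7] <- FALSE
  diag <- genotype_diagnostics(o$forward, o$reverse, g)
  expect_identical(nrow(diag), 58L)
  fwd <- diag[diag$direction == "forward", ]
  expect_identical(fwd$status[3], "mismatch")
  expect_identical(fwd$status[7], "ignored")
  expect_true(all(fwd$status[-c(3, 7)] == "match"))
})
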