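# flank anchoring, tract window detection, indel QC

anchors <- cftr_flank_anchors()

test_that("anchors pass their structural invariants", {
  expect_identical(nchar(anchors$upstream15), 15L)
  expect_identical(nchar(anchors$downstream15), 15L)
  expect_false(endsWith(anchors$upstream15, "TG"))
  expect_false(startsWith(anchors$downstream15, "TT"))
  # and they flank the tract in the bundled reference
  ref <- cftr_reference_amplicon()
  ts <- attr(ref, "tract_start"); te <- attr(ref, "tract_end")
  seq <- as.vector(ref)
  expect_identical(substr(seq, ts - 14L, ts), anchors$upstream15)
  expect_identical(substr(seq, te + 2L, te + 16L), anchors$downstream15)
})

test_that("find_anchor locates exact and mutated anchors and rejects others", {
  spec <- simulation_spec("(TG)11T7", seed = 1)
  prof <- relative_intensities(simulate_read(spec, "forward"))
  at <- find_anchor(prof, anchors$upstream15)
  expect_identical(substr(prof$base_sequence, at + 1L, at + 15L),
                   anchors$upstream15)

  # a profile of unrelated sequence has no anchor
  other <- relative_intensities(pure_read(paste(
    rep("GATCCA", 20), collapse = "")))
  expect_error(find_anchor(other, anchors$upstream15),
               class = "polytg_anchor_not_found")

  # planted anchor with 2 substitutions is found; with 3 it is not
  plant <- function(k) {
    a <- strsplit(anchors$upstream15, "")[[1]]
    swap <- c("G", "T", "G")  # anchors are A/C-only, so these all mismatch
    a[c(2, 8, 13)[seq_len(k)]] <- swap[seq_len(k)]
    pure_read(paste0(strrep("GAT", 15), paste(a, collapse = ""),
                     strrep("CTA", 15)))
  }
  expect_identical(find_anchor(relative_intensities(plant(2)),
                               anchors$upstream15), 45L)
  expect_error(find_anchor(relative_intensities(plant(3)),
                           anchors$upstream15),
               class = "polytg_anchor_not_found")
})

test_that("tied best windows raise an ambiguity error", {
  seq <- paste0("GAT", anchors$upstream15, strrep("CAT", 4),
                anchors$upstream15, "TAC")
  prof <- relative_intensities(pure_read(seq))
  expect_error(find_anchor(prof, anchors$upstream15),
               class = "polytg_ambiguous_anchor")
})

test_that("noiseless homozygote windows equal 2m + n in both directions", {
  for (lab in c("(TG)11T7", "(TG)8T3", "(TG)16T11", "(TG)12T5")) {
    g <- parse_genotype(lab)
    L <- g$allele_a$tract_length
    obs <- pipeline_obs(g, seed = 4)
    expect_identical(obs$forward$length, L)
    expect_identical(obs$reverse$length, L)
    expect_true(obs$forward$fully_detected)
    expect_true(obs$reverse$fully_detected)
  }
})

test_that("heterozygous windows extend to the longer allele in both directions", {
  cases <- list(c("(TG)12T5/(TG)11T9", 31L),
                c("(TG)10T5/(TG)13T9", 35L),
                c("(TG)8T3/(TG)16T11", 43L),
                c("(TG)11T7/(TG)11T8", 30L))
  for (cs in cases) {
    obs <- pipeline_obs(cs[[1]], seed = 9)
    expect_identical(obs$forward$length, as.integer(cs[[2]]))
    expect_identical(obs$reverse$length, as.integer(cs[[2]]))
  }
})

test_that("a read truncated shortly after the anchor is flagged as partial", {
  spec <- simulation_spec("(TG)11T7", seed = 1)
  r <- simulate_read(spec, "forward")
  prof <- relative_intensities(r)
  a_start <- find_anchor(prof, anchors$upstream15)
  keep <- a_start + 15L + 10L  # 10 tract bases, then cut
  cut <- chromatogram_read(r$sample_name, "forward",
                           substr(r$called_bases, 1L, keep),
                           r$peak_locations[seq_len(keep)], r$traces)
  obs <- detect_forward_tract(relative_intensities(cut))
  expect_false(obs$fully_detected)
  # the 10th kept tract base is a guanine that cannot be confirmed as tract
  # without a following position, so the window holds the 9 confirmed bases
  expect_identical(obs$length, 9L)
})

test_that("an uninformative gap inside the poly-T run does not shrink the window", {
  spec <- simulation_spec("(TG)11T7", seed = 6)
  r <- simulate_read(spec, "forward")
  prof0 <- relative_intensities(r)
  a_start <- find_anchor(prof0, anchors$upstream15)
  gap <- a_start + 15L + 25L  # inside the poly-T run (0-based position)
  for (b in names(r$traces)) r$traces[[b]][r$peak_locations[gap + 1L] + 1L] <- 0L
  obs <- detect_forward_tract(relative_intensities(r))
  expect_identical(obs$length, 29L)
  expect_true(obs$fully_detected)
  expect_false(obs$informative_mask[26])
  expect_identical(sum(!obs$informative_mask), 1L)
})

test_that("a reverse profile with no scan terminator is flagged as partial", {
  # poly-T all the way to the read start: no position free of tract signal
  seq <- paste0(strrep("T", 50), allele_sequence(allele(11, 7)),
                anchors$downstream15, strrep("CA", 10))
  prof <- relative_intensities(pure_read(seq))
  obs <- detect_reverse_tract(prof)
  expect_false(obs$fully_detected)
})

test_that("flank indel interference is flagged only above 3 dirty positions", {
  spec <- simulation_spec("(TG)11T7", seed = 2)
  prof <- relative_intensities(simulate_read(spec, "forward"))
  a_start <- find_anchor(prof, anchors$upstream15)
  clean <- flank_indel_check(prof, a_start, anchors$upstream15)
  expect_false(clean$flag)
  expect_identical(clean$n_dirty, 0L)

  dirty_profile <- function(k) {
    r <- simulate_read(spec, "forward")
    for (j in seq_len(k)) {
      p <- r$peak_locations[a_start + j]  # 0-based position a_start + j - 1
      r$traces$G[p + 1L] <- 500L          # anchor is A/C-only: G is foreign
    }
    relative_intensities(r)
  }
  expect_false(flank_indel_check(dirty_profile(3), a_start,
                                 anchors$upstream15)$flag)
  qc4 <- flank_indel_check(dirty_profile(4), a_start, anchors$upstream15)
  expect_true(qc4$flag)
  expect_identical(qc4$n_dirty, 4L)
  expect_match(qc4$message, "indel")
})

test_that("a superposed shifted duplication trips the reverse-side QC", {
  g <- parse_genotype("(TG)11T7")
  ref <- cftr_reference_amplicon()
  down15 <- cftr_flank_anchors()$downstream15
  # duplication of 4 bases downstream of the anchor on one allele copy: from
  # the reverse read's shared 3' end, the whole downstream anchor region of
  # the duplicated copy is shifted out of register
  spec <- simulation_spec(g, seed = 8, full_amplicon = TRUE,
                          extra_duplication = c(attr(ref, "tract_end") + 25L, 4L))
  pr <- orient_reverse(relative_intensities(simulate_read(spec, "reverse")))
  # the anchor's in-frame position, measured from the shared 3' end
  at0 <- as.integer(regexpr(down15, ref, fixed = TRUE)) - 1L
  from_end <- nchar(ref) - (at0 + 15L)
  anchor_start <- nrow(pr$rel) - from_end - 15L
  qc <- flank_indel_check(pr, anchor_start, down15)
  expect_true(qc$flag)
  expect_gt(qc$n_dirty, 3L)

  # while an unduplicated sample stays clean on the same side
  clean_spec <- simulation_spec(g, seed = 8, full_amplicon = TRUE)
  pr2 <- orient_reverse(relative_intensities(simulate_read(clean_spec,
                                                           "reverse")))
  obsR2 <- detect_reverse_tract(pr2)
  expect_false(flank_indel_check(pr2, attr(obsR2, "anchor_start"),
                                 down15)$flag)
})
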