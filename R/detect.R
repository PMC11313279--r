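#' @title Locating the poly-T/TG tract
#' @description The tract is found by anchoring on its 15 bp flanking
#'   sequences: the upstream flank pins the 5' end in the forward
#'   chromatogram and the downstream flank pins the 3' end in the
#'   (orientation-normalized) reverse chromatogram; the opposite end of each
#'   window is then found by scanning until the tract signal runs out. The
#'   flank length balances uniqueness against compatibility with arbitrary
#'   primer designs, so any chromatogram covering the tract plus 15 bp on
#'   each side can be analyzed.
#' @name tract-detection
NULL

# Frozen flank constants. Extracted from the package's bundled reference
# amplicon (inst/extdata/synthetic_cftr_amplicon.fa), which is a SYNTHETIC
# stand-in: only its primer sites, product size and (TG)11T7 tract follow
# published constants, the remaining sequence is invented. Analyzing real
# chromatograms requires re-freezing these anchors from the genuine GRCh38
# CFTR intron 9 flanks (see the package vignette).
.UPSTREAM15   <- "CCAACACCACAACCA"
.DOWNSTREAM15 <- "AACCACAACACCAAC"

#' The 15 bp flank anchors
#'
#' @return List with `upstream15` (immediately 5' of the TG repeat) and
#'   `downstream15` (immediately 3' of the poly-T run), both validated: 15
#'   bases each, the upstream anchor must not end in `TG` and the downstream
#'   anchor must not start with `TT`, either of which would extend the tract
#'   ambiguously.
#' @export
cftr_flank_anchors <- function() {
  up <- .UPSTREAM15; down <- .DOWNSTREAM15
  stopifnot(nchar(up) == 15L, nchar(down) == 15L,
            substr(up, 14L, 15L) != "TG", substr(down, 1L, 2L) != "TT")
  list(upstream15 = up, downstream15 = down)
}

#' The bundled reference amplicon
#'
#' Returns the 427 bp reference amplicon shipped with the package, with the
#' 0-based tract bounds attached as attributes `tract_start` and `tract_end`
#' (the reference tract is (TG)11T7). The bundled sequence is a synthetic
#' stand-in whose primer sites, product size and tract follow published
#' constants; see the vignette before using it as a proxy for GRCh38.
#'
#' @return A character scalar with attributes `tract_start`, `tract_end`.
#' @export
cftr_reference_amplicon <- function() {
  path <- system.file("extdata", "synthetic_cftr_amplicon.fa",
                      package = "polytg", mustWork = TRUE)
  seq <- as.character(Biostrings::readDNAStringSet(path)[[1]])
  anchors <- cftr_flank_anchors()
  up_at <- as.integer(regexpr(anchors$upstream15, seq, fixed = TRUE))
  stopifnot(up_at > 0)
  tract_start <- up_at + 15L - 1L            # 0-based first tract position
  rest <- substr(seq, tract_start + 1L, nchar(seq))
  tract_len <- attr(regexpr("^(TG)+T+", rest), "match.length")
  stopifnot(tract_len > 0)
  structure(seq, tract_start = tract_start,
            tract_end = tract_start + tract_len - 1L)
}

#' Locate a primer pair on a reference sequence
#'
#' Finds the forward primer on the given strand and the reverse primer as
#' its reverse complement, requiring each to match exactly once, and returns
#' the amplicon they delimit (primers included).
#'
#' @param reference Reference sequence (character or `DNAString`). Defaults
#'   to the bundled reference amplicon.
#' @param fwd_primer,rev_primer Primer sequences, 5' to 3' as synthesized.
#'   Defaults are the assay primers for the CFTR intron 9-exon 10 junction.
#' @return List with 0-based `start`, `end` (inclusive) and `product_size`.
#' @export
locate_amplicon <- function(reference = cftr_reference_amplicon(),
                            fwd_primer = "CCATGTGCTTTTCAAACTAATTG",
                            rev_primer = "CCAAAAATACCTTCCAGCACTACA") {
  ref <- Biostrings::DNAString(as.character(reference))
  fwd_hits <- Biostrings::matchPattern(Biostrings::DNAString(fwd_primer), ref)
  rev_site <- Biostrings::reverseComplement(Biostrings::DNAString(rev_primer))
  rev_hits <- Biostrings::matchPattern(rev_site, ref)
  if (length(fwd_hits) != 1L || length(rev_hits) != 1L)
    polytg_abort("primers must each match the reference exactly once", "io")
  start <- BiocGenerics::start(fwd_hits)[1] - 1L
  end <- BiocGenerics::end(rev_hits)[1] - 1L
  if (end <= start) polytg_abort("primer pair is not convergent", "io")
  list(start = start, end = end, product_size = end - start + 1L)
}

#' Find a flank anchor in a profile
#'
#' Slides the anchor along the profile's argmax base sequence and scores each
#' window by Hamming distance, with uninformative positions counting as
#' matches. The best-scoring window must be unique at its distance and within
#' `max_mismatch` of the anchor.
#'
#' @param profile A `polytg_profile` in genomic-forward orientation.
#' @param anchor A 15-base anchor sequence.
#' @param max_mismatch Maximum tolerated mismatches (default 2: isolated
#'   miscalls are tolerated while the flanks stay specific).
#' @return 0-based start position of the match.
#' @export
find_anchor <- function(profile, anchor, max_mismatch = 2L) {
  stopifnot(inherits(profile, "polytg_profile"))
  k <- nchar(anchor)
  obs <- .argmax_bases(profile)
  if (sum(!is.na(obs)) < k)
    polytg_abort("profile has fewer informative positions than the anchor",
                 "anchor_not_found")
  n_win <- length(obs) - k + 1L
  if (n_win < 1L)
    polytg_abort("profile shorter than the anchor", "anchor_not_found")
  a <- strsplit(anchor, "")[[1]]
  # windowed Hamming distance; NA (uninformative) counts as a match
  d <- vapply(seq_len(n_win), function(s) {
    w <- obs[s:(s + k - 1L)]
    sum(w != a, na.rm = TRUE)
  }, integer(1))
  best <- min(d)
  if (best > max_mismatch)
    polytg_abort("flank anchor not found within the mismatch tolerance",
                 "anchor_not_found")
  at <- which(d == best)
  if (length(at) > 1L)
    polytg_abort("flank anchor matches ambiguously (tied windows)",
                 "ambiguous_anchor")
  at - 1L
}

.new_observed_tract <- function(profile, direction, start0, len,
                                fully_detected, anchor_start) {
  idx <- if (len > 0) (start0 + 1L):(start0 + len) else integer(0)
  structure(list(direction = direction,
                 start = start0,
                 length = len,
                 ot = unname(profile$rel[idx, "T"]),
                 og = unname(profile$rel[idx, "G"]),
                 informative_mask = profile$informative[idx],
                 fully_detected = fully_detected),
            class = "polytg_observed_tract",
            anchor_start = anchor_start)
}

#' @export
print.polytg_observed_tract <- function(x, ...) {
  cat(sprintf("<polytg_observed_tract> %s: start %d, length %d%s\n",
              x$direction, x$start, x$length,
              if (x$fully_detected) "" else " (PARTIAL detection)"))
  invisible(x)
}

# scan cap: longest default-space allele (2*16 + 11 = 43) plus margin;
# bounds runaway scans on degenerate traces
.SCAN_CAP <- 60L

#' Detect the tract in the forward chromatogram
#'
#' Anchors the tract's 5'-most position immediately after the upstream 15 bp
#' flank, then scans 3'-ward: the tract continues while thymine is present at
#' the position or the next one, and ends at the first position where thymine
#' is absent at both (that position is excluded). The two-consecutive rule is
#' needed because clean guanine positions inside the TG repeat carry no
#' thymine themselves; the downstream flank starts with two non-T bases, so
#' termination lands exactly at the tract boundary. Uninformative positions
#' never terminate the scan. If no termination is found before the read end
#' or the scan cap, the window is truncated and flagged (`fully_detected =
#' FALSE`).
#'
#' @param profile Forward-read `polytg_profile`.
#' @param anchors Flank anchors, as from [cftr_flank_anchors()].
#' @param cfg A [signal_config()].
#' @param max_mismatch Anchor mismatch tolerance, see [find_anchor()].
#' @return A `polytg_observed_tract`.
#' @export
detect_forward_tract <- function(profile, anchors = cftr_flank_anchors(),
                                 cfg = signal_config(), max_mismatch = 2L) {
  a_start <- find_anchor(profile, anchors$upstream15, max_mismatch)
  start0 <- a_start + nchar(anchors$upstream15)
  n <- nrow(profile$rel)
  len <- 0L
  fully <- FALSE
  while (len < .SCAN_CAP) {
    p <- start0 + len
    if (p >= n) break  # ran off the read end
    t_here <- .present_or(profile, p, "T", cfg, uninformative_value = TRUE)
    if (!t_here) {
      if (p + 1L >= n) break  # read ends before the terminator is confirmed
      t_next <- .present_or(profile, p + 1L, "T", cfg,
                            uninformative_value = TRUE)
      if (!t_next) { fully <- TRUE; break }
    }
    len <- len + 1L
  }
  .new_observed_tract(profile, "forward", start0, len, fully, a_start)
}

#' Detect the tract in the oriented reverse chromatogram
#'
#' Anchors the tract's 3'-most position immediately before the downstream
#' 15 bp flank in the orientation-normalized (genomic-forward) profile, then
#' scans 5'-ward: the tract continues while tract signal (thymine or
#' guanine) is present and ends just past the first position free of both.
#' In the reference that first non-tract base is the adenine immediately 5'
#' of the TG repeat, matching the rule of stopping where adenine is first
#' detected; phrasing the scan in terms of tract signal keeps a heterozygous
#' shorter allele's shifted flank (which superposes an adenine inside the
#' longer allele's tract) from truncating the window. Positions are reported
#' 5' to 3' so the result is co-oriented with the forward tract.
#'
#' @inheritParams detect_forward_tract
#' @param profile Oriented (genomic-forward) `polytg_profile` of the reverse
#'   read, see [orient_reverse()].
#' @return A `polytg_observed_tract`.
#' @export
detect_reverse_tract <- function(profile, anchors = cftr_flank_anchors(),
                                 cfg = signal_config(), max_mismatch = 2L) {
  a_start <- find_anchor(profile, anchors$downstream15, max_mismatch)
  end0 <- a_start - 1L  # last tract position
  len <- 0L
  fully <- FALSE
  while (len < .SCAN_CAP) {
    p <- end0 - len
    if (p < 0L) break  # ran off the read start
    t_here <- .present_or(profile, p, "T", cfg, uninformative_value = TRUE)
    g_here <- .present_or(profile, p, "G", cfg, uninformative_value = FALSE)
    if (!t_here && !g_here) { fully <- TRUE; break }
    len <- len + 1L
  }
  .new_observed_tract(profile, "reverse", end0 - len + 1L, len, fully, a_start)
}

#' Check a flank for heterozygous indel interference
#'
#' A heterozygous insertion, duplication or deletion elsewhere in the
#' amplicon puts the two allele copies out of register across the tract
#' flanks, which shows up as overlapping peaks on the anchor. If more than 3
#' of the 15 anchor positions carry a second nucleotide besides the anchor
#' base, the sample is flagged as unreliable (such samples should be
#' resolved manually, not by tract genotyping).
#'
#' @param profile `polytg_profile` in genomic-forward orientation.
#' @param anchor_start 0-based start of the matched anchor window.
#' @param anchor Anchor sequence that was matched.
#' @param cfg A [signal_config()].
#' @return List with `flag` (logical), `n_dirty` (count of anchor positions
#'   with extra signal) and `message` (`NULL` when clean).
#' @export
flank_indel_check <- function(profile, anchor_start, anchor,
                              cfg = signal_config()) {
  bases <- strsplit(anchor, "")[[1]]
  n_dirty <- 0L
  for (k in seq_along(bases)) {
    p <- anchor_start + k - 1L
    others <- setdiff(c("A", "C", "G", "T"), bases[k])
    extra <- any(vapply(others, function(b)
      .present_or(profile, p, b, cfg, uninformative_value = FALSE), logical(1)))
    if (extra) n_dirty <- n_dirty + 1L
  }
  flag <- n_dirty > 3L
  list(flag = flag, n_dirty = n_dirty,
       message = if (flag)
         "possible heterozygous indel in amplicon - results unreliable"
       else NULL)
}
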