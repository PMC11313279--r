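#' Signal interpretation parameters
#'
#' @param min_total_signal Minimum total raw signal (sum of the four analyzed
#'   channels at a peak location, in analyzer units) for a position to be
#'   informative. Positions below the threshold are ignored when comparing
#'   observed and expected patterns. Default 50.
#' @param presence_fraction Relative-intensity threshold (inclusive) above
#'   which a nucleotide's signal counts as "present" at a position. Relative
#'   rather than absolute so the predicate is invariant to scanner gain; the
#'   default 0.10 keeps a 50/50 heterozygous peak (about 0.5) robustly
#'   present while typical bleed-through (below 10 percent) stays absent.
#' @return An object of class `polytg_signal_config`.
#' @export
signal_config <- function(min_total_signal = 50, presence_fraction = 0.10) {
  stopifnot(min_total_signal >= 0,
            presence_fraction > 0, presence_fraction < 1)
  structure(list(min_total_signal = min_total_signal,
                 presence_fraction = presence_fraction),
            class = "polytg_signal_config")
}

#' Per-base relative signal intensities
#'
#' Samples each trace channel at every called base's peak location and
#' converts the four raw values to relative intensities (each channel divided
#' by the four-channel total). Positions whose total signal falls below
#' `cfg$min_total_signal` are uninformative: their relative intensities are
#' defined as 0 and they are excluded from all downstream comparisons.
#'
#' @param read A [chromatogram_read()] object.
#' @param cfg A [signal_config()].
#' @return An object of class `polytg_profile` with fields `base_sequence`
#'   (called bases, one string), `rel` (n x 4 matrix of relative intensities,
#'   columns `A`,`C`,`G`,`T`), `total_signal`, `informative` (logical),
#'   `direction` and `oriented` (`TRUE` once the profile is in genomic-forward
#'   orientation).
#' @export
relative_intensities <- function(read, cfg = signal_config()) {
  stopifnot(inherits(read, "polytg_read"))
  idx <- read$peak_locations + 1L
  raw_mat <- cbind(A = read$traces$A[idx], C = read$traces$C[idx],
                   G = read$traces$G[idx], T = read$traces$T[idx])
  if (is.null(dim(raw_mat))) raw_mat <- matrix(raw_mat, ncol = 4,
                                               dimnames = list(NULL, c("A", "C", "G", "T")))
  total <- rowSums(raw_mat)
  informative <- total >= cfg$min_total_signal
  rel <- raw_mat / ifelse(total > 0, total, 1)
  rel[!informative, ] <- 0
  structure(list(base_sequence = read$called_bases,
                 rel = rel,
                 total_signal = as.numeric(total),
                 informative = informative,
                 direction = read$direction,
                 oriented = read$direction == "forward"),
            class = "polytg_profile")
}

#' @export
print.polytg_profile <- function(x, ...) {
  cat(sprintf("<polytg_profile> %s%s: %d positions (%d informative)\n",
              x$direction, if (x$oriented) " (genomic-forward)" else "",
              nrow(x$rel), sum(x$informative)))
  invisible(x)
}

#' Normalize a reverse-read profile to genomic-forward orientation
#'
#' Reverses position order and complements the channel labels (A with T, C
#' with G), so that downstream tract detection and scoring see both
#' sequencing directions in the same genomic-forward coordinate frame. The
#' base sequence is replaced by its reverse complement; informative flags
#' and totals follow the position reversal. Applying the function twice
#' returns the original profile.
#'
#' @param profile A `polytg_profile` built from a reverse read.
#' @return The oriented `polytg_profile`.
#' @export
orient_reverse <- function(profile) {
  stopifnot(inherits(profile, "polytg_profile"))
  n <- nrow(profile$rel)
  ord <- if (n) n:1 else integer(0)
  rel <- profile$rel[ord, c("T", "G", "C", "A"), drop = FALSE]
  colnames(rel) <- c("A", "C", "G", "T")
  seq_rc <- chartr("ACGTN", "TGCAN",
                   paste(rev(strsplit(profile$base_sequence, "")[[1]]),
                         collapse = ""))
  structure(list(base_sequence = seq_rc,
                 rel = rel,
                 total_signal = profile$total_signal[ord],
                 informative = profile$informative[ord],
                 direction = profile$direction,
                 oriented = !profile$oriented),
            class = "polytg_profile")
}

#' Is a nucleotide's signal present at a position?
#'
#' A base is present when its relative intensity at the position is at least
#' `cfg$presence_fraction` (inclusive). Querying an uninformative position is
#' an error because no presence statement can be made there.
#'
#' @param profile A `polytg_profile`.
#' @param position 0-based position in the profile.
#' @param base One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param cfg A [signal_config()].
#' @return Logical scalar.
#' @export
base_present <- function(profile, position, base, cfg = signal_config()) {
  i <- position + 1L
  if (i < 1L || i > nrow(profile$rel))
    polytg_abort(sprintf("position %d out of range", position),
                 "index_out_of_range")
  if (!profile$informative[i])
    polytg_abort(sprintf("position %d is uninformative", position),
                 "uninformative_position")
  profile$rel[i, base] >= cfg$presence_fraction
}

# presence for scan loops: uninformative positions make no claim, so the
# caller chooses what they count as (forward scan: T "present" so masked
# gaps never terminate the tract; reverse scan: tract signal "present").
.present_or <- function(profile, i0, base, cfg, uninformative_value) {
  i <- i0 + 1L
  if (i < 1L || i > nrow(profile$rel)) return(FALSE)
  if (!profile$informative[i]) return(uninformative_value)
  profile$rel[i, base] >= cfg$presence_fraction
}

# argmax base per position; uninformative positions give NA
.argmax_bases <- function(profile) {
  bases <- colnames(profile$rel)[max.col(profile$rel, ties.method = "first")]
  bases[!profile$informative] <- NA_character_
  bases
}
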