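#' @title Alleles, genotypes and expected peak patterns
#' @description The poly-T/TG tract allele is written `(TG)mTn`: m copies of
#'   the TG dinucleotide followed by n thymines, for a tract length of
#'   `2m + n` bases. A genotype is an unordered pair of alleles. Expected
#'   peak patterns superpose the two allele sequences with dual alignment:
#'   left-aligned (5') in the forward direction and right-aligned (3') in
#'   the reverse direction, which is what disambiguates heterozygotes of
#'   unequal length.
#' @name genotype-model
NULL

#' Construct a (TG)mTn allele
#'
#' @param m Number of TG dinucleotide repeats (`m >= 1`).
#' @param n Length of the poly-T run (`n >= 1`).
#' @return An object of class `polytg_allele` with fields `m`, `n` and
#'   `tract_length` (`2m + n`).
#' @export
allele <- function(m, n) {
  m <- as.integer(m); n <- as.integer(n)
  stopifnot(length(m) == 1L, length(n) == 1L, m >= 1L, n >= 1L)
  structure(list(m = m, n = n, tract_length = 2L * m + n),
            class = "polytg_allele")
}

#' Allele base sequence
#'
#' @param a A [allele()] object.
#' @return The tract sequence `"TGTG...TT...T"` of length `2m + n`.
#' @export
allele_sequence <- function(a) {
  stopifnot(inherits(a, "polytg_allele"))
  paste0(strrep("TG", a$m), strrep("T", a$n))
}

.allele_label <- function(m, n) sprintf("(TG)%dT%d", m, n)

#' Construct a genotype (unordered allele pair)
#'
#' Alleles are stored in canonical order, ascending by tract length and then
#' by TG count, so construction from `(x, y)` and `(y, x)` yields the same
#' object and label.
#'
#' @param a,b [allele()] objects.
#' @return An object of class `polytg_genotype` with fields `allele_a`,
#'   `allele_b` and `label` (for example `"(TG)12T5/(TG)11T9"`).
#' @export
genotype <- function(a, b) {
  stopifnot(inherits(a, "polytg_allele"), inherits(b, "polytg_allele"))
  key <- function(x) c(x$tract_length, x$m)
  if (isTRUE(key(b)[1] < key(a)[1]) ||
      (key(b)[1] == key(a)[1] && key(b)[2] < key(a)[2])) {
    tmp <- a; a <- b; b <- tmp
  }
  structure(list(allele_a = a, allele_b = b,
                 label = paste0(.allele_label(a$m, a$n), "/",
                                .allele_label(b$m, b$n))),
            class = "polytg_genotype")
}

#' @export
print.polytg_genotype <- function(x, ...) {
  cat("<polytg_genotype>", x$label, "\n")
  invisible(x)
}

#' Parse a genotype label
#'
#' @param label Text of the form `"(TG)12T5/(TG)11T9"` (a single allele such
#'   as `"(TG)11T7"` is taken as homozygous).
#' @return A [genotype()] object.
#' @export
parse_genotype <- function(label) {
  parts <- strsplit(label, "/", fixed = TRUE)[[1]]
  if (length(parts) == 1L) parts <- c(parts, parts)
  if (length(parts) != 2L)
    stop("genotype label must be one or two '(TG)mTn' alleles separated by /")
  parse1 <- function(s) {
    mt <- regmatches(s, regexec("^\\(TG\\)([0-9]+)T([0-9]+)$", trimws(s)))[[1]]
    if (length(mt) != 3L) stop(sprintf("cannot parse allele '%s'", s))
    allele(as.integer(mt[2]), as.integer(mt[3]))
  }
  genotype(parse1(parts[1]), parse1(parts[2]))
}

#' Define the allele search space
#'
#' The default space covers T3 to T11 in combination with (TG)8 to (TG)16,
#' which encompasses all known poly-T/TG alleles.
#'
#' @param min_t,max_t Bounds on the poly-T run length n.
#' @param min_tg,max_tg Bounds on the TG repeat count m.
#' @return An object of class `polytg_search_space`.
#' @export
search_space <- function(min_t = 3, max_t = 11, min_tg = 8, max_tg = 16) {
  min_t <- as.integer(min_t); max_t <- as.integer(max_t)
  min_tg <- as.integer(min_tg); max_tg <- as.integer(max_tg)
  stopifnot(min_t >= 1L, min_tg >= 1L)
  if (min_t > max_t || min_tg > max_tg)
    polytg_abort("empty search space (min exceeds max)", "empty_space")
  structure(list(min_t = min_t, max_t = max_t,
                 min_tg = min_tg, max_tg = max_tg),
            class = "polytg_search_space")
}

#' Enumerate all genotypes in a search space
#'
#' Generates every unordered pair (with replacement) of alleles on the
#' `(m, n)` grid, in deterministic canonical order. For `A` alleles there are
#' `A (A + 1) / 2` genotypes (3321 for the default space's 81 alleles).
#'
#' @param space A [search_space()].
#' @return A list of [genotype()] objects.
#' @export
enumerate_genotypes <- function(space = search_space()) {
  tab <- .genotype_grid(space)
  lapply(seq_len(nrow(tab)), function(i)
    genotype(allele(tab$m1[i], tab$n1[i]), allele(tab$m2[i], tab$n2[i])))
}

# data.frame of canonical allele pairs, ordered by (len_a, m_a, len_b, m_b)
.genotype_grid <- function(space) {
  al <- expand.grid(m = space$min_tg:space$max_tg, n = space$min_t:space$max_t,
                    KEEP.OUT.ATTRS = FALSE)
  al$len <- 2L * al$m + al$n
  al <- al[order(al$len, al$m, al$n), , drop = FALSE]
  A <- nrow(al)
  i <- rep(seq_len(A), times = A - seq_len(A) + 1L)
  j <- unlist(lapply(seq_len(A), function(k) k:A))
  tab <- data.frame(m1 = al$m[i], n1 = al$n[i], len1 = al$len[i],
                    m2 = al$m[j], n2 = al$n[j], len2 = al$len[j])
  tab$L <- pmax(tab$len1, tab$len2)
  tab$label <- paste0(.allele_label(tab$m1, tab$n1), "/",
                      .allele_label(tab$m2, tab$n2))
  ord <- order(tab$len1, tab$m1, tab$n1, tab$len2, tab$m2, tab$n2)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# base code of allele (m, n) at 0-based position i (forward, 5' anchored):
# 1 = T, 2 = G, 0 = beyond the allele
.allele_code_fwd <- function(m, n, i) {
  ifelse(i >= 2 * m + n, 0L,
         ifelse(i < 2 * m, ifelse(i %% 2 == 0, 1L, 2L), 1L))
}

# same, with j counted from the 3' end (right-aligned frame)
.allele_code_rev <- function(m, n, j) {
  ifelse(j >= 2 * m + n, 0L,
         ifelse(j < n, 1L, ifelse((j - n) %% 2 == 0, 2L, 1L)))
}

.codes_to_sets <- function(codes) c("-", "T", "G", "TG")[codes + 1L]

# expected relative intensities are allele-dosage fractions: each of the two
# alleles contributes 0.5 to the channel of the base it places at a position
# (and nothing where it has ended). Positions covered by both alleles give
# the 1/0 (single base) and 0.5/0.5 (both T and G) values of the score's
# definition; positions beyond the shorter allele give 0.5 for the longer
# allele's base, matching the dosage dilution actually observed there.
.dosage_pattern <- function(ca, cb) {
  et <- 0.5 * ((ca == 1L) + (cb == 1L))
  eg <- 0.5 * ((ca == 2L) + (cb == 2L))
  list(et = et, eg = eg, codes = (et > 0) + 2L * (eg > 0))
}

#' Expected peak pattern of a genotype
#'
#' Superposes the two allele sequences: left-aligned at the tract 5' end for
#' the forward direction, right-aligned at the tract 3' end for the reverse
#' direction (both reported 5' to 3'). Each position's expected base set is
#' the union of the bases the two aligned alleles place there; positions
#' beyond the shorter allele carry only the longer allele's base. Expected
#' relative intensities are allele-dosage fractions: 1/0 for a base both
#' alleles place, 0.5/0.5 where one allele places T and the other G, and
#' 0.5/0 (or 0/0.5) at positions past the shorter allele's end, where the
#' longer allele supplies half the molecules' signal.
#'
#' @param g A [genotype()].
#' @param direction `"forward"` or `"reverse"`.
#' @return An object of class `polytg_expected_tract` with fields
#'   `direction`, `length` (the longer allele's tract length; identical for
#'   both directions), `sets` (character vector over `"T"`, `"G"`, `"TG"`),
#'   `et` and `eg` (expected relative T and G intensities).
#' @export
expected_pattern <- function(g, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(g, "polytg_genotype"))
  a <- g$allele_a; b <- g$allele_b
  L <- max(a$tract_length, b$tract_length)
  if (direction == "forward") {
    i <- 0:(L - 1)
    dp <- .dosage_pattern(.allele_code_fwd(a$m, a$n, i),
                          .allele_code_fwd(b$m, b$n, i))
  } else {
    j <- (L - 1):0  # leftmost reported position is farthest from the 3' end
    dp <- .dosage_pattern(.allele_code_rev(a$m, a$n, j),
                          .allele_code_rev(b$m, b$n, j))
  }
  structure(list(direction = direction, length = L,
                 sets = .codes_to_sets(dp$codes),
                 et = dp$et, eg = dp$eg),
            class = "polytg_expected_tract")
}

#' Positions that discriminate among surviving genotypes
#'
#' Given the expected patterns of the surviving genotypes for one direction,
#' returns the alignment-frame positions at which the expected base set
#' (including "no base expected" beyond a pattern's length) is not identical
#' across all of them. These are the shaded, highly informative positions in
#' the report plots. Patterns are compared in the alignment frame of the
#' direction: padded at the 3' end for forward (left-aligned) patterns and at
#' the 5' end for reverse (right-aligned) ones.
#'
#' @param patterns List of [expected_pattern()] results, all with the same
#'   direction.
#' @param direction `"forward"` or `"reverse"`.
#' @return Sorted 0-based integer positions in the alignment frame (empty if
#'   fewer than two patterns are supplied).
#' @export
informative_positions <- function(patterns, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (length(patterns) < 2L) return(integer(0))
  stopifnot(all(vapply(patterns, function(p) p$direction, "") == direction))
  Lmax <- max(vapply(patterns, function(p) p$length, 0L))
  padded <- vapply(patterns, function(p) {
    pad <- rep("-", Lmax - p$length)
    if (direction == "forward") c(p$sets, pad) else c(pad, p$sets)
  }, character(Lmax))
  if (is.null(dim(padded))) padded <- matrix(padded, nrow = Lmax)
  differs <- apply(padded, 1L, function(row) length(unique(row)) > 1L)
  which(differs) - 1L
}
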