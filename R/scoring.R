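#' @title Genotype elimination and goodness-of-fit ranking
#' @description Candidate genotypes are first eliminated when their expected
#'   pattern is incompatible with the observation: at some informative
#'   observed position inside the expected tract a single expected base has
#'   no observed signal. Elimination is deliberately one-directional -
#'   observed-but-unexpected signal never eliminates, it only worsens the
#'   score. Survivors are ranked by the normalized difference score
#'   \deqn{D = \frac{\sum_{i=1}^{n_F+n_R} (O_{G,i}-E_{G,i})^2 +
#'   (O_{T,i}-E_{T,i})^2}{2\,(n_F+n_R)} + \frac{100 - m_F - m_R}{10^5}}
#'   where \eqn{n_F, n_R} are the observed tract lengths, \eqn{m_F, m_R} the
#'   expected tract lengths, and O/E the observed and expected relative T and
#'   G intensities. Observed positions beyond the expected length take
#'   expected intensities of 0 (so unexpected peaks are penalized);
#'   uninformative positions contribute nothing to the sum but still count
#'   in \eqn{n_F + n_R}. The final term mildly favors longer expected tracts
#'   as a tie-break. Lower D is better.
#' @name scoring
NULL

# Eq. constants: fixed, not user-adjustable
.LENGTH_BONUS_OFFSET <- 100
.LENGTH_BONUS_SCALE <- 1e5

# per-direction alignment of an observed tract against an expected pattern:
# forward tracts share the 5' edge, reverse tracts share the 3' edge.
# Returns for each observed position (5'->3') the expected et/eg (0 beyond
# the expected length) and the expected set code ("-" beyond).
.align_expected <- function(obs, exp_tract) {
  n <- obs$length; m <- exp_tract$length
  et <- numeric(n); eg <- numeric(n); sets <- rep("-", n)
  if (n == 0L) return(list(et = et, eg = eg, sets = sets))
  if (obs$direction == "forward") {
    k <- min(n, m)
    if (k > 0) {
      et[1:k] <- exp_tract$et[1:k]
      eg[1:k] <- exp_tract$eg[1:k]
      sets[1:k] <- exp_tract$sets[1:k]
    }
  } else {
    # right-aligned: observed position i (1-based) sits j = n - i positions
    # from the 3' end and pairs with the expected position at the same j
    i <- seq_len(n)
    j <- n - i
    ok <- j < m
    ei <- m - j[ok]  # 1-based index into the 5'->3' expected vectors
    et[ok] <- exp_tract$et[ei]
    eg[ok] <- exp_tract$eg[ei]
    sets[ok] <- exp_tract$sets[ei]
  }
  list(et = et, eg = eg, sets = sets)
}

#' Is a genotype compatible with the observed tracts?
#'
#' `FALSE` when, in either direction, some informative observed position
#' within the expected tract expects a single base whose signal is absent,
#' or when the expected tract is longer than the observed one - the tract
#' scan terminated precisely because tract signal was absent past the
#' window, so a genotype expecting signal there expects what was certified
#' unobserved. Positions expecting both T and G never eliminate, and
#' observed signal beyond the expected tract never eliminates (it is scored
#' instead).
#'
#' @param obsF,obsR Observed tracts from [detect_forward_tract()] and
#'   [detect_reverse_tract()].
#' @param g A [genotype()].
#' @param patterns Optional list with the genotype's `forward` and `reverse`
#'   [expected_pattern()]s (computed if omitted).
#' @param cfg A [signal_config()].
#' @return Logical scalar.
#' @export
is_compatible <- function(obsF, obsR, g, patterns = NULL,
                          cfg = signal_config()) {
  if (is.null(patterns))
    patterns <- list(forward = expected_pattern(g, "forward"),
                     reverse = expected_pattern(g, "reverse"))
  pf <- cfg$presence_fraction
  for (pair in list(list(obsF, patterns$forward),
                    list(obsR, patterns$reverse))) {
    if (pair[[2]]$length > pair[[1]]$length) return(FALSE)
    obs <- pair[[1]]; al <- .align_expected(obs, pair[[2]])
    for (i in seq_len(obs$length)) {
      if (!obs$informative_mask[i]) next
      if (al$sets[i] == "T" && obs$ot[i] < pf) return(FALSE)
      if (al$sets[i] == "G" && obs$og[i] < pf) return(FALSE)
    }
  }
  TRUE
}

#' Normalized difference score for one genotype
#'
#' Direct evaluation of the score described in [scoring]: squared
#' differences between observed and expected relative T and G intensities
#' over all observed tract positions in both directions, normalized by twice
#' the total observed length, plus `(100 - mF - mR) / 1e5`.
#'
#' @param obsF,obsR Observed tracts.
#' @param expF,expR The genotype's [expected_pattern()]s.
#' @param cfg A [signal_config()].
#' @return The score `d` (numeric scalar; lower is better).
#' @export
difference_score <- function(obsF, obsR, expF, expR, cfg = signal_config()) {
  nF <- obsF$length; nR <- obsR$length
  if (nF + nR == 0L)
    polytg_abort("no observed tract positions to score",
                 "degenerate_observation")
  num <- 0
  for (pair in list(list(obsF, expF), list(obsR, expR))) {
    obs <- pair[[1]]; al <- .align_expected(obs, pair[[2]])
    for (i in seq_len(obs$length)) {
      if (!obs$informative_mask[i]) next  # ignored when comparing
      num <- num + (obs$og[i] - al$eg[i])^2 + (obs$ot[i] - al$et[i])^2
    }
  }
  num / (2 * (nF + nR)) +
    (.LENGTH_BONUS_OFFSET - expF$length - expR$length) / .LENGTH_BONUS_SCALE
}

# ---- vectorized ranking engine ------------------------------------------

# pattern matrices for a whole search space, cached per space.
# CF/ETF/EGF: forward frame (column i = tract position i, 5'-anchored).
# CRr/ETRr/EGRr: reverse frame stored 3'-anchored (column j = position j
# from the 3' end), so both frames align observations from a shared edge.
.polytg_cache <- new.env(parent = emptyenv())

.genotype_table <- function(space) {
  key <- paste(space$min_t, space$max_t, space$min_tg, space$max_tg, sep = "_")
  hit <- .polytg_cache[[key]]
  if (!is.null(hit)) return(hit)
  tab <- .genotype_grid(space)
  Lmax <- max(tab$L)
  i <- 0:(Lmax - 1)
  CA_f <- t(mapply(function(m, n) .allele_code_fwd(m, n, i), tab$m1, tab$n1))
  CB_f <- t(mapply(function(m, n) .allele_code_fwd(m, n, i), tab$m2, tab$n2))
  CA_r <- t(mapply(function(m, n) .allele_code_rev(m, n, i), tab$m1, tab$n1))
  CB_r <- t(mapply(function(m, n) .allele_code_rev(m, n, i), tab$m2, tab$n2))
  dp_f <- .dosage_pattern(CA_f, CB_f)
  dp_r <- .dosage_pattern(CA_r, CB_r)
  out <- list(tab = tab, Lmax = Lmax,
              CF = dp_f$codes, ETF = dp_f$et, EGF = dp_f$eg,
              CRr = dp_r$codes, ETRr = dp_r$et, EGRr = dp_r$eg)
  .polytg_cache[[key]] <- out
  out
}

# numerator contributions and elimination flags for one direction.
# obs_* are 5'->3' for the forward frame and reversed (3'-anchored) for the
# reverse frame, matching the table's column convention.
.score_direction <- function(ot, og, w, ET, EG, CC, pf) {
  n <- length(ot)
  G <- nrow(ET)
  if (n == 0L)
    return(list(num = numeric(G), elim = logical(G)))
  k <- min(n, ncol(ET))
  num <- numeric(G)
  elim <- logical(G)
  if (k > 0) {
    wk <- w[1:k]
    # t() so the obs vectors recycle down columns (= along positions)
    dT <- t(ET[, 1:k, drop = FALSE]) - ot[1:k]
    dG <- t(EG[, 1:k, drop = FALSE]) - og[1:k]
    num <- colSums(wk * (dT * dT + dG * dG))
    Ck <- t(CC[, 1:k, drop = FALSE])
    bad <- (Ck == 1L & ot[1:k] < pf & wk) | (Ck == 2L & og[1:k] < pf & wk)
    elim <- colSums(bad) > 0L
  }
  if (n > ncol(ET)) {
    # observed positions beyond every pattern in the table: expected 0/0
    extra <- (ncol(ET) + 1):n
    num <- num + sum(w[extra] * (ot[extra]^2 + og[extra]^2))
  }
  list(num = num, elim = elim)
}

#' Rank all genotypes in a search space against the observed tracts
#'
#' Enumerates the search space, eliminates incompatible genotypes, scores
#' the survivors with the normalized difference score, and returns them
#' sorted ascending by score (ties broken by canonical label, so the order
#' is deterministic).
#'
#' @param obsF,obsR Observed tracts from [detect_forward_tract()] and
#'   [detect_reverse_tract()].
#' @param space A [search_space()].
#' @param cfg A [signal_config()].
#' @return A data.frame with one row per genotype: `label`, `m1`, `n1`,
#'   `m2`, `n2`, `expected_length`, `eliminated`, `d` and `rank` (`NA` for
#'   eliminated genotypes). Survivors come first, in rank order.
#' @export
rank_genotypes <- function(obsF, obsR, space = search_space(),
                           cfg = signal_config()) {
  nF <- obsF$length; nR <- obsR$length
  if (nF + nR == 0L)
    polytg_abort("no observed tract positions to score",
                 "degenerate_observation")
  tb <- .genotype_table(space)
  pf <- cfg$presence_fraction
  f <- .score_direction(obsF$ot, obsF$og, as.numeric(obsF$informative_mask),
                        tb$ETF, tb$EGF, tb$CF, pf)
  r <- .score_direction(rev(obsR$ot), rev(obsR$og),
                        as.numeric(rev(obsR$informative_mask)),
                        tb$ETRr, tb$EGRr, tb$CRr, pf)
  eliminated <- f$elim | r$elim | tb$tab$L > nF | tb$tab$L > nR
  d <- (f$num + r$num) / (2 * (nF + nR)) +
    (.LENGTH_BONUS_OFFSET - 2 * tb$tab$L) / .LENGTH_BONUS_SCALE
  if (all(eliminated))
    polytg_abort(
      "unable to find a matching (TG)mTn genotype in the search space",
      "no_matching_genotype")
  res <- data.frame(label = tb$tab$label,
                    m1 = tb$tab$m1, n1 = tb$tab$n1,
                    m2 = tb$tab$m2, n2 = tb$tab$n2,
                    expected_length = tb$tab$L,
                    eliminated = eliminated,
                    d = ifelse(eliminated, NA_real_, d),
                    stringsAsFactors = FALSE)
  ord <- order(res$eliminated, res$d, res$label)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res$rank <- NA_integer_
  n_surv <- sum(!res$eliminated)
  res$rank[seq_len(n_surv)] <- seq_len(n_surv)
  res
}

#' Per-position diagnostics for one genotype
#'
#' Pairs every observed tract position with the genotype's expected base set
#' and intensities, and classifies it as `match`, `mismatch` or `ignored`
#' (uninformative). Useful for reports and for inspecting why a genotype
#' scored as it did.
#'
#' @inheritParams is_compatible
#' @return A data.frame with columns `direction`, `position` (0-based within
#'   the observed tract, 5' to 3'), `ot`, `og`, `expected`, `et`, `eg`,
#'   `status`.
#' @export
genotype_diagnostics <- function(obsF, obsR, g, cfg = signal_config()) {
  patterns <- list(forward = expected_pattern(g, "forward"),
                   reverse = expected_pattern(g, "reverse"))
  pf <- cfg$presence_fraction
  out <- lapply(list(list(obsF, patterns$forward),
                     list(obsR, patterns$reverse)), function(pair) {
    obs <- pair[[1]]; al <- .align_expected(obs, pair[[2]])
    n <- obs$length
    if (n == 0L) return(NULL)
    t_present <- obs$ot >= pf
    g_present <- obs$og >= pf
    t_expected <- al$sets %in% c("T", "TG")
    g_expected <- al$sets %in% c("G", "TG")
    agrees <- (t_present == t_expected) & (g_present == g_expected)
    status <- ifelse(!obs$informative_mask, "ignored",
                     ifelse(agrees, "match", "mismatch"))
    data.frame(direction = obs$direction, position = seq_len(n) - 1L,
               ot = obs$ot, og = obs$og, expected = al$sets,
               et = al$et, eg = al$eg, status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
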