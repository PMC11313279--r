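# Independent brute-force reference for elimination and scoring. Shares no
# code with the package: patterns are built by string manipulation and the
# score is evaluated per genotype from first principles.

oracle_allele_string <- function(m, n)
  paste0(paste(rep("TG", m), collapse = ""), paste(rep("T", n), collapse = ""))

# expected T/G dosage vectors for one aligned pair of allele strings;
# align = "left" (forward) or "right" (reverse), frame length = longer allele
oracle_pattern <- function(s1, s2, align) {
  L <- max(nchar(s1), nchar(s2))
  pad <- function(s) {
    fill <- paste(rep("-", L - nchar(s)), collapse = "")
    if (align == "left") paste0(s, fill) else paste0(fill, s)
  }
  c1 <- strsplit(pad(s1), "")[[1]]
  c2 <- strsplit(pad(s2), "")[[1]]
  list(et = 0.5 * (c1 == "T") + 0.5 * (c2 == "T"),
       eg = 0.5 * (c1 == "G") + 0.5 * (c2 == "G"),
       L = L)
}

# align an expected vector to the n observed positions: forward tracts share
# the 5' edge (truncate/extend on the right), reverse tracts share the 3'
# edge (truncate/extend on the left); beyond-pattern positions expect 0
oracle_fit_obs <- function(v, n, align) {
  if (align == "left") {
    if (length(v) >= n) v[seq_len(n)] else c(v, rep(0, n - length(v)))
  } else {
    if (length(v) >= n) v[(length(v) - n + 1L):length(v)]
    else c(rep(0, n - length(v)), v)
  }
}

# full evaluation of one genotype against both observed tracts
oracle_eval <- function(m1, n1, m2, n2, obsF, obsR, pf = 0.10) {
  s1 <- oracle_allele_string(m1, n1)
  s2 <- oracle_allele_string(m2, n2)
  num <- 0
  eliminated <- FALSE
  for (dir in c("left", "right")) {
    obs <- if (dir == "left") obsF else obsR
    p <- oracle_pattern(s1, s2, dir)
    if (p$L > obs$length) eliminated <- TRUE
    et <- oracle_fit_obs(p$et, obs$length, dir)
    eg <- oracle_fit_obs(p$eg, obs$length, dir)
    for (i in seq_len(obs$length)) {
      if (!obs$informative_mask[i]) next
      if (et[i] > 0 && eg[i] == 0 && obs$ot[i] < pf) eliminated <- TRUE
      if (eg[i] > 0 && et[i] == 0 && obs$og[i] < pf) eliminated <- TRUE
      num <- num + (obs$og[i] - eg[i])^2 + (obs$ot[i] - et[i])^2
    }
  }
  L <- max(nchar(s1), nchar(s2))
  list(eliminated = eliminated,
       d = num / (2 * (obsF$length + obsR$length)) + (100 - 2 * L) / 1e5)
}

# evaluate every genotype of a rectangular search space; returns a
# data.frame keyed by the same label format the package prints
oracle_rank <- function(obsF, obsR, t_range = 3:11, tg_range = 8:16,
                        pf = 0.10) {
  rows <- list()
  al <- expand.grid(m = tg_range, n = t_range)
  for (i in seq_len(nrow(al))) for (j in seq_len(nrow(al))) {
    len_i <- 2 * al$m[i] + al$n[i]
    len_j <- 2 * al$m[j] + al$n[j]
    # canonical unordered pair: keep (i, j) with i's allele not after j's
    if (len_i > len_j || (len_i == len_j && al$m[i] > al$m[j])) next
    if (len_i == len_j && al$m[i] == al$m[j] && al$n[i] > al$n[j]) next
    ev <- oracle_eval(al$m[i], al$n[i], al$m[j], al$n[j], obsF, obsR, pf)
    rows[[length(rows) + 1L]] <- data.frame(
      label = sprintf("(TG)%dT%d/(TG)%dT%d", al$m[i], al$n[i],
                      al$m[j], al$n[j]),
      eliminated = ev$eliminated, d = ev$d, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
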