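# Shared fixture builders. Everything is generated in code at test time.

# a chromatogram read with one clean rectangular peak per base (no overlap),
# for tests that need full control over the trace content
pure_read <- function(seq, direction = "forward", height = 1000,
                      spacing = 10L, name = "fixture") {
  bases <- strsplit(seq, "")[[1]]
  n <- length(bases)
  tl <- spacing * n + spacing
  traces <- list(A = integer(tl), C = integer(tl),
                 G = integer(tl), T = integer(tl))
  centers <- spacing * seq_len(n) - (spacing %/% 2)
  for (j in seq_len(n)) {
    b <- bases[j]
    if (b %in% names(traces)) traces[[b]][centers[j] + 1L] <- height
  }
  chromatogram_read(name, direction, seq, centers, traces)
}

# profile with explicit per-position channel values (rows = positions)
profile_from_matrix <- function(mat, cfg = signal_config(),
                                direction = "forward") {
  seq <- paste(rep("N", nrow(mat)), collapse = "")
  n <- nrow(mat)
  spacing <- 10L
  tl <- spacing * n + spacing
  centers <- spacing * seq_len(n) - 5L
  traces <- list(A = integer(tl), C = integer(tl),
                 G = integer(tl), T = integer(tl))
  for (j in seq_len(n)) for (b in colnames(mat))
    traces[[b]][centers[j] + 1L] <- mat[j, b]
  relative_intensities(
    chromatogram_read("fixture", direction, seq, centers, traces), cfg)
}

# hand-built observed tract for scoring tests
obs_tract <- function(ot, og, direction = "forward",
                      informative = rep(TRUE, length(ot)),
                      fully_detected = TRUE, start = 20L) {
  structure(list(direction = direction, start = start, length = length(ot),
                 ot = ot, og = og, informative_mask = informative,
                 fully_detected = fully_detected),
            class = "polytg_observed_tract", anchor_start = start - 15L)
}

# simulate both directions and run detection, in memory
pipeline_obs <- function(g, seed = 1L, noise_sd = 0, bleed = 0, ...) {
  if (is.character(g)) g <- parse_genotype(g)
  spec <- simulation_spec(g, seed = seed, noise_sd = noise_sd,
                          bleed_through = bleed, ...)
  pf <- relative_intensities(simulate_read(spec, "forward"))
  pr <- orient_reverse(relative_intensities(simulate_read(spec, "reverse")))
  list(forward = detect_forward_tract(pf),
       reverse = detect_reverse_tract(pr),
       profile_forward = pf, profile_reverse = pr)
}

top_call <- function(g, seed = 1L, noise_sd = 0, ...) {
  obs <- pipeline_obs(g, seed = seed, noise_sd = noise_sd, ...)
  rank_genotypes(obs$forward, obs$reverse)$label[1]
}

# the reduced allele grid used for exhaustive recovery runs
subgrid_genotypes <- function(t_range = 5:9, tg_range = 10:13) {
  al <- expand.grid(m = tg_range, n = t_range)
  out <- list()
  for (i in seq_len(nrow(al))) for (j in i:nrow(al))
    out[[length(out) + 1L]] <- genotype(allele(al$m[i], al$n[i]),
                                        allele(al$m[j], al$n[j]))
  out
}

# byte-level patcher for crafting malformed ABIF fixtures
patch_bytes <- function(path, find, replace) {
  stopifnot(nchar(find) == nchar(replace))
  bytes <- readBin(path, "raw", file.info(path)$size)
  pat <- charToRaw(find)
  hit <- NULL
  for (i in seq_len(length(bytes) - length(pat) + 1L))
    if (all(bytes[i:(i + length(pat) - 1L)] == pat)) { hit <- i; break }
  stopifnot(!is.null(hit))
  bytes[hit:(hit + length(pat) - 1L)] <- charToRaw(replace)
  writeBin(bytes, path)
  path
}
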