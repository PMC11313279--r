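#' @title Synthetic chromatogram simulation
#' @description Seeded simulator producing bidirectional ABIF chromatograms
#'   for any poly-T/TG genotype. Each allele's full template (5' context +
#'   tract + 3' context) is rendered as Gaussian peaks at uniform spacing
#'   and half amplitude; the two allele traces are summed anchored at the
#'   read's 5' end, so alleles of unequal length drift out of register
#'   downstream of the tract and produce the overlapping peaks that make
#'   compound heterozygotes hard to read. Channel bleed-through, baseline
#'   noise and an optional superposed duplication (to mimic heterozygous
#'   indel interference) complete the picture. Trace physics is
#'   intentionally idealized (uniform spacing, symmetric peaks): the
#'   pipeline consumes peak-sampled relative intensities, so richer
#'   modeling would add no test power.
#' @name synthetic
NULL

.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Specify a simulated sample
#'
#' @param genotype A [genotype()] (or a label accepted by
#'   [parse_genotype()]).
#' @param context_5p,context_3p Flanking sequences around the tract. The
#'   defaults take 40 reference bases on each side (which include the 15 bp
#'   anchors); `full_amplicon = TRUE` uses the whole primer-to-primer
#'   reference region instead.
#' @param peak_spacing Trace points per called base (default 12).
#' @param peak_sigma Gaussian peak width in trace points (default 3).
#' @param amplitude Summed two-allele peak height in analyzer units
#'   (default 1000; each allele contributes half).
#' @param noise_sd Standard deviation of additive Gaussian baseline noise
#'   (default 0).
#' @param bleed_through Fraction of each channel's signal leaked into its
#'   spectrally adjacent channel (T into G, G into T, A into C, C into A);
#'   default 0. A value of 0.08 mimics the guanine shoulder seen under
#'   clean thymine peaks on real instruments.
#' @param seed Integer seed; simulation output is a deterministic function
#'   of the spec, and forward/reverse reads use distinct substreams.
#' @param extra_duplication Optional `c(offset, length)`: the second
#'   allele's template additionally carries a tandem duplication of the
#'   `length` bases ending at 0-based template position `offset - 1`,
#'   shifting everything downstream out of register - the signature of a
#'   heterozygous duplication elsewhere in the amplicon.
#' @param full_amplicon Use the full reference amplicon as context.
#' @return An object of class `polytg_sim_spec`.
#' @export
simulation_spec <- function(genotype, context_5p = NULL, context_3p = NULL,
                            peak_spacing = 12, peak_sigma = 3,
                            amplitude = 1000, noise_sd = 0,
                            bleed_through = 0, seed = 1L,
                            extra_duplication = NULL,
                            full_amplicon = FALSE) {
  if (is.character(genotype)) genotype <- parse_genotype(genotype)
  stopifnot(inherits(genotype, "polytg_genotype"))
  if (is.null(context_5p) || is.null(context_3p)) {
    ref <- cftr_reference_amplicon()
    ts <- attr(ref, "tract_start"); te <- attr(ref, "tract_end")
    if (is.null(context_5p))
      context_5p <- if (full_amplicon) substr(ref, 1L, ts)
                    else substr(ref, ts - 40L + 1L, ts)
    if (is.null(context_3p))
      context_3p <- if (full_amplicon) substr(ref, te + 2L, nchar(ref))
                    else substr(ref, te + 2L, te + 1L + 40L)
  }
  if (!(peak_spacing > 2 * peak_sigma))
    polytg_abort("peak_spacing must exceed 2 * peak_sigma", "invalid_spec")
  if (amplitude <= 0 || noise_sd < 0 ||
      bleed_through < 0 || bleed_through >= 0.5)
    polytg_abort("invalid amplitude/noise/bleed-through", "invalid_spec")
  if (nchar(context_5p) < 15L || nchar(context_3p) < 15L)
    polytg_abort("contexts must cover at least the 15 bp anchors",
                 "invalid_spec")
  if (!is.null(extra_duplication) &&
      (length(extra_duplication) != 2L || any(extra_duplication < 1)))
    polytg_abort("extra_duplication must be c(offset, length)", "invalid_spec")
  structure(list(genotype = genotype,
                 context_5p = toupper(context_5p),
                 context_3p = toupper(context_3p),
                 peak_spacing = as.integer(peak_spacing),
                 peak_sigma = peak_sigma, amplitude = amplitude,
                 noise_sd = noise_sd, bleed_through = bleed_through,
                 seed = as.integer(seed),
                 extra_duplication = extra_duplication),
            class = "polytg_sim_spec")
}

.sim_templates <- function(spec) {
  g <- spec$genotype
  t1 <- paste0(spec$context_5p, allele_sequence(g$allele_a), spec$context_3p)
  t2 <- paste0(spec$context_5p, allele_sequence(g$allele_b), spec$context_3p)
  if (!is.null(spec$extra_duplication)) {
    off <- as.integer(spec$extra_duplication[1])
    len <- as.integer(spec$extra_duplication[2])
    if (off > nchar(t2) || off - len < 0)
      polytg_abort("extra_duplication outside the template", "invalid_spec")
    t2 <- paste0(substr(t2, 1L, off),
                 substr(t2, off - len + 1L, off),
                 substr(t2, off + 1L, nchar(t2)))
  }
  c(t1, t2)
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate one sequencing direction
#'
#' Renders the two allele templates as summed Gaussian peak traces (see
#' [synthetic]), applies bleed-through and noise, integerizes, and calls
#' bases by the per-peak argmax channel. Deterministic given the spec.
#'
#' @param spec A [simulation_spec()].
#' @param direction `"forward"` or `"reverse"` (the reverse read is the
#'   reverse complement of the templates, as sequenced from the other
#'   primer).
#' @return A [chromatogram_read()] object.
#' @export
simulate_read <- function(spec, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(spec, "polytg_sim_spec"))
  templates <- .sim_templates(spec)
  if (direction == "reverse") templates <- vapply(templates, .revcomp, "")
  nb <- max(nchar(templates))
  sp <- spec$peak_spacing
  centers0 <- 18L + sp * (0:(nb - 1L))          # 0-based trace indices
  trace_len <- centers0[nb] + 19L
  # each peak is rendered on a support of one base cell (under one spacing),
  # so a peak-center sample sees only its own base's signal and noiseless
  # relative intensities are exactly the allele-dosage ratios
  halfwin <- sp - 1L
  kern_off <- -halfwin:halfwin
  kern <- exp(-(kern_off)^2 / (2 * spec$peak_sigma^2)) * spec$amplitude / 2

  ch <- list(A = numeric(trace_len), C = numeric(trace_len),
             G = numeric(trace_len), T = numeric(trace_len))
  for (tmpl in templates) {
    bases <- strsplit(tmpl, "")[[1]]
    for (j in seq_along(bases)) {
      b <- bases[j]
      if (!b %in% names(ch)) next
      at <- centers0[j] + 1L + kern_off
      keep <- at >= 1L & at <= trace_len
      ch[[b]][at[keep]] <- ch[[b]][at[keep]] + kern[keep]
    }
  }
  if (spec$bleed_through > 0) {
    bt <- spec$bleed_through
    orig <- ch
    ch$G <- ch$G + bt * orig$T
    ch$T <- ch$T + bt * orig$G
    ch$C <- ch$C + bt * orig$A
    ch$A <- ch$A + bt * orig$C
  }
  if (spec$noise_sd > 0) {
    s <- (spec$seed %% 1073741823L) * 2L + (direction == "reverse")
    .with_seed(s, {
      for (b in names(ch))
        ch[[b]] <- ch[[b]] + stats::rnorm(trace_len, 0, spec$noise_sd)
    })
  }
  ch <- lapply(ch, function(x) pmin(32767L, pmax(0L, as.integer(round(x)))))

  peak_mat <- rbind(A = ch$A[centers0 + 1L], C = ch$C[centers0 + 1L],
                    G = ch$G[centers0 + 1L], T = ch$T[centers0 + 1L])
  called <- rownames(peak_mat)[apply(peak_mat, 2L, which.max)]
  called[colSums(peak_mat) == 0L] <- "N"

  chromatogram_read(
    sample_name = sprintf("%s_seed%d", .safe_label(spec$genotype$label),
                          spec$seed),
    direction = direction,
    called_bases = paste(called, collapse = ""),
    peak_locations = centers0,
    traces = ch)
}

.safe_label <- function(label) gsub("[^A-Za-z0-9]+", "-", gsub("[()]", "", label))

#' Simulate a bidirectional sample and write ABIF files
#'
#' @param spec A [simulation_spec()].
#' @param out_dir Output directory (created if needed). Filenames embed the
#'   genotype label and seed.
#' @return Named character vector with the `forward` and `reverse` file
#'   paths.
#' @export
simulate_sample <- function(spec, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stem <- sprintf("%s_seed%d", .safe_label(spec$genotype$label), spec$seed)
  paths <- c(forward = file.path(out_dir, paste0(stem, "_F.ab1")),
             reverse = file.path(out_dir, paste0(stem, "_R.ab1")))
  write_abif(simulate_read(spec, "forward"), paths[["forward"]])
  write_abif(simulate_read(spec, "reverse"), paths[["reverse"]])
  paths
}
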