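#' @title End-to-end sample analysis, reporting and plotting
#' @name cli-report
#' @description [run_sample()] drives the whole pipeline for one sample and
#'   never raises on the two clinically meaningful failure modes - failing
#'   to detect the tract and finding no matching genotype - which become
#'   report statuses instead. Reports serialize to JSON; positions in
#'   reports and plots are 1-based and inclusive (the human-facing
#'   convention), while everything internal is 0-based.
NULL

.md5_or_na <- function(path) {
  x <- tryCatch(unname(tools::md5sum(path)), error = function(e) NA_character_)
  if (length(x) != 1L) NA_character_ else x
}

#' Analyze one bidirectional sample
#'
#' Reads both chromatograms, builds oriented intensity profiles, locates the
#' tract in each direction, screens the flanks for heterozygous indel
#' interference, ranks all genotypes in the search space, and assembles a
#' report. The two clinical failure classes surface as `status`
#' (`"tract_not_detected"`, `"no_matching_genotype"`) rather than errors;
#' partial tract detection and indel suspicion surface as warnings.
#'
#' @param forward_path,reverse_path Paths to the forward and reverse `.ab1`
#'   files.
#' @param space A [search_space()].
#' @param cfg A [signal_config()].
#' @param max_mismatch Anchor mismatch tolerance, see [find_anchor()].
#' @param sample_id Sample identifier (defaults to the forward file stem).
#' @return An object of class `polytg_report`; see [write_report()] for the
#'   serialized fields. Profiles and observed tracts are attached as
#'   attributes for [render_plot()].
#' @export
run_sample <- function(forward_path, reverse_path, space = search_space(),
                       cfg = signal_config(), max_mismatch = 2L,
                       sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.ab1$", "", basename(forward_path))
  read_f <- read_abif(forward_path, "forward")
  read_r <- read_abif(reverse_path, "reverse")
  prof_f <- relative_intensities(read_f, cfg)
  prof_r <- orient_reverse(relative_intensities(read_r, cfg))
  anchors <- cftr_flank_anchors()

  warnings <- character(0)
  status <- "ok"
  detection <- list()
  obsF <- obsR <- NULL
  genotypes <- NULL
  informative <- list(forward = integer(0), reverse = integer(0),
                      frame_length = NA_integer_)

  detect_one <- function(profile, direction) {
    tryCatch(
      if (direction == "forward")
        detect_forward_tract(profile, anchors, cfg, max_mismatch)
      else detect_reverse_tract(profile, anchors, cfg, max_mismatch),
      polytg_anchor_not_found = function(e) e,
      polytg_ambiguous_anchor = function(e) e)
  }
  obsF <- detect_one(prof_f, "forward")
  obsR <- detect_one(prof_r, "reverse")
  for (side in list(list(obsF, "forward"), list(obsR, "reverse"))) {
    if (inherits(side[[1]], "condition")) {
      status <- "tract_not_detected"
      warnings <- c(warnings,
                    sprintf("%s: unable to detect the (TG)mTn tract (%s)",
                            side[[2]], conditionMessage(side[[1]])))
    }
  }

  if (status == "ok") {
    qc_f <- flank_indel_check(prof_f, attr(obsF, "anchor_start"),
                              anchors$upstream15, cfg)
    qc_r <- flank_indel_check(prof_r, attr(obsR, "anchor_start"),
                              anchors$downstream15, cfg)
    for (side in list(list(qc_f, "forward"), list(qc_r, "reverse"))) {
      if (side[[1]]$flag)
        warnings <- c(warnings, sprintf("%s flank: %s", side[[2]],
                                        side[[1]]$message))
    }
    for (side in list(list(obsF, "forward"), list(obsR, "reverse"))) {
      if (!side[[1]]$fully_detected)
        warnings <- c(warnings, sprintf(
          "%s: (TG)mTn tract only partially detected - consider discarding this result",
          side[[2]]))
    }
    detection <- list(
      forward = list(anchor_start = attr(obsF, "anchor_start") + 1L,
                     tract_start = obsF$start + 1L,
                     tract_length = obsF$length,
                     fully_detected = obsF$fully_detected,
                     indel_suspected = qc_f$flag,
                     dirty_anchor_positions = qc_f$n_dirty),
      reverse = list(anchor_start = attr(obsR, "anchor_start") + 1L,
                     tract_start = obsR$start + 1L,
                     tract_length = obsR$length,
                     fully_detected = obsR$fully_detected,
                     indel_suspected = qc_r$flag,
                     dirty_anchor_positions = qc_r$n_dirty))

    genotypes <- tryCatch(rank_genotypes(obsF, obsR, space, cfg),
                          polytg_no_matching_genotype = function(e) e)
    if (inherits(genotypes, "condition")) {
      status <- "no_matching_genotype"
      warnings <- c(warnings, conditionMessage(genotypes))
      genotypes <- NULL
    } else {
      surv <- genotypes[!genotypes$eliminated, , drop = FALSE]
      if (nrow(surv) >= 2L) {
        pats <- function(direction) lapply(seq_len(nrow(surv)), function(i)
          expected_pattern(genotype(allele(surv$m1[i], surv$n1[i]),
                                    allele(surv$m2[i], surv$n2[i])),
                           direction))
        informative <- list(
          forward = informative_positions(pats("forward"), "forward") + 1L,
          reverse = informative_positions(pats("reverse"), "reverse") + 1L,
          frame_length = max(surv$expected_length))
      }
    }
  }

  report <- structure(list(
    sample_id = sample_id,
    inputs = list(forward = list(path = forward_path,
                                 md5 = .md5_or_na(forward_path)),
                  reverse = list(path = reverse_path,
                                 md5 = .md5_or_na(reverse_path))),
    parameters = list(min_t = space$min_t, max_t = space$max_t,
                      min_tg = space$min_tg, max_tg = space$max_tg,
                      min_total_signal = cfg$min_total_signal,
                      presence_fraction = cfg$presence_fraction,
                      max_mismatch = max_mismatch),
    status = status,
    detection = detection,
    genotypes = genotypes,
    informative_positions = informative,
    warnings = warnings
  ), class = "polytg_report")
  attr(report, "profiles") <- list(forward = prof_f, reverse = prof_r)
  attr(report, "reads") <- list(forward = read_f, reverse = read_r)
  attr(report, "tracts") <- if (status != "tract_not_detected")
    list(forward = obsF, reverse = obsR) else NULL
  report
}

#' @export
print.polytg_report <- function(x, ...) {
  cat(sprintf("<polytg_report> %s: status %s\n", x$sample_id, x$status))
  if (!is.null(x$genotypes)) {
    surv <- x$genotypes[!x$genotypes$eliminated, , drop = FALSE]
    top <- utils::head(surv, 5L)
    cat(sprintf("  %d genotypes survive (of %d); top ranked:\n",
                nrow(surv), nrow(x$genotypes)))
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %d. %-22s d = %.6g\n", top$rank[i], top$label[i],
                  top$d[i]))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Map a report status to a shell exit code
#'
#' `0` for ok, `2` when the tract could not be detected, `3` when no
#' genotype in the search space matched (I/O failures raise and exit 1).
#'
#' @param report A `polytg_report`.
#' @return Integer exit code.
#' @export
report_exit_code <- function(report) {
  switch(report$status, ok = 0L, tract_not_detected = 2L,
         no_matching_genotype = 3L, 1L)
}

#' Serialize a report to JSON
#'
#' The payload is deterministic for identical inputs and parameters (no
#' timestamps). The ranked genotype table is truncated to `max_genotypes`
#' rows (eliminated genotypes are summarized by a count).
#'
#' @param report A `polytg_report`.
#' @param path Output path; `NULL` returns the JSON string.
#' @param max_genotypes Ranked rows to include (default 25).
#' @return `path` (or the JSON string), invisibly.
#' @export
write_report <- function(report, path = NULL, max_genotypes = 25L) {
  payload <- unclass(report)
  attributes(payload) <- list(names = names(payload))
  if (!is.null(payload$genotypes)) {
    g <- payload$genotypes
    payload$n_genotypes <- nrow(g)
    payload$n_eliminated <- sum(g$eliminated)
    payload$n_survivors <- sum(!g$eliminated)
    keep <- g[!g$eliminated, , drop = FALSE]
    payload$genotypes <- utils::head(
      keep[, c("rank", "label", "d", "expected_length")], max_genotypes)
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}

#' Batch analysis from a manifest
#'
#' @param manifest Path to a headerless 3-column TSV: sample id, forward
#'   `.ab1` path, reverse `.ab1` path.
#' @param out_dir Output directory; one `<sample>.json` per sample plus a
#'   `summary.tsv` with the top-ranked call per sample.
#' @param ... Passed on to [run_sample()].
#' @return The summary data.frame, invisibly.
#' @export
run_batch <- function(manifest, out_dir, ...) {
  man <- utils::read.delim(manifest, header = FALSE,
                           col.names = c("sample_id", "forward", "reverse"),
                           stringsAsFactors = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- lapply(seq_len(nrow(man)), function(i) {
    rep <- tryCatch(run_sample(man$forward[i], man$reverse[i],
                               sample_id = man$sample_id[i], ...),
                    error = function(e) e)
    if (inherits(rep, "error")) {
      return(data.frame(sample_id = man$sample_id[i], status = "error",
                        rank1_genotype = NA_character_, d = NA_real_,
                        warnings = conditionMessage(rep),
                        stringsAsFactors = FALSE))
    }
    write_report(rep, file.path(out_dir, paste0(man$sample_id[i], ".json")))
    surv <- if (is.null(rep$genotypes)) NULL
            else rep$genotypes[!rep$genotypes$eliminated, , drop = FALSE]
    data.frame(sample_id = man$sample_id[i], status = rep$status,
               rank1_genotype = if (!is.null(surv) && nrow(surv))
                 surv$label[1] else NA_character_,
               d = if (!is.null(surv) && nrow(surv)) surv$d[1] else NA_real_,
               warnings = paste(rep$warnings, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summary)
}

# orient a reverse read's raw traces into genomic-forward coordinates so
# plots can show both directions on the same axis
.oriented_read <- function(read) {
  if (read$direction == "forward") return(read)
  tl <- read$trace_length
  traces <- list(A = rev(read$traces$T), C = rev(read$traces$G),
                 G = rev(read$traces$C), T = rev(read$traces$A))
  list(sample_name = read$sample_name,
       called_bases = chartr("ACGTN", "TGCAN",
                             paste(rev(strsplit(read$called_bases, "")[[1]]),
                                   collapse = "")),
       peak_locations = rev(tl - 1L - read$peak_locations),
       traces = traces, trace_length = tl)
}

.CHANNEL_COLORS <- c(A = "forestgreen", C = "blue3", G = "grey20", T = "red3")

#' Plot observed traces against a genotype's expected pattern
#'
#' One panel per direction: the observed four-channel traces over the tract
#' plus 15 bp on each side, the detected tract shaded grey, positions that
#' discriminate among surviving genotypes shaded blue, and the chosen
#' genotype's expected letters (T, G or T/G) beneath the peaks. The header
#' gives the genotype label, its rank and its score.
#'
#' @param report A `polytg_report` from [run_sample()] with status `"ok"`.
#' @param genotype_index 1-based rank of the (surviving) genotype to
#'   display.
#' @param file Output image path (`.png` or `.svg`); `NULL` draws on the
#'   current device.
#' @param flank Bases of context shown on each side of the tract.
#' @return `file` (or `NULL`), invisibly.
#' @export
render_plot <- function(report, genotype_index = 1L, file = NULL,
                        flank = 15L) {
  stopifnot(inherits(report, "polytg_report"))
  if (report$status != "ok")
    polytg_abort("can only plot reports with status ok", "io")
  surv <- report$genotypes[!report$genotypes$eliminated, , drop = FALSE]
  if (genotype_index < 1L || genotype_index > nrow(surv))
    polytg_abort(sprintf("genotype_index %d out of range (1..%d)",
                         genotype_index, nrow(surv)), "index_out_of_range")
  row <- surv[genotype_index, ]
  g <- genotype(allele(row$m1, row$n1), allele(row$m2, row$n2))
  profiles <- attr(report, "profiles")
  reads <- attr(report, "reads")
  tracts <- attr(report, "tracts")

  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 10, height = 7)
    else grDevices::png(file, width = 1400, height = 900, res = 120)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(4.5, 3, 2.5, 1))
  on.exit(graphics::par(op), add = TRUE)

  for (direction in c("forward", "reverse")) {
    prof <- profiles[[direction]]
    obs <- tracts[[direction]]
    rd <- .oriented_read(reads[[direction]])
    pat <- expected_pattern(g, direction)
    n_pos <- nrow(prof$rel)

    # profile positions (0-based) of the expected letters, per alignment
    if (direction == "forward") {
      letter_pos <- obs$start + seq_len(pat$length) - 1L
      info_pos <- report$informative_positions$forward - 1L + obs$start
    } else {
      tract_end <- obs$start + obs$length - 1L
      frame_len <- max(pat$length, obs$length,
                       report$informative_positions$frame_length, na.rm = TRUE)
      letter_pos <- tract_end - (pat$length - seq_len(pat$length))
      info_pos <- tract_end - (frame_len - report$informative_positions$reverse)
    }
    win <- max(0L, obs$start - flank):
           min(n_pos - 1L, max(obs$start + obs$length - 1L,
                               letter_pos) + flank)
    ploc <- rd$peak_locations[win + 1L]
    xr <- pmax(0, pmin(rd$trace_length - 1L, range(ploc) + c(-6, 6)))
    ymax <- max(1, vapply(rd$traces, function(tr)
      max(tr[(xr[1]:xr[2]) + 1L], na.rm = TRUE), numeric(1)))

    graphics::plot(NA, xlim = xr, ylim = c(-0.18 * ymax, ymax * 1.05),
                   xlab = "", ylab = "signal", xaxt = "n", yaxt = "n",
                   main = sprintf("%s  |  %s  rank %d  d = %.6g",
                                  direction, g$label, row$rank, row$d),
                   cex.main = 0.95)
    # detected tract: grey; informative positions: blue
    tr_idx <- obs$start + seq_len(obs$length) - 1L
    .shade <- function(pos0, col) {
      pos0 <- pos0[pos0 >= 0L & pos0 < n_pos]
      for (p in pos0) {
        x <- rd$peak_locations[p + 1L]
        graphics::rect(x - 5, -0.18 * ymax, x + 5, ymax * 1.05,
                       col = col, border = NA)
      }
    }
    .shade(tr_idx, grDevices::adjustcolor("grey70", 0.35))
    .shade(info_pos, grDevices::adjustcolor("steelblue1", 0.45))
    xs <- xr[1]:xr[2]
    for (b in names(.CHANNEL_COLORS))
      graphics::lines(xs, rd$traces[[b]][xs + 1L],
                      col = .CHANNEL_COLORS[b], lwd = 1.3)
    # expected letters under the axis
    lab <- ifelse(pat$sets == "TG", "T/G", pat$sets)
    ok <- letter_pos >= 0L & letter_pos < n_pos
    graphics::text(rd$peak_locations[letter_pos[ok] + 1L],
                   -0.10 * ymax, lab[ok], cex = 0.75, font = 2)
    graphics::axis(1, at = rd$peak_locations[win + 1L],
                   labels = win + 1L, cex.axis = 0.55, las = 2)
    graphics::mtext("position (1-based, genomic-forward)", side = 1,
                    line = 3, cex = 0.7)
  }
  invisible(file)
}
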