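#' @title ABIF chromatogram input/output
#' @description Minimal, bit-exact reader and writer for Applied Biosystems
#'   ABIF (.ab1) trace files. Only the records the genotyping pipeline needs
#'   are interpreted: called bases, per-base peak locations, the channel-order
#'   record, and the four analyzed trace channels. Everything is big-endian.
#' @name abif-io
NULL

# ABIF element type codes we decode
.ABIF_TYPES <- c(byte = 1L, char = 2L, word = 3L, short = 4L, long = 5L,
                 float = 7L, double = 8L, pString = 18L, cString = 19L)

.abif_elt_size <- function(type) {
  switch(as.character(type),
         "1" = 1L, "2" = 1L, "3" = 2L, "4" = 2L, "5" = 4L,
         "7" = 4L, "8" = 8L, "18" = 1L, "19" = 1L,
         1L)  # unknown types: treat payload as raw bytes
}

.decode_payload <- function(raw, type, n) {
  switch(as.character(type),
         "1"  = as.integer(raw),
         "2"  = rawToChar(raw),
         "3"  = readBin(raw, "integer", n = n, size = 2L, signed = FALSE,
                        endian = "big"),
         "4"  = readBin(raw, "integer", n = n, size = 2L, signed = TRUE,
                        endian = "big"),
         "5"  = readBin(raw, "integer", n = n, size = 4L, endian = "big"),
         "7"  = readBin(raw, "numeric", n = n, size = 4L, endian = "big"),
         "8"  = readBin(raw, "numeric", n = n, size = 8L, endian = "big"),
         "18" = if (length(raw) >= 1L)
                  rawToChar(raw[-1L]) else "",
         "19" = rawToChar(raw[raw != as.raw(0L)]),
         raw)
}

#' Read the full ABIF record directory
#'
#' Parses the header and directory of an ABIF file and decodes every entry's
#' payload according to its element type. Mostly useful for inspection and
#' testing; [read_abif()] is the pipeline-facing reader.
#'
#' @param path Path to an `.ab1` file.
#' @return A list of records. Each record is a list with elements `tag_name`,
#'   `tag_number`, `element_type`, `n_elements` and `payload` (decoded per the
#'   element type; unknown types are kept as raw bytes).
#' @export
read_abif_directory <- function(path) {
  if (!file.exists(path)) polytg_abort(sprintf("file not found: %s", path), "io")
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- readBin(con, "raw", n = size)
  if (length(bytes) < 128L || rawToChar(bytes[1:4]) != "ABIF")
    polytg_abort(sprintf("not an ABIF file (bad magic): %s", path), "not_abif")

  # header directory entry (offset 6, 28 bytes) points at the record directory
  tdir <- .parse_dir_entry(bytes, 7L)
  n_rec <- tdir$n_elements
  dir_off <- tdir$data_offset
  if (n_rec < 0L || dir_off < 0L || dir_off + 28 * n_rec > length(bytes))
    polytg_abort("ABIF directory offset/length out of bounds",
                 "malformed_directory")

  records <- vector("list", n_rec)
  seen <- character(0)
  for (k in seq_len(n_rec)) {
    e <- .parse_dir_entry(bytes, dir_off + 28L * (k - 1L) + 1L)
    key <- paste0(e$tag_name, "#", e$tag_number)
    if (key %in% seen)
      polytg_abort(sprintf("duplicate ABIF directory entry %s", key),
                   "malformed_directory")
    seen <- c(seen, key)
    if (e$data_size <= 4L) {
      payload_raw <- e$inline[seq_len(max(e$data_size, 0L))]
    } else {
      if (e$data_offset < 0L || e$data_offset + e$data_size > length(bytes))
        polytg_abort(sprintf("record %s data out of bounds", key),
                     "malformed_directory")
      payload_raw <- bytes[(e$data_offset + 1L):(e$data_offset + e$data_size)]
    }
    payload <- .decode_payload(payload_raw, e$element_type, e$n_elements)
    expected_n <- if (e$element_type %in% c(2L, 18L, 19L)) NA_integer_
                  else e$n_elements
    if (!is.na(expected_n) && !is.raw(payload) &&
        length(payload) != expected_n)
      polytg_abort(sprintf("record %s: decoded %d elements, directory says %d",
                           key, length(payload), expected_n),
                   "malformed_directory")
    records[[k]] <- list(tag_name = e$tag_name, tag_number = e$tag_number,
                         element_type = e$element_type,
                         n_elements = e$n_elements, payload = payload)
  }
  records
}

.parse_dir_entry <- function(bytes, at) {
  # 28-byte directory entry starting at 1-based index `at`
  slice <- bytes[at:(at + 27L)]
  list(tag_name     = rawToChar(slice[1:4]),
       tag_number   = readBin(slice[5:8],  "integer", size = 4L, endian = "big"),
       element_type = readBin(slice[9:10], "integer", size = 2L, endian = "big"),
       element_size = readBin(slice[11:12], "integer", size = 2L, endian = "big"),
       n_elements   = readBin(slice[13:16], "integer", size = 4L, endian = "big"),
       data_size    = readBin(slice[17:20], "integer", size = 4L, endian = "big"),
       data_offset  = readBin(slice[21:24], "integer", size = 4L, endian = "big"),
       inline       = slice[21:24])
}

.abif_get <- function(records, name, number) {
  for (r in records)
    if (r$tag_name == name && r$tag_number == number) return(r)
  NULL
}

.abif_get_pref <- function(records, name, numbers) {
  # record-preference rule: first tag number that exists wins
  # (tag 1 = user-editable copy, tag 2 = original base-caller output)
  for (num in numbers) {
    r <- .abif_get(records, name, num)
    if (!is.null(r)) return(r)
  }
  polytg_abort(sprintf("required ABIF record %s (tag %s) is missing",
                       name, paste(numbers, collapse = "/")),
               "missing_record", tag = name)
}

#' Construct a chromatogram read
#'
#' Container for one sequencing direction of a sample: the called bases, the
#' trace-array index of each called base's peak, and the four analyzed trace
#' channels keyed by nucleotide. All indices are 0-based.
#'
#' @param sample_name Sample identifier.
#' @param direction `"forward"` or `"reverse"`. Assigned by the caller; the
#'   ABIF file itself does not record direction.
#' @param called_bases Single string over `A`, `C`, `G`, `T`, `N`.
#' @param peak_locations Integer vector, one 0-based trace index per called
#'   base, strictly increasing.
#' @param traces Named list of four non-negative integer vectors (`A`, `C`,
#'   `G`, `T`), all of identical length.
#' @return An object of class `polytg_read`.
#' @export
chromatogram_read <- function(sample_name, direction, called_bases,
                              peak_locations, traces) {
  direction <- match.arg(direction, c("forward", "reverse"))
  lens <- lengths(traces)
  stopifnot(
    is.character(called_bases), length(called_bases) == 1L,
    length(peak_locations) == nchar(called_bases),
    setequal(names(traces), c("A", "C", "G", "T")),
    length(unique(lens)) == 1L
  )
  peak_locations <- as.integer(peak_locations)
  if (length(peak_locations) > 1L && any(diff(peak_locations) <= 0L))
    stop("peak_locations must be strictly increasing")
  if (length(peak_locations) && (min(peak_locations) < 0L ||
      max(peak_locations) >= lens[[1]]))
    stop("peak_locations must lie within the trace arrays")
  structure(list(sample_name = sample_name, direction = direction,
                 called_bases = called_bases,
                 peak_locations = peak_locations,
                 traces = traces[c("A", "C", "G", "T")],
                 trace_length = unname(lens[[1]])),
            class = "polytg_read")
}

#' @export
print.polytg_read <- function(x, ...) {
  cat(sprintf("<polytg_read> %s (%s): %d called bases, trace length %d\n",
              x$sample_name, x$direction, nchar(x$called_bases),
              x$trace_length))
  invisible(x)
}

#' Read an ABIF (.ab1) chromatogram
#'
#' Returns the called bases, peak locations and the four analyzed trace
#' channels of an ABIF file. Trace channels are mapped to nucleotides using
#' the file's channel-order record (`FWO_`), never by on-disk position. The
#' user-edited copies of the called-base and peak-location records are
#' preferred over the original base-caller output when both exist.
#'
#' @param path Path to an `.ab1` file.
#' @param direction `"forward"` or `"reverse"`; the sequencing direction is
#'   not stored in the file and must be supplied by the caller.
#' @return A [chromatogram_read()] object.
#' @export
read_abif <- function(path, direction = "forward") {
  records <- read_abif_directory(path)

  fwo <- .abif_get_pref(records, "FWO_", 1L)$payload
  order_bases <- strsplit(fwo, "")[[1]]
  if (length(order_bases) != 4L || !setequal(order_bases, c("A", "C", "G", "T")))
    polytg_abort(sprintf("invalid channel-order record: %s", fwo),
                 "malformed_directory")

  traces <- vector("list", 4L)
  names(traces) <- order_bases
  for (k in 1:4) {
    # DATA 9-12 hold the analyzed (post-processing) traces; raw traces
    # (DATA 1-4) are never used because peak locations index the analyzed ones
    traces[[k]] <- .abif_get_pref(records, "DATA", 8L + k)$payload
  }
  if (length(unique(lengths(traces))) != 1L)
    polytg_abort("analyzed trace channels differ in length",
                 "malformed_directory")

  bases <- .abif_get_pref(records, "PBAS", c(1L, 2L))$payload
  ploc  <- .abif_get_pref(records, "PLOC", c(1L, 2L))$payload
  smpl  <- .abif_get(records, "SMPL", 1L)
  name  <- if (is.null(smpl)) sub("\\.ab1$", "", basename(path))
           else smpl$payload

  chromatogram_read(sample_name = name, direction = direction,
                    called_bases = bases, peak_locations = ploc,
                    traces = traces)
}

.dir_entry_bytes <- function(tag_name, tag_number, type, n, payload_raw,
                             offset) {
  size <- .abif_elt_size(type)
  data_size <- length(payload_raw)
  buf <- raw(28L)
  buf[1:4]   <- charToRaw(tag_name)
  buf[5:8]   <- writeBin(as.integer(tag_number), raw(), size = 4L, endian = "big")
  buf[9:10]  <- writeBin(as.integer(type), raw(), size = 2L, endian = "big")
  buf[11:12] <- writeBin(size, raw(), size = 2L, endian = "big")
  buf[13:16] <- writeBin(as.integer(n), raw(), size = 4L, endian = "big")
  buf[17:20] <- writeBin(as.integer(data_size), raw(), size = 4L, endian = "big")
  if (data_size <= 4L) {
    if (data_size > 0L) buf[21:(20L + data_size)] <- payload_raw
  } else {
    buf[21:24] <- writeBin(as.integer(offset), raw(), size = 4L, endian = "big")
  }
  buf
}

.encode_short <- function(x) {
  x <- as.integer(x)
  if (length(x) && (min(x) < -32768L || max(x) > 32767L))
    polytg_abort("value out of 16-bit range for ABIF short record", "io")
  writeBin(x, raw(), size = 2L, endian = "big")
}

#' Write a chromatogram to an ABIF (.ab1) file
#'
#' Emits a minimal valid big-endian ABIF file containing the analyzed trace
#' channels (`DATA` 9-12), the channel order (`FWO_` 1), the called bases
#' (`PBAS` 2), the peak locations (`PLOC` 2) and the sample name (`SMPL` 1).
#' [read_abif()] round-trips the result exactly.
#'
#' @param read A [chromatogram_read()] object.
#' @param path Output file path.
#' @param channel_order Order in which the four trace channels are laid out
#'   on disk (the `FWO_` record). Any permutation of `"ACGT"`; readers must
#'   honor it, so permuting it does not change what [read_abif()] returns.
#' @return `path`, invisibly.
#' @export
write_abif <- function(read, path, channel_order = "GATC") {
  stopifnot(inherits(read, "polytg_read"))
  ord <- strsplit(channel_order, "")[[1]]
  if (!setequal(ord, c("A", "C", "G", "T")))
    polytg_abort("channel_order must be a permutation of ACGT", "io")

  recs <- list(
    list("FWO_", 1L, 2L, 4L, charToRaw(channel_order)),
    list("PBAS", 2L, 2L, nchar(read$called_bases),
         charToRaw(read$called_bases)),
    list("PLOC", 2L, 4L, length(read$peak_locations),
         .encode_short(read$peak_locations)),
    list("SMPL", 1L, 18L, nchar(read$sample_name) + 1L,
         c(as.raw(nchar(read$sample_name)), charToRaw(read$sample_name)))
  )
  for (k in 1:4) {
    recs[[length(recs) + 1L]] <-
      list("DATA", 8L + k, 4L, read$trace_length,
           .encode_short(read$traces[[ord[k]]]))
  }

  # lay out data blocks after the 128-byte header, directory last
  offset <- 128L
  blocks <- list()
  entries <- raw(0)
  for (r in recs) {
    payload <- r[[5]]
    entries <- c(entries, .dir_entry_bytes(r[[1]], r[[2]], r[[3]], r[[4]],
                                           payload, offset))
    if (length(payload) > 4L) {
      blocks[[length(blocks) + 1L]] <- payload
      offset <- offset + length(payload)
    }
  }
  dir_offset <- offset

  header <- raw(128L)
  header[1:4] <- charToRaw("ABIF")
  header[5:6] <- writeBin(101L, raw(), size = 2L, endian = "big")
  header[7:34] <- .dir_entry_bytes("tdir", 1L, 1023L, length(recs),
                                   raw(28L * length(recs)), dir_offset)

  con <- tryCatch(file(path, "wb"),
                  error = function(e) polytg_abort(conditionMessage(e), "io"))
  on.exit(close(con))
  writeBin(header, con)
  for (b in blocks) writeBin(b, con)
  writeBin(entries, con)
  invisible(path)
}
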