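# Minimal multiframe DICOM (Part 10, Explicit VR Little Endian) reader/writer.
# Covers exactly the tags the pipeline needs: Rows, Columns, NumberOfFrames,
# FrameTimeVector / FrameTime / CineRate, SamplesPerPixel, BitsAllocated and
# 8-bit PixelData. Anything else in a file is skipped; transfer syntaxes other
# than Explicit VR LE are refused.

.DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.DICOM_UID_ROOT <- "1.2.826.0.1.3680043.10.1431"

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16le <- function(x) {
  x <- as.integer(x)
  as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L)))
}

.u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.read_u16 <- function(bytes, at) {
  as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
}

.read_u32 <- function(bytes, at) {
  as.numeric(bytes[at]) + 256 * as.numeric(bytes[at + 1L]) +
    65536 * as.numeric(bytes[at + 2L]) + 16777216 * as.numeric(bytes[at + 3L])
}

# Encode one data element (explicit VR little endian)
.dicom_element <- function(group, elem, vr, value) {
  if (vr == "US") {
    payload <- do.call(c, lapply(as.integer(value), .u16le))
  } else if (vr == "OB") {
    payload <- as.raw(value)
    if (length(payload) %% 2L == 1L) payload <- c(payload, as.raw(0L))
  } else { # string VRs: UI, CS, IS, DS, LO, SH
    s <- paste(value, collapse = "\\")
    payload <- charToRaw(s)
    if (length(payload) %% 2L == 1L) {
      pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
      payload <- c(payload, pad)
    }
  }
  head <- c(.u16le(group), .u16le(elem), charToRaw(vr))
  if (vr %in% .long_vrs) {
    head <- c(head, as.raw(c(0L, 0L)), .u32le(length(payload)))
  } else {
    head <- c(head, .u16le(length(payload)))
  }
  c(head, payload)
}

# pixels: numeric array rows x cols x nframes, values in [0, 255]
# frame_times_s: absolute frame times (seconds, starting at 0)
.dicom_write_multiframe <- function(path, pixels, frame_times_s,
                                    instance_uid = NULL) {
  dm <- dim(pixels)
  if (length(dm) != 3L) stop("pixels must be a rows x cols x frames array")
  rows <- dm[1L]; cols <- dm[2L]; nf <- dm[3L]
  if (length(frame_times_s) != nf)
    stop("frame_times_s length must equal the number of frames")
  if (is.null(instance_uid))
    instance_uid <- paste0(.DICOM_UID_ROOT, ".1.",
                           format(nf), ".", format(rows * cols))
  # FrameTimeVector holds inter-frame increments in ms (first entry 0)
  incr_ms <- c(0, diff(frame_times_s)) * 1000
  ftv <- formatC(incr_ms, format = "fg", digits = 10, width = 1)

  sop_class <- "1.2.840.10008.5.1.4.1.1.7.2" # multiframe grayscale byte SC
  meta <- c(
    .dicom_element(0x0002, 0x0001, "OB", c(0L, 1L)),
    .dicom_element(0x0002, 0x0002, "UI", sop_class),
    .dicom_element(0x0002, 0x0003, "UI", instance_uid),
    .dicom_element(0x0002, 0x0010, "UI", .DICOM_TS_EXPLICIT_LE),
    .dicom_element(0x0002, 0x0012, "UI", paste0(.DICOM_UID_ROOT, ".0.1"))
  )
  # (0002,0000) FileMetaInformationGroupLength: byte count of the elements
  # above, written by hand as UL
  gl <- c(.u16le(0x0002), .u16le(0x0000), charToRaw("UL"), .u16le(4L),
          .u32le(length(meta)))
  meta <- c(gl, meta)

  # row-major bytes, frame by frame
  px <- aperm(pixels, c(2L, 1L, 3L))
  bytes_px <- as.raw(as.integer(round(pmin(pmax(px, 0), 255))))

  body <- c(
    .dicom_element(0x0008, 0x0016, "UI", sop_class),
    .dicom_element(0x0008, 0x0018, "UI", instance_uid),
    .dicom_element(0x0008, 0x0060, "CS", "US"),
    .dicom_element(0x0018, 0x1065, "DS", ftv),
    .dicom_element(0x0028, 0x0002, "US", 1L),
    .dicom_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dicom_element(0x0028, 0x0008, "IS", format(nf)),
    .dicom_element(0x0028, 0x0010, "US", rows),
    .dicom_element(0x0028, 0x0011, "US", cols),
    .dicom_element(0x0028, 0x0100, "US", 8L),
    .dicom_element(0x0028, 0x0101, "US", 8L),
    .dicom_element(0x0028, 0x0102, "US", 7L),
    .dicom_element(0x0028, 0x0103, "US", 0L),
    .dicom_element(0x7FE0, 0x0010, "OB", bytes_px)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 128L)), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# Parse a Part-10 explicit-VR-LE file into a tag -> value list.
.dicom_parse <- function(path) {
  n <- file.info(path)$size
  if (is.na(n) || n < 140) stop("not a DICOM file: ", path)
  bytes <- readBin(path, "raw", n = n)
  if (rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  p <- 133L
  out <- list()
  while (p + 7L <= n) {
    group <- .read_u16(bytes, p)
    elem <- .read_u16(bytes, p + 2L)
    vr <- rawToChar(bytes[(p + 4L):(p + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported DICOM encoding (implicit VR?) in ", path)
    if (vr %in% .long_vrs) {
      len <- .read_u32(bytes, p + 8L)
      vstart <- p + 12L
    } else {
      len <- .read_u16(bytes, p + 6L)
      vstart <- p + 8L
    }
    key <- sprintf("%04X,%04X", group, elem)
    val_bytes <- if (len > 0) bytes[vstart:(vstart + len - 1L)] else raw(0)
    out[[key]] <- list(vr = vr, bytes = val_bytes)
    p <- vstart + len
  }
  ts <- .dicom_string(out, "0002,0010")
  if (!is.null(ts) && ts != .DICOM_TS_EXPLICIT_LE)
    stop("unsupported transfer syntax: ", ts)
  out
}

.dicom_string <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  b <- el$bytes
  while (length(b) && (b[length(b)] == as.raw(0L) || b[length(b)] == charToRaw(" ")))
    b <- b[-length(b)]
  rawToChar(b)
}

.dicom_numeric <- function(tags, key) {
  s <- .dicom_string(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.dicom_us <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  .read_u16(el$bytes, 1L)
}
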