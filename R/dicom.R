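## Minimal DICOM (single-frame CT) reader.
##
## Supports uncompressed Implicit / Explicit VR Little Endian transfer
## syntaxes, which covers CT series as archived by clinical PACS exports.
## Only the tags the pipeline needs are interpreted; everything else is
## skipped by length. Compressed or big-endian syntaxes are rejected.

DICOM_TAGS <- list(
  modality          = c(0x0008L, 0x0060L),
  series_uid        = c(0x0020L, 0x000EL),
  instance_number   = c(0x0020L, 0x0013L),
  position          = c(0x0020L, 0x0032L),
  orientation       = c(0x0020L, 0x0037L),
  rows              = c(0x0028L, 0x0010L),
  columns           = c(0x0028L, 0x0011L),
  pixel_spacing     = c(0x0028L, 0x0030L),
  slice_thickness   = c(0x0018L, 0x0050L),
  bits_allocated    = c(0x0028L, 0x0100L),
  pixel_repr        = c(0x0028L, 0x0103L),
  rescale_intercept = c(0x0028L, 0x1052L),
  rescale_slope     = c(0x0028L, 0x1053L),
  patient_age       = c(0x0010L, 0x1010L),
  pixel_data        = c(0x7FE0L, 0x0010L)
)

raw_to_string <- function(bytes) {
  trimws(rawToChar(bytes[bytes != as.raw(0)]))
}

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM") {
    stop(sprintf("not a DICOM part-10 file: %s", path), call. = FALSE)
  }
  pos <- 133L
  n <- length(raw)
  main_explicit <- TRUE   # updated from the transfer syntax UID (0002,0010)

  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) {
    as.numeric(raw[at]) + 256 * as.numeric(raw[at + 1L]) +
      65536 * as.numeric(raw[at + 2L]) + 16777216 * as.numeric(raw[at + 3L])
  }

  elems <- list()
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

  skip_undefined_sequence <- function(pos) {
    # advance past items until the (FFFE,E0DD) sequence delimiter
    repeat {
      if (pos + 7L > n) stop("truncated DICOM sequence", call. = FALSE)
      g <- u16(pos); e <- u16(pos + 2L); len <- u32(pos + 4L)
      pos <- pos + 8L
      if (g == 0xFFFEL && e == 0xE0DDL) return(pos)
      if (g == 0xFFFEL && e == 0xE000L && len == 4294967295) {
        repeat {  # undefined-length item: scan for (FFFE,E00D)
          gg <- u16(pos); ee <- u16(pos + 2L); ll <- u32(pos + 4L)
          pos <- pos + 8L
          if (gg == 0xFFFEL && ee == 0xE00DL) break
          pos <- pos + ll
        }
      } else {
        pos <- pos + len
      }
    }
  }

  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    use_explicit <- if (group == 0x0002L) TRUE else main_explicit
    if (use_explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- "UN"; len <- u32(pos + 4L); hdr <- 8L
    }
    body <- pos + hdr
    if (len == 4294967295) {          # undefined length: sequence
      pos <- skip_undefined_sequence(body)
      next
    }
    if (group == 0x0002L && element == 0x0010L) {
      ts <- raw_to_string(raw[body:(body + len - 1L)])
      if (ts == "1.2.840.10008.1.2") {
        main_explicit <- FALSE
      } else if (ts != "1.2.840.10008.1.2.1") {
        stop(sprintf("unsupported DICOM transfer syntax '%s' in %s", ts, path),
             call. = FALSE)
      }
    }
    for (nm in names(DICOM_TAGS)) {
      tg <- DICOM_TAGS[[nm]]
      if (group == tg[1] && element == tg[2] && len > 0) {
        elems[[nm]] <- list(bytes = raw[body:(body + len - 1L)], vr = vr)
        break
      }
    }
    pos <- body + len
  }

  txt <- function(key) {
    el <- elems[[key]]
    if (is.null(el)) return(NULL)
    raw_to_string(el$bytes)
  }
  num_vec <- function(key) {
    s <- txt(key)
    if (is.null(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  us <- function(key) {
    el <- elems[[key]]
    if (is.null(el)) return(NULL)
    as.integer(el$bytes[1]) + 256L * as.integer(el$bytes[2])
  }

  for (req in c("rows", "columns", "pixel_spacing", "position")) {
    if (is.null(elems[[req]])) {
      stop(sprintf(
        "DICOM file %s is missing required geometry tag '%s' (%04X,%04X)",
        path, req, DICOM_TAGS[[req]][1], DICOM_TAGS[[req]][2]), call. = FALSE)
    }
  }
  if (is.null(elems$pixel_data)) {
    stop(sprintf("DICOM file %s has no PixelData", path), call. = FALSE)
  }
  rows <- us("rows"); cols <- us("columns")
  bits <- us("bits_allocated")
  if (is.null(bits)) bits <- 16L
  if (bits != 16L) stop("only 16-bit DICOM pixel data is supported", call. = FALSE)
  signed <- identical(us("pixel_repr"), 1L)
  px <- readBin(elems$pixel_data$bytes, what = "integer", size = 2L,
                n = rows * cols, signed = signed, endian = "little")
  img <- matrix(px, nrow = rows, ncol = cols, byrow = TRUE)

  age <- txt("patient_age")
  age_y <- if (is.null(age)) NA_real_ else {
    suppressWarnings(as.numeric(gsub("[^0-9]", "", age)))
  }

  list(
    modality = txt("modality"),
    series_uid = txt("series_uid"),
    instance_number = suppressWarnings(as.integer(txt("instance_number"))),
    position = num_vec("position"),
    orientation = num_vec("orientation"),
    pixel_spacing = num_vec("pixel_spacing"),
    slice_thickness = suppressWarnings(as.numeric(txt("slice_thickness"))),
    rescale_intercept = if (is.null(txt("rescale_intercept"))) 0 else as.numeric(txt("rescale_intercept")),
    rescale_slope = if (is.null(txt("rescale_slope"))) 1 else as.numeric(txt("rescale_slope")),
    patient_age = age_y,
    image = img
  )
}
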