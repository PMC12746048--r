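# Minimal DICOM support: explicit VR little endian only, the handful of
# VRs needed for single-plane RT Dose and a small RT Plan subset.
# A dataset is a named list keyed "GGGG,EEEE" (upper-case hex); each element
# is list(vr = <2-char VR>, value = <vector / raw / list-of-datasets>).

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
UID_IMPLEMENTATION <- "2.25.424242.1"

dcm_el <- function(vr, value) list(vr = vr, value = value)

tag_parts <- function(tag) {
  strtoi(strsplit(tag, ",", fixed = TRUE)[[1]], 16L)
}

dcm_string_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                    "PN", "SH", "ST", "TM", "UI", "UC", "UR", "UT")
dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN") # 4-byte length form

raw_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
raw_uint32 <- function(x) {
  # writeBin has no unsigned 32-bit; values < 2^31 are what we emit
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

encode_value <- function(vr, value) {
  if (vr %in% dcm_string_vrs) {
    s <- if (is.numeric(value)) paste(format(value, digits = 12, trim = TRUE,
                                             scientific = FALSE),
                                      collapse = "\\")
         else paste(as.character(value), collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L)
      b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    b
  } else if (vr %in% c("US")) {
    raw_uint16(value)
  } else if (vr %in% c("UL")) {
    raw_uint32(value)
  } else if (vr %in% c("FL")) {
    writeBin(as.numeric(value), raw(), size = 4, endian = "little")
  } else if (vr %in% c("FD")) {
    writeBin(as.numeric(value), raw(), size = 8, endian = "little")
  } else if (vr %in% c("OB", "OW")) {
    stopifnot(is.raw(value))
    if (length(value) %% 2L == 1L) c(value, as.raw(0L)) else value
  } else if (vr == "SQ") {
    unlist(lapply(value, function(item) {
      body <- encode_dataset(item)
      c(raw_uint16(c(0xFFFE, 0xE000)), raw_uint32(length(body)), body)
    }))
  } else stop("unsupported VR for encoding: ", vr)
}

encode_element <- function(tag, el) {
  gp <- tag_parts(tag)
  body <- encode_value(el$vr, el$value)
  if (is.null(body)) body <- raw(0)
  head <- c(raw_uint16(gp), charToRaw(el$vr))
  if (el$vr %in% dcm_long_vrs) {
    c(head, as.raw(c(0L, 0L)), raw_uint32(length(body)), body)
  } else {
    c(head, raw_uint16(length(body)), body)
  }
}

encode_dataset <- function(ds) {
  ds <- ds[order(names(ds))]
  do.call(c, lapply(names(ds), function(tag) encode_element(tag, ds[[tag]])))
}

write_dicom_file <- function(ds, path, sop_class, sop_instance) {
  meta <- list(
    "0002,0001" = dcm_el("OB", as.raw(c(0L, 1L))),
    "0002,0002" = dcm_el("UI", sop_class),
    "0002,0003" = dcm_el("UI", sop_instance),
    "0002,0010" = dcm_el("UI", UID_EXPLICIT_VR_LE),
    "0002,0012" = dcm_el("UI", UID_IMPLEMENTATION))
  meta_body <- encode_dataset(meta)
  meta_len <- encode_element("0002,0000", dcm_el("UL", length(meta_body)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta_len, meta_body), con)
  writeBin(encode_dataset(ds), con)
  invisible(path)
}

# --- reading ---------------------------------------------------------------

dcm_cursor <- function(bytes) {
  e <- new.env(parent = emptyenv())
  e$b <- bytes
  e$pos <- 1L
  e
}

take <- function(cur, n) {
  if (n == 0L) return(raw(0))
  if (cur$pos + n - 1L > length(cur$b)) stop("DICOM parse: unexpected end of file")
  out <- cur$b[cur$pos:(cur$pos + n - 1L)]
  cur$pos <- cur$pos + n
  out
}

peek_uint16 <- function(cur, offset = 0L) {
  i <- cur$pos + offset
  as.integer(cur$b[i]) + 256L * as.integer(cur$b[i + 1L])
}

read_uint16 <- function(cur) {
  b <- take(cur, 2L); as.integer(b[1]) + 256L * as.integer(b[2])
}

read_uint32 <- function(cur) {
  b <- take(cur, 4L)
  sum(as.numeric(b) * c(1, 256, 65536, 16777216))
}

decode_value <- function(vr, bytes) {
  if (vr %in% dcm_string_vrs) {
    s <- rawToChar(bytes[bytes != as.raw(0L)])
    s <- sub("[ ]+$", "", s)
    parts <- strsplit(s, "\\", fixed = TRUE)[[1]]
    if (vr %in% c("DS", "IS")) as.numeric(parts) else parts
  } else if (vr == "US") {
    readBin(bytes, "integer", n = length(bytes) / 2L, size = 2,
            endian = "little", signed = FALSE)
  } else if (vr == "UL") {
    readBin(bytes, "integer", n = length(bytes) / 4L, size = 4,
            endian = "little")
  } else if (vr == "FL") {
    readBin(bytes, "numeric", n = length(bytes) / 4L, size = 4,
            endian = "little")
  } else if (vr == "FD") {
    readBin(bytes, "numeric", n = length(bytes) / 8L, size = 8,
            endian = "little")
  } else {
    bytes # OB/OW/UN kept raw
  }
}

read_element <- function(cur) {
  group <- read_uint16(cur)
  elem <- read_uint16(cur)
  tag <- sprintf("%04X,%04X", group, elem)
  if (group == 0xFFFE) { # delimitation items carry no VR
    len <- read_uint32(cur)
    return(list(tag = tag, vr = "  ", len = len))
  }
  vr <- rawToChar(take(cur, 2L))
  if (vr %in% dcm_long_vrs) {
    take(cur, 2L) # reserved
    len <- read_uint32(cur)
  } else {
    len <- read_uint16(cur)
  }
  list(tag = tag, vr = vr, len = len)
}

read_sq_items <- function(cur, len) {
  end <- if (len == 0xFFFFFFFF) NA_integer_ else cur$pos + len
  items <- list()
  repeat {
    if (!is.na(end) && cur$pos >= end) break
    hdr <- read_element(cur)
    if (hdr$tag == "FFFE,E0DD") break # sequence delimiter
    if (hdr$tag != "FFFE,E000") stop("DICOM parse: expected item tag, got ", hdr$tag)
    if (hdr$len == 0xFFFFFFFF) {
      items[[length(items) + 1L]] <- read_dataset(cur, NA_integer_, in_item = TRUE)
    } else {
      item_end <- cur$pos + hdr$len
      items[[length(items) + 1L]] <- read_dataset(cur, item_end)
    }
  }
  items
}

read_dataset <- function(cur, end = NA_integer_, in_item = FALSE) {
  ds <- list()
  repeat {
    if (!is.na(end) && cur$pos >= end) break
    if (is.na(end) && cur$pos > length(cur$b)) break
    if (is.na(end) && cur$pos + 7L > length(cur$b)) break
    hdr <- read_element(cur)
    if (hdr$tag == "FFFE,E00D") { if (in_item) break else next }
    if (hdr$vr == "SQ") {
      ds[[hdr$tag]] <- dcm_el("SQ", read_sq_items(cur, hdr$len))
    } else {
      bytes <- take(cur, hdr$len)
      ds[[hdr$tag]] <- dcm_el(hdr$vr, decode_value(hdr$vr, bytes))
    }
  }
  ds
}

read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140L) stop("not a DICOM file (too short): ", path)
  if (rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  cur <- dcm_cursor(bytes)
  cur$pos <- 133L
  # file meta group (always explicit VR LE)
  hdr <- read_element(cur)
  if (hdr$tag != "0002,0000") stop("DICOM parse: file meta group length missing")
  meta_len <- decode_value("UL", take(cur, hdr$len))
  meta_end <- cur$pos + meta_len
  meta <- read_dataset(cur, meta_end)
  ts <- meta[["0002,0010"]]$value
  if (!identical(ts, UID_EXPLICIT_VR_LE))
    stop("unsupported DICOM transfer syntax: ", ts,
         " (only explicit VR little endian is supported)")
  ds <- read_dataset(cur)
  attr(ds, "meta") <- meta
  ds
}

dcm_get <- function(ds, tag, required = TRUE) {
  el <- ds[[tag]]
  if (is.null(el)) {
    if (required) stop("DICOM dataset is missing required attribute (", tag, ")")
    return(NULL)
  }
  el$value
}

# deterministic pseudo-UID from content, so identical runs write identical files
content_uid <- function(...) {
  x <- unlist(lapply(list(...), function(v) as.numeric(v)))
  h <- 0
  for (v in x) h <- (h * 31 + abs(v) * 1e6) %% 1e12
  sprintf("%s.%.0f", UID_IMPLEMENTATION, h)
}
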