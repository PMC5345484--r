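# Minimal DICOM (Explicit VR Little Endian) serializer/parser.
#
# Scope: exactly what an RTPLAN needs -- string VRs, DS/IS numeric strings,
# and nested SQ sequences with defined or undefined lengths.  No other
# transfer syntax is supported; files written by dcm_write() are standard
# part-10 objects readable by any DICOM toolkit.

DCM_LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_RTPLAN_STORAGE <- "1.2.840.10008.5.1.4.1.1.481.5"

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) {
  # R has no native u32 write for values >= 2^31; lengths here are far smaller
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

dcm_read_u16 <- function(bytes, pos) {
  sum(as.integer(bytes[pos:(pos + 1L)]) * c(1, 256))
}
dcm_read_u32 <- function(bytes, pos) {
  sum(as.numeric(bytes[pos:(pos + 3L)]) * c(1, 256, 65536, 16777216))
}

# one serialized element; payload must already have even length
dcm_element <- function(group, element, vr, payload) {
  if (length(payload) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    payload <- c(payload, pad)
  }
  head <- c(dcm_u16(group), dcm_u16(element), charToRaw(vr))
  if (vr %in% DCM_LONG_VRS) {
    c(head, as.raw(c(0L, 0L)), dcm_u32(length(payload)), payload)
  } else {
    if (length(payload) > 65534) abort("DICOM element payload too long for short VR")
    c(head, dcm_u16(length(payload)), payload)
  }
}

dcm_str <- function(group, element, vr, values) {
  dcm_element(group, element, vr, charToRaw(paste(values, collapse = "\\")))
}

# DS: decimal string, <= 16 chars per value; 10 significant digits round-trips
# leaf positions to ~5e-11 relative
dcm_ds <- function(group, element, values) {
  dcm_str(group, element, "DS", sprintf("%.10g", as.numeric(values)))
}
dcm_is <- function(group, element, values) {
  dcm_str(group, element, "IS", sprintf("%d", as.integer(values)))
}

# sequence with defined lengths; items is a list of raw vectors
dcm_sq <- function(group, element, items) {
  payload <- raw(0)
  for (it in items) {
    payload <- c(payload, dcm_u16(0xFFFE), dcm_u16(0xE000),
                 dcm_u32(length(it)), it)
  }
  dcm_element(group, element, "SQ", payload)
}

# deterministic pseudo-UIDs under a private-ish root; DICOM only requires
# uniqueness within the files a run writes
dcm_uid <- function(suffix) {
  paste0("1.2.826.0.1.3680043.9.7435.", suffix)
}

# file = 128-byte preamble + "DICM" + group-0002 meta + dataset
dcm_write_file <- function(path, sop_class_uid, sop_instance_uid, dataset) {
  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_str(0x0002, 0x0002, "UI", sop_class_uid),
    dcm_str(0x0002, 0x0003, "UI", sop_instance_uid),
    dcm_str(0x0002, 0x0010, "UI", UID_EXPLICIT_LE)
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_u32(length(meta_body))),
            meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, dataset), con)
  invisible(path)
}

# ---- parsing ---------------------------------------------------------------

dcm_tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

dcm_decode_value <- function(vr, payload) {
  if (vr %in% c("DS", "IS")) {
    s <- strsplit(rawToChar(payload), "\\", fixed = TRUE)[[1]]
    s <- trimws(s)
    return(as.numeric(s[nzchar(s)]))
  }
  if (vr %in% c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH", "ST",
                "TM", "UC", "UI", "UR", "UT")) {
    s <- rawToChar(payload[payload != as.raw(0L)])
    parts <- strsplit(s, "\\", fixed = TRUE)[[1]]
    return(trimws(parts))
  }
  if (vr == "UL") return(dcm_read_u32(payload, 1L))
  if (vr == "US") return(dcm_read_u16(payload, 1L))
  payload
}

# parse [pos, end] of an explicit-VR-LE byte stream into a named list
# ("GGGG,EEEE" -> decoded value; SQ -> list of item lists)
dcm_parse_dataset <- function(bytes, pos, end) {
  out <- list()
  while (pos <= end) {
    if (pos + 7L > length(bytes) + 1L) abort("truncated DICOM element")
    group <- dcm_read_u16(bytes, pos)
    element <- dcm_read_u16(bytes, pos + 2L)
    if (group == 0xFFFE) {  # delimiter leaked to caller's level
      break
    }
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      abort("unsupported transfer syntax: expected explicit VR little endian")
    }
    if (vr %in% DCM_LONG_VRS) {
      len <- dcm_read_u32(bytes, pos + 8L)
      pos <- pos + 12L
    } else {
      len <- dcm_read_u16(bytes, pos + 6L)
      pos <- pos + 8L
    }
    key <- dcm_tag_key(group, element)
    if (vr == "SQ") {
      parsed <- dcm_parse_sequence(bytes, pos, len)
      out[[key]] <- parsed$items
      pos <- parsed$pos
    } else {
      if (len == 4294967295) abort("undefined length only supported for SQ")
      payload <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
      out[[key]] <- dcm_decode_value(vr, payload)
      pos <- pos + len
    }
  }
  list(data = out, pos = pos)
}

dcm_parse_sequence <- function(bytes, pos, len) {
  undefined <- len == 4294967295
  end <- if (undefined) length(bytes) else pos + len - 1L
  items <- list()
  while (pos <= end) {
    group <- dcm_read_u16(bytes, pos)
    element <- dcm_read_u16(bytes, pos + 2L)
    ilen <- dcm_read_u32(bytes, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && element == 0xE0DD) break      # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000)) abort("malformed DICOM sequence item")
    if (ilen == 4294967295) {                            # undefined-length item
      parsed <- dcm_parse_dataset(bytes, pos, end)
      items[[length(items) + 1L]] <- parsed$data
      pos <- parsed$pos
      # expect item delimiter FFFE,E00D
      if (dcm_read_u16(bytes, pos) == 0xFFFE &&
          dcm_read_u16(bytes, pos + 2L) == 0xE00D) pos <- pos + 8L
    } else {
      parsed <- dcm_parse_dataset(bytes, pos, pos + ilen - 1L)
      items[[length(items) + 1L]] <- parsed$data
      pos <- pos + ilen
    }
    if (!undefined && pos > end) break
  }
  list(items = items, pos = pos)
}

# read a part-10 file -> list(meta = ..., data = ...)
dcm_read_file <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    abort("not a DICOM file (missing DICM magic): ", path)
  }
  pos <- 133L
  # group-0002 meta is always explicit LE; read its declared length
  if (dcm_read_u16(bytes, pos) != 0x0002) abort("missing DICOM file meta group")
  meta_len_vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
  stopifnot(meta_len_vr == "UL")
  meta_len <- dcm_read_u32(bytes, pos + 8L)
  pos <- pos + 12L
  meta <- dcm_parse_dataset(bytes, pos, pos + meta_len - 1L)
  ts <- meta$data[["0002,0010"]]
  if (is.null(ts) || ts != UID_EXPLICIT_LE) {
    abort("unsupported transfer syntax (only explicit VR little endian): ",
          if (is.null(ts)) "<missing>" else ts)
  }
  body <- dcm_parse_dataset(bytes, meta$pos, length(bytes))
  list(meta = meta$data, data = body$data)
}
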