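# Programmatic DICOM fixture writer (explicit VR little endian, defined
# lengths). Only what the readers consume; fixtures are written to
# tempfiles at test time.

.u16raw <- function(v) writeBin(as.integer(v), raw(), size = 2,
                                endian = "little")
.u32raw <- function(v) writeBin(as.integer(v), raw(), size = 4,
                                endian = "little")

.dcm_pad <- function(s) {
  b <- charToRaw(s)
  if (length(b) %% 2 == 1) b <- c(b, charToRaw(" "))
  b
}

dcm_element <- function(group, elem, vr, bytes) {
  long <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  head <- c(.u16raw(group), .u16raw(elem), charToRaw(vr))
  if (long) {
    c(head, as.raw(c(0, 0)), .u32raw(length(bytes)), bytes)
  } else {
    c(head, .u16raw(length(bytes)), bytes)
  }
}

dcm_str <- function(group, elem, vr, value) {
  dcm_element(group, elem, vr, .dcm_pad(paste(value, collapse = "\\")))
}

dcm_item <- function(content) {
  c(.u16raw(0xFFFE), .u16raw(0xE000), .u32raw(length(content)), content)
}

dcm_file <- function(path, body) {
  meta <- dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), path)
  path
}

# RT Dose fixture: values (3D array, pixel counts), scaling (Gy/pixel),
# spacing (x, y, z mm), ipp (origin mm). Frame offsets default uniform.
write_rtdose_fixture <- function(path, values, scaling, spacing, ipp,
                                 frameOffsets = NULL) {
  d <- dim(values)
  if (is.null(frameOffsets)) frameOffsets <- (seq_len(d[3]) - 1) * spacing[3]
  # pixel order: column fastest, then row, then frame = as.vector of [x,y,z]
  px <- writeBin(as.integer(as.vector(values)), raw(), size = 2,
                 endian = "little")
  body <- c(
    dcm_str(0x0020, 0x0032, "DS", format(ipp, trim = TRUE)),
    dcm_element(0x0028, 0x0008, "IS", .dcm_pad(as.character(d[3]))),
    dcm_element(0x0028, 0x0010, "US", .u16raw(d[2])),      # rows = y
    dcm_element(0x0028, 0x0011, "US", .u16raw(d[1])),      # cols = x
    dcm_str(0x0028, 0x0030, "DS", format(c(spacing[2], spacing[1]),
                                         trim = TRUE)),
    dcm_element(0x0028, 0x0100, "US", .u16raw(16)),
    dcm_str(0x3004, 0x000C, "DS", format(frameOffsets, trim = TRUE)),
    dcm_str(0x3004, 0x000E, "DS", format(scaling, scientific = FALSE)),
    dcm_element(0x7FE0, 0x0010, "OW", px)
  )
  dcm_file(path, body)
}

# RT Structure Set fixture: structures = named list; each element a list of
# contours, each contour an n x 3 matrix of world points (closed planar).
write_rtstruct_fixture <- function(path, structures) {
  roi_items <- raw(0)
  con_items <- raw(0)
  for (i in seq_along(structures)) {
    nm <- names(structures)[i]
    roi_items <- c(roi_items, dcm_item(c(
      dcm_element(0x3006, 0x0022, "IS", .dcm_pad(as.character(i))),
      dcm_str(0x3006, 0x0026, "LO", nm))))
    contours <- raw(0)
    for (pts in structures[[i]]) {
      contours <- c(contours, dcm_item(c(
        dcm_str(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_element(0x3006, 0x0046, "IS", .dcm_pad(as.character(nrow(pts)))),
        dcm_str(0x3006, 0x0050, "DS",
                format(as.vector(t(pts)), trim = TRUE)))))
    }
    con_items <- c(con_items, dcm_item(c(
      dcm_element(0x3006, 0x0040, "SQ", contours),
      dcm_element(0x3006, 0x0084, "IS", .dcm_pad(as.character(i))))))
  }
  body <- c(dcm_element(0x3006, 0x0020, "SQ", roi_items),
            dcm_element(0x3006, 0x0039, "SQ", con_items))
  dcm_file(path, body)
}
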