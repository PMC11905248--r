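# Minimal DICOM reading for RT Dose and RT Structure Set objects.
# Scope: explicit-VR little-endian transfer syntax, uncompressed pixel data,
# axis-aligned (identity orientation) grids — the subset these RT QA
# workflows exchange. Elements are collected into a flat environment keyed
# by "GGGG,EEEE"; sequences (SQ) recurse into lists of item datasets.

.vr_long <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN", "UC", "UR")
.vr_string <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT", "PN",
                "SH", "ST", "TM", "UI", "UT", "UC", "UR")

#' @noRd
.u16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}
#' @noRd
.u32 <- function(raw, at) {
  as.numeric(raw[at]) + 256 * as.numeric(raw[at + 1L]) +
    65536 * as.numeric(raw[at + 2L]) + 16777216 * as.numeric(raw[at + 3L])
}

# Parse one dataset starting at `at` (1-based), stopping at `end` or at an
# item/sequence delimiter. Returns list(elements = named list, next_at).
#' @noRd
.dcm_parse <- function(raw, at, end) {
  out <- list()
  while (at + 7 <= end + 1 && at <= length(raw) - 7) {
    group <- .u16(raw, at); elem <- .u16(raw, at + 2L)
    tag <- sprintf("%04X,%04X", group, elem)
    if (group == 0xFFFE) {                       # delimitation items
      len <- .u32(raw, at + 4L)
      at <- at + 8L
      if (elem %in% c(0xE00D, 0xE0DD)) return(list(elements = out, next_at = at))
      stop("unexpected item tag outside a sequence at offset ", at)
    }
    vr <- rawToChar(raw[(at + 4L):(at + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("not an explicit-VR little-endian DICOM stream (tag ", tag, ")")
    if (vr %in% .vr_long) {
      len <- .u32(raw, at + 8L)
      at <- at + 12L
    } else {
      len <- .u16(raw, at + 6L)
      at <- at + 8L
    }
    if (vr == "SQ") {
      items <- list()
      sq_end <- if (len == 4294967295) length(raw) else at + len - 1L
      while (at + 7 <= sq_end + 1) {
        ig <- .u16(raw, at); ie <- .u16(raw, at + 2L)
        ilen <- .u32(raw, at + 4L)
        at <- at + 8L
        if (ig == 0xFFFE && ie == 0xE0DD) break       # sequence delimiter
        if (!(ig == 0xFFFE && ie == 0xE000))
          stop("malformed sequence ", tag, ": expected an item tag")
        item_end <- if (ilen == 4294967295) length(raw) else at + ilen - 1L
        parsed <- .dcm_parse(raw, at, item_end)
        items[[length(items) + 1L]] <- parsed$elements
        at <- parsed$next_at
        if (len != 4294967295 && at > sq_end) break
      }
      out[[tag]] <- items
    } else if (len > 0) {
      bytes <- raw[at:(at + len - 1L)]
      at <- at + len
      out[[tag]] <-
        if (vr %in% .vr_string) {
          trimws(rawToChar(bytes[bytes != as.raw(0)]))
        } else if (vr == "US") {
          readBin(bytes, "integer", n = len / 2, size = 2,
                  signed = FALSE, endian = "little")
        } else if (vr == "SS") {
          readBin(bytes, "integer", n = len / 2, size = 2,
                  signed = TRUE, endian = "little")
        } else if (vr %in% c("UL", "SL")) {
          readBin(bytes, "integer", n = len / 4, size = 4, endian = "little")
        } else if (vr == "FL") {
          readBin(bytes, "double", n = len / 4, size = 4, endian = "little")
        } else if (vr == "FD") {
          readBin(bytes, "double", n = len / 8, size = 8, endian = "little")
        } else {
          bytes                                   # OB/OW/UN: keep raw
        }
    } else {
      out[[tag]] <- character(0)
    }
  }
  list(elements = out, next_at = at)
}

#' @noRd
.dcm_read <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  .dcm_parse(raw, 133L, length(raw))$elements
}

#' @noRd
.dcm_num <- function(el, tag, what) {
  v <- el[[tag]]
  if (is.null(v)) stop("DICOM format error: missing ", what, " (", tag, ")")
  if (is.character(v)) as.numeric(strsplit(v, "\\\\")[[1]]) else as.numeric(v)
}

#' Read a DICOM RT Dose object
#'
#' Pixel values are scaled to Gy by the Dose Grid Scaling attribute; the
#' grid is assembled from Image Position (Patient), Pixel Spacing and the
#' Grid Frame Offset Vector (which must be uniform).
#'
#' @param path a DICOM RT Dose file (explicit VR little endian).
#' @return an [ImageVolume-class] in Gy.
#' @export
readRTDose <- function(path) {
  el <- .dcm_read(path)
  rows <- .dcm_num(el, "0028,0010", "Rows")
  cols <- .dcm_num(el, "0028,0011", "Columns")
  frames <- .dcm_num(el, "0028,0008", "Number of Frames")
  scaling <- el[["3004,000E"]]
  if (is.null(scaling))
    stop("DICOM format error: missing Dose Grid Scaling (3004,000E)")
  scaling <- as.numeric(scaling)
  ps <- .dcm_num(el, "0028,0030", "Pixel Spacing")        # row, then column
  ipp <- .dcm_num(el, "0020,0032", "Image Position (Patient)")
  gfov <- .dcm_num(el, "3004,000C", "Grid Frame Offset Vector")
  if (length(gfov) != frames)
    stop("DICOM format error: Grid Frame Offset Vector length != frames")
  dz <- diff(gfov)
  if (frames > 1 && (max(dz) - min(dz)) > 1e-6)
    stop("DICOM format error: nonuniform Grid Frame Offset Vector")
  dz <- if (frames > 1) dz[1] else 1
  bits <- .dcm_num(el, "0028,0100", "Bits Allocated")
  px <- el[["7FE0,0010"]]
  if (is.null(px)) stop("DICOM format error: missing Pixel Data")
  vals <- readBin(px, "integer", n = rows * cols * frames,
                  size = bits / 8, signed = FALSE, endian = "little")
  # row-major within frame: fastest index is the column (x)
  arr <- array(as.numeric(vals) * scaling, c(cols, rows, frames))
  imageVolume(arr, gridDescriptor(c(cols, rows, frames),
                                  c(ps[2], ps[1], dz), ipp))
}

# Even-odd (crossing-number) point-in-polygon test, vectorized over points.
#' @noRd
.point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read a DICOM RT Structure Set and rasterize it onto a grid
#'
#' Each planar contour polygon is rasterized with an even-odd fill and a
#' voxel-center inclusion test onto the slice of `targetGrid` nearest to the
#' contour plane. Contours lying outside the grid are clipped with a
#' warning.
#'
#' @param path a DICOM RT Structure Set file (explicit VR little endian).
#' @param targetGrid the [GridDescriptor-class] to rasterize onto.
#' @return a [StructureSet-class].
#' @export
readRTStruct <- function(path, targetGrid) {
  el <- .dcm_read(path)
  rois <- el[["3006,0020"]]                        # Structure Set ROI Sequence
  if (is.null(rois)) stop("DICOM format error: missing StructureSetROISequence")
  roi_names <- character(0)
  for (item in rois) {
    num <- as.character(as.integer(.dcm_num(item, "3006,0022", "ROI Number")))
    roi_names[num] <- if (is.null(item[["3006,0026"]])) paste0("ROI_", num)
                      else item[["3006,0026"]]
  }
  contours <- el[["3006,0039"]]                    # ROI Contour Sequence
  if (is.null(contours)) stop("DICOM format error: missing ROIContourSequence")

  g <- targetGrid
  masks <- list()
  for (item in contours) {
    num <- as.character(as.integer(.dcm_num(item, "3006,0084",
                                            "Referenced ROI Number")))
    nm <- roi_names[num]
    mask <- array(FALSE, g@shape)
    for (ct in item[["3006,0040"]] %||% list()) {
      cd <- .dcm_num(ct, "3006,0050", "Contour Data")
      pts <- matrix(cd, ncol = 3, byrow = TRUE)
      k <- round((pts[1, 3] - g@origin[3]) / g@spacing[3])
      if (k < 0 || k >= g@shape[3] ||
          abs(pts[1, 3] - (g@origin[3] + k * g@spacing[3])) >
            g@spacing[3] / 2 + 1e-6) {
        warning("contour slice at z = ", pts[1, 3], " mm for '", nm,
                "' lies outside the grid; clipped")
        next
      }
      xs <- g@origin[1] + (seq_len(g@shape[1]) - 1) * g@spacing[1]
      ys <- g@origin[2] + (seq_len(g@shape[2]) - 1) * g@spacing[2]
      xi <- which(xs >= min(pts[, 1]) - g@spacing[1] &
                  xs <= max(pts[, 1]) + g@spacing[1])
      yi <- which(ys >= min(pts[, 2]) - g@spacing[2] &
                  ys <= max(pts[, 2]) + g@spacing[2])
      if (!length(xi) || !length(yi)) next
      gx <- rep(xs[xi], times = length(yi))
      gy <- rep(ys[yi], each = length(xi))
      inside <- .point_in_polygon(gx, gy, pts[, 1], pts[, 2])
      slab <- mask[xi, yi, k + 1L]
      mask[xi, yi, k + 1L] <- xor(slab, array(inside, c(length(xi), length(yi))))
    }
    masks[[nm]] <- mask
  }
  structureSet(masks, g)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
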