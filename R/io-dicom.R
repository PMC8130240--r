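# Minimal DICOM reader/writer (explicit VR little endian) covering the three
# radiotherapy IODs this tool consumes: CT image series, RTDOSE and RTSTRUCT.
# Only the attributes needed to reconstruct geometry, values and contours are
# handled; vendor private tags are ignored. The writer exists so that tests
# and examples can build well-formed files programmatically.

DCM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DCM_UID_ROOT <- "1.2.826.0.1.3680043.9590"

u16r <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32r <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_pad <- function(s, pad = " ") {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, charToRaw(pad))
  r
}

# UIDs are null-padded to even length
dcm_pad_ui <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, as.raw(0))
  r
}

# drop trailing null/space padding bytes before decoding
raw_to_trimmed_char <- function(payload) {
  while (length(payload) && payload[length(payload)] %in% as.raw(c(0, 32)))
    payload <- payload[-length(payload)]
  rawToChar(payload)
}

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_elem <- function(group, elem, vr, payload) {
  stopifnot(is.raw(payload))
  hdr <- c(u16r(group), u16r(elem), charToRaw(vr))
  if (vr %in% .long_vrs) {
    c(hdr, raw(2), u32r(length(payload)), payload)
  } else {
    if (length(payload) > 65534) stop("value too long for short VR")
    c(hdr, u16r(length(payload)), payload)
  }
}

enc_str <- function(vals, pad = " ") dcm_pad(paste(vals, collapse = "\\"), pad)
enc_ds <- function(vals) enc_str(sprintf("%.10g", vals))
enc_is <- function(vals) enc_str(sprintf("%d", as.integer(vals)))
enc_us <- function(vals) writeBin(as.integer(vals), raw(), size = 2, endian = "little")

dcm_item <- function(payload) c(u16r(0xFFFE), u16r(0xE000), u32r(length(payload)), payload)

dcm_file <- function(dataset, sop_class, sop_instance) {
  meta <- c(
    dcm_elem(0x0002, 0x0002, "UI", dcm_pad_ui(sop_class)),
    dcm_elem(0x0002, 0x0003, "UI", dcm_pad_ui(sop_instance)),
    dcm_elem(0x0002, 0x0010, "UI", dcm_pad_ui(DCM_TS_EXPLICIT_LE))
  )
  c(raw(128), charToRaw("DICM"),
    dcm_elem(0x0002, 0x0000, "UL", u32r(length(meta))),
    meta, dataset)
}

# ---- parser ---------------------------------------------------------------

rd_u16 <- function(buf, at) {
  as.integer(buf[at]) + 256L * as.integer(buf[at + 1L])
}
rd_u32 <- function(buf, at) {
  as.numeric(as.integer(buf[at])) + 256 * as.integer(buf[at + 1L]) +
    65536 * as.integer(buf[at + 2L]) + 16777216 * as.integer(buf[at + 3L])
}

parse_value <- function(vr, payload) {
  if (vr %in% c("DS", "IS")) {
    s <- raw_to_trimmed_char(payload)
    if (!nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, "\\\\")[[1]])
  } else if (vr %in% c("UI", "CS", "LO", "SH", "PN", "DA", "TM", "ST", "LT", "AE")) {
    raw_to_trimmed_char(payload)
  } else if (vr == "US") {
    readBin(payload, "integer", n = length(payload) / 2, size = 2,
            signed = FALSE, endian = "little")
  } else if (vr == "UL") {
    readBin(payload, "integer", n = length(payload) / 4, size = 4,
            endian = "little")
  } else if (vr %in% c("FD")) {
    readBin(payload, "double", n = length(payload) / 8, size = 8,
            endian = "little")
  } else {
    payload  # OW/OB and anything else stay raw
  }
}

# parse one dataset spanning buf[from..to]; returns named list keyed "GGGG,EEEE"
parse_dataset <- function(buf, from, to) {
  out <- list()
  pos <- from
  while (pos + 7 <= to + 1 && pos <= to) {
    group <- rd_u16(buf, pos); elem <- rd_u16(buf, pos + 2L)
    if (group == 0xFFFE) {  # item delimiters inside undefined-length parsing
      len <- rd_u32(buf, pos + 4L)
      pos <- pos + 8L
      if (elem == 0xE00D || elem == 0xE0DD) next
      stop("unexpected item tag in dataset")
    }
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("only explicit VR little endian DICOM is supported")
    if (vr %in% .long_vrs) {
      len <- rd_u32(buf, pos + 8L)
      body <- pos + 12L
    } else {
      len <- rd_u16(buf, pos + 6L)
      body <- pos + 8L
    }
    key <- sprintf("%04X,%04X", group, elem)
    if (vr == "SQ") {
      if (len == 4294967295) {  # undefined length: scan to sequence delimiter
        items <- list(); p <- body
        repeat {
          g <- rd_u16(buf, p); e <- rd_u16(buf, p + 2L); l <- rd_u32(buf, p + 4L)
          if (g == 0xFFFE && e == 0xE0DD) { p <- p + 8L; break }
          if (!(g == 0xFFFE && e == 0xE000)) stop("malformed sequence")
          if (l == 4294967295) stop("nested undefined-length items unsupported")
          items[[length(items) + 1L]] <- parse_dataset(buf, p + 8L, p + 7L + l)
          p <- p + 8L + l
        }
        out[[key]] <- list(vr = vr, value = items)
        pos <- p
      } else {
        items <- list(); p <- body; end <- body + len - 1L
        while (p + 7 <= end + 1 && p <= end) {
          g <- rd_u16(buf, p); e <- rd_u16(buf, p + 2L); l <- rd_u32(buf, p + 4L)
          if (!(g == 0xFFFE && e == 0xE000)) stop("malformed sequence item")
          items[[length(items) + 1L]] <- parse_dataset(buf, p + 8L, p + 7L + l)
          p <- p + 8L + l
        }
        out[[key]] <- list(vr = vr, value = items)
        pos <- body + len
      }
    } else {
      payload <- if (len > 0) buf[body:(body + len - 1L)] else raw(0)
      out[[key]] <- list(vr = vr, value = parse_value(vr, payload))
      pos <- body + len
    }
  }
  out
}

read_dicom_file <- function(path) {
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  ds <- parse_dataset(buf, 133L, length(buf))
  ts <- ds[["0002,0010"]]$value
  if (!is.null(ts) && ts != DCM_TS_EXPLICIT_LE)
    stop("unsupported transfer syntax: ", ts)
  ds
}

dcm_get <- function(ds, key, default = NULL) {
  v <- ds[[key]]
  if (is.null(v)) return(default)
  v$value
}

dcm_require <- function(ds, key, what) {
  v <- ds[[key]]
  if (is.null(v)) stop("missing required DICOM attribute ", what, " (", key, ")")
  v$value
}

# ---- CT series ------------------------------------------------------------

#' Write an image volume as a DICOM CT series
#'
#' One explicit-VR little-endian file per axial slice, with HU encoded
#' through the usual rescale slope/intercept (16-bit signed stored values).
#'
#' @param vol an [image_volume()].
#' @param dir output directory (created if needed).
#' @param slope,intercept rescale relation `HU = slope * stored + intercept`.
#' @param series_uid series instance UID; a fixed package root UID by default.
#' @return Invisibly, the written file paths.
#' @export
write_ct_series <- function(vol, dir, slope = 1, intercept = -1024,
                            series_uid = paste0(DCM_UID_ROOT, ".1.1")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(vol$data); nz <- d[1]; ny <- d[2]; nx <- d[3]
  sop_class <- "1.2.840.10008.5.1.4.1.1.2"
  files <- character(nz)
  for (i in seq_len(nz)) {
    stored <- round((vol$data[i, , ] - intercept) / slope)
    if (any(stored < -32768 | stored > 32767))
      stop("stored values out of 16-bit range; adjust slope/intercept")
    # pixel data is row-major (rows = y, columns = x)
    pix <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
    sop_uid <- paste0(series_uid, ".", i)
    zpos <- vol$origin[1] + (i - 1) * vol$spacing[1]
    dsl <- c(
      dcm_elem(0x0008, 0x0016, "UI", dcm_pad_ui(sop_class)),
      dcm_elem(0x0008, 0x0018, "UI", dcm_pad_ui(sop_uid)),
      dcm_elem(0x0008, 0x0060, "CS", enc_str("CT")),
      dcm_elem(0x0020, 0x000E, "UI", dcm_pad_ui(series_uid)),
      dcm_elem(0x0020, 0x0013, "IS", enc_is(i)),
      dcm_elem(0x0020, 0x0032, "DS", enc_ds(c(vol$origin[3], vol$origin[2], zpos))),
      dcm_elem(0x0020, 0x0037, "DS", enc_ds(c(1, 0, 0, 0, 1, 0))),
      dcm_elem(0x0028, 0x0010, "US", enc_us(ny)),
      dcm_elem(0x0028, 0x0011, "US", enc_us(nx)),
      dcm_elem(0x0028, 0x0030, "DS", enc_ds(c(vol$spacing[2], vol$spacing[3]))),
      dcm_elem(0x0028, 0x0100, "US", enc_us(16)),
      dcm_elem(0x0028, 0x0101, "US", enc_us(16)),
      dcm_elem(0x0028, 0x0103, "US", enc_us(1)),
      dcm_elem(0x0028, 0x1052, "DS", enc_ds(intercept)),
      dcm_elem(0x0028, 0x1053, "DS", enc_ds(slope)),
      dcm_elem(0x7FE0, 0x0010, "OW", pix)
    )
    files[i] <- file.path(dir, sprintf("ct_%04d.dcm", i))
    writeBin(dcm_file(dsl, sop_class, sop_uid), files[i])
  }
  invisible(files)
}

#' Read a DICOM CT series into an image volume
#'
#' Slices are sorted by their position along the slice axis regardless of
#' file order, the rescale slope/intercept is applied so values are HU, and
#' spacing is taken from PixelSpacing plus the inter-slice gap.
#'
#' @param dir directory holding exactly one CT series.
#' @param spacing_tol_mm maximum allowed deviation of any slice gap from the
#'   median gap, in mm.
#' @return An [image_volume()].
#' @export
read_ct_series <- function(dir, spacing_tol_mm = 0.01) {
  files <- list.files(dir, full.names = TRUE, pattern = "\\.dcm$")
  if (!length(files)) files <- list.files(dir, full.names = TRUE)
  if (!length(files)) stop("no files found in ", dir)
  slices <- lapply(files, read_dicom_file)
  uids <- vapply(slices, function(s) dcm_require(s, "0020,000E", "SeriesInstanceUID"), "")
  if (length(unique(uids)) != 1L)
    stop("directory contains mixed series UIDs: ", paste(unique(uids), collapse = ", "))
  zs <- vapply(slices, function(s) dcm_require(s, "0020,0032", "ImagePositionPatient")[3], 0)
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  nz <- length(slices)
  if (nz < 2L) stop("need at least 2 slices")
  gaps <- diff(zs)
  dz <- stats::median(gaps)
  bad <- which(abs(gaps - dz) > spacing_tol_mm)
  if (length(bad))
    stop(sprintf(
      "non-uniform slice spacing: gap of %.4f mm between slices %d and %d (expected %.4f mm)",
      gaps[bad[1]], bad[1], bad[1] + 1L, dz))
  s1 <- slices[[1]]
  ny <- dcm_require(s1, "0028,0010", "Rows")
  nx <- dcm_require(s1, "0028,0011", "Columns")
  ps <- dcm_require(s1, "0028,0030", "PixelSpacing")  # (row = y, col = x)
  ipp <- dcm_require(s1, "0020,0032", "ImagePositionPatient")  # (x, y, z)
  data <- array(0, c(nz, ny, nx))
  for (i in seq_len(nz)) {
    s <- slices[[i]]
    slope <- dcm_get(s, "0028,1053", 1)
    inter <- dcm_get(s, "0028,1052", 0)
    pix <- dcm_require(s, "7FE0,0010", "PixelData")
    signed <- isTRUE(dcm_get(s, "0028,0103", 1L)[1] == 1L)
    stored <- readBin(pix, "integer", n = ny * nx, size = 2,
                      signed = signed, endian = "little")
    data[i, , ] <- t(matrix(stored, nrow = nx)) * slope + inter
  }
  image_volume(data, spacing = c(dz, ps[1], ps[2]),
               origin = c(zs[1], ipp[2], ipp[1]))
}

# ---- RTDOSE ---------------------------------------------------------------

#' Write a dose grid as a DICOM RTDOSE object
#'
#' 32-bit unsigned stored values with a DoseGridScaling chosen from the
#' grid maximum (unless given).
#'
#' @param dose a [dose_grid()].
#' @param file output path.
#' @param scaling Gy per stored unit; default `1e-6`.
#' @return Invisibly, `file`.
#' @export
write_rtdose <- function(dose, file, scaling = 1e-6) {
  d <- dim(dose$data); nz <- d[1]; ny <- d[2]; nx <- d[3]
  stored <- round(dose$data / scaling)
  if (any(stored > 2^31 - 1)) stop("dose exceeds 32-bit range at this scaling")
  sop_class <- "1.2.840.10008.5.1.4.1.1.481.2"
  sop_uid <- paste0(DCM_UID_ROOT, ".2.1")
  pix <- raw(0)
  frames <- lapply(seq_len(nz), function(i) as.integer(t(stored[i, , ])))
  pix <- writeBin(unlist(frames), raw(), size = 4, endian = "little")
  dsl <- c(
    dcm_elem(0x0008, 0x0016, "UI", dcm_pad_ui(sop_class)),
    dcm_elem(0x0008, 0x0018, "UI", dcm_pad_ui(sop_uid)),
    dcm_elem(0x0008, 0x0060, "CS", enc_str("RTDOSE")),
    dcm_elem(0x0020, 0x0032, "DS", enc_ds(c(dose$origin[3], dose$origin[2], dose$origin[1]))),
    dcm_elem(0x0020, 0x0037, "DS", enc_ds(c(1, 0, 0, 0, 1, 0))),
    dcm_elem(0x0028, 0x0008, "IS", enc_is(nz)),
    dcm_elem(0x0028, 0x0010, "US", enc_us(ny)),
    dcm_elem(0x0028, 0x0011, "US", enc_us(nx)),
    dcm_elem(0x0028, 0x0030, "DS", enc_ds(c(dose$spacing[2], dose$spacing[3]))),
    dcm_elem(0x0028, 0x0100, "US", enc_us(32)),
    dcm_elem(0x0028, 0x0103, "US", enc_us(0)),
    dcm_elem(0x3004, 0x000C, "DS", enc_ds((seq_len(nz) - 1) * dose$spacing[1])),
    dcm_elem(0x3004, 0x000E, "DS", enc_ds(scaling)),
    dcm_elem(0x7FE0, 0x0010, "OW", pix)
  )
  writeBin(dcm_file(dsl, sop_class, sop_uid), file)
  invisible(file)
}

#' Read a DICOM RTDOSE object
#'
#' Stored integers are multiplied by DoseGridScaling to give Gy; the grid
#' keeps its own geometry (which may differ from the CT grid).
#'
#' @param file an RTDOSE file.
#' @return A [dose_grid()].
#' @export
read_rtdose <- function(file) {
  ds <- read_dicom_file(file)
  scaling <- dcm_get(ds, "3004,000E")
  if (is.null(scaling)) stop("missing DoseGridScaling (3004,000E) in ", file)
  nz <- as.integer(dcm_require(ds, "0028,0008", "NumberOfFrames"))
  ny <- dcm_require(ds, "0028,0010", "Rows")
  nx <- dcm_require(ds, "0028,0011", "Columns")
  ps <- dcm_require(ds, "0028,0030", "PixelSpacing")
  ipp <- dcm_require(ds, "0020,0032", "ImagePositionPatient")
  gfo <- dcm_require(ds, "3004,000C", "GridFrameOffsetVector")
  dz <- if (nz > 1) stats::median(diff(gfo)) else 1
  bits <- dcm_get(ds, "0028,0100", 32)
  pix <- dcm_require(ds, "7FE0,0010", "PixelData")
  stored <- if (bits == 32) {
    readBin(pix, "integer", n = nz * ny * nx, size = 4, endian = "little")
  } else {
    readBin(pix, "integer", n = nz * ny * nx, size = 2, signed = FALSE,
            endian = "little")
  }
  data <- array(0, c(nz, ny, nx))
  per <- ny * nx
  for (i in seq_len(nz))
    data[i, , ] <- t(matrix(stored[((i - 1) * per + 1):(i * per)], nrow = nx))
  dose_grid(data * scaling, spacing = c(dz, ps[1], ps[2]),
            origin = c(ipp[3] + gfo[1], ipp[2], ipp[1]))
}

# ---- RTSTRUCT -------------------------------------------------------------

#' Write planar contours as a DICOM RTSTRUCT object
#'
#' @param structures list of `list(name =, contours = list of n x 3 matrices
#'   of (x, y, z) world mm on axial planes)`.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_rtstruct <- function(structures, file) {
  sop_class <- "1.2.840.10008.5.1.4.1.1.481.3"
  sop_uid <- paste0(DCM_UID_ROOT, ".3.1")
  roi_items <- raw(0); cont_items <- raw(0)
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    roi_items <- c(roi_items, dcm_item(c(
      dcm_elem(0x3006, 0x0022, "IS", enc_is(i)),
      dcm_elem(0x3006, 0x0026, "LO", enc_str(s$name))
    )))
    citems <- raw(0)
    for (ct in s$contours) {
      stopifnot(is.matrix(ct), ncol(ct) == 3)
      citems <- c(citems, dcm_item(c(
        dcm_elem(0x3006, 0x0042, "CS", enc_str("CLOSED_PLANAR")),
        dcm_elem(0x3006, 0x0046, "IS", enc_is(nrow(ct))),
        dcm_elem(0x3006, 0x0050, "DS", enc_ds(as.numeric(t(ct))))
      )))
    }
    cont_items <- c(cont_items, dcm_item(c(
      dcm_elem(0x3006, 0x0040, "SQ", citems),
      dcm_elem(0x3006, 0x0084, "IS", enc_is(i))
    )))
  }
  dsl <- c(
    dcm_elem(0x0008, 0x0016, "UI", dcm_pad_ui(sop_class)),
    dcm_elem(0x0008, 0x0018, "UI", dcm_pad_ui(sop_uid)),
    dcm_elem(0x0008, 0x0060, "CS", enc_str("RTSTRUCT")),
    dcm_elem(0x3006, 0x0020, "SQ", roi_items),
    dcm_elem(0x3006, 0x0039, "SQ", cont_items)
  )
  writeBin(dcm_file(dsl, sop_class, sop_uid), file)
  invisible(file)
}

# even-odd (crossing number) point-in-polygon over a grid of voxel centers;
# returns logical [y, x] matrix
poly_raster <- function(xs, ys, px, py) {
  ny <- length(ys); nx <- length(xs)
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  inside <- matrix(FALSE, ny, nx)
  j <- length(px)
  for (i in seq_along(px)) {
    yi <- py[i]; yj <- py[j]
    if (yi != yj) {
      cross <- ((yi > Y) != (yj > Y)) &
        (X < (px[j] - px[i]) * (Y - yi) / (yj - yi) + px[i])
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

#' Rasterize RTSTRUCT contours to structure masks
#'
#' Planar polygons are rasterized slice by slice with the even-odd rule; a
#' voxel is counted when its center lies inside. Multiple polygons on one
#' slice combine by exclusive-or (disjoint polygons union; nested polygons
#' form holes). Contour planes not matching any slice within half a slice
#' spacing are assigned to the nearest slice with a warning.
#'
#' @param file an RTSTRUCT file.
#' @param geom target [grid_geometry()] (usually the CT's).
#' @return Named list of [structure_mask()]s, one per ROI.
#' @export
read_rtstruct_masks <- function(file, geom) {
  geom <- geometry_of(geom)
  ds <- read_dicom_file(file)
  rois <- dcm_require(ds, "3006,0020", "StructureSetROISequence")
  names_by_num <- list()
  for (it in rois) {
    names_by_num[[as.character(dcm_get(it, "3006,0022"))]] <- dcm_get(it, "3006,0026")
  }
  conts <- dcm_require(ds, "3006,0039", "ROIContourSequence")
  xs <- geom$origin[3] + (seq_len(geom$dim[3]) - 1) * geom$spacing[3]
  ys <- geom$origin[2] + (seq_len(geom$dim[2]) - 1) * geom$spacing[2]
  out <- list()
  for (it in conts) {
    num <- as.character(dcm_get(it, "3006,0084"))
    nm <- names_by_num[[num]]
    if (is.null(nm)) nm <- paste0("ROI_", num)
    mask <- array(FALSE, geom$dim)
    cseq <- dcm_get(it, "3006,0040", list())
    for (cit in cseq) {
      cd <- dcm_get(cit, "3006,0050")
      if (is.null(cd) || !length(cd)) next
      pts <- matrix(cd, ncol = 3, byrow = TRUE)  # (x, y, z)
      zv <- (pts[1, 3] - geom$origin[1]) / geom$spacing[1]
      si <- min(max(round(zv), 0), geom$dim[1] - 1)
      if (abs(zv - si) > 0.5 + 1e-9)
        warning(sprintf(
          "contour plane z = %.3f mm is %.2f slices from the nearest slice; assigning to nearest",
          pts[1, 3], abs(zv - si)))
      sl <- poly_raster(xs, ys, pts[, 1], pts[, 2])
      mask[si + 1, , ] <- xor(mask[si + 1, , ], sl)
    }
    if (!any(mask)) warning("structure '", nm, "' rasterized to an empty mask")
    out[[nm]] <- structure_mask(nm, mask, geom$spacing, geom$origin)
  }
  out
}

# ---- landmarks ------------------------------------------------------------

#' Read / write paired landmarks as CSV
#'
#' The single landmark interchange format: columns `label, ref_z, ref_y,
#' ref_x, flt_z, flt_y, flt_x`, coordinates always in world mm.
#'
#' @param file CSV path.
#' @return [read_landmarks()] returns a [landmark_set()];
#'   `write_landmarks()` returns `file` invisibly.
#' @export
read_landmarks <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  landmark_set(df)
}

#' @rdname read_landmarks
#' @param lm a [landmark_set()].
#' @export
write_landmarks <- function(lm, file) {
  stopifnot(inherits(lm, "landmark_set"))
  utils::write.csv(as.data.frame(lm), file, row.names = FALSE)
  invisible(file)
}

# ---- internal serialized format ------------------------------------------

#' Save / load package objects in the internal serialized format
#'
#' One compressed archive per object (gzip-compressed R serialization)
#' holding the array plus spacing/origin metadata and the object class.
#'
#' @param obj any package container (volume, dose, field, mask, report ...).
#' @param path file path (conventionally `.rds`).
#' @return `load_object()` returns the object; `save_object()` returns
#'   `path` invisibly.
#' @export
save_object <- function(obj, path) {
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_object
#' @export
load_object <- function(path) readRDS(path)
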