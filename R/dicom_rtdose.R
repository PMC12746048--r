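# Single-plane DICOM RT Dose read/write. Deliberately minimal: one frame,
# DoseUnits GY, 32-bit unsigned pixels, explicit VR little endian. Dose
# values are stored pixel values times Dose Grid Scaling; the scaling is
# chosen on write so that quantization error is < 1e-9 of the maximum dose.

write_dicom_rtdose <- function(img, path) {
  v <- img$values
  maxv <- max(v)
  scaling <- if (maxv > 0) maxv / (2^31 - 2) else 1
  pix <- round(t(v) / scaling) # row-major order for DICOM
  pixel_bytes <- writeBin(as.integer(pix), raw(), size = 4, endian = "little")
  sop_instance <- content_uid(dim(v), img$spacing, img$origin, maxv)
  ds <- list(
    "0008,0016" = dcm_el("UI", UID_RTDOSE),
    "0008,0018" = dcm_el("UI", sop_instance),
    "0008,0060" = dcm_el("CS", "RTDOSE"),
    "0020,0032" = dcm_el("DS", c(img$origin[2], img$origin[1], 0)), # IPP (x,y,z)
    "0020,0037" = dcm_el("DS", c(1, 0, 0, 0, 1, 0)),
    "0028,0002" = dcm_el("US", 1L),
    "0028,0004" = dcm_el("CS", "MONOCHROME2"),
    "0028,0008" = dcm_el("IS", 1),
    "0028,0010" = dcm_el("US", nrow(v)),
    "0028,0011" = dcm_el("US", ncol(v)),
    "0028,0030" = dcm_el("DS", c(img$spacing[1], img$spacing[2])),
    "0028,0100" = dcm_el("US", 32L),
    "0028,0101" = dcm_el("US", 32L),
    "0028,0102" = dcm_el("US", 31L),
    "0028,0103" = dcm_el("US", 0L),
    "3004,0002" = dcm_el("CS", "GY"),
    "3004,0004" = dcm_el("CS", "PHYSICAL"),
    "3004,000A" = dcm_el("CS", "PLAN"),
    "3004,000E" = dcm_el("DS", scaling),
    "7FE0,0010" = dcm_el("OW", pixel_bytes))
  write_dicom_file(ds, path, UID_RTDOSE, sop_instance)
}

read_dicom_rtdose <- function(path, frame = NULL) {
  ds <- read_dicom_file(path)
  nr <- dcm_get(ds, "0028,0010")
  nc <- dcm_get(ds, "0028,0011")
  spacing <- dcm_get(ds, "0028,0030")
  scaling <- dcm_get(ds, "3004,000E")
  if (is.null(nr) || is.null(nc)) stop("RT Dose: missing Rows/Columns")
  if (length(spacing) != 2L) stop("RT Dose: missing or malformed PixelSpacing")
  if (!length(scaling)) stop("RT Dose: missing DoseGridScaling")
  ipp <- dcm_get(ds, "0020,0032", required = FALSE)
  origin <- if (is.null(ipp)) c(0, 0) else c(ipp[2], ipp[1]) # (y, x)
  nframes <- dcm_get(ds, "0028,0008", required = FALSE)
  nframes <- if (is.null(nframes)) 1L else as.integer(nframes)
  bits <- dcm_get(ds, "0028,0100", required = FALSE)
  if (is.null(bits)) bits <- 32L
  bytes_per <- as.integer(bits) / 8L
  if (!bytes_per %in% c(2L, 4L)) stop("RT Dose: unsupported BitsAllocated: ", bits)
  raw_pix <- dcm_get(ds, "7FE0,0010")
  if (!is.raw(raw_pix)) stop("RT Dose: missing PixelData")
  npix <- as.integer(nr) * as.integer(nc)
  if (nframes > 1L) {
    if (is.null(frame))
      stop("RT Dose file has ", nframes,
           " frames; a frame index must be supplied")
    if (frame < 1L || frame > nframes) stop("frame index out of range")
    off <- (frame - 1L) * npix * bytes_per
    raw_pix <- raw_pix[(off + 1L):(off + npix * bytes_per)]
  }
  if (length(raw_pix) < npix * bytes_per) stop("RT Dose: PixelData truncated")
  if (bytes_per == 4L) {
    pix <- readBin(raw_pix, "integer", n = npix, size = 4, endian = "little")
    pix <- ifelse(pix < 0, pix + 2^32, pix) # reinterpret as unsigned
  } else {
    pix <- readBin(raw_pix, "integer", n = npix, size = 2, endian = "little",
                   signed = FALSE)
  }
  vals <- t(matrix(pix, nrow = nc, ncol = nr)) # stored row-major
  dose_image(vals * scaling, spacing = spacing, origin = origin,
             unit_label = "Gy")
}
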