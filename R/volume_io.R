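#' Write a volume to NIfTI
#'
#' HU volumes are stored as 32-bit float, label volumes as 16-bit signed
#' integers. Spacing is stored in the NIfTI `pixdim` field (32-bit float by
#' format definition).
#'
#' @param vol An [hu_volume()] or [label_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, "panospec_volume")) stop("not a panospec volume")
  if (!grepl("\\.nii(\\.gz)?$", path)) stop("path must end in .nii or .nii.gz")
  datatype <- if (inherits(vol, "label_volume")) "int16" else "float"
  arr <- vol$voxels
  attr(arr, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(arr, datatype = datatype)
  ok <- try(RNifti::writeNifti(img, path, datatype = datatype), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write ", path)
  invisible(path)
}

#' Load a head CT volume
#'
#' Reads a NIfTI file (`.nii` / `.nii.gz`) or a directory containing a DICOM
#' series. DICOM stored values are converted to Hounsfield units using the
#' rescale slope and intercept tags; the series is sorted along the slice
#' normal, and inconsistent slice spacing or mixed slice orientations are
#' errors rather than silently reordered data.
#'
#' @param path NIfTI file path or DICOM series directory.
#' @param labels If `TRUE`, return a [label_volume()] (integer labels)
#'   instead of an [hu_volume()].
#' @return An [hu_volume()] (or [label_volume()]).
#' @export
load_volume <- function(path, labels = FALSE) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stop("no such file: ", path)
  if (!grepl("\\.nii(\\.gz)?$", path)) stop("unsupported volume format: ", path)
  img <- try(RNifti::readNifti(path), silent = TRUE)
  if (inherits(img, "try-error")) stop("unreadable NIfTI file: ", path)
  spacing <- RNifti::pixdim(img)[1:3]
  vox <- as.array(img)
  attributes(vox) <- list(dim = dim(vox))
  if (labels) label_volume(round(vox), spacing)
  else hu_volume(vox, spacing)
}

# ---- minimal DICOM series reader ------------------------------------------
# Supports uncompressed single-frame CT slices in implicit or explicit VR
# little endian. Only the tags needed to assemble an HU volume are kept.

dicom_read_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132 + 8 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  n <- length(raw)
  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) sum(as.numeric(raw[at + 0:3]) * 256^(0:3))
  explicit_vrs_long <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
  elems <- list()
  transfer_syntax <- NULL
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    tag <- sprintf("%04X%04X", group, elem)
    # the file meta group (0002) is always explicit VR; the dataset follows
    # the transfer syntax declared there (default: explicit little endian)
    is_explicit <- group == 2L || is.null(transfer_syntax) ||
      transfer_syntax != "1.2.840.10008.1.2"
    if (is_explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% explicit_vrs_long) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- "UN"; len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) {  # undefined length (sequences): skip to delimiter
      pos <- dicom_skip_undefined(raw, pos + hdr, u16, u32)
      next
    }
    body <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    elems[[tag]] <- list(vr = vr, bytes = body)
    if (tag == "00020010")
      transfer_syntax <- sub("\\s+$", "", rawToChar(body[body != as.raw(0)]))
    pos <- pos + hdr + len
  }
  if (!is.null(transfer_syntax) &&
      !transfer_syntax %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    stop("unsupported DICOM transfer syntax: ", transfer_syntax)
  elems
}

dicom_skip_undefined <- function(raw, pos, u16, u32) {
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L); len <- u32(pos + 4L)
    if (group == 0xFFFE && elem == 0xE0DD) return(pos + 8L)  # seq delimiter
    if (group == 0xFFFE && elem == 0xE000) {                 # item
      pos <- if (len == 4294967295) pos + 8L else pos + 8L + len
    } else if (group == 0xFFFE && elem == 0xE00D) {
      pos <- pos + 8L
    } else {
      pos <- pos + 8L + len
    }
  }
  stop("unterminated DICOM sequence")
}

dicom_str <- function(el) {
  if (is.null(el)) return(NULL)
  s <- rawToChar(el$bytes[el$bytes != as.raw(0)])
  sub("\\s+$", "", sub("^\\s+", "", s))
}

dicom_nums <- function(el) {
  s <- dicom_str(el)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_u16val <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$bytes, "integer", n = 1, size = 2, endian = "little", signed = FALSE)
}

#' Read a DICOM series directory into an HU volume
#'
#' @param dir Directory containing one uncompressed little-endian CT series.
#' @return An [hu_volume()]; stored values are rescaled to HU.
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, dicom_read_file)

  need <- function(el, what, f) {
    if (is.null(el)) stop("DICOM slice ", f, " missing ", what)
    el
  }
  meta <- lapply(seq_along(slices), function(i) {
    e <- slices[[i]]; f <- basename(files[i])
    rows <- dicom_u16val(need(e[["00280010"]], "Rows", f))
    cols <- dicom_u16val(need(e[["00280011"]], "Columns", f))
    pxsp <- dicom_nums(need(e[["00280030"]], "PixelSpacing", f))
    slope <- dicom_nums(e[["00281053"]])
    inter <- dicom_nums(e[["00281052"]])
    if (is.null(slope) || is.null(inter))
      stop("DICOM slice ", f, " missing rescale slope/intercept tags")
    pos <- dicom_nums(need(e[["00200032"]], "ImagePositionPatient", f))
    orient <- dicom_nums(need(e[["00200037"]], "ImageOrientationPatient", f))
    bits <- dicom_u16val(need(e[["00280100"]], "BitsAllocated", f))
    signed <- dicom_u16val(need(e[["00280103"]], "PixelRepresentation", f))
    px <- need(e[["7FE00010"]], "PixelData", f)
    if (bits != 16) stop("only 16-bit DICOM pixel data supported")
    vals <- readBin(px$bytes, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = signed == 1)
    list(rows = rows, cols = cols, pxsp = pxsp, slope = slope, inter = inter,
         pos = pos, orient = orient, vals = vals)
  })

  o1 <- meta[[1]]$orient
  same_orient <- vapply(meta, function(m) max(abs(m$orient - o1)) < 1e-4, logical(1))
  if (!all(same_orient))
    stop("DICOM series has mixed slice orientations; refusing to reorder")
  normal <- c(o1[2] * o1[6] - o1[3] * o1[5],
              o1[3] * o1[4] - o1[1] * o1[6],
              o1[1] * o1[5] - o1[2] * o1[4])
  zpos <- vapply(meta, function(m) sum(m$pos * normal), numeric(1))
  ord <- order(zpos)
  meta <- meta[ord]; zpos <- zpos[ord]
  if (length(meta) > 1) {
    dz <- diff(zpos)
    if (any(dz <= 0) || (max(dz) - min(dz)) > 1e-3 * mean(dz) + 1e-6)
      stop("inconsistent DICOM slice spacing: ",
           paste(format(unique(round(dz, 4))), collapse = ", "))
    dz <- mean(dz)
  } else dz <- 1
  rows <- meta[[1]]$rows; cols <- meta[[1]]$cols
  vox <- array(0, dim = c(cols, rows, length(meta)))
  for (i in seq_along(meta)) {
    m <- meta[[i]]
    # PixelData is row-major (columns fastest); our x axis is the column axis
    vox[, , i] <- matrix(m$vals * m$slope + m$inter, nrow = cols, ncol = rows)
  }
  spacing <- c(meta[[1]]$pxsp[2], meta[[1]]$pxsp[1], dz)
  hu_volume(vox, spacing, origin = meta[[1]]$pos)
}
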