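#' 3D grayscale volume with voxel spacing
#'
#' Light container for a scalar voxel grid with per-axis spacing and origin,
#' both in millimetres. World coordinates refer to voxel centers: the center
#' of voxel `(i, j, k)` (1-based, R convention) is
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param intensities 3D numeric array of voxel intensities (finite).
#' @param spacing Numeric length-3, mm per axis; all strictly positive.
#'   A single value is recycled (isotropic).
#' @param origin Numeric length-3, world position (mm) of the first voxel
#'   center. Defaults to `c(0, 0, 0)`.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(intensities, spacing, origin = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, length(origin) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing must be strictly positive on all axes", call. = FALSE)
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop("intensities must be finite", call. = FALSE)
  structure(
    list(intensities = intensities, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "volume3d"
  )
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g], origin (%s) mm\n",
              min(x$intensities), max(x$intensities),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$intensities)

world_to_index <- function(vol, xyz) {
  round((as.numeric(xyz) - vol$origin) / vol$spacing) + 1
}

index_to_world <- function(vol, ijk) {
  sweep(sweep(ijk - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Read a 3D volume from disk
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`; spacing taken from the
#' header), a multi-page TIFF stack with a JSON sidecar carrying the spacing,
#' or raw doubles with a JSON sidecar. The sidecar is `<path>.json` and must
#' contain `spacing_mm` (and for raw, `dim`); spacing is load-bearing because
#' every diameter downstream is reported in mm, so a stack without it is an
#' error rather than a guess.
#'
#' @param path File path.
#' @param format `"nifti"`, `"tiff"` or `"raw"`; guessed from the extension
#'   when `NULL`.
#' @return A [volume3d].
#' @export
read_volume <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- format %||% guess_format(path)
  switch(format,
    nifti = {
      img <- RNifti::readNifti(path)
      # header stores pixdim/origin as float32 (~7 significant digits)
      sp <- signif(attr(img, "pixdim")[1:3], 7)
      xf <- RNifti::xform(img)
      org <- if (is.matrix(xf)) signif(xf[1:3, 4], 7) else c(0, 0, 0)
      volume3d(array(as.numeric(img), dim = dim(img)), spacing = sp,
               origin = org)
    },
    tiff = {
      side <- read_sidecar(path, "TIFF stack")
      pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
      if (!is.list(pages)) pages <- list(pages)
      arr <- simplify2array(lapply(pages, function(p) t(p)))
      volume3d(arr * attr_or(side$intensity_scale, 1),
               spacing = side$spacing_mm,
               origin = attr_or(side$origin_mm, c(0, 0, 0)))
    },
    raw = {
      side <- read_sidecar(path, "raw volume")
      if (is.null(side$dim)) stop("sidecar for raw volume must give `dim`", call. = FALSE)
      n <- prod(side$dim)
      vals <- readBin(path, what = "double", n = n, size = 8, endian = "little")
      volume3d(array(vals, dim = side$dim), spacing = side$spacing_mm,
               origin = attr_or(side$origin_mm, c(0, 0, 0)))
    },
    stop("unknown volume format: ", format, call. = FALSE)
  )
}

#' Write a 3D volume to disk
#'
#' Inverse of [read_volume()]: round-tripping preserves intensities
#' bit-exactly (NIfTI is written as float64) and spacing to better than
#' 1e-9 mm. TIFF stacks are 32-bit float pages rescaled to `[0, 1]` with the
#' scale recorded in the sidecar, so the raw format is preferred when exact
#' intensities matter.
#'
#' @param volume A [volume3d].
#' @param path Output path.
#' @param format `"nifti"`, `"tiff"` or `"raw"`; guessed from the extension
#'   when `NULL`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = NULL) {
  stopifnot(inherits(volume, "volume3d"))
  format <- format %||% guess_format(path)
  switch(format,
    nifti = {
      arr <- volume$intensities
      attr(arr, "pixdim") <- volume$spacing
      img <- RNifti::asNifti(arr, datatype = "double")
      m <- diag(c(volume$spacing, 1))
      m[1:3, 4] <- volume$origin
      RNifti::qform(img) <- structure(m, code = 2L)
      RNifti::writeNifti(img, path, datatype = "double")
    },
    tiff = {
      sc <- max(abs(volume$intensities), 1e-300)
      pages <- lapply(seq_len(dim(volume$intensities)[3]),
                      function(k) t(volume$intensities[, , k]) / sc)
      tiff::writeTIFF(pages, path, bits.per.sample = 32L)
      write_sidecar(path, volume, intensity_scale = sc)
    },
    raw = {
      writeBin(as.numeric(volume$intensities), path, size = 8, endian = "little")
      write_sidecar(path, volume, dim = dim(volume$intensities))
    },
    stop("unknown volume format: ", format, call. = FALSE)
  )
  invisible(path)
}

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
  else if (grepl("\\.raw$", path)) "raw"
  else stop("cannot guess volume format from: ", path, call. = FALSE)
}

read_sidecar <- function(path, what) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc))
    stop(what, " requires a JSON sidecar with voxel spacing (missing: ",
         sc, "); spacing in mm is required for diameter measurements",
         call. = FALSE)
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(side$spacing_mm))
    stop("sidecar ", sc, " lacks `spacing_mm`", call. = FALSE)
  side
}

write_sidecar <- function(path, volume, ...) {
  jsonlite::write_json(
    c(list(spacing_mm = volume$spacing, origin_mm = volume$origin), list(...)),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
}

attr_or <- function(x, default) if (is.null(x)) default else x
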