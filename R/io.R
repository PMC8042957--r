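#' Read a micro-CT volume from a multi-page TIFF stack
#'
#' Reads a grayscale image stack (one TIFF page per z slice) together with
#' a JSON sidecar carrying the isotropic voxel size. Intensities are kept
#' on the 8-bit 0-255 convention: 8-bit input is read unmodified; 16-bit
#' input is linearly rescaled to 0-255 (the mapping is reported via
#' \code{message}).
#'
#' @param path Path to a multi-page TIFF stack.
#' @param sidecar Path to the JSON sidecar; must contain a positive
#'   \code{voxel_size_um}. Defaults to \code{<path>.json}, which is what
#'   \code{\link{writeVolume}} produces.
#' @return A \linkS4class{CTVolume}.
#' @examples
#' v <- CTVolume(array(rep(0:255, length.out = 4 * 8 * 8), c(4, 8, 8)), 20)
#' f <- file.path(tempdir(), "vol.tif")
#' writeVolume(v, f)
#' v2 <- readVolume(f)
#' stopifnot(identical(voxels(v), voxels(v2)))
#' @seealso \code{\link{writeVolume}}
#' @export
readVolume <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  if (!file.exists(sidecar)) stop("sidecar file not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  vs <- meta$voxel_size_um
  if (is.null(vs) || !is.numeric(vs) || length(vs) != 1L || !is.finite(vs) ||
      vs <= 0) {
    stop("sidecar must provide a single positive voxel_size_um")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("format error: TIFF pages have unequal shapes")
  }
  nz <- length(pages); ny <- dims[1, 1]; nx <- dims[2, 1]
  vox <- array(0, c(nz, ny, nx))
  for (k in seq_len(nz)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # first channel of RGB input
    vox[k, , ] <- pg
  }
  if (max(vox) > 255) {
    message("16-bit input detected; rescaling intensities by 255/65535 to the 0-255 scale")
    vox <- vox * (255 / 65535)
  }
  message(sprintf("read volume %s: %d x %d x %d voxels (z,y,x), %g um",
                  path, nz, ny, nx, vs))
  CTVolume(vox, vs)
}

#' Write a micro-CT volume as a multi-page TIFF stack
#'
#' Writes one 8-bit grayscale TIFF page per z slice plus a JSON sidecar
#' (\code{<path>.json}) holding the voxel size, so
#' \code{\link{readVolume}} recovers an identical volume. Intensities are
#' rounded to integers and clipped to 0-255 on write (the on-disk format
#' is 8-bit).
#'
#' @param v A \linkS4class{CTVolume}.
#' @param path Target TIFF path; the parent directory must exist.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readVolume}}
#' @export
writeVolume <- function(v, path) {
  stopifnot(is(v, "CTVolume"))
  if (!dir.exists(dirname(path))) {
    stop("cannot write volume: directory does not exist: ", dirname(path))
  }
  vox <- pmin(pmax(round(voxels(v)), 0), 255)
  pages <- lapply(seq_len(dim(vox)[1]), function(k) vox[k, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  jsonlite::write_json(
    list(voxel_size_um = voxelSize(v),
         shape_zyx = dim(vox),
         writer = "microBIC"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  message(sprintf("wrote volume %s: %d x %d x %d voxels (z,y,x), %g um",
                  path, dim(vox)[1], dim(vox)[2], dim(vox)[3], voxelSize(v)))
  invisible(path)
}

.configDefaults <- function() {
  list(
    bone_min = 60,
    bone_max = 90,
    implant_min = 200,
    min_component_px = 0,
    exclusion_layers = 1,
    grooves_per_side = 4,
    angles = c(0, 45, 90, 135),
    angle_offset = 0,
    pooling = "pooled",
    side_selection = "both",
    allow_fewer_grooves = FALSE
  )
}

#' Load a pipeline configuration file
#'
#' Reads a YAML (or JSON) configuration and fills unset keys with the
#' pipeline defaults: bone threshold window 60-90 and implant threshold
#' 200 on the 8-bit scale, one interface exclusion layer, slice angles
#' 0/45/90/135 degrees, and four measured grooves per side. Unknown keys
#' produce a warning and are dropped; type- or range-invalid values are
#' errors.
#'
#' @param path Path to a YAML/JSON file; an empty file yields all defaults.
#' @return Named list of validated configuration values.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("bone_min: 65", f)
#' cfg <- loadConfig(f)
#' cfg$bone_min; cfg$bone_max
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config must be a key/value mapping")
  cfg <- .configDefaults()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  }
  for (k in intersect(names(user), names(cfg))) cfg[[k]] <- user[[k]]

  num1 <- function(key, lo = -Inf) {
    x <- cfg[[key]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo) {
      stop("config key '", key, "' must be a single number >= ", lo)
    }
  }
  num1("bone_min", 0); num1("bone_max", 0); num1("implant_min", 0)
  num1("min_component_px", 0); num1("exclusion_layers", 0)
  num1("grooves_per_side", 1); num1("angle_offset")
  if (cfg$bone_min > cfg$bone_max) {
    stop("invalid bone window: bone_min (", cfg$bone_min,
         ") exceeds bone_max (", cfg$bone_max, ")")
  }
  if (cfg$bone_max >= cfg$implant_min) {
    stop("bone_max must be below implant_min")
  }
  if (!is.numeric(cfg$angles) || !length(cfg$angles) ||
      any(cfg$angles < 0 | cfg$angles >= 360)) {
    stop("angles must be numeric and in [0, 360)")
  }
  if (!cfg$pooling %in% c("pooled", "groove-mean")) {
    stop("pooling must be 'pooled' or 'groove-mean'")
  }
  if (!cfg$side_selection %in% c("both", "left", "right")) {
    stop("side_selection must be both, left or right")
  }
  if (!is.logical(cfg$allow_fewer_grooves) || length(cfg$allow_fewer_grooves) != 1L) {
    stop("allow_fewer_grooves must be a single logical")
  }
  cfg
}
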