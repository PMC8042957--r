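#' @import methods
NULL

#' Label codes for tri-class segmentations
#'
#' Segmented longitudinal slices use a fixed integer palette:
#' 0 = background (air and soft tissue), 1 = bone, 2 = implant.
#'
#' @return Named integer vector with elements \code{BACKGROUND}, \code{BONE},
#'   \code{IMPLANT}.
#' @examples
#' labelCodes()
#' @export
labelCodes <- function() {
  c(BACKGROUND = 0L, BONE = 1L, IMPLANT = 2L)
}

.LBL <- labelCodes()

#' CTVolume: a reconstructed grayscale micro-CT volume
#'
#' Holds an isotropic 3D grayscale image on the 8-bit (0-255) intensity
#' convention used throughout the package. The array is indexed
#' \code{[z, y, x]}: z is the stack/slice index, y the image row, x the
#' image column. Voxel centers sit at \code{(index - 1) * voxelSizeUm}
#' micrometres (0-based voxel-center coordinates).
#'
#' @slot voxels 3D numeric array \code{[z, y, x]} of intensities.
#' @slot voxelSizeUm Positive scalar, isotropic voxel edge length in
#'   micrometres.
#' @export
setClass("CTVolume", representation(
  voxels = "array",
  voxelSizeUm = "numeric"
))

setValidity("CTVolume", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("voxels must be a 3D array")
  if (any(dim(v) < 1L)) return("all three dimensions must be >= 1")
  if (length(object@voxelSizeUm) != 1L || !is.finite(object@voxelSizeUm) ||
      object@voxelSizeUm <= 0) {
    return("voxelSizeUm must be a single positive finite number")
  }
  if (!all(is.finite(v))) return("voxel intensities must all be finite")
  TRUE
})

#' Construct a CTVolume
#'
#' @param voxels 3D numeric array \code{[z, y, x]}.
#' @param voxelSizeUm Isotropic voxel size in micrometres.
#' @return A \linkS4class{CTVolume}.
#' @examples
#' v <- CTVolume(array(0, c(4, 8, 8)), voxelSizeUm = 20)
#' dim(voxels(v))
#' @export
CTVolume <- function(voxels, voxelSizeUm) {
  new("CTVolume", voxels = voxels, voxelSizeUm = as.numeric(voxelSizeUm))
}

#' CTSlice: a longitudinal 2D grayscale slice through the implant axis
#'
#' Rows run along the implant axis (row 1 = implant top, the end with the
#' smaller axial coordinate); columns run along the radial direction of the
#' extraction plane, with the plane's nominal angle on the positive-column
#' side and angle + 180 degrees on the negative side. Geometry slots are in
#' voxel units of the source volume, as (x, y, z) coordinate vectors.
#'
#' @slot pixels 2D numeric matrix (axial rows x radial columns).
#' @slot pixelSizeUm Positive scalar pixel size (micrometres).
#' @slot angleDeg Extraction angle about the implant axis, in [0, 360).
#' @slot origin Position (x, y, z, voxel units) of pixel [1, 1].
#' @slot basisAxial Unit vector along increasing row index.
#' @slot basisRadial Unit vector along increasing column index.
#' @export
setClass("CTSlice", representation(
  pixels = "matrix",
  pixelSizeUm = "numeric",
  angleDeg = "numeric",
  origin = "numeric",
  basisAxial = "numeric",
  basisRadial = "numeric"
))

setValidity("CTSlice", function(object) {
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
  if (object@angleDeg < 0 || object@angleDeg >= 360) {
    return("angleDeg must lie in [0, 360)")
  }
  a <- object@basisAxial; r <- object@basisRadial
  if (length(a) != 3L || length(r) != 3L || length(object@origin) != 3L) {
    return("origin and basis vectors must have length 3")
  }
  if (abs(sum(a * a) - 1) > 1e-9 || abs(sum(r * r) - 1) > 1e-9) {
    return("basis vectors must be unit length (tol 1e-9)")
  }
  if (abs(sum(a * r)) > 1e-9) return("basis vectors must be orthogonal (tol 1e-9)")
  TRUE
})

#' LabelSlice: tri-class segmentation of a longitudinal slice
#'
#' Same geometry as its source \linkS4class{CTSlice}; pixel values are the
#' codes of \code{\link{labelCodes}} (0 background, 1 bone, 2 implant).
#'
#' @slot labels Integer matrix over \{0, 1, 2\}.
#' @slot pixelSizeUm Pixel size in micrometres.
#' @slot angleDeg Extraction angle of the source slice.
#' @export
setClass("LabelSlice", representation(
  labels = "matrix",
  pixelSizeUm = "numeric",
  angleDeg = "numeric"
))

setValidity("LabelSlice", function(object) {
  l <- object@labels
  if (!all(l %in% .LBL)) {
    return("labels must be a partition over {0 background, 1 bone, 2 implant}")
  }
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
  TRUE
})

#' ImplantAxis: estimated long axis of the implant
#'
#' @slot point A point on the axis (x, y, z, voxel units); the centroid of
#'   the supra-threshold implant voxels.
#' @slot direction Unit direction vector, sign-normalized so the z
#'   component (stack direction) is positive.
#' @export
setClass("ImplantAxis", representation(
  point = "numeric",
  direction = "numeric"
))

setValidity("ImplantAxis", function(object) {
  if (length(object@point) != 3L || length(object@direction) != 3L) {
    return("point and direction must have length 3")
  }
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9) {
    return("direction must be a unit vector (tol 1e-9)")
  }
  TRUE
})

#' ContactMap: prescribed osseointegration pattern of a phantom
#'
#' Piecewise-constant contact indicator over an angular x groove grid.
#' Rows index thread grooves from the implant top; columns index angular
#' sectors of width \code{360 / ncol} degrees starting at 0.
#'
#' @slot contact Logical matrix [grooves x sectors]; TRUE where bone
#'   directly contacts the thread profile.
#' @export
setClass("ContactMap", representation(contact = "matrix"))

setValidity("ContactMap", function(object) {
  m <- object@contact
  if (!is.logical(m)) return("contact must be a logical matrix")
  if (nrow(m) < 1L || ncol(m) < 4L) {
    return("need >= 1 groove and >= 4 angular sectors")
  }
  if (anyNA(m)) return("contact indicator must be defined everywhere")
  TRUE
})

#' PhantomConfig: parameters of the synthetic implant-in-bone phantom
#'
#' Defaults reproduce the study conditions: a threaded cylindrical implant
#' of 4 mm diameter and 8.5 mm length scanned at 20 um isotropic
#' resolution, with class intensity means placed so that the default
#' segmentation windows (bone 60-90, implant >= 200) separate the classes.
#' Thread pitch and depth are free parameters of the generator (the implant
#' thread geometry is not otherwise constrained); the crest axial thickness
#' is fixed at half the pitch.
#'
#' @slot implantDiameterUm Outer (crest) diameter, micrometres.
#' @slot implantLengthUm Implant length, micrometres.
#' @slot threadDepthUm Radial depth of the thread groove, micrometres.
#' @slot threadPitchUm Axial distance between thread crests, micrometres.
#' @slot boneOuterRadiusUm Outer radius of the cortical bone shell.
#' @slot volumeShape Integer (z, y, x) array dimensions; NA = derived from
#'   the geometry with a safety margin.
#' @slot voxelSizeUm Isotropic voxel size, micrometres.
#' @slot intensityMeans Named numeric: background, bone, implant class means.
#' @slot noiseSd Additive Gaussian noise standard deviation (intensity units).
#' @slot haloWidthVoxels Width of the residual beam-hardening halo shell.
#' @slot haloIntensity Brightness floor applied within the halo shell.
#' @slot granuleCount Number of ceramic (beta-TCP-like) granules.
#' @slot granuleRadiusUm Granule radius, micrometres.
#' @slot seed Integer seed for granule placement and noise.
#' @export
setClass("PhantomConfig", representation(
  implantDiameterUm = "numeric",
  implantLengthUm = "numeric",
  threadDepthUm = "numeric",
  threadPitchUm = "numeric",
  boneOuterRadiusUm = "numeric",
  volumeShape = "numeric",
  voxelSizeUm = "numeric",
  intensityMeans = "numeric",
  noiseSd = "numeric",
  haloWidthVoxels = "numeric",
  haloIntensity = "numeric",
  granuleCount = "numeric",
  granuleRadiusUm = "numeric",
  seed = "numeric"
))

setValidity("PhantomConfig", function(object) {
  im <- object@intensityMeans
  if (!all(c("background", "bone", "implant") %in% names(im))) {
    return("intensityMeans needs named entries background, bone, implant")
  }
  if (!(im["background"] < im["bone"] && im["bone"] < im["implant"])) {
    return("class intensity means must be ordered background < bone < implant")
  }
  if (object@voxelSizeUm <= 0) return("voxelSizeUm must be positive")
  if (object@threadDepthUm >= object@implantDiameterUm / 2) {
    return("thread depth must be smaller than the implant radius")
  }
  if (object@boneOuterRadiusUm <= object@implantDiameterUm / 2) {
    return("bone outer radius must exceed the implant radius")
  }
  if (object@haloWidthVoxels < 0 || object@granuleCount < 0) {
    return("haloWidthVoxels and granuleCount must be >= 0")
  }
  geo <- .phantomGeometry(object)
  if (!is.null(geo$error)) return(geo$error)
  if (geo$nGrooves < 4L) {
    return("geometry must provide at least 4 grooves per side")
  }
  TRUE
})

#' PhantomTruth: analytic ground-truth BIC of a phantom
#'
#' @slot perGroove data.frame (angle_deg, side, groove, bic_percent).
#' @slot perPlane data.frame (angle_deg, bic_percent), pooled over the
#'   selected upper grooves on both sides.
#' @slot meanBIC Arithmetic mean of the per-plane values (percent).
#' @slot contactMap The generating \linkS4class{ContactMap}.
#' @slot config The generating \linkS4class{PhantomConfig}.
#' @export
setClass("PhantomTruth", representation(
  perGroove = "data.frame",
  perPlane = "data.frame",
  meanBIC = "numeric",
  contactMap = "ContactMap",
  config = "PhantomConfig"
))

setValidity("PhantomTruth", function(object) {
  b <- c(object@perGroove$bic_percent, object@perPlane$bic_percent,
         object@meanBIC)
  if (any(b < 0 | b > 100)) return("BIC values must lie in [0, 100]")
  if (abs(object@meanBIC - mean(object@perPlane$bic_percent)) > 1e-9) {
    return("meanBIC must equal the mean of the per-plane values")
  }
  TRUE
})

#' BICResult: per-slice bone-to-implant contact measurement
#'
#' @slot perGroove data.frame with columns side, groove, contact_px,
#'   total_px, bic_percent for each measured groove.
#' @slot perSliceBIC Pooled per-slice BIC in percent.
#' @slot angleDeg Angle of the measured slice.
#' @slot pooling Pooling rule used ("pooled" lengths or "groove-mean").
#' @export
setClass("BICResult", representation(
  perGroove = "data.frame",
  perSliceBIC = "numeric",
  angleDeg = "numeric",
  pooling = "character"
))

setValidity("BICResult", function(object) {
  g <- object@perGroove
  if (any(g$bic_percent < 0 | g$bic_percent > 100)) {
    return("groove BIC must lie in [0, 100]")
  }
  if (any(g$contact_px > g$total_px)) {
    return("contact length cannot exceed total length")
  }
  if (object@perSliceBIC < 0 || object@perSliceBIC > 100) {
    return("per-slice BIC must lie in [0, 100]")
  }
  TRUE
})

#' ImplantBIC: multi-angle mean BIC for one implant
#'
#' @slot perAngle Named numeric vector of per-slice BIC values (percent),
#'   names are the slice angles in degrees.
#' @slot meanBIC Unweighted arithmetic mean of \code{perAngle} (percent);
#'   the implant-level summary measure.
#' @export
setClass("ImplantBIC", representation(
  perAngle = "numeric",
  meanBIC = "numeric"
))

setValidity("ImplantBIC", function(object) {
  if (length(object@perAngle) < 1L) return("need at least one per-slice BIC")
  if (abs(object@meanBIC - mean(object@perAngle)) > 1e-9) {
    return("meanBIC must equal the arithmetic mean of perAngle")
  }
  TRUE
})
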