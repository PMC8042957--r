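#' Accessors for package classes
#'
#' Accessor generics for the S4 containers: \code{voxels} and
#' \code{voxelSize} for \linkS4class{CTVolume}; \code{pixels},
#' \code{pixelSize} and \code{angleDeg} for slices; \code{contactMatrix}
#' and \code{sectorWidthDeg} for \linkS4class{ContactMap};
#' \code{truthPerGroove}, \code{truthPerPlane} and \code{meanBICPercent}
#' for \linkS4class{PhantomTruth}; \code{perGrooveBIC},
#' \code{perSliceBIC}, \code{perAngleBIC} and \code{meanBICPercent} for
#' measurement results.
#'
#' @param object An object of the matching class.
#' @return The slot contents (see the class documentation).
#' @name accessors
#' @aliases voxels voxelSize pixels pixelSize angleDeg labelMatrix
#'   contactMatrix sectorWidthDeg truthPerGroove truthPerPlane
#'   perGrooveBIC perSliceBIC perAngleBIC meanBICPercent
#' @examples
#' v <- CTVolume(array(0, c(2, 4, 4)), 20)
#' voxelSize(v)
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setMethod("voxels", "CTVolume", function(object) object@voxels)

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setMethod("voxelSize", "CTVolume", function(object) object@voxelSizeUm)

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "CTSlice", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "CTSlice", function(object) object@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("pixelSize", "LabelSlice", function(object) object@pixelSizeUm)

#' @rdname accessors
#' @export
setGeneric("angleDeg", function(object) standardGeneric("angleDeg"))
#' @rdname accessors
#' @export
setMethod("angleDeg", "CTSlice", function(object) object@angleDeg)
#' @rdname accessors
#' @export
setMethod("angleDeg", "LabelSlice", function(object) object@angleDeg)
#' @rdname accessors
#' @export
setMethod("angleDeg", "BICResult", function(object) object@angleDeg)

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))
#' @rdname accessors
#' @export
setMethod("labelMatrix", "LabelSlice", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("contactMatrix", function(object) standardGeneric("contactMatrix"))
#' @rdname accessors
#' @export
setMethod("contactMatrix", "ContactMap", function(object) object@contact)

#' @rdname accessors
#' @export
setGeneric("sectorWidthDeg", function(object) standardGeneric("sectorWidthDeg"))
#' @rdname accessors
#' @export
setMethod("sectorWidthDeg", "ContactMap",
          function(object) 360 / ncol(object@contact))

#' @rdname accessors
#' @export
setGeneric("truthPerGroove", function(object) standardGeneric("truthPerGroove"))
#' @rdname accessors
#' @export
setMethod("truthPerGroove", "PhantomTruth", function(object) object@perGroove)

#' @rdname accessors
#' @export
setGeneric("truthPerPlane", function(object) standardGeneric("truthPerPlane"))
#' @rdname accessors
#' @export
setMethod("truthPerPlane", "PhantomTruth", function(object) object@perPlane)

#' @rdname accessors
#' @export
setGeneric("meanBICPercent", function(object) standardGeneric("meanBICPercent"))
#' @rdname accessors
#' @export
setMethod("meanBICPercent", "PhantomTruth", function(object) object@meanBIC)
#' @rdname accessors
#' @export
setMethod("meanBICPercent", "ImplantBIC", function(object) object@meanBIC)

#' @rdname accessors
#' @export
setGeneric("perGrooveBIC", function(object) standardGeneric("perGrooveBIC"))
#' @rdname accessors
#' @export
setMethod("perGrooveBIC", "BICResult", function(object) object@perGroove)

#' @rdname accessors
#' @export
setGeneric("perSliceBIC", function(object) standardGeneric("perSliceBIC"))
#' @rdname accessors
#' @export
setMethod("perSliceBIC", "BICResult", function(object) object@perSliceBIC)

#' @rdname accessors
#' @export
setGeneric("perAngleBIC", function(object) standardGeneric("perAngleBIC"))
#' @rdname accessors
#' @export
setMethod("perAngleBIC", "ImplantBIC", function(object) object@perAngle)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume: %d x %d x %d voxels (z,y,x), %.4g um isotropic\n",
              d[1], d[2], d[3], object@voxelSizeUm))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "CTSlice", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "CTSlice at %g deg: %d axial x %d radial pixels, %.4g um/px\n",
    object@angleDeg, d[1], d[2], object@pixelSizeUm))
})

setMethod("show", "LabelSlice", function(object) {
  tab <- tabulate(factor(object@labels, levels = .LBL), nbins = 3L)
  cat(sprintf(
    "LabelSlice at %g deg: %d x %d px (background %d, bone %d, implant %d)\n",
    object@angleDeg, nrow(object@labels), ncol(object@labels),
    tab[1], tab[2], tab[3]))
})

setMethod("show", "ImplantAxis", function(object) {
  cat(sprintf("ImplantAxis: point (%.2f, %.2f, %.2f) vx, direction (%.4f, %.4f, %.4f)\n",
              object@point[1], object@point[2], object@point[3],
              object@direction[1], object@direction[2], object@direction[3]))
})

setMethod("show", "ContactMap", function(object) {
  m <- object@contact
  cat(sprintf("ContactMap: %d grooves x %d sectors (%.3g deg), contact fraction %.3f\n",
              nrow(m), ncol(m), 360 / ncol(m), mean(m)))
})

setMethod("show", "PhantomTruth", function(object) {
  pp <- object@perPlane
  cat(sprintf("PhantomTruth: %d planes, per-plane BIC %s %%, mean %.2f %%\n",
              nrow(pp), paste(sprintf("%.1f", pp$bic_percent), collapse = "/"),
              object@meanBIC))
})

setMethod("show", "BICResult", function(object) {
  cat(sprintf("BICResult at %g deg: %d grooves, per-slice BIC %.2f %% (%s pooling)\n",
              object@angleDeg, nrow(object@perGroove), object@perSliceBIC,
              object@pooling))
})

setMethod("show", "ImplantBIC", function(object) {
  cat(sprintf("ImplantBIC: angles {%s}, per-angle BIC {%s} %%, mean %.2f %%\n",
              paste(names(object@perAngle), collapse = ", "),
              paste(sprintf("%.2f", object@perAngle), collapse = ", "),
              object@meanBIC))
})
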