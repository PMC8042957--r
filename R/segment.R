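#' Segmentation parameters for tri-class thresholding
#'
#' The bone window defaults to the intensity range 60-90 (inclusive at
#' both ends) on the 8-bit scale -- the window identified for newly formed
#' bone against histology -- and the implant class to intensities at or
#' above 200 (titanium reconstructs far above the bone window; the exact
#' cut is configurable). Everything else, including intensities between
#' the bone ceiling and the implant floor, is background ("blank": air and
#' soft tissue).
#'
#' @param bone_min,bone_max Inclusive bone window bounds.
#' @param implant_min Implant threshold; must exceed \code{bone_max}.
#' @param min_component_px If positive, 8-connected bone components
#'   smaller than this many pixels are relabeled background (speckle
#'   cleanup; off by default).
#' @return Named list of validated parameters.
#' @examples
#' segmentationConfig()
#' @export
segmentationConfig <- function(bone_min = 60, bone_max = 90,
                               implant_min = 200, min_component_px = 0) {
  if (!(bone_min <= bone_max && bone_max < implant_min)) {
    stop("need bone_min <= bone_max < implant_min")
  }
  if (min_component_px < 0) stop("min_component_px must be >= 0")
  list(bone_min = bone_min, bone_max = bone_max, implant_min = implant_min,
       min_component_px = min_component_px)
}

#' Classify a grayscale slice into background, bone and implant
#'
#' Windowed thresholding of a longitudinal slice: a pixel is implant if
#' its intensity is at or above \code{implant_min}, else bone if it lies
#' inside the inclusive bone window \code{[bone_min, bone_max]}, else
#' background. With \code{min_component_px > 0}, bone components
#' (8-connectivity) below that size are relabeled background; the cleanup
#' is idempotent. No smoothing is applied before thresholding.
#'
#' @param s A \linkS4class{CTSlice}.
#' @param cfg A list from \code{\link{segmentationConfig}} (or a
#'   compatible configuration from \code{\link{loadConfig}}).
#' @return A \linkS4class{LabelSlice}.
#' @examples
#' cfg <- phantomConfig(voxelSizeUm = 80)
#' ph <- buildPhantom(cfg, sampleContactMap(1, seed = 1))
#' ax <- estimateAxis(ph$volume)
#' sl <- extractLongitudinalSlice(ph$volume, ax, 0)
#' table(labelMatrix(classifySlice(sl)))
#' @export
classifySlice <- function(s, cfg = segmentationConfig()) {
  stopifnot(is(s, "CTSlice"))
  px <- pixels(s)
  lab <- matrix(.LBL[["BACKGROUND"]], nrow(px), ncol(px))
  lab[px >= cfg$bone_min & px <= cfg$bone_max] <- .LBL[["BONE"]]
  lab[px >= cfg$implant_min] <- .LBL[["IMPLANT"]]
  if (cfg$min_component_px > 0) {
    comp <- .label8(lab == .LBL[["BONE"]])
    if (max(comp) > 0) {
      sizes <- tabulate(comp[comp > 0], nbins = max(comp))
      drop <- which(sizes < cfg$min_component_px)
      lab[comp %in% drop] <- .LBL[["BACKGROUND"]]
    }
  }
  new("LabelSlice", labels = lab, pixelSizeUm = pixelSize(s),
      angleDeg = angleDeg(s))
}
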