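# Core BIC measurement: trace the implant thread profile in a label image,
# select the upper grooves of each side, exclude the interface voxel band,
# and score each boundary element by probing outward for bone.

#' Measurement parameters for groove-wise BIC
#'
#' Defaults follow the measurement protocol: one excluded voxel layer at
#' the bone-implant junction and the upper four grooves on each side of
#' the longitudinal slice. The per-slice value pools boundary lengths
#' (sum of contact lengths over sum of profile lengths) by default;
#' \code{pooling = "groove-mean"} averages the per-groove ratios instead.
#'
#' @param exclusion_layers Width (voxels, chessboard metric) of the
#'   interface band excluded from contact assessment.
#' @param grooves_per_side Number of upper grooves measured per side.
#' @param side_selection Measure \code{"both"} sides (default) or only
#'   \code{"left"} / \code{"right"}.
#' @param allow_fewer_grooves If TRUE, a profile with fewer grooves than
#'   requested is measured with a warning instead of an error.
#' @param pooling Per-slice pooling rule: \code{"pooled"} or
#'   \code{"groove-mean"}.
#' @return Named list of validated parameters.
#' @export
measurementConfig <- function(exclusion_layers = 1, grooves_per_side = 4,
                              side_selection = c("both", "left", "right"),
                              allow_fewer_grooves = FALSE,
                              pooling = c("pooled", "groove-mean")) {
  side_selection <- match.arg(side_selection)
  pooling <- match.arg(pooling)
  if (exclusion_layers < 0) stop("exclusion_layers must be >= 0")
  if (grooves_per_side < 1) stop("grooves_per_side must be >= 1")
  list(exclusion_layers = as.integer(exclusion_layers),
       grooves_per_side = as.integer(grooves_per_side),
       side_selection = side_selection,
       allow_fewer_grooves = isTRUE(allow_fewer_grooves),
       pooling = pooling)
}

#' ImplantProfile: traced lateral boundary of the implant cross-section
#'
#' @slot elements data.frame of boundary elements (pixel edges of length
#'   one): side, kind ("v" lateral face / "h" thread flank), row/col of
#'   the adjacent outside pixel, probe direction (dr, dc), and the axial
#'   ordering key u.
#' @slot rowDist data.frame (side, row, dist): lateral extent of the
#'   implant from its axis column, per image row -- the thread profile
#'   height used for crest detection.
#' @slot centerCol Column of the implant axis in the label image.
#' @export
setClass("ImplantProfile", representation(
  elements = "data.frame",
  rowDist = "data.frame",
  centerCol = "numeric"
))

setMethod("show", "ImplantProfile", function(object) {
  e <- object@elements
  cat(sprintf("ImplantProfile: %d boundary elements (left %d, right %d), %d implant rows\n",
              nrow(e), sum(e$side == "left"), sum(e$side == "right"),
              nrow(object@rowDist) / 2))
})

#' GrooveProfile: boundary path of one thread groove
#'
#' @slot side "left" or "right".
#' @slot indexFromTop Groove index, 1 = nearest the implant top.
#' @slot elements Boundary elements of the crest-to-crest path (see
#'   \linkS4class{ImplantProfile}).
#' @slot pathLengthPx Path length in pixel-edge units.
#' @export
setClass("GrooveProfile", representation(
  side = "character",
  indexFromTop = "integer",
  elements = "data.frame",
  pathLengthPx = "numeric"
))

setMethod("show", "GrooveProfile", function(object) {
  cat(sprintf("GrooveProfile: %s side, groove %d from top, path length %g px\n",
              object@side, object@indexFromTop, object@pathLengthPx))
})

#' Trace the lateral implant boundary of a label image
#'
#' Returns the left and right lateral boundary paths of the implant
#' region as pixel-edge elements between implant and non-implant pixels,
#' ordered top to bottom. The implant's top and bottom end faces are not
#' part of the profile. Each element carries the adjacent outside pixel
#' and the outward probe direction (radial for lateral faces, axial for
#' thread flanks), quantized to the 4-neighborhood of the staircase
#' contour.
#'
#' @param li A \linkS4class{LabelSlice} whose implant pixels form a single
#'   connected component.
#' @return An \linkS4class{ImplantProfile}.
#' @export
traceImplantProfile <- function(li) {
  stopifnot(is(li, "LabelSlice"))
  lab <- labelMatrix(li)
  mask <- lab == .LBL[["IMPLANT"]]
  if (!any(mask)) stop("no implant pixels in label image")
  ncomp <- max(.label8(mask))
  if (ncomp > 1L) {
    stop("expected a single implant component, found ", ncomp)
  }
  rows <- which(rowSums(mask) > 0)
  if (any(diff(rows) != 1L)) {
    stop("implant rows are not contiguous; cannot trace a lateral profile")
  }
  minc <- maxc <- integer(length(rows))
  for (i in seq_along(rows)) {
    cc <- which(mask[rows[i], ])
    minc[i] <- min(cc); maxc[i] <- max(cc)
  }
  center <- mean((minc + maxc) / 2)

  oneSide <- function(side) {
    edge <- if (side == "right") maxc else minc
    dc <- if (side == "right") 1L else -1L
    vert <- data.frame(side = side, kind = "v", row = rows,
                       col = edge + dc, dr = 0L, dc = dc, u = rows)
    hlist <- list()
    for (i in seq_len(length(rows) - 1L)) {
      c1 <- edge[i]; c2 <- edge[i + 1L]
      if (c1 == c2) next
      # recede: the implant narrows going down -> downward-facing flank
      # whose outside pixels sit in row i+1; otherwise it widens and the
      # flank faces upward with outside pixels in row i.
      recede <- if (side == "right") c2 < c1 else c2 > c1
      cc <- if (side == "right") {
        if (recede) (c2 + 1L):c1 else (c1 + 1L):c2
      } else {
        if (recede) c1:(c2 - 1L) else c2:(c1 - 1L)
      }
      hlist[[length(hlist) + 1L]] <- data.frame(
        side = side, kind = "h",
        row = if (recede) rows[i + 1L] else rows[i], col = cc,
        dr = if (recede) 1L else -1L, dc = 0L, u = rows[i] + 0.5)
    }
    h <- do.call(rbind, hlist)
    if (!is.null(h) && nrow(h)) {
      # concave-corner flank elements sit beside the valley wall; a purely
      # axial probe from there hugs the wall's exclusion band all the way
      # along it, so deflect it one step toward the radial direction
      # (8-neighborhood quantization of the corner normal)
      wallCol <- h$col - dc
      inb <- wallCol >= 1L & wallCol <= ncol(mask)
      corner <- inb
      corner[inb] <- mask[cbind(h$row[inb], wallCol[inb])]
      h$dc[corner] <- dc
    }
    out <- rbind(vert, h)
    out[order(out$u, out$col), ]
  }

  elements <- rbind(oneSide("left"), oneSide("right"))
  rowDist <- rbind(
    data.frame(side = "left", row = rows, dist = center - minc),
    data.frame(side = "right", row = rows, dist = maxc - center))
  new("ImplantProfile", elements = elements, rowDist = rowDist,
      centerCol = center)
}

#' Select the upper thread grooves of a traced profile
#'
#' Thread crests are detected per side as rows whose profile height
#' exceeds the midpoint between the valley and crest heights; a groove is
#' a maximal run of non-crest rows delimited by a crest on both sides
#' (so partial grooves at the implant ends are never measured). The
#' \code{grooves_per_side} grooves nearest the implant top are returned,
#' indexed 1..n from the top; each groove's boundary path runs crest to
#' crest (both flanks plus the valley).
#'
#' @param profile An \linkS4class{ImplantProfile}.
#' @param cfg A list from \code{\link{measurementConfig}}.
#' @return List of \linkS4class{GrooveProfile} objects (left side first).
#' @export
selectGrooves <- function(profile, cfg = measurementConfig()) {
  stopifnot(is(profile, "ImplantProfile"))
  sides <- switch(cfg$side_selection,
                  both = c("left", "right"), left = "left", right = "right")
  out <- list()
  for (sd in sides) {
    rd <- profile@rowDist[profile@rowDist$side == sd, ]
    rd <- rd[order(rd$row), ]
    thr <- (min(rd$dist) + max(rd$dist)) / 2
    if (max(rd$dist) - min(rd$dist) < 1) {
      stop("no crest pair found on ", sd, " side (threadless profile?)")
    }
    isCrest <- rd$dist > thr
    r <- rle(isCrest)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    grooves <- which(!r$values &
                       seq_along(r$values) > 1L &
                       seq_along(r$values) < length(r$values))
    if (!length(grooves)) {
      stop("no crest pair found on ", sd, " side (threadless profile?)")
    }
    if (length(grooves) < cfg$grooves_per_side) {
      msg <- sprintf("found %d grooves on %s side, required %d",
                     length(grooves), sd, cfg$grooves_per_side)
      if (cfg$allow_fewer_grooves) warning(msg) else stop(msg)
    }
    take <- grooves[seq_len(min(cfg$grooves_per_side, length(grooves)))]
    el <- profile@elements[profile@elements$side == sd, ]
    for (gi in seq_along(take)) {
      ua <- rd$row[starts[take[gi]]]
      ub <- rd$row[ends[take[gi]]]
      ge <- el[el$u >= ua - 0.5 & el$u <= ub + 0.5, ]
      out[[length(out) + 1L]] <- new("GrooveProfile", side = sd,
                                     indexFromTop = as.integer(gi),
                                     elements = ge,
                                     pathLengthPx = nrow(ge))
    }
  }
  out
}

#' Measure groove-wise and per-slice BIC on a label image
#'
#' Builds the interface exclusion band -- all non-implant pixels within
#' \code{exclusion_layers} of the implant in the chessboard metric (one
#' layer = one full voxel shell including diagonals) -- then scores every
#' boundary element of every groove: stepping outward from the element
#' along its probe direction, past any band pixels, the element is in
#' contact if and only if the first pixel beyond the band is bone. BIC is
#' 100 x contact length / profile length per groove; the per-slice value
#' pools lengths over all measured grooves (or averages groove ratios
#' under \code{pooling = "groove-mean"}).
#'
#' @param li The \linkS4class{LabelSlice} the grooves were traced on.
#' @param grooves List of \linkS4class{GrooveProfile} from
#'   \code{\link{selectGrooves}}.
#' @param cfg A list from \code{\link{measurementConfig}}.
#' @return A \linkS4class{BICResult}.
#' @export
measureBIC <- function(li, grooves, cfg = measurementConfig()) {
  stopifnot(is(li, "LabelSlice"), length(grooves) >= 1L)
  lab <- labelMatrix(li)
  mask <- lab == .LBL[["IMPLANT"]]
  band <- .dilateChessboard(mask, cfg$exclusion_layers) & !mask
  nr <- nrow(lab); nc <- ncol(lab)

  probe <- function(row, col, dr, dc) {
    while (TRUE) {
      if (row < 1L || row > nr || col < 1L || col > nc) {
        stop("groove path leaves the image during contact probing")
      }
      if (!band[row, col] && !mask[row, col]) {
        return(lab[row, col] == .LBL[["BONE"]])
      }
      row <- row + dr; col <- col + dc
    }
  }

  res <- lapply(grooves, function(g) {
    e <- g@elements
    hit <- vapply(seq_len(nrow(e)), function(i) {
      probe(e$row[i], e$col[i], e$dr[i], e$dc[i])
    }, logical(1))
    data.frame(side = g@side, groove = g@indexFromTop,
               contact_px = sum(hit), total_px = nrow(e),
               bic_percent = 100 * sum(hit) / nrow(e))
  })
  perGroove <- do.call(rbind, res)
  perSlice <- if (cfg$pooling == "pooled") {
    100 * sum(perGroove$contact_px) / sum(perGroove$total_px)
  } else {
    mean(perGroove$bic_percent)
  }
  new("BICResult", perGroove = perGroove, perSliceBIC = perSlice,
      angleDeg = angleDeg(li), pooling = cfg$pooling)
}

#' Multi-angle mean BIC for one implant
#'
#' Averages per-slice BIC values measured at distinct angles into the
#' implant-level summary (the unweighted arithmetic mean of the per-slice
#' values).
#'
#' @param results Non-empty list of per-slice \linkS4class{BICResult}
#'   objects at distinct angles.
#' @return An \linkS4class{ImplantBIC}.
#' @examples
#' ## mean of per-slice BICs 40, 50, 60, 70 is 55
#' @export
meanBIC <- function(results) {
  if (!length(results)) stop("need at least one per-slice result")
  stopifnot(all(vapply(results, is, logical(1), "BICResult")))
  ang <- vapply(results, angleDeg, numeric(1))
  if (anyDuplicated(ang)) stop("per-slice results must have distinct angles")
  per <- vapply(results, perSliceBIC, numeric(1))
  names(per) <- ang
  new("ImplantBIC", perAngle = per, meanBIC = mean(per))
}
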