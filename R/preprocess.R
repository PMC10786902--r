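# Photograph preprocessing: eye/marker sub-images, square resize with zero
# padding, and mapping masks back to original coordinates.
#
# The acquisition protocol centers the face so that the left and right eyes
# fall in the two vertical halves of the frame and the forehead marker in the
# middle half; the network input is a 512 x 512 square obtained by scaling
# the longer side to 512, preserving the aspect ratio, and zero-padding the
# remainder.  All measurement downstream happens in original-image
# coordinates after mapping masks back, so the marker calibration and the eye
# measurements share one scale.

#' Split a photograph into left-eye, right-eye and marker sub-images
#'
#' The two eye images are the vertical halves (columns [0, floor(W/2)) and
#' [floor(W/2), W)); the marker crop is the middle half (columns
#' [floor(W/4), floor(3W/4))), full height.
#'
#' @param image numeric array (height x width or height x width x channels).
#' @return list with elements \code{leftEye}, \code{rightEye},
#'   \code{markerCrop}.
#' @export
splitImage <- function(image) {
  d <- dim(image)
  .stopIf(is.null(d) || length(d) < 2L, "image must be a matrix or array")
  W <- d[2]
  .stopIf(W < 4L, "image width must be at least 4 pixels")
  half <- W %/% 2L
  q1 <- W %/% 4L
  q3 <- (3L * W) %/% 4L
  sel <- function(cols) {
    if (length(d) == 2L) image[, cols, drop = FALSE]
    else image[, cols, , drop = FALSE]
  }
  list(leftEye = sel(seq_len(half)),
       rightEye = sel((half + 1L):W),
       markerCrop = sel((q1 + 1L):q3))
}

# resize a single-channel matrix to exact target dims
.resizeMatrix <- function(m, outRows, outCols, bilinear = TRUE) {
  filt <- if (bilinear) "bilinear" else "none"
  as.matrix(EBImage::resize(EBImage::as.Image(m), w = outRows, h = outCols,
                            filter = filt))
}

#' Resize an image to a square with zero padding
#'
#' Scales the longer dimension to \code{side} and the shorter by the same
#' factor (rounded to the nearest pixel), anchors the content top-left and
#' zero-pads the right or bottom remainder.
#'
#' @param image matrix or 3-channel array.
#' @param side output square side, default 512.
#' @param bilinear use bilinear interpolation (TRUE for images; masks should
#'   be resized with \code{FALSE} to stay binary).
#' @return list(resized, transform) where \code{transform} is a
#'   \code{\link{ResizeTransform-class}} recording everything needed to invert
#'   the operation.
#' @export
resizeWithPadding <- function(image, side = 512L, bilinear = TRUE) {
  d <- dim(image)
  .stopIf(is.null(d) || length(d) < 2L || d[1] < 1L || d[2] < 1L,
          "image must be a nonempty matrix or array")
  .stopIf(side < 2L, "side must be at least 2")
  side <- as.integer(side)
  H <- d[1]; W <- d[2]
  scale <- side / max(W, H)
  outH <- if (H >= W) side else as.integer(round(H * scale))
  outW <- if (W >= H) side else as.integer(round(W * scale))
  nch <- if (length(d) == 3L) d[3] else 1L
  out <- array(0, c(side, side, nch))
  for (ch in seq_len(nch)) {
    m <- if (length(d) == 3L) image[, , ch] else image
    out[seq_len(outH), seq_len(outW), ch] <-
      .resizeMatrix(m, outH, outW, bilinear = bilinear)
  }
  if (length(d) == 2L) out <- out[, , 1L]
  t <- new("ResizeTransform", scale = scale,
           padRightPx = side - outW, padBottomPx = side - outH,
           inputSize = c(W, H), outputSize = c(side, side))
  list(resized = out, transform = t)
}

#' Map a mask from the padded square frame back to original coordinates
#'
#' Strips the zero padding and rescales the content region to the original
#' dimensions with nearest-neighbour interpolation so the mask stays binary.
#'
#' @param mask logical or 0/1 matrix with dimensions equal to the transform's
#'   output size.
#' @param t a \code{ResizeTransform} from \code{\link{resizeWithPadding}}.
#' @return logical matrix of the original dimensions.
#' @export
maskToOriginal <- function(mask, t) {
  stopifnot(is(t, "ResizeTransform"))
  mask <- .asMask(mask)
  side <- t@outputSize[1]
  .stopIf(nrow(mask) != side || ncol(mask) != side,
          "mask dimensions (", nrow(mask), " x ", ncol(mask),
          ") do not match the transform output size (", side, " x ", side, ")")
  contentH <- side - t@padBottomPx
  contentW <- side - t@padRightPx
  content <- mask[seq_len(contentH), seq_len(contentW), drop = FALSE]
  W <- t@inputSize[1]; H <- t@inputSize[2]
  if (contentH == H && contentW == W) return(content)
  .resizeMatrix(content * 1, H, W, bilinear = FALSE) > 0.5
}
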