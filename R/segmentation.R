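# Segmentation backend contract and mask scoring.
#
# The measurement pipeline is decoupled from how masks are produced: any
# backend that returns one binary mask per requested class (sclera, cornea,
# light_reflex, marker) can drive it.  Three desk-scale backends ship here:
#
#   * oracle   -- returns the synthetic scene's own ground-truth masks;
#   * color    -- nearest-reference-color classification of the rendered
#                 flat-color image, followed by largest-component cleanup;
#   * external -- reads mask PNGs from a directory (e.g. exported by a
#                 semantic-segmentation network).
#
# A neural-network adapter would plug in behind the same contract -- the
# intended deployment is one semantic-segmentation model (e.g. DeepLab V3+)
# per class, trained on a few hundred annotated photographs with left-right
# augmentation, a 0.6/0.2/0.2 train/val/test split, batch size 32, ~30
# epochs, AdamW at learning rate 1e-3.  No trained weights ship with the
# package, so that adapter is not implemented here.

.knownClasses <- c("sclera", "cornea", "light_reflex", "marker")

#' Segmentation backends
#'
#' Construct a segmentation backend for \code{\link{segmentTargets}}.
#'
#' @param directory for \code{externalBackend}: directory containing
#'   \code{mask_<class>.png} files.
#' @return a backend object (list with class \code{"lidBackend"}).
#' @export
oracleBackend <- function() {
  structure(list(name = "oracle",
                 fun = function(x, targets) {
                   .stopIf(!is(x, "Scene"),
                           "oracle backend requires a Scene object")
                   x@masks[targets]
                 }),
            class = "lidBackend")
}

#' @rdname oracleBackend
#' @export
colorBackend <- function() {
  structure(list(name = "color",
                 fun = function(x, targets) {
                   img <- if (is(x, "Scene")) x@image else x
                   .stopIf(length(img) == 0L,
                           "color backend requires a rendered image")
                   .colorRuleMasks(img, targets)
                 }),
            class = "lidBackend")
}

#' @rdname oracleBackend
#' @export
externalBackend <- function(directory) {
  force(directory)
  structure(list(name = "external",
                 fun = function(x, targets) {
                   out <- list()
                   for (cl in targets) {
                     f <- file.path(directory, paste0("mask_", cl, ".png"))
                     .stopIf(!file.exists(f),
                             "external backend: missing mask file ", f)
                     out[[cl]] <- png::readPNG(f) > 0.5
                   }
                   out
                 }),
            class = "lidBackend")
}

.colorRuleMasks <- function(img, targets) {
  refs <- .sceneColors
  H <- dim(img)[1]; W <- dim(img)[2]
  px <- matrix(img, H * W, 3)
  d <- vapply(refs, function(cl) {
    (px[, 1] - cl[1])^2 + (px[, 2] - cl[2])^2 + (px[, 3] - cl[3])^2
  }, numeric(H * W))
  lab <- max.col(-d, ties.method = "first")
  out <- list()
  for (cl in targets) {
    m <- matrix(lab == match(cl, names(refs)), H, W)
    if (cl == "cornea") # the light reflex sits on the cornea
      m <- m | matrix(lab == match("light_reflex", names(refs)), H, W)
    if (any(m)) m <- largestComponent(m)
    out[[cl]] <- m
  }
  out
}

#' Run a segmentation backend
#'
#' @param backend a backend from \code{\link{oracleBackend}},
#'   \code{\link{colorBackend}} or \code{\link{externalBackend}}.
#' @param x input: a \code{Scene} (oracle/color) or an RGB array (color); the
#'   external backend ignores it.
#' @param targets character vector of class names to segment, a subset of
#'   sclera, cornea, light_reflex, marker.
#' @param frame coordinate-frame tag recorded on the bundle.
#' @return a \code{\link{SegmentationBundle-class}}.
#' @export
segmentTargets <- function(backend, x,
                           targets = c("sclera", "cornea", "light_reflex",
                                       "marker"),
                           frame = "original") {
  stopifnot(inherits(backend, "lidBackend"))
  bad <- setdiff(targets, .knownClasses)
  .stopIf(length(bad) > 0,
          "unknown segmentation class(es): ", paste(bad, collapse = ", "))
  masks <- tryCatch(backend$fun(x, targets), error = function(e) {
    stop("segmentation backend '", backend$name, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })
  masks <- lapply(masks, .asMask)
  if ("light_reflex" %in% targets && !any(masks$light_reflex))
    warning("light reflex not detected (empty mask)")
  new("SegmentationBundle", masks = masks, frame = frame)
}

#' Mean intersection-over-union between two mask bundles
#'
#' IoU per class is |pred & truth| / |pred | truth|; a class whose union is
#' empty scores 1 (vacuous agreement).  The mean is the arithmetic mean over
#' the shared classes.
#'
#' @param pred,truth \code{SegmentationBundle}s with the same classes and
#'   dimensions.
#' @return list with \code{per_class_iou} (named numeric) and
#'   \code{mean_iou}.
#' @export
meanIoU <- function(pred, truth) {
  stopifnot(is(pred, "SegmentationBundle"), is(truth, "SegmentationBundle"))
  cls <- names(pred@masks)
  .stopIf(!setequal(cls, names(truth@masks)),
          "pred and truth must contain the same classes")
  iou <- vapply(cls, function(cl) {
    a <- pred@masks[[cl]]; b <- truth@masks[[cl]]
    .stopIf(!all(dim(a) == dim(b)), "dimension mismatch for class ", cl)
    u <- sum(a | b)
    if (u == 0) 1 else sum(a & b) / u
  }, numeric(1))
  list(per_class_iou = iou, mean_iou = mean(iou))
}
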