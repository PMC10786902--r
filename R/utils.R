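# Shared raster helpers.
#
# Raster convention used throughout the package: masks are logical matrices in
# row-major image order (row 1 = top image row, y increases downward).  Pixel
# (r, c) in 0-based coordinates lives at matrix element [r + 1, c + 1] and
# occupies the unit square [c, c+1) x [r, r+1); its center is (r + 0.5,
# c + 0.5).  All exported point values are c(row, col) in these 0-based
# lattice coordinates.

.isMask <- function(x) {
  is.matrix(x) && (is.logical(x) || (is.numeric(x) && all(x %in% c(0, 1))))
}

.asMask <- function(x, what = "mask") {
  if (!.isMask(x)) stop(what, " must be a binary (logical or 0/1) matrix")
  if (!is.logical(x)) x <- x > 0.5
  x
}

#' Label connected components with 8-connectivity
#'
#' Thin wrapper over \code{EBImage::bwlabel} (4-connected) that merges labels
#' touching diagonally, giving 8-connected components.
#'
#' @param mask logical matrix.
#' @return integer matrix of labels, 0 = background.
#' @keywords internal
labelComponents8 <- function(mask) {
  mask <- .asMask(mask)
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  # union-find over labels that touch across a diagonal
  parent <- seq_len(nlab)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1L), if (off[2] == 1L) seq_len(nc - 1L) else 2:nc]
    b <- lab[2:nr, if (off[2] == 1L) 2:nc else seq_len(nc - 1L)]
    touch <- a > 0L & b > 0L & a != b
    if (any(touch)) {
      pairs <- unique(cbind(a[touch], b[touch]))
      for (i in seq_len(nrow(pairs))) {
        ra <- findRoot(pairs[i, 1]); rb <- findRoot(pairs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(nlab), findRoot, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

#' Keep the largest 8-connected foreground component
#'
#' @param mask logical matrix.
#' @param warnMultiple warn when more than one component is present.
#' @return logical matrix with only the largest component retained.
#' @keywords internal
largestComponent <- function(mask, warnMultiple = FALSE) {
  mask <- .asMask(mask)
  if (!any(mask)) return(mask)
  lab <- labelComponents8(mask)
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) > 1L && warnMultiple) {
    warning("mask has ", length(sizes),
            " connected components; using the largest")
  }
  lab == which.max(sizes)
}

# round half away from zero at `digits` decimals (printed partition intervals)
roundHalfAway <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

.stopIf <- function(cond, ...) if (cond) stop(..., call. = FALSE)

# deterministic child seeds below 2^31, derived from a master seed
deriveSeeds <- function(seed, n) {
  stopifnot(n >= 0)
  if (n == 0L) return(integer(0))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
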