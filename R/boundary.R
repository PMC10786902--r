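# Crack-boundary tracing and corner-corrected (quadrant) length measurement.
#
# The boundary of a binary region is traced along the pixel edges (the
# "crack" boundary), so a single foreground pixel yields the four unit edges
# of its square.  Raw digital perimeters overestimate smooth objects badly
# (a 45-degree staircase costs |cos| + |sin| = sqrt(2) times its true
# length), so lengths here are measured on the taut (minimum enclosing
# convex) polygon of the crack boundary -- the convex hull of the boundary
# vertices, the classical convergent perimeter estimator for digitized convex
# shapes.  On that polygon the quadrant correction replaces every 90-degree
# corner (two adjacent half-edges, total 1 px) by a quarter-circle arc of
# radius 0.5 px (length pi/4): an isolated pixel becomes a circle of diameter
# 1, a 2 x 2 block a rounded square of perimeter 4 + pi, and rasterized disks
# converge to pi * d with the error shrinking as the radius grows.  Eyelid
# margins and the corneal outline are convex by anatomy, which is what makes
# the taut polygon the right substrate; concavities (e.g. pathological
# contour bumps) are bridged by the hull, where the margin length becomes a
# lower bound.

#' Construct a BoundaryChain
#'
#' @param vertices n x 2 numeric matrix of (row, col) lattice vertices.
#' @param closed logical; closed chains must repeat their first vertex last.
#' @return a \code{\link{BoundaryChain-class}} object.
#' @export
boundaryChain <- function(vertices, closed = FALSE) {
  new("BoundaryChain", vertices = vertices, closed = closed)
}

#' Trace the outer crack boundary of a binary mask
#'
#' Follows the pixel-edge boundary of the largest 8-connected component,
#' keeping the foreground on the right of the walking direction, starting at
#' the top-left corner of the topmost-leftmost foreground pixel.  Returns a
#' closed chain of lattice vertices in 0-based (row, col) coordinates.
#'
#' @param mask logical matrix.
#' @return a closed \code{BoundaryChain}.
#' @export
traceBoundary <- function(mask) {
  mask <- .asMask(mask)
  .stopIf(!any(mask), "cannot trace boundary: mask is empty")
  mask <- largestComponent(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- function(r, c) { # 0-based pixel query
    r >= 0L && r < nr && c >= 0L && c < nc && mask[r + 1L, c + 1L]
  }
  idx <- which(mask)
  r0 <- min((idx - 1L) %% nr)
  c0 <- min((which(mask[r0 + 1L, ]) - 1L))
  # directions in (dr, dc): 1=E, 2=S, 3=W, 4=N
  dirs <- rbind(c(0L, 1L), c(1L, 0L), c(0L, -1L), c(-1L, 0L))
  # right-ahead / left-ahead pixel offsets (top-left corners) per direction,
  # relative to the current vertex
  ra <- rbind(c(0L, 0L), c(0L, -1L), c(-1L, -1L), c(-1L, 0L))
  la <- rbind(c(-1L, 0L), c(0L, 0L), c(0L, -1L), c(-1L, -1L))
  maxSteps <- 4L * (sum(mask) + nr * nc)
  v <- c(r0, c0); d <- 1L
  out <- matrix(NA_real_, min(maxSteps, 4L * sum(mask) + 8L), 2L)
  out[1L, ] <- v
  n <- 1L
  repeat {
    v <- v + dirs[d, ]
    n <- n + 1L
    if (n > nrow(out)) out <- rbind(out, matrix(NA_real_, nrow(out), 2L))
    out[n, ] <- v
    if (v[1] == r0 && v[2] == c0) break
    raFg <- fg(v[1] + ra[d, 1], v[2] + ra[d, 2])
    laFg <- fg(v[1] + la[d, 1], v[2] + la[d, 2])
    if (!raFg) {
      d <- if (d == 4L) 1L else d + 1L        # turn right
    } else if (laFg) {
      d <- if (d == 1L) 4L else d - 1L        # turn left
    }                                          # else straight
    .stopIf(n > maxSteps, "boundary tracing did not terminate")
  }
  boundaryChain(out[seq_len(n), , drop = FALSE], closed = TRUE)
}

# turn classification at interior vertices of a chain: +1 convex (right turn
# with foreground kept on the right), -1 concave, 0 straight
.chainTurns <- function(vertices, closed) {
  d <- diff(vertices)
  if (closed) {
    # turn at each vertex between consecutive edges, including the start/end
    # vertex (edge n-1 -> edge 1)
    prev <- rbind(d[nrow(d), ], d[-nrow(d), , drop = FALSE])
    nxt <- d
  } else {
    prev <- d[-nrow(d), , drop = FALSE]
    nxt <- d[-1L, , drop = FALSE]
  }
  cross <- prev[, 1] * nxt[, 2] - prev[, 2] * nxt[, 1]
  -sign(cross) # convex corners have cross = -1 under this traversal
}

# number of (near-)exact 90-degree turns along a polygon path; edges is the
# matrix of consecutive edge vectors
.rightAngleTurns <- function(edges) {
  if (nrow(edges) < 2L) return(0L)
  e1 <- edges[-nrow(edges), , drop = FALSE]
  e2 <- edges[-1L, , drop = FALSE]
  dots <- rowSums(e1 * e2)
  len1 <- sqrt(rowSums(e1^2)); len2 <- sqrt(rowSums(e2^2))
  sum(abs(dots) < 1e-9 & len1 >= 0.5 - 1e-9 & len2 >= 0.5 - 1e-9)
}

# closed convex-hull cycle (vertices, first not repeated) of a vertex set
.hullCycle <- function(v) {
  h <- grDevices::chull(v[, 2], v[, 1])
  v[h, , drop = FALSE]
}

.pathLengthCorrected <- function(path, closed) {
  edges <- diff(path)
  if (closed) {
    total <- sum(sqrt(rowSums(edges^2)))
    loopEdges <- rbind(edges, edges[1L, ])
    n90 <- .rightAngleTurns(loopEdges)
  } else {
    total <- sum(sqrt(rowSums(edges^2)))
    n90 <- .rightAngleTurns(edges)
  }
  total - n90 * (1 - pi / 4)
}

#' Corner-corrected (quadrant) perimeter of a binary mask
#'
#' Traces the crack boundary of the (largest component of the) mask, takes
#' its taut polygon (the convex hull of the boundary vertices), and sums the
#' polygon's edge lengths, replacing each 90-degree corner by a
#' quarter-circle arc of radius 0.5 px: the corner's two adjacent half-edges
#' (total 1 px) become an arc of length pi/4.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return perimeter in pixels.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
#' quadrantPerimeter(m) # pi: a single pixel counts as a circle of diameter 1
#' @export
quadrantPerimeter <- function(mask) {
  mask <- .asMask(mask)
  .stopIf(!any(mask), "cannot measure perimeter: mask is empty")
  lab <- labelComponents8(mask)
  if (max(lab) > 1L)
    warning("mask has multiple components; measuring the largest")
  chain <- traceBoundary(mask)
  v <- chain@vertices[-nrow(chain@vertices), , drop = FALSE]
  hull <- .hullCycle(v)
  .pathLengthCorrected(rbind(hull, hull[1L, , drop = FALSE]), closed = TRUE)
}

# mean distance from points to a polyline (used to pick the hull path lying
# on the chain's side)
.meanDistToPath <- function(pts, path) {
  if (nrow(path) < 2L) return(mean(sqrt((pts[, 1] - path[1, 1])^2 +
                                        (pts[, 2] - path[1, 2])^2)))
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(path) - 1L)) {
    p <- path[i, ]; q <- path[i + 1L, ]
    e <- q - p
    L2 <- sum(e^2)
    t <- ((pts[, 1] - p[1]) * e[1] + (pts[, 2] - p[2]) * e[2]) / L2
    t[t < 0] <- 0; t[t > 1] <- 1
    d2 <- (pts[, 1] - (p[1] + t * e[1]))^2 + (pts[, 2] - (p[2] + t * e[2]))^2
    best <- pmin(best, d2)
  }
  mean(sqrt(best))
}

#' Corner-corrected length of an open boundary chain
#'
#' Measures the taut path of the chain: the convex-hull path between the two
#' chain endpoints lying on the chain's side, with the same 90-degree
#' quarter-arc corner rule as \code{\link{quadrantPerimeter}} applied to its
#' interior turns, converted to millimetres.
#'
#' @param chain an open \code{BoundaryChain}.
#' @param cal a \code{\link{calibrate}} result; use
#'   \code{calibrate(1, 1)} for lengths in pixels.
#' @return length in millimetres.
#' @export
marginLength <- function(chain, cal) {
  stopifnot(is(chain, "BoundaryChain"), is(cal, "Calibration"))
  .stopIf(chain@closed,
          "marginLength expects an open chain; use quadrantPerimeter for closed boundaries")
  v <- chain@vertices
  a <- v[1L, ]; b <- v[nrow(v), ]
  # collinear chain: taut path is the straight segment
  e <- b - a
  offs <- (v[, 1] - a[1]) * e[2] - (v[, 2] - a[2]) * e[1]
  if (all(abs(offs) < 1e-9))
    return(sqrt(sum(e^2)) * cal@mmPerPx)
  hull <- .hullCycle(v)
  ia <- which(hull[, 1] == a[1] & hull[, 2] == a[2])[1]
  ib <- which(hull[, 1] == b[1] & hull[, 2] == b[2])[1]
  extra <- 0
  if (is.na(ia)) {
    # endpoint just inside the hull (snapped cut vertex off the extreme tip):
    # attach it to the nearest hull vertex with a short connector
    d2 <- (hull[, 1] - a[1])^2 + (hull[, 2] - a[2])^2
    ia <- which.min(d2)
    extra <- extra + sqrt(d2[ia])
  }
  if (is.na(ib)) {
    d2 <- (hull[, 1] - b[1])^2 + (hull[, 2] - b[2])^2
    ib <- which.min(d2)
    extra <- extra + sqrt(d2[ib])
  }
  if (ia == ib) return((sqrt(sum(e^2)) + extra) * cal@mmPerPx)
  n <- nrow(hull)
  idx1 <- if (ia <= ib) ia:ib else c(ia:n, 1:ib)
  idx2 <- if (ib <= ia) ib:ia else c(ib:n, 1:ia)
  p1 <- hull[idx1, , drop = FALSE]
  p2 <- hull[rev(idx2), , drop = FALSE] # both oriented a -> b
  path <- if (.meanDistToPath(v, p1) <= .meanDistToPath(v, p2)) p1 else p2
  (.pathLengthCorrected(path, closed = FALSE) + extra) * cal@mmPerPx
}
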