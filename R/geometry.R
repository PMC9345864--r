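# Plane-projection and line-angle primitives the posture features are built
# from. All angle functions work on 2D in-plane points (u horizontal, v
# vertical) and are vectorised over rows; exported entry points reject
# degenerate segments, the internal .safe variants return NA for them so
# frame-level extraction can drop bad frames instead of aborting.

.asPlaneMatrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2L, byrow = FALSE)
  p <- as.matrix(p)
  if (ncol(p) != 2L) stop("plane points need two coordinates (u, v)")
  p
}

#' Project a 3D point onto a body plane
#'
#' The coronal (frontal) plane keeps the lateral and vertical coordinates
#' `(X, Y)`; the sagittal plane keeps depth and vertical `(Z, Y)`. In both
#' cases the second in-plane coordinate `v` is the vertical axis, so angles
#' to the vertical line of the ground can be measured in-plane.
#'
#' @param p numeric vector `c(x, y, z)` in metres, or an n x 3 matrix.
#' @param plane `"coronal"` or `"sagittal"`.
#' @return an n x 2 matrix with columns `u`, `v` (a 1-row matrix for a
#'   single point).
#' @examples
#' projectPoint(c(0.3, 1.2, 2.0), "coronal")   # (0.3, 1.2)
#' projectPoint(c(0.3, 1.2, 2.0), "sagittal")  # (2.0, 1.2)
#' @export
projectPoint <- function(p, plane = c("coronal", "sagittal")) {
  plane <- match.arg(plane)
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  p <- as.matrix(p)
  if (ncol(p) != 3L) stop("points need three coordinates (x, y, z)")
  if (!all(is.finite(p))) stop("non-finite coordinate")
  u <- if (plane == "coronal") p[, 1L] else p[, 3L]
  cbind(u = u, v = p[, 2L])
}

.angleToVerticalSafe <- function(a, b) {
  a <- .asPlaneMatrix(a); b <- .asPlaneMatrix(b)
  du <- b[, 1L] - a[, 1L]
  dv <- b[, 2L] - a[, 2L]
  out <- atan2(abs(du), abs(dv)) * 180 / pi
  out[du == 0 & dv == 0] <- NA_real_
  out
}

#' Acute angle between a segment and the vertical
#'
#' The unsigned angle in `[0, 90]` degrees between the undirected line
#' through two in-plane points and the vertical line of the ground:
#' `atan(|du| / |dv|)`, 90 when the segment is horizontal.
#'
#' @param a,b in-plane points (length-2 vectors or n x 2 matrices).
#' @return angle(s) in degrees.
#' @examples
#' angleToVertical(c(0, 0), c(0, 1))  # 0
#' angleToVertical(c(0, 0), c(1, 1))  # 45
#' @export
angleToVertical <- function(a, b) {
  out <- .angleToVerticalSafe(a, b)
  if (anyNA(out)) stop("degenerate segment: coincident points")
  out
}

.angleBetweenSafe <- function(a1, a2, b1, b2) {
  a1 <- .asPlaneMatrix(a1); a2 <- .asPlaneMatrix(a2)
  b1 <- .asPlaneMatrix(b1); b2 <- .asPlaneMatrix(b2)
  u <- a2 - a1
  w <- b2 - b1
  nu <- sqrt(rowSums(u^2))
  nw <- sqrt(rowSums(w^2))
  cosang <- rowSums(u * w) / (nu * nw)
  cosang <- pmin(1, pmax(-1, cosang))
  out <- 180 - acos(cosang) * 180 / pi
  out[nu == 0 | nw == 0] <- NA_real_
  out
}

#' Deviation-from-collinearity angle between two segments
#'
#' Returns 180 degrees minus the angle between the direction vectors
#' `a2 - a1` and `b2 - b1`, so an erect configuration (one segment pointing
#' down, the other up from a shared origin) scores 0 and increasing flexion
#' increases the value; range `[0, 180]`.
#'
#' @param a1,a2 first segment endpoints (vectors or n x 2 matrices).
#' @param b1,b2 second segment endpoints.
#' @return angle(s) in degrees.
#' @examples
#' angleBetween(c(0, 1), c(0, 0), c(0, 1), c(0, 2))  # 0: straight trunk
#' angleBetween(c(0, 1), c(0, 0), c(0, 1), c(1, 2))  # 45
#' @export
angleBetween <- function(a1, a2, b1, b2) {
  out <- .angleBetweenSafe(a1, a2, b1, b2)
  if (anyNA(out)) stop("degenerate segment: zero-length direction")
  out
}

.perpDistanceSafe <- function(p, l1, l2) {
  p <- .asPlaneMatrix(p); l1 <- .asPlaneMatrix(l1); l2 <- .asPlaneMatrix(l2)
  d <- l2 - l1
  nd <- sqrt(rowSums(d^2))
  cross <- d[, 1L] * (p[, 2L] - l1[, 2L]) - d[, 2L] * (p[, 1L] - l1[, 1L])
  out <- abs(cross) / nd
  out[nd == 0] <- NA_real_
  out
}

#' Perpendicular distance from a point to a line
#'
#' Distance from `p` to the infinite line through `l1` and `l2`, via the 2D
#' cross-product formula; always non-negative.
#'
#' @param p in-plane point(s).
#' @param l1,l2 two distinct points on the line.
#' @return distance(s) in the input units (metres for landmark data).
#' @examples
#' perpDistance(c(1, 5), c(0, 0), c(0, 10))  # 1
#' @export
perpDistance <- function(p, l1, l2) {
  out <- .perpDistanceSafe(p, l1, l2)
  if (anyNA(out)) stop("degenerate line: coincident points")
  out
}
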