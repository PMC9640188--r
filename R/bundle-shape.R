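#' Least-squares circle fit to a bundle trace
#'
#' Fits a circle to tracked points along a microtubule bundle (typically a
#' 10-point trace with the first and last points at the spindle poles): an
#' algebraic (Kasa) fit followed by geometric Gauss-Newton refinement of the
#' sum of squared radial residuals. The fitted radius is the bundle's radius of
#' curvature. 3D traces are first projected onto their best-fit plane, since
#' traces are made on rotated 2D images. Collinear points yield an
#' infinite-radius result flagged via \code{is_line} (distinct from failure).
#'
#' @param points n x 2 or n x 3 matrix of positions, um (n >= 3).
#' @param collinear_tol relative tolerance below which the points are treated
#'   as collinear.
#' @param refine logical; run the geometric refinement (default) or return the
#'   algebraic fit.
#' @return An object of class \code{"circle_fit"}: \code{center} (in the
#'   fitting plane), \code{radius} (um, Inf for lines), \code{rms_residual}
#'   (um), \code{contour_length} (um), \code{is_line}.
#' @examples
#' fit_circle(rbind(c(1, 0), c(0, 1), c(-1, 0)))  # unit circle
#' @export
fit_circle <- function(points, collinear_tol = 1e-9, refine = TRUE) {
  pts <- rbind_pts(points)
  if (nrow(pts) < 3) stop("circle fit needs at least 3 points")
  if (ncol(pts) == 3) pts <- project_to_plane(pts)
  ctr <- colMeans(pts)
  x <- pts[, 1] - ctr[1]; y <- pts[, 2] - ctr[2]
  clen <- contour_length(points)

  # collinearity via the smaller singular value of the centered coordinates
  sv <- svd(cbind(x, y), nu = 0, nv = 0)$d
  if (sv[2] <= collinear_tol * max(sv[1], 1)) {
    return(structure(list(center = c(NA_real_, NA_real_), radius = Inf,
                          rms_residual = 0, contour_length = clen,
                          is_line = TRUE), class = "circle_fit"))
  }

  # Kasa algebraic fit: minimize ||x^2+y^2 - 2ax - 2by - c||
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- unname(stats::lsfit(A, b, intercept = FALSE)$coefficients)
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(sol[3] + cx^2 + cy^2)

  if (refine) {
    par <- c(cx, cy, r)
    for (it in 1:50) {
      dx <- x - par[1]; dy <- y - par[2]
      di <- sqrt(dx^2 + dy^2)
      res <- di - par[3]
      J <- cbind(-dx / di, -dy / di, -1)
      step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 3))
      par <- par + step
      if (sqrt(sum(step^2)) < 1e-12 * max(1, par[3])) break
    }
    cx <- par[1]; cy <- par[2]; r <- par[3]
  }
  di <- sqrt((x - cx)^2 + (y - cy)^2)
  structure(list(center = c(cx + ctr[1], cy + ctr[2]), radius = r,
                 rms_residual = sqrt(mean((di - r)^2)),
                 contour_length = clen, is_line = FALSE),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  if (x$is_line) {
    cat("circle_fit: collinear points (infinite radius)\n")
  } else {
    cat(sprintf(
      "circle_fit: center (%.3f, %.3f), radius %.3f um, rms residual %.2e um\n",
      x$center[1], x$center[2], x$radius, x$rms_residual))
  }
  cat(sprintf("  contour length %.3f um\n", x$contour_length))
  invisible(x)
}

# orthogonal projection of 3D points onto their best-fit (PCA) plane
project_to_plane <- function(pts) {
  ctr <- colMeans(pts)
  s <- svd(sweep(pts, 2, ctr))
  sweep(pts, 2, ctr) %*% s$v[, 1:2]
}

#' Contour length of a bundle trace
#'
#' Cumulative distance along consecutive trace points, from the first to the
#' last point.
#'
#' @param points n x 2 or n x 3 matrix of positions, um (n >= 2).
#' @return length, um.
#' @export
contour_length <- function(points) {
  pts <- rbind_pts(points)
  if (nrow(pts) < 2) stop("contour length needs at least 2 points")
  sum(sqrt(rowSums(diff(pts)^2)))
}
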