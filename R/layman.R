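# Layman community-wide metrics of a point cloud in d13C x d15N space.

#' Layman community metrics in bivariate isotope space
#'
#' Computes the six community-wide metrics of a group's point cloud in
#' \eqn{\delta^{13}}C \eqn{\times} \eqn{\delta^{15}}N space:
#' \describe{
#'   \item{dC_range, dN_range}{max - min per axis (basal resource and trophic
#'     range).}
#'   \item{TA}{total area of the 2-D convex hull (per-mil squared; proxy for
#'     total niche space). Requires n >= 3; 0 for collinear points.}
#'   \item{CD}{mean Euclidean distance to the arithmetic centroid (trophic
#'     diversity).}
#'   \item{NND, SDNND}{mean and sample standard deviation of each point's
#'     distance to its nearest distinct point (trophic redundancy and
#'     evenness). Require n >= 2; duplicated points give NND contributions
#'     of 0.}
#' }
#' Metrics whose minimum sample size is not met are returned as `NA` rather
#' than errors, so small groups can still be summarised descriptively.
#'
#' @param d13C,d15N numeric vectors of equal length (per-mil); all finite.
#' @return a `layman_metrics` list with fields `dC_range`, `dN_range`, `TA`,
#'   `CD`, `NND`, `SDNND`, `n`.
#' @export
layman_metrics <- function(d13C, d15N) {
  stopifnot(length(d13C) == length(d15N))
  n <- length(d13C)
  if (n == 0L) stop("no points supplied", call. = FALSE)
  if (any(!is.finite(d13C)) || any(!is.finite(d15N))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  dC_range <- max(d13C) - min(d13C)
  dN_range <- max(d15N) - min(d15N)
  TA <- if (n >= 3) convex_hull_area(d13C, d15N) else NA_real_

  cx <- mean(d13C); cy <- mean(d15N)
  CD <- mean(sqrt((d13C - cx)^2 + (d15N - cy)^2))

  if (n >= 2) {
    nnd <- nearest_neighbour_distances(d13C, d15N)
    NND <- mean(nnd)
    SDNND <- stats::sd(nnd)
  } else {
    NND <- NA_real_
    SDNND <- NA_real_
  }
  structure(list(dC_range = dC_range, dN_range = dN_range, TA = TA,
                 CD = CD, NND = NND, SDNND = SDNND, n = n),
            class = "layman_metrics")
}

# Shoelace area of the convex hull (0 for collinear clouds).
convex_hull_area <- function(x, y) {
  h <- grDevices::chull(x, y)
  if (length(h) < 3) return(0)
  hx <- x[h]; hy <- y[h]
  0.5 * abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy))
}

# Distance from each point to its nearest other point (O(n^2) via dist()).
nearest_neighbour_distances <- function(x, y) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  apply(d, 1L, min)
}

#' @export
print.layman_metrics <- function(x, ...) {
  cat(sprintf(paste0("<layman_metrics> n=%d  dC_range=%.2f  dN_range=%.2f  ",
                     "TA=%.2f  CD=%.2f  NND=%.2f  SDNND=%.2f\n"),
              x$n, x$dC_range, x$dN_range, x$TA, x$CD, x$NND, x$SDNND))
  invisible(x)
}
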