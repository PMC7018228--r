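#' Minimal angular separation of two angles on the circle
#'
#' @param theta1,theta2 angles in radians (any real; wrapped internally).
#'   Vectorized.
#' @return separation(s) in `[0, pi]`.
#' @export
angular_separation <- function(theta1, theta2) {
  if (!all(is.finite(theta1)) || !all(is.finite(theta2))) {
    stop("angles must be finite")
  }
  d <- abs(theta1 - theta2) %% (2 * pi)
  pi - abs(pi - d)
}

#' Euclidean distance between 3D points
#'
#' @param p1,p2 numeric coordinate vectors of equal length, or matrices with
#'   one point per row.
#' @return distance(s).
#' @export
euclidean_distance <- function(p1, p2) {
  if (is.matrix(p1) || is.matrix(p2)) {
    p1 <- rbind(p1); p2 <- rbind(p2)
    if (ncol(p1) != ncol(p2)) stop("dimension mismatch")
    return(sqrt(rowSums((p1 - p2)^2)))
  }
  if (length(p1) != length(p2)) stop("dimension mismatch")
  sqrt(sum((p1 - p2)^2))
}

#' Hyperbolic distance in the 2D hyperbolic disk (exact)
#'
#' Law of cosines: x = arccosh(cosh r1 cosh r2 - sinh r1 sinh r2 cos dtheta).
#' The arccosh argument is clamped to `[1, Inf)` to absorb round-off near
#' coincident points. Vectorized.
#'
#' @param r1,r2 radial coordinates (>= 0).
#' @param theta1,theta2 angular coordinates (radians).
#' @return geodesic distance(s).
#' @export
hyperbolic_distance <- function(r1, theta1, r2, theta2) {
  if (!all(is.finite(c(r1, r2, theta1, theta2)))) stop("non-finite input")
  dtheta <- angular_separation(theta1, theta2)
  arg <- cosh(r1) * cosh(r2) - sinh(r1) * sinh(r2) * cos(dtheta)
  acosh(pmax(arg, 1))
}

#' Hyperbolic distance, large-radius approximation
#'
#' x ~ r1 + r2 + 2 log(dtheta / 2), highly accurate when
#' dtheta >> exp(-min(r1, r2)). Undefined at dtheta = 0 (an error: callers
#' must fall back to the exact form).
#'
#' @inheritParams hyperbolic_distance
#' @return approximate distance(s).
#' @export
hyperbolic_distance_approx <- function(r1, theta1, r2, theta2) {
  if (!all(is.finite(c(r1, r2, theta1, theta2)))) stop("non-finite input")
  dtheta <- angular_separation(theta1, theta2)
  if (any(dtheta == 0)) {
    stop("approximation undefined at zero angular separation; use the exact form")
  }
  r1 + r2 + 2 * log(dtheta / 2)
}

# Unordered pair indices (i < j) for n items, as a list(i, j).
# Much faster than utils::combn for large n.
pair_indices <- function(n) {
  list(i = sequence(seq_len(n - 1L)),
       j = rep.int(2:n, seq_len(n - 1L)))
}

# Full pairwise Euclidean distance matrix from a position matrix.
euclidean_distance_matrix <- function(positions) {
  as.matrix(stats::dist(positions))
}

# Full pairwise exact hyperbolic distance matrix from coordinate vectors.
hyperbolic_distance_matrix <- function(r, theta) {
  n <- length(r)
  dtheta <- outer(theta, theta, function(a, b) pi - abs(pi - (abs(a - b) %% (2 * pi))))
  arg <- outer(cosh(r), cosh(r)) - outer(sinh(r), sinh(r)) * cos(dtheta)
  m <- acosh(pmax(arg, 1))
  diag(m) <- 0
  m
}

#' Alignment-corrected angular agreement
#'
#' Agreement between two sets of angles after the optimal global rotation
#' and reflection: max over the reflection s in \{+1, -1\} and rotation
#' delta of mean(cos(theta - s * phi - delta)). For each reflection the
#' optimal rotation is the circular mean of the residuals, so the search is
#' closed-form. Equals 1 for perfectly matching angle sets (up to any
#' rotation/reflection), and is O(1/sqrt(N)) for unrelated ones.
#'
#' This concordance is robust where moment-based circular correlation
#' coefficients degenerate (e.g. multimodal angle distributions, for which
#' [circular_correlation()] can be near zero even for well-matched maps).
#'
#' @param theta,phi angle vectors (radians), equal length.
#' @return agreement in `[-1, 1]`.
#' @export
angular_agreement <- function(theta, phi) {
  stopifnot(length(theta) == length(phi))
  best <- -1
  for (s in c(1, -1)) {
    d <- theta - s * phi
    delta <- atan2(mean(sin(d)), mean(cos(d)))
    best <- max(best, mean(cos(d - delta)))
  }
  best
}

#' Circular correlation between two sets of angles
#'
#' The Fisher-Lee circular correlation coefficient. It is invariant under
#' independent rotations of either variable and changes sign under
#' reflection, so `abs()` of it is an alignment-free measure of angular
#' agreement (rotation and reflection corrected).
#'
#' @param theta,phi angle vectors (radians), equal length.
#' @return correlation in `[-1, 1]`.
#' @export
circular_correlation <- function(theta, phi) {
  stopifnot(length(theta) == length(phi))
  tb <- atan2(mean(sin(theta)), mean(cos(theta)))
  pb <- atan2(mean(sin(phi)), mean(cos(phi)))
  st <- sin(theta - tb); sp <- sin(phi - pb)
  sum(st * sp) / sqrt(sum(st^2) * sum(sp^2))
}
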