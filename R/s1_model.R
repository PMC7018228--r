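#' Hyperbolic map of a network
#'
#' Per-node polar coordinates in the hyperbolic disk plus the model's global
#' parameters: disk radius `R` and inverse temperature `beta`.
#'
#' @param node_ids character vector of node ids.
#' @param r radial coordinates (>= 0), same length.
#' @param theta angular coordinates; wrapped into `[0, 2*pi)`.
#' @param R disk radius (> 0).
#' @param beta inverse temperature (> 1, the finite-clustering regime).
#' @return object of class `hyperbolic_map`.
#' @export
hyperbolic_map <- function(node_ids, r, theta, R, beta) {
  node_ids <- as.character(node_ids)
  stopifnot(length(r) == length(node_ids), length(theta) == length(node_ids))
  if (!all(is.finite(r)) || any(r < 0)) stop("radial coordinates must be finite and >= 0")
  if (!is.finite(R) || R <= 0) stop("R must be positive")
  if (!is.finite(beta) || beta <= 1) stop("beta must be > 1")
  if (any(r > R + 1e-6)) {
    warning("some radial coordinates exceed the disk radius R")
  }
  structure(
    list(node_ids = node_ids, r = as.numeric(r),
         theta = as.numeric(theta) %% (2 * pi), R = R, beta = beta),
    class = "hyperbolic_map")
}

#' @export
print.hyperbolic_map <- function(x, ...) {
  cat("<hyperbolic_map> ", length(x$node_ids), " nodes, R = ",
      signif(x$R, 4), ", beta = ", signif(x$beta, 4), "\n", sep = "")
  invisible(x)
}

#' S1 model parameters
#'
#' Hidden degrees kappa and angles theta on the circle, plus the global
#' parameters mu (plays the role of the disk radius R) and beta. Isomorphic
#' to a [hyperbolic_map] via [s1_to_hyperbolic()].
#'
#' @param node_ids character vector of node ids.
#' @param kappa hidden degrees (> 0).
#' @param theta angles; wrapped into `[0, 2*pi)`.
#' @param mu global density parameter (> 0).
#' @param beta inverse temperature (> 1).
#' @return object of class `s1_params`.
#' @export
s1_params <- function(node_ids, kappa, theta, mu, beta) {
  node_ids <- as.character(node_ids)
  stopifnot(length(kappa) == length(node_ids),
            length(theta) == length(node_ids))
  if (!all(is.finite(kappa)) || any(kappa <= 0)) stop("kappa must be positive")
  if (!is.finite(mu) || mu <= 0) stop("mu must be positive")
  if (!is.finite(beta) || beta <= 1) stop("beta must be > 1")
  structure(
    list(node_ids = node_ids, kappa = as.numeric(kappa),
         theta = as.numeric(theta) %% (2 * pi), mu = mu, beta = beta,
         N = length(node_ids)),
    class = "s1_params")
}

#' @export
print.s1_params <- function(x, ...) {
  cat("<s1_params> ", x$N, " nodes, mu = ", signif(x$mu, 4),
      ", beta = ", signif(x$beta, 4), "\n", sep = "")
  invisible(x)
}

#' H2 connection probability
#'
#' Logistic law in hyperbolic distance: p = 1 / (1 + exp(beta/2 * (x - R))).
#' Strictly decreasing in x; p = 1/2 at x = R.
#'
#' @param x hyperbolic distance(s), >= 0.
#' @param R disk radius.
#' @param beta inverse temperature.
#' @return connection probability in (0, 1).
#' @export
connection_prob_h2 <- function(x, R, beta) {
  if (!all(is.finite(x)) || !all(is.finite(R)) || !all(is.finite(beta))) {
    stop("non-finite input")
  }
  1 / (1 + exp(beta / 2 * (x - R)))
}

#' S1 connection probability
#'
#' p = 1 / (1 + (dtheta / (mu * ki * kj))^beta): nodes are likely to be
#' linked when angularly close, unless their hidden degrees compensate.
#'
#' @param dtheta angular separation(s), >= 0.
#' @param ki,kj hidden degrees (> 0).
#' @param mu global density parameter.
#' @param beta inverse temperature.
#' @return connection probability in (0, 1]; equals 1 at dtheta = 0.
#' @export
connection_prob_s1 <- function(dtheta, ki, kj, mu, beta) {
  if (!all(is.finite(dtheta)) || !all(is.finite(c(ki, kj, mu, beta)))) {
    stop("non-finite input")
  }
  1 / (1 + (dtheta / (mu * ki * kj))^beta)
}

#' Map a hidden degree to a radial coordinate (and back)
#'
#' The popularity-similarity convention r = R - 2 log(kappa / kappa0) places
#' the lowest hidden degree kappa0 on the disk boundary (r = R) and large
#' hubs near the center.
#'
#' @param kappa hidden degree(s), >= kappa0.
#' @param kappa0 minimum hidden degree (> 0).
#' @param R disk radius.
#' @return radial coordinate(s).
#' @export
kappa_to_radius <- function(kappa, kappa0, R) {
  if (any(kappa < kappa0) || any(kappa0 <= 0)) {
    stop("kappa must satisfy kappa >= kappa0 > 0")
  }
  R - 2 * log(kappa / kappa0)
}

#' @rdname kappa_to_radius
#' @param r radial coordinate(s).
#' @export
radius_to_kappa <- function(r, kappa0, R) {
  kappa0 * exp((R - r) / 2)
}

#' Disk radius implied by S1 parameters
#'
#' Under the change of variables r = R - 2 log(kappa/kappa0) and the
#' large-radius distance approximation, the S1 and H2 connection
#' probabilities coincide exactly when R = 2 log(2 / (mu * kappa0^2)).
#'
#' @param mu S1 density parameter.
#' @param kappa0 minimum hidden degree.
#' @return disk radius R.
#' @export
s1_disk_radius <- function(mu, kappa0) {
  2 * log(2 / (mu * kappa0^2))
}

#' Convert S1 parameters to the isomorphic hyperbolic map
#'
#' @param params an [s1_params] object.
#' @return a [hyperbolic_map] with identical angles and
#'   r_i = R - 2 log(kappa_i / kappa0), R = 2 log(2 / (mu * kappa0^2)).
#' @export
s1_to_hyperbolic <- function(params) {
  kappa0 <- min(params$kappa)
  R <- s1_disk_radius(params$mu, kappa0)
  if (R <= 0) stop("implied disk radius is not positive; mu * kappa0^2 >= 2")
  hyperbolic_map(params$node_ids,
                 r = kappa_to_radius(params$kappa, kappa0, R),
                 theta = params$theta, R = R, beta = params$beta)
}

# Cumulative integral F(x) = int_0^x du/(1+u^beta), vectorized and fast:
# dense trapezoid grid on [0, 10], three-term alternating tail expansion
# around C_beta = (pi/beta)/sin(pi/beta) = F(Inf) beyond.
make_s1_cumint <- function(beta) {
  xs <- seq(0, 10, length.out = 4001L)
  vals <- 1 / (1 + xs^beta)
  Fg <- c(0, cumsum((vals[-1L] + vals[-4001L]) / 2) * (xs[2L] - xs[1L]))
  cbeta <- (pi / beta) / sin(pi / beta)
  function(x) {
    out <- numeric(length(x))
    small <- x <= 10
    if (any(small)) out[small] <- stats::approx(xs, Fg, x[small])$y
    if (any(!small)) {
      xb <- x[!small]
      out[!small] <- cbeta - xb^(1 - beta) / (beta - 1) +
        xb^(1 - 2 * beta) / (2 * beta - 1) -
        xb^(1 - 3 * beta) / (3 * beta - 1)
    }
    out
  }
}

# Expected mean degree of the S1 ensemble for given kappas, beta, mu.
# The angular average over a uniform pair separation reduces per pair to
# (a/pi) * F(pi/a) with a = mu*ki*kj. Deterministic: no sampling noise
# enters the calibration.
s1_expected_mean_degree <- function(kappas, beta, mu, kk = NULL,
                                    cumint = NULL) {
  n <- length(kappas)
  if (is.null(kk)) {
    pr <- pair_indices(n)
    kk <- kappas[pr$i] * kappas[pr$j]
  }
  if (is.null(cumint)) cumint <- make_s1_cumint(beta)
  a <- mu * kk
  mean_p <- a / pi * cumint(pi / a)
  2 * sum(mean_p) / n
}

#' Calibrate the S1 density parameter mu for a target mean degree
#'
#' Starts from the analytic seed mu0 = beta * sin(pi/beta) / (2*pi*<kappa>),
#' brackets the target and bisects (in log mu) until the ensemble's expected
#' mean degree is within 2% of the target. The expected degree is the exact
#' angular average of the S1 connection probability over all hidden-degree
#' pairs, evaluated by deterministic quadrature.
#'
#' @param kappas hidden degrees.
#' @param beta inverse temperature (> 1).
#' @param target_mean_degree desired expected mean degree, < N - 1.
#' @param tol relative tolerance on the mean degree (default 0.02).
#' @param max_steps bisection step budget (default 60).
#' @return calibrated mu.
#' @export
calibrate_mu <- function(kappas, beta, target_mean_degree, tol = 0.02,
                         max_steps = 60L) {
  n <- length(kappas)
  if (beta <= 1) stop("beta must be > 1")
  if (target_mean_degree >= n - 1) {
    stop("target mean degree must be below N - 1")
  }
  if (target_mean_degree <= 0) stop("target mean degree must be positive")
  mu <- beta * sin(pi / beta) / (2 * pi * mean(kappas))
  pr <- pair_indices(n)
  kk <- kappas[pr$i] * kappas[pr$j]
  cumint <- make_s1_cumint(beta)
  f <- function(m) {
    s1_expected_mean_degree(kappas, beta, m, kk = kk, cumint = cumint)
  }
  # the expected degree is close to linear in mu at low density, so jump
  # to a linear guess from the seed, then expand a geometric bracket
  k_seed <- f(mu)
  if (k_seed > 0) mu <- mu * target_mean_degree / k_seed
  lo <- hi <- mu
  if (f(mu) < target_mean_degree) {
    while (f(hi) < target_mean_degree) {
      hi <- hi * 2
      if (hi > 1e12) stop("calibration failed to bracket the target")
    }
    lo <- hi / 2
  } else {
    while (f(lo) > target_mean_degree) {
      lo <- lo / 2
      if (lo < 1e-15) stop("calibration failed to bracket the target")
    }
    hi <- lo * 2
  }
  for (step in seq_len(max_steps)) {
    mid <- sqrt(lo * hi)
    km <- f(mid)
    if (abs(km - target_mean_degree) <= tol * target_mean_degree) {
      return(mid)
    }
    if (km < target_mean_degree) lo <- mid else hi <- mid
  }
  stop("mu calibration did not converge within ", max_steps, " steps")
}

#' Log-likelihood of a topology under a hyperbolic map
#'
#' Bernoulli likelihood over unordered node pairs,
#' sum over i < j of a_ij log p_ij + (1 - a_ij) log(1 - p_ij), with p_ij the
#' H2 connection probability at the exact hyperbolic distance. Probabilities
#' are clamped to `[1e-15, 1 - 1e-15]` before taking logs.
#'
#' @param x a `connectome`.
#' @param map a [hyperbolic_map] covering every node of `x`.
#' @return the log-likelihood (a scalar).
#' @export
log_likelihood <- function(x, map) {
  idx <- match(x$nodes, map$node_ids)
  if (anyNA(idx)) {
    stop("map lacks coordinates for node(s): ",
         paste(utils::head(x$nodes[is.na(idx)], 5L), collapse = ", "))
  }
  r <- map$r[idx]; theta <- map$theta[idx]
  d <- hyperbolic_distance_matrix(r, theta)
  p <- connection_prob_h2(d, map$R, map$beta)
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  a <- adjacency_matrix(x)
  ut <- upper.tri(p)
  sum(ifelse(a[ut], log(p[ut]), log1p(-p[ut])))
}

#' Write / read a hyperbolic map
#'
#' TSV with columns id, r, theta plus a JSON sidecar (same path with
#' `.json` appended) carrying R and beta.
#'
#' @param map a [hyperbolic_map].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hyperbolic_map <- function(map, path) {
  utils::write.table(
    data.frame(id = map$node_ids, r = sprintf("%.17g", map$r),
               theta = sprintf("%.17g", map$theta)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  jsonlite::write_json(list(R = map$R, beta = map$beta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hyperbolic_map
#' @export
read_hyperbolic_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "numeric", "numeric"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  hyperbolic_map(tab$id, tab$r, tab$theta, R = meta$R, beta = meta$beta)
}
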