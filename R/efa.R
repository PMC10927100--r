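#' Smooth an outline by a cyclic moving average
#'
#' Each pass replaces vertex i with the mean of vertices i-1, i, i+1 under
#' cyclic indexing; the vertex count is unchanged. Used to suppress
#' digitization noise before Fourier decomposition.
#'
#' @param x an [outline()].
#' @param iterations non-negative number of passes (default 5).
#' @return The smoothed [outline()].
#' @export
smooth_outline <- function(x, iterations = 5L) {
  stopifnot(inherits(x, "outline"))
  if (iterations < 0) stop("iterations must be >= 0", call. = FALSE)
  p <- x$coords
  n <- nrow(p)
  for (it in seq_len(iterations)) {
    p <- (p[c(n, 1:(n - 1)), , drop = FALSE] + p +
            p[c(2:n, 1), , drop = FALSE]) / 3
  }
  x$coords <- p
  x
}

# principal elongation axis of a vertex cloud (first eigenvector of the
# coordinate covariance); returns a unit vector
.principal_axis <- function(p) {
  v <- eigen(stats::cov(p), symmetric = TRUE)$vectors[, 1]
  v / sqrt(sum(v^2))
}

# distal-extremity vertex: the outline's two extremes along the principal
# elongation axis are candidates; when their distances from the centroid are
# within 10% of the axis range the pointier end (smaller RMS off-axis width
# near the end) wins, so the start vertex does not flip between the ends of
# a near-symmetric piece under digitization noise
.tip_index <- function(p) {
  v <- .principal_axis(p)
  proj <- drop(p %*% v)
  rng <- diff(range(proj))
  i_hi <- which(proj == max(proj))[1]
  i_lo <- which(proj == min(proj))[1]
  if (abs(abs(proj[i_hi]) - abs(proj[i_lo])) > 0.1 * rng) {
    return(if (abs(proj[i_hi]) >= abs(proj[i_lo])) i_hi else i_lo)
  }
  off <- abs(drop(p %*% c(-v[2], v[1])))
  width_near <- function(i) {
    sel <- abs(proj - proj[i]) < 0.15 * rng
    sqrt(mean(off[sel]^2))
  }
  w_hi <- width_near(i_hi)
  w_lo <- width_near(i_lo)
  if (abs(w_hi - w_lo) > 1e-12) {
    if (w_hi < w_lo) i_hi else i_lo
  } else if (abs(proj[i_hi]) != abs(proj[i_lo])) {
    if (abs(proj[i_hi]) > abs(proj[i_lo])) i_hi else i_lo
  } else {
    min(i_hi, i_lo)
  }
}

#' Normalize position, scale, traversal direction and starting vertex
#'
#' Translates the outline to its centroid, scales it to unit centroid size
#' (root mean squared vertex distance from the centroid), enforces
#' counter-clockwise traversal, and cyclically re-indexes the vertices so
#' that index 1 is the tip (distal extremity): the vertex at maximal
#' distance from the centroid along the principal elongation axis. When the
#' two axis ends are within 10% of each other the pointier end (smaller
#' local off-axis width) is chosen, keeping the start vertex stable for
#' near-symmetric pieces; remaining ties break to the lowest vertex index.
#'
#' @param x an [outline()].
#' @return The normalized [outline()].
#' @export
orient_outline <- function(x) {
  stopifnot(inherits(x, "outline"))
  p <- x$coords
  ctr <- colMeans(p)
  p <- sweep(p, 2, ctr)
  size <- sqrt(mean(rowSums(p^2)))
  if (size < .Machine$double.eps) {
    stop("degenerate outline: all vertices coincide", call. = FALSE)
  }
  p <- p / size
  # counter-clockwise by the shoelace sign
  n <- nrow(p)
  area2 <- sum(p[, 1] * p[c(2:n, 1), 2] - p[c(2:n, 1), 1] * p[, 2])
  if (area2 < 0) p <- p[c(1, n:2), , drop = FALSE]
  tip <- .tip_index(p)
  if (tip > 1L) p <- p[c(tip:n, 1:(tip - 1L)), , drop = FALSE]
  colnames(p) <- c("x", "y")
  x$coords <- p
  x
}

#' Interpolate equally spaced semi-landmarks along a closed outline
#'
#' Resamples the closed polygon at `k` points equally spaced in arc length,
#' keeping the current starting vertex (the tip after [orient_outline()]) at
#' index 1.
#'
#' @param x an [outline()].
#' @param k number of semi-landmarks (default 500).
#' @return An [outline()] with exactly `k` vertices.
#' @export
interpolate_semilandmarks <- function(x, k = 500L) {
  stopifnot(inherits(x, "outline"))
  if (k < 3L) stop("k must be >= 3", call. = FALSE)
  p <- x$coords
  n <- nrow(p)
  closed <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  per <- sum(seg)
  if (per <= 0) stop("zero-perimeter outline", call. = FALSE)
  cum <- c(0, cumsum(seg))
  target <- per * (seq_len(k) - 1) / k
  xi <- stats::approx(cum, closed[, 1], xout = target, ties = "ordered")$y
  yi <- stats::approx(cum, closed[, 2], xout = target, ties = "ordered")$y
  x$coords <- cbind(x = xi, y = yi)
  x
}

#' Standard outline preprocessing chain
#'
#' Smoothing, orientation/normalization and semi-landmark interpolation in
#' the canonical order. After this the tip sits at vertex 1 of exactly `k`
#' equally spaced semi-landmarks.
#'
#' @param x an [outline()].
#' @param smooth_iterations moving-average passes (default 5).
#' @param k semi-landmark count (default 500).
#' @return Preprocessed [outline()].
#' @export
preprocess_outline <- function(x, smooth_iterations = 5L, k = 500L) {
  interpolate_semilandmarks(orient_outline(smooth_outline(x, smooth_iterations)),
                            k = k)
}

#' Elliptic Fourier decomposition of a closed outline
#'
#' Computes the standard elliptic Fourier coefficients (per-harmonic
#' quadruples a_n, b_n, c_n, d_n plus the offsets a_0, c_0) of the closed
#' polygon parameterized by cumulative chord length.
#'
#' @param x an [outline()] (ideally preprocessed).
#' @param n_harmonics number of harmonics; at most `floor(k/2)` for `k`
#'   vertices (aliasing limit).
#' @return An object of class `efa_coefficients`: list with `coef`
#'   (n_harmonics x 4 matrix, columns `a,b,c,d`), `a0`, `c0`, `perimeter`.
#' @export
efa_forward <- function(x, n_harmonics) {
  stopifnot(inherits(x, "outline"))
  k <- nrow(x$coords)
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1", call. = FALSE)
  if (n_harmonics > floor(k / 2)) {
    stop(sprintf("n_harmonics (%d) exceeds the aliasing limit floor(k/2) = %d",
                 n_harmonics, floor(k / 2)), call. = FALSE)
  }
  p <- x$coords
  dx <- diff(c(p[, 1], p[1, 1]))
  dy <- diff(c(p[, 2], p[1, 2]))
  dt <- sqrt(dx^2 + dy^2)
  if (any(dt == 0)) {
    keep <- dt > 0
    dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
    p <- p[keep, , drop = FALSE]
  }
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-length(t1)])
  per <- t1[length(t1)]
  co <- matrix(0, n_harmonics, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (h in seq_len(n_harmonics)) {
    w <- 2 * pi * h / per
    f <- per / (2 * pi^2 * h^2)
    dcos <- cos(w * t1) - cos(w * t0)
    dsin <- sin(w * t1) - sin(w * t0)
    co[h, 1] <- f * sum(dx / dt * dcos)
    co[h, 2] <- f * sum(dx / dt * dsin)
    co[h, 3] <- f * sum(dy / dt * dcos)
    co[h, 4] <- f * sum(dy / dt * dsin)
  }
  xprev <- cumsum(c(0, dx[-length(dx)]))
  yprev <- cumsum(c(0, dy[-length(dy)]))
  ksi <- xprev - dx / dt * t0
  dlt <- yprev - dy / dt * t0
  a0 <- sum(dx / (2 * dt) * (t1^2 - t0^2) + ksi * (t1 - t0)) / per + p[1, 1]
  c0 <- sum(dy / (2 * dt) * (t1^2 - t0^2) + dlt * (t1 - t0)) / per + p[1, 2]
  structure(list(coef = co, a0 = a0, c0 = c0, perimeter = per,
                 n_harmonics = n_harmonics),
            class = "efa_coefficients")
}

#' @export
print.efa_coefficients <- function(x, ...) {
  cat(sprintf("efa_coefficients: %d harmonics, perimeter %.4g\n",
              x$n_harmonics, x$perimeter))
  invisible(x)
}

#' Reconstruct an outline from elliptic Fourier coefficients
#'
#' Evaluates the truncated Fourier series at `k_points` parameter values
#' equally spaced over one period.
#'
#' @param coeffs an `efa_coefficients` object.
#' @param k_points number of evaluation points (>= 3).
#' @param artefact_id id given to the reconstructed outline.
#' @return An [outline()].
#' @export
efa_inverse <- function(coeffs, k_points = 128L, artefact_id = "reconstruction") {
  stopifnot(inherits(coeffs, "efa_coefficients"))
  if (k_points < 3L) stop("k_points must be >= 3", call. = FALSE)
  tt <- coeffs$perimeter * (seq_len(k_points) - 1) / k_points
  xs <- rep(coeffs$a0, k_points)
  ys <- rep(coeffs$c0, k_points)
  for (h in seq_len(coeffs$n_harmonics)) {
    w <- 2 * pi * h / coeffs$perimeter
    xs <- xs + coeffs$coef[h, 1] * cos(w * tt) + coeffs$coef[h, 2] * sin(w * tt)
    ys <- ys + coeffs$coef[h, 3] * cos(w * tt) + coeffs$coef[h, 4] * sin(w * tt)
  }
  outline(cbind(xs, ys), artefact_id)
}

#' Per-harmonic power of an elliptic Fourier decomposition
#'
#' Harmonic power is \eqn{P_n = (a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2}; its
#' cumulative share governs harmonic retention.
#'
#' @param coeffs an `efa_coefficients` object.
#' @return Numeric vector of powers, one per harmonic.
#' @export
harmonic_power <- function(coeffs) {
  stopifnot(inherits(coeffs, "efa_coefficients"))
  rowSums(coeffs$coef^2) / 2
}

#' Calibrate the retained harmonic count from cumulative harmonic power
#'
#' Decomposes every outline at the aliasing limit and returns the smallest
#' harmonic count whose mean (across outlines) cumulative power share reaches
#' `power_threshold` (default 99.9%).
#'
#' @param x an [outline_set()] of preprocessed outlines (equal vertex
#'   counts).
#' @param power_threshold fraction in (0, 1].
#' @return Integer harmonic count.
#' @export
calibrate_harmonics <- function(x, power_threshold = 0.999) {
  stopifnot(inherits(x, "outline_set"))
  if (power_threshold <= 0 || power_threshold > 1) {
    stop("power_threshold must be in (0, 1]", call. = FALSE)
  }
  k <- nrow(x[[1]]$coords)
  nmax <- floor(k / 2)
  shares <- vapply(x, function(o) {
    pw <- harmonic_power(efa_forward(o, nmax))
    cumsum(pw) / sum(pw)
  }, numeric(nmax))
  mean_share <- if (is.matrix(shares)) rowMeans(shares) else mean(shares)
  hit <- which(mean_share >= power_threshold)
  if (length(hit) == 0L) return(nmax)
  as.integer(hit[1])
}

#' Coefficient table for a set of outlines
#'
#' One row per outline; columns are the flattened harmonic quadruples
#' `a1,b1,c1,d1,a2,...`. Offsets are omitted (they are ~0 after centering).
#'
#' @param x an [outline_set()] of preprocessed outlines.
#' @param n_harmonics harmonics to retain.
#' @return Numeric matrix with rownames = artefact ids.
#' @export
efa_coefficient_table <- function(x, n_harmonics) {
  stopifnot(inherits(x, "outline_set"))
  tab <- t(vapply(x, function(o) {
    as.numeric(t(efa_forward(o, n_harmonics)$coef))
  }, numeric(n_harmonics * 4L)))
  colnames(tab) <- as.vector(t(outer(seq_len(n_harmonics),
                                     c("a", "b", "c", "d"),
                                     function(h, l) paste0(l, h))))
  rownames(tab) <- names(x)
  tab
}

#' PCA shape space over elliptic Fourier coefficients
#'
#' Centered (unscaled) principal components of the coefficient table, with
#' all components up to the matrix rank retained. Because only an orthogonal
#' rotation is applied, pairwise Euclidean distances in the full PC space
#' equal those between centered coefficient rows.
#'
#' @param coeff_table outlines x coefficients matrix from
#'   [efa_coefficient_table()].
#' @return Object of class `shape_space`: list with `scores`, `eigenvalues`,
#'   `loadings`, `center`, `component_count`.
#' @export
pca_shapespace <- function(coeff_table) {
  coeff_table <- as.matrix(coeff_table)
  if (nrow(coeff_table) < 2L) {
    stop("need at least 2 outlines for a shape space", call. = FALSE)
  }
  if (nrow(unique(coeff_table)) < 2L) {
    stop("fewer than 2 distinct outlines", call. = FALSE)
  }
  pc <- stats::prcomp(coeff_table, center = TRUE, scale. = FALSE)
  tol <- max(dim(coeff_table)) * .Machine$double.eps * max(pc$sdev)
  rank <- sum(pc$sdev > tol)
  structure(list(scores = pc$x[, seq_len(rank), drop = FALSE],
                 eigenvalues = pc$sdev[seq_len(rank)]^2,
                 loadings = pc$rotation[, seq_len(rank), drop = FALSE],
                 center = pc$center,
                 component_count = rank),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("shape_space: %d outlines x %d components\n",
              nrow(x$scores), x$component_count))
  invisible(x)
}
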