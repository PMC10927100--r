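# Independent oracles and small fixture builders used across the suite.

# brute-force Gower: mean |xi - xj| over traits known in both rows
oracle_gower <- function(vals) {
  n <- nrow(vals)
  d <- matrix(0, n, n, dimnames = list(rownames(vals), rownames(vals)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    k <- !is.na(vals[i, ]) & !is.na(vals[j, ])
    d[i, j] <- sum(abs(vals[i, k] - vals[j, k])) / sum(k)
  }
  d
}

# brute-force agglomeration with the ward.D2 Lance-Williams update
oracle_ward_d2 <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labs <- rownames(d)
  active <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  heights <- numeric(0)
  merges <- list()
  cur <- d
  ids <- -seq_len(n)          # hclust convention: negatives are leaves
  while (length(active) > 1L) {
    m <- length(active)
    best <- c(1L, 2L); bestv <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (cur[i, j] < bestv) { bestv <- cur[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bestv)
    merges[[length(merges) + 1L]] <- sort(c(ids[i], ids[j]))
    ni <- sizes[i]; nj <- sizes[j]
    new_row <- vapply(seq_len(m), function(k) {
      if (k == i || k == j) return(NA_real_)
      nk <- sizes[k]
      sqrt(((ni + nk) * cur[i, k]^2 + (nj + nk) * cur[j, k]^2 -
              nk * bestv^2) / (ni + nj + nk))
    }, numeric(1))
    keep <- setdiff(seq_len(m), c(i, j))
    nxt <- matrix(0, length(keep) + 1L, length(keep) + 1L)
    nxt[seq_along(keep), seq_along(keep)] <- cur[keep, keep]
    nxt[length(keep) + 1L, seq_along(keep)] <- new_row[keep]
    nxt[seq_along(keep), length(keep) + 1L] <- new_row[keep]
    cur <- nxt
    sizes <- c(sizes[keep], ni + nj)
    ids <- c(ids[keep], length(merges))
    active <- c(active[keep], list(length(merges)))
  }
  list(heights = heights, merges = merges, labels = labs)
}

# Fourier coefficients of a closed curve sampled at N equally spaced
# parameter positions, via the DFT (independent of the package's
# per-segment chord integrals)
oracle_fft_efa <- function(xy, n_harmonics) {
  stopifnot(nrow(xy) %% 2L == 0L)
  N <- nrow(xy)
  X <- stats::fft(xy[, 1]) / N
  Y <- stats::fft(xy[, 2]) / N
  idx <- seq_len(n_harmonics) + 1L
  cbind(a = 2 * Re(X[idx]), b = -2 * Im(X[idx]),
        c = 2 * Re(Y[idx]), d = -2 * Im(Y[idx]))
}

# symmetric matrix of iid U(0,1) dissimilarities with zero diagonal
random_dist_matrix <- function(n, labels = sprintf("e%03d", seq_len(n))) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2)
  m <- m + t(m)
  dimnames(m) <- list(labels, labels)
  dist_matrix(m, metric = "gower")
}

# minimal trait matrix from a values matrix, single slice, one region
tiny_traits <- function(vals, macro_unit = "unassigned", domain = "tools") {
  if (is.null(rownames(vals))) {
    rownames(vals) <- sprintf("N%02d", seq_len(nrow(vals)))
  }
  meta <- data.frame(nac_id = rownames(vals), region = "R01",
                     time_slices = "I",
                     macro_unit = rep_len(macro_unit, nrow(vals)),
                     stringsAsFactors = FALSE)
  trait_matrix(vals, meta, domain = domain)
}

# closed curve sampled at k points of the angular parameter
ellipse_outline <- function(A, B, k = 500L, id = "ellipse") {
  th <- seq(0, 2 * pi, length.out = k + 1L)[seq_len(k)]
  outline(cbind(A * cos(th), B * sin(th)), id)
}

small_generator <- function(seed = 1L, ...) {
  generator_config(seed = seed, n_nacs = 30L, n_regions = 9L,
                   outlines_per_nac = 4L, n_unassigned = 2L,
                   n_multi_slice = 1L, ...)
}
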