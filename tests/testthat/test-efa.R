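test_that("moving-average smoothing contracts noise but keeps the centroid", {
  sq <- outline(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), "sq")
  expect_identical(smooth_outline(sq, 0L)$coords, sq$coords)
  sm <- smooth_outline(sq, 4L)
  expect_equal(colMeans(sm$coords), colMeans(sq$coords), tolerance = 1e-12)
  expect_equal(nrow(sm$coords), 4L)
  set.seed(42)
  th <- seq(0, 2 * pi, length.out = 201)[1:200]
  r <- 1 + stats::runif(200, -0.05, 0.05)
  noisy <- outline(cbind(r * cos(th), r * sin(th)), "noisy")
  rad_var <- function(o) stats::var(sqrt(rowSums(
    sweep(o$coords, 2, colMeans(o$coords))^2)))
  expect_lt(rad_var(smooth_outline(noisy, 5L)), rad_var(noisy))
  expect_error(smooth_outline(sq, -1), "iterations")
})

test_that("semi-landmark interpolation spaces points equally in arc length", {
  sq <- outline(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), "sq")
  si <- interpolate_semilandmarks(sq, 8L)
  gaps <- sqrt(rowSums(diff(rbind(si$coords, si$coords[1, ]))^2))
  expect_equal(unname(gaps), rep(0.5, 8), tolerance = 1e-12)
  ci <- interpolate_semilandmarks(ellipse_outline(1, 1), 500L)
  chords <- sqrt(rowSums(diff(rbind(ci$coords, ci$coords[1, ]))^2))
  expect_lt(diff(range(chords)) / mean(chords), 1e-9)
  expect_equal(nrow(interpolate_semilandmarks(ellipse_outline(2, 1),
                                              500L)$coords), 500L)
  expect_error(interpolate_semilandmarks(sq, 2L), "k must be")
})

test_that("orientation normalizes start, direction, translation and scale", {
  iso <- outline(rbind(c(0, 3), c(-1, 0), c(-0.5, -0.1), c(0.5, -0.1),
                       c(1, 0)), "iso")
  o1 <- orient_outline(iso)
  # apex (the farthest, pointier end) must land at index 1
  apex_dist <- sqrt(sum((o1$coords[1, ])^2))
  expect_equal(apex_dist, max(sqrt(rowSums(o1$coords^2))), tolerance = 1e-12)
  # clockwise traversal of the same shape yields the identical result
  cw <- outline(iso$coords[rev(seq_len(nrow(iso$coords))), ], "cw")
  expect_equal(orient_outline(cw)$coords, o1$coords, tolerance = 1e-12)
  # translation and scale leave the normalized outline unchanged
  tr <- outline(sweep(iso$coords * 3.7, 2, c(100, -40), "+"), "tr")
  expect_equal(orient_outline(tr)$coords, o1$coords, tolerance = 1e-9)
  # unit centroid size
  expect_equal(sqrt(mean(rowSums(o1$coords^2))), 1, tolerance = 1e-12)
  expect_error(orient_outline(outline(matrix(1, 4, 2), "pt")), "degenerate")
})

test_that("tip indexing is idempotent and recovers the authored tip", {
  fams <- shape_families()
  for (nm in names(fams)) {
    o <- efa_inverse(fams[[nm]]$template, 256L)
    oo <- orient_outline(o)
    # orientation is idempotent
    expect_equal(orient_outline(oo)$coords, oo$coords, tolerance = 1e-9)
    # templates are authored tip-first: the chosen start must match the
    # template's own first vertex (allow +/- 1 vertex of drift)
    ctr <- sweep(o$coords, 2, colMeans(o$coords))
    ctr <- ctr / sqrt(mean(rowSums(ctr^2)))
    n <- nrow(ctr)
    d_near <- min(vapply(c(n, 1, 2), function(k) {
      sqrt(sum((oo$coords[1, ] - ctr[k, ])^2))
    }, numeric(1)))
    expect_lt(d_near, 0.05)
  }
})

test_that("circle coefficients match the closed form to 1e-6", {
  r <- 2
  circ <- ellipse_outline(r, r, k = 4000L)
  co <- efa_forward(circ, 8L)
  expect_equal(unname(co$coef[1, "a"]), r, tolerance = 1e-6)
  expect_equal(unname(co$coef[1, "d"]), r, tolerance = 1e-6)
  expect_lt(max(abs(co$coef[-1, ])), 1e-6 * r)
  expect_lt(max(abs(c(co$coef[1, "b"], co$coef[1, "c"]))), 1e-6 * r)
  expect_lt(max(abs(c(co$a0, co$c0))), 1e-6 * r)
  pw <- harmonic_power(co)
  expect_equal(pw[1], r^2, tolerance = 1e-5)
})

test_that("ellipse coefficients match an independent DFT oracle", {
  # chord-length parameterization: compare against the DFT of the same
  # curve resampled at equal arc length, not the angular closed form
  ell <- interpolate_semilandmarks(ellipse_outline(1.5, 1, k = 4096L), 4096L)
  co <- efa_forward(ell, 6L)
  ref <- oracle_fft_efa(ell$coords, 6L)
  expect_equal(unname(co$coef), unname(ref), tolerance = 1e-5)
  # the eccentricity-induced third harmonic is real, not an artefact
  expect_gt(abs(co$coef[3, "a"]), 1e-3)
})

test_that("inverse reconstruction and forward analysis are mutually consistent", {
  # pure first-harmonic coefficients reconstruct the parametric ellipse
  # exactly (closed form)
  A <- 3; B <- 1.2
  co <- structure(list(
    coef = matrix(c(A, 0, 0, B), 1,
                  dimnames = list(NULL, c("a", "b", "c", "d"))),
    a0 = 0, c0 = 0, perimeter = 2 * pi, n_harmonics = 1L),
    class = "efa_coefficients")
  rec <- efa_inverse(co, 360L)
  tt <- 2 * pi * (0:359) / 360
  expect_equal(unname(rec$coords),
               unname(cbind(A * cos(tt), B * sin(tt))), tolerance = 1e-9)
  # forward . inverse . forward is a fixed point at full resolution
  set.seed(7)
  th <- seq(0, 2 * pi, length.out = 257)[1:256]
  blob <- outline(cbind((1 + 0.2 * sin(3 * th)) * cos(th),
                        (1 + 0.1 * cos(5 * th)) * sin(th)), "blob")
  cb <- efa_forward(blob, 32L)
  cb2 <- efa_forward(efa_inverse(cb, 2048L), 32L)
  expect_equal(cb2$coef, cb$coef, tolerance = 1e-3)
  # reconstruction error decreases monotonically with harmonic count
  errs <- vapply(c(2L, 8L, 32L), function(nh) {
    rc <- efa_inverse(efa_forward(blob, nh), 256L)
    max(sqrt(rowSums((rc$coords - blob$coords)^2)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_error(efa_forward(blob, 200L), "aliasing")
  expect_error(efa_inverse(cb, 2L), "k_points")
})

test_that("harmonic power calibration finds the smallest sufficient count", {
  ells <- outline_set(lapply(1:5, function(i) {
    o <- ellipse_outline(1 + 0.02 * i, 1, k = 360L,
                         id = sprintf("e%d", i))
    interpolate_semilandmarks(o, 360L)
  }))
  expect_identical(calibrate_harmonics(ells, 0.999), 1L)
  # threshold 1.0 drives N to the Nyquist region (the very last harmonic
  # can carry numerically zero power at even sampling)
  n_all <- calibrate_harmonics(ells, 1.0)
  expect_gte(n_all, 179L)
  expect_error(calibrate_harmonics(ells, 0), "power_threshold")
  # definition check on irregular outlines: N reaches the threshold, N-1 not
  set.seed(11)
  fam <- shape_families()[["arch_backed"]]
  outs <- outline_set(lapply(1:6, function(i) {
    o <- simulate_outline(fam, 0.08, seed = i, artefact_id = paste0("s", i))
    preprocess_outline(o, smooth_iterations = 0, k = 200L)
  }))
  n <- calibrate_harmonics(outs, 0.999)
  share <- function(nh) {
    mean(vapply(outs, function(o) {
      pw <- harmonic_power(efa_forward(o, 100L))
      sum(pw[seq_len(nh)]) / sum(pw)
    }, numeric(1)))
  }
  expect_gte(share(n), 0.999)
  expect_lt(share(n - 1L), 0.999)
})

test_that("harmonic power shares sum to one at the Nyquist limit", {
  o <- preprocess_outline(
    simulate_outline(shape_families()[["triangle"]], 0.05, seed = 2),
    smooth_iterations = 0, k = 128L)
  pw <- harmonic_power(efa_forward(o, 64L))
  expect_equal(sum(pw / sum(pw)), 1, tolerance = 1e-12)
  expect_true(all(pw >= 0))
})

test_that("full-PC distances equal centered-coefficient distances", {
  set.seed(3)
  fam <- shape_families()
  outs <- outline_set(lapply(1:12, function(i) {
    nm <- names(fam)[(i %% 6) + 1]
    o <- simulate_outline(fam[[nm]], 0.08, seed = i,
                          artefact_id = sprintf("o%02d", i))
    preprocess_outline(o, smooth_iterations = 0, k = 150L)
  }))
  tab <- efa_coefficient_table(outs, 8L)
  space <- pca_shapespace(tab)
  d_pc <- shape_distance(space)
  centered <- sweep(tab, 2, colMeans(tab))
  d_raw <- as.matrix(stats::dist(centered))
  expect_lt(max(abs(unclass(d_pc) - d_raw)), 1e-9)
  expect_equal(space$component_count,
               qr(centered)$rank)
  # a duplicated outline sits at distance zero
  tab2 <- rbind(tab, dup = tab[1, ])
  d2 <- shape_distance(pca_shapespace(tab2))
  expect_equal(unclass(d2)["o01", "dup"], 0, tolerance = 1e-9)
  expect_error(pca_shapespace(tab[1, , drop = FALSE]), "at least 2")
})
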