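#' Mantel test between two distance matrices
#'
#' Correlation of the vectorized upper triangles with a one-tailed
#' permutation p-value, p = (1 + #(r* >= r)) / (1 + n_perm) under
#' row/column permutations of one matrix. Delegates the permutation
#' machinery to `vegan::mantel()`.
#'
#' @param dist_a,dist_b [dist_matrix()] objects with identical labels in
#'   identical order.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return Object of class `mantel_result`: list with `r`, `p`, `n_perm`,
#'   `method`.
#' @export
mantel_test <- function(dist_a, dist_b, method = c("pearson", "spearman"),
                        n_perm = 999L, seed = NULL) {
  method <- match.arg(method)
  .check_mantel_pair(dist_a, dist_b)
  run <- function() {
    vegan::mantel(stats::as.dist(unclass(dist_a)),
                  stats::as.dist(unclass(dist_b)),
                  method = method, permutations = n_perm)
  }
  fit <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(r = unname(fit$statistic), p = unname(fit$signif),
                 n_perm = n_perm, method = method),
            class = "mantel_result")
}

.check_mantel_pair <- function(dist_a, dist_b) {
  stopifnot(inherits(dist_a, "dist_matrix"), inherits(dist_b, "dist_matrix"))
  if (!identical(rownames(dist_a), rownames(dist_b))) {
    stop("distance matrices must share labels in the same order",
         call. = FALSE)
  }
  if (stats::sd(.upper_vec(unclass(dist_a))) == 0 ||
      stats::sd(.upper_vec(unclass(dist_b))) == 0) {
    stop("zero variance in a distance triangle; correlation undefined",
         call. = FALSE)
  }
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel (%s): r = %.4f, p = %.4g (%d permutations)\n",
              x$method, x$r, x$p, x$n_perm))
  invisible(x)
}

#' Mantel correlogram over geographic distance classes
#'
#' Splits the geographic distances into non-overlapping equal-width classes
#' (Sturges' rule on the number of distance pairs by default) and computes,
#' per class, the Mantel correlation between the cultural distances and
#' membership in that class, with permutation p-values adjusted across
#' classes by Hochberg's step-up rule. Built on `vegan::mantel.correlog()`
#' (all classes computed, no distance cutoff); classes with fewer than 10
#' pairs are flagged untestable.
#'
#' @param cultural a [dist_matrix()] of cultural dissimilarities.
#' @param geographic a [dist_matrix()] in km with the same labels.
#' @param n_classes `"auto"` (Sturges) or an integer class count.
#' @param n_perm permutations per class (default 999).
#' @param seed optional integer seed.
#' @return Object of class `correlogram_result`: data frame `classes` with
#'   columns `class_index, midpoint_km, n_pairs, mantel_r, p_raw,
#'   p_adjusted, untestable, significant`, plus attributes `break_points`,
#'   `n_perm`.
#' @export
mantel_correlogram <- function(cultural, geographic, n_classes = "auto",
                               n_perm = 999L, seed = NULL) {
  .check_mantel_pair(cultural, geographic)
  dg <- stats::as.dist(unclass(geographic))
  n_pairs_total <- length(dg)
  k <- if (identical(n_classes, "auto")) {
    ceiling(log2(n_pairs_total) + 1)
  } else {
    as.integer(n_classes)
  }
  if (k < 2L) stop("need at least 2 distance classes", call. = FALSE)
  brk <- seq(min(dg), max(dg), length.out = k + 1L)
  # vegan bins into (lower, upper]; nudge the first break down so the
  # minimum-distance pair is not dropped and the classes are exhaustive
  brk_pass <- brk
  brk_pass[1] <- brk[1] - max(1e-9, 1e-9 * (brk[k + 1L] - brk[1]))
  run <- function() {
    vegan::mantel.correlog(stats::as.dist(unclass(cultural)), D.geo = dg,
                           break.pts = brk_pass, cutoff = FALSE,
                           nperm = n_perm, mult = "hochberg",
                           progressive = FALSE)
  }
  fit <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  m <- as.data.frame(unclass(fit$mantel.res))
  classes <- data.frame(
    class_index = seq_len(nrow(m)),
    lower_km = brk[-length(brk)],
    upper_km = brk[-1],
    midpoint_km = m[["class.index"]],
    n_pairs = as.integer(m[["n.dist"]] / 2),  # vegan counts ordered pairs
    mantel_r = m[["Mantel.cor"]],
    p_raw = m[["Pr(Mantel)"]],
    p_adjusted = m[["Pr(corrected)"]]
  )
  classes$untestable <- classes$n_pairs < 10L
  classes$significant <- !classes$untestable &
    !is.na(classes$p_adjusted) & classes$p_adjusted < 0.05
  structure(list(classes = classes, n_perm = n_perm,
                 break_points = brk),
            class = "correlogram_result")
}

#' @export
print.correlogram_result <- function(x, ...) {
  cat(sprintf("Mantel correlogram: %d classes, %d permutations\n",
              nrow(x$classes), x$n_perm))
  print(x$classes, digits = 4)
  invisible(x)
}

#' Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "hochberg")`, kept as a named
#' surface because correlogram p-values are corrected with it.
#'
#' @param p numeric vector of raw p-values.
#' @return Adjusted p-values, same order as input.
#' @export
hochberg_adjust <- function(p) stats::p.adjust(p, method = "hochberg")

#' Correlation of cultural distance with chronological distance
#'
#' Spearman Mantel-type permutation test between a cultural distance matrix
#' and the time-slice rank distance of single-slice observations (see
#' [timeslice_distance()]).
#'
#' @param cultural a [dist_matrix()].
#' @param temporal a [dist_matrix()] with metric `"timeslice"`, same labels.
#' @param n_perm permutations (default 999).
#' @param seed optional integer seed.
#' @return A `mantel_result`.
#' @export
time_distance_correlation <- function(cultural, temporal, n_perm = 999L,
                                      seed = NULL) {
  mantel_test(cultural, temporal, method = "spearman", n_perm = n_perm,
              seed = seed)
}
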