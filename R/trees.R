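#' Ward dendrogram on a distance matrix
#'
#' Agglomerative clustering with Ward's minimum-variance criterion in the
#' `ward.D2` convention (Lance--Williams update on squared dissimilarities,
#' applied to unsquared input distances). `ward.D1` applies the same update
#' to the distances as given.
#'
#' @param dist a [dist_matrix()] with >= 3 labels.
#' @param variant `"ward.D2"` (default) or `"ward.D"`.
#' @return An `hclust` object.
#' @export
ward_tree <- function(dist, variant = c("ward.D2", "ward.D")) {
  stopifnot(inherits(dist, "dist_matrix"))
  variant <- match.arg(variant)
  if (nrow(dist) < 3L) stop("need at least 3 labels", call. = FALSE)
  stats::hclust(stats::as.dist(unclass(dist)), method = variant)
}

# rooted clades (leaf-label sets, size >= 2, < n) of an hclust/phylo tree
.clade_sets <- function(tree) {
  phy <- if (inherits(tree, "phylo")) tree else ape::as.phylo(tree)
  parts <- ape::prop.part(phy)
  labs <- attr(parts, "labels")
  n <- length(labs)
  sets <- lapply(parts, function(p) sort(labs[p]))
  sets <- sets[vapply(sets, length, integer(1)) < n]
  unique(sets)
}

#' Bootstrap a Ward dendrogram and collapse weak branches
#'
#' Builds the reference Ward tree from the full data, then resamples the
#' variable columns (traits, or PC scores) with replacement `n_boot` times,
#' recomputing the distance matrix and tree each time. The support of every
#' internal branch of the reference tree is the percentage of replicates
#' containing the same leaf clade; branches below `threshold` are collapsed
#' into polytomies. Rows (observations) are never resampled: support is
#' character support, not sample support.
#'
#' @param data a [trait_matrix()] (distance: Gower) or [pca_shapespace()]
#'   result / plain score matrix (distance: Euclidean).
#' @param n_boot bootstrap replicates (default 1000).
#' @param threshold collapse threshold in percent (default 50).
#' @param seed optional integer seed.
#' @param variant Ward variant passed to [ward_tree()].
#' @return Object of class `consensus_tree`: list with `tree` (collapsed
#'   `phylo`, node labels = supports), `full_tree` (uncollapsed `phylo`),
#'   `hclust`, `supports` (per internal node, percent), `threshold`,
#'   `n_boot`.
#' @export
bootstrap_consensus <- function(data, n_boot = 1000L, threshold = 50,
                                seed = NULL, variant = "ward.D2") {
  if (inherits(data, "trait_matrix")) {
    mat <- data$values
    dfun <- function(m) gower_distance(m)
  } else {
    mat <- if (inherits(data, "shape_space")) data$scores else as.matrix(data)
    dfun <- function(m) shape_distance(m)
  }
  if (ncol(mat) < 2L) stop("need >= 2 resamplable columns", call. = FALSE)
  if (nrow(mat) < 3L) stop("need >= 3 rows", call. = FALSE)
  ref_hc <- ward_tree(dfun(mat), variant = variant)
  ref_phy <- ape::as.phylo(ref_hc)
  ref_clades <- .clade_sets(ref_phy)

  boot_once <- function() {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    bm <- mat[, cols, drop = FALSE]
    colnames(bm) <- make.unique(colnames(mat)[cols])
    .clade_sets(ward_tree(dfun(bm), variant = variant))
  }
  run <- function() replicate(n_boot, boot_once(), simplify = FALSE)
  reps <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  keys <- vapply(ref_clades, paste, character(1), collapse = "\r")
  counts <- integer(length(keys))
  names(counts) <- keys
  for (rp in reps) {
    rk <- vapply(rp, paste, character(1), collapse = "\r")
    hit <- keys %in% rk
    counts[hit] <- counts[hit] + 1L
  }
  support_pct <- 100 * counts / n_boot

  # map supports onto the phylo internal nodes (root has support 100 by
  # convention: the full leaf set is in every replicate)
  n_tip <- length(ref_phy$tip.label)
  node_support <- numeric(ref_phy$Nnode)
  for (nd in seq_len(ref_phy$Nnode)) {
    tips <- sort(ref_phy$tip.label[
      .tips_under(ref_phy, nd + n_tip)])
    key <- paste(tips, collapse = "\r")
    node_support[nd] <- if (length(tips) == n_tip) 100 else support_pct[[key]]
  }
  full <- ref_phy
  full$node.label <- formatC(node_support, format = "f", digits = 1)

  collapsed <- .collapse_by_support(full, node_support, threshold)
  structure(list(tree = collapsed, full_tree = full, hclust = ref_hc,
                 supports = node_support, threshold = threshold,
                 n_boot = n_boot),
            class = "consensus_tree")
}

# tips descending from `node` in a phylo tree
.tips_under <- function(phy, node) {
  n_tip <- length(phy$tip.label)
  if (node <= n_tip) return(node)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, .tips_under, phy = phy))
}

# collapse internal edges whose child-node support falls below threshold;
# zero their branch length and let di2multi create the polytomies
.collapse_by_support <- function(phy, node_support, threshold) {
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  weak <- which(node_support < threshold) + n_tip
  weak <- setdiff(weak, root)
  if (length(weak)) {
    eidx <- which(phy$edge[, 2] %in% weak)
    phy$edge.length[eidx] <- 0
    phy <- ape::di2multi(phy, tol = 1e-12)
  }
  phy
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(sprintf(
    "consensus_tree: %d leaves, %d/%d internal branches >= %.0f%% support (%d bootstraps)\n",
    length(x$full_tree$tip.label), sum(x$supports >= x$threshold) - 1L,
    length(x$supports) - 1L, x$threshold, x$n_boot))
  invisible(x)
}

#' Stratified subsample of outlines per NAC
#'
#' Samples up to `per_nac` outlines per NAC uniformly without replacement;
#' NACs with fewer outlines keep everything they have. Used to tame the
#' strongly uneven per-NAC outline counts before tree building.
#'
#' @param x an [outline_set()], or a character vector of NAC ids (in which
#'   case selected indices are returned).
#' @param per_nac outlines to keep per NAC (default 2).
#' @param seed optional integer seed.
#' @return An [outline_set()] (or integer indices for the vector method).
#' @export
stratified_subsample <- function(x, per_nac = 2L, seed = NULL) {
  if (per_nac < 1L) stop("per_nac must be >= 1", call. = FALSE)
  nacs <- if (inherits(x, "outline_set")) outline_meta(x)$nac_id else as.character(x)
  if (length(nacs) == 0L) stop("empty set", call. = FALSE)
  pick <- function() {
    unlist(lapply(split(seq_along(nacs), nacs), function(idx) {
      if (length(idx) <= per_nac) idx else sort(sample(idx, per_nac))
    }), use.names = FALSE)
  }
  sel <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  sel <- sort(sel)
  if (inherits(x, "outline_set")) x[sel] else sel
}

#' Compare two dendrograms over the same leaves
#'
#' Reports the non-trivial clades (leaf sets) present in both trees and an
#' entanglement score in \[0, 1\]: after one greedy bottom-up rotation pass
#' that reorders each subtree of `treeB` toward the fixed leaf order of
#' `treeA`, the normalized L1 distance between the two leaf rank orders.
#' 0 means perfectly aligned leaf orders; the score is an artifact-defined
#' summary of what a tanglegram shows visually.
#'
#' @param treeA,treeB `hclust` trees (or `consensus_tree` objects, whose
#'   reference `hclust` is used) over identical leaf sets.
#' @return List with `shared_clades` (list of character vectors) and
#'   `entanglement` (numeric scalar).
#' @export
tanglegram_compare <- function(treeA, treeB) {
  hcA <- if (inherits(treeA, "consensus_tree")) treeA$hclust else treeA
  hcB <- if (inherits(treeB, "consensus_tree")) treeB$hclust else treeB
  stopifnot(inherits(hcA, "hclust"), inherits(hcB, "hclust"))
  if (!setequal(hcA$labels, hcB$labels)) {
    stop("leaf sets differ: ",
         paste(c(setdiff(hcA$labels, hcB$labels),
                 setdiff(hcB$labels, hcA$labels)), collapse = ", "),
         call. = FALSE)
  }
  cladesA <- .clade_sets(hcA)
  cladesB <- .clade_sets(hcB)
  kA <- vapply(cladesA, paste, character(1), collapse = "\r")
  kB <- vapply(cladesB, paste, character(1), collapse = "\r")
  shared <- cladesA[kA %in% kB]

  posA <- stats::setNames(seq_along(hcA$order), hcA$labels[hcA$order])
  orderB <- .untangle_order(hcB, posA)
  posB <- stats::setNames(seq_along(orderB), orderB)
  n <- length(posA)
  l1 <- sum(abs(posA - posB[names(posA)]))
  list(shared_clades = shared,
       entanglement = if (n < 2) 0 else l1 / floor(n^2 / 2))
}

# bottom-up greedy rotation: at each merge place the subtree whose leaves
# sit earlier (on average) in the reference order first
.untangle_order <- function(hc, ref_pos) {
  n <- length(hc$labels)
  sub <- vector("list", nrow(hc$merge))
  leaf <- function(i) hc$labels[-i]
  for (m in seq_len(nrow(hc$merge))) {
    get <- function(j) if (j < 0) leaf(j) else sub[[j]]
    L <- get(hc$merge[m, 1]); R <- get(hc$merge[m, 2])
    sub[[m]] <- if (mean(ref_pos[L]) <= mean(ref_pos[R])) c(L, R) else c(R, L)
  }
  sub[[nrow(hc$merge)]]
}
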