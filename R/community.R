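#' Bray-Curtis dissimilarities between station profiles
#'
#' `BC(s, t) = sum_g |x_gs - x_gt| / sum_g (x_gs + x_gt)` over gene families
#' (or ESTUs). Accepts a relative-stage [abundance_table()] (masked samples
#' are excluded first) or a samples-in-rows matrix such as an ESTU table.
#' Computation is delegated to [vegan::vegdist()].
#'
#' @param x `abundance_table` (families x samples) or numeric matrix with
#'   samples in rows.
#' @return a `dist` object over samples (diagonal 0, values in `[0, 1]`).
#' @export
bray_curtis <- function(x) {
  m <- profile_matrix(x)            # samples x features
  if (any(rowSums(m) == 0))
    stop("sample(s) with all-zero profile: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "),
         " (Bray-Curtis undefined)")
  vegan::vegdist(m, method = "bray")
}

# samples-in-rows numeric matrix from either input form, dropping masked
# samples of a relative-stage table
profile_matrix <- function(x) {
  if (inherits(x, "abundance_table")) {
    v <- x$values
    keep <- colSums(!is.na(v)) > 0
    m <- t(v[, keep, drop = FALSE])
  } else {
    m <- as.matrix(x)
  }
  if (!is.numeric(m)) stop("profiles must be numeric")
  m
}

#' Ward's minimum-variance clustering of stations
#'
#' Agglomerative clustering of a Bray-Curtis dissimilarity matrix under the
#' Ward.D2 Lance-Williams update (squared-dissimilarity criterion), via
#' [stats::hclust()].
#'
#' @param d `dist` object or symmetric dissimilarity matrix.
#' @param method linkage; `"ward.D2"` is the package reading of "Ward's
#'   minimum variance" (configurable because the original variant is
#'   unnamed in most method sections).
#' @return an `hclust` dendrogram.
#' @export
ward_cluster <- function(d, method = "ward.D2") {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isSymmetric(unname(m)))
      stop("dissimilarity matrix must be symmetric")
    d <- stats::as.dist(m)
  }
  if (attr(d, "Size") < 2) stop("need >= 2 samples to cluster")
  stats::hclust(d, method = method)
}

#' Cut a dendrogram into k groups
#'
#' Cuts the `k - 1` highest merges; ties at the cut height are resolved
#' deterministically by merge order (the [stats::cutree()] convention) and
#' logged.
#'
#' @param tree `hclust` object.
#' @param k number of groups, `1 <= k <=` number of leaves.
#' @return named integer vector sample -> group.
#' @export
cut_k <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  if (k > 1 && k < n) {
    h <- sort(tree$height, decreasing = TRUE)
    if (h[k - 1] == h[k])
      ecag_log("cut_k: tie at the cut height resolved by merge order")
  }
  stats::cutree(tree, k = k)
}

#' Export a dendrogram as a newick string or file
#' @param tree `hclust` object.
#' @param path optional output file; when `NULL` the newick string is
#'   returned.
#' @export
write_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Mantel test of congruence between two distance matrices
#'
#' Pearson correlation `r` of the lower-triangle entries, with a one-sided
#' permutation p-value: rows and columns of the second matrix are permuted
#' jointly and `p = (1 + #{r* >= r}) / (1 + n_perm)` (add-one correction, so
#' p is never 0 and `p < 1e-4` is resolvable at the default 10,000
#' permutations). Delegated to [vegan::mantel()].
#'
#' @param d1,d2 `dist` objects over the same samples in the same order.
#' @param n_perm number of permutations.
#' @param seed optional integer seed for the permutations.
#' @return list with `r`, `p` and `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 10000, seed = NULL) {
  if (attr(d1, "Size") != attr(d2, "Size"))
    stop("distance matrices differ in size")
  l1 <- labels(d1); l2 <- labels(d2)
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stop("distance matrices must cover the same samples in the same order")
  if (attr(d1, "Size") < 3) stop("need >= 3 samples for a Mantel test")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel(d1, d2, method = "pearson", permutations = n_perm)
  list(r = unname(fit$statistic), p = unname(fit$signif), n_perm = n_perm)
}

#' Compare two partitions of the same samples
#'
#' @param p1,p2 named group labels over the same sample set.
#' @return list with the contingency `table` and the adjusted Rand index
#'   `ari` ([mclust::adjustedRandIndex()]); identical partitions give
#'   `ari = 1`.
#' @export
compare_partitions <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2)))
      stop("partitions cover different sample sets")
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    stop("partitions differ in length")
  }
  list(table = table(p1, p2),
       ari = mclust::adjustedRandIndex(p1, p2))
}
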