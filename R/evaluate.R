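# Evaluation of a run against the recorded ground truth of the synthetic
# generator: planted-module recovery and planted-eCAG recovery.

#' Adjusted Rand index between detected modules and planted niche labels
#'
#' Computed over the genes that carry a planted niche label (neutral
#' families have no planted module and are excluded) and were retained in
#' the partition; detected labels are the module colors, `"grey"` counting
#' as its own group.
#'
#' @param partition `module_partition`.
#' @param truth `truth` component of a simulated dataset.
#' @return list with `ari`, `n_genes` and the contingency `table`.
#' @export
module_recovery_ari <- function(partition, truth) {
  planted <- truth$planted_modules
  planted <- planted[planted != "neutral"]
  common <- intersect(names(planted), names(partition))
  if (!length(common)) stop("no planted gene retained in the partition")
  cmp <- compare_partitions(stats::setNames(unname(planted[common]), common),
                            stats::setNames(unname(partition[common]), common))
  list(ari = cmp$ari, n_genes = length(common), table = cmp$table)
}

#' Pair-level precision and recall of recovered eCAGs
#'
#' Truth pairs are all unordered gene pairs within a planted eCAG;
#' recovered pairs all pairs within a delineated eCAG. Precision is the
#' fraction of recovered pairs that are planted, recall the fraction of
#' planted pairs recovered. Pair-level scoring degrades gracefully when a
#' single gene is lost from an otherwise perfect cluster, unlike exact
#' set matching.
#'
#' @param ecags `ecag_set` (or list with `members` elements).
#' @param truth `truth` component of a simulated dataset.
#' @return list with `precision`, `recall`, `n_recovered_pairs`,
#'   `n_truth_pairs`.
#' @export
ecag_pair_scores <- function(ecags, truth) {
  pair_key <- function(members) {
    if (length(members) < 2) return(character())
    cmb <- utils::combn(sort(members), 2)
    paste(cmb[1, ], cmb[2, ], sep = "|")
  }
  truth_pairs <- unique(unlist(lapply(truth$planted_ecags,
                                      function(e) pair_key(e$members))))
  rec_pairs <- unique(unlist(lapply(ecags, function(e) pair_key(e$members))))
  tp <- length(intersect(rec_pairs, truth_pairs))
  list(precision = if (length(rec_pairs)) tp / length(rec_pairs) else NA_real_,
       recall = if (length(truth_pairs)) tp / length(truth_pairs) else NA_real_,
       n_recovered_pairs = length(rec_pairs),
       n_truth_pairs = length(truth_pairs))
}

#' Planted direction of each niche module along each gradient
#'
#' The reference direction against which module-trait correlation signs are
#' checked: the Pearson correlation of each ESTU's noise-free niche
#' response profile (row-normalised Gaussian response at the simulated
#' stations) with each environmental parameter.
#'
#' @param env simulated environment table.
#' @param truth `truth` component of a simulated dataset.
#' @return matrix ESTU/niche x parameter of correlations.
#' @export
planted_trait_direction <- function(env, truth) {
  abund <- simulate_community(env, truth)
  stats::cor(abund, as.matrix(env[rownames(abund), , drop = FALSE]),
             use = "pairwise.complete.obs")
}
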