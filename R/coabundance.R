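# Weighted gene co-abundance network analysis: soft-thresholded unsigned
# adjacency, topological overlap, static-cut module detection with
# eigengene merging, module eigengenes/kME and module-trait correlation.
# This is the package's own implementation of the weighted-correlation-
# network methodology, not a wrapper.

module_color_names <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta")

# genes-in-rows numeric matrix restricted to unmasked samples; drops (and
# logs) constant genes, whose correlations are undefined
network_profiles <- function(profiles, transform = "none") {
  v <- if (inherits(profiles, "abundance_table")) profiles$values
       else as.matrix(profiles)
  v <- v[, colSums(!is.na(v)) > 0, drop = FALSE]
  if (transform == "log10") {
    nz <- v[v > 0 & !is.na(v)]
    c0 <- if (length(nz)) min(nz) / 2 else 1
    v <- log10(v + c0)
  }
  sds <- apply(v, 1, stats::sd, na.rm = TRUE)
  means <- rowMeans(v, na.rm = TRUE)
  # constant up to floating point: correlations would be meaningless
  keep <- !is.na(sds) & sds > 1e-10 * pmax(abs(means), 1e-12)
  if (any(!keep))
    ecag_log("network: %d constant gene profile(s) excluded", sum(!keep))
  v[keep, , drop = FALSE]
}

# Pearson across samples, pairwise complete; pairs with < 4 complete
# observations are set to 0 and counted. When a control profile is given
# (the observed log marker coverage), first-order partial correlations
# controlling for it are returned: ratios with a common noisy divisor are
# spuriously correlated (the marker's sampling noise is shared by every
# gene's relative abundance), and partialling the observed divisor out
# removes that technical component.
gene_correlation <- function(v, control = NULL) {
  r <- suppressWarnings(stats::cor(t(v), use = "pairwise.complete.obs"))
  if (!is.null(control)) {
    control <- control[colnames(v)]
    if (stats::sd(control, na.rm = TRUE) >
        1e-10 * max(abs(mean(control, na.rm = TRUE)), 1e-12)) {
      rm_ <- suppressWarnings(
        stats::cor(t(v), control, use = "pairwise.complete.obs"))[, 1]
      rm_[is.na(rm_)] <- 0
      rm_ <- pmin(pmax(rm_, -1 + 1e-8), 1 - 1e-8)
      r <- (r - outer(rm_, rm_)) /
        sqrt(outer(1 - rm_^2, 1 - rm_^2))
      r <- pmin(pmax(r, -1), 1)
    }
  }
  n_obs <- crossprod(!is.na(t(v)))
  low <- n_obs < 4 & row(r) != col(r)
  bad <- is.na(r) | low
  n_low <- sum(bad[upper.tri(bad)])
  r[bad] <- 0
  diag(r) <- 1
  attr(r, "n_low_support") <- n_low
  r
}

#' Pick the soft-threshold power by the scale-free fit criterion
#'
#' For each candidate power the unsigned adjacency `|r|^beta` is formed and
#' the signed scale-free topology fit is evaluated: connectivities are
#' binned, and `R^2` of `log10 p(k)` on `log10 k` is signed by the negative
#' of the regression slope (scale-free networks have decreasing `p(k)`).
#' The smallest power reaching `target_fit` is chosen; if none reaches it,
#' the power with the best fit is used. The full fit table is returned for
#' logging/reporting.
#'
#' @param profiles relative-abundance `abundance_table` (or genes x samples
#'   matrix) of retained flexible genes.
#' @param powers candidate integer powers.
#' @param target_fit required signed `R^2` (default 0.8).
#' @param n_bins connectivity histogram bins for the fit.
#' @param transform `"none"` or `"log10"` (offset of half the smallest
#'   nonzero value).
#' @param control optional named per-sample control profile (typically the
#'   observed log marker coverage): first-order partial correlations
#'   controlling for it are used, removing the spurious correlation that a
#'   shared noisy denominator induces between marker-relative profiles.
#' @return list with `power` (chosen beta) and `fits` (data.frame: power,
#'   signed fit, slope, mean/median/max connectivity).
#' @export
pick_soft_threshold <- function(profiles, powers = 1:20, target_fit = 0.8,
                                n_bins = 10, transform = "none",
                                control = NULL) {
  v <- network_profiles(profiles, transform)
  if (ncol(v) < 8)
    stop("need >= 8 samples to assess scale-free fit")
  r <- abs(gene_correlation(v, control))
  fits <- do.call(rbind, lapply(powers, function(beta) {
    a <- r^beta
    k <- rowSums(a) - 1
    data.frame(power = beta, fit = scale_free_fit(k, n_bins)["fit"],
               slope = scale_free_fit(k, n_bins)["slope"],
               mean_k = mean(k), median_k = stats::median(k),
               max_k = max(k))
  }))
  rownames(fits) <- NULL
  ok <- which(!is.na(fits$fit) & fits$fit >= target_fit)
  if (length(ok)) {
    power <- fits$power[ok[1]]
  } else {
    # No power achieves approximate scale-free topology (typical for
    # strongly modular, block-structured co-abundance data, where the fit
    # curve is uninformative). Prefer the strongest suppression of
    # background correlation that keeps the average gene connected:
    # the largest candidate power with mean connectivity >= 1.
    cand <- which(!is.na(fits$mean_k) & fits$mean_k >= 1)
    power <- if (length(cand)) fits$power[max(cand)] else
      fits$power[which.max(fits$fit)]
  }
  ecag_log("soft threshold: power %d (signed R^2 = %s)", power,
           format(fits$fit[fits$power == power], digits = 3))
  list(power = power, fits = fits)
}

# Signed scale-free fit of a connectivity distribution. Equal-occupancy
# (quantile) bins with a proper density normalisation: equal-width bins on
# the heavily skewed k distributions of soft-thresholded networks produce
# noisy, artifact-prone fit values, whereas equal-occupancy bins give a
# stable estimate (and, on genuinely scale-free degree sequences, fits
# close to 1).
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  # a power law fitted to a dispersion-free connectivity distribution is
  # vacuous: report no fit rather than an arbitrary one
  if (length(k) < n_bins || stats::sd(k) < 0.1 * mean(k))
    return(c(fit = NA_real_, slope = NA_real_))
  br <- unique(stats::quantile(k, probs = seq(0, 1,
                                              length.out = n_bins + 1)))
  if (length(br) < 4) return(c(fit = NA_real_, slope = NA_real_))
  bins <- cut(k, br, include.lowest = TRUE)
  cnt <- tapply(k, bins, length)
  dens <- cnt / (length(k) * diff(br))
  k_mean <- tapply(k, bins, mean)
  use <- !is.na(dens) & dens > 0 & k_mean > 0
  if (sum(use) < 3) return(c(fit = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(dens[use]) ~ log10(k_mean[use]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  c(fit = unname(-sign(slope) * r2), slope = unname(slope))
}

#' Build the weighted gene network (adjacency and topological overlap)
#'
#' Unsigned adjacency `a_ij = |cor(x_i, x_j)|^beta` (Pearson, pairwise
#' complete across unmasked samples; pairs with fewer than 4 complete
#' observations get correlation 0 and are counted), connectivity
#' `k_i = sum_{j != i} a_ij`, and topological overlap
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `TOM_ii = 1`.
#'
#' @param profiles relative-abundance table or genes x samples matrix.
#' @param power soft-threshold beta from [pick_soft_threshold()].
#' @param transform see [pick_soft_threshold()].
#' @param control see [pick_soft_threshold()].
#' @return object of class `gene_network`: `adjacency`, `tom`,
#'   `connectivity`, `power`, `profiles` (the filtered matrix used).
#' @export
build_network <- function(profiles, power, transform = "none",
                          control = NULL) {
  v <- network_profiles(profiles, transform)
  r <- gene_correlation(v, control)
  n_low <- attr(r, "n_low_support")
  a <- abs(r)^power
  attributes(a) <- attributes(a)["dim"]
  dimnames(a) <- dimnames(r)
  diag(a) <- 1
  k <- rowSums(a) - 1
  b <- a
  diag(b) <- 0
  num <- b %*% b + b
  denom <- outer(k, k, pmin) + 1 - b
  tom <- num / denom
  diag(tom) <- 1
  tom <- pmin(pmax(tom, 0), 1)
  structure(list(adjacency = a, tom = tom, connectivity = k, power = power,
                 profiles = v, control = control,
                 n_low_support = n_low),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, power %d, mean connectivity %.2f\n",
              nrow(x$adjacency), x$power, mean(x$connectivity)))
  invisible(x)
}

#' Detect co-abundance modules from topological overlap
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut statically at `cut_height` times the highest merge; branches with at
#' least `min_module_size` genes become modules (colors assigned by
#' decreasing size), everything else is `grey`. Modules whose eigengenes
#' correlate above `1 - merge_height` are then merged iteratively and colors
#' reassigned by final size. This is a deliberately simple static cut plus
#' eigengene merging; recovery of planted modules, not replication of any
#' particular module count, is the supported use.
#'
#' @param net `gene_network` from [build_network()].
#' @param min_module_size smallest module size (grey excepted).
#' @param cut_height fraction of the maximum merge height at which the tree
#'   is cut.
#' @param merge_height modules with eigengene correlation above
#'   `1 - merge_height` are merged.
#' @param min_gene_kme cohesion screen: genes whose correlation with their
#'   own module's eigengene falls below this are returned to grey, and
#'   modules dropping below `min_module_size` dissolve. This removes the
#'   incoherent "leftover" branch that a static height cut otherwise
#'   gathers near the top of the tree (the same concern the kME-based
#'   refinement stage of dynamic tree cutting addresses).
#' @return object of class `module_partition`: named character vector gene
#'   -> module color (`"grey"` = unassigned), with attributes `sizes` and
#'   `tree`.
#' @export
detect_modules <- function(net, min_module_size = 10, cut_height = 0.995,
                           merge_height = 0.25, min_gene_kme = 0.5) {
  ctrl <- net$control
  stopifnot(inherits(net, "gene_network"))
  diss <- 1 - net$tom
  tree <- stats::hclust(stats::as.dist(diss), method = "average")
  genes <- rownames(net$tom)
  h_cut <- cut_height * max(tree$height)
  cl <- cut_static(tree, h_cut)
  labels <- rep("grey", length(genes))
  names(labels) <- genes
  sizes <- sort(table(cl), decreasing = TRUE)
  big <- names(sizes)[sizes >= min_module_size]
  if (length(big) == 0) {
    warning("no module reaches min_module_size; all genes grey")
  } else {
    for (i in seq_along(big))
      labels[cl == as.integer(big[i])] <- module_color(i)
    labels <- prune_low_kme(labels, net$profiles, min_gene_kme,
                            min_module_size, ctrl)
    labels <- merge_close_modules(labels, net$profiles, merge_height, ctrl)
    labels <- relabel_by_size(labels)
  }
  ecag_log("modules: %d module(s), %d/%d genes assigned",
           length(setdiff(unique(labels), "grey")),
           sum(labels != "grey"), length(labels))
  structure(labels, sizes = table(labels), tree = tree,
            class = "module_partition")
}

# static branch cut: leaves joined by merges at height <= h form one
# cluster. Implemented by walking the merge list so that the occasional
# tiny floating-point height inversion of average linkage is harmless.
cut_static <- function(tree, h) {
  n <- length(tree$labels)
  leaf_of_merge <- integer(nrow(tree$merge))   # representative leaf
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_len(nrow(tree$merge))) {
    a <- tree$merge[k, 1]; b <- tree$merge[k, 2]
    la <- if (a < 0) -a else leaf_of_merge[a]
    lb <- if (b < 0) -b else leaf_of_merge[b]
    leaf_of_merge[k] <- la
    if (tree$height[k] <= h) {
      ra <- find(la); rb <- find(lb)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  cl <- as.integer(factor(roots, levels = unique(roots)))
  stats::setNames(cl, tree$labels)
}

module_color <- function(i) {
  if (i <= length(module_color_names)) module_color_names[i]
  else paste0("module", i)
}

# correlation between columns of x and columns (or a vector) y over
# samples, optionally partialling out the control profile; sample_ids give
# the row alignment for the control vector
controlled_cor <- function(x, y, control = NULL, sample_ids = NULL) {
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  r <- suppressWarnings(stats::cor(x, y, use = "pairwise.complete.obs"))
  if (!is.null(control)) {
    ctl <- if (!is.null(sample_ids)) control[sample_ids] else control
    if (stats::sd(ctl, na.rm = TRUE) >
        1e-10 * max(abs(mean(ctl, na.rm = TRUE)), 1e-12)) {
      rxc <- suppressWarnings(
        stats::cor(x, ctl, use = "pairwise.complete.obs"))[, 1]
      ryc <- suppressWarnings(
        stats::cor(y, ctl, use = "pairwise.complete.obs"))[, 1]
      rxc <- pmin(pmax(rxc, -1 + 1e-8), 1 - 1e-8)
      ryc <- pmin(pmax(ryc, -1 + 1e-8), 1 - 1e-8)
      r <- (r - outer(rxc, ryc)) / sqrt(outer(1 - rxc^2, 1 - ryc^2))
      r <- pmin(pmax(r, -1), 1)
    }
  }
  if (ncol(r) == 1) r[, 1] else r
}

# cohesion screen: members must track their own module eigengene, in the
# same (possibly control-partialled) correlation space the network used
prune_low_kme <- function(labels, profiles, min_gene_kme, min_module_size,
                          control = NULL) {
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (!length(mods)) return(labels)
    me <- eigengene_matrix(profiles, labels, mods)
    changed <- FALSE
    for (m in mods) {
      members <- names(labels)[labels == m]
      kme <- controlled_cor(t(profiles[members, , drop = FALSE]), me[m, ],
                            control, colnames(profiles))
      drop <- members[is.na(kme) | kme < min_gene_kme]
      if (length(drop)) {
        labels[drop] <- "grey"
        changed <- TRUE
      }
      if (sum(labels == m) < min_module_size) {
        labels[labels == m] <- "grey"
        changed <- TRUE
      }
    }
    if (!changed) return(labels)
  }
}

merge_close_modules <- function(labels, profiles, merge_height,
                                control = NULL) {
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) return(labels)
    me <- eigengene_matrix(profiles, labels, mods)
    cc <- controlled_cor(t(me), t(me), control, colnames(profiles))
    diag(cc) <- -Inf
    cc[is.na(cc)] <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[best[1], best[2]] <= 1 - merge_height) return(labels)
    from <- mods[max(best)]; into <- mods[min(best)]
    ecag_log("modules: merging '%s' into '%s' (eigengene r = %.3f)",
             from, into, cc[best[1], best[2]])
    labels[labels == from] <- into
  }
}

relabel_by_size <- function(labels) {
  mods <- setdiff(unique(labels), "grey")
  sz <- sort(table(labels[labels != "grey"])[mods], decreasing = TRUE)
  map <- stats::setNames(vapply(seq_along(sz), module_color, ""), names(sz))
  out <- labels
  out[labels != "grey"] <- map[labels[labels != "grey"]]
  out
}

# module x sample eigengene matrix (used internally during merging and by
# module_eigengene)
eigengene_matrix <- function(v, labels, mods) {
  t(vapply(mods, function(m) {
    x <- v[names(labels)[labels == m], , drop = FALSE]
    single_eigengene(x)
  }, numeric(ncol(v))))
}

# first right singular vector of the gene-standardized module submatrix,
# sign-oriented towards the mean standardized member profile; unit norm
single_eigengene <- function(x) {
  xz <- t(scale(t(x)))
  xz[is.na(xz)] <- 0
  if (nrow(xz) == 1) {
    me <- xz[1, ]
    n <- sqrt(sum(me^2))
    return(if (n > 0) me / n else me)
  }
  sv <- svd(xz, nu = 0, nv = 1)
  me <- sv$v[, 1]
  avg <- colMeans(xz)
  s <- suppressWarnings(stats::cor(me, avg))
  if (!is.na(s) && s < 0) me <- -me
  stats::setNames(me, colnames(x))
}

#' Module eigengenes and gene-module correlations (kME)
#'
#' The eigengene of a module is the first principal component (first right
#' singular vector) of its gene-standardized abundance submatrix across
#' unmasked stations: a unit-norm per-station profile representative of the
#' module, sign-oriented so that it correlates positively with the mean
#' member profile. `kME[g, m]` is the Pearson correlation of gene `g`'s
#' profile with module `m`'s eigengene, computed for every gene against
#' every module.
#'
#' @param profiles relative-abundance table or genes x samples matrix
#'   covering the partitioned genes.
#' @param partition `module_partition` from [detect_modules()].
#' @return object of class `eigengene_set`: `ME` (module x sample), `kME`
#'   (gene x module), `var_explained` (per module).
#' @export
module_eigengene <- function(profiles, partition) {
  v <- network_profiles(profiles)
  v <- v[intersect(rownames(v), names(partition)), , drop = FALSE]
  mods <- setdiff(unique(partition), "grey")
  if (!length(mods)) stop("partition has no modules")
  mods <- names(sort(table(partition[partition != "grey"])[mods],
                     decreasing = TRUE))
  me <- eigengene_matrix(v, partition[rownames(v)], mods)
  colnames(me) <- colnames(v)
  kme <- suppressWarnings(stats::cor(t(v), t(me),
                                     use = "pairwise.complete.obs"))
  ve <- vapply(mods, function(m) {
    x <- t(scale(t(v[names(partition)[partition == m] |>
                       intersect(rownames(v)), , drop = FALSE])))
    x[is.na(x)] <- 0
    tot <- sum(x^2)
    if (tot == 0) return(0)
    sum((x %*% me[m, ])^2) / tot
  }, 0)
  structure(list(ME = me, kME = kme, var_explained = ve),
            class = "eigengene_set")
}

#' @export
print.eigengene_set <- function(x, ...) {
  cat(sprintf("eigengene_set: %d modules x %d stations\n",
              nrow(x$ME), ncol(x$ME)))
  invisible(x)
}

#' Correlate module eigengenes with environment and ESTU profiles
#'
#' Pearson correlation for environmental parameters, Spearman for ESTU
#' relative abundances, over pairwise-complete stations. P-values use the
#' Student asymptotic form `t = r sqrt((n - 2) / (1 - r^2))` with `n - 2`
#' degrees of freedom (two-sided); no multiple-testing correction is
#' applied, matching the raw `p > alpha` masking of module-trait heatmaps.
#' Parameters with fewer than 3 paired observations are reported as
#' missing.
#'
#' @param me `eigengene_set`.
#' @param env environment data.frame (stations in rows) or `NULL`.
#' @param estu ESTU matrix (stations in rows) or `NULL`.
#' @param alpha significance threshold for the `significant` flag.
#' @return list with components `environment` and `estu`, each a list of
#'   module x parameter matrices `r`, `p`, `n`, `significant`.
#' @export
module_trait_correlation <- function(me, env = NULL, estu = NULL,
                                     alpha = 0.01) {
  out <- list()
  if (!is.null(env))
    out$environment <- trait_block(me$ME, as.matrix(env), "pearson", alpha)
  if (!is.null(estu))
    out$estu <- trait_block(me$ME, as.matrix(estu), "spearman", alpha)
  out
}

trait_block <- function(ME, traits, method, alpha) {
  st <- intersect(colnames(ME), rownames(traits))
  if (!length(st)) stop("no stations shared between eigengenes and traits")
  r <- p <- n <- matrix(NA_real_, nrow(ME), ncol(traits),
                        dimnames = list(rownames(ME), colnames(traits)))
  for (m in rownames(ME)) for (tr in colnames(traits)) {
    x <- ME[m, st]; y <- traits[st, tr]
    ok <- !is.na(x) & !is.na(y)
    n[m, tr] <- sum(ok)
    if (sum(ok) < 3) next
    rr <- suppressWarnings(stats::cor(x[ok], y[ok], method = method))
    r[m, tr] <- rr
    p[m, tr] <- cor_student_p(rr, sum(ok))
  }
  list(r = r, p = p, n = n, significant = !is.na(p) & p <= alpha,
       method = method)
}

# two-sided Student asymptotic p for a correlation coefficient
cor_student_p <- function(r, n) {
  if (is.na(r) || n < 3) return(NA_real_)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Most representative genes of each module
#'
#' Genes whose correlation with their own module's eigengene (kME) reaches
#' `min_kme`, per module, sorted by decreasing kME; the full kME table (the
#' violin-plot data) is attached as attribute `kme`.
#'
#' @param me `eigengene_set`.
#' @param partition `module_partition`.
#' @param min_kme own-module kME threshold.
#' @return named list (one data.frame `family`, `kme` per module), with the
#'   full own-module kME table in `attr(, "kme")`.
#' @export
representative_genes <- function(me, partition, min_kme = 0.7) {
  mods <- rownames(me$ME)
  own <- data.frame(
    family = rownames(me$kME),
    module = unname(partition[rownames(me$kME)]),
    stringsAsFactors = FALSE)
  own$kme <- NA_real_
  in_mod <- !is.na(own$module) & own$module %in% mods
  own$kme[in_mod] <- me$kME[cbind(own$family[in_mod], own$module[in_mod])]
  out <- lapply(mods, function(m) {
    d <- own[!is.na(own$kme) & own$module == m & own$kme >= min_kme, ,
             drop = FALSE]
    d <- d[order(-d$kme), c("family", "kme")]
    rownames(d) <- NULL
    d
  })
  names(out) <- mods
  attr(out, "kme") <- own
  out
}
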