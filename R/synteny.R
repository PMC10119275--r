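#' Minimal gene-gap distance between two families in one genome
#'
#' Rank distance between the occurrences of two families: immediate
#' neighbours are 1 apart. On a circular replicon of `m` genes the distance
#' between ranks `p` and `q` is `min(|p - q|, m - |p - q|)`; on a linear
#' replicon it is `|p - q|`. Families on different replicons have no
#' distance (`NA`): split pairs never count as adjacent. With paralogs the
#' minimum over all occurrence pairs is taken.
#'
#' @param genome a [genome_annotation()].
#' @param famA,famB family ids.
#' @return integer distance (>= 1) or `NA_integer_` when the two families
#'   do not share a replicon (including absence from the genome).
#' @export
gene_gap_distance <- function(genome, famA, famB) {
  g <- genome$genes
  d_best <- NA_integer_
  for (rep_id in unique(g$replicon_id)) {
    sub <- g[g$replicon_id == rep_id, ]
    rA <- sub$rank[sub$family_id == famA]
    rB <- sub$rank[sub$family_id == famB]
    if (!length(rA) || !length(rB)) next
    dd <- abs(outer(rA, rB, "-"))
    if (genome$topology[[rep_id]] == "circular")
      dd <- pmin(dd, nrow(sub) - dd)
    d <- min(dd)
    if (is.na(d_best) || d < d_best) d_best <- as.integer(d)
  }
  d_best
}

#' Synteny edges between gene families across reference genomes
#'
#' For every family pair co-occurring in at least one genome, counts
#' `n_both` (genomes containing both families), `n_close` (genomes where
#' their minimal gap distance is `<= D`; pairs split across replicons count
#' in `n_both` but never in `n_close`) and `support = n_close / n_both`.
#' Two adjacency rules are provided:
#'
#' * `support` mode (default, D = 5): edge iff `support >= min_support` ---
#'   "less than 6 genes apart in 80% of the genomes possessing them";
#' * `any_genome` mode (D = 4): edge iff `n_close >= 1` --- "less than five
#'   genes apart in at least one genome".
#'
#' @param genomes list of [genome_annotation()] objects.
#' @param mode `"support"` or `"any_genome"`.
#' @param D maximum gap distance; defaults to 5 (support) or 4
#'   (any_genome).
#' @param min_support required fraction of co-carrying genomes (support
#'   mode).
#' @param families optional restriction to a family subset.
#' @return data.frame of class `synteny_edges` with columns `famA`, `famB`
#'   (famA < famB), `n_both`, `n_close`, `support`, `d_min` (overall
#'   minimum), `edge`; rule parameters kept as attributes.
#' @export
build_edges <- function(genomes, mode = c("support", "any_genome"),
                        D = NULL, min_support = 0.8, families = NULL) {
  mode <- match.arg(mode)
  if (is.null(D)) D <- if (mode == "support") 5L else 4L
  fams <- if (is.null(families))
    sort(unique(unlist(lapply(genomes, function(g) g$genes$family_id))))
  else sort(unique(families))
  nf <- length(fams)
  idx <- stats::setNames(seq_len(nf), fams)
  n_both <- n_close <- matrix(0L, nf, nf)
  d_min <- matrix(NA_integer_, nf, nf)

  for (g in genomes) {
    gg <- g$genes[g$genes$family_id %in% fams, , drop = FALSE]
    pres <- unique(gg$family_id)
    if (length(pres) < 2) next
    pi <- idx[pres]
    n_both[pi, pi] <- n_both[pi, pi] + 1L
    # within-replicon minimal distances, aggregated over paralogs
    gmin <- matrix(NA_integer_, length(pres), length(pres),
                   dimnames = list(pres, pres))
    for (rep_id in unique(gg$replicon_id)) {
      sub <- g$genes[g$genes$replicon_id == rep_id, ]
      sub <- sub[sub$family_id %in% fams, , drop = FALSE]
      if (nrow(sub) < 2) next
      m <- sum(g$genes$replicon_id == rep_id)
      dd <- abs(outer(sub$rank, sub$rank, "-"))
      if (g$topology[[rep_id]] == "circular") dd <- pmin(dd, m - dd)
      f <- sub$family_id
      if (anyDuplicated(f)) {
        for (a in unique(f)) for (b in unique(f)) {
          v <- min(dd[f == a, f == b])
          if (a != b && (is.na(gmin[a, b]) || v < gmin[a, b]))
            gmin[a, b] <- v
        }
      } else {
        cur <- gmin[f, f]
        upd <- is.na(cur) | dd < cur
        cur[upd] <- dd[upd]
        gmin[f, f] <- cur
      }
    }
    diag(gmin) <- NA_integer_
    close <- !is.na(gmin) & gmin <= D
    n_close[pi, pi] <- n_close[pi, pi] + (close * 1L)
    old <- d_min[pi, pi]
    better <- !is.na(gmin) & (is.na(old) | gmin < old)
    old[better] <- gmin[better]
    d_min[pi, pi] <- old
  }

  ut <- which(upper.tri(n_both) & n_both >= 1, arr.ind = TRUE)
  out <- data.frame(
    famA = fams[ut[, 1]], famB = fams[ut[, 2]],
    n_both = n_both[ut], n_close = n_close[ut],
    support = n_close[ut] / n_both[ut],
    d_min = d_min[ut], stringsAsFactors = FALSE)
  out$edge <- if (mode == "support") out$support >= min_support
              else out$n_close >= 1
  out <- out[order(out$famA, out$famB), ]
  rownames(out) <- NULL
  structure(out, mode = mode, D = D, min_support = min_support,
            class = c("synteny_edges", "data.frame"))
}

#' Write a synteny edge list as TSV
#' @param edges `synteny_edges` data.frame.
#' @param path output path.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
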