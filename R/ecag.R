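#' Delineate eCAGs: module-restricted connected synteny components
#'
#' Within each co-abundance module (grey/unassigned genes excluded), the
#' synteny edge subgraph induced on the module's genes is taken and its
#' connected components of at least `min_size` genes become eCAGs:
#' clusters of genes that are both adjacent in reference genomes and share
#' an in-situ distribution pattern. No eCAG can span two modules. Ids are
#' assigned per genus by decreasing size, ties broken lexicographically by
#' first member. Module genes in no eCAG are reported separately in
#' `attr(, "unclustered")` (genes whose phyletic pattern isolates them from
#' their neighbours form their own smaller eCAGs or none).
#'
#' @param edges `synteny_edges` from [build_edges()].
#' @param partition `module_partition` from [detect_modules()].
#' @param min_size minimum member count (default 2, the smallest observable
#'   cluster of adjacent genes).
#' @param genus_prefix id prefix, e.g. `"Pro"` or `"Syn"`.
#' @param annotations optional genome annotations; fills each eCAG's
#'   carrier genomes (genomes containing every member).
#' @param rel optional relative-abundance table; fills each eCAG's
#'   per-station mean profile.
#' @return object of class `ecag_set`: list of eCAGs (`id`, `module`,
#'   `members`, `edges`, optionally `carrier_genomes`, `profile`).
#' @export
delineate_ecags <- function(edges, partition, min_size = 2,
                            genus_prefix = "Pro", annotations = NULL,
                            rel = NULL) {
  stopifnot(inherits(edges, "synteny_edges"))
  comps <- list()
  for (m in setdiff(unique(partition), "grey")) {
    members <- names(partition)[partition == m]
    e <- edges[edges$edge & edges$famA %in% members &
                 edges$famB %in% members, c("famA", "famB"), drop = FALSE]
    gr <- igraph::graph_from_data_frame(
      e, directed = FALSE, vertices = data.frame(name = sort(members)))
    cmp <- igraph::components(gr)
    for (ci in seq_len(cmp$no)) {
      fam <- sort(names(cmp$membership)[cmp$membership == ci])
      if (length(fam) < min_size) next
      comps[[length(comps) + 1]] <- list(
        module = m, members = fam,
        edges = e[e$famA %in% fam & e$famB %in% fam, , drop = FALSE])
    }
  }
  ord <- order(-vapply(comps, function(x) length(x$members), 0L),
               vapply(comps, function(x) x$members[1], ""))
  comps <- comps[ord]
  for (i in seq_along(comps)) {
    comps[[i]]$id <- sprintf("%s-eCAG_%03d", genus_prefix, i)
    if (!is.null(annotations))
      comps[[i]]$carrier_genomes <- vapply(annotations, function(g) {
        if (all(comps[[i]]$members %in% g$genes$family_id))
          g$genome_id else NA_character_
      }, "") |> stats::na.omit() |> as.character()
    if (!is.null(rel))
      comps[[i]]$profile <- ecag_profile(rel, comps[[i]]$members)
  }
  in_ecag <- unlist(lapply(comps, `[[`, "members"))
  uncl <- setdiff(names(partition)[partition != "grey"], in_ecag)
  ecag_log("eCAGs: %d delineated (%d genes); %d module genes unclustered",
           length(comps), length(in_ecag), length(uncl))
  structure(comps, unclustered = uncl, class = "ecag_set")
}

#' @export
print.ecag_set <- function(x, ...) {
  cat(sprintf("ecag_set: %d eCAGs\n", length(x)))
  for (e in x)
    cat(sprintf("  %s [%s] %d genes: %s\n", e$id, e$module,
                length(e$members), paste(e$members, collapse = ", ")))
  invisible(x)
}

#' Per-station summary profile of an eCAG
#'
#' Mean (or median) of the member genes' marker-relative abundances at each
#' station; masked stations propagate `NA` (the black-dot stations of the
#' distribution maps).
#'
#' @param rel relative-stage `abundance_table`.
#' @param ecag an eCAG (from an `ecag_set`) or a character vector of member
#'   family ids.
#' @param summary `"mean"` or `"median"`.
#' @return named per-station numeric vector.
#' @export
ecag_profile <- function(rel, ecag, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  members <- if (is.list(ecag)) ecag$members else ecag
  present <- intersect(members, families(rel))
  if (!length(present))
    stop("no eCAG member present in the abundance table")
  v <- rel$values[present, , drop = FALSE]
  apply(v, 2, if (summary == "mean") mean else stats::median)
}

#' Welch t-tests of niche enrichment between two station groups
#'
#' For each unit (gene or eCAG profile row), a two-sided Welch two-sample
#' t-test of its relative abundances between two user-supplied station
#' sets (for instance low-iron vs iron-replete station assemblages from
#' [cut_k()]). Units with fewer than 2 unmasked stations in either group
#' are skipped with a warning; zero variance in both groups with equal
#' means gives p = 1 by convention (p = 0 if the means differ). A
#' Benjamini-Hochberg column is emitted alongside the raw p-values for
#' users who want multiplicity control.
#'
#' @param x units x stations numeric matrix (e.g. `rel$values`).
#' @param group_a,group_b station id vectors.
#' @return data.frame: `unit`, `n_a`, `n_b`, `t`, `p`, `direction` (sign of
#'   mean(a) - mean(b)), `p_bh`.
#' @export
niche_enrichment <- function(x, group_a, group_b) {
  x <- as.matrix(x)
  miss <- setdiff(c(group_a, group_b), colnames(x))
  if (length(miss))
    stop("unknown station(s): ", paste(miss, collapse = ", "))
  res <- lapply(rownames(x), function(u) {
    a <- x[u, group_a]; b <- x[u, group_b]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      warning("unit '", u, "' skipped: < 2 unmasked stations in a group")
      return(data.frame(unit = u, n_a = length(a), n_b = length(b),
                        t = NA_real_, p = NA_real_,
                        direction = NA_real_))
    }
    welch <- welch_t(a, b)
    data.frame(unit = u, n_a = length(a), n_b = length(b),
               t = welch["t"], p = welch["p"],
               direction = sign(mean(a) - mean(b)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

welch_t <- function(a, b) {
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(c(t = 0, p = 1))
    return(c(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  c(t = unname(ht$statistic), p = ht$p.value)
}

#' Per-gene enrichment of eCAG members, with an all-members flag
#'
#' Runs [niche_enrichment()] on each eCAG's member genes and flags eCAGs
#' whose members are all individually significant at `alpha` in the same
#' direction --- the claim structure used when reporting, e.g., capsule
#' gene clusters depleted in low-iron waters.
#'
#' @param rel relative-stage `abundance_table`.
#' @param ecags `ecag_set`.
#' @param group_a,group_b station id vectors.
#' @param alpha per-gene significance threshold.
#' @return list with `genes` (per-gene test table with an `ecag` column)
#'   and `ecags` (per-eCAG: n members, all_significant, direction).
#' @export
ecag_enrichment <- function(rel, ecags, group_a, group_b, alpha = 0.05) {
  members <- unlist(lapply(ecags, `[[`, "members"))
  genes <- niche_enrichment(rel$values[intersect(members, families(rel)), ,
                                       drop = FALSE], group_a, group_b)
  genes$ecag <- rep(vapply(ecags, `[[`, "", "id"),
                    vapply(ecags, function(e)
                      length(intersect(e$members, genes$unit)), 0L))
  per <- do.call(rbind, lapply(ecags, function(e) {
    g <- genes[genes$ecag == e$id, , drop = FALSE]
    ok <- nrow(g) > 0 && !anyNA(g$p) && all(g$p < alpha) &&
      length(unique(g$direction)) == 1
    data.frame(ecag = e$id, module = e$module, n_members = length(e$members),
               all_significant = ok,
               direction = if (ok) g$direction[1] else NA_real_)
  }))
  rownames(per) <- NULL
  list(genes = genes, ecags = per)
}

#' Export the module-colored gene synteny network
#'
#' Nodes are module-assigned gene families (colored by module, annotated
#' with their eCAG id when any), links are the synteny edges under the
#' chosen rule. Optionally attaches deterministic 2-D coordinates from a
#' seeded Fruchterman-Reingold layout, and writes GraphML.
#'
#' @param edges `synteny_edges`.
#' @param partition `module_partition`.
#' @param ecags optional `ecag_set` for node eCAG annotation.
#' @param path optional GraphML output path.
#' @param layout `"force_directed"` (seeded Fruchterman-Reingold) or
#'   `"none"`.
#' @param seed layout seed.
#' @return the `igraph` graph, invisibly.
#' @export
export_network <- function(edges, partition, ecags = NULL, path = NULL,
                           layout = c("force_directed", "none"), seed = 1) {
  layout <- match.arg(layout)
  nodes <- sort(names(partition)[partition != "grey"])
  e <- edges[edges$edge & edges$famA %in% nodes & edges$famB %in% nodes,
             c("famA", "famB"), drop = FALSE]
  gr <- igraph::graph_from_data_frame(e, directed = FALSE,
                                      vertices = data.frame(name = nodes))
  igraph::V(gr)$module <- unname(partition[nodes])
  ecag_of <- stats::setNames(rep("", length(nodes)), nodes)
  for (ec in ecags) ecag_of[ec$members] <- ec$id
  igraph::V(gr)$ecag <- unname(ecag_of[nodes])
  if (layout == "force_directed" && length(nodes)) {
    set.seed(seed)
    xy <- igraph::layout_with_fr(gr)
    igraph::V(gr)$x <- xy[, 1]
    igraph::V(gr)$y <- xy[, 2]
  }
  if (!is.null(path))
    igraph::write_graph(gr, path, format = "graphml")
  invisible(gr)
}

#' Write an eCAG inventory as JSON
#' @param ecags `ecag_set`.
#' @param path output JSON path.
#' @export
write_ecags <- function(ecags, path) {
  out <- lapply(ecags, function(e) {
    x <- list(id = e$id, module = e$module, members = e$members,
              edges = e$edges)
    if (!is.null(e$carrier_genomes)) x$carrier_genomes <- e$carrier_genomes
    if (!is.null(e$profile)) x$profile <- as.list(e$profile)
    x
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
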