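#' Run the full analysis on prepared inputs
#'
#' Chains every stage under one configuration and seed: coverage
#' normalization and filtering to marker-relative flexible-gene abundances;
#' Bray-Curtis/Ward station clustering on gene and (when supplied) ESTU
#' profiles with a Mantel congruence test; soft-threshold pick, weighted
#' network and topological overlap, module detection, eigengenes,
#' module-trait correlation and representative genes; synteny edges in both
#' rule modes; and eCAG delineation under the configured rule. A
#' deterministic run manifest is attached.
#'
#' @param counts raw `abundance_table`.
#' @param families_tab [gene_families()] table.
#' @param annotations list of [genome_annotation()].
#' @param env optional environment data.frame (stations in rows).
#' @param estu optional ESTU matrix (stations in rows).
#' @param config configuration list, see [ecag_config()].
#' @param seed integer seed controlling every random element (Mantel
#'   permutations).
#' @param input_paths optional named file paths recorded (checksummed) in
#'   the manifest.
#' @return object of class `ecag_analysis`; a list with elements
#'   `abundance`, `clustering`, `modules`, `synteny`, `ecags`, `manifest`.
#' @export
run_pipeline <- function(counts, families_tab, annotations, env = NULL,
                         estu = NULL, config = ecag_config(), seed = 1,
                         input_paths = NULL) {
  norm <- normalize_pipeline(counts, families_tab, annotations,
                             config = config$normalize)
  rel <- norm$relative

  bc_gene <- bray_curtis(rel)
  tree_gene <- ward_cluster(bc_gene, config$cluster$linkage)
  clustering <- list(bc_gene = bc_gene, tree_gene = tree_gene)
  if (!is.null(estu)) {
    st <- labels(bc_gene)
    bc_estu <- bray_curtis(estu[st, , drop = FALSE])
    clustering$bc_estu <- bc_estu
    clustering$tree_estu <- ward_cluster(bc_estu, config$cluster$linkage)
    clustering$mantel <- mantel_test(bc_gene, bc_estu,
                                     n_perm = config$cluster$n_perm,
                                     seed = seed)
    if (!is.null(config$cluster$k)) {
      k <- config$cluster$k
      clustering$partitions <- list(
        gene = cut_k(tree_gene, k), estu = cut_k(clustering$tree_estu, k))
      clustering$agreement <- compare_partitions(
        clustering$partitions$gene, clustering$partitions$estu)
    }
  }

  mo <- config$modules
  # observed log marker coverage: partialled out of the gene-gene
  # correlations (when enabled) to suppress the spurious co-variation that
  # the shared noisy denominator of marker-relative profiles induces
  ctrl <- if (isTRUE(mo$marker_control))
    log(pmax(norm$marker_coverage, .Machine$double.xmin)) else NULL
  sft <- pick_soft_threshold(rel, powers = mo$powers,
                             target_fit = mo$target_fit,
                             n_bins = mo$n_bins, transform = mo$transform,
                             control = ctrl)
  net <- build_network(rel, sft$power, transform = mo$transform,
                       control = ctrl)
  partition <- detect_modules(net, min_module_size = mo$min_module_size,
                              cut_height = mo$cut_height,
                              merge_height = mo$merge_height,
                              min_gene_kme = mo$min_gene_kme)
  me <- module_eigengene(rel, partition)
  traits <- module_trait_correlation(me, env = env, estu = estu,
                                     alpha = mo$alpha)
  reps <- representative_genes(me, partition, min_kme = mo$min_kme)

  sy <- config$synteny
  edges_support <- build_edges(annotations, mode = "support",
                               D = sy$D_support,
                               min_support = sy$min_support)
  edges_any <- build_edges(annotations, mode = "any_genome", D = sy$D_any)
  edges_used <- if (sy$mode == "support") edges_support else edges_any

  ecags <- delineate_ecags(edges_used, partition,
                           min_size = config$ecags$min_size,
                           genus_prefix = config$ecags$genus_prefix,
                           annotations = annotations, rel = rel)

  structure(list(
    abundance = norm,
    clustering = clustering,
    modules = list(soft_threshold = sft, network = net,
                   partition = partition, eigengenes = me,
                   traits = traits, representative = reps),
    synteny = list(support = edges_support, any_genome = edges_any,
                   used = sy$mode),
    ecags = ecags,
    manifest = run_manifest(config, seed, input_paths)),
    class = "ecag_analysis")
}

#' @export
print.ecag_analysis <- function(x, ...) {
  rel <- x$abundance$relative
  cat("ecag_analysis\n")
  cat(sprintf("  relative table: %d flexible genes x %d stations\n",
              nrow(rel$values), ncol(rel$values)))
  if (!is.null(x$clustering$mantel))
    cat(sprintf("  gene/ESTU Mantel: r = %.3f, p = %.2g\n",
                x$clustering$mantel$r, x$clustering$mantel$p))
  mods <- setdiff(unique(x$modules$partition), "grey")
  cat(sprintf("  modules: %d (power %d)\n", length(mods),
              x$modules$soft_threshold$power))
  cat(sprintf("  eCAGs [%s mode]: %d\n", x$synteny$used, length(x$ecags)))
  invisible(x)
}

#' Simulate a study and analyse it in one call
#'
#' Runs [simulate_dataset()] under the configuration's `simulate` section
#' and [run_pipeline()] on the result, and scores the run against the
#' recorded truth (planted-module ARI, pair-level eCAG precision/recall).
#'
#' @param config configuration list.
#' @param seed master seed.
#' @param noiseless simulate expected counts exactly (no sampling noise).
#' @param gradients gradient specs for the simulation.
#' @return list with `dataset`, `analysis` and `scores`.
#' @export
run_synthetic_study <- function(config = ecag_config(), seed = 1,
                                noiseless = FALSE,
                                gradients = default_gradients()) {
  ds <- simulate_dataset(config$simulate, seed = seed,
                         gradients = gradients, noiseless = noiseless)
  an <- run_pipeline(ds$counts, ds$families, ds$annotations,
                     env = ds$env, estu = ds$estu, config = config,
                     seed = seed)
  scores <- list(
    module_recovery = module_recovery_ari(an$modules$partition, ds$truth),
    ecag_recovery = ecag_pair_scores(an$ecags, ds$truth))
  list(dataset = ds, analysis = an, scores = scores)
}

#' Write the analysis outputs of a run to a directory
#'
#' TSVs for the relative table, module assignment, eigengenes, kME and
#' trait correlations; newick dendrograms; edge lists; eCAG inventory JSON;
#' GraphML network; and the run manifest.
#'
#' @param analysis `ecag_analysis` from [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_abundance_table(analysis$abundance$relative, p("relative.tsv"))
  write_newick(analysis$clustering$tree_gene, p("stations_genes.nwk"))
  if (!is.null(analysis$clustering$tree_estu))
    write_newick(analysis$clustering$tree_estu, p("stations_estus.nwk"))
  part <- analysis$modules$partition
  utils::write.table(
    data.frame(family_id = names(part), module = unname(part)),
    p("modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_sample_table(t(analysis$modules$eigengenes$ME), p("eigengenes.tsv"))
  utils::write.table(attr(analysis$modules$representative, "kme"),
                     p("kme.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (blk in names(analysis$modules$traits)) {
    tr <- analysis$modules$traits[[blk]]
    utils::write.table(cbind(module = rownames(tr$r), as.data.frame(tr$r)),
                       p(sprintf("traits_%s_r.tsv", blk)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cbind(module = rownames(tr$p), as.data.frame(tr$p)),
                       p(sprintf("traits_%s_p.tsv", blk)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_edges(analysis$synteny$support, p("edges_support.tsv"))
  write_edges(analysis$synteny$any_genome, p("edges_any_genome.tsv"))
  write_ecags(analysis$ecags, p("ecags.json"))
  export_network(
    if (analysis$synteny$used == "support") analysis$synteny$support
    else analysis$synteny$any_genome,
    analysis$modules$partition, analysis$ecags, p("network.graphml"),
    seed = analysis$manifest$seed)
  write_manifest(analysis$manifest, p("manifest.json"))
  invisible(dir)
}
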