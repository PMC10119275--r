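#' Normalize raw read counts to fold-coverage
#'
#' `coverage(g, s) = count(g, s) * L_read(s) / L_gene(g)`: the normalization
#' by gene and read length that makes a single-copy gene in the whole
#' population read as coverage `depth` regardless of its length.
#'
#' @param raw an `abundance_table` at stage `"raw"` with gene and read
#'   lengths.
#' @return an `abundance_table` at stage `"coverage"`.
#' @export
normalize_coverage <- function(raw) {
  stopifnot(inherits(raw, "abundance_table"))
  if (raw$stage != "raw")
    stop("normalize_coverage expects a 'raw' table (stage transitions are ",
         "raw -> coverage -> relative)")
  gl <- raw$gene_lengths[families(raw)]
  if (any(is.na(gl)) || any(gl <= 0))
    stop("zero or missing gene length")
  rl <- raw$read_lengths[samples(raw)]
  if (is.null(rl) || any(is.na(rl)))
    stop("missing read length for sample(s)")
  cov <- sweep(raw$values, 2, rl, "*") / gl
  abundance_table(cov, "coverage", gene_lengths = raw$gene_lengths,
                  read_lengths = raw$read_lengths)
}

#' Keep samples that detect enough gene families
#'
#' A sample is kept when its number of families with coverage strictly
#' greater than 0 exceeds `min_families` (strictly: "more families than"),
#' where `min_families` is typically the mean gene count of the designated
#' reference genomes. Samples dominated by another genus or too shallow to
#' sample a whole genome are removed here.
#'
#' @param cov coverage-stage `abundance_table`.
#' @param min_families detection threshold (strict).
#' @return filtered `abundance_table` (same stage).
#' @export
filter_samples <- function(cov, min_families) {
  stopifnot(inherits(cov, "abundance_table"))
  detected <- colSums(cov$values > 0)
  keep <- detected > min_families
  if (!any(keep))
    stop("no sample passes the detection filter (min_families = ",
         min_families, ")")
  ecag_log("filter_samples: %d/%d samples kept (> %s detected families)",
           sum(keep), length(keep), format(min_families))
  out <- cov
  out$values <- cov$values[, keep, drop = FALSE]
  out$read_lengths <- cov$read_lengths[colnames(out$values)]
  out
}

#' Keep gene families covered in enough samples
#'
#' A family is kept when its coverage is strictly greater than `min_cov`
#' (default 1x) in at least `min_samples` of the retained samples. Applied
#' after [filter_samples()].
#'
#' @param cov coverage-stage `abundance_table`.
#' @param min_cov coverage threshold (strict inequality).
#' @param min_samples minimum number of qualifying samples.
#' @return filtered `abundance_table`.
#' @export
filter_genes <- function(cov, min_cov = 1, min_samples = 2) {
  stopifnot(inherits(cov, "abundance_table"))
  keep <- rowSums(cov$values > min_cov) >= min_samples
  ecag_log("filter_genes: %d/%d families kept (coverage > %s in >= %d samples)",
           sum(keep), length(keep), format(min_cov), min_samples)
  if (!any(keep))
    warning("no gene family passes the coverage filter")
  out <- cov
  out$values <- cov$values[keep, , drop = FALSE]
  out
}

#' Drop core gene families, keeping the flexible genome
#'
#' Niche analysis is performed on flexible (non-core) genes only; core genes
#' track total genus abundance rather than niche-specific gene content. The
#' marker gene is removed here like any core gene but its coverage is taken
#' from the unfiltered table by [relative_abundance()].
#'
#' @param cov coverage-stage `abundance_table`.
#' @param families_tab data.frame from [gene_families()] with `is_core`.
#' @return `abundance_table` restricted to flexible families.
#' @export
drop_core <- function(cov, families_tab) {
  stopifnot(inherits(cov, "abundance_table"))
  core <- families_tab$family_id[families_tab$is_core]
  keep <- !(families(cov) %in% core)
  ecag_log("drop_core: %d/%d families kept (flexible)",
           sum(keep), length(keep))
  if (!any(keep))
    warning("all families are core; empty flexible table")
  out <- cov
  out$values <- cov$values[keep, , drop = FALSE]
  out
}

#' Convert coverage to single-copy-marker relative abundance
#'
#' `rel(g, s) = cov(g, s) / cov(marker, s)`, the fraction of the genus
#' population carrying gene `g` at station `s` (it can exceed 1 for
#' multi-copy or multi-carrier situations; values are not clipped). Samples
#' whose marker coverage is below `min_marker_cov` are masked (all-`NA`
#' column): the genus is too rare there for relative abundances to be
#' meaningful, mirroring the blacked-out stations of global distribution
#' maps.
#'
#' @param cov coverage-stage `abundance_table` (typically after filtering
#'   and [drop_core()]).
#' @param marker marker family id (single-copy core gene, default petB).
#' @param min_marker_cov mask threshold on marker coverage (x).
#' @param marker_coverage named per-sample marker coverage, required when
#'   the marker row is no longer in `cov` (after [drop_core()]); take it
#'   from the sample-filtered coverage table.
#' @return an `abundance_table` at stage `"relative"`.
#' @export
relative_abundance <- function(cov, marker = "petB", min_marker_cov = 0.1,
                               marker_coverage = NULL) {
  stopifnot(inherits(cov, "abundance_table"))
  if (cov$stage != "coverage")
    stop("relative_abundance expects a 'coverage' table")
  if (marker %in% families(cov)) {
    mc <- cov$values[marker, ]
  } else if (!is.null(marker_coverage)) {
    if (!all(samples(cov) %in% names(marker_coverage)))
      stop("marker_coverage does not cover all samples")
    mc <- marker_coverage[samples(cov)]
  } else {
    stop("marker '", marker, "' absent from the table and no ",
         "marker_coverage supplied")
  }
  masked <- mc < min_marker_cov | mc == 0  # zero marker always masks
  ecag_log("relative_abundance: %d/%d samples masked (marker '%s' < %s)",
           sum(masked), length(masked), marker, format(min_marker_cov))
  rel <- sweep(cov$values, 2, mc, "/")
  rel[, masked] <- NA_real_
  abundance_table(rel, "relative")
}

#' Run the full normalization chain on a raw count table
#'
#' Fixed order: coverage normalization, sample detection filter, gene
#' coverage filter, core-gene removal, marker-relative abundance (marker
#' coverage taken from the sample-filtered table, before core removal).
#'
#' @param raw raw `abundance_table`.
#' @param families_tab [gene_families()] table.
#' @param min_families sample filter threshold; default: mean number of
#'   genes per genome in `annotations`.
#' @param annotations optional list of [genome_annotation()] used to derive
#'   the default `min_families`.
#' @param config `normalize` section of [ecag_config()].
#' @return list with the tables of every stage: `coverage`, `filtered`
#'   (samples+genes), `flexible`, `relative`, plus `marker_coverage`.
#' @export
normalize_pipeline <- function(raw, families_tab, annotations = NULL,
                               min_families = NULL,
                               config = ecag_config()$normalize) {
  if (is.null(min_families)) min_families <- config$min_families
  if (is.null(min_families)) {
    if (is.null(annotations))
      stop("supply min_families or annotations to derive it from")
    min_families <- mean(vapply(annotations,
                                function(g) nrow(g$genes), 0))
  }
  cov <- normalize_coverage(raw)
  cov_s <- filter_samples(cov, min_families)
  cov_sg <- filter_genes(cov_s, config$min_cov, config$min_samples)
  flex <- drop_core(cov_sg, families_tab)
  marker_cov <- if (config$marker %in% families(cov_s))
    cov_s$values[config$marker, ] else
      stop("marker '", config$marker, "' absent from the coverage table")
  rel <- relative_abundance(flex, marker = config$marker,
                            min_marker_cov = config$min_marker_cov,
                            marker_coverage = marker_cov)
  list(coverage = cov, filtered = cov_sg, flexible = flex, relative = rel,
       marker_coverage = marker_cov, min_families = min_families)
}
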