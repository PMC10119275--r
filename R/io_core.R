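#' Gene-family by sample abundance table
#'
#' The central container of the pipeline: a non-negative numeric matrix of
#' gene-family (CLOG) values per sample, together with the gene lengths (bp)
#' and per-sample read lengths (bp) needed to convert raw read counts into
#' fold-coverage. The `stage` records where the table sits in the fixed
#' normalization chain `raw -> coverage -> relative`; stage transitions are
#' enforced by [normalize_coverage()] and [relative_abundance()].
#'
#' Masked samples (marker coverage below threshold at the `relative` stage)
#' are represented as all-`NA` columns so that downstream correlations and
#' per-station profiles propagate missingness rather than dividing by zero.
#'
#' @param values numeric matrix, rows = family ids, columns = sample ids.
#' @param stage one of `"raw"`, `"coverage"`, `"relative"`.
#' @param gene_lengths named numeric vector of gene lengths in bp; required
#'   at the `raw` stage (it is what coverage normalization consumes) and
#'   must cover every family when given.
#' @param read_lengths named numeric vector of per-sample read lengths in bp.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(values, stage = c("raw", "coverage", "relative"),
                            gene_lengths = NULL, read_lengths = NULL) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have family row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate family identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(values < 0, na.rm = TRUE))
    stop("negative count: abundance values must be >= 0")
  if (stage != "relative" && anyNA(values))
    stop("missing values are only allowed at the 'relative' stage (masked samples)")
  if (stage == "raw" || (stage == "coverage" && !is.null(gene_lengths))) {
    if (is.null(gene_lengths))
      stop("gene_lengths are required at the 'raw' stage")
    missing_len <- setdiff(rownames(values), names(gene_lengths))
    if (length(missing_len))
      stop("missing gene length for family: ", paste(missing_len, collapse = ", "))
    if (any(gene_lengths[rownames(values)] <= 0))
      stop("gene lengths must be positive")
  }
  structure(
    list(values = values, stage = stage,
         gene_lengths = gene_lengths, read_lengths = read_lengths),
    class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  masked <- sum(colSums(!is.na(x$values)) == 0)
  cat(sprintf("abundance_table [%s]: %d families x %d samples%s\n",
              x$stage, nrow(x$values), ncol(x$values),
              if (masked) sprintf(" (%d masked)", masked) else ""))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

families <- function(x) rownames(x$values)
samples <- function(x) colnames(x$values)

#' Read a raw gene-family count table and its length metadata
#'
#' The count file is a UTF-8 TSV with a header row of sample ids and a first
#' column (`family_id`) of gene-family ids. The metadata file is a TSV with
#' columns `id`, `type` (`"family"` or `"sample"`) and `length` supplying the
#' gene length of every family and the read length of every sample, in bp.
#'
#' @param path path to the count TSV.
#' @param metadata_path path to the length-metadata TSV.
#' @return an `abundance_table` at stage `"raw"`.
#' @export
read_abundance_table <- function(path, metadata_path) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("count table needs a family column plus >=1 sample")
  fam <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(fam, colnames(mat))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell '%s' at family %s, sample %s",
                 mat[bad[1], bad[2]], fam[bad[1]], colnames(mat)[bad[2]]))
  }
  if (any(num < 0))
    stop("negative count in ", basename(path))
  meta <- utils::read.delim(metadata_path, check.names = FALSE)
  need <- c("id", "type", "length")
  if (!all(need %in% colnames(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  gl <- as.numeric(meta$length[meta$type == "family"])
  names(gl) <- meta$id[meta$type == "family"]
  rl <- as.numeric(meta$length[meta$type == "sample"])
  names(rl) <- meta$id[meta$type == "sample"]
  missing_s <- setdiff(colnames(num), names(rl))
  if (length(missing_s))
    stop("missing read length for sample: ", paste(missing_s, collapse = ", "))
  abundance_table(num, "raw", gene_lengths = gl,
                  read_lengths = rl[colnames(num)])
}

#' Write an abundance table (and optionally its metadata) as canonical TSV
#'
#' Canonical form: tab-separated, UTF-8, `.` decimal separator, first column
#' `family_id`, numbers formatted by [as.character()]. Re-reading and
#' re-writing a canonical file is byte-identical.
#'
#' @param x an `abundance_table`.
#' @param path output TSV path.
#' @param metadata_path optional path for the length-metadata TSV.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "abundance_table"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("family_id", colnames(x$values)), collapse = "\t"), con)
  body <- apply(x$values, 1, function(v) paste(as.character(v), collapse = "\t"))
  writeLines(paste(rownames(x$values), body, sep = "\t"), con)
  if (!is.null(metadata_path)) {
    meta <- data.frame(
      id = c(names(x$gene_lengths), names(x$read_lengths)),
      type = rep(c("family", "sample"),
                 c(length(x$gene_lengths), length(x$read_lengths))),
      length = c(unname(x$gene_lengths), unname(x$read_lengths)))
    utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Ordered gene annotation of one genome
#'
#' Holds the gene order of a reference genome: one row per gene occurrence
#' with its replicon, rank (1-based consecutive position along the replicon),
#' strand and gene-family id. Replicons are circular by default, matching the
#' single circular chromosome of most picocyanobacterial genomes; topology is
#' recorded per replicon.
#'
#' @param genome_id genome identifier.
#' @param genes data.frame with columns `replicon_id`, `rank`, `strand`,
#'   `family_id`.
#' @param topology named character vector per replicon, `"circular"` or
#'   `"linear"`; unnamed scalar recycles to all replicons.
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, genes, topology = "circular") {
  need <- c("replicon_id", "rank", "strand", "family_id")
  if (!all(need %in% colnames(genes)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  genes <- genes[order(genes$replicon_id, genes$rank), need, drop = FALSE]
  rownames(genes) <- NULL
  for (rep_id in unique(genes$replicon_id)) {
    r <- genes$rank[genes$replicon_id == rep_id]
    if (anyDuplicated(r))
      stop(sprintf("genome %s replicon %s: duplicated ranks", genome_id, rep_id))
    if (!identical(as.integer(sort(r)), seq_along(r)))
      stop(sprintf("genome %s replicon %s: non-consecutive ranks", genome_id, rep_id))
  }
  reps <- unique(genes$replicon_id)
  if (is.null(names(topology))) topology <- stats::setNames(rep(topology[1], length(reps)), reps)
  if (!all(topology %in% c("circular", "linear")))
    stop("topology must be 'circular' or 'linear'")
  structure(list(genome_id = genome_id, genes = genes,
                 topology = topology[reps]),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation %s: %d genes on %d replicon(s), %d families\n",
              x$genome_id, nrow(x$genes), length(unique(x$genes$replicon_id)),
              length(unique(x$genes$family_id))))
  invisible(x)
}

#' Read per-genome ordered gene annotations
#'
#' Two dialects are supported. `tsv`: columns `genome_id`, `replicon_id`,
#' `rank`, `strand`, `family_id` (optionally `topology`); ranks must be
#' consecutive integers starting at 1 on each replicon. `gff3`: one genome per
#' file, the family id taken from a GFF3 attribute (default `clog`); ranks
#' are assigned by start-coordinate order per seqid, and features lacking the
#' attribute are skipped with a logged count.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param family_attribute GFF3 attribute key carrying the family id.
#' @param genome_id genome id for the GFF3 dialect (default: file base name).
#' @param topology default replicon topology.
#' @return a list of [genome_annotation()] objects.
#' @export
read_genome_annotations <- function(path, dialect = c("tsv", "gff3"),
                                    family_attribute = "clog",
                                    genome_id = NULL,
                                    topology = "circular") {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE)
    need <- c("genome_id", "replicon_id", "rank", "strand", "family_id")
    if (!all(need %in% colnames(tab)))
      stop("annotation TSV needs columns: ", paste(need, collapse = ", "))
    out <- lapply(split(tab, tab$genome_id), function(g) {
      topo <- if ("topology" %in% colnames(g)) {
        t1 <- tapply(g$topology, g$replicon_id, function(v) v[1])
        stats::setNames(as.character(t1), names(t1))
      } else topology
      genome_annotation(g$genome_id[1], g, topo)
    })
    return(unname(out)[order(vapply(out, function(g) g$genome_id, ""))])
  }
  gff <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  fam <- if (family_attribute %in% colnames(gff))
    as.character(gff[[family_attribute]]) else rep(NA_character_, nrow(gff))
  keep <- !is.na(fam)
  n_skip <- sum(!keep)
  if (n_skip)
    warning(sprintf("%s: %d feature(s) without '%s' attribute skipped",
                    basename(path), n_skip, family_attribute))
  g <- data.frame(
    replicon_id = as.character(gff$seqnames)[keep],
    start = gff$start[keep],
    strand = as.character(gff$strand)[keep],
    family_id = fam[keep], stringsAsFactors = FALSE)
  g <- g[order(g$replicon_id, g$start), ]
  g$rank <- stats::ave(g$start, g$replicon_id, FUN = seq_along)
  list(genome_annotation(genome_id, g[, c("replicon_id", "rank", "strand",
                                          "family_id")], topology))
}

#' Write genome annotations as canonical TSV
#' @param annotations list of `genome_annotation` objects.
#' @param path output TSV path.
#' @export
write_genome_annotations <- function(annotations, path) {
  tab <- do.call(rbind, lapply(annotations, function(g) {
    data.frame(genome_id = g$genome_id, g$genes,
               topology = unname(g$topology[g$genes$replicon_id]))
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the gene-family metadata table
#'
#' @param family_id character vector of unique family ids.
#' @param core_ids ids flagged as core (the core-gene list input); families
#'   not listed are flexible.
#' @param genus `"prochlorococcus"` or `"synechococcus"`.
#' @param annotation optional free-text functional annotation.
#' @return data.frame with columns `family_id`, `annotation`, `is_core`,
#'   `genus`.
#' @export
gene_families <- function(family_id, core_ids = character(),
                          genus = c("prochlorococcus", "synechococcus"),
                          annotation = "") {
  genus <- match.arg(genus)
  if (anyDuplicated(family_id))
    stop("duplicate family_id")
  data.frame(family_id = family_id,
             annotation = rep_len(annotation, length(family_id)),
             is_core = family_id %in% core_ids,
             genus = genus, stringsAsFactors = FALSE)
}

#' Read a core-gene list (one family id per line)
#' @param path text file path.
#' @return character vector of family ids.
#' @export
read_core_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Read a per-station environmental parameter table
#'
#' TSV with first column `sample_id` and one numeric column per parameter
#' (temperature, nutrients, iron-limitation proxy, PAR30, DCM, ...). Missing
#' values are allowed; parameters with fewer than 3 observations are reported
#' as missing by [module_trait_correlation()].
#'
#' @param path TSV path.
#' @return data.frame with sample ids as row names.
#' @export
read_environment_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  rownames(tab) <- tab[[1]]
  tab <- tab[, -1, drop = FALSE]
  if (!all(vapply(tab, is.numeric, TRUE)))
    stop("environmental parameters must be numeric")
  tab
}

#' Read a per-station ESTU relative-abundance table
#'
#' Rows are stations, columns ESTUs of one genus; each row must sum to
#' 1 within 1e-6 and all values must lie in `[0, 1]`.
#'
#' @param path TSV path.
#' @return numeric matrix stations x ESTUs.
#' @export
read_estu_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  validate_estu_table(m)
}

validate_estu_table <- function(m) {
  if (any(m < 0 | m > 1, na.rm = TRUE))
    stop("ESTU relative abundances must lie in [0, 1]")
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-6))
    stop("ESTU abundances of station(s) ",
         paste(rownames(m)[abs(rs - 1) > 1e-6], collapse = ", "),
         " do not sum to 1")
  m
}

#' Write a samples-in-rows matrix (ESTU or environment table) as TSV
#' @param m matrix or data.frame with sample row names.
#' @param path output path.
#' @param id_col name of the first (id) column.
#' @export
write_sample_table <- function(m, path, id_col = "sample_id") {
  out <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE)
  colnames(out)[1] <- id_col
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' One nested list with a section per stage; every threshold used anywhere in
#' the pipeline is a named key here so that a run is fully described by
#' (config, inputs, seed). [read_config()] merges a YAML file over these
#' defaults.
#'
#' Defaults of note: both abundance filters use strict inequalities
#' (`> min_families` detected families per sample, coverage `> 1` in at least
#' 2 samples); the synteny rule is `support` mode with distance cap 5 and 80%
#' support, with `any_genome` mode (cap 4) available; module detection uses an
#' unsigned network and a static branch cut followed by eigengene merging.
#'
#' @return nested configuration list.
#' @export
ecag_config <- function() {
  list(
    simulate = list(
      n_genomes = 24L, n_estus = 6L, core_size = 60L, flex_size = 240L,
      n_ecags = 6L, ecag_size_min = 3L, ecag_size_max = 7L, max_gap = 1L,
      n_neutral = 120L, neutral_carriage = 0.5,
      n_stations = 40L, depth = 5, read_length = 100L,
      gene_length_min = 800L, gene_length_max = 2500L,
      overdispersion = 0, marker_length = 645L),
    normalize = list(
      min_families = NULL, min_cov = 1, min_samples = 2L,
      marker = "petB", min_marker_cov = 0.1),
    cluster = list(linkage = "ward.D2", n_perm = 10000L, k = NULL),
    modules = list(
      powers = 1:20, target_fit = 0.8, n_bins = 10L,
      min_module_size = 10L, cut_height = 0.995, merge_height = 0.25,
      min_gene_kme = 0.5, min_kme = 0.7, alpha = 0.01, transform = "none",
      marker_control = TRUE),
    synteny = list(mode = "support", D_support = 5L, D_any = 4L,
                   min_support = 0.8),
    ecags = list(min_size = 2L, genus_prefix = "Pro",
                 enrichment_alpha = 0.05))
}

#' Read a YAML configuration, merged over the package defaults
#' @param path YAML file; missing keys fall back to [ecag_config()].
#' @return nested configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(ecag_config(), user)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Build a deterministic run manifest
#'
#' Records the package version, seed, full configuration and the MD5 checksum
#' of every input file so that a run is exactly reproducible. The manifest is
#' a pure function of its arguments (no timestamps), so two runs with the
#' same inputs produce byte-identical manifests.
#'
#' @param config configuration list.
#' @param seed integer seed of the run.
#' @param inputs named character vector of input file paths (checksummed) or
#'   `NULL`.
#' @return manifest list.
#' @export
run_manifest <- function(config, seed, inputs = NULL) {
  checksums <- if (length(inputs)) {
    md5 <- tools::md5sum(unname(unlist(inputs)))
    stats::setNames(as.vector(md5), names(inputs))
  } else NULL
  list(package = "ecag",
       version = as.character(utils::packageVersion("ecag")),
       seed = as.integer(seed),
       config = config,
       input_md5 = as.list(checksums))
}

#' Write a manifest (or any list) as pretty JSON
#' @param manifest list from [run_manifest()].
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# Internal: filter/threshold logging. Every filtering operation reports
# before/after counts through here; messages can be silenced the usual way.
ecag_log <- function(fmt, ...) {
  message(sprintf(paste0("[ecag] ", fmt), ...))
}
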