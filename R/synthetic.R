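#' Default environmental gradient specifications
#'
#' Five parameters typical of the surface-ocean stations the pipeline is
#' aimed at: temperature (deg C), phosphate (uM), an iron-limitation proxy
#' (phi_sat, dimensionless 0-1), surface PAR averaged over 30 days
#' (E m-2 d-1) and depth of the deep chlorophyll maximum (m). The first
#' three are `niche` gradients: ESTU niche optima are placed along them.
#' PAR30 and DCM are distractors with no planted effect, so that
#' module-trait correlation has true negatives to report.
#'
#' @return named list of specs: `range` (length-2 numeric), `smooth`
#'   (logical, spatial autocorrelation along station order), `niche`
#'   (logical, does the gradient structure ESTU niches).
#' @export
default_gradients <- function() {
  list(
    temperature = list(range = c(10, 30), smooth = FALSE, niche = TRUE),
    phosphate   = list(range = c(0, 1),   smooth = FALSE, niche = TRUE),
    phi_sat     = list(range = c(0, 1),   smooth = FALSE, niche = TRUE),
    PAR30       = list(range = c(20, 60), smooth = FALSE, niche = FALSE),
    DCM         = list(range = c(20, 150), smooth = FALSE, niche = FALSE))
}

# Spread permutations used to place ESTU optima on the niche gradients so
# that no two ESTUs are close on every gradient at once (distinct niches are
# the generator's contract). Cycled when there are more than 3 gradients.
spread_permutation <- function(n, which) {
  if (n < 2) return(rep(1L, n))
  inter <- c(seq(1L, n, by = 2L), seq(2L, n, by = 2L))
  switch(((which - 1L) %% 3L) + 1L, seq_len(n), inter, rev(inter))
}

assign_niche_params <- function(estu_ids, gradients) {
  niche <- names(gradients)[vapply(gradients, `[[`, TRUE, "niche")]
  if (!length(niche)) stop("at least one niche gradient is required")
  n <- length(estu_ids)
  mu <- sigma <- matrix(0, n, length(niche),
                        dimnames = list(estu_ids, niche))
  for (j in seq_along(niche)) {
    rg <- gradients[[niche[j]]]$range
    levels <- rg[1] + (rg[2] - rg[1]) * (seq_len(n) - 0.5) / n
    mu[, j] <- levels[spread_permutation(n, j)]
    sigma[, j] <- (rg[2] - rg[1]) / 6
  }
  list(mu = mu, sigma = sigma)
}

#' Simulate a picocyanobacterial pangenome with planted structure
#'
#' Generates `n_genomes` single-replicon (circular by default) genome
#' annotations organised into `n_estus` ESTUs, with three family classes:
#'
#' * core families (conserved circular order in every genome; the first is
#'   the single-copy marker `petB`),
#' * niche families, each tied to one ESTU ("niche label") and carried by
#'   every genome of that ESTU and no other --- strictly vertical gene
#'   content; a subset of them form the planted eCAGs, placed as contiguous
#'   blocks (consecutive-member rank gap <= `max_gap`) in every carrier
#'   genome,
#' * neutral families, carried by a fixed fraction of the genomes of every
#'   ESTU (fraction `neutral_carriage`, genomes drawn at random per ESTU),
#'   so their expected community-weighted carriage is flat across stations.
#'
#' Within each genome, niche genes that are not eCAG members are kept at
#' least 6 ranks away from any same-niche gene (when enough core plus
#' neutral spacers are available), so conserved adjacency is unique to the
#' planted eCAGs by construction.
#'
#' @param n_genomes,n_estus genomes and ESTUs; `n_genomes` must be a
#'   multiple of `n_estus` here (equal ESTU sizes).
#' @param core_size number of core families (>= 1; includes `petB`).
#' @param flex_size total flexible families (niche + neutral).
#' @param n_ecags planted eCAGs, assigned to ESTUs round-robin.
#' @param ecag_size_range integer pair, members per planted eCAG.
#' @param max_gap maximum rank gap between consecutive eCAG members
#'   (1 = strictly contiguous).
#' @param n_neutral neutral flexible families (rest are niche families).
#' @param neutral_carriage fraction of each ESTU's genomes carrying a
#'   neutral family.
#' @param gradients gradient specs (see [default_gradients()]); niche
#'   gradients receive the ESTU optima recorded in the returned truth.
#' @param seed integer seed; output is bit-reproducible.
#' @return list with `annotations` (list of [genome_annotation()]),
#'   `families` (see [gene_families()]) and `truth` (planted modules,
#'   planted eCAGs, ESTU niche parameters, genome-to-ESTU map).
#' @export
simulate_pangenome <- function(n_genomes = 24, n_estus = 6, core_size = 60,
                               flex_size = 240, n_ecags = 6,
                               ecag_size_range = c(3, 7), max_gap = 1,
                               n_neutral = 120, neutral_carriage = 0.5,
                               gradients = default_gradients(), seed = 1) {
  if (core_size < 1) stop("core_size must be >= 1 (petB is always core)")
  if (n_genomes < n_estus) stop("need n_genomes >= n_estus")
  if (n_genomes %% n_estus != 0)
    stop("n_genomes must be a multiple of n_estus")
  if (n_neutral > flex_size) stop("n_neutral cannot exceed flex_size")
  set.seed(seed)

  estu_ids <- paste0("ESTU_", LETTERS[seq_len(n_estus)])
  genome_ids <- sprintf("G%03d", seq_len(n_genomes))
  genome_estu <- stats::setNames(rep(estu_ids, each = n_genomes / n_estus),
                                 genome_ids)

  core_ids <- c("petB",
                if (core_size > 1) sprintf("core_%03d", seq_len(core_size)[-1]))
  flex_ids <- sprintf("flex_%03d", seq_len(flex_size))

  # -- niche/neutral split and planted eCAG membership -----------------------
  n_niche <- flex_size - n_neutral
  per_niche <- diff(round(seq(0, n_niche, length.out = n_estus + 1)))
  if (n_niche > 0 && any(per_niche <= 0))
    stop("too few niche families for the requested number of ESTUs")
  niche_of_flex <- rep(c(estu_ids, "neutral"), c(per_niche, n_neutral))
  names(niche_of_flex) <- flex_ids

  ecag_sizes <- if (n_ecags > 0)
    sample(seq(ecag_size_range[1], ecag_size_range[2]), n_ecags,
           replace = TRUE) else integer()
  ecag_niche <- estu_ids[((seq_len(n_ecags) - 1) %% n_estus) + 1]
  planted_ecags <- vector("list", n_ecags)
  ecag_members_of <- stats::setNames(vector("list", n_estus), estu_ids)
  for (k in seq_len(n_ecags)) {
    niche <- ecag_niche[k]
    pool <- setdiff(flex_ids[niche_of_flex == niche],
                    unlist(ecag_members_of[[niche]]))
    if (length(pool) < ecag_sizes[k])
      stop("planted eCAG sizes exceed the niche gene allocation ",
           "(increase flex_size or reduce n_ecags/ecag sizes)")
    members <- pool[seq_len(ecag_sizes[k])]
    ecag_members_of[[niche]] <- c(ecag_members_of[[niche]], list(members))
    planted_ecags[[k]] <- list(
      id = sprintf("planted_%02d", k), members = members, niche = niche,
      carrier_estus = niche,
      carrier_genomes = genome_ids[genome_estu == niche])
  }

  # -- neutral carriage: same count of carrier genomes in every ESTU ---------
  neutral_ids <- flex_ids[niche_of_flex == "neutral"]
  g_per_estu <- n_genomes / n_estus
  n_carry <- max(0L, min(g_per_estu, round(neutral_carriage * g_per_estu)))
  neutral_carriers <- stats::setNames(vector("list", length(neutral_ids)),
                                      neutral_ids)
  for (f in neutral_ids) {
    neutral_carriers[[f]] <- unlist(lapply(estu_ids, function(e) {
      sample(genome_ids[genome_estu == e], n_carry)
    }), use.names = FALSE)
  }

  # -- per-genome circular layout -------------------------------------------
  annotations <- lapply(genome_ids, function(g) {
    e <- genome_estu[[g]]
    blocks <- ecag_members_of[[e]]
    if (is.null(blocks)) blocks <- list()
    in_block <- unlist(blocks, use.names = FALSE)
    singles <- setdiff(flex_ids[niche_of_flex == e], in_block)
    neutrals <- neutral_ids[vapply(neutral_carriers[neutral_ids],
                                   function(cg) g %in% cg, TRUE)]
    order_fams <- layout_genome(core_ids, singles, blocks,
                                sample(neutrals), max_gap)
    genes <- data.frame(
      replicon_id = "chr",
      rank = seq_along(order_fams),
      strand = sample(c("+", "-"), length(order_fams), replace = TRUE),
      family_id = order_fams, stringsAsFactors = FALSE)
    genome_annotation(g, genes, "circular")
  })

  fam_tab <- gene_families(c(core_ids, flex_ids), core_ids = core_ids)
  niche_params <- assign_niche_params(estu_ids, gradients)
  truth <- list(
    planted_modules = niche_of_flex,
    planted_ecags = planted_ecags,
    estu_niche_params = niche_params,
    genome_estu = genome_estu,
    core_families = core_ids,
    marker = "petB")
  list(annotations = annotations, families = fam_tab, truth = truth)
}

# Assemble one circular gene order: niche units (singles and eCAG blocks)
# separated by runs of spacers (core genes in conserved order, randomly
# interleaved with this genome's neutral genes). Inter-unit runs get at
# least 5 spacers when the spacer budget allows, so two same-niche units are
# never within rank distance 5 of each other.
layout_genome <- function(core_ids, singles, blocks, neutrals, max_gap) {
  units <- c(as.list(sample(singles)), blocks[sample.int(length(blocks))])
  units <- units[sample.int(length(units))]
  # internal eCAG gaps: consecutive members max_gap apart at most
  hole_sizes <- lapply(units, function(u) {
    if (length(u) < 2) integer() else sample.int(max_gap, length(u) - 1,
                                                 replace = TRUE) - 1L
  })
  n_holes <- sum(unlist(hole_sizes), 0L)
  n_units <- length(units)
  # spacer stream: core order conserved, neutrals interleaved at random
  n_spacer <- length(core_ids) + length(neutrals)
  if (n_holes > n_spacer)
    stop("not enough spacer genes for the requested eCAG gaps")
  stream <- character(n_spacer)
  core_pos <- sort(sample.int(n_spacer, length(core_ids)))
  stream[core_pos] <- core_ids
  stream[-core_pos] <- neutrals
  if (n_units == 0) return(stream)
  avail <- n_spacer - n_holes
  base_gap <- min(5L, avail %/% n_units)
  extra <- avail - base_gap * n_units
  gaps <- base_gap + if (extra > 0)
    as.integer(stats::rmultinom(1, extra, rep(1, n_units))) else
      integer(n_units)
  out <- character(0)
  cursor <- 0L
  take <- function(n) {
    if (n == 0) return(character())
    s <- stream[(cursor + 1L):(cursor + n)]
    cursor <<- cursor + n
    s
  }
  for (i in seq_len(n_units)) {
    u <- units[[i]]
    h <- hole_sizes[[i]]
    for (j in seq_along(u)) {
      out <- c(out, u[j])
      if (j < length(u)) out <- c(out, take(h[j]))
    }
    out <- c(out, take(gaps[i]))
  }
  out
}

#' Simulate per-station environmental parameters
#'
#' Values are drawn within each gradient's range; gradients with
#' `smooth = TRUE` are additionally smoothed by a 5-point moving average
#' along station order, emulating spatial autocorrelation along a transect.
#'
#' When `anchors` (ESTU niche optima and widths, as recorded in a simulated
#' truth) are supplied, a fraction of the stations is drawn around the
#' niche optima, cycling over ESTUs: transects cross the habitats the
#' organisms occupy, so every assemblage is represented among the sampled
#' stations. Purely uniform draws over a multi-gradient space routinely
#' leave one niche unsampled at desk-scale station counts, which would make
#' that niche's gene module unobservable by construction. The remaining
#' stations are uniform; anchored values are clipped to the gradient range.
#'
#' @param n_stations number of stations.
#' @param gradients gradient specs, see [default_gradients()].
#' @param seed integer seed.
#' @param anchors optional list with `mu` and `sigma` matrices (ESTU x
#'   niche gradient), e.g. `truth$estu_niche_params`.
#' @param anchor_fraction fraction of stations anchored to niche optima
#'   when `anchors` are given.
#' @return data.frame stations x parameters with station row names.
#' @export
simulate_environment <- function(n_stations, gradients = default_gradients(),
                                 seed = 1, anchors = NULL,
                                 anchor_fraction = 0.5) {
  set.seed(seed)
  n_anchor <- if (is.null(anchors)) 0L
  else min(n_stations, round(anchor_fraction * n_stations))
  anchor_estu <- if (n_anchor)
    rep(seq_len(nrow(anchors$mu)), length.out = n_anchor) else integer()
  cols <- lapply(names(gradients), function(nm) {
    sp <- gradients[[nm]]
    x <- stats::runif(n_stations, sp$range[1], sp$range[2])
    if (n_anchor && !is.null(anchors) && nm %in% colnames(anchors$mu)) {
      drawn <- stats::rnorm(n_anchor, anchors$mu[anchor_estu, nm],
                            anchors$sigma[anchor_estu, nm])
      x[seq_len(n_anchor)] <- pmin(pmax(drawn, sp$range[1]), sp$range[2])
    }
    if (isTRUE(sp$smooth) && n_stations >= 5) {
      pad <- c(x[1], x[1], x, x[n_stations], x[n_stations])
      x <- as.numeric(stats::filter(pad, rep(1 / 5, 5),
                                    sides = 2))[3:(n_stations + 2)]
    }
    x
  })
  names(cols) <- names(gradients)
  env <- as.data.frame(cols)
  rownames(env) <- sprintf("TARA_%03d", seq_len(n_stations))
  env
}

#' Simulate the ESTU community from Gaussian niche responses
#'
#' Each ESTU responds to the niche gradients with an axis-aligned Gaussian,
#' `r_e(s) = exp(-sum_p (x_ps - mu_ep)^2 / (2 sigma_ep^2))`, and relative
#' abundances are the row-normalised responses, so each station's ESTU
#' abundances sum to 1.
#'
#' @param env environment table from [simulate_environment()].
#' @param truth `truth` component of [simulate_pangenome()] (uses
#'   `estu_niche_params`).
#' @return numeric matrix stations x ESTUs (rows sum to 1).
#' @export
simulate_community <- function(env, truth) {
  mu <- truth$estu_niche_params$mu
  sigma <- truth$estu_niche_params$sigma
  miss <- setdiff(colnames(mu), colnames(env))
  if (length(miss))
    stop("environment table lacks niche gradient(s): ",
         paste(miss, collapse = ", "))
  x <- as.matrix(env[, colnames(mu), drop = FALSE])
  resp <- sapply(rownames(mu), function(e) {
    z <- sweep(x, 2, mu[e, ], "-")
    z <- sweep(z, 2, sigma[e, ], "/")
    exp(-rowSums(z^2) / 2)
  })
  resp <- matrix(resp, nrow = nrow(x),
                 dimnames = list(rownames(env), rownames(mu)))
  tot <- rowSums(resp)
  if (any(tot == 0))
    stop("station outside all niches: ",
         paste(rownames(resp)[tot == 0], collapse = ", "))
  validate_estu_table(resp / tot)
}

#' Simulate metagenomic read counts from a pangenome and community
#'
#' Expected fold-coverage of family `g` at station `s` is
#' `depth * sum_e abundance(e, s) * carriage(g, e)` with binary per-genome
#' carriage averaged within each ESTU; expected reads are
#' `lambda = coverage * L_g / L_read`. Counts are Poisson, negative binomial
#' when `overdispersion > 0` (variance `lambda + overdispersion * lambda^2`),
#' or exactly `lambda` in noiseless mode. The single-copy core marker `petB`
#' has expected coverage `depth` at every station.
#'
#' @param pangenome result of [simulate_pangenome()].
#' @param community stations x ESTUs matrix from [simulate_community()].
#' @param depth expected fold-coverage of a single-copy core gene (>= 0).
#' @param read_length read length in bp (all samples).
#' @param gene_length_range bp range for simulated gene lengths (`petB` is
#'   fixed at its real 645 bp).
#' @param overdispersion negative-binomial overdispersion; 0 = Poisson.
#' @param noiseless if `TRUE`, return expected counts exactly (variance off).
#' @param seed integer seed.
#' @param marker_length length of the `petB` marker in bp (its real gene
#'   length by default).
#' @return an [abundance_table()] at stage `"raw"`.
#' @export
simulate_counts <- function(pangenome, community, depth = 5,
                            read_length = 100,
                            gene_length_range = c(800, 2500),
                            overdispersion = 0, noiseless = FALSE,
                            seed = 1, marker_length = 645) {
  if (depth < 0) stop("depth must be >= 0")
  set.seed(seed)
  anns <- pangenome$annotations
  fams <- pangenome$families$family_id
  genome_estu <- pangenome$truth$genome_estu
  estus <- colnames(community)

  presence <- matrix(
    vapply(anns, function(g) fams %in% g$genes$family_id,
           logical(length(fams))),
    nrow = length(fams),
    dimnames = list(fams, vapply(anns, function(g) g$genome_id, "")))
  carriage <- matrix(
    vapply(estus, function(e) {
      rowMeans(presence[, names(genome_estu)[genome_estu == e],
                        drop = FALSE])
    }, numeric(length(fams))),
    nrow = length(fams), dimnames = list(fams, estus))

  lens <- stats::setNames(
    round(stats::runif(length(fams), gene_length_range[1],
                       gene_length_range[2])), fams)
  lens[pangenome$truth$marker] <- marker_length

  cov_exp <- depth * carriage %*% t(community[, estus, drop = FALSE])
  lambda <- cov_exp * lens[fams] / read_length
  counts <- if (noiseless) lambda
  else if (overdispersion > 0)
    matrix(stats::rnbinom(length(lambda), mu = lambda,
                          size = 1 / overdispersion),
           nrow = nrow(lambda), dimnames = dimnames(lambda))
  else matrix(stats::rpois(length(lambda), lambda),
              nrow = nrow(lambda), dimnames = dimnames(lambda))
  abundance_table(counts, "raw", gene_lengths = lens,
                  read_lengths = stats::setNames(
                    rep(read_length, nrow(community)), rownames(community)))
}

#' Simulate a complete study: pangenome, environment, community, counts
#'
#' Convenience wrapper reproducing the package's reference study conditions
#' (see the `simulate` section of [ecag_config()]): 24 genomes in 6 ESTUs,
#' 60 core + 240 flexible families, 6 planted eCAGs of 3-7 genes, 40
#' stations, Poisson counts at 5x single-copy depth.
#'
#' @param sim `simulate` section of a configuration list.
#' @param seed integer master seed; stage seeds are derived from it.
#' @param gradients gradient specs.
#' @param noiseless pass-through to [simulate_counts()].
#' @return list with `annotations`, `families`, `truth`, `env`, `estu`
#'   (community matrix) and `counts`.
#' @export
simulate_dataset <- function(sim = ecag_config()$simulate, seed = 1,
                             gradients = default_gradients(),
                             noiseless = FALSE) {
  pan <- simulate_pangenome(
    n_genomes = sim$n_genomes, n_estus = sim$n_estus,
    core_size = sim$core_size, flex_size = sim$flex_size,
    n_ecags = sim$n_ecags,
    ecag_size_range = c(sim$ecag_size_min, sim$ecag_size_max),
    max_gap = sim$max_gap, n_neutral = sim$n_neutral,
    neutral_carriage = sim$neutral_carriage,
    gradients = gradients, seed = seed)
  env <- simulate_environment(sim$n_stations, gradients, seed = seed + 1,
                              anchors = pan$truth$estu_niche_params)
  estu <- simulate_community(env, pan$truth)
  counts <- simulate_counts(
    pan, estu, depth = sim$depth, read_length = sim$read_length,
    gene_length_range = c(sim$gene_length_min, sim$gene_length_max),
    overdispersion = sim$overdispersion, noiseless = noiseless,
    seed = seed + 2, marker_length = sim$marker_length)
  c(pan, list(env = env, estu = estu, counts = counts))
}

#' Write a simulated dataset in the exact formats the readers consume
#'
#' Emits `counts.tsv` + `meta.tsv` ([read_abundance_table()]),
#' `annotations.tsv` ([read_genome_annotations()]), `env.tsv`
#' ([read_environment_table()]), `estu.tsv` ([read_estu_table()]),
#' `core_list.txt` ([read_core_list()]) and `truth.json` (planted ground
#' truth).
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_abundance_table(dataset$counts, p("counts.tsv"), p("meta.tsv"))
  write_genome_annotations(dataset$annotations, p("annotations.tsv"))
  write_sample_table(dataset$env, p("env.tsv"))
  write_sample_table(dataset$estu, p("estu.tsv"))
  writeLines(dataset$truth$core_families, p("core_list.txt"))
  truth <- dataset$truth
  truth$planted_modules <- as.list(truth$planted_modules)
  truth$genome_estu <- as.list(truth$genome_estu)
  truth$estu_niche_params <- lapply(truth$estu_niche_params, function(m)
    as.data.frame(m))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}
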