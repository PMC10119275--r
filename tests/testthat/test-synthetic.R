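test_that("pangenome simulation is reproducible and respects its contract", {
  pan1 <- simulate_pangenome(n_genomes = 12, n_estus = 4, core_size = 60,
                             flex_size = 80, n_ecags = 4, n_neutral = 32,
                             seed = 5)
  pan2 <- simulate_pangenome(n_genomes = 12, n_estus = 4, core_size = 60,
                             flex_size = 80, n_ecags = 4, n_neutral = 32,
                             seed = 5)
  expect_identical(pan1, pan2)

  truth <- pan1$truth
  anns <- pan1$annotations
  names(anns) <- vapply(anns, function(g) g$genome_id, "")
  for (ec in truth$planted_ecags) {
    for (g in ec$carrier_genomes) {
      fams <- anns[[g]]$genes$family_id
      expect_true(all(ec$members %in% fams))
      # consecutive members contiguous (max_gap = 1 by default)
      for (i in seq_len(length(ec$members) - 1))
        expect_lte(gene_gap_distance(anns[[g]], ec$members[i],
                                     ec$members[i + 1]), 1)
    }
    non_carriers <- setdiff(names(anns), ec$carrier_genomes)
    for (g in non_carriers)
      expect_false(any(ec$members %in% anns[[g]]$genes$family_id))
  }

  # same-niche genes outside an eCAG never sit close in any genome
  in_ecag <- unlist(lapply(truth$planted_ecags, `[[`, "members"))
  for (g in anns) {
    niche <- truth$genome_estu[[g$genome_id]]
    singles <- setdiff(
      names(truth$planted_modules)[truth$planted_modules == niche], in_ecag)
    singles <- intersect(singles, g$genes$family_id)
    pairs <- utils::combn(singles, 2)
    for (k in seq_len(ncol(pairs)))
      expect_gt(gene_gap_distance(g, pairs[1, k], pairs[2, k]), 5)
  }
})

test_that("degenerate pangenomes behave: single core gene, oversized eCAGs", {
  pan <- simulate_pangenome(n_genomes = 2, n_estus = 2, core_size = 1,
                            flex_size = 0, n_ecags = 0, n_neutral = 0,
                            seed = 1)
  for (g in pan$annotations)
    expect_identical(g$genes$family_id, "petB")
  expect_error(
    simulate_pangenome(n_genomes = 4, n_estus = 2, core_size = 5,
                       flex_size = 4, n_ecags = 2,
                       ecag_size_range = c(4, 4), n_neutral = 0, seed = 1),
    "exceed")
})

test_that("community abundances follow the Gaussian niche model", {
  truth1 <- list(estu_niche_params = list(
    mu = matrix(20, 1, 1, dimnames = list("E1", "temperature")),
    sigma = matrix(4, 1, 1, dimnames = list("E1", "temperature"))))
  env <- data.frame(temperature = c(10, 20, 30),
                    row.names = c("S1", "S2", "S3"))
  one <- simulate_community(env, truth1)
  expect_equal(unname(one[, 1]), c(1, 1, 1))

  truth2 <- list(estu_niche_params = list(
    mu = matrix(c(15, 25), 2, 1, dimnames = list(c("A", "B"), "temperature")),
    sigma = matrix(2, 2, 1, dimnames = list(c("A", "B"), "temperature"))))
  mid <- simulate_community(data.frame(temperature = 20, row.names = "S1"),
                            truth2)
  expect_equal(unname(mid[1, ]), c(0.5, 0.5))

  # station at A's optimum, B five sigma away: expected share from the
  # Gaussian ratio 1 / (1 + exp(-12.5))
  far <- simulate_community(data.frame(temperature = 15, row.names = "S1"),
                            truth2)
  expect_gte(far[1, "A"], 0.99)
  expect_equal(unname(far[1, "A"]), 1 / (1 + exp(-25 / 2)), tolerance = 1e-12)
})

test_that("expected read counts follow the coverage model exactly", {
  pan <- simulate_pangenome(n_genomes = 2, n_estus = 1, core_size = 2,
                            flex_size = 0, n_ecags = 0, n_neutral = 0,
                            seed = 2)
  comm <- matrix(1, 2, 1, dimnames = list(c("S1", "S2"), "ESTU_A"))
  cnt <- simulate_counts(pan, comm, depth = 2, read_length = 100,
                         gene_length_range = c(1000, 1000),
                         noiseless = TRUE, seed = 3)
  # carried by all genomes, L = 1000, L_read = 100, depth = 2 -> 20 reads
  expect_equal(unname(cnt$values["core_002", ]), c(20, 20))
  # petB expected coverage = depth at every station
  cov <- normalize_coverage(cnt)
  expect_equal(unname(cov$values["petB", ]), c(2, 2))

  z <- simulate_counts(pan, comm, depth = 0, noiseless = TRUE, seed = 3)
  expect_true(all(z$values == 0))
  expect_error(simulate_counts(pan, comm, depth = -1), ">= 0")
})

test_that("genes absent from the local community draw zero reads", {
  pan <- simulate_pangenome(n_genomes = 4, n_estus = 2, core_size = 2,
                            flex_size = 4, n_ecags = 1,
                            ecag_size_range = c(2, 2), n_neutral = 0,
                            seed = 4)
  # community entirely ESTU_A: ESTU_B's genes must be absent
  comm <- matrix(c(1, 0), 1, 2,
                 dimnames = list("S1", c("ESTU_A", "ESTU_B")))
  cnt <- simulate_counts(pan, comm, depth = 5, seed = 1)
  b_genes <- names(pan$truth$planted_modules)[
    pan$truth$planted_modules == "ESTU_B"]
  expect_true(all(cnt$values[b_genes, ] == 0))
})

test_that("petB-relative abundance converges to community-weighted carriage", {
  pan <- simulate_pangenome(n_genomes = 8, n_estus = 2, core_size = 10,
                            flex_size = 10, n_ecags = 0, n_neutral = 4,
                            seed = 6)
  env <- simulate_environment(6, seed = 7,
                              anchors = pan$truth$estu_niche_params)
  comm <- simulate_community(env, pan$truth)
  # expected value: carriage-weighted community abundance
  fam <- names(pan$truth$planted_modules)[1]
  carriers <- vapply(pan$annotations,
                     function(g) fam %in% g$genes$family_id, TRUE)
  estus <- colnames(comm)
  genome_estu <- pan$truth$genome_estu
  carriage <- vapply(estus, function(e)
    mean(carriers[genome_estu == e]), 0)
  expected <- as.vector(comm %*% carriage)
  n_rep <- 120
  rels <- matrix(NA_real_, n_rep, nrow(comm))
  for (r in seq_len(n_rep)) {
    cnt <- simulate_counts(pan, comm, depth = 5, seed = 1000 + r)
    cov <- normalize_coverage(cnt)
    rels[r, ] <- cov$values[fam, ] / cov$values["petB", ]
  }
  mn <- colMeans(rels)
  se <- apply(rels, 2, stats::sd) / sqrt(n_rep)
  # ratio estimator: allow 3 standard errors plus its O(1/lambda) bias
  expect_true(all(abs(mn - expected) <= 3 * se + 0.05 * expected + 1e-3))
})

test_that("environment draws stay within bounds and smoothing preserves them", {
  grads <- list(temperature = list(range = c(10, 30), smooth = TRUE,
                                   niche = TRUE),
                phi_sat = list(range = c(0, 1), smooth = FALSE,
                               niche = TRUE))
  env1 <- simulate_environment(25, grads, seed = 3)
  env2 <- simulate_environment(25, grads, seed = 3)
  expect_identical(env1, env2)
  expect_true(all(env1$temperature >= 10 & env1$temperature <= 30))
  expect_true(all(env1$phi_sat >= 0 & env1$phi_sat <= 1))
  expect_equal(dim(env1), c(25L, 2L))
})

test_that("a full simulated dataset is bit-reproducible under one seed", {
  cfg <- small_sim_config()
  ds1 <- simulate_dataset(cfg$simulate, seed = 11)
  ds2 <- simulate_dataset(cfg$simulate, seed = 11)
  expect_identical(ds1$counts$values, ds2$counts$values)
  expect_identical(ds1$env, ds2$env)
  expect_identical(ds1$estu, ds2$estu)
  expect_identical(ds1$truth, ds2$truth)
})
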