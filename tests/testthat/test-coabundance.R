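test_that("topological overlap follows the formula in closed-form cases", {
  # two genes connected only to each other with a = 1 -> TOM (0+1)/(1+1-1)
  prof <- rbind(g1 = c(1, 2, 3, 4, 5), g2 = c(1, 2, 3, 4, 5),
                g3 = c(2, -1, 3, -2, 1))
  colnames(prof) <- paste0("S", 1:5)
  net <- suppressMessages(build_network(prof, power = 50))
  expect_equal(net$tom["g1", "g2"], 1, tolerance = 1e-10)

  # perfectly correlated triple: all pairwise TOM = 1
  tri <- rbind(a = 1:6, b = 2 * (1:6) + 3, c = 0.5 * (1:6) - 1)
  colnames(tri) <- paste0("S", 1:6)
  nt <- suppressMessages(build_network(tri, power = 6))
  expect_equal(unname(nt$tom[upper.tri(nt$tom)]), rep(1, 3),
               tolerance = 1e-10)

  # zero adjacency everywhere -> zero off-diagonal TOM
  a0 <- diag(3)
  dimnames(a0) <- list(letters[1:3], letters[1:3])
  t0 <- tom_brute(a0)
  expect_equal(unname(t0[upper.tri(t0)]), rep(0, 3))
})

test_that("TOM equals the brute-force triple sum on random networks", {
  set.seed(41)
  prof <- matrix(rnorm(20 * 15), 20, 15,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("S%02d", 1:15)))
  net <- suppressMessages(build_network(prof, power = 6))
  expect_equal(net$tom, tom_brute(net$adjacency), tolerance = 1e-12)
  expect_true(isSymmetric(net$tom))
  expect_true(all(net$tom >= 0 & net$tom <= 1))
})

test_that("scale-free fit is high for power-law degrees, low for noise", {
  set.seed(42)
  g <- igraph::sample_pa(500, power = 1, m = 2, directed = FALSE)
  k <- igraph::degree(g)
  expect_gte(ecag:::scale_free_fit(k)["fit"], 0.8)
  k_unif <- runif(500, 10, 20)
  expect_lt(ecag:::scale_free_fit(k_unif)["fit"], 0.8)
})

test_that("soft-threshold selection is deterministic and handles degeneracy", {
  set.seed(43)
  prof <- matrix(rnorm(30 * 20), 30, 20,
                 dimnames = list(sprintf("g%02d", 1:30), sprintf("S%02d", 1:20)))
  s1 <- suppressMessages(pick_soft_threshold(prof))
  s2 <- suppressMessages(pick_soft_threshold(prof))
  expect_identical(s1, s2)
  expect_equal(nrow(s1$fits), 20)
  # constant profiles are excluded before fitting
  prof2 <- rbind(prof, const = rep(1, 20))
  msgs <- capture_messages(pick_soft_threshold(prof2))
  expect_true(any(grepl("constant", msgs)))
  expect_error(suppressMessages(
    pick_soft_threshold(prof[, 1:5])), ">= 8 samples")
})

test_that("module detection recovers planted correlation blocks", {
  set.seed(44)
  n_s <- 30
  base1 <- rnorm(n_s); base2 <- rnorm(n_s)
  mk <- function(base, n) t(sapply(seq_len(n),
                                   function(i) base + rnorm(n_s, sd = 0.05)))
  prof <- rbind(mk(base1, 12), mk(base2, 12))
  rownames(prof) <- sprintf("g%02d", 1:24)
  colnames(prof) <- sprintf("S%02d", 1:n_s)
  net <- suppressMessages(build_network(prof, power = 6))
  part <- suppressMessages(detect_modules(net, min_module_size = 5))
  expect_length(setdiff(unique(part), "grey"), 2)
  truth <- rep(c("m1", "m2"), each = 12)
  expect_equal(mclust::adjustedRandIndex(part, truth), 1.0)

  # duplicated profiles double sizes, not module count
  dup <- rbind(prof, prof)
  rownames(dup) <- sprintf("g%02d", 1:48)
  netd <- suppressMessages(build_network(dup, power = 6))
  partd <- suppressMessages(detect_modules(netd, min_module_size = 5))
  expect_length(setdiff(unique(partd), "grey"), 2)
  expect_equal(sort(unname(table(partd[partd != "grey"]))),
               sort(unname(table(part[part != "grey"]))) * 2L)

  # min_module_size larger than the gene count: everything grey
  expect_warning(allgrey <- detect_modules(net, min_module_size = 50),
                 "grey")
  expect_true(all(allgrey == "grey"))
})

test_that("eigengenes are unit-norm, sign-oriented, first-PC optimal", {
  set.seed(45)
  prof <- rbind(a = 1:8, b = 2 * (1:8), c = 3 * (1:8))
  colnames(prof) <- paste0("S", 1:8)
  part <- structure(stats::setNames(rep("turquoise", 3), rownames(prof)),
                    class = "module_partition")
  me <- module_eigengene(prof, part)
  expect_equal(sum(me$ME["turquoise", ]^2), 1, tolerance = 1e-12)
  # identical standardized profiles: kME = 1 for every member
  expect_equal(unname(me$kME[, "turquoise"]), rep(1, 3), tolerance = 1e-12)
  # sign rule: positively oriented towards the mean member profile
  zc <- colMeans(t(scale(t(prof))))
  expect_gte(stats::cor(me$ME["turquoise", ], zc), 0)

  # variance explained beats random unit-norm sample vectors
  prof2 <- matrix(rnorm(10 * 12), 10, 12,
                  dimnames = list(sprintf("g%02d", 1:10), sprintf("S%02d", 1:12)))
  part2 <- structure(stats::setNames(rep("blue", 10), rownames(prof2)),
                     class = "module_partition")
  me2 <- module_eigengene(prof2, part2)
  xz <- t(scale(t(prof2)))
  tot <- sum(xz^2)
  ve_me <- sum((xz %*% me2$ME["blue", ])^2) / tot
  expect_equal(unname(me2$var_explained["blue"]), ve_me, tolerance = 1e-12)
  for (i in 1:50) {
    u <- rnorm(12); u <- u / sqrt(sum(u^2))
    expect_lte(sum((xz %*% u)^2) / tot, ve_me + 1e-12)
  }
})

test_that("trait correlations use the Student asymptotic p and Spearman ranks", {
  set.seed(46)
  n_s <- 15
  me_mat <- matrix(rnorm(n_s), 1, n_s,
                   dimnames = list("turquoise", sprintf("S%02d", 1:n_s)))
  me <- structure(list(ME = me_mat), class = "eigengene_set")
  env <- data.frame(temperature = me_mat[1, ] * 2 + 1,
                    noise = rnorm(n_s),
                    row.names = colnames(me_mat))
  tr <- module_trait_correlation(me, env = env)
  expect_equal(unname(tr$environment$r["turquoise", "temperature"]), 1)
  expect_lt(tr$environment$p["turquoise", "temperature"], 0.01)

  estu <- cbind(E1 = stats::plogis(me_mat[1, ]))
  estu <- cbind(estu, E2 = 1 - estu[, 1])
  rownames(estu) <- colnames(me_mat)
  tr2 <- module_trait_correlation(me, estu = estu)
  # Spearman is invariant under monotone transforms
  estu_m <- cbind(E1 = estu[, "E1"]^3, E2 = exp(estu[, "E2"]))
  tr3 <- module_trait_correlation(me, estu = estu_m)
  expect_equal(tr2$estu$r, tr3$estu$r, tolerance = 1e-12)

  # too few paired observations reported missing
  env$sparse <- c(1, 2, rep(NA, n_s - 2))
  tr4 <- module_trait_correlation(me, env = env)
  expect_true(is.na(tr4$environment$r["turquoise", "sparse"]))
})

test_that("asymptotic correlation p-values agree with a permutation null", {
  set.seed(47)
  n <- 25
  for (i in 1:8) {
    x <- rnorm(n); y <- rnorm(n)
    r_obs <- stats::cor(x, y)
    p_asym <- ecag:::cor_student_p(r_obs, n)
    n_perm <- 2000
    r_perm <- replicate(n_perm, abs(stats::cor(x, sample(y))))
    p_perm <- (1 + sum(r_perm >= abs(r_obs))) / (1 + n_perm)
    se <- sqrt(p_perm * (1 - p_perm) / n_perm)
    expect_lt(abs(p_asym - p_perm), 4 * se + 0.02)
  }
})

test_that("representative genes are ranked by own-module kME", {
  prof <- rbind(a = 1:8, b = 2 * (1:8), c = 3 * (1:8))
  colnames(prof) <- paste0("S", 1:8)
  part <- structure(stats::setNames(rep("turquoise", 3), rownames(prof)),
                    class = "module_partition")
  me <- module_eigengene(prof, part)
  reps <- representative_genes(me, part, min_kme = 0.7)
  expect_setequal(reps$turquoise$family, c("a", "b", "c"))
  expect_equal(reps$turquoise$kme, rep(1, 3), tolerance = 1e-12)
  none <- representative_genes(me, part, min_kme = 1.01)
  expect_equal(nrow(none$turquoise), 0)
  # planted module plus unrelated noise genes: only members selected
  set.seed(48)
  noise <- matrix(rnorm(3 * 8), 3, 8,
                  dimnames = list(c("n1", "n2", "n3"), paste0("S", 1:8)))
  prof2 <- rbind(prof, noise)
  part2 <- structure(
    stats::setNames(c(rep("turquoise", 3), rep("grey", 3)),
                    rownames(prof2)), class = "module_partition")
  me2 <- module_eigengene(prof2, part2)
  reps2 <- representative_genes(me2, part2, min_kme = 0.7)
  expect_setequal(reps2$turquoise$family, c("a", "b", "c"))
})
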