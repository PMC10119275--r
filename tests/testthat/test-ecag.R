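make_edges_df <- function(pairs, mode = "support") {
  lo <- ifelse(pairs[, 1] < pairs[, 2], pairs[, 1], pairs[, 2])
  hi <- ifelse(pairs[, 1] < pairs[, 2], pairs[, 2], pairs[, 1])
  df <- data.frame(famA = lo, famB = hi,
                   n_both = 5L, n_close = 5L, support = 1, d_min = 1L,
                   edge = TRUE, stringsAsFactors = FALSE)
  structure(df, mode = mode, D = 5L, min_support = 0.8,
            class = c("synteny_edges", "data.frame"))
}

test_that("eCAGs are module-restricted connected components", {
  part <- structure(stats::setNames(
    c("blue", "blue", "blue", "blue", "red", "grey"),
    c("a", "b", "c", "d", "e", "f")), class = "module_partition")
  edges <- make_edges_df(cbind(c("a", "b", "d", "e", "f"),
                               c("b", "c", "e", "f", "a")))
  ecs <- suppressMessages(delineate_ecags(edges, part, genus_prefix = "Pro"))
  expect_length(ecs, 1)
  expect_identical(ecs[[1]]$members, c("a", "b", "c"))   # chain a-b-c
  expect_identical(ecs[[1]]$id, "Pro-eCAG_001")
  # d-e edge crosses modules, e-f and f-a touch grey: no eCAG spans them
  expect_identical(attr(ecs, "unclustered"), c("d", "e"))
})

test_that("eCAG ids are ordered by decreasing size then lexicographically", {
  part <- structure(stats::setNames(
    rep(c("blue", "red"), c(2, 3)), c("x", "y", "p", "q", "r")),
    class = "module_partition")
  edges <- make_edges_df(cbind(c("x", "p", "q"), c("y", "q", "r")))
  ecs <- suppressMessages(delineate_ecags(edges, part, genus_prefix = "Syn"))
  expect_identical(vapply(ecs, `[[`, "", "id"),
                   c("Syn-eCAG_001", "Syn-eCAG_002"))
  expect_identical(ecs[[1]]$members, c("p", "q", "r"))   # bigger first
})

test_that("eCAG profiles summarise members and propagate masking", {
  v <- matrix(c(0.2, 0.5, NA,
                0.4, 0.1, NA,
                0.9, 0.3, NA), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("S1", "S2", "S3")))
  rel <- abundance_table(v, "relative")
  expect_equal(unname(ecag_profile(rel, c("a", "b"))["S1"]), 0.3)
  expect_true(is.na(ecag_profile(rel, c("a", "b"))["S3"]))
  med <- ecag_profile(rel, c("a", "b", "c"), summary = "median")
  mn <- ecag_profile(rel, c("a", "b", "c"), summary = "mean")
  expect_equal(unname(med["S1"]), 0.4)
  expect_equal(unname(mn["S1"]), 0.5)
  expect_error(ecag_profile(rel, c("zz")), "no eCAG member")
})

test_that("Welch enrichment: symmetry, conventions, and power", {
  set.seed(61)
  x <- matrix(rnorm(40), 2, 20,
              dimnames = list(c("u1", "u2"), sprintf("S%02d", 1:20)))
  a <- sprintf("S%02d", 1:10); b <- sprintf("S%02d", 11:20)
  fwd <- niche_enrichment(x, a, b)
  rev_ <- niche_enrichment(x, b, a)
  expect_equal(fwd$t, -rev_$t)
  expect_equal(fwd$p, rev_$p)

  const <- matrix(1, 1, 20, dimnames = list("c1", colnames(x)))
  expect_equal(niche_enrichment(const, a, b)$p, 1)   # zero var, equal means
  shift <- const; shift[, b] <- 2
  expect_equal(niche_enrichment(shift, a, b)$p, 0)

  # 5 pooled-SD shift at n = 10 per group is essentially always detected
  y <- matrix(c(rnorm(10), rnorm(10, mean = 5)), 1, 20,
              dimnames = list("power", colnames(x)))
  expect_lt(niche_enrichment(y, a, b)$p, 0.05)

  sparse <- matrix(c(1, NA, NA, NA, NA, NA, 2, 3, 4, 5), 1, 10,
                   dimnames = list("s", sprintf("S%02d", 1:10)))
  expect_warning(out <- niche_enrichment(sparse, sprintf("S%02d", 1:5),
                                         sprintf("S%02d", 6:10)),
                 "skipped")
  expect_true(is.na(out$p))
})

test_that("per-eCAG enrichment flags require all members significant", {
  set.seed(62)
  n_s <- 24
  stations <- sprintf("S%02d", 1:n_s)
  a <- stations[1:12]; b <- stations[13:24]
  strong <- t(sapply(1:3, function(i)
    c(rnorm(12, 1, 0.1), rnorm(12, 0.2, 0.1))))
  weak <- t(sapply(1:2, function(i) rnorm(n_s, 0.5, 0.1)))
  v <- rbind(strong, weak)
  dimnames(v) <- list(c("s1", "s2", "s3", "w1", "w2"), stations)
  rel <- abundance_table(v, "relative")
  ecags <- structure(list(
    list(id = "Pro-eCAG_001", module = "blue",
         members = c("s1", "s2", "s3")),
    list(id = "Pro-eCAG_002", module = "red", members = c("w1", "w2"))),
    class = "ecag_set")
  enr <- ecag_enrichment(rel, ecags, a, b)
  expect_true(enr$ecags$all_significant[enr$ecags$ecag == "Pro-eCAG_001"])
  expect_false(enr$ecags$all_significant[enr$ecags$ecag == "Pro-eCAG_002"])
  expect_equal(enr$ecags$direction[enr$ecags$ecag == "Pro-eCAG_001"], 1)
})

test_that("network export writes a consistent, seeded GraphML", {
  part <- structure(stats::setNames(
    c("blue", "blue", "blue", "grey"), c("a", "b", "c", "z")),
    class = "module_partition")
  edges <- make_edges_df(cbind(c("a", "b"), c("b", "c")))
  ecs <- suppressMessages(delineate_ecags(edges, part))
  f <- tempfile(fileext = ".graphml")
  g <- export_network(edges, part, ecs, path = f, seed = 9)
  expect_true(file.exists(f))
  expect_equal(igraph::vcount(g), 3)   # grey node excluded
  expect_equal(igraph::ecount(g), 2)
  g2 <- export_network(edges, part, ecs, seed = 9)
  expect_identical(igraph::V(g)$x, igraph::V(g2)$x)
  expect_identical(igraph::V(g)$ecag[igraph::V(g)$name == "a"],
                   "Pro-eCAG_001")
  # empty partition -> valid empty graph
  empty_part <- structure(stats::setNames(character(0), character(0)),
                          class = "module_partition")
  f0 <- tempfile(fileext = ".graphml")
  g0 <- export_network(edges, empty_part, NULL, path = f0)
  expect_true(file.exists(f0))
  expect_equal(igraph::vcount(g0), 0)
})
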