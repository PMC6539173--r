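rand_dist <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(rnorm(n * 2), n)
  rownames(pts) <- paste0("p", seq_len(n))
  as.matrix(dist(pts))
}

test_that("Mantel statistic and permutation floor behave canonically", {
  d1 <- rand_dist(10, 1)
  res <- mantel_test(d1, d1, n_perm = 199, seed = 3)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 200)

  d2 <- rand_dist(10, 2)
  res2 <- mantel_test(d1, d2, n_perm = 199, seed = 3)
  expect_gte(res2$p, 1 / 200)
  expect_true(abs(res2$r) <= 1)

  # relabeling both matrices identically leaves r unchanged
  pp <- sample(10)
  res3 <- mantel_test(d1[pp, pp], d2[pp, pp], n_perm = 99, seed = 3)
  expect_equal(res3$r, res2$r)

  expect_error(mantel_test(matrix(1, 5, 5) - diag(5) * 0, d1[1:5, 1:5]),
               "Constant")
})

test_that("Mantel r agrees with vegan", {
  skip_if_not_installed("vegan")
  d1 <- rand_dist(12, 11)
  d2 <- 0.6 * d1 + 0.4 * rand_dist(12, 12)
  ours <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("partial Mantel nulls out self-control and keeps real signal", {
  d1 <- rand_dist(12, 21)
  d3 <- rand_dist(12, 22)
  # controlling D2 for itself removes the signal
  res <- partial_mantel(d1, d3, d3, n_perm = 99, seed = 5)
  expect_lt(abs(res$r), 1e-10)
  # D1 = D2, random control: r near 1, p at floor
  res2 <- partial_mantel(d1, d1, d3, n_perm = 199, seed = 5)
  expect_gt(res2$r, 0.9)
  expect_equal(res2$p, 1 / 200)
  # uncorrelated control: partial ~ simple
  d2 <- 0.7 * d1 + 0.3 * rand_dist(12, 23)
  simple <- mantel_test(d1, d2, n_perm = 99, seed = 7)
  partial <- partial_mantel(d1, d2, rand_dist(12, 24), n_perm = 99, seed = 7)
  expect_lt(abs(simple$r - partial$r), 0.15)
})

test_that("partial Mantel r agrees with vegan", {
  skip_if_not_installed("vegan")
  d1 <- rand_dist(12, 31)
  d2 <- 0.6 * d1 + 0.4 * rand_dist(12, 32)
  d3 <- 0.5 * d1 + 0.5 * rand_dist(12, 33)
  ours <- partial_mantel(d1, d2, d3, n_perm = 99, seed = 1)
  ref <- vegan::mantel.partial(as.dist(d1), as.dist(d2), as.dist(d3),
                               permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("permutations are reproducible under a fixed seed", {
  d1 <- rand_dist(10, 41)
  d2 <- rand_dist(10, 42)
  a <- mantel_test(d1, d2, n_perm = 199, seed = 99)
  b <- mantel_test(d1, d2, n_perm = 199, seed = 99)
  expect_identical(tidy(a), tidy(b))
})

test_that("taxon connectivity Mantel detects a planted association", {
  set.seed(51)
  # network of 12 taxon members: node i connected to its i nearest ids
  # so that degree increases with index; GS increases the same way
  n <- 12
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(sprintf("t%02d", 1:n))
  for (i in 2:n) for (j in 1:(i - 1)) {
    if (j > i - 1 - (i - 2) / 2) {
      g <- igraph::add_edges(g, c(sprintf("t%02d", i), sprintf("t%02d", j)))
    }
  }
  igraph::E(g)$weight <- 0.9
  igraph::E(g)$sign <- 1
  deg <- igraph::degree(g)
  gs <- dplyr::bind_rows(
    tibble::tibble(otu_id = names(deg), trait = "BUN",
                   gs = rank(deg) / n, r = sqrt(rank(deg) / n)),
    tibble::tibble(otu_id = names(deg), trait = "SOD",
                   gs = runif(n), r = NA_real_))
  taxonomy <- setNames(rep("Bacteria; Proteo; FamX", n), names(deg))
  res <- taxon_connectivity_mantel(g, gs, taxonomy, "FamX", "BUN",
                                   n_perm = 999, seed = 1)
  expect_gt(res$r, 0)
  expect_lte(res$p, 0.05)
  expect_true(res$partial)

  expect_error(
    taxon_connectivity_mantel(g, gs, taxonomy[1:3], "FamX", "BUN"),
    class = "rmtnet_too_few_taxon_members")
})
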