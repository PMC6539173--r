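test_that("Zi follows the star-module hand calculation", {
  # module A: 4-node star; module B: triangle; one bridge from a leaf to B
  g <- igraph::make_graph(~ hub - l1, hub - l2, hub - l3,
                          b1 - b2, b2 - b3, b3 - b1, l1 - b1)
  igraph::E(g)$weight <- 0.9
  igraph::E(g)$sign <- 1
  mem <- c(hub = 1, l1 = 1, l2 = 1, l3 = 1, b1 = 2, b2 = 2, b3 = 2)
  roles <- node_roles(g, mem)

  kw <- c(3, 1, 1, 1)  # within-degrees of module A
  sd_pop <- sqrt(mean((kw - mean(kw))^2))
  zi_hub <- (3 - mean(kw)) / sd_pop
  expect_equal(roles$zi[roles$otu_id == "hub"], zi_hub)
  expect_equal(roles$k_within[roles$otu_id == "hub"], 3)

  # z-score property per module with spread
  for (m in 1:2) {
    if (sd(roles$k_within[roles$module == m]) > 0) {
      expect_equal(mean(roles$zi[roles$module == m]), 0, tolerance = 1e-9)
      expect_equal(sqrt(mean(roles$zi[roles$module == m]^2)), 1,
                   tolerance = 1e-9)
    }
  }

  # l1: 2 links, 1 within, 1 out -> Pi = 1 - (1/4 + 1/4) = 1/2
  expect_equal(roles$pi[roles$otu_id == "l1"], 0.5)
  # all-internal nodes have Pi exactly 0
  expect_true(all(roles$pi[roles$otu_id %in% c("hub", "l2", "l3")] == 0))
})

test_that("uniform within-degree modules give Zi = 0 by convention", {
  g <- clique_union(2, 4)
  mem <- setNames(rep(1:2, each = 4), igraph::V(g)$name)
  roles <- node_roles(g, mem)
  expect_true(all(roles$zi == 0))
  expect_true(all(roles$pi == 0))
  expect_true(all(roles$role == "peripheral"))
})

test_that("participation coefficient has its symmetric closed forms", {
  # node 'x' with k links spread equally over t modules
  for (t in 2:4) {
    edges <- unlist(lapply(seq_len(t), function(m) c("x", paste0("m", m, "_1"))))
    g <- igraph::make_graph(edges, directed = FALSE)
    igraph::E(g)$weight <- 1; igraph::E(g)$sign <- 1
    mem <- setNames(c(1, seq_len(t)),
                    c("x", paste0("m", seq_len(t), "_1")))
    roles <- node_roles(g, mem)
    expect_equal(roles$pi[roles$otu_id == "x"], 1 - 1 / t)
    # Pi bounded by 1 - 1/M over the M touched modules
    expect_lte(roles$pi[roles$otu_id == "x"], 1 - 1 / t)
  }

  # 3 links: 2 into own module, 1 into another -> Pi = 4/9
  g <- igraph::make_graph(~ x - a, x - b, x - c)
  igraph::E(g)$weight <- 1; igraph::E(g)$sign <- 1
  mem <- c(x = 1, a = 1, b = 1, c = 2)
  roles <- node_roles(g, mem)
  expect_equal(roles$pi[roles$otu_id == "x"], 1 - (4 / 9 + 1 / 9))
})

test_that("Zi and Pi match naive edge enumeration on random graphs", {
  set.seed(23)
  for (i in 1:20) {
    g <- random_named_graph(sample(8:20, 1), 0.35)
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
    if (igraph::vcount(g) < 4 || igraph::ecount(g) < 3) next
    mem <- sample(1:3, igraph::vcount(g), replace = TRUE)
    names(mem) <- igraph::V(g)$name
    roles <- node_roles(g, mem)
    oracle <- naive_zipi(g, mem)
    expect_equal(setNames(roles$zi, roles$otu_id), oracle$zi[roles$otu_id])
    expect_equal(setNames(roles$pi, roles$otu_id), oracle$pi[roles$otu_id])
  }
})

test_that("role classification uses the documented boundary conventions", {
  expect_equal(classify_roles(3.0, 0.2), "module_hub")
  expect_equal(classify_roles(2.5, 0.62), "peripheral")
  expect_equal(classify_roles(2.6, 0.7), "network_hub")
  expect_equal(classify_roles(1.0, 0.7), "connector")
  expect_equal(classify_roles(c(3, 0), c(0.1, 0.1)),
               c("module_hub", "peripheral"))
})

test_that("role tables write and plot", {
  g <- clique_union(2, 3)
  part <- fast_greedy_modules(g)
  roles <- node_roles(g, part)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_role_table(roles, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 6)
  expect_true(all(c("otu_id", "zi", "pi", "role") %in% names(back)))
  p <- ggplot2::ggplot_build(plot_zipi(roles))
  expect_gt(length(p$data), 0)
})
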