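test_that("a rank-1 module yields its common profile as eigengene", {
  base <- c(1, 3, 2, 5, 4, 6, 8, 7)
  x <- rbind(a = base, b = 2 * base + 1, c = -0.5 * base + 3,
             d = 3 * base, e = base - 2, f = 0.1 * base)
  colnames(x) <- paste0("s", 1:8)
  mem <- setNames(rep(1, 6), rownames(x))
  eg <- module_eigengene(x, mem, 1)
  expect_equal(eg$variance_explained, 1)
  std <- (base - mean(base)) / sqrt(mean((base - mean(base))^2))
  expect_equal(unname(eg$scores), std, tolerance = 1e-8)
  # scores standardized: zero mean, unit population SD
  expect_equal(mean(eg$scores), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(eg$scores^2)), 1, tolerance = 1e-12)
})

test_that("eigengene recovers a planted factor and ignores PC sign", {
  set.seed(71)
  f <- rnorm(8)
  x <- t(vapply(1:10, function(i) {
    sqrt(0.9) * f + sqrt(0.1) * rnorm(8)
  }, numeric(8)))
  dimnames(x) <- list(paste0("o", 1:10), paste0("s", 1:8))
  mem <- setNames(rep(1, 10), rownames(x))
  eg <- module_eigengene(x, mem, 1)
  expect_gte(abs(cor(eg$scores, f)), 0.9)
  # orientation anchored: recompute from the negated matrix of members
  eg2 <- module_eigengene(-x, mem, 1)
  expect_gte(cor(eg$scores, -eg2$scores), 0.999)

  expect_error(module_eigengene(x[1:3, ], setNames(rep(1, 3), paste0("o", 1:3)), 1),
               class = "rmtnet_module_too_small")
})

test_that("correlate matches cor.test and floors extreme p-values", {
  set.seed(73)
  x <- rnorm(10); y <- rnorm(10)
  res <- correlate(x, y)
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p, ct$p.value)
  expect_equal(res$n, 10)

  perfect <- correlate(x, x)
  expect_equal(perfect$r, 1)
  expect_lte(perfect$p, .Machine$double.xmin)

  # pairwise deletion
  y2 <- y; y2[1:2] <- NA
  expect_equal(correlate(x, y2)$n, 8)
  expect_error(correlate(1:3, 3:1), ">= 4")
})

test_that("module-trait table has one calibrated row per pair", {
  set.seed(79)
  sc <- simulate_community(synthetic_config(seed = 79))
  ab <- transform_abundance(sc$otu)
  mem <- setNames(sc$truth$partition$module, sc$truth$partition$otu_id)
  mem <- mem[mem > 0]
  egs <- module_eigengenes(ab, mem, min_size = 6)
  mt <- module_trait_table(egs, sc$truth$traits)
  expect_equal(nrow(mt), length(egs) * 4)
  expect_true(all(mt$r >= -1 & mt$r <= 1))
  expect_true(all(mt$p > 0 & mt$p <= 1))

  # trait identical to an eigengene -> r = 1
  tr2 <- sc$truth$traits
  tr2$BUN <- unname(egs[[1]]$scores)
  mt2 <- module_trait_table(egs[1], tr2)
  expect_equal(mt2$r[mt2$trait == "BUN"], 1)

  bad <- sc$truth$traits[1:4, ]
  expect_error(module_trait_table(egs, bad), "absent")
})

test_that("eigengene-trait p-values are uniform under the null", {
  set.seed(83)
  f <- rnorm(8)
  x <- t(vapply(1:10, function(i) sqrt(0.9) * f + sqrt(0.1) * rnorm(8),
                numeric(8)))
  dimnames(x) <- list(paste0("o", 1:10), paste0("s", 1:8))
  eg <- module_eigengene(x, setNames(rep(1, 10), rownames(x)), 1)
  hits <- mean(replicate(1000, correlate(eg$scores, rnorm(8))$p < 0.05))
  expect_gte(hits, 0.03)
  expect_lte(hits, 0.07)
})

test_that("OTU significance is the squared correlate r", {
  set.seed(89)
  v <- matrix(rnorm(40), 5, 8,
              dimnames = list(paste0("o", 1:5), paste0("s", 1:8)))
  traits <- tibble::tibble(sample_id = paste0("s", 1:8), BUN = rnorm(8))
  gs <- otu_significance(v, traits)
  expect_equal(nrow(gs), 5)
  for (i in 1:5) {
    expect_equal(gs$gs[i], correlate(v[i, ], traits$BUN)$r^2)
  }
  # profile equal to the trait -> GS = 1
  v[1, ] <- traits$BUN
  gs2 <- otu_significance(v, traits)
  expect_equal(gs2$gs[1], 1)
  # orthogonal profile -> GS = 0
  y <- traits$BUN - mean(traits$BUN)
  o <- rnorm(8); o <- o - mean(o)
  o <- o - y * sum(o * y) / sum(y * y)
  v[2, ] <- o
  gs3 <- otu_significance(v, traits)
  expect_equal(gs3$gs[2], 0, tolerance = 1e-20)
})
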