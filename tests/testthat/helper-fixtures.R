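# Fixtures and independent oracles shared across the suite.

# small OTU table with optional zero pattern
toy_otu <- function(values = NULL) {
  if (is.null(values)) {
    values <- matrix(c(5, 0, 2,
                       1, 3, 4), nrow = 3,
                     dimnames = list(paste0("OTU_", 1:3), c("s1", "s2")))
  }
  otu_table(values)
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# similarity_matrix built directly from a symmetric matrix
sim_from_matrix <- function(s, sign = NULL) {
  diag(s) <- 0
  if (is.null(rownames(s))) {
    dimnames(s) <- list(paste0("OTU_", seq_len(nrow(s))),
                        paste0("OTU_", seq_len(nrow(s))))
  }
  if (is.null(sign)) sign <- (s > 0) * 1
  structure(list(s = s, sign = sign, otu_ids = rownames(s)),
            class = "similarity_matrix")
}

# union of k disjoint cliques of equal size, as igraph with names/weights
clique_union <- function(k, size, weight = 0.95) {
  g <- igraph::make_empty_graph(directed = FALSE)
  for (i in seq_len(k)) {
    cl <- igraph::make_full_graph(size)
    igraph::V(cl)$name <- sprintf("n%d_%d", i, seq_len(size))
    g <- igraph::disjoint_union(g, cl)
  }
  igraph::E(g)$weight <- weight
  igraph::E(g)$sign <- 1
  g
}

random_named_graph <- function(n, p = 0.3) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  igraph::E(g)$weight <- 0.9
  igraph::E(g)$sign <- 1
  g
}

# naive Zi/Pi by explicit edge enumeration (independent of node_roles)
naive_zipi <- function(g, mem) {
  nodes <- igraph::V(g)$name
  el <- igraph::as_edgelist(g, names = TRUE)
  k_it <- function(v) {
    partners <- c(el[el[, 1] == v, 2], el[el[, 2] == v, 1])
    table(factor(mem[partners], levels = sort(unique(mem))))
  }
  kw <- vapply(nodes, function(v) {
    partners <- c(el[el[, 1] == v, 2], el[el[, 2] == v, 1])
    sum(mem[partners] == mem[v])
  }, numeric(1))
  zi <- numeric(length(nodes)); names(zi) <- nodes
  for (m in unique(mem[nodes])) {
    idx <- nodes[mem[nodes] == m]
    mu <- mean(kw[idx]); s <- sqrt(mean((kw[idx] - mu)^2))
    zi[idx] <- if (s == 0) 0 else (kw[idx] - mu) / s
  }
  pi_v <- vapply(nodes, function(v) {
    kt <- k_it(v); k <- sum(kt)
    if (k == 0) return(0)
    1 - sum((kt / k)^2)
  }, numeric(1))
  list(zi = zi, pi = pi_v, k_within = kw)
}

# all set partitions of n elements via restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, m) {
    i <- length(prefix) + 1
    if (i > n) { out[[length(out) + 1]] <<- prefix; return() }
    for (v in seq_len(m + 1)) rec(c(prefix, v), max(m, v))
  }
  rec(integer(0), 0L)
  out
}

# two-block latent-factor similarity with a genuine GOE->Poisson transition
two_block_similarity <- function(seed, block = 30, n_samples = 12, rho = 0.9) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  X <- rbind(
    t(vapply(seq_len(block), function(i)
      sqrt(rho) * f1 + sqrt(1 - rho) * rnorm(n_samples), numeric(n_samples))),
    t(vapply(seq_len(block), function(i)
      sqrt(rho) * f2 + sqrt(1 - rho) * rnorm(n_samples), numeric(n_samples))))
  rownames(X) <- sprintf("OTU_%02d", seq_len(2 * block))
  pearson_similarity(X)
}

# inverse-CDF sampler for the Wigner surmise spacing distribution
rwigner <- function(n) sqrt(-4 / pi * log(1 - runif(n)))

# symmetric GOE matrix
rgoe <- function(n) {
  m <- matrix(rnorm(n * n), n)
  (m + t(m)) / sqrt(2)
}
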