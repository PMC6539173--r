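#' Build a co-occurrence network at a threshold
#'
#' Nodes are OTUs; an edge joins two OTUs whenever their similarity
#' (absolute Pearson r) is at least `s_t`. Edges carry the similarity as
#' `weight` and the sign of the underlying correlation as `sign` (+1 for
#' positive, -1 for negative co-occurrence). OTUs with no edge are
#' excluded.
#'
#' @param sim A `similarity_matrix` from [pearson_similarity()].
#' @param s_t Correlation cutoff, typically from [detect_rmt_threshold()].
#' @return An undirected [igraph::igraph] graph.
#' @export
build_network <- function(sim, s_t) {
  th <- threshold_matrix(sim, s_t)
  if (th$empty) abort(sprintf("No edges survive the threshold s_t = %.3f.", s_t))
  g <- igraph::graph_from_adjacency_matrix(th$a, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  sg <- sim$sign[cbind(match(el[, 1], sim$otu_ids), match(el[, 2], sim$otu_ids))]
  igraph::E(g)$sign <- sg
  igraph::graph_attr(g, "s_t") <- s_t
  g
}

#' Newman modularity of a partition
#'
#' `Q = sum_m (e_mm - a_m^2)` where `e_mm` is the fraction of edges with
#' both ends in module m and `a_m` the fraction of edge endpoints in m.
#' Computed on the unweighted edge set: every edge already passed the
#' stringent similarity threshold, and weights compressed just above the
#' cutoff add little signal.
#'
#' @param net An igraph network.
#' @param membership Named vector (by node name) or vector in vertex order
#'   assigning each node to a module, or a `module_partition`.
#' @param weighted Use edge weights in Q (default FALSE).
#' @return Modularity Q in \[-0.5, 1\].
#' @export
modularity_q <- function(net, membership, weighted = FALSE) {
  mem <- partition_membership(net, membership)
  el <- igraph::as_edgelist(net, names = TRUE)
  w <- if (weighted) igraph::E(net)$weight else rep(1, nrow(el))
  m1 <- mem[el[, 1]]
  m2 <- mem[el[, 2]]
  tot <- sum(w)
  mods <- unique(mem)
  e_mm <- vapply(mods, function(m) sum(w[m1 == m & m2 == m]) / tot, numeric(1))
  a_m <- vapply(mods, function(m) (sum(w[m1 == m]) + sum(w[m2 == m])) / (2 * tot),
                numeric(1))
  sum(e_mm - a_m^2)
}

partition_membership <- function(net, membership) {
  if (inherits(membership, "module_partition")) {
    membership <- setNames(membership$membership$module,
                           membership$membership$otu_id)
  }
  nodes <- igraph::V(net)$name
  if (is.null(names(membership))) {
    if (length(membership) != length(nodes)) {
      abort("Unnamed membership must have one entry per vertex.")
    }
    names(membership) <- nodes
  }
  missing <- setdiff(nodes, names(membership))
  if (length(missing)) {
    abort(paste0("Node(s) missing from the partition: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  membership[nodes]
}

#' Separate modules by fast-greedy modularity optimization
#'
#' Agglomerative greedy merging in the Clauset-Newman-Moore scheme:
#' starting from singleton communities, the pair whose merge most increases
#' modularity is merged repeatedly, and the partition at the maximum Q
#' along the merge path is returned. Modularity is evaluated on the
#' unweighted edge set (see [modularity_q()]). Module ids are relabelled in
#' decreasing size order (ties broken by the smallest member id) so module
#' labels M01, M02, ... are stable across runs; the procedure is fully
#' deterministic.
#'
#' @param net An igraph network from [build_network()].
#' @param weighted Optimize weighted modularity instead (default FALSE).
#' @return An object of class `module_partition`: list with `membership`
#'   (tibble: otu_id, module, module_label, module_size), `Q`,
#'   `n_modules`, `method`.
#' @export
fast_greedy_modules <- function(net, weighted = FALSE) {
  if (igraph::ecount(net) == 0) abort("Network has no edges.")
  wt <- if (weighted) igraph::E(net)$weight else NA
  cl <- igraph::cluster_fast_greedy(net, weights = wt)
  nodes <- igraph::V(net)$name

  # pick the cut along the merge path that maximizes Q under our own
  # modularity evaluation; ties go to the coarser partition
  best_q <- -Inf
  mem <- igraph::membership(cl)
  for (k in seq_len(igraph::vcount(net))) {
    cand <- tryCatch(suppressWarnings(igraph::cut_at(cl, no = k)),
                     error = function(e) NULL)
    if (is.null(cand) || length(cand) != length(nodes) || anyNA(cand)) next
    q <- modularity_q(net, setNames(cand, nodes), weighted = weighted)
    if (q > best_q + 1e-12) { best_q <- q; mem <- cand; names(mem) <- nodes }
  }

  # relabel by decreasing size, ties by smallest member id
  sizes <- table(mem)
  first_member <- vapply(names(sizes),
                         function(m) min(nodes[mem == as.integer(m)]),
                         character(1))
  ord <- order(-as.integer(sizes), first_member)
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  new_mem <- relabel[as.character(mem)]

  membership <- tibble(
    otu_id = nodes,
    module = as.integer(new_mem),
    module_label = sprintf("M%02d", as.integer(new_mem))
  )
  membership <- dplyr::add_count(membership, .data$module, name = "module_size")
  q <- modularity_q(net, setNames(membership$module, membership$otu_id),
                    weighted = weighted)
  structure(list(membership = membership, Q = q,
                 n_modules = length(unique(new_mem)),
                 method = if (weighted) "fast_greedy (weighted Q)"
                          else "fast_greedy (unweighted Q)"),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d nodes in %d modules, Q = %.3f (%s)\n",
              nrow(x$membership), x$n_modules, x$Q, x$method))
  invisible(x)
}

#' @export
tidy.module_partition <- function(x, ...) x$membership

#' @export
glance.module_partition <- function(x, ...) {
  tibble(n_nodes = nrow(x$membership), n_modules = x$n_modules,
         Q = x$Q, method = x$method)
}

#' Global topology statistics
#'
#' Counts, mean degree, and module-size summaries of a network under a
#' partition, including the number of modules at the size floors reported
#' for co-occurrence networks (>= 2 members, >= 6 members).
#'
#' @param net An igraph network.
#' @param partition A `module_partition` (or membership vector).
#' @return A one-row tibble: `n_nodes`, `n_edges`, `mean_degree`,
#'   `n_modules`, `mean_nodes_per_module`, `Q`, `n_modules_ge2`,
#'   `n_modules_ge6`.
#' @export
global_topology <- function(net, partition) {
  mem <- partition_membership(net, partition)
  sizes <- as.integer(table(mem))
  nn <- igraph::vcount(net)
  ne <- igraph::ecount(net)
  q <- if (inherits(partition, "module_partition")) partition$Q
       else modularity_q(net, mem)
  tibble(n_nodes = nn, n_edges = ne, mean_degree = 2 * ne / nn,
         n_modules = length(sizes),
         mean_nodes_per_module = nn / length(sizes),
         Q = q,
         n_modules_ge2 = sum(sizes >= 2),
         n_modules_ge6 = sum(sizes >= 6))
}
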