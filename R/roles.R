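#' Within-module degree z-score and participation coefficient
#'
#' For node i in module m, `Zi = (k_i,within - mean_m) / sd_m` where
#' `mean_m` and `sd_m` are the mean and population standard deviation of
#' within-module degree over m (the Guimera-Amaral z-score the Olesen role
#' scheme inherits); modules with `sd_m = 0` give Zi = 0 by convention.
#' `Pi = 1 - sum_t (k_it / k_i)^2` over modules t, where `k_it` counts
#' links from i into module t; Pi = 0 exactly when all links stay inside
#' the node's own module. Degrees are unweighted, consistent with the
#' unweighted modularity.
#'
#' Roles follow the Olesen quadrants of the Zi-Pi plane: module hubs have
#' `Zi > z_cut` and `Pi <= p_cut`; connectors `Zi <= z_cut` and
#' `Pi > p_cut`; network hubs exceed both cuts; everything else is
#' peripheral. Both boundaries are non-strict on the peripheral side.
#'
#' @param net An igraph network from [build_network()].
#' @param partition A `module_partition` (or membership vector).
#' @param z_cut Within-module degree cut (default 2.5).
#' @param p_cut Participation coefficient cut (default 0.62).
#' @return A tibble: `otu_id`, `module`, `module_label`, `k`, `k_within`,
#'   `zi`, `pi`, `role`.
#' @export
node_roles <- function(net, partition, z_cut = 2.5, p_cut = 0.62) {
  mem <- partition_membership(net, partition)
  nodes <- igraph::V(net)$name
  el <- igraph::as_edgelist(net, names = TRUE)

  # k_it: links from node i into module t, from both edge orientations
  ends_long <- tibble(
    node = c(el[, 1], el[, 2]),
    other_module = c(mem[el[, 2]], mem[el[, 1]])
  )
  k_all <- dplyr::count(ends_long, .data$node, name = "k")
  k_it <- dplyr::count(ends_long, .data$node, .data$other_module, name = "k_t")

  own <- tibble(node = nodes, module = unname(mem[nodes]))
  k_within <- dplyr::left_join(k_it, own, by = "node") |>
    dplyr::filter(.data$other_module == .data$module) |>
    dplyr::select("node", k_within = "k_t")

  pi_tbl <- dplyr::left_join(k_it, k_all, by = "node") |>
    dplyr::summarise(pi = 1 - sum((.data$k_t / .data$k)^2),
                     .by = "node")

  out <- own |>
    dplyr::left_join(k_all, by = "node") |>
    dplyr::left_join(k_within, by = "node") |>
    dplyr::left_join(pi_tbl, by = "node") |>
    dplyr::mutate(k = dplyr::coalesce(.data$k, 0L),
                  k_within = dplyr::coalesce(.data$k_within, 0L),
                  pi = dplyr::coalesce(.data$pi, 0))

  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- out |>
    dplyr::mutate(
      zi = {
        s <- pop_sd(.data$k_within)
        if (s == 0) rep(0, dplyr::n()) else (.data$k_within - mean(.data$k_within)) / s
      },
      .by = "module"
    ) |>
    dplyr::mutate(
      module_label = sprintf("M%02d", .data$module),
      role = classify_roles(.data$zi, .data$pi, z_cut = z_cut, p_cut = p_cut)
    ) |>
    dplyr::select(otu_id = "node", "module", "module_label",
                  "k", "k_within", "zi", "pi", "role")
  out
}

#' Classify Olesen topological roles from Zi and Pi
#'
#' @param zi Within-module degree z-scores.
#' @param pi Participation coefficients.
#' @param z_cut,p_cut Role thresholds (defaults 2.5 and 0.62).
#' @return A character vector in `{"peripheral", "connector",
#'   "module_hub", "network_hub"}`.
#' @export
classify_roles <- function(zi, pi, z_cut = 2.5, p_cut = 0.62) {
  stopifnot(length(zi) == length(pi))
  dplyr::case_when(
    zi > z_cut & pi > p_cut ~ "network_hub",
    zi > z_cut ~ "module_hub",
    pi > p_cut ~ "connector",
    .default = "peripheral"
  )
}

#' Zi-Pi scatter of node topological roles
#'
#' @param roles Tibble from [node_roles()].
#' @param z_cut,p_cut Thresholds drawn as quadrant lines.
#' @return A ggplot object.
#' @export
plot_zipi <- function(roles, z_cut = 2.5, p_cut = 0.62) {
  ggplot2::ggplot(roles, ggplot2::aes(x = .data$pi, y = .data$zi,
                                      colour = .data$role)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = z_cut, linetype = 2) +
    ggplot2::geom_vline(xintercept = p_cut, linetype = 2) +
    ggplot2::labs(x = "among-module connectivity (Pi)",
                  y = "within-module degree (Zi)",
                  colour = "role") +
    ggplot2::theme_minimal()
}

#' Write the Zi-Pi role table as TSV
#'
#' @param roles Tibble from [node_roles()].
#' @param path Output path.
#' @export
write_role_table <- function(roles, path) {
  write.table(roles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
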