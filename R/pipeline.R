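#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis with documented
#' defaults; the configuration is echoed verbatim into the run manifest so
#' a run is reproducible from its manifest alone.
#'
#' @param otu Path to an OTU TSV (see [read_otu_table()]) or an
#'   [otu_table()].
#' @param traits Path to a trait TSV (see [read_trait_table()]) or a trait
#'   tibble; optional.
#' @param out_dir Output directory (created if needed).
#' @param transform Abundance transform (default `"log10_relative"`).
#' @param min_prevalence Prevalence filter fraction (default 0.5).
#' @param grid,alpha,min_nodes,run_length Threshold scan settings (see
#'   [detect_rmt_threshold()]).
#' @param threshold Optional fixed cutoff overriding the scan.
#' @param z_cut,p_cut Role thresholds (defaults 2.5, 0.62).
#' @param min_module_size Eigengene module-size floor (default 6).
#' @param taxon_min_members Minimum network members for a taxon Mantel
#'   test (default 4).
#' @param n_perm Mantel permutations (default 999).
#' @param seed Integer seed for permutation procedures (default 1).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(otu, traits = NULL, out_dir,
                            transform = "log10_relative",
                            min_prevalence = 0.5,
                            grid = seq(0.30, 0.99, by = 0.01),
                            alpha = 0.05, min_nodes = 50, run_length = 3,
                            threshold = NULL,
                            z_cut = 2.5, p_cut = 0.62,
                            min_module_size = 6,
                            taxon_min_members = 4,
                            n_perm = 999, seed = 1) {
  structure(list(otu = otu, traits = traits, out_dir = out_dir,
                 transform = transform, min_prevalence = min_prevalence,
                 grid = grid, alpha = alpha, min_nodes = min_nodes,
                 run_length = run_length, threshold = threshold,
                 z_cut = z_cut, p_cut = p_cut,
                 min_module_size = min_module_size,
                 taxon_min_members = taxon_min_members,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full co-occurrence network pipeline
#'
#' filter -> transform -> similarity -> RMT threshold -> network ->
#' fast-greedy modules -> Zi/Pi roles -> eigengene-trait correlations ->
#' taxon partial-Mantel tests, with every table written as TSV plus a
#' machine-readable JSON manifest.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`otu`, `abund`,
#'   `scan`, `network`, `partition`, `topology`, `roles`, `eigengenes`,
#'   `module_trait`, `taxon_mantel`, `manifest`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
    inform(sprintf("[%s] done in %.2fs", name,
                   proc.time()[["elapsed"]] - t0))
    res
  }

  ot <- stage("read", {
    if (inherits(cfg$otu, "otu_table")) cfg$otu else read_otu_table(cfg$otu)
  })
  traits <- NULL
  if (!is.null(cfg$traits)) {
    traits <- if (is.data.frame(cfg$traits)) cfg$traits
              else read_trait_table(cfg$traits)
  }
  ot_f <- stage("prevalence_filter", prevalence_filter(ot, cfg$min_prevalence))
  ab <- stage("transform", transform_abundance(ot_f, cfg$transform))
  sim <- stage("similarity", pearson_similarity(ab))

  scan <- NULL
  if (is.null(cfg$threshold)) {
    scan <- stage("rmt_threshold",
                  detect_rmt_threshold(sim, grid = cfg$grid,
                                       alpha = cfg$alpha,
                                       min_nodes = cfg$min_nodes,
                                       run_length = cfg$run_length))
    s_t <- scan$threshold
    write_scan_report(scan, file.path(cfg$out_dir, "scan_report.tsv"))
  } else {
    s_t <- cfg$threshold
  }

  net <- stage("network", build_network(sim, s_t))
  part <- stage("modules", fast_greedy_modules(net))
  topo <- global_topology(net, part)
  roles <- stage("roles", node_roles(net, part, cfg$z_cut, cfg$p_cut))

  export_network(net, roles = roles, partition = part,
                 format = "edge-tsv",
                 path = file.path(cfg$out_dir, "edges.tsv"))
  write.table(part$membership, file.path(cfg$out_dir, "modules.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_role_table(roles, file.path(cfg$out_dir, "node_roles.tsv"))

  mt <- NULL; tm <- NULL; egs <- NULL
  if (!is.null(traits)) {
    egs <- stage("eigengenes",
                 module_eigengenes(ab, part, min_size = cfg$min_module_size))
    if (length(egs)) {
      mt <- stage("module_trait", module_trait_table(egs, traits))
      write.table(mt, file.path(cfg$out_dir, "module_trait.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(ot$taxonomy)) {
      tm <- stage("taxon_mantel",
                  taxon_mantel_screen(net, ab, traits, ot$taxonomy,
                                      min_members = cfg$taxon_min_members,
                                      n_perm = cfg$n_perm, seed = cfg$seed))
      write.table(tm, file.path(cfg$out_dir, "taxon_mantel.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("rmtnet")),
    config = cfg[setdiff(names(cfg), c("otu", "traits"))],
    input = list(n_otus = n_otus(ot), n_samples = n_samples(ot),
                 n_otus_after_filter = n_otus(ot_f)),
    threshold = s_t,
    threshold_rule = if (!is.null(scan)) scan$rule else "user override",
    topology = as.list(topo),
    seed = cfg$seed
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(otu = ot_f, abund = ab, scan = scan, network = net,
                 partition = part, topology = topo, roles = roles,
                 eigengenes = egs, module_trait = mt, taxon_mantel = tm,
                 manifest = manifest))
}

#' Screen taxa for connectivity-trait association
#'
#' Runs [taxon_connectivity_mantel()] for every lineage component with
#' enough network members, against every usable trait.
#'
#' @param net An igraph network.
#' @param abund An `abundance_matrix` covering the network OTUs.
#' @param traits Trait tibble with `sample_id`.
#' @param taxonomy Named lineage strings by OTU id.
#' @param min_members,n_perm,seed See [taxon_connectivity_mantel()].
#' @return A tibble: `taxon`, `trait`, `r`, `p`, `n_members`, `partial`.
#' @export
taxon_mantel_screen <- function(net, abund, traits, taxonomy,
                                min_members = 4, n_perm = 999, seed = 1) {
  nodes <- igraph::V(net)$name
  tax_net <- taxonomy[intersect(nodes, names(taxonomy))]
  comps <- unlist(lapply(tax_net, function(lin) {
    trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
  }))
  counts <- table(comps)
  cands <- setdiff(names(counts)[counts >= min_members], c("Bacteria", ""))
  gs <- otu_significance(abund, traits)
  trait_names <- unique(gs$trait)
  rows <- list()
  for (tx in cands) {
    for (tr in trait_names) {
      res <- tryCatch(
        taxon_connectivity_mantel(net, gs, taxonomy, tx, tr,
                                  n_perm = n_perm, seed = seed,
                                  min_members = min_members),
        rmtnet_too_few_taxon_members = function(e) NULL,
        error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1]] <- tibble(taxon = tx, trait = tr,
                                         r = res$r, p = res$p,
                                         n_members = res$n,
                                         partial = res$partial)
    }
  }
  dplyr::bind_rows(rows)
}

#' Export a network for external viewers
#'
#' GraphML carries node attributes (module, Zi, Pi, role, taxonomy) and
#' edge attributes (weight; sign as "+"/"-", the usual solid/dashed
#' positive/negative co-occurrence annotation); SIF uses interaction type
#' "pp"; edge-TSV is a headered table that round-trips through
#' [read_edge_tsv()].
#'
#' @param net An igraph network from [build_network()].
#' @param roles Optional tibble from [node_roles()].
#' @param partition Optional `module_partition`.
#' @param taxonomy Optional named lineage strings.
#' @param format `"graphml"`, `"sif"`, or `"edge-tsv"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, roles = NULL, partition = NULL,
                           taxonomy = NULL,
                           format = c("graphml", "sif", "edge-tsv"),
                           path) {
  if (!is.character(format) || !all(format %in% c("graphml", "sif", "edge-tsv"))) {
    abort("Unknown format; options are 'graphml', 'sif', 'edge-tsv'.")
  }
  format <- match.arg(format)
  g <- net
  nodes <- igraph::V(g)$name
  if (!is.null(partition)) {
    mem <- partition_membership(g, partition)
    igraph::V(g)$module <- as.integer(mem[nodes])
  }
  if (!is.null(roles)) {
    idx <- match(nodes, roles$otu_id)
    igraph::V(g)$zi <- roles$zi[idx]
    igraph::V(g)$pi <- roles$pi[idx]
    igraph::V(g)$role <- roles$role[idx]
  }
  if (!is.null(taxonomy)) {
    igraph::V(g)$taxonomy <- unname(taxonomy[nodes])
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  sign_chr <- ifelse(igraph::E(g)$sign >= 0, "+", "-")
  if (format == "graphml") {
    igraph::E(g)$sign <- sign_chr
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    writeLines(paste(el[, 1], "pp", el[, 2], sep = "\t"), path)
  } else {
    df <- data.frame(from = el[, 1], to = el[, 2],
                     weight = igraph::E(g)$weight, sign = sign_chr,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Rebuild a network from an exported edge TSV
#'
#' @param path Path written by [export_network()] with `format =
#'   "edge-tsv"`.
#' @return An undirected igraph graph with `weight` and `sign` edge
#'   attributes.
#' @export
read_edge_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df[, c("from", "to")], directed = FALSE)
  igraph::E(g)$weight <- df$weight
  igraph::E(g)$sign <- ifelse(df$sign == "+", 1, -1)
  g
}
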