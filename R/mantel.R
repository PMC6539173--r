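#' Mantel test between two distance matrices
#'
#' The Mantel statistic is the Pearson correlation of the off-diagonal
#' upper triangles; significance comes from a one-sided permutation test in
#' which the rows and columns of the second matrix are permuted
#' simultaneously, with `p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`.
#'
#' @param d1,d2 Symmetric distance/dissimilarity matrices (or `dist`
#'   objects) over the same objects.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for reproducible permutations.
#' @return An object of class `mantel_result`: list with `r`, `p`,
#'   `n_perm`, `n` (objects), `partial`, `control`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  m1 <- as_dist_matrix(d1)
  m2 <- as_dist_matrix(d2)
  check_aligned(m1, m2)
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  if (sd(v1) == 0 || sd(m2[ut]) == 0) {
    abort("Constant distance matrix: Mantel correlation undefined.")
  }
  if (!is.null(seed)) set.seed(seed)
  r_obs <- cor(v1, m2[ut])
  n <- nrow(m1)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    pp <- sample.int(n)
    cor(v1, m2[pp, pp][ut])
  }, numeric(1))
  p <- (1 + sum(r_perm >= r_obs, na.rm = TRUE)) / (n_perm + 1)
  new_mantel(r = r_obs, p = p, n_perm = n_perm, n = n,
             partial = FALSE, control = NA_character_)
}

#' Partial Mantel test controlling for a third matrix
#'
#' Correlates the residuals of `d1 ~ d3` and `d2 ~ d3` (over the upper
#' triangles); the permutation scheme permutes the rows/columns of `d2`,
#' re-residualizes against `d3`, and compares to the observed partial
#' correlation one-sidedly.
#'
#' @inheritParams mantel_test
#' @param d3 Control distance matrix, aligned with `d1` and `d2`.
#' @param control_tag Description of the controlled matrix recorded in the
#'   result (default "d3").
#' @return A `mantel_result` with `partial = TRUE`.
#' @export
partial_mantel <- function(d1, d2, d3, n_perm = 999, seed = NULL,
                           control_tag = "d3") {
  m1 <- as_dist_matrix(d1)
  m2 <- as_dist_matrix(d2)
  m3 <- as_dist_matrix(d3)
  check_aligned(m1, m2)
  check_aligned(m1, m3)
  ut <- upper.tri(m1)
  v1 <- m1[ut]; v3 <- m3[ut]
  if (sd(v1) == 0 || sd(m2[ut]) == 0) {
    abort("Constant distance matrix: Mantel correlation undefined.")
  }
  resid_on <- function(v, z) {
    if (sd(z) == 0) return(v - mean(v))
    stats::residuals(stats::lm.fit(cbind(1, z), v))
  }
  r1 <- resid_on(v1, v3)
  r2 <- resid_on(m2[ut], v3)
  if (sd(r1) < 1e-12 || sd(r2) < 1e-12) {
    # a matrix explained entirely by the control carries no partial signal
    return(new_mantel(r = 0, p = 1, n_perm = n_perm, n = nrow(m1),
                      partial = TRUE, control = control_tag))
  }
  r_obs <- cor(r1, r2)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(m1)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    pp <- sample.int(n)
    cor(r1, resid_on(m2[pp, pp][ut], v3))
  }, numeric(1))
  p <- (1 + sum(r_perm >= r_obs, na.rm = TRUE)) / (n_perm + 1)
  new_mantel(r = r_obs, p = p, n_perm = n_perm, n = n,
             partial = TRUE, control = control_tag)
}

new_mantel <- function(r, p, n_perm, n, partial, control) {
  structure(list(r = r, p = p, n_perm = n_perm, n = n,
                 partial = partial, control = control),
            class = "mantel_result")
}

as_dist_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d)) abort("Expected a distance matrix or dist.")
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    abort("Distance matrix must be symmetric.")
  }
  d
}

check_aligned <- function(a, b) {
  if (nrow(a) != nrow(b)) abort("Distance matrices have different sizes.")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    abort(paste0("Distance matrices are not id-aligned; mismatches: ",
                 paste(head(setdiff(rownames(a), rownames(b)), 5),
                       collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<%s> r = %.4f, p = %.4g (%d permutations, n = %d%s)\n",
              if (x$partial) "partial Mantel" else "Mantel",
              x$r, x$p, x$n_perm, x$n,
              if (x$partial) paste0(", controlling ", x$control) else ""))
  invisible(x)
}

#' @export
tidy.mantel_result <- function(x, ...) {
  tibble(r = x$r, p = x$p, n_perm = x$n_perm, n = x$n,
         partial = x$partial, control = x$control)
}

#' @export
glance.mantel_result <- tidy.mantel_result

#' Node-connectivity vs trait-significance partial Mantel within a taxon
#'
#' Restricts to the network OTUs annotated to a taxon and asks whether
#' nodes of similar connectivity also have similar trait association,
#' controlling for the remaining traits: D1 = |k_i - k_j| on unweighted
#' degree, D2 = |GS_i - GS_j| for the focal trait, D3 = Euclidean distance
#' over the GS of the other traits, combined by [partial_mantel()] (simple
#' [mantel_test()] when no other trait is available).
#'
#' @param net An igraph network from [build_network()].
#' @param gs Tibble from [otu_significance()] (columns otu_id, trait, gs).
#' @param taxonomy Named character vector of lineage strings by OTU id
#'   (semicolon-separated ranks).
#' @param taxon Taxon name matched against the lineage components.
#' @param trait Focal trait name.
#' @param n_perm,seed Permutation settings (defaults 999, NULL).
#' @param min_members Minimum taxon members in the network (default 4);
#'   fewer raises a condition of class `rmtnet_too_few_taxon_members`.
#' @return A `mantel_result`.
#' @export
taxon_connectivity_mantel <- function(net, gs, taxonomy, taxon, trait,
                                      n_perm = 999, seed = NULL,
                                      min_members = 4) {
  nodes <- igraph::V(net)$name
  in_taxon <- vapply(taxonomy, function(lin) {
    taxon %in% trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
  }, logical(1))
  members <- intersect(nodes, names(taxonomy)[in_taxon])
  if (length(members) < min_members) {
    abort(sprintf("Taxon '%s' has %d network member(s) (< %d); skipped.",
                  taxon, length(members), min_members),
          class = "rmtnet_too_few_taxon_members",
          taxon = taxon, n_members = length(members))
  }
  deg <- igraph::degree(net)[members]
  gs_tax <- dplyr::filter(gs, .data$otu_id %in% members)
  focal <- dplyr::filter(gs_tax, .data$trait == !!trait)
  if (!nrow(focal)) abort(sprintf("Trait '%s' not present in `gs`.", trait))
  focal_v <- setNames(focal$gs, focal$otu_id)[members]
  d1 <- abs(outer(unname(deg), unname(deg), "-"))
  d2 <- abs(outer(unname(focal_v), unname(focal_v), "-"))
  dimnames(d1) <- dimnames(d2) <- list(members, members)
  others <- dplyr::filter(gs_tax, .data$trait != !!trait)
  if (nrow(others)) {
    wide <- tidyr::pivot_wider(others, id_cols = "otu_id",
                               names_from = "trait", values_from = "gs")
    gm <- as.matrix(wide[, -1, drop = FALSE])
    rownames(gm) <- wide$otu_id
    gm <- gm[members, , drop = FALSE]
    d3 <- as.matrix(stats::dist(gm))
    partial_mantel(d1, d2, d3, n_perm = n_perm, seed = seed,
                   control_tag = "GS of remaining traits")
  } else {
    mantel_test(d1, d2, n_perm = n_perm, seed = seed)
  }
}
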