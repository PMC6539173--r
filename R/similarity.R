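#' Pearson similarity matrix between OTU abundance profiles
#'
#' The similarity between two OTUs is the absolute Pearson correlation of
#' their abundance profiles across samples; the sign of the correlation is
#' retained separately for edge annotation (positive vs negative
#' co-occurrence). OTUs with zero variance across samples have undefined
#' correlations; their similarities are set to 0 with a warning rather than
#' dropped silently.
#'
#' @param abund An `abundance_matrix` from [transform_abundance()], an
#'   [otu_table()] (used as-is), or a plain numeric matrix (OTUs x samples).
#' @return An object of class `similarity_matrix`: list with `s` (symmetric
#'   matrix of |r|, zero diagonal), `sign` (matrix in -1/0/+1), `otu_ids`.
#' @export
pearson_similarity <- function(abund) {
  v <- abundance_values(abund)
  if (ncol(v) < 3) abort("Pearson similarity needs at least 3 samples.")
  if (is.null(rownames(v))) rownames(v) <- paste0("OTU_", seq_len(nrow(v)))
  zero_var <- apply(v, 1, function(x) stats::var(x) == 0)
  r <- suppressWarnings(cor(t(v)))
  if (any(zero_var)) {
    warn(paste0("Zero-variance OTU profile(s), similarity set to 0: ",
                paste(head(rownames(v)[zero_var], 5), collapse = ", "),
                if (sum(zero_var) > 5) ", ..." else ""))
    r[zero_var, ] <- 0
    r[, zero_var] <- 0
  }
  s <- abs(r)
  sg <- sign(r)
  diag(s) <- 0
  diag(sg) <- 0
  structure(list(s = s, sign = sg, otu_ids = rownames(v)),
            class = "similarity_matrix")
}

abundance_values <- function(abund) {
  if (inherits(abund, "abundance_matrix")) return(abund$values)
  if (inherits(abund, "otu_table")) return(abund$values)
  if (is.matrix(abund) && is.numeric(abund)) return(abund)
  abort("Expected an abundance_matrix, otu_table, or numeric matrix.")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d OTUs\n", length(x$otu_ids)))
  invisible(x)
}

#' Threshold a similarity matrix
#'
#' Entries below the cutoff `s_t` are zeroed and OTUs left with no
#' surviving link are removed. An empty result is a signal (an object with
#' `empty = TRUE`), not an error, so that threshold scans can pass through
#' it.
#'
#' @param sim A `similarity_matrix`.
#' @param s_t Cutoff in (0, 1).
#' @return A list of class `thresholded_matrix`: `a` (weighted adjacency
#'   among retained OTUs, zero diagonal), `otu_ids`, `n_nodes`, `n_edges`,
#'   `s_t`, `empty`.
#' @export
threshold_matrix <- function(sim, s_t) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (!is.numeric(s_t) || length(s_t) != 1 || s_t <= 0 || s_t >= 1) {
    abort("`s_t` must be a single value in (0, 1).")
  }
  a <- sim$s
  a[a < s_t] <- 0
  diag(a) <- 0
  keep <- rowSums(a > 0) > 0
  a <- a[keep, keep, drop = FALSE]
  n_edges <- sum(a[upper.tri(a)] > 0)
  structure(list(a = a, otu_ids = sim$otu_ids[keep],
                 n_nodes = sum(keep), n_edges = n_edges,
                 s_t = s_t, empty = n_edges == 0),
            class = "thresholded_matrix")
}
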