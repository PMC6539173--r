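#' Module eigengene
#'
#' The eigengene summarizes a module's abundance behaviour across samples
#' in one vector: each member OTU profile is standardized to zero mean and
#' unit SD across samples, and the eigengene is the first principal
#' component's sample scores of the member x sample matrix, re-standardized
#' to zero mean and unit population SD. The PC sign is arbitrary, so the
#' orientation is anchored to have non-negative correlation with the mean
#' standardized member profile.
#'
#' @param abund An `abundance_matrix` (or `otu_table`/matrix) covering the
#'   module members.
#' @param partition A `module_partition` (or named membership vector).
#' @param module Module id (integer) to summarize.
#' @param min_size Minimum module size (default 6, the floor commonly used
#'   when relating modules to traits); smaller modules raise an error of
#'   class `rmtnet_module_too_small`.
#' @return An object of class `module_eigengene`: list with `module`,
#'   `scores` (named by sample), `variance_explained`, `n_members`.
#' @export
module_eigengene <- function(abund, partition, module, min_size = 6) {
  v <- abundance_values(abund)
  mem <- if (inherits(partition, "module_partition")) {
    setNames(partition$membership$module, partition$membership$otu_id)
  } else partition
  members <- names(mem)[mem == module]
  members <- intersect(members, rownames(v))
  if (length(members) < min_size) {
    abort(sprintf("Module %s has %d members (< min_size = %d); skipped.",
                  as.character(module), length(members), min_size),
          class = "rmtnet_module_too_small",
          module = module, size = length(members))
  }
  x <- v[members, , drop = FALSE]
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    warn(paste0("Dropping zero-variance member(s): ",
                paste(members[sds == 0], collapse = ", ")))
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) < min_size) {
      abort(sprintf("Module %s falls below min_size after dropping flat members.",
                    as.character(module)),
            class = "rmtnet_module_too_small", module = module, size = nrow(x))
    }
  }
  xs <- t(scale(t(x)))
  sv <- svd(xs)
  scores <- sv$v[, 1]
  mean_profile <- colMeans(xs)
  if (cor(scores, mean_profile) < 0) scores <- -scores
  scores <- (scores - mean(scores)) / sqrt(mean((scores - mean(scores))^2))
  structure(list(module = module,
                 scores = setNames(scores, colnames(v)),
                 variance_explained = sv$d[1]^2 / sum(sv$d^2),
                 n_members = nrow(xs)),
            class = "module_eigengene")
}

#' @export
print.module_eigengene <- function(x, ...) {
  cat(sprintf("<module_eigengene> module %s: %d members, %.1f%% variance\n",
              as.character(x$module), x$n_members,
              100 * x$variance_explained))
  invisible(x)
}

#' @export
tidy.module_eigengene <- function(x, ...) {
  tibble(sample_id = names(x$scores), score = unname(x$scores))
}

#' All module eigengenes of sufficient size
#'
#' @inheritParams module_eigengene
#' @return A named list of `module_eigengene` objects (modules smaller than
#'   `min_size` are skipped with a message).
#' @export
module_eigengenes <- function(abund, partition, min_size = 6) {
  mem <- if (inherits(partition, "module_partition")) {
    setNames(partition$membership$module, partition$membership$otu_id)
  } else partition
  mods <- sort(unique(mem))
  out <- list()
  skipped <- integer(0)
  for (m in mods) {
    eg <- tryCatch(module_eigengene(abund, mem, m, min_size = min_size),
                   rmtnet_module_too_small = function(e) NULL)
    if (is.null(eg)) skipped <- c(skipped, m) else out[[sprintf("M%02d", m)]] <- eg
  }
  if (length(skipped)) {
    inform(sprintf("Skipped %d module(s) below min_size = %d.",
                   length(skipped), min_size))
  }
  out
}

#' Pearson correlation with a two-sided t-test
#'
#' Missing values are removed pairwise; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom. For
#' |r| = 1 the p-value is reported at the numerical floor rather than 0.
#'
#' @param x,y Sample-aligned numeric vectors.
#' @return A one-row tibble: `r`, `p`, `n`.
#' @export
correlate <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 4) abort("Need >= 4 paired non-missing values.")
  r <- cor(x[ok], y[ok])
  if (abs(r) >= 1 - 1e-15) {
    p <- .Machine$double.xmin
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- max(2 * pt(-abs(tstat), df = n - 2), .Machine$double.xmin)
  }
  tibble(r = r, p = p, n = n)
}

#' Module-trait correlation table
#'
#' One row per (module eigengene, trait) pair with Pearson r, raw two-sided
#' p (no multiple-testing adjustment, matching the customary presentation;
#' set `adjust = TRUE` for Benjamini-Hochberg columns), and sample count.
#'
#' @param eigengenes A named list from [module_eigengenes()] (or a single
#'   `module_eigengene`).
#' @param traits Trait tibble with `sample_id` column (see
#'   [read_trait_table()]).
#' @param adjust Add a BH-adjusted `p_adj` column (default FALSE).
#' @return A tibble: `module`, `module_label`, `trait`, `r`, `p`, `n`,
#'   `module_size` (and `p_adj` when requested).
#' @export
module_trait_table <- function(eigengenes, traits, adjust = FALSE) {
  if (inherits(eigengenes, "module_eigengene")) eigengenes <- list(eigengenes)
  if (!length(eigengenes)) abort("No eigengenes supplied.")
  if (!"sample_id" %in% names(traits)) {
    abort("`traits` must contain a sample_id column.")
  }
  trait_names <- setdiff(names(traits), "sample_id")
  usable <- attr(traits, "usable")
  if (!is.null(usable)) trait_names <- trait_names[usable[trait_names]]
  rows <- list()
  for (eg in eigengenes) {
    miss <- setdiff(names(eg$scores), traits$sample_id)
    if (length(miss)) {
      abort(paste0("Sample(s) absent from the trait table: ",
                   paste(miss, collapse = ", ")))
    }
    tt <- traits[match(names(eg$scores), traits$sample_id), ]
    for (tr in trait_names) {
      cres <- correlate(eg$scores, tt[[tr]])
      rows[[length(rows) + 1]] <- tibble(
        module = eg$module, module_label = sprintf("M%02d", eg$module),
        trait = tr, r = cres$r, p = cres$p, n = cres$n,
        module_size = eg$n_members)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' OTU significance (GS) against traits
#'
#' GS is the squared Pearson correlation of each OTU abundance profile with
#' a trait, in \[0, 1\].
#'
#' @param abund An `abundance_matrix` (or `otu_table`/matrix).
#' @param traits Trait tibble with `sample_id` (all usable traits are
#'   scored), or a single named numeric vector.
#' @return A tibble: `otu_id`, `trait`, `r`, `gs`.
#' @export
otu_significance <- function(abund, traits) {
  v <- abundance_values(abund)
  if (is.numeric(traits)) {
    traits <- tibble(sample_id = names(traits), trait = unname(traits))
  }
  if (!"sample_id" %in% names(traits)) {
    abort("`traits` must contain a sample_id column.")
  }
  miss <- setdiff(colnames(v), traits$sample_id)
  if (length(miss)) {
    abort(paste0("Sample(s) absent from the trait table: ",
                 paste(miss, collapse = ", ")))
  }
  tt <- traits[match(colnames(v), traits$sample_id), ]
  trait_names <- setdiff(names(tt), "sample_id")
  usable <- attr(traits, "usable")
  if (!is.null(usable)) trait_names <- trait_names[usable[trait_names]]
  purrr::map(trait_names, function(tr) {
    y <- tt[[tr]]
    rr <- apply(v, 1, function(x) {
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 4 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
      cor(x[ok], y[ok])
    })
    tibble(otu_id = rownames(v), trait = tr, r = unname(rr),
           gs = unname(rr)^2)
  }) |> dplyr::bind_rows()
}

#' Heatmap of module-trait correlations
#'
#' @param mt Tibble from [module_trait_table()].
#' @return A ggplot object.
#' @export
plot_module_trait <- function(mt) {
  ggplot2::ggplot(mt, ggplot2::aes(x = .data$trait, y = .data$module_label,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(%.3g)", .data$r, .data$p)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}
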