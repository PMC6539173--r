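#' Configuration for the synthetic community generator
#'
#' Defaults emulate the study regime the pipeline targets: a small-sample
#' 16S experiment (8 samples, the size of a typical treatment group) with a
#' few tightly co-varying OTU modules (within-module correlation target
#' 0.9, the high-|r| regime in which automatically selected thresholds land
#' between 0.87 and 0.98), a background of unstructured OTUs, a couple of
#' connector OTUs loading on two module factors, and physiological traits
#' (BUN, CR, MDA, SOD) coupled to module latent factors.
#'
#' @param n_samples Number of samples (default 8).
#' @param module_sizes Integer sizes of the planted modules (default
#'   `c(22, 20, 18, 16)`).
#' @param within_cor Target pairwise within-module correlation in (0, 0.99]
#'   (default 0.9).
#' @param n_noise Number of unstructured OTUs (default 50).
#' @param n_connectors OTUs loading equally on two module factors
#'   (default 2).
#' @param trait_spec Named list mapping trait name to
#'   `list(module = id, cor = target)`; `module = 0` gives a pure-noise
#'   trait. Default couples BUN and CR to module 1 (0.9, 0.8), MDA to
#'   module 2 (0.7), and leaves SOD unstructured.
#' @param count_model `"lognormal_poisson"` (default) or
#'   `"negative_binomial"`.
#' @param dispersion NB size parameter is `1/dispersion` (default 0.5,
#'   used only by the NB model).
#' @param base_log_mean,base_log_sd Log-scale mean abundance distribution
#'   across OTUs (defaults 4.5, 1.5 — heavy-tailed, 16S-like).
#' @param seed Mandatory integer seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 8,
                             module_sizes = c(22, 20, 18, 16),
                             within_cor = 0.9,
                             n_noise = 50,
                             n_connectors = 2,
                             trait_spec = list(
                               BUN = list(module = 1, cor = 0.9),
                               CR  = list(module = 1, cor = 0.8),
                               MDA = list(module = 2, cor = 0.7),
                               SOD = list(module = 0, cor = 0)),
                             count_model = c("lognormal_poisson",
                                             "negative_binomial"),
                             dispersion = 0.5,
                             base_log_mean = 4.5, base_log_sd = 1.5,
                             seed) {
  if (missing(seed) || !is.numeric(seed)) abort("A numeric `seed` is mandatory.")
  count_model <- match.arg(count_model)
  if (any(module_sizes < 2)) abort("Module sizes must be >= 2.")
  if (within_cor <= 0 || within_cor > 0.99) {
    abort("`within_cor` must lie in (0, 0.99]; higher targets are infeasible.")
  }
  for (tr in trait_spec) {
    if (tr$module > length(module_sizes)) {
      abort("trait_spec refers to a module that does not exist.")
    }
    if (tr$module > 0 && (tr$cor <= 0 || tr$cor > 0.99)) {
      abort("Trait correlation targets must lie in (0, 0.99].")
    }
  }
  structure(list(n_samples = n_samples, module_sizes = module_sizes,
                 within_cor = within_cor, n_noise = n_noise,
                 n_connectors = n_connectors, trait_spec = trait_spec,
                 count_model = count_model, dispersion = dispersion,
                 base_log_mean = base_log_mean, base_log_sd = base_log_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate an OTU community with known network ground truth
#'
#' Per module, a latent factor over samples is drawn; factors are
#' orthogonalized in-sample so that, even with very few samples, "distinct"
#' modules really are uncorrelated in the realized data (independently
#' drawn factors correlate substantially by chance at n = 8). Member
#' log-abundances are `sqrt(rho) * f_m + sqrt(1 - rho) * e`, with the
#' member noise residualized against the own-module factor, which
#' calibrates pairwise within-module correlations to the target rho.
#' Connectors load equally on two factors. Counts are drawn from a
#' lognormal-Poisson (or negative binomial) model around a heavy-tailed
#' base abundance. Trait vectors are constructed with their in-sample
#' correlation to the coupled factor scaled exactly to the target.
#' Everything is deterministic given the config seed.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `otu` (an [otu_table()] with taxonomy) and `truth`:
#'   `partition` (tibble otu_id, module; 0 = noise, -1 = connector),
#'   `roles` (tibble otu_id, role), `factors` (modules x samples matrix),
#'   `traits` (tibble with sample_id and one column per trait).
#' @export
simulate_community <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  ns <- cfg$n_samples
  k <- length(cfg$module_sizes)
  rho <- cfg$within_cor

  # orthonormal in-sample factors, scaled to unit population SD
  F0 <- matrix(rnorm(ns * k), ns, k)
  F0 <- sweep(F0, 2, colMeans(F0))
  Fq <- qr.Q(qr(F0))
  Fq <- sweep(Fq, 2, colMeans(Fq))
  Fq <- apply(Fq, 2, function(f) f / sqrt(mean(f^2)))

  sample_ids <- sprintf("S%02d", seq_len(ns))
  profiles <- list(); otu_ids <- character(0)
  module_of <- integer(0); role_of <- character(0)

  member_profile <- function(f) {
    e <- rnorm(ns)
    e <- e - f * sum(e * f) / sum(f * f)
    e <- e - mean(e)
    e <- e / sqrt(mean(e^2))
    sqrt(rho) * f + sqrt(1 - rho) * e
  }
  for (m in seq_len(k)) {
    for (i in seq_len(cfg$module_sizes[m])) {
      otu_ids <- c(otu_ids, sprintf("OTU_M%d_%02d", m, i))
      profiles[[length(profiles) + 1]] <- member_profile(Fq[, m])
      module_of <- c(module_of, m)
      role_of <- c(role_of, "peripheral")
    }
  }
  if (cfg$n_connectors > 0 && k >= 2) {
    pairs <- utils::combn(k, 2)
    for (i in seq_len(cfg$n_connectors)) {
      pr <- pairs[, ((i - 1) %% ncol(pairs)) + 1]
      f <- (Fq[, pr[1]] + Fq[, pr[2]]) / sqrt(2)
      otu_ids <- c(otu_ids, sprintf("OTU_C%02d", i))
      profiles[[length(profiles) + 1]] <- member_profile(f)
      module_of <- c(module_of, -1L)
      role_of <- c(role_of, "connector")
    }
  }
  for (i in seq_len(cfg$n_noise)) {
    otu_ids <- c(otu_ids, sprintf("OTU_N%02d", i))
    profiles[[length(profiles) + 1]] <- rnorm(ns)
    module_of <- c(module_of, 0L)
    role_of <- c(role_of, "noise")
  }

  X <- do.call(rbind, profiles)
  mu <- rnorm(nrow(X), cfg$base_log_mean, cfg$base_log_sd)
  lam <- exp(mu + X)
  counts <- switch(cfg$count_model,
    lognormal_poisson = matrix(rpois(length(lam), lam), nrow(lam)),
    negative_binomial = matrix(rnbinom(length(lam), mu = lam,
                                       size = 1 / cfg$dispersion), nrow(lam)))
  dimnames(counts) <- list(otu_ids, sample_ids)

  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
             "Actinobacteria", "Deferribacteres")
  tax <- character(length(otu_ids))
  for (i in seq_along(otu_ids)) {
    m <- module_of[i]
    ph <- if (m > 0) phyla[((m - 1) %% length(phyla)) + 1]
          else phyla[(i %% length(phyla)) + 1]
    fam <- if (m > 0) sprintf("Family_M%d", m) else
           if (m == -1) "Family_connector" else
           sprintf("Family_N%d", (i %% 5) + 1)
    tax[i] <- sprintf("Bacteria; %s; Class_x; Order_x; %s; Genus_%s",
                      ph, fam, otu_ids[i])
  }
  names(tax) <- otu_ids

  # traits: exact in-sample correlation to the coupled factor
  traits <- tibble(sample_id = sample_ids)
  for (tn in names(cfg$trait_spec)) {
    spec <- cfg$trait_spec[[tn]]
    if (spec$module == 0) {
      traits[[tn]] <- rnorm(ns)
    } else {
      f <- Fq[, spec$module]
      e <- rnorm(ns)
      e <- e - f * sum(e * f) / sum(f * f)
      e <- e - mean(e)
      e <- e / sqrt(mean(e^2))
      traits[[tn]] <- spec$cor * f + sqrt(1 - spec$cor^2) * e
    }
  }

  truth <- list(
    partition = tibble(otu_id = otu_ids, module = module_of),
    roles = tibble(otu_id = otu_ids, role = role_of),
    factors = t(Fq),
    traits = traits
  )
  rownames(truth$factors) <- sprintf("F%d", seq_len(k))
  colnames(truth$factors) <- sample_ids
  list(otu = otu_table(counts, taxonomy = tax), truth = truth)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects:
#' 1 for identical partitions (up to label names), ~0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return The ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Score recovery of planted structure
#'
#' Compares an inferred module partition (and optionally inferred node
#' roles) against the generator's ground truth. The ARI is computed over
#' planted module members only (noise OTUs and connectors, which genuinely
#' belong to two modules, are excluded); OTUs absent from the inferred
#' partition count as an extra "unassigned" module.
#'
#' @param partition A `module_partition` (or tibble with otu_id, module).
#' @param truth The `truth` element from [simulate_community()].
#' @param roles Optional tibble from [node_roles()] for connector/hub
#'   recall.
#' @return A one-row tibble: `ari`, `n_structured`, `n_recovered`,
#'   `connector_recall` (NA without `roles`).
#' @export
score_recovery <- function(partition, truth, roles = NULL) {
  memb <- if (inherits(partition, "module_partition")) partition$membership
          else partition
  structured <- dplyr::filter(truth$partition, .data$module > 0)
  inferred <- setNames(memb$module, memb$otu_id)[structured$otu_id]
  inferred[is.na(inferred)] <- -99L   # unassigned pseudo-module
  ari <- adjusted_rand_index(structured$module, inferred)
  connector_recall <- NA_real_
  if (!is.null(roles)) {
    planted <- truth$roles$otu_id[truth$roles$role == "connector"]
    if (length(planted)) {
      found <- roles$otu_id[roles$role %in% c("connector", "network_hub",
                                              "module_hub")]
      connector_recall <- mean(planted %in% found)
    }
  }
  tibble(ari = ari, n_structured = nrow(structured),
         n_recovered = sum(inferred != -99L),
         connector_recall = connector_recall)
}
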