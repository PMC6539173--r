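#' Unfold an eigenvalue spectrum
#'
#' Spectral unfolding removes the global eigenvalue density so that the mean
#' local spacing is 1, leaving only the fluctuation statistics that
#' distinguish random-matrix ensembles. The empirical cumulative spectral
#' function (staircase at plotting positions (i - 1/2)/n) is fitted with a
#' cubic smoothing spline of deliberately low flexibility, monotonicity is
#' enforced by a running maximum, and the unfolded positions are
#' `e_i = n * F(lambda_i)`; spacings are their first differences.
#'
#' The spline must follow the smooth density trend but not the staircase's
#' local jitter: an over-flexible fit (e.g. one tuned by cross-validation)
#' reproduces the staircase itself, which forces every spacing toward 1 and
#' erases the very statistics being tested. The default stiffness is
#' `df = min(10, max(4, round(n/15)))`.
#'
#' @param lambda Numeric vector of eigenvalues, length >= 20 (sorted
#'   internally).
#' @param df_spline Equivalent degrees of freedom for the smoothing spline;
#'   `NULL` (default) uses the stiffness rule above.
#' @return Numeric vector of `length(lambda) - 1` unfolded spacings with
#'   mean approximately 1.
#' @export
unfold_spectrum <- function(lambda, df_spline = NULL) {
  if (!is.numeric(lambda) || length(lambda) < 20) {
    abort("Need at least 20 eigenvalues to unfold.")
  }
  lambda <- sort(lambda)
  n <- length(lambda)
  if (diff(range(lambda)) < .Machine$double.eps * max(1, abs(lambda[1]))) {
    abort("Degenerate spectrum: all eigenvalues identical.")
  }
  if (is.null(df_spline)) df_spline <- min(10, max(4, round(n / 15)))
  p <- (seq_len(n) - 0.5) / n
  n_unique <- length(unique(lambda))
  df_spline <- min(df_spline, n_unique - 1)
  if (df_spline < 2) abort("Too few distinct eigenvalues to unfold.")
  fit <- smooth.spline(lambda, p, df = df_spline)
  Fhat <- predict(fit, lambda)$y
  Fhat <- cummax(pmin(pmax(Fhat, 0), 1))
  diff(n * Fhat)
}

# Closed-form spacing CDFs: Poisson P(d) = exp(-d); GOE (Wigner surmise)
# P(d) = (pi d / 2) exp(-pi d^2 / 4).
spacing_cdf <- function(x, family) {
  switch(family,
         poisson = 1 - exp(-x),
         goe     = 1 - exp(-pi * x^2 / 4))
}

#' Nearest-neighbor spacing density of the reference ensembles
#'
#' @param d Spacings (non-negative).
#' @param family `"poisson"` (`exp(-d)`) or `"goe"` (Wigner surmise,
#'   `(pi d/2) exp(-pi d^2/4)`).
#' @return Density values at `d`.
#' @export
spacing_density <- function(d, family = c("poisson", "goe")) {
  family <- match.arg(family)
  switch(family,
         poisson = exp(-d),
         goe     = (pi * d / 2) * exp(-pi * d^2 / 4))
}

#' Goodness of fit of spacings to Poisson or GOE statistics
#'
#' Spacings are binned on \[0, 3\] with fixed width 0.1 plus an overflow
#' bin; expected counts come from the closed-form ensemble CDF. Adjacent
#' bins are pooled until each pooled bin has expected count >= 5 (the
#' standard validity rule for the Pearson chi-square), and the statistic is
#' referred to chi-square with `occupied bins - 1` degrees of freedom.
#'
#' @param d Unfolded spacings, length >= 20.
#' @param family `"poisson"` or `"goe"`.
#' @return A one-row tibble: `family`, `chi2`, `df`, `p`, `n`.
#' @export
nnsd_gof <- function(d, family = c("poisson", "goe")) {
  family <- match.arg(family)
  if (!is.numeric(d) || length(d) < 20) {
    abort("Need at least 20 spacings for the spacing GOF; use a larger network.")
  }
  breaks <- c(seq(0, 3, by = 0.1), Inf)
  obs <- as.numeric(table(cut(d, breaks, include.lowest = TRUE)))
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  pr <- ifelse(is.finite(hi), spacing_cdf(hi, family), 1) - spacing_cdf(lo, family)
  expected <- length(d) * pr

  # pool adjacent bins until expected >= 5
  O <- numeric(0); E <- numeric(0); co <- 0; ce <- 0
  for (i in seq_along(obs)) {
    co <- co + obs[i]; ce <- ce + expected[i]
    if (ce >= 5) { O <- c(O, co); E <- c(E, ce); co <- 0; ce <- 0 }
  }
  if (ce > 0) {
    if (length(O)) { O[length(O)] <- O[length(O)] + co; E[length(E)] <- E[length(E)] + ce }
    else { O <- co; E <- ce }
  }
  chi2 <- sum((O - E)^2 / E)
  dof <- max(1L, sum(O > 0) - 1L)
  tibble(family = family, chi2 = chi2, df = dof,
         p = pchisq(chi2, dof, lower.tail = FALSE), n = length(d))
}

#' Detect the RMT correlation threshold
#'
#' Scans a grid of candidate cutoffs; at each, the similarity matrix is
#' thresholded, isolated OTUs are dropped, and the nearest-neighbor spacing
#' distribution of the eigenvalues of the full weighted thresholded matrix
#' is tested against Poisson and GOE statistics. At low cutoffs the dense
#' correlated matrix shows GOE-like level repulsion; once the cutoff
#' isolates the system-specific block structure the spacings become
#' Poisson. The selected threshold is the lowest candidate that begins a
#' run of `run_length` consecutive Poisson-consistent candidates
#' (`p_poisson > alpha`), which guards against single-grid-point flukes.
#' Candidates retaining fewer than `min_nodes` OTUs (or fewer than 21
#' eigenvalues) are skipped, not failed.
#'
#' @param sim A `similarity_matrix`.
#' @param grid Ascending candidate cutoffs; default `seq(0.30, 0.99, 0.01)`.
#' @param alpha Significance level for Poisson consistency (default 0.05).
#' @param min_nodes Minimum retained OTUs for spectral statistics (default 50).
#' @param run_length Consecutive Poisson-consistent candidates required
#'   (default 3).
#' @return An object of class `rmt_scan`: list with `scan` (tibble of
#'   per-candidate statistics), `threshold`, `alpha`, `rule`. If no
#'   candidate qualifies an error of class `rmt_no_transition` is thrown
#'   carrying the scan tibble in its `scan` field.
#' @export
detect_rmt_threshold <- function(sim, grid = seq(0.30, 0.99, by = 0.01),
                                 alpha = 0.05, min_nodes = 50,
                                 run_length = 3) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (is.unsorted(grid)) abort("`grid` must be ascending.")
  if (length(sim$otu_ids) < min_nodes) {
    abort(sprintf("Similarity matrix has %d OTUs; need >= min_nodes (%d).",
                  length(sim$otu_ids), min_nodes))
  }
  rows <- purrr::map(grid, function(st) {
    th <- threshold_matrix(sim, st)
    out <- tibble(s_t = st, n_nodes = th$n_nodes, n_edges = th$n_edges,
                  chi2_poisson = NA_real_, p_poisson = NA_real_,
                  chi2_goe = NA_real_, p_goe = NA_real_, evaluated = FALSE)
    if (th$empty || th$n_nodes < min_nodes || th$n_nodes < 21) return(out)
    lam <- eigen(th$a, symmetric = TRUE, only.values = TRUE)$values
    d <- tryCatch(unfold_spectrum(lam), error = function(e) NULL)
    if (is.null(d)) return(out)
    gp <- nnsd_gof(d, "poisson")
    gg <- nnsd_gof(d, "goe")
    out$chi2_poisson <- gp$chi2; out$p_poisson <- gp$p
    out$chi2_goe <- gg$chi2; out$p_goe <- gg$p
    out$evaluated <- TRUE
    out
  })
  scan <- dplyr::bind_rows(rows)

  ev <- which(scan$evaluated)
  pass <- scan$p_poisson[ev] > alpha
  sel <- NA_real_
  if (length(ev) >= run_length) {
    for (i in seq_len(length(ev) - run_length + 1)) {
      if (all(pass[i:(i + run_length - 1)])) { sel <- scan$s_t[ev[i]]; break }
    }
  }
  if (is.na(sel)) {
    abort("No RMT transition found: no run of Poisson-consistent thresholds.",
          class = "rmt_no_transition", scan = scan)
  }
  scan$selected <- scan$s_t == sel
  structure(list(scan = scan, threshold = sel, alpha = alpha,
                 rule = sprintf(
                   "lowest candidate starting %d consecutive p_poisson > %g",
                   run_length, alpha)),
            class = "rmt_scan")
}

#' @export
print.rmt_scan <- function(x, ...) {
  cat(sprintf("<rmt_scan> %d candidates, selected threshold s_t = %.2f (%s)\n",
              nrow(x$scan), x$threshold, x$rule))
  invisible(x)
}

#' @rdname detect_rmt_threshold
#' @param x An `rmt_scan`.
#' @param path Output TSV path for the per-candidate scan report.
#' @export
write_scan_report <- function(x, path) {
  stopifnot(inherits(x, "rmt_scan"))
  write.table(x$scan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
tidy.rmt_scan <- function(x, ...) x$scan

#' @export
glance.rmt_scan <- function(x, ...) {
  tibble(threshold = x$threshold, alpha = x$alpha,
         n_candidates = nrow(x$scan), n_evaluated = sum(x$scan$evaluated),
         rule = x$rule)
}

#' @export
autoplot.rmt_scan <- function(object, ...) {
  dat <- dplyr::filter(object$scan, .data$evaluated)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$s_t, y = .data$p_poisson)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p_poisson > object$alpha)) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$threshold, colour = "red") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2b8cbe", `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::labs(x = "candidate threshold s_t",
                  y = "Poisson-consistency p value",
                  title = sprintf("RMT threshold scan (selected s_t = %.2f)",
                                  object$threshold)) +
    ggplot2::theme_minimal()
}
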