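#' Construct an OTU abundance table
#'
#' The primary input container of the pipeline: a matrix of non-negative
#' abundances (counts or proportions) with OTUs as rows and samples as
#' columns, plus an optional taxonomy annotation per OTU.
#'
#' @param values Numeric matrix, OTUs x samples. Row names are OTU ids and
#'   column names are sample ids; both must be unique and non-empty.
#' @param taxonomy Optional named character vector mapping OTU ids to
#'   semicolon-ranked lineage strings. May cover a subset of the OTUs.
#' @return An object of class `otu_table`.
#' @examples
#' m <- matrix(c(5, 0, 2, 1, 3, 4), nrow = 3,
#'             dimnames = list(paste0("OTU_", 1:3), c("s1", "s2")))
#' ot <- otu_table(m)
#' n_otus(ot)
#' @export
otu_table <- function(values, taxonomy = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (OTUs x samples).")
  }
  otu_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(otu_ids) || is.null(sample_ids)) {
    abort("`values` must have row names (OTU ids) and column names (sample ids).")
  }
  if (anyDuplicated(otu_ids)) {
    abort(paste0("Duplicate OTU id(s): ",
                 paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(sample_ids)) {
    abort(paste0("Duplicate sample id(s): ",
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  if (any(!is.finite(values))) abort("Abundances must be finite.")
  if (any(values < 0)) abort("Abundances must be non-negative.")
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) abort("`taxonomy` must be named by OTU id.")
    unknown <- setdiff(names(taxonomy), otu_ids)
    if (length(unknown)) {
      abort(paste0("taxonomy refers to unknown OTU id(s): ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
    taxonomy <- taxonomy[intersect(otu_ids, names(taxonomy))]
  }
  structure(list(values = values, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d OTUs x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$taxonomy)) "" else
                sprintf(", taxonomy for %d OTUs", length(x$taxonomy))))
  invisible(x)
}

#' @rdname otu_table
#' @param x An `otu_table`.
#' @export
n_otus <- function(x) nrow(x$values)

#' @rdname otu_table
#' @export
n_samples <- function(x) ncol(x$values)

#' Read an OTU table from TSV or BIOM-JSON
#'
#' The TSV dialect is: first column OTU id, header row of sample ids, and an
#' optional trailing `taxonomy` column holding a semicolon-ranked lineage.
#' BIOM tables (JSON flavor) are accepted read-only via the biomformat
#' package.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "biom") return(read_otu_biom(path))

  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) {
    abort(paste0("Malformed OTU table ", path,
                 ": need a header row and at least one OTU row."))
  }
  df <- read.delim(text = paste(lines, collapse = "\n"),
                   check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) abort("Malformed header: expected at least one sample column.")
  has_tax <- tolower(names(df)[ncol(df)]) == "taxonomy"
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate OTU id(s) in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  val_cols <- seq(2, ncol(df) - has_tax)
  vals <- matrix(NA_real_, nrow(df), length(val_cols),
                 dimnames = list(ids, names(df)[val_cols]))
  for (j in seq_along(val_cols)) {
    col <- names(df)[val_cols[j]]
    v <- suppressWarnings(as.numeric(df[[val_cols[j]]]))
    bad <- which(is.na(v) & !is.na(df[[val_cols[j]]]))
    if (length(bad)) {
      abort(sprintf("Non-numeric value in column '%s', row '%s': '%s'",
                    col, ids[bad[1]], df[[val_cols[j]]][bad[1]]))
    }
    if (anyNA(v)) {
      abort(sprintf("Missing abundance in column '%s', row '%s'",
                    col, ids[which(is.na(v))[1]]))
    }
    vals[, j] <- v
  }
  tax <- NULL
  if (has_tax) tax <- setNames(df[[ncol(df)]], ids)
  otu_table(vals, taxonomy = tax)
}

read_otu_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("BIOM support requires the 'biomformat' package.")
  }
  b <- biomformat::read_biom(path)
  vals <- as.matrix(biomformat::biom_data(b))
  md <- biomformat::observation_metadata(b)
  tax <- NULL
  if (!is.null(md) && length(md)) {
    collapse1 <- function(x) paste(unlist(x), collapse = "; ")
    if (is.data.frame(md)) {
      tax <- setNames(apply(md, 1, collapse1), rownames(md))
    } else {
      tax <- setNames(vapply(md, collapse1, character(1)), names(md))
    }
  }
  otu_table(vals, taxonomy = tax)
}

#' Write an OTU table as TSV
#'
#' Inverse of [read_otu_table()]: first column `otu_id`, one column per
#' sample, and a trailing `taxonomy` column when annotations are present.
#'
#' @param x An [otu_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(otu_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$taxonomy)) {
    df$taxonomy <- unname(x$taxonomy[rownames(x$values)])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample trait table
#'
#' Rows are samples, columns are physiological traits (e.g. BUN, CR, MDA,
#' SOD); empty cells are missing. Traits with fewer than three non-missing
#' values are kept but flagged unusable (attribute `"usable"`), since no
#' meaningful correlation can be computed from them.
#'
#' @param path Path to a TSV file whose first column holds sample ids.
#' @return A tibble with column `sample_id` followed by one numeric column
#'   per trait, carrying a named logical attribute `"usable"`.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  if (ncol(df) < 2) abort("Trait table needs a sample id column plus >= 1 trait.")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate sample id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  out <- tibble(sample_id = ids)
  for (j in 2:ncol(df)) out[[names(df)[j]]] <- as.numeric(df[[j]])
  usable <- vapply(out[-1], function(v) sum(!is.na(v)) >= 3, logical(1))
  if (any(!usable)) {
    warn(paste0("Trait(s) with < 3 non-missing values flagged unusable: ",
                paste(names(usable)[!usable], collapse = ", ")))
  }
  attr(out, "usable") <- usable
  out
}

#' Remove rare OTUs by prevalence
#'
#' OTUs detected (abundance > 0) in fewer than `ceiling(min_prevalence *
#' n_samples)` samples are excluded before network inference; sparse OTUs
#' inflate the false-positive rate of correlation-based edge detection.
#' Ties at the boundary are retained.
#'
#' @param table An [otu_table()].
#' @param min_prevalence Minimum fraction of samples in which an OTU must be
#'   detected, in (0, 1]. Default 0.5.
#' @return A filtered [otu_table()]; the sample set is unchanged.
#' @export
prevalence_filter <- function(table, min_prevalence = 0.5) {
  stopifnot(inherits(table, "otu_table"))
  if (!is.numeric(min_prevalence) || min_prevalence <= 0 || min_prevalence > 1) {
    abort("`min_prevalence` must lie in (0, 1].")
  }
  need <- ceiling(min_prevalence * n_samples(table))
  keep <- rowSums(table$values > 0) >= need
  if (!any(keep)) {
    abort(sprintf(paste0(
      "Prevalence filter at %.2f removed every OTU ",
      "(needed presence in >= %d of %d samples); lower the threshold."),
      min_prevalence, need, n_samples(table)))
  }
  otu_table(table$values[keep, , drop = FALSE],
            taxonomy = table$taxonomy[names(table$taxonomy) %in%
                                        rownames(table$values)[keep]] %||% NULL)
}

#' Transform abundances for correlation analysis
#'
#' `relative` divides each sample column by its total; `log10_relative`
#' additionally applies log10 after adding a pseudocount equal to half the
#' smallest nonzero relative abundance in the table (so zeros stay below
#' every observed value on the log scale); `raw` returns values unchanged.
#' The default for network inference is `log10_relative`, the variance
#' stabilizing choice customary in ecological network practice.
#'
#' @param table An [otu_table()].
#' @param method One of `"log10_relative"`, `"relative"`, `"raw"`.
#' @return An object of class `abundance_matrix`: list with `values`
#'   (same shape as the input), `transform`, and `pseudocount` (NA unless
#'   log10_relative).
#' @export
transform_abundance <- function(table,
                                method = c("log10_relative", "relative", "raw")) {
  stopifnot(inherits(table, "otu_table"))
  method <- match.arg(method)
  v <- table$values
  pseudo <- NA_real_
  if (method != "raw") {
    tot <- colSums(v)
    if (any(tot == 0)) {
      abort(paste0("All-zero sample column(s): ",
                   paste(colnames(v)[tot == 0], collapse = ", ")))
    }
    v <- sweep(v, 2, tot, "/")
    if (method == "log10_relative") {
      nz <- v[v > 0]
      if (!length(nz)) abort("Table has no nonzero abundance.")
      pseudo <- min(nz) / 2
      v <- log10(v + pseudo)
    }
  }
  structure(list(values = v, transform = method, pseudocount = pseudo),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d OTUs x %d samples, transform = %s\n",
              nrow(x$values), ncol(x$values), x$transform))
  invisible(x)
}
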