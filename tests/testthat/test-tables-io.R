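test_that("TSV parsing handles taxonomy, preserves order, and round-trips", {
  path <- write_tsv_lines(c(
    "otu_id\tsA\tsB\ttaxonomy",
    "OTU_1\t5\t1\tBacteria; Firmicutes; GenusA",
    "OTU_2\t0\t3\tBacteria; Bacteroidetes; GenusB",
    "OTU_3\t2\t4\tBacteria; Proteobacteria; GenusC"))
  ot <- read_otu_table(path)
  expect_s3_class(ot, "otu_table")
  expect_identical(rownames(ot$values), paste0("OTU_", 1:3))
  expect_identical(colnames(ot$values), c("sA", "sB"))
  expect_length(ot$taxonomy, 3)
  expect_equal(unname(ot$values["OTU_3", ]), c(2, 4))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(ot, out)
  ot2 <- read_otu_table(out)
  expect_equal(ot2$values, ot$values)
  expect_equal(ot2$taxonomy, ot$taxonomy)
})

test_that("malformed OTU tables produce named parse errors", {
  empty <- write_tsv_lines(character(0))
  expect_error(read_otu_table(empty), "header")

  dup <- write_tsv_lines(c("otu_id\ts1\ts2",
                           "OTU_1\t1\t2",
                           "OTU_1\t3\t4"))
  expect_error(read_otu_table(dup), "OTU_1")

  bad <- write_tsv_lines(c("otu_id\ts1\ts2",
                           "OTU_1\t1\t2",
                           "OTU_2\tx\t4"))
  expect_error(read_otu_table(bad), "s1.*OTU_2|OTU_2.*s1")

  expect_error(read_otu_table(tempfile("nope")), "not found")
})

test_that("otu_table validates ids and values", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(otu_table(m), "Duplicate OTU")
  m2 <- matrix(c(1, -1, 2, 3), 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(otu_table(m2), "non-negative")
})

test_that("prevalence filter keeps boundary ties and is idempotent", {
  vals <- rbind(
    present3of6 = c(1, 2, 3, 0, 0, 0),
    present2of6 = c(1, 2, 0, 0, 0, 0),
    everywhere  = c(1, 1, 1, 1, 1, 1))
  colnames(vals) <- paste0("s", 1:6)
  ot <- otu_table(vals)
  f <- prevalence_filter(ot, 0.5)
  expect_setequal(rownames(f$values), c("present3of6", "everywhere"))
  expect_identical(colnames(f$values), colnames(vals))
  # idempotent
  f2 <- prevalence_filter(f, 0.5)
  expect_equal(f2$values, f$values)
})

test_that("prevalence filter matches a direct scan and errors when empty", {
  set.seed(42)
  vals <- matrix(rpois(10 * 6, 0.8), 10, 6,
                 dimnames = list(sprintf("OTU_%02d", 1:10), paste0("s", 1:6)))
  vals[1:4, ] <- 0
  vals[, 1] <- 0  # no OTU present everywhere
  ot <- otu_table(vals)
  for (mp in c(0.2, 0.5, 0.8)) {
    expected <- rowSums(vals > 0) >= ceiling(mp * 6)
    if (!any(expected)) next
    f <- prevalence_filter(ot, mp)
    expect_identical(rownames(f$values), rownames(vals)[expected])
    expect_lte(nrow(f$values), 6)
  }
  expect_error(prevalence_filter(ot, 1), "lower the threshold")
})

test_that("abundance transforms follow their definitions", {
  vals <- matrix(c(2, 2, 98, 2, 0, 2), nrow = 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  ot <- otu_table(vals)

  raw <- transform_abundance(ot, "raw")
  expect_equal(raw$values, vals)

  rel <- transform_abundance(ot, "relative")
  expect_equal(unname(colSums(rel$values)), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(rel$values["a", "s1"]), 2 / 100)

  lr <- transform_abundance(ot, "log10_relative")
  min_nz <- min(rel$values[rel$values > 0])
  expect_equal(lr$pseudocount, min_nz / 2)
  expect_equal(lr$values, log10(rel$values + min_nz / 2))

  # sample column (2, 2) under relative -> (0.5, 0.5)
  simple <- otu_table(matrix(c(2, 2), 2,
                             dimnames = list(c("a", "b"), "s1")))
  expect_equal(unname(transform_abundance(simple, "relative")$values[, 1]),
               c(0.5, 0.5))

  zero <- otu_table(matrix(c(1, 2, 0, 0), 2,
                           dimnames = list(c("a", "b"), c("ok", "empty"))))
  expect_error(transform_abundance(zero, "relative"), "empty")
})

test_that("trait tables flag traits with too few observations", {
  path <- write_tsv_lines(c(
    "sample_id\tBUN\tSOD",
    "s1\t10\t",
    "s2\t12\t",
    "s3\t\t5",
    "s4\t14\t"))
  expect_warning(tt <- read_trait_table(path), "SOD")
  expect_identical(attr(tt, "usable"), c(BUN = TRUE, SOD = FALSE))
  expect_equal(tt$BUN, c(10, 12, NA, 14))
})

test_that("BIOM-JSON tables are read when biomformat is available", {
  skip_if_not_installed("biomformat")
  vals <- matrix(c(5, 0, 2, 1, 3, 4), nrow = 3,
                 dimnames = list(paste0("OTU_", 1:3), c("s1", "s2")))
  b <- biomformat::make_biom(vals)
  path <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(b, path)
  ot <- read_otu_table(path, format = "biom")
  expect_equal(ot$values[rownames(vals), colnames(vals)], vals)
})
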