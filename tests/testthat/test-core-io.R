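test_that("count table TSV round-trips and rejects bad input", {
  tbl <- tiny_counts()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tbl, path)
  back <- read_count_table(path)
  expect_equal(abund_matrix(back), abund_matrix(tbl))
  expect_identical(taxon_ids(back), taxon_ids(tbl))
  expect_identical(abund_unit(back), "reads")

  expect_error(read_count_table(file.path(tempdir(), "nope.tsv")), "not found")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1", "z1\tabc"), bad)
  expect_error(read_count_table(bad), "not numeric")
  expect_error(abund_tbl(data.frame(taxon_id = "z1", s1 = -1)), "non-negative")
  expect_error(abund_tbl(data.frame(taxon_id = c("z1", "z1"), s1 = c(1, 2))),
               "duplicate")
})

test_that("organelle filtering removes chloroplast/mitochondria at any rank", {
  ids <- paste0("z", 1:5)
  tax <- tiny_taxonomy(ids, phylum = rep("Proteobacteria", 5))
  tax$order[2] <- "Chloroplast"
  tax$family[4] <- "Mitochondria"
  tbl <- abund_tbl(data.frame(taxon_id = ids, s1 = 1:5, s2 = 5:1))
  out <- filter_organelles(tbl, tax)
  expect_identical(taxon_ids(out), c("z1", "z3", "z5"))
  # idempotent; identity when no organelles
  expect_identical(filter_organelles(out, tax), out)
  expect_error(filter_organelles(tbl, tax[-1, ]), "missing")
})

test_that("to_relative normalises columns and is idempotent", {
  tbl <- abund_tbl(data.frame(taxon_id = c("a", "b"), s1 = c(3, 1)))
  rel <- to_relative(tbl)
  expect_equal(unname(abund_matrix(rel)[, 1]), c(0.75, 0.25))
  expect_identical(abund_unit(rel), "relative_fraction")
  expect_equal(abund_matrix(to_relative(rel)), abund_matrix(rel))
  one <- abund_tbl(data.frame(taxon_id = "a", s1 = 5))
  expect_equal(unname(abund_matrix(to_relative(one))[, 1]), 1)
  zero <- abund_tbl(data.frame(taxon_id = c("a", "b"), s1 = c(0, 0), s2 = c(1, 1)))
  expect_error(to_relative(zero), "s1")
})

test_that("qPCR integration scales per marker and conserves totals", {
  prok <- abund_tbl(data.frame(taxon_id = c("pA", "pB"), s1 = c(3, 1), s2 = c(1, 1)))
  euk <- abund_tbl(data.frame(taxon_id = c("eA", "eB"), s1 = c(1, 4), s2 = c(2, 0)))
  qpcr <- tibble::tibble(sample_id = c("s1", "s2"),
                         copies_16s = c(2e8, 0), copies_18s = c(5e7, 1e6))
  out <- integrate_qpcr(prok, euk, qpcr)
  m <- abund_matrix(out)
  expect_equal(m["pA", "s1"], 1.5e8)
  expect_equal(m["pB", "s1"], 5e7)
  expect_identical(abund_unit(out), "copies_per_ml")
  expect_equal(colSums(m), c(s1 = 2.5e8, s2 = 1e6), tolerance = 1e-9)
  expect_true(all(m[c("pA", "pB"), "s2"] == 0))

  expect_error(integrate_qpcr(prok, prok, qpcr), "overlapping")
  expect_error(integrate_qpcr(prok, euk, qpcr[1, ]), "absent")
})

test_that("rank aggregation sums rows and conserves the grand total", {
  ids <- paste0("z", 1:6)
  tax <- tiny_taxonomy(ids, phylum = c("A", "A", "B", "B", "C", "C"))
  tbl <- abund_tbl(data.frame(taxon_id = ids, s1 = 1:6, s2 = 6:1))
  agg <- aggregate_by_rank(tbl, tax, "phylum")
  expect_identical(nrow(agg), 3L)
  expect_equal(sum(abund_matrix(agg)), sum(abund_matrix(tbl)))
  expect_equal(unname(abund_matrix(agg)["A", ]), c(1 + 2, 6 + 5))

  # unclassified kept distinct per parent lineage
  tax2 <- tax
  tax2$phylum[c(1, 3)] <- "unclassified"
  tax2$domain[1] <- "Bacteria"; tax2$domain[3] <- "Eukaryota"
  agg2 <- aggregate_by_rank(tbl, tax2, "phylum")
  expect_identical(sum(grepl("^unclassified", taxon_ids(agg2))), 2L)
})

test_that("taxonomy reader accepts QIIME-style lineage strings", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tlineage",
               "z1\td__Bacteria; p__Cyanobacteria; c__; o__; f__; g__",
               "z2\td__Bacteria; p__Proteobacteria"), path)
  tax <- read_taxonomy(path)
  expect_identical(tax$phylum, c("Cyanobacteria", "Proteobacteria"))
  expect_identical(tax$genus, c("unclassified", "unclassified"))
})
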