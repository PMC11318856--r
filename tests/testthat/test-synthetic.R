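test_that("generation is deterministic for a fixed seed", {
  spec <- architecture_spec(5, n_decoys = 2, n_duplicates = 1)
  g1 <- generate_chromosome(spec, 7)
  g2 <- generate_chromosome(spec, 7)
  expect_identical(g1, g2)
  g3 <- generate_chromosome(spec, 8)
  expect_false(identical(g1$chromosome$orfs, g3$chromosome$orfs))
})

test_that("unsatisfiable prophage specs are rejected", {
  expect_error(prophage_spec(defects = "mosaic_region", morphology = "untyped"),
               "untyped")
  expect_error(prophage_spec(defects = c("mosaic_region", "intron_split_gene")),
               "alone")
  expect_error(prophage_spec(defects = c("split_integrase",
                                         "truncated_integrase")),
               "mutually exclusive")
  expect_error(prophage_spec(remnant = TRUE, morphology = "myovirus"),
               "remnant")
  expect_error(prophage_spec(lysogeny_type = "ci_cro",
                             promoter_geometry = "convergent"),
               "ImmR/ImmA")
  expect_error(architecture_spec(0, n_decoys = 2, n_duplicates = 3),
               "duplicate")
})

test_that("a chromosome with no prophages confirms nothing", {
  g <- generate_chromosome(architecture_spec(0, n_decoys = 5,
                                             n_duplicates = 0), 3)
  cur <- curate(g$chromosome, g$hits, g$completeness)
  expect_identical(sum(cur$report$confirmed), 0L)
  expect_identical(nrow(cur$report), 5L)
})

test_that("a 15-prophage, 14-decoy-hit genome confirms exactly 15 regions", {
  g <- generate_chromosome(architecture_spec(15, n_decoys = 8,
                                             n_duplicates = 6), 1)
  expect_identical(nrow(g$hits), 29L)
  cur <- curate(g$chromosome, g$hits, g$completeness, max_gap = 1000)
  expect_identical(sum(cur$report$confirmed), 15L)
  expect_length(recover_one(g), 0)
})

test_that("generated chromosomes satisfy the annotation-model invariants", {
  for (seed in 4:6) {
    g <- generate_chromosome(architecture_spec(6, n_decoys = 2,
                                               n_duplicates = 2), seed)
    expect_s3_class(validate_orf_table(
      g$chromosome$orfs[setdiff(names(g$chromosome$orfs), "region")]),
      "orf_table")
    for (r in g$chromosome$regions) {
      expect_true(all(r$orfs$start >= r$start & r$orfs$end <= r$end))
      expect_gte(r$completeness, 0)
      expect_lte(r$completeness, 100)
    }
    expect_true(all(g$promoters$score >= 0 & g$promoters$score <= 1))
    expect_identical(nrow(g$truth), 8L)  # one record per element
  }
})
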