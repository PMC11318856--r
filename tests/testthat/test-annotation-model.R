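test_that("region_length follows the 1-based inclusive convention", {
  expect_identical(region_length(194517, 235362), 40846L)
  expect_identical(region_length(5, 5), 1L)
  expect_identical(region_length(6632999, 6769447), 136449L)
  expect_error(region_length(10, 5), "invalid interval")
  expect_error(region_length(0, 5), "invalid interval")
})

test_that("published coordinates reproduce published sizes except phi4", {
  tab <- lm41$table1
  ok <- tab$region != "phi4"
  expect_equal(region_length(tab$start[ok], tab$end[ok]),
               tab$size_printed[ok])
  phi4 <- tab[tab$region == "phi4", ]
  expect_identical(region_length(phi4$start, phi4$end), 41886L)
  expect_identical(phi4$size_printed, 41690L)
  expect_false(phi4$size_consistent)
  expect_equal(sum(!tab$size_consistent), 1L)
})

test_that("ORF tables enforce coordinates, vocabulary and forced traits", {
  expect_error(orf_table("a", 10, 5, "+"), "invalid coordinates")
  expect_error(orf_table("a", 1, 9, "x"), "invalid strand")
  expect_error(orf_table("a", 1, 9, "+", category = "nonsense"),
               "unknown category")
  expect_error(orf_table("a", 1, 9, "+", traits = "flagellum"),
               "unknown trait")
  # a tail sheath gene cannot sit outside the tail category
  expect_error(orf_table("a", 1, 9, "+", category = "lysis",
                         traits = "tail_sheath"), "force category")
  ok <- orf_table(c("b", "a"), c(100, 1), c(200, 50), c("+", "-"),
                  category = "unknown")
  expect_identical(ok$id, c("a", "b")) # ordered by start
})

test_that("prophage regions validate span containment and completeness", {
  orfs <- orf_table("a", 50, 100, "+")
  expect_error(prophage_region("r", "c", 60, 200, orfs = orfs),
               "outside")
  expect_error(prophage_region("r", "c", 1, 200, completeness = 130),
               "completeness")
  r <- prophage_region("r", "c", 1, 200, orfs = orfs, completeness = 99)
  expect_s3_class(r, "prophage_region")
  expect_identical(region_length(r$start, r$end), 200L)
})

test_that("canonicalize_orientation mirrors reverse regions and is idempotent", {
  orfs <- orf_table(c("x1", "x2", "x3"), c(100, 300, 500),
                    c(200, 400, 600), c("+", "-", "+"))
  fwd <- prophage_region("f", "c", 1, 700, "forward", orfs)
  expect_identical(canonicalize_orientation(fwd)$orfs, fwd$orfs)

  rev <- prophage_region("r", "c", 1, 700, "reverse", orfs)
  can <- canonicalize_orientation(rev)
  # brute-force mirror of the toy list: reversed order, flipped strands,
  # coordinates untouched
  expect_identical(can$orfs$id, c("x3", "x2", "x1"))
  expect_identical(can$orfs$strand, c("-", "+", "-"))
  expect_identical(sort(can$orfs$start), sort(orfs$start))
  expect_identical(canonicalize_orientation(can)$orfs, can$orfs)
  # span preserved
  expect_identical(c(can$start, can$end), c(rev$start, rev$end))
})

test_that("promoter tables are validated and score-filtered", {
  p <- data.frame(region = "r", position = c(10, 20, 30),
                  strand = c("+", "-", "+"), score = c(0.95, 0.5, 0.87))
  expect_identical(nrow(filter_promoters(p)), 2L)
  p$score[1] <- 1.2
  expect_error(filter_promoters(p), "scores")
})
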