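test_that("merge_hits unions overlapping hits and respects the gap", {
  h <- data.frame(chrom = "c", start = c(100, 450), end = c(500, 900))
  m <- merge_hits(h, max_gap = 0)
  expect_identical(c(m$start, m$end), c(100L, 900L))

  h2 <- data.frame(chrom = "c", start = c(100, 700), end = c(500, 900))
  m2 <- merge_hits(h2, max_gap = 100) # gap of 199 stays open
  expect_identical(nrow(m2), 2L)
  expect_identical(nrow(merge_hits(h2, max_gap = 199)), 1L)

  expect_error(merge_hits(h, max_gap = -1), "non-negative")
  expect_error(merge_hits(data.frame(chrom = c("a", "b"), start = 1,
                                     end = 2), 0), "single chromosome")
  # idempotence
  expect_identical(merge_hits(m, 0)[, c("start", "end")],
                   m[, c("start", "end")])
})

test_that("merge_hits equals the brute-force interval-union oracle", {
  set.seed(42)
  for (k in 1:200) {
    h <- random_hits(sample(2:50, 1))
    gap <- sample(c(0L, 10L, 1000L, 5000L), 1)
    got <- merge_hits(h, gap)
    exp <- merge_hits_oracle(h, gap)
    expect_identical(cbind(got$start, got$end), unname(exp))
  }
})

test_that("module profiling finds the five canonical modules", {
  p1 <- assign_modules(lm41$chromosome$regions$phi1)
  expect_setequal(modules_present(p1), module_names())

  p7 <- assign_modules(lm41$chromosome$regions$phi7)
  expect_setequal(modules_present(p7), c("lysogeny_control", "dna_replication"))

  blank <- prophage_region("b", "c", 1, 20000,
                           orfs = orf_table(paste0("u", 1:10),
                                            seq(1, by = 1000, length.out = 10),
                                            seq(900, by = 1000, length.out = 10),
                                            "+", category = "unknown"))
  expect_length(modules_present(assign_modules(blank)), 0)
  expect_false(confirm_phage(assign_modules(blank)))
  expect_true(confirm_phage(p7))   # remnant with one+ module is retained
  expect_true(confirm_phage(p1))
})

test_that("defect detection reproduces the fixture defect taxonomy", {
  regs <- lm41_curation$regions
  expect_setequal(defect_kinds(detect_defects(regs$phi5)),
                  c("truncated_integrase", "missing_terminase_or_portal"))
  expect_setequal(defect_kinds(detect_defects(regs$phi12)),
                  "misoriented_late_orf")
  expect_setequal(defect_kinds(detect_defects(regs$phi3)), "split_integrase")
  expect_setequal(defect_kinds(detect_defects(regs$phi6)), "intron_split_gene")
  expect_setequal(defect_kinds(detect_defects(regs$phi13)), "mosaic_region")
  for (nm in c("phi1", "phi4", "phi10", "phi15", "phi2", "phi7"))
    expect_length(detect_defects(regs[[nm]]), 0)
})

test_that("categorization applies the completeness bands with defect overrides", {
  expect_identical(categorize(100, list()), "functional")
  expect_identical(categorize(100, list(defect_flag("split_integrase", "o"))),
                   "unknown")
  expect_identical(categorize(49.4, list()), "defective")
  expect_identical(categorize(75, list()), "unknown")
  expect_identical(categorize(60, list()), "defective")  # boundary low
  expect_identical(categorize(NA, list()), "unclassified")
  expect_error(categorize(101), "completeness")

  # monotone: lower completeness or extra defects never promote a region
  rank <- c(defective = 1, unknown = 2, functional = 3)
  set.seed(1)
  for (k in 1:100) {
    comp <- stats::runif(1, 0, 100)
    base <- rank[[categorize(comp, list())]]
    lower <- rank[[categorize(comp * stats::runif(1), list())]]
    expect_lte(lower, base)
    with_def <- rank[[categorize(comp, list(defect_flag("mosaic_region", "o")))]]
    expect_lte(with_def, base)
  }
  expect_lte(rank[[categorize(100, list(defect_flag("mosaic_region", "o")))]],
             rank[[categorize(100, list())]])
})

test_that("mosaic delineation splits phi13 into five ordered sub-regions", {
  subs <- delineate_mosaic(lm41_curation$regions$phi13)
  expect_length(subs, 5)
  expect_identical(vapply(subs, function(s) s$name, character(1)),
                   paste0("phi13", letters[1:5]))
  starts <- vapply(subs, function(s) s$start, integer(1))
  expect_identical(starts, sort(starts))
  expect_error(delineate_mosaic(lm41_curation$regions$phi1), "mosaic")
})

test_that("mosaic delineation falls back to the ORF before the next opener", {
  orfs <- orf_table(paste0("o", 1:7),
                    seq(100, by = 1000, length.out = 7),
                    seq(900, by = 1000, length.out = 7), "+",
                    category = c("replication", "replication", "unknown",
                                 "unknown", "unknown", "replication",
                                 "replication"))
  r <- prophage_region("m", "c", 1, 8000, orfs = orfs)
  subs <- delineate_mosaic(r)
  expect_length(subs, 2)
  # no tail/recombinase closer: first sub-region ends on the ORF preceding
  # the second opener
  expect_identical(subs[[1]]$orfs$id, paste0("o", 1:5))
  expect_identical(subs[[2]]$orfs$id, paste0("o", 6:7))
})

test_that("full curation of the fixture yields 15 regions in a 4/2/9 split", {
  rep <- lm41_curation$report
  expect_identical(nrow(rep), 23L)  # 29 hits collapse to 23 intervals
  expect_identical(sum(rep$confirmed), 15L)
  conf <- rep[rep$confirmed, ]
  expect_setequal(conf$name[conf$category == "functional"],
                  c("phi1", "phi4", "phi10", "phi15"))
  expect_setequal(conf$name[conf$category == "defective"],
                  c("phi7", "phi9"))
  expect_identical(sum(conf$category == "unknown"), 9L)
  expect_identical(lm41_curation$regions$phi13$category, "unknown")
})
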