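test_that("the screen maps fixture cargo to the expected classes", {
  regs <- lm41$chromosome$regions
  s5 <- screen_accessory(regs$phi5)
  rm5 <- s5[s5$accessory_class == "rm_system", ]
  # complete type I system: three specificity subunits, a methyltransferase
  # and a restriction subunit
  expect_identical(sum(grepl("HsdS", rm5$putative_function)), 3L)
  expect_identical(sum(grepl("HsdM", rm5$putative_function)), 1L)
  expect_identical(sum(grepl("HsdR", rm5$putative_function)), 1L)

  s10 <- screen_accessory(regs$phi10)
  hic <- s10[s10$orf_id %in% c("phi10_orf2", "phi10_orf3"), ]
  expect_identical(unique(hic$accessory_class), "ta_system")

  # solitary antitoxin (no toxin partner in the region) is counter-defence
  s13d <- screen_accessory(regs$phi13d)
  expect_identical(
    s13d$accessory_class[s13d$orf_id == "phi13_orf155"], "anti_phage_defence")

  # oversized uncategorized ORFs read as large-polyvalent-like cargo
  s1 <- screen_accessory(regs$phi1)
  expect_identical(s1$accessory_class[s1$orf_id == "phi1_orf64"],
                   "large_polyvalent_like")

  empty <- prophage_region("e", "c", 1, 5000,
                           orfs = orf_table("u1", 100, 900, "+"))
  expect_identical(nrow(screen_accessory(empty)), 0L)
})

test_that("defence summary locates anti-CRISPRs in phi1, phi4 and phi9 only", {
  recs <- do.call(rbind, lapply(lm41$chromosome$regions[paste0("phi", 1:15)],
                                screen_accessory))
  acr <- recs[grepl("Anti-CRISPR", recs$putative_function), ]
  expect_setequal(unique(acr$region), c("phi1", "phi4", "phi9"))
  tab <- summarize_defence(recs)
  expect_true(all(tab$n >= 1))
  expect_true(attr(tab, "no_classical_morons"))

  empty <- summarize_defence(recs[0, ])
  expect_identical(nrow(empty), 0L)
  expect_true(attr(empty, "no_classical_morons"))
})

test_that("vocabulary edits change the screen but never curation or typing", {
  vocab <- default_accessory_vocab()
  vocab$putative_function[vocab$trait == "anti_crispr"] <- "edited text"
  edited <- screen_accessory(lm41$chromosome$regions$phi1, vocab = vocab)
  expect_true(any(edited$putative_function == "edited text"))

  # curation and typing do not consult the vocabulary
  cur2 <- curate(lm41$chromosome, lm41$hits, lm41$completeness, max_gap = 0)
  expect_identical(cur2$report, lm41_curation$report)
  expect_identical(
    type_regions(lm41$chromosome$regions["phi1"], lm41$promoters),
    type_regions(lm41$chromosome$regions["phi1"], lm41$promoters))
})
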