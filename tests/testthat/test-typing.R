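test_that("morphology precedence is sheath > tape measure > baseplate", {
  regs <- lm41$chromosome$regions
  expect_identical(call_morphology(regs$phi3)$morphology, "myovirus")
  expect_identical(call_morphology(regs$phi1)$morphology, "podovirus")
  m7 <- call_morphology(regs$phi7)
  expect_identical(m7$morphology, "untyped")
  expect_length(m7$evidence, 0)
  # evidence is the deciding trait's ORFs
  expect_identical(call_morphology(regs$phi3)$evidence, "phi3_orf55")
})

test_that("fixture morphology matches the published predictions row for row", {
  for (i in seq_len(nrow(lm41$expected))) {
    nm <- lm41$expected$region[i]
    expect_identical(call_morphology(lm41$chromosome$regions[[nm]])$morphology,
                     lm41$expected$morphology[i], label = nm)
  }
})

test_that("promoter pair geometry follows strand orientation", {
  p <- function(pos, st, sc = 0.95) list(position = pos, strand = st, score = sc)
  expect_identical(promoter_pair_geometry(p(100, "-"), p(200, "+")), "divergent")
  expect_identical(promoter_pair_geometry(p(100, "+"), p(200, "-")), "convergent")
  expect_identical(promoter_pair_geometry(p(100, "+"), p(200, "+")), "tandem")
  expect_error(promoter_pair_geometry(p(100, "+", 0.5), p(200, "+")),
               "score-filtered")
  expect_error(promoter_pair_geometry(p(300, "+"), p(200, "+")), "precede")
})

test_that("lysogeny-switch calls reproduce the fixture assignments", {
  regs <- lm41$chromosome$regions
  pro <- lm41$promoters
  one <- function(nm) call_lysogeny(regs[[nm]],
                                    pro[pro$region %in% c(nm, "phi13"), ])
  c2 <- one("phi2")
  expect_identical(c2$system, "immr_imma")
  expect_identical(c2$promoter_geometry, "divergent")
  c12 <- one("phi12")
  expect_identical(c12$system, "immr_imma")
  expect_identical(c12$promoter_geometry, "convergent")
  expect_identical(one("phi5")$promoter_geometry, "convergent")
  expect_identical(one("phi13b")$system, "c_ner")
  expect_identical(one("phi13d")$system, "c_ner")
  expect_identical(one("phi13")$system, "c_ner")
  expect_identical(one("phi8")$system, "undetermined")

  ty <- type_regions(regs, pro)
  top <- ty[ty$region %in% paste0("phi", 1:15), ]
  expect_identical(sum(top$lysogeny_system == "ci_cro"), 10L)
  expect_setequal(top$region[top$lysogeny_system == "immr_imma"],
                  c("phi2", "phi5", "phi12"))
  expect_identical(top$region[top$lysogeny_system == "c_ner"], "phi13")
})

test_that("every region yields exactly one call and a repressor when typed", {
  ty <- type_regions(lm41$chromosome$regions, lm41$promoters)
  expect_identical(nrow(ty), length(lm41$chromosome$regions))
  typed <- ty$lysogeny_system != "undetermined"
  expect_true(all(!is.na(ty$repressor_orf[typed])))
  expect_true(all(is.na(ty$repressor_orf[!typed])))
})

test_that("unrelated ORFs outside the lysogeny span do not change the call", {
  base <- toy_cicro_region()
  expect_identical(call_lysogeny(base)$system, "ci_cro")
  extra <- data.frame(id = paste0("x", 1:4),
                      start = seq(11000, by = 1000, length.out = 4),
                      end = seq(11900, by = 1000, length.out = 4),
                      strand = c("+", "-", "+", "-"),
                      category = c("moron_accessory", "unknown", "other",
                                   "moron_accessory"),
                      traits = "", product = "p",
                      length_aa = 200L, stringsAsFactors = FALSE)
  grown <- toy_cicro_region(extra = extra)
  expect_identical(call_lysogeny(grown)$system, "ci_cro")
  expect_identical(call_lysogeny(grown)$repressor_orf,
                   call_lysogeny(base)$repressor_orf)
})

test_that("a region without HTH regulators stays undetermined", {
  orfs <- orf_table(paste0("o", 1:4), seq(100, by = 1000, length.out = 4),
                    seq(900, by = 1000, length.out = 4), c("+", "-", "+", "+"),
                    category = c("integration_excision", "replication",
                                 "replication", "tail"))
  r <- prophage_region("r", "c", 1, 5000, orfs = orfs)
  call <- call_lysogeny(r)
  expect_identical(call$system, "undetermined")
  expect_identical(call$promoter_geometry, "none")
  expect_true(is.na(call$repressor_orf))
})

test_that("CI/Cro is still called when promoter data are absent", {
  expect_identical(call_lysogeny(toy_cicro_region(), promoters = NULL)$system,
                   "ci_cro")
  expect_identical(call_lysogeny(toy_cicro_region())$promoter_geometry, "none")
})
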