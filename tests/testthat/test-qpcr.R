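test_that("replicate aggregation imputes silent wells at the cycle cap", {
  expect_identical(aggregate_cq(c(20, 21, 22)), 21)
  expect_identical(aggregate_cq(c(30, NA), cq_cap = 40), 35)
  expect_identical(aggregate_cq(27.3), 27.3)
  expect_error(aggregate_cq(numeric(0)), "empty")
  expect_error(aggregate_cq(c(20, 45)), "cq_cap")
})

test_that("delta-Cq and fold change follow the 2^-ddCq arithmetic", {
  expect_identical(delta_cq(30, 25), 5)
  expect_identical(delta_cq(12.5, 12.5), 0)
  expect_identical(fold_change(5, 5), 1)
  expect_identical(fold_change(5, 8), 8)

  # direct-formula oracle on random pairs
  set.seed(9)
  a <- stats::runif(1e4, -20, 20); b <- stats::runif(1e4, -20, 20)
  got <- mapply(fold_change, a, b)
  oracle <- 2^(-(a - b))
  expect_lt(max(abs(got - oracle) / oracle), 1e-12)
  # reciprocal pairs multiply to one
  expect_equal(mapply(fold_change, a, b) * mapply(fold_change, b, a),
               rep(1, 1e4), tolerance = 1e-12)
})

test_that("detection is called against the no-template control", {
  expect_true(detection_call(28, 35))
  expect_false(detection_call(36, 35))
  expect_false(detection_call(35, 35))
  expect_false(detection_call(30, NA))
  expect_false(detection_call(34.5, 35, margin = 1))
})

test_that("the fixture panel reproduces the published delta-Cq structure", {
  res <- analyze_qpcr(lm41$qpcr, housekeeper = "s10p")
  dcq <- setNames(res$delta_cq, res$target)
  expect_equal(dcq[["phi1"]], 5.11, tolerance = 1e-9)
  expect_equal(dcq[["phi4"]], 8.06, tolerance = 1e-9)
  expect_equal(dcq[["phi2"]], 8.37, tolerance = 1e-9)
  expect_equal(dcq[["phi10"]], 8.69, tolerance = 1e-9)
  phage <- res[res$target != "s10p", ]
  # the four released phages have the smallest deltas, in the printed order
  expect_identical(phage$target[order(phage$delta_cq)][1:4],
                   c("phi1", "phi4", "phi2", "phi10"))
  # every phage target detected except phi13e; housekeeper fully degraded
  expect_setequal(phage$target[!phage$detected], "phi13e")
  expect_true(res$housekeeper_degraded[res$target == "s10p"])
  expect_false(res$detected[res$target == "s10p"])
  # ranking by fold change equals the inverse delta-Cq ranking; phi1 leads
  expect_identical(order(-phage$fold_change), order(phage$delta_cq))
  expect_identical(phage$target[which.max(phage$fold_change)], "phi1")
  expect_identical(res$target[1], "phi1")
})

test_that("the panel analysis is invariant to a constant Cq shift", {
  res0 <- analyze_qpcr(lm41$qpcr)
  shifted <- lm41$qpcr
  shifted$cq <- shifted$cq - 1.25
  res1 <- analyze_qpcr(shifted)
  expect_equal(res1$fold_change, res0$fold_change, tolerance = 1e-9)
  expect_equal(res1$delta_cq, res0$delta_cq, tolerance = 1e-9)
})

test_that("panel validation rejects malformed input", {
  expect_error(analyze_qpcr(lm41$qpcr, housekeeper = "nope"), "housekeeper")
  broken <- lm41$qpcr[lm41$qpcr$condition != "untreated" |
                      lm41$qpcr$target != "phi1", ]
  expect_error(analyze_qpcr(broken), "phi1")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(target = "t", condition = "weird",
                              replicate = 1, cq = 20), path,
                   row.names = FALSE)
  expect_error(read_qpcr(path), "condition")
})
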