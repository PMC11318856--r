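# Shared fixtures: the LM41 bundle is deterministic and moderately costly,
# so build it once per test run.
lm41 <- build_lm41_fixture()

lm41_curation <- curate(lm41$chromosome, lm41$hits, lm41$completeness,
                        max_gap = 0)

# A small forward-strand toy region with a lambda-like switch.
toy_cicro_region <- function(name = "toy", extra = NULL) {
  orfs <- data.frame(
    id = paste0(name, "_orf", 1:10),
    start = seq(100, by = 1000, length.out = 10),
    end = seq(100, by = 1000, length.out = 10) + 900,
    strand = c("+", "-", "+", "+", "+", "+", "+", "+", "+", "+"),
    category = c("integration_excision", "transcription_regulation",
                 "transcription_regulation", "replication", "replication",
                 "packaging_capsid", "packaging_capsid", "packaging_capsid",
                 "lysis", "lysis"),
    traits = c("integrase", "hth_regulator", "hth_regulator", "helicase", "",
               "terminase_large", "portal", "major_capsid", "", ""),
    product = "p", length_aa = c(400L, 230L, 70L, 450L, 320L, 550L, 480L,
                                 400L, 120L, 280L),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) orfs <- rbind(orfs, extra)
  prophage_region(name, "chr", 1, max(orfs$end) + 100, orfs = orfs)
}

# Brute-force interval union: repeated pairwise merging to a fixed point.
merge_hits_oracle <- function(hits, max_gap) {
  iv <- unname(as.matrix(hits[, c("start", "end")]))
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  repeat {
    merged <- FALSE
    n <- nrow(iv)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        gap <- max(iv[i, 1], iv[j, 1]) - min(iv[i, 2], iv[j, 2]) - 1
        if (gap <= max_gap) {
          iv[i, ] <- c(min(iv[i, 1], iv[j, 1]), max(iv[i, 2], iv[j, 2]))
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged || nrow(iv) == 1) break
  }
  iv[order(iv[, 1]), , drop = FALSE]
}

# Compare a generated chromosome's pipeline outputs against its planted
# truth; returns a character vector of mismatch descriptions (empty when
# recovery is exact).
recover_one <- function(g) {
  cur <- curate(g$chromosome, g$hits, g$completeness, max_gap = 1000)
  mism <- character(0)
  note <- function(...) mism <<- c(mism, paste(...))
  conf <- cur$report$name[cur$report$confirmed]
  truth <- g$truth
  if (!setequal(conf, truth$name[truth$confirmed])) note("confirmed set")
  for (nm in intersect(conf, truth$name[truth$confirmed])) {
    r <- cur$regions[[nm]]
    trow <- truth[truth$name == nm, ]
    if (paste(sort(defect_kinds(r$defects)), collapse = ",") != trow$defects)
      note(nm, "defects")
    if (r$category != trow$category) note(nm, "category")
    ty <- type_regions(list(r), g$promoters)
    if (ty$morphology != trow$morphology) note(nm, "morphology")
    if (ty$lysogeny_system != trow$lysogeny) note(nm, "lysogeny")
    if (ty$promoter_geometry != trow$promoter_geometry) note(nm, "geometry")
    cls <- paste(sort(unique(screen_accessory(r)$accessory_class)),
                 collapse = ",")
    if (cls != trow$accessory) note(nm, "accessory")
    if (nzchar(trow$sub_regions)) {
      segs <- delineate_mosaic(r)
      got <- paste(vapply(segs, function(s) {
        o <- canonicalize_orientation(s)$orfs
        paste(o$id[1], o$id[nrow(o)], sep = ":")
      }, character(1)), collapse = ",")
      if (got != trow$sub_regions) note(nm, "sub-regions")
    }
  }
  mism
}

random_hits <- function(n, span = 100000L) {
  s <- sample.int(span, n, replace = TRUE)
  w <- sample.int(5000L, n, replace = TRUE)
  data.frame(chrom = "c", start = s, end = s + w, stringsAsFactors = FALSE)
}
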