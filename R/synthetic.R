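## Synthetic annotated chromosomes with planted prophage architectures and
## ground truth, for end-to-end pipeline validation. Only annotations are
## generated (no nucleotide sequence): the pipeline consumes annotations,
## and defects are encoded as the trait/length/orientation patterns the
## detectors are defined on.

.lysogeny_types <- c("ci_cro", "immr_imma", "c_ner", "none")
.morphologies <- c("podovirus", "siphovirus", "myovirus", "untyped")
.defect_kinds_all <- c("split_integrase", "truncated_integrase",
                       "missing_terminase_or_portal", "intron_split_gene",
                       "misoriented_late_orf", "mosaic_region")

#' Specify one planted prophage
#'
#' @param lysogeny_type One of `ci_cro`, `immr_imma`, `c_ner`, `none`.
#' @param morphology One of `podovirus`, `siphovirus`, `myovirus`,
#'   `untyped`.
#' @param defects Character vector of planted defect kinds (see
#'   [detect_defects]); `mosaic_region` must be planted alone.
#' @param completeness Completeness score to attach (0-100).
#' @param packaging_strand `"forward"` or `"reverse"`.
#' @param remnant Logical; a remnant carries only lysogeny-control and
#'   replication modules (and must be `untyped`).
#' @param accessory Character vector of accessory trait tokens to plant
#'   (subset of [orf_traits]).
#' @param promoters Logical; emit high-scoring promoter calls for the
#'   lysogeny switch.
#' @param promoter_geometry `"divergent"` or `"convergent"` (ImmR/ImmA
#'   systems admit both).
#' @return A validated `prophage_spec` list.
#' @export
prophage_spec <- function(lysogeny_type = "ci_cro", morphology = "siphovirus",
                          defects = character(0), completeness = 100,
                          packaging_strand = "forward", remnant = FALSE,
                          accessory = character(0), promoters = TRUE,
                          promoter_geometry = "divergent") {
  if (!lysogeny_type %in% .lysogeny_types)
    stop("unknown lysogeny_type: ", lysogeny_type)
  if (!morphology %in% .morphologies)
    stop("unknown morphology: ", morphology)
  if (length(setdiff(defects, .defect_kinds_all)))
    stop("unknown defect kind(s): ",
         paste(setdiff(defects, .defect_kinds_all), collapse = ", "))
  if ("mosaic_region" %in% defects && length(defects) > 1L)
    stop("mosaic_region must be planted alone")
  if ("mosaic_region" %in% defects && morphology == "untyped")
    stop("a mosaic region is delimited by tail genes and cannot be untyped")
  if (all(c("split_integrase", "truncated_integrase") %in% defects))
    stop("split and truncated integrase defects are mutually exclusive")
  if (remnant && morphology != "untyped")
    stop("a remnant (lysogeny+replication only) cannot carry tail genes: ",
         "morphology must be 'untyped'")
  if (remnant && length(setdiff(defects, c("split_integrase", "truncated_integrase"))))
    stop("remnants only admit integrase defects")
  if (morphology == "untyped" && "misoriented_late_orf" %in% defects && remnant)
    stop("misoriented_late_orf needs a lysis module")
  if (!completeness >= 0 || !completeness <= 100)
    stop("completeness must lie in [0, 100]")
  if (!promoter_geometry %in% c("divergent", "convergent"))
    stop("promoter_geometry must be divergent or convergent")
  if (promoter_geometry == "convergent" && lysogeny_type != "immr_imma")
    stop("convergent switch promoters are only modelled for ImmR/ImmA systems")
  structure(list(lysogeny_type = lysogeny_type, morphology = morphology,
                 defects = defects, completeness = completeness,
                 packaging_strand = packaging_strand, remnant = remnant,
                 accessory = accessory, promoters = promoters,
                 promoter_geometry = promoter_geometry),
            class = "prophage_spec")
}

#' Specify a synthetic chromosome architecture
#'
#' @param n_prophages Number of planted prophages.
#' @param prophages Optional list of [prophage_spec]s (length
#'   `n_prophages`); when `NULL`, specs are sampled at generation time from
#'   a study-like mix (mostly CI/Cro switches, mixed morphotypes, a
#'   minority of regions carrying defects).
#' @param n_decoys Number of non-phage gene-cluster decoys (candidate hits
#'   with no phage modules).
#' @param n_duplicates Number of duplicate/overlapping hits planted inside
#'   randomly chosen prophages.
#' @param gap_mean Mean intergenic distance (bp) between planted elements.
#' @return A validated `architecture_spec` list.
#' @export
architecture_spec <- function(n_prophages = 15L, prophages = NULL,
                              n_decoys = 8L, n_duplicates = 6L,
                              gap_mean = 40000L) {
  n_prophages <- as.integer(n_prophages)
  if (n_prophages < 0L) stop("n_prophages must be >= 0")
  if (!is.null(prophages)) {
    if (length(prophages) != n_prophages)
      stop("length(prophages) must equal n_prophages")
    lapply(prophages, function(p) {
      if (!inherits(p, "prophage_spec")) stop("prophages must be prophage_spec objects")
    })
  }
  if (n_duplicates > 0L && n_prophages == 0L)
    stop("duplicate hits need at least one prophage")
  structure(list(n_prophages = n_prophages, prophages = prophages,
                 n_decoys = as.integer(n_decoys),
                 n_duplicates = as.integer(n_duplicates),
                 gap_mean = as.integer(gap_mean)),
            class = "architecture_spec")
}

# Sample a study-like prophage spec.
.sample_prophage_spec <- function() {
  remnant <- stats::runif(1) < 0.12
  if (remnant) {
    morph <- "untyped"
    lys <- sample(c("ci_cro", "none"), 1L, prob = c(0.7, 0.3))
    defects <- if (stats::runif(1) < 0.3) "truncated_integrase" else character(0)
  } else {
    morph <- sample(.morphologies, 1L, prob = c(0.2, 0.35, 0.35, 0.1))
    lys <- sample(.lysogeny_types, 1L, prob = c(0.55, 0.2, 0.15, 0.1))
    defects <- character(0)
    r <- stats::runif(1)
    if (r < 0.10) defects <- "mosaic_region"
    else if (r < 0.50) {
      pool <- c("split_integrase", "truncated_integrase",
                "missing_terminase_or_portal", "intron_split_gene",
                "misoriented_late_orf")
      defects <- sample(pool, 1L)
      if (stats::runif(1) < 0.3) {
        extra <- setdiff(pool, c(defects,
          if (defects %in% c("split_integrase", "truncated_integrase"))
            c("split_integrase", "truncated_integrase")))
        defects <- c(defects, sample(extra, 1L))
      }
    }
  }
  if ("mosaic_region" %in% defects) {
    lys <- "none"
    if (morph == "untyped")
      morph <- sample(c("podovirus", "siphovirus", "myovirus"), 1L)
  }
  comp <- if (length(defects) || stats::runif(1) < 0.4) {
    if (stats::runif(1) < 0.5) 100 else round(stats::runif(1, 15, 99.5), 1)
  } else 100
  if (remnant) comp <- round(stats::runif(1, 15, 55), 1)
  acc_pool <- c("anti_crispr", "rm_hsdS", "rm_hsdM", "rm_hsdR", "ta_toxin",
                "ta_antitoxin", "restriction_alleviation", "mom_modification",
                "darB_antirestriction", "amidoligase", "ggct",
                "paps_reductase", "haemolysin", "avd_dgr",
                "cm_phosphotransferase", "dextransucrase")
  acc <- sample(acc_pool, min(stats::rpois(1, 1.2), 4L))
  geom <- if (lys == "immr_imma" && stats::runif(1) < 0.5) "convergent" else "divergent"
  prophage_spec(lysogeny_type = lys, morphology = morph, defects = defects,
                completeness = comp,
                packaging_strand = sample(c("forward", "reverse"), 1L),
                remnant = remnant, accessory = acc,
                promoters = stats::runif(1) < 0.9,
                promoter_geometry = geom)
}

# Anchor list (canonical order) realizing one prophage spec. Returns
# list(anchors, proms, truth_extra).
.build_prophage_anchors <- function(ps) {
  n <- 0L
  nxt <- function() { n <<- n + 1L; n }
  anchors <- list(); proms <- list()
  add <- function(cat, tr = "", aa = 150L, st = "+", pr = "hypothetical protein") {
    anchors[[length(anchors) + 1L]] <<- .mk(nxt(), cat, tr, aa, st, pr)
    n
  }
  jig <- function(aa) as.integer(aa + sample(-20:20, 1L))

  mosaic <- "mosaic_region" %in% ps$defects
  sub_bounds <- NULL
  if (mosaic) {
    n_sub <- sample(2:3, 1L)
    sub_bounds <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      first <- add("replication", "", jig(300L), "+", "replicative ATPase")
      add("replication", "helicase", jig(450L), "+", "replicative DNA helicase")
      add("packaging_capsid", "terminase_large", jig(550L), "+", "terminase large subunit")
      add("packaging_capsid", "portal", jig(480L), "+", "portal protein")
      add("packaging_capsid", "major_capsid", jig(400L), "+", "major capsid protein")
      if (s == 1L) for (tr in ps$accessory)
        add("moron_accessory", tr, jig(220L), "+", paste0("accessory: ", tr))
      tr_tail <- switch(ps$morphology,
        myovirus = "tail_sheath", podovirus = "baseplate_or_fiber",
        "tail_tape_measure")
      add("tail", tr_tail, jig(600L), "+", "tail gene")
      last <- add("tail", "", jig(250L), "+", "tail protein")
      sub_bounds[[s]] <- c(first, last)
    }
  } else {
    ## lysogeny control -----------------------------------------------------
    if ("split_integrase" %in% ps$defects) {
      add("integration_excision", "integrase", 180L, "+", "integrase N fragment")
      add("integration_excision", "integrase", 150L, "+", "integrase C fragment")
    } else if ("truncated_integrase" %in% ps$defects) {
      add("integration_excision", "integrase", 160L, "+", "truncated integrase")
    } else {
      add("integration_excision", "integrase", jig(420L), "+", "integrase")
    }
    add("integration_excision", "", jig(110L), "+", "excisionase")
    prom_after <- NA_integer_
    if (ps$lysogeny_type == "ci_cro") {
      prom_after <- add("transcription_regulation", "hth_regulator", jig(230L),
                        "-", "CI-like repressor")
      add("transcription_regulation", "hth_regulator", jig(70L), "+",
          "Cro-like regulator")
    } else if (ps$lysogeny_type == "immr_imma") {
      add("transcription_regulation", "imma_metallopeptidase", jig(205L), "-",
          "ImmA/IrrE family metallo-endopeptidase")
      prom_after <- add("transcription_regulation", "hth_regulator", jig(140L),
                        "-", "ImmR-like repressor")
      add("transcription_regulation", "hth_regulator", jig(120L), "+",
          "HTH transcriptional regulator")
    } else if (ps$lysogeny_type == "c_ner") {
      prom_after <- add("transcription_regulation", "hth_regulator", jig(195L),
                        "-", "C-like repressor")
      for (k in seq_len(sample(0:6, 1L))) add("unknown", "", jig(110L), "+")
      add("transcription_regulation", "hth_regulator",
          as.integer(sample(45:78, 1L)), "+", "Ner-like regulator")
      add("replication", "transposase_mu", jig(480L), "+", "Mu-like transposase")
    }
    if (isTRUE(ps$promoters) && !is.na(prom_after))
      proms[[1L]] <- list(after = prom_after, kind = ps$promoter_geometry)

    ## replication ----------------------------------------------------------
    if ("intron_split_gene" %in% ps$defects) {
      add("replication", "helicase", jig(310L), "+", "DNA helicase, N part")
      add("moron_accessory", "reverse_transcriptase_maturase", jig(430L), "+",
          "group II intron reverse transcriptase/maturase")
      add("replication", "helicase", jig(290L), "+", "DNA helicase, C part")
    } else {
      add("replication", "helicase", jig(450L), "+", "replicative DNA helicase")
    }
    add("replication", "", jig(320L), "+", "DNA primase")
    add("replication", "dna_polymerase", jig(600L), "+", "DNA polymerase")

    if (ps$remnant) {
      ## residual cargo carried by the remnant
      for (tr in ps$accessory)
        add("moron_accessory", tr, jig(220L), "+", paste0("accessory: ", tr))
    }
    if (!ps$remnant) {
      ## packaging ----------------------------------------------------------
      add("packaging_capsid", "", jig(170L), "+", "terminase small subunit")
      if (!"missing_terminase_or_portal" %in% ps$defects) {
        add("packaging_capsid", "terminase_large", jig(550L), "+",
            "terminase large subunit")
        add("packaging_capsid", "portal", jig(480L), "+", "portal protein")
      } else {
        add("packaging_capsid", "", jig(380L), "+", "procapsid maturation protease")
      }
      add("packaging_capsid", "major_capsid", jig(400L), "+", "major capsid protein")
      add("connector", "", jig(130L), "+", "head-tail adaptor")
      add("connector", "", jig(115L), "+", "head closure protein")

      ## accessory cargo (between packaging and tail) -----------------------
      for (tr in ps$accessory)
        add("moron_accessory", tr, jig(220L), "+", paste0("accessory: ", tr))

      ## tail ---------------------------------------------------------------
      if (ps$morphology == "podovirus") {
        add("tail", "baseplate_or_fiber", jig(350L), "+", "baseplate wedge subunit")
      } else if (ps$morphology == "siphovirus") {
        add("tail", "tail_tape_measure", jig(880L), "+", "tail tape measure protein")
        add("tail", "", jig(280L), "+", "tail protein")
      } else if (ps$morphology == "myovirus") {
        add("tail", "tail_sheath", jig(510L), "+", "tail sheath protein")
        add("tail", "", jig(160L), "+", "tail tube protein")
        add("tail", "tail_tape_measure", jig(880L), "+", "tail tape measure protein")
        add("tail", "baseplate_or_fiber", jig(350L), "+", "baseplate wedge subunit")
      }

      ## lysis --------------------------------------------------------------
      add("lysis", "", jig(120L), "+", "holin")
      add("lysis", "", jig(280L), "+", "endolysin")
      if ("misoriented_late_orf" %in% ps$defects) {
        add("moron_accessory", "reverse_transcriptase_maturase", jig(430L), "-",
            "group II intron reverse transcriptase/maturase")
      }
      add("lysis", "", jig(180L), "+", "spanin")
    }
  }
  list(anchors = anchors, proms = proms, sub_bounds = sub_bounds)
}

# Truth accessory classes for planted traits (vocabulary semantics applied
# at plant time).
.truth_accessory_classes <- function(traits, vocab = default_accessory_vocab()) {
  if (!length(traits)) return(character(0))
  cls <- vocab$accessory_class[match(traits, vocab$trait)]
  if ("ta_antitoxin" %in% traits && !"ta_toxin" %in% traits)
    cls[traits == "ta_antitoxin"] <- "anti_phage_defence"
  sort(unique(stats::na.omit(cls)))
}

#' Generate a synthetic annotated chromosome with ground truth
#'
#' Plants `spec$n_prophages` prophages (architectures realized as the gene
#' grammars the typing and defect detectors are defined on), decoy
#' non-phage gene clusters and duplicate/overlapping candidate hits, and
#' returns the chromosome together with promoter calls, candidate hits, a
#' completeness table and a per-element truth record. Deterministic given
#' `seed`.
#'
#' @param spec An [architecture_spec].
#' @param seed Integer RNG seed.
#' @return List: `chromosome`, `promoters`, `hits`, `completeness`,
#'   `truth` (data.frame: one row per planted prophage and decoy).
#' @export
generate_chromosome <- function(spec = architecture_spec(), seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  set.seed(seed)
  pspecs <- spec$prophages
  if (is.null(pspecs) && spec$n_prophages > 0L)
    pspecs <- lapply(seq_len(spec$n_prophages), function(i) .sample_prophage_spec())

  pos <- 1L
  orfs <- list(); proms <- list(); truth <- list(); hits <- list()
  comp <- list(); regions <- list()

  gap_draw <- function() as.integer(stats::runif(1, spec$gap_mean * 0.5,
                                                 spec$gap_mean * 1.5))

  # interleave prophages and decoys along the chromosome
  kinds <- c(rep("phage", length(pspecs)), rep("decoy", spec$n_decoys))
  if (length(kinds)) kinds <- sample(kinds)
  ip <- 0L; id <- 0L
  for (k in kinds) {
    pos <- pos + gap_draw()
    if (k == "phage") {
      ip <- ip + 1L
      ps <- pspecs[[ip]]
      nm <- sprintf("sp%02d", ip)
      built <- .build_prophage_anchors(ps)
      need <- sum(vapply(built$anchors, function(a) a$aa * 3L + 63L,
                         integer(1))) + 240L
      out <- .layout_region(nm, pos, pos + need - 1L, ps$packaging_strand,
                            built$anchors, built$proms)
      st <- min(out$orfs$start); en <- max(out$orfs$end)
      orfs[[nm]] <- out$orfs
      if (!is.null(out$promoters)) proms[[nm]] <- out$promoters
      regions[[nm]] <- prophage_region(nm, "synthetic", st, en,
                                       packaging_strand = ps$packaging_strand,
                                       orfs = validate_orf_table(
                                         out$orfs[setdiff(names(out$orfs), "region")]),
                                       completeness = ps$completeness)
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = "synthetic", start = st, end = en, source = "planted",
        stringsAsFactors = FALSE)
      comp[[nm]] <- data.frame(region = nm, completeness = ps$completeness,
                               stringsAsFactors = FALSE)
      sub_str <- ""
      if (!is.null(built$sub_bounds)) {
        ids <- out$orfs$id
        # anchor numbering equals canonical position; map to ids
        nums <- as.integer(sub("^.*_orf", "", ids))
        sub_str <- paste(vapply(built$sub_bounds, function(b) {
          paste(ids[match(b, nums)], collapse = ":")
        }, character(1)), collapse = ",")
      }
      lys_truth <- if (ps$lysogeny_type == "none") "undetermined" else ps$lysogeny_type
      geom_truth <- if (isTRUE(ps$promoters) && ps$lysogeny_type != "none" &&
                        !"mosaic_region" %in% ps$defects)
        ps$promoter_geometry else "none"
      truth[[length(truth) + 1L]] <- data.frame(
        name = nm, kind = "prophage", confirmed = TRUE,
        completeness = ps$completeness,
        category = categorize(ps$completeness, ps$defects),
        defects = paste(sort(ps$defects), collapse = ","),
        morphology = ps$morphology, lysogeny = lys_truth,
        promoter_geometry = geom_truth,
        accessory = paste(.truth_accessory_classes(c(ps$accessory,
          if (any(c("intron_split_gene", "misoriented_late_orf") %in% ps$defects))
            "reverse_transcriptase_maturase")), collapse = ","),
        sub_regions = sub_str, stringsAsFactors = FALSE)
      pos <- en
    } else {
      id <- id + 1L
      nm <- sprintf("dec%02d", id)
      n_orf <- sample(6:10, 1L)
      anchors <- lapply(seq_len(n_orf), function(j)
        .mk(j, sample(c("other", "unknown"), 1L), "", sample(150:500, 1L),
            sample(c("+", "-"), 1L), "housekeeping gene"))
      need <- sum(vapply(anchors, function(a) a$aa * 3L + 63L, integer(1))) + 240L
      out <- .layout_region(nm, pos, pos + need - 1L, "forward", anchors)
      st <- min(out$orfs$start); en <- max(out$orfs$end)
      orfs[[nm]] <- out$orfs
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = "synthetic", start = st, end = en, source = "planted",
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        name = nm, kind = "decoy", confirmed = FALSE,
        completeness = NA_real_, category = NA_character_, defects = "",
        morphology = "", lysogeny = "", promoter_geometry = "",
        accessory = "", sub_regions = "", stringsAsFactors = FALSE)
      pos <- en
    }
  }

  # duplicate/overlapping hits inside randomly chosen prophages
  phage_names <- names(regions)
  if (spec$n_duplicates > 0L && length(phage_names)) {
    for (d in seq_len(spec$n_duplicates)) {
      nm <- sample(phage_names, 1L)
      r <- regions[[nm]]
      w <- r$end - r$start
      a <- r$start + as.integer(stats::runif(1, 0, w * 0.4))
      b <- a + as.integer(stats::runif(1, w * 0.3, w * 0.6))
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = "synthetic", start = a, end = min(b, r$end),
        source = "duplicate", stringsAsFactors = FALSE)
    }
  }

  all_orfs <- if (length(orfs)) do.call(rbind, orfs) else
    cbind(empty_orf_table(), region = character(0))
  rownames(all_orfs) <- NULL
  promoters <- if (length(proms)) do.call(rbind, proms) else
    data.frame(region = character(0), position = integer(0),
               strand = character(0), score = numeric(0))
  rownames(promoters) <- NULL
  chrom <- annotated_chromosome("synthetic", all_orfs, regions,
                                length = pos + 10000L)
  list(chromosome = chrom, promoters = promoters,
       hits = do.call(rbind, hits),
       completeness = if (length(comp)) do.call(rbind, comp) else
         data.frame(region = character(0), completeness = numeric(0)),
       truth = do.call(rbind, truth))
}
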