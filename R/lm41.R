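## The packaged LM41 study fixture: an annotation-level encoding of the
## 15-prophage poly-lysogen chromosome (plus the five phi13 sub-regions),
## with decoy candidate hits, promoter calls, completeness scores and a
## synthetic DNase-protection qPCR panel. Gene architectures follow the
## published region characteristics; raw coordinates of individual ORFs and
## all Cq replicate values are synthetic (the study prints neither), and
## are constrained only by the printed sizes, orderings and relationships.

# Anchor ORF shorthand used by the region blueprints.
.mk <- function(n, cat = "unknown", tr = "", aa = 150L, st = "+",
                pr = "hypothetical protein") {
  list(n = n, cat = cat, tr = tr, aa = as.integer(aa), st = st, pr = pr)
}

# Lay out one region: anchors are given in canonical (lysogeny-to-lysis)
# order and packed from the region start with fixed intergenic gaps; for
# reverse-packaged regions the whole layout is mirrored onto the
# chromosome (coordinates flipped within the span, strands inverted).
# Promoter specs are (after = anchor number, kind = divergent/convergent).
.layout_region <- function(name, start, end, dir, anchors, proms = list(),
                           gap = 60L, lead = 120L) {
  span <- end - start + 1L
  off <- lead
  can <- data.frame(n = integer(0), s = integer(0), e = integer(0))
  for (a in anchors) {
    nt <- a$aa * 3L + 3L
    can <- rbind(can, data.frame(n = a$n, s = off, e = off + nt - 1L))
    off <- off + nt + gap
  }
  if (max(can$e) + lead > span)
    stop("fixture layout for ", name, " exceeds its span (needs ",
         max(can$e) + lead, " of ", span, " bp)")
  orfs <- do.call(rbind, lapply(seq_along(anchors), function(i) {
    a <- anchors[[i]]
    if (dir == "forward") {
      cs <- start + can$s[i]; ce <- start + can$e[i]; st <- a$st
    } else {
      cs <- end - can$e[i]; ce <- end - can$s[i]
      st <- if (a$st == "+") "-" else "+"
    }
    data.frame(id = sprintf("%s_orf%d", name, a$n), start = cs, end = ce,
               strand = st, category = a$cat, traits = a$tr, product = a$pr,
               length_aa = a$aa, region = name, stringsAsFactors = FALSE)
  }))
  prom_rows <- list()
  for (p in proms) {
    i <- match(p$after, can$n)
    if (is.na(i)) stop("promoter anchor ", p$after, " not found in ", name)
    p1 <- can$e[i] + 15L; p2 <- can$e[i] + 42L
    st <- switch(p$kind, divergent = c("-", "+"), convergent = c("+", "-"),
                 stop("unknown promoter kind ", p$kind))
    sc <- c(0.93, 0.95)
    if (dir == "forward") {
      pos <- start + c(p1, p2); strands <- st
    } else {
      pos <- end - c(p1, p2)
      strands <- ifelse(st == "+", "-", "+")
    }
    prom_rows[[length(prom_rows) + 1L]] <- data.frame(
      region = name, position = pos, strand = strands, score = sc,
      stringsAsFactors = FALSE)
    # a sub-threshold call in the same neighbourhood, to exercise filtering
    prom_rows[[length(prom_rows) + 1L]] <- data.frame(
      region = name,
      position = if (dir == "forward") start + p1 + 6L else end - p1 - 6L,
      strand = "+", score = 0.55, stringsAsFactors = FALSE)
  }
  list(orfs = orfs,
       promoters = if (length(prom_rows)) do.call(rbind, prom_rows) else NULL)
}

# Shared blocks.
.blk_cicro <- function(int_aa = 420L, ci_aa = 230L, cro_aa = 70L) list(
  .mk(1, "integration_excision", "integrase", int_aa, "+", "integrase"),
  .mk(2, "transcription_regulation", "hth_regulator", ci_aa, "-", "CI-like repressor"),
  .mk(3, "transcription_regulation", "hth_regulator", cro_aa, "+", "Cro-like regulator"))
.blk_repl <- function(n0 = 5L) list(
  .mk(n0, "replication", "helicase", 450L, "+", "replicative DNA helicase"),
  .mk(n0 + 1L, "replication", "", 320L, "+", "DNA primase"),
  .mk(n0 + 2L, "replication", "dna_polymerase", 600L, "+", "DNA polymerase"))
.blk_pack <- function(n0 = 20L) list(
  .mk(n0, "packaging_capsid", "", 170L, "+", "terminase small subunit"),
  .mk(n0 + 1L, "packaging_capsid", "terminase_large", 550L, "+", "terminase large subunit"),
  .mk(n0 + 2L, "packaging_capsid", "portal", 480L, "+", "portal protein"),
  .mk(n0 + 3L, "packaging_capsid", "major_capsid", 400L, "+", "major capsid protein"),
  .mk(n0 + 4L, "connector", "", 130L, "+", "head-tail adaptor"),
  .mk(n0 + 5L, "connector", "", 115L, "+", "head closure protein"))
.blk_lysis <- function(n0) list(
  .mk(n0, "lysis", "", 120L, "+", "holin"),
  .mk(n0 + 1L, "lysis", "", 280L, "+", "endolysin"))

# Region blueprints: anchors in canonical order.
.lm41_blueprints <- function() {
  bp <- list()

  bp$phi1 <- list(
    dir = "forward", proms = list(list(after = 2, kind = "divergent")),
    anchors = c(.blk_cicro(420L),
      list(.mk(4, "moron_accessory", "dextransucrase", 310L, "+", "dextransucrase")),
      .blk_repl(5L), .blk_pack(20L),
      list(.mk(52, "moron_accessory", "anti_crispr", 95L, "+", "anti-CRISPR protein"),
           .mk(61, "tail", "baseplate_or_fiber", 350L, "+", "baseplate wedge subunit")),
      .blk_lysis(62L),
      list(.mk(64, "unknown", "", 2660L, "+",
               "hypothetical protein (large polyvalent-like)"))))

  bp$phi2 <- list(
    dir = "forward", proms = list(list(after = 5, kind = "divergent")),
    anchors = c(list(
      .mk(1, "integration_excision", "integrase", 410L, "+", "integrase"),
      .mk(2), .mk(3),
      .mk(4, "transcription_regulation", "imma_metallopeptidase", 210L, "-",
          "ImmA/IrrE family metallo-endopeptidase"),
      .mk(5, "transcription_regulation", "hth_regulator", 140L, "-", "ImmR-like repressor"),
      .mk(6, "transcription_regulation", "hth_regulator", 120L, "+", "HTH transcriptional regulator")),
      .blk_repl(7L), .blk_pack(20L),
      list(.mk(51, "moron_accessory", "reverse_transcriptase_maturase", 420L, "+",
               "group II intron reverse transcriptase/maturase"),
           .mk(65, "tail", "tail_tape_measure", 850L, "+", "tail tape measure protein"),
           .mk(66, "tail", "tail_tape_measure", 600L, "+", "tail tape measure protein"),
           .mk(67, "tail", "", 300L, "+", "tail protein")),
      .blk_lysis(68L)))

  bp$phi3 <- list(
    dir = "forward", proms = list(list(after = 3, kind = "divergent")),
    anchors = c(list(
      .mk(1, "integration_excision", "integrase", 199L, "+", "integrase N-terminal fragment"),
      .mk(2, "integration_excision", "integrase", 120L, "+",
          "integrase C-terminal fragment (frameshift)"),
      .mk(3, "transcription_regulation", "hth_regulator", 225L, "-", "CI-like repressor"),
      .mk(4, "transcription_regulation", "hth_regulator", 68L, "+", "Cro-like regulator")),
      .blk_repl(5L),
      list(.mk(13, "moron_accessory", "", 290L, "+",
               "formylglycine-generating sulfatase enzyme"),
           .mk(25, "moron_accessory", "", 270L, "+", "metal-dependent phosphohydrolase")),
      .blk_pack(30L),
      list(.mk(55, "tail", "tail_sheath", 520L, "+", "tail sheath protein"),
           .mk(57, "tail", "", 160L, "+", "tail tube protein"),
           .mk(59, "tail", "tail_tape_measure", 900L, "+", "tail tape measure protein"),
           .mk(64, "tail", "baseplate_or_fiber", 340L, "+", "baseplate wedge subunit"),
           .mk(71, "moron_accessory", "", 285L, "+",
               "formylglycine-generating sulfatase enzyme"),
           .mk(73, "moron_accessory", "avd_dgr", 130L, "+", "Avd protein of DGR"),
           .mk(76, "moron_accessory", "reverse_transcriptase_maturase", 410L, "+",
               "reverse transcriptase/maturase family protein")),
      .blk_lysis(77L)))

  bp$phi4 <- list(
    dir = "forward", proms = list(list(after = 2, kind = "divergent")),
    anchors = c(.blk_cicro(415L, 228L, 72L),
      .blk_repl(5L), .blk_pack(20L),
      list(.mk(55, "moron_accessory", "anti_crispr", 92L, "+", "anti-CRISPR protein"),
           .mk(63, "tail", "baseplate_or_fiber", 350L, "+", "baseplate wedge subunit")),
      .blk_lysis(64L),
      list(.mk(67, "unknown", "", 2650L, "+",
               "hypothetical protein (large polyvalent-like)"))))

  bp$phi5 <- list(
    dir = "reverse", proms = list(list(after = 13, kind = "convergent")),
    anchors = c(list(
      .mk(1, "moron_accessory", "amidoligase", 280L, "+", "amidoligase enzyme"),
      .mk(2), .mk(3),
      .mk(4, "moron_accessory", "rm_hsdR", 1000L, "+", "type I RM restriction subunit R"),
      .mk(5, "moron_accessory", "rm_hsdS", 420L, "+", "type I RM DNA specificity subunit"),
      .mk(6, "integration_excision", "integrase", 165L, "-", "putative integrase fragment"),
      .mk(7, "integration_excision", "integrase", 167L, "+", "putative integrase fragment"),
      .mk(8, "moron_accessory", "rm_hsdS", 410L, "+", "type I RM DNA specificity subunit"),
      .mk(9, "moron_accessory", "rm_hsdS", 400L, "+", "type I RM DNA specificity subunit"),
      .mk(11, "moron_accessory", "rm_hsdM", 530L, "+", "type I RM methyltransferase subunit"),
      .mk(12, "transcription_regulation", "imma_metallopeptidase", 190L, "-",
          "IrrE N-terminal-like metallopeptidase"),
      .mk(13, "transcription_regulation", "hth_regulator", 135L, "-", "ImmR-like repressor"),
      .mk(14, "transcription_regulation", "hth_regulator", 118L, "+",
          "HTH transcriptional regulator")),
      .blk_repl(15L),
      list(.mk(21),
           .mk(24, "packaging_capsid", "", 380L, "+", "procapsid maturation protease"),
           .mk(25, "packaging_capsid", "major_capsid", 400L, "+", "major capsid protein"),
           .mk(26, "connector", "", 130L, "+", "head-tail adaptor"),
           .mk(27, "connector", "", 120L, "+", "head closure protein"),
           .mk(33, "moron_accessory", "mom_modification", 240L, "+",
               "Mom-like DNA modification protein"),
           .mk(34, "moron_accessory", "mom_modification", 230L, "+",
               "Mom-like DNA modification protein"),
           .mk(58, "tail", "tail_tape_measure", 900L, "+", "tail tape measure protein"),
           .mk(59, "tail", "", 300L, "+", "tail protein"),
           .mk(60, "moron_accessory", "cm_phosphotransferase", 180L, "+",
               "chloramphenicol phosphotransferase-like protein"),
           .mk(63, "moron_accessory", "ta_toxin", 85L, "+", "toxin SymE, type I TA system")),
      .blk_lysis(65L),
      list(.mk(68, "integration_excision", "recombinase", 420L, "-", "recombinase"),
           .mk(69, "integration_excision", "recombinase", 282L, "+", "recombinase"))))

  bp$phi6 <- list(
    dir = "reverse", proms = list(list(after = 2, kind = "divergent")),
    anchors = c(.blk_cicro(405L, 232L, 69L),
      list(.mk(17, "replication", "helicase", 310L, "+",
               "virulence-associated protein E (DNA helicase), N-terminal part"),
           .mk(20, "moron_accessory", "reverse_transcriptase_maturase", 430L, "+",
               "group II intron reverse transcriptase/maturase"),
           .mk(21, "replication", "helicase", 290L, "+",
               "virulence-associated protein E (DNA helicase), C-terminal part"),
           .mk(22, "replication", "dna_polymerase", 600L, "+", "DNA polymerase"),
           .mk(23, "replication", "", 320L, "+", "DNA primase"),
           .mk(30, "moron_accessory", "paps_reductase", 250L, "+",
               "phosphoadenosine phosphosulfate reductase")),
      .blk_pack(35L),
      list(.mk(52, "tail", "tail_tape_measure", 880L, "+", "tail tape measure protein"),
           .mk(53, "tail", "", 280L, "+", "tail protein")),
      .blk_lysis(55L)))

  bp$phi7 <- list(
    dir = "reverse", proms = list(list(after = 2, kind = "divergent")),
    anchors = c(.blk_cicro(400L, 226L, 71L),
      .blk_repl(5L),
      list(.mk(18, "replication", "", 260L, "+", "DnaC-like helicase loader"))))

  bp$phi8 <- list(
    dir = "reverse", proms = list(),
    anchors = c(list(
      .mk(1, "integration_excision", "integrase", 410L, "+", "integrase")),
      .blk_repl(5L), .blk_pack(20L),
      list(.mk(39, "tail", "tail_sheath", 510L, "+", "tail sheath protein"),
           .mk(41, "tail", "", 160L, "+", "tail tube protein"),
           .mk(47, "tail", "baseplate_or_fiber", 350L, "+", "baseplate wedge subunit"),
           .mk(48, "tail", "baseplate_or_fiber", 340L, "+", "baseplate wedge subunit")),
      .blk_lysis(50L),
      list(.mk(57, "moron_accessory", "reverse_transcriptase_maturase", 415L, "+",
               "group II intron reverse transcriptase/maturase"),
           .mk(60, "moron_accessory", "haemolysin", 320L, "+", "putative haemolysin"))))

  bp$phi9 <- list(
    dir = "reverse", proms = list(list(after = 2, kind = "divergent")),
    anchors = c(.blk_cicro(420L, 230L, 72L),
      .blk_repl(5L),
      list(.mk(27, "moron_accessory", "", 300L, "+", "metal-dependent hydrolase"),
           .mk(48, "moron_accessory", "paps_reductase", 255L, "+",
               "phosphoadenosine phosphosulfate reductase")),
      .blk_pack(60L),
      list(.mk(102, "moron_accessory", "ta_toxin", 140L, "+",
               "endonuclease toxin of TA system"),
           .mk(110, "moron_accessory", "mom_modification", 235L, "+",
               "Mom-like DNA modification protein"),
           .mk(111, "moron_accessory", "darB_antirestriction", 210L, "+",
               "DarB-like antirestriction protein"),
           .mk(124, "moron_accessory", "anti_crispr", 98L, "+", "anti-CRISPR protein"),
           .mk(133, "tail", "tail_tape_measure", 910L, "+", "tail tape measure protein"),
           .mk(134, "tail", "", 300L, "+", "tail protein")),
      .blk_lysis(140L),
      list(.mk(149, "moron_accessory", "haemolysin", 310L, "+",
               "putative haemolysin (CHAP domain)"))))

  bp$phi10 <- list(
    dir = "reverse", proms = list(list(after = 5, kind = "divergent")),
    anchors = c(list(
      .mk(1, "integration_excision", "integrase", 425L, "+", "integrase"),
      .mk(2, "moron_accessory", "ta_antitoxin", 90L, "+", "HicB-like antitoxin"),
      .mk(3, "moron_accessory", "ta_toxin", 60L, "+", "HicA toxin"),
      .mk(5, "transcription_regulation", "hth_regulator", 230L, "-", "CI-like repressor"),
      .mk(6, "transcription_regulation", "hth_regulator", 70L, "+", "Cro-like regulator")),
      .blk_repl(8L), .blk_pack(20L),
      list(.mk(49, "moron_accessory", "restriction_alleviation", 150L, "+",
               "Lar-like restriction alleviation protein"),
           .mk(71, "tail", "tail_sheath", 505L, "+", "tail sheath protein"),
           .mk(73, "tail", "", 150L, "+", "tail tube protein"),
           .mk(75, "tail", "tail_tape_measure", 890L, "+", "tail tape measure protein"),
           .mk(78, "tail", "", 250L, "+", "tail protein"),
           .mk(80, "tail", "baseplate_or_fiber", 350L, "+", "baseplate wedge subunit"),
           .mk(81, "tail", "baseplate_or_fiber", 330L, "+", "baseplate wedge subunit")),
      .blk_lysis(85L)))

  bp$phi11 <- list(
    dir = "reverse", proms = list(list(after = 2, kind = "divergent")),
    anchors = c(.blk_cicro(410L, 229L, 73L),
      .blk_repl(5L), .blk_pack(20L),
      list(.mk(53, "tail", "tail_tape_measure", 870L, "+", "tail tape measure protein"),
           .mk(54, "tail", "", 290L, "+", "tail protein")),
      .blk_lysis(60L)))

  bp$phi12 <- list(
    dir = "forward", proms = list(list(after = 5, kind = "convergent")),
    anchors = c(list(
      .mk(1, "integration_excision", "integrase", 415L, "+", "integrase"),
      .mk(2), .mk(3),
      .mk(4, "transcription_regulation", "imma_metallopeptidase", 205L, "-",
          "ImmA/IrrE family metallo-endopeptidase"),
      .mk(5, "transcription_regulation", "hth_regulator", 138L, "-", "ImmR-like repressor"),
      .mk(6, "transcription_regulation", "hth_regulator", 122L, "+",
          "HTH transcriptional regulator")),
      .blk_repl(8L), .blk_pack(40L),
      list(.mk(63, "tail", "tail_tape_measure", 900L, "+", "tail tape measure protein"),
           .mk(64, "tail", "", 280L, "+", "tail protein"),
           .mk(76, "lysis", "", 120L, "+", "holin"),
           .mk(77, "lysis", "", 260L, "+", "endolysin"),
           .mk(78, "moron_accessory", "reverse_transcriptase_maturase", 430L, "-",
               "group II intron reverse transcriptase/maturase"),
           .mk(79, "lysis", "", 180L, "+", "spanin"),
           .mk(80, "lysis", "", 140L, "+", "lysis accessory protein"))))

  bp$phi14 <- list(
    dir = "forward", proms = list(list(after = 2, kind = "divergent")),
    anchors = c(.blk_cicro(418L, 231L, 71L),
      .blk_repl(5L), .blk_pack(20L),
      list(.mk(40, "moron_accessory", "paps_reductase", 250L, "+",
               "phosphoadenosine phosphosulfate reductase"),
           .mk(42, "moron_accessory", "paps_reductase", 245L, "+",
               "phosphoadenosine phosphosulfate reductase"),
           .mk(57, "tail", "tail_sheath", 510L, "+", "tail sheath protein"),
           .mk(59, "tail", "", 155L, "+", "tail tube protein"),
           .mk(61, "tail", "tail_tape_measure", 885L, "+", "tail tape measure protein"),
           .mk(63, "tail", "", 240L, "+", "tail protein"),
           .mk(65, "tail", "baseplate_or_fiber", 350L, "+", "baseplate wedge subunit")),
      .blk_lysis(67L),
      list(.mk(73, "moron_accessory", "reverse_transcriptase_maturase", 420L, "+",
               "group II intron reverse transcriptase/maturase"))))

  bp$phi15 <- list(
    dir = "forward", proms = list(list(after = 2, kind = "divergent")),
    anchors = c(.blk_cicro(417L, 233L, 74L),
      .blk_repl(5L), .blk_pack(20L),
      list(.mk(63, "tail", "tail_sheath", 515L, "+", "tail sheath protein"),
           .mk(65, "tail", "", 150L, "+", "tail tube protein"),
           .mk(68, "tail", "tail_tape_measure", 875L, "+", "tail tape measure protein"),
           .mk(70, "tail", "", 260L, "+", "tail protein"),
           .mk(72, "tail", "baseplate_or_fiber", 345L, "+", "baseplate wedge subunit")),
      .blk_lysis(74L)))

  bp
}

# phi13 sub-region blueprints (all forward); keyed by sub-span name.
.lm41_phi13_blueprints <- function() {
  list(
    phi13a = list(proms = list(), anchors = list(
      .mk(1, "replication", "", 300L, "+", "replicative ATPase"),
      .mk(2, "replication", "helicase", 450L, "+", "replicative DNA helicase"),
      .mk(3, "replication", "dna_polymerase", 600L, "+", "DNA polymerase"),
      .mk(5, "moron_accessory", "", 200L, "+", "acetyltransferase"),
      .mk(20, "packaging_capsid", "", 180L, "+", "terminase small subunit"),
      .mk(21, "packaging_capsid", "terminase_large", 545L, "+", "terminase large subunit"),
      .mk(22, "packaging_capsid", "portal", 470L, "+", "portal protein"),
      .mk(23, "packaging_capsid", "major_capsid", 405L, "+", "major capsid protein"),
      .mk(24, "connector", "", 130L, "+", "head-tail adaptor"),
      .mk(25, "connector", "", 120L, "+", "head closure protein"),
      .mk(28, "moron_accessory", "ta_toxin", 95L, "+", "SymE-like type I toxin"),
      .mk(35, "moron_accessory", "amidoligase", 260L, "+", "amidoligase enzyme"),
      .mk(37, "moron_accessory", "amidoligase", 255L, "+", "amidoligase enzyme"),
      .mk(39, "moron_accessory", "ggct", 180L, "+", "gamma-glutamyl cyclotransferase"),
      .mk(50, "moron_accessory", "ta_antitoxin", 100L, "+", "RelB/DinJ family antitoxin"),
      .mk(51, "moron_accessory", "ta_toxin", 95L, "+", "ParE family toxin"),
      .mk(65, "tail", "tail_tape_measure", 870L, "+", "tail tape measure protein"),
      .mk(66, "tail", "", 300L, "+", "tail protein"),
      .mk(70, "lysis", "", 120L, "+", "holin"),
      .mk(71, "lysis", "", 280L, "+", "endolysin"),
      .mk(78, "integration_excision", "recombinase", 420L, "+", "site-specific recombinase"),
      .mk(79, "integration_excision", "recombinase", 300L, "+", "recombinase"))),
    phi13b = list(proms = list(list(after = 80, kind = "divergent")), anchors = list(
      .mk(80, "transcription_regulation", "hth_regulator", 168L, "-", "C-like repressor"),
      .mk(81, "unknown", "", 120L, "+", "hypothetical protein"),
      .mk(82, "transcription_regulation", "hth_regulator", 51L, "+", "Ner-like regulator"),
      .mk(83, "replication", "transposase_mu", 480L, "+", "Mu-like transposase"),
      .mk(84, "replication", "", 310L, "+", "DNA transposition protein"),
      .mk(95, "other", "", 250L, "+", "transposase DDE domain protein"),
      .mk(96, "other", "", 240L, "+", "IS4 family transposase"),
      .mk(98, "moron_accessory", "reverse_transcriptase_maturase", 400L, "+",
          "reverse transcriptase (RNA-dependent DNA polymerase)"),
      .mk(104, "moron_accessory", "ta_antitoxin", 98L, "+", "antitoxin of a TA module"),
      .mk(105, "moron_accessory", "rm_hsdM", 520L, "+", "type I RM methyltransferase (HsdM)"),
      .mk(106, "moron_accessory", "rm_hsdS", 430L, "+", "type I RM specificity subunit (HsdS)"),
      .mk(107, "moron_accessory", "rm_type3", 980L, "+",
          "type III restriction-modification subunit"))),
    phi13c = list(proms = list(), anchors = list(
      .mk(110, "replication", "", 280L, "+", "replication initiation ATPase"),
      .mk(111, "replication", "", 260L, "+", "replication protein"),
      .mk(115, "other", "", 230L, "+", "DNA transcription initiation protein"),
      .mk(117, "unknown", "", 150L, "+", "hypothetical protein"))),
    phi13d = list(proms = list(list(after = 129, kind = "divergent")), anchors = c(list(
      .mk(129, "transcription_regulation", "hth_regulator", 197L, "-", "C repressor")),
      lapply(130:138, function(k) .mk(k, "unknown", "", 110L, "+", "hypothetical protein")),
      list(
      .mk(139, "transcription_regulation", "hth_regulator", 76L, "+",
          "Ner-like DNA binding protein"),
      .mk(140, "replication", "transposase_mu", 480L, "+", "Mu transposase"),
      .mk(141, "replication", "", 300L, "+", "DNA transposition protein"),
      .mk(149, "moron_accessory", "paps_reductase", 255L, "+",
          "phosphoadenosine phosphosulfate reductase"),
      .mk(155, "moron_accessory", "ta_antitoxin", 96L, "+", "antitoxin from a TA system"),
      .mk(158, "transcription_regulation", "", 130L, "+", "Mor-family transcription activator"),
      .mk(164, "packaging_capsid", "terminase_large", 540L, "+", "terminase large subunit"),
      .mk(165, "packaging_capsid", "", 175L, "+", "terminase small subunit"),
      .mk(166, "packaging_capsid", "", 360L, "+", "phage Mu protein F-like protein"),
      .mk(167, "packaging_capsid", "portal", 460L, "+", "Mu-like prophage I protein (portal)"),
      .mk(169, "packaging_capsid", "major_capsid", 410L, "+", "major head subunit gpT"),
      .mk(174, "tail", "baseplate_or_fiber", 345L, "+", "baseplate wedge subunit"),
      .mk(176, "tail", "", 200L, "+", "tail protein"),
      .mk(180, "tail", "tail_sheath", 515L, "+", "tail sheath protein"),
      .mk(182, "tail", "", 160L, "+", "tail tube protein"),
      .mk(184, "tail", "tail_tape_measure", 880L, "+", "tail tape measure protein"),
      .mk(185, "tail", "tail_tape_measure", 590L, "+", "tail tape measure protein"),
      .mk(188, "lysis", "", 120L, "+", "holin"),
      .mk(189, "lysis", "", 275L, "+", "endolysin")))),
    phi13e = list(proms = list(), anchors = list(
      .mk(200, "replication", "", 290L, "+", "replicative helicase loader"),
      .mk(201, "replication", "helicase", 440L, "+", "replicative DNA helicase"),
      .mk(206, "moron_accessory", "amidoligase", 250L, "+", "amidoligase enzyme"),
      .mk(208, "moron_accessory", "amidoligase", 245L, "+", "amidoligase enzyme"),
      .mk(210, "moron_accessory", "ggct", 175L, "+", "gamma-glutamyl cyclotransferase"),
      .mk(219, "packaging_capsid", "major_capsid", 400L, "+", "major capsid protein"),
      .mk(220, "connector", "", 125L, "+", "head-tail connector"),
      .mk(227, "tail", "tail_tape_measure", 860L, "+", "tail tape measure protein")))
  )
}

#' Printed region coordinate table of the LM41 fixture
#'
#' The 15 top-level regions plus the five phi13 sub-regions with their
#' chromosome coordinates, packaging strand and published size. For phi4
#' the published size (41,690 bp) disagrees with the size implied by its
#' coordinates (41,886 bp); both are retained and the inconsistency is
#' flagged in the `size_consistent` column.
#'
#' @return Data.frame: region, start, end, packaging_strand, size_printed,
#'   size_implied, size_consistent, parent.
#' @export
lm41_table1 <- function() {
  df <- data.frame(
    region = c("phi1", "phi2", "phi3", "phi4", "phi5", "phi6", "phi7", "phi8",
               "phi9", "phi10", "phi11", "phi12", "phi13", "phi13a", "phi13b",
               "phi13c", "phi13d", "phi13e", "phi14", "phi15"),
    start = c(194517L, 301574L, 1072300L, 1281572L, 3073910L, 3448526L,
              3885600L, 3846360L, 3997064L, 4120662L, 5193058L, 6190004L,
              6632999L, 6632999L, 6684149L, 6706413L, 6715266L, 6750116L,
              7473893L, 7532147L),
    end = c(235362L, 342165L, 1120599L, 1323457L, 3122116L, 3490199L,
            3901899L, 3885591L, 4063629L, 4165801L, 5226919L, 6237536L,
            6769447L, 6684039L, 6706426L, 6714990L, 6749468L, 6769447L,
            7529677L, 7579680L),
    packaging_strand = c("forward", "forward", "forward", "forward", "reverse",
                         "reverse", "reverse", "reverse", "reverse", "reverse",
                         "reverse", "forward", "forward", "forward", "forward",
                         "forward", "forward", "forward", "forward", "forward"),
    size_printed = c(40846L, 40592L, 48300L, 41690L, 48207L, 41674L, 16300L,
                     39232L, 66566L, 45140L, 33862L, 47533L, 136449L, 51041L,
                     22278L, 8578L, 34203L, 19332L, 55785L, 47534L),
    parent = c(rep(NA_character_, 13), rep("phi13", 5), NA_character_,
               NA_character_),
    stringsAsFactors = FALSE
  )
  df$size_implied <- df$end - df$start + 1L
  df$size_consistent <- df$size_implied == df$size_printed
  df
}

#' Completeness scores of the LM41 fixture regions
#'
#' Scores of 100 and the phi13 sub-region scores (99.65, 49.4, 18.8, 94.11,
#' 41.2) are the published values; scores inside the open bands (>60-<100
#' and <60) are synthetic values consistent with the published band
#' membership.
#'
#' @return Data.frame: region, completeness.
#' @export
lm41_completeness <- function() {
  data.frame(
    region = c("phi1", "phi2", "phi3", "phi4", "phi5", "phi6", "phi7", "phi8",
               "phi9", "phi10", "phi11", "phi12", "phi13", "phi14", "phi15",
               "phi13a", "phi13b", "phi13c", "phi13d", "phi13e"),
    completeness = c(100, 92.4, 100, 100, 100, 100, 41.5, 78.9, 52.7, 100,
                     88.2, 100, 100, 83.6, 100, 99.65, 49.4, 18.8, 94.11, 41.2),
    stringsAsFactors = FALSE)
}

# Synthetic qPCR replicate panel: untreated means and treated-minus-
# untreated deltas; the four released phages carry the published deltas
# (phi1 5.11 < phi4 8.06 < phi2 8.37 < phi10 8.69); all other targets sit
# near their NTC; phi13e falls at/above its NTC (undetected); the s10p
# housekeeper is degraded below its NTC.
.lm41_qpcr_design <- function() {
  data.frame(
    target = c("s10p", "phi1", "phi2", "phi3", "phi4", "phi5", "phi6", "phi7",
               "phi8", "phi9", "phi10", "phi11", "phi12", "phi13a", "phi13b",
               "phi13c", "phi13d", "phi13e", "phi14", "phi15"),
    untreated = c(15.0, 22.4, 22.8, 24.0, 23.0, 23.6, 24.2, 24.5, 24.1, 25.0,
                  23.3, 24.8, 24.3, 24.6, 25.2, 25.5, 24.9, 26.0, 25.1, 24.4),
    delta = c(21.5, 5.11, 8.37, 10.2, 8.06, 11.4, 10.8, 12.1, 11.9, 10.5,
              8.69, 12.4, 11.2, 11.8, 13.0, 12.7, 11.5, 12.6, 12.9, 12.2),
    ntc = c(35.0, 36.0, 36.2, 37.0, 36.5, 37.2, 37.5, 37.8, 37.4, 37.1, 36.8,
            37.9, 37.3, 37.6, 38.8, 38.9, 37.7, 38.0, 38.5, 38.1),
    stringsAsFactors = FALSE)
}

#' Synthetic Cq replicate table of the LM41 fixture
#'
#' Three technical replicates per target per condition plus one NTC well,
#' on a treated/untreated/NTC design with a 40-cycle cap.
#'
#' @return Data.frame: target, condition, replicate, cq.
#' @export
lm41_qpcr_panel <- function() {
  des <- .lm41_qpcr_design()
  rows <- lapply(seq_len(nrow(des)), function(i) {
    un <- des$untreated[i]; tr <- un + des$delta[i]
    rbind(
      data.frame(target = des$target[i], condition = "untreated",
                 replicate = 1:3, cq = c(un - 0.1, un, un + 0.1)),
      data.frame(target = des$target[i], condition = "treated",
                 replicate = 1:3, cq = c(tr - 0.1, tr, tr + 0.1)),
      data.frame(target = des$target[i], condition = "ntc",
                 replicate = 1L, cq = des$ntc[i]))
  })
  do.call(rbind, rows)
}

#' Build the packaged LM41 fixture bundle
#'
#' Assembles, entirely in code, the annotation-level fixture used by the
#' tests and the acceptance script: the annotated chromosome (15 prophage
#' regions, 5 phi13 sub-regions, 8 decoy gene clusters), the 29 candidate
#' hits (15 region hits, 6 duplicate/overlapping hits, 8 decoy hits),
#' promoter calls, completeness scores, the synthetic qPCR panel, the
#' region coordinate table and the expected per-region characterization.
#'
#' @return A list with elements `chromosome`, `hits`, `completeness`,
#'   `promoters`, `qpcr`, `table1`, `expected`, `genome_size`.
#' @export
build_lm41_fixture <- function() {
  tab <- lm41_table1()
  bps <- .lm41_blueprints()
  orfs <- list(); proms <- list()

  for (nm in names(bps)) {
    row <- tab[tab$region == nm, ]
    out <- .layout_region(nm, row$start, row$end, bps[[nm]]$dir,
                          bps[[nm]]$anchors, bps[[nm]]$proms)
    orfs[[nm]] <- out$orfs
    if (!is.null(out$promoters)) proms[[nm]] <- out$promoters
  }

  # phi13: sub-regions laid out inside their own printed spans, all ORFs
  # labelled phi13 (the sub-regions are derived views).
  for (sub in names(.lm41_phi13_blueprints())) {
    row <- tab[tab$region == sub, ]
    b <- .lm41_phi13_blueprints()[[sub]]
    out <- .layout_region("phi13", row$start, row$end, "forward",
                          b$anchors, b$proms)
    orfs[[sub]] <- out$orfs
    if (!is.null(out$promoters)) proms[[sub]] <- out$promoters
  }

  # decoy gene clusters: housekeeping-like content, no phage modules
  decoy_pos <- c(450000L, 700000L, 900000L, 2000000L, 2500000L, 4500000L,
                 5600000L, 7000000L)
  decoy_products <- c("ABC transporter permease", "MFS transporter",
                      "two-component sensor kinase", "response regulator",
                      "glycoside hydrolase", "aminotransferase",
                      "ribosomal protein paralogue", "cell wall hydrolase")
  for (k in seq_along(decoy_pos)) {
    nm <- sprintf("decoy%d", k)
    anchors <- lapply(1:8, function(j)
      .mk(j, c("other", "unknown")[(j %% 2L) + 1L], "", 250L,
          c("+", "-")[(j %% 2L) + 1L], decoy_products[(j + k) %% 8L + 1L]))
    out <- .layout_region(nm, decoy_pos[k], decoy_pos[k] + 7999L, "forward",
                          anchors)
    orfs[[nm]] <- out$orfs
  }

  all_orfs <- do.call(rbind, orfs)
  rownames(all_orfs) <- NULL
  promoters <- do.call(rbind, proms)
  rownames(promoters) <- NULL

  # regions: printed spans + packaging strands; sub-regions carved from
  # phi13 by coordinates; decoys get envelope regions.
  regions <- list()
  for (i in seq_len(nrow(tab))) {
    nm <- tab$region[i]
    lab <- if (!is.na(tab$parent[i])) tab$parent[i] else nm
    sub <- all_orfs[all_orfs$region == lab &
                    all_orfs$start >= tab$start[i] &
                    all_orfs$end <= tab$end[i], , drop = FALSE]
    regions[[nm]] <- prophage_region(
      nm, "LM41", tab$start[i], tab$end[i],
      packaging_strand = tab$packaging_strand[i],
      orfs = validate_orf_table(sub[setdiff(names(sub), "region")]),
      completeness = lm41_completeness()$completeness[
        match(nm, lm41_completeness()$region)])
  }

  chrom <- annotated_chromosome("LM41", all_orfs, regions, length = 7780000L)

  top <- tab[is.na(tab$parent), ]
  hits <- data.frame(chrom = "LM41", start = top$start, end = top$end,
                     source = "finder", stringsAsFactors = FALSE)
  dup <- data.frame(chrom = "LM41",
                    start = c(6632999L, 6715266L, 6750116L, 3997064L,
                              1072300L, 7473893L),
                    end = c(6684039L, 6749468L, 6769447L, 4030000L,
                            1100000L, 7500000L),
                    source = "finder", stringsAsFactors = FALSE)
  dec <- data.frame(chrom = "LM41", start = decoy_pos,
                    end = decoy_pos + 7999L, source = "finder",
                    stringsAsFactors = FALSE)
  hits <- rbind(hits, dup, dec)

  expected <- data.frame(
    region = c("phi1", "phi2", "phi3", "phi4", "phi5", "phi6", "phi7", "phi8",
               "phi9", "phi10", "phi11", "phi12", "phi13", "phi14", "phi15",
               "phi13a", "phi13b", "phi13c", "phi13d", "phi13e"),
    category = c("functional", "unknown", "unknown", "functional", "unknown",
                 "unknown", "defective", "unknown", "defective", "functional",
                 "unknown", "unknown", "unknown", "unknown", "functional",
                 "unknown", "defective", "defective", "unknown", "defective"),
    morphology = c("podovirus", "siphovirus", "myovirus", "podovirus",
                   "siphovirus", "siphovirus", "untyped", "myovirus",
                   "siphovirus", "myovirus", "siphovirus", "siphovirus",
                   "myovirus", "myovirus", "myovirus", "siphovirus", "untyped",
                   "untyped", "myovirus", "siphovirus"),
    lysogeny = c("ci_cro", "immr_imma", "ci_cro", "ci_cro", "immr_imma",
                 "ci_cro", "ci_cro", "undetermined", "ci_cro", "ci_cro",
                 "ci_cro", "immr_imma", "c_ner", "ci_cro", "ci_cro",
                 "undetermined", "c_ner", "undetermined", "c_ner",
                 "undetermined"),
    stringsAsFactors = FALSE)

  list(chromosome = chrom, hits = hits, completeness = lm41_completeness(),
       promoters = promoters, qpcr = lm41_qpcr_panel(), table1 = tab,
       expected = expected, genome_size = 7780000L)
}

#' Write the LM41 fixture bundle to disk
#'
#' Emits the fixture in the package's exchange formats: feature_table TSV,
#' promoter TSV, candidate-hit TSV, completeness TSV, qPCR CSV and the
#' coordinate table.
#'
#' @param dir Output directory (created if needed).
#' @param fixture A fixture bundle from [build_lm41_fixture].
#' @return The directory, invisibly.
#' @export
write_lm41_fixture <- function(dir, fixture = build_lm41_fixture()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(fixture$chromosome, file.path(dir, "annotations.tsv"))
  write_promoters(fixture$promoters, file.path(dir, "promoters.tsv"))
  utils::write.table(fixture$hits, file.path(dir, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$completeness, file.path(dir, "completeness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(fixture$qpcr, file.path(dir, "qpcr.csv"), row.names = FALSE)
  utils::write.table(fixture$table1, file.path(dir, "regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
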