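## Curation: candidate-hit filtering by functional-module conformance,
## defect detection, completeness categorization, mosaic delineation.

# The five canonical functional modules and the ORF categories feeding them.
.module_families <- list(
  lysogeny_control = c("integration_excision", "transcription_regulation"),
  dna_replication  = "replication",
  packaging_capsid = c("packaging_capsid", "connector"),
  tail             = "tail",
  lysis            = "lysis"
)

#' Module names recognized by the curation stage
#' @return Character vector of the five canonical module names.
#' @export
module_names <- function() names(.module_families)

#' Merge overlapping or near-adjacent candidate hits
#'
#' Upstream prophage finders often report several hits inside one prophage;
#' hits that overlap or are separated by at most `max_gap` bp are unioned
#' into a single interval. The result is sorted, non-overlapping, and the
#' operation is idempotent.
#'
#' @param hits Data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `source`; all on one chromosome.
#' @param max_gap Maximum separating gap (bp) still merged. `0` merges only
#'   overlapping or directly abutting hits.
#' @return Data.frame `chrom`, `start`, `end`, `n_hits` sorted by `start`.
#' @export
merge_hits <- function(hits, max_gap = 1000) {
  if (!is.numeric(max_gap) || length(max_gap) != 1L || max_gap < 0)
    stop("max_gap must be a single non-negative number")
  if (!nrow(hits))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_hits = integer(0)))
  if (length(unique(hits$chrom)) > 1L)
    stop("merge_hits expects hits on a single chromosome")
  if (any(hits$end < hits$start) || any(hits$start < 1))
    stop("invalid hit interval: need 1 <= start <= end")
  ir <- IRanges::IRanges(hits$start, hits$end)
  red <- IRanges::reduce(ir, min.gapwidth = max_gap + 1, with.revmap = TRUE)
  data.frame(chrom = hits$chrom[1],
             start = IRanges::start(red), end = IRanges::end(red),
             n_hits = lengths(S4Vectors::mcols(red)$revmap),
             stringsAsFactors = FALSE)
}

# Chains of family ORFs: runs of ORF rows whose category belongs to the
# family, where successive members are separated by at most `gap`
# interspersed non-family ORFs. Returns a list of integer row-index vectors.
.family_chains <- function(orfs, family_cats, gap = 2L) {
  idx <- which(orfs$category %in% family_cats)
  if (!length(idx)) return(list())
  breaks <- which(diff(idx) > gap + 1L)
  split(idx, cumsum(seq_along(idx) %in% (breaks + 1L)))
}

# A chain is module evidence when >=2 of its members share a strand
# (divergent repressor pairs may sit inside a lysogeny cluster), or - for
# the single-gene modules tail and lysis - when it has any member at all.
.qualifying_chains <- function(orfs, module, gap = 2L) {
  chains <- .family_chains(orfs, .module_families[[module]], gap)
  single_ok <- module %in% c("tail", "lysis")
  Filter(function(ch) {
    if (single_ok && length(ch) >= 1L) return(TRUE)
    length(ch) >= 2L && max(table(orfs$strand[ch])) >= 2L
  }, chains)
}

#' Profile the canonical functional modules of a region
#'
#' A module is present when the region carries a cluster of co-oriented ORFs
#' of the module's category family: at least `min_orfs` members with at most
#' `gap` interspersed non-family ORFs between successive members. Tail and
#' lysis accept single-gene evidence (single-tail-gene phages occur).
#'
#' @param region A `prophage_region` (canonicalized internally).
#' @param gap Interspersed-ORF tolerance within a cluster.
#' @return A `module_profile`: named list per module with `present` and
#'   `clusters` (list of supporting ORF-id vectors).
#' @export
assign_modules <- function(region, gap = 2L) {
  region <- .canonical(region)
  orfs <- region$orfs
  profile <- lapply(module_names(), function(m) {
    chains <- .qualifying_chains(orfs, m, gap)
    list(present = length(chains) > 0L,
         clusters = lapply(chains, function(ch) orfs$id[ch]))
  })
  names(profile) <- module_names()
  structure(profile, class = "module_profile", region = region$name)
}

#' @export
print.module_profile <- function(x, ...) {
  pres <- names(x)[vapply(x, function(m) m$present, logical(1))]
  cat("<module_profile>", attr(x, "region"), ":",
      if (length(pres)) paste(pres, collapse = ", ") else "(no modules)", "\n")
  invisible(x)
}

#' Modules present in a profile
#' @param profile A `module_profile`.
#' @return Character vector of present module names.
#' @export
modules_present <- function(profile) {
  names(profile)[vapply(profile, function(m) isTRUE(m$present), logical(1))]
}

#' Confirm a candidate hit as prophage (or prophage remnant)
#'
#' A hit is retained when it conforms to at least one classical functional
#' module; remnants carrying only, say, lysogeny control still pass.
#'
#' @param profile A `module_profile`.
#' @return `TRUE` iff at least one module is present.
#' @export
confirm_phage <- function(profile) {
  length(modules_present(profile)) >= 1L
}

#' Detect architecture defects predicted to affect prophage viability
#'
#' Formalizes the defect taxonomy used for manual demotion of
#' completeness-100 prophages:
#' \itemize{
#' \item `split_integrase`: >=2 adjacent co-oriented integrase-trait ORFs
#'   each shorter than `truncation_aa` (a frameshift-split gene annotated as
#'   consecutive fragments).
#' \item `truncated_integrase`: integrase-trait ORFs present and all shorter
#'   than `truncation_aa`, without the split signature.
#' \item `missing_terminase_or_portal`: a packaging/capsid module with
#'   neither a large-terminase nor a portal gene.
#' \item `intron_split_gene`: a group II intron reverse-transcriptase/
#'   maturase ORF directly between two co-oriented ORFs sharing a helicase
#'   or DNA-polymerase trait (one gene split by the intron insertion).
#' \item `misoriented_late_orf`: an ORF inside a tail or lysis cluster span
#'   running against >=2 flanking cluster members (breaks the polycistronic
#'   late transcript).
#' \item `mosaic_region`: >=2 disjoint lysogeny-control clusters or >=2
#'   disjoint DNA-replication clusters (consecutive/overlapping prophage
#'   remnants).
#' }
#'
#' @param region A `prophage_region` (canonicalized internally).
#' @param truncation_aa Integrase length (aa) below which a fragment is
#'   considered truncated. Default 200 separates observed defective
#'   fragments (165/167 aa) from intact recombinases (282/420 aa).
#' @param gap Cluster gap tolerance, as in [assign_modules].
#' @return List of [defect_flag] objects (possibly empty).
#' @export
detect_defects <- function(region, truncation_aa = 200L, gap = 2L) {
  region <- .canonical(region)
  orfs <- region$orfs
  flags <- list()
  add <- function(kind, evidence) {
    flags[[length(flags) + 1L]] <<- defect_flag(kind, evidence)
  }

  ## integrase defects -----------------------------------------------------
  int_idx <- which(orf_has_trait(orfs, "integrase"))
  if (length(int_idx)) {
    short <- orfs$length_aa[int_idx] < truncation_aa
    split_ev <- character(0)
    if (length(int_idx) >= 2L) {
      for (k in seq_len(length(int_idx) - 1L)) {
        i <- int_idx[k]; j <- int_idx[k + 1L]
        if (j == i + 1L && short[k] && short[k + 1L] &&
            orfs$strand[i] == orfs$strand[j])
          split_ev <- union(split_ev, orfs$id[c(i, j)])
      }
    }
    if (length(split_ev)) {
      add("split_integrase", split_ev)
    } else if (all(short)) {
      add("truncated_integrase", orfs$id[int_idx])
    }
  }

  ## packaging completeness ------------------------------------------------
  pack_chains <- .qualifying_chains(orfs, "packaging_capsid", gap)
  if (length(pack_chains) &&
      !any(orf_has_trait(orfs, "terminase_large")) &&
      !any(orf_has_trait(orfs, "portal"))) {
    add("missing_terminase_or_portal", orfs$id[pack_chains[[1]]])
  }

  ## intron-split gene -----------------------------------------------------
  rt_idx <- which(orf_has_trait(orfs, "reverse_transcriptase_maturase"))
  for (i in rt_idx) {
    if (i <= 1L || i >= nrow(orfs)) next
    l <- i - 1L; r <- i + 1L
    if (orfs$strand[l] != orfs$strand[r]) next
    shares <- any(vapply(c("helicase", "dna_polymerase"), function(tr) {
      orf_has_trait(orfs[l, , drop = FALSE], tr) &&
        orf_has_trait(orfs[r, , drop = FALSE], tr)
    }, logical(1)))
    if (shares) add("intron_split_gene", orfs$id[c(l, i, r)])
  }

  ## misoriented late ORF --------------------------------------------------
  for (m in c("tail", "lysis")) {
    for (ch in .qualifying_chains(orfs, m, gap)) {
      lo <- min(ch); hi <- max(ch)
      members <- intersect(lo:hi, which(orfs$category %in% .module_families[[m]]))
      if (length(members) < 2L) next
      consensus <- names(which.max(table(orfs$strand[members])))
      for (r in lo:hi) {
        if (orfs$strand[r] == consensus) next
        others <- setdiff(members, r)
        nb <- sum(others < r); na <- sum(others > r)
        if (nb >= 1L && na >= 1L && nb + na >= 2L)
          add("misoriented_late_orf", orfs$id[r])
      }
    }
  }

  ## mosaic region ---------------------------------------------------------
  for (m in c("lysogeny_control", "dna_replication")) {
    chains <- .qualifying_chains(orfs, m, gap)
    if (length(chains) >= 2L) {
      add("mosaic_region", vapply(chains, function(ch) orfs$id[ch[1]], character(1)))
      break
    }
  }

  flags
}

#' Categorize a region from its completeness score and defect flags
#'
#' Completeness bands: exactly 100 with no defects is `functional`; below 60
#' (inclusive at the boundary, resolved low) is `defective`; strictly
#' between 60 and 100 is `unknown`. A score of 100 with any defect flag is
#' demoted to `unknown` (viability in doubt pending investigation). A
#' missing score yields `unclassified`.
#'
#' @param completeness Numeric in `[0, 100]` or `NA`.
#' @param defects List of defect flags (or character vector of kinds).
#' @return One of `"functional"`, `"unknown"`, `"defective"`,
#'   `"unclassified"`.
#' @export
categorize <- function(completeness, defects = list()) {
  if (is.na(completeness)) return("unclassified")
  if (!is.numeric(completeness) || completeness < 0 || completeness > 100)
    stop("completeness must lie in [0, 100]")
  n_def <- if (is.character(defects)) length(defects) else length(defects)
  if (completeness <= 60) return("defective")
  if (completeness < 100) return("unknown")
  if (n_def == 0L) "functional" else "unknown"
}

#' Split a mosaic region into consecutive sub-regions
#'
#' Scans the canonical ORF order. A sub-region opens at an ORF marking a
#' likely phage start - a Mu-type transposase, an integrase, or a
#' DNA-replication/ATP-binding gene - and closes at the last consecutive
#' likely-end ORF (tail gene or recombinase) seen before the next opener;
#' when no closer occurred, the boundary falls on the ORF preceding the next
#' opener. Openers consecutive with the opening run (e.g. a transposase
#' followed by its transposition and replication genes) extend the current
#' sub-region rather than starting a new one.
#'
#' @param region A `prophage_region` flagged `mosaic_region` by
#'   [detect_defects] (calling on a non-mosaic region is an error).
#' @param gap Cluster gap tolerance used to verify the mosaic flag.
#' @return List of `prophage_region` sub-regions named
#'   `<region>a`, `<region>b`, ... in genomic order.
#' @export
delineate_mosaic <- function(region, gap = 2L) {
  region <- .canonical(region)
  if (!"mosaic_region" %in% defect_kinds(detect_defects(region, gap = gap)))
    stop("delineate_mosaic called on a region without the mosaic_region defect")
  orfs <- region$orfs
  opener <- orf_has_trait(orfs, "transposase_mu") |
    orf_has_trait(orfs, "integrase") | orfs$category == "replication"
  closer <- orfs$category == "tail" | orf_has_trait(orfs, "recombinase")

  segs <- list()
  open <- FALSE; cur_start <- NA_integer_; last_closer <- NA_integer_
  opening_run <- FALSE
  for (i in seq_len(nrow(orfs))) {
    if (!open) {
      if (opener[i]) {
        open <- TRUE; cur_start <- i; last_closer <- NA_integer_
        opening_run <- TRUE
      }
    } else if (opener[i]) {
      if (!opening_run) {
        end_at <- if (!is.na(last_closer)) last_closer else i - 1L
        segs[[length(segs) + 1L]] <- c(cur_start, end_at)
        cur_start <- i; last_closer <- NA_integer_; opening_run <- TRUE
      }
    } else {
      opening_run <- FALSE
      if (closer[i]) last_closer <- i
    }
  }
  if (open) {
    end_at <- if (!is.na(last_closer)) last_closer else nrow(orfs)
    segs[[length(segs) + 1L]] <- c(cur_start, end_at)
  }

  out <- vector("list", length(segs))
  for (k in seq_along(segs)) {
    rows <- segs[[k]][1]:segs[[k]][2]
    sub <- orfs[rows, , drop = FALSE]
    out[[k]] <- prophage_region(
      name = paste0(region$name, letters[k]), chrom = region$chrom,
      start = min(sub$start), end = max(sub$end),
      packaging_strand = region$packaging_strand,
      orfs = sub)
  }
  out
}

#' Run the full curation stage on a chromosome
#'
#' Merges candidate hits, confirms them by module conformance, detects
#' defects, attaches completeness scores, and categorizes each confirmed
#' region.
#'
#' @param chrom An `annotated_chromosome`.
#' @param hits Candidate-hit data.frame (`chrom`, `start`, `end`, optional
#'   `source`).
#' @param completeness Data.frame `region`, `completeness` (score 0-100), or
#'   `NULL`.
#' @param max_gap Hit-merging gap (bp); use 0 when distinct prophages may
#'   directly abut on the chromosome.
#' @param gap Module-cluster gap tolerance.
#' @param truncation_aa Integrase truncation threshold (aa).
#' @return A list with `report` (one row per merged hit: name, span, length,
#'   confirmed, modules, defects, completeness, category) and `regions`
#'   (named list of confirmed, categorized `prophage_region` objects).
#' @export
curate <- function(chrom, hits, completeness = NULL, max_gap = 1000,
                   gap = 2L, truncation_aa = 200L) {
  merged <- merge_hits(hits, max_gap = max_gap)
  rows <- list(); regions <- list()
  for (i in seq_len(nrow(merged))) {
    st <- merged$start[i]; en <- merged$end[i]
    in_hit <- chrom$orfs$start <= en & chrom$orfs$end >= st
    sub <- chrom$orfs[in_hit, , drop = FALSE]
    labs <- setdiff(unique(sub$region), "")
    name <- if (length(labs)) {
      names(sort(table(sub$region[sub$region != ""]), decreasing = TRUE))[1]
    } else sprintf("region_%02d", i)
    orfs <- validate_orf_table(sub[setdiff(names(sub), "region")])
    reg <- prophage_region(name, chrom$seqid, st, en,
                           packaging_strand = .infer_packaging_strand(orfs),
                           orfs = orfs)
    profile <- assign_modules(reg, gap = gap)
    ok <- confirm_phage(profile)
    comp <- NA_real_
    if (ok && !is.null(completeness) && name %in% completeness$region)
      comp <- completeness$completeness[match(name, completeness$region)]
    defs <- if (ok) detect_defects(reg, truncation_aa = truncation_aa, gap = gap) else list()
    cat_ <- if (ok) categorize(comp, defs) else NA_character_
    if (ok) {
      reg$completeness <- comp; reg$defects <- defs; reg$category <- cat_
      regions[[name]] <- reg
    }
    rows[[i]] <- data.frame(
      name = name, chrom = chrom$seqid, start = st, end = en,
      length = region_length(st, en), n_orfs = nrow(orfs),
      confirmed = ok,
      modules = paste(modules_present(profile), collapse = ","),
      defects = paste(defect_kinds(defs), collapse = ","),
      completeness = comp, category = cat_, stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  list(report = report, regions = regions)
}
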