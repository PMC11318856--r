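## Typing: virion morphology from tail-gene content; lysogeny-switch type
## from gene synteny and promoter orientation.

#' Call virion morphology from tail-gene content
#'
#' Precedence sheath > tape measure > baseplate: any tail-sheath gene makes
#' the phage a myovirus (contractile tail); otherwise a tape-measure gene
#' without a sheath indicates a siphovirus (long non-contractile tail);
#' otherwise a baseplate/fiber gene alone indicates a podovirus (short
#' tail); with no tail genes the region stays untyped.
#'
#' @param region A `prophage_region`.
#' @return A `morphology_call`: list with `morphology` and `evidence`
#'   (ORF ids carrying the deciding trait; empty iff untyped).
#' @export
call_morphology <- function(region) {
  orfs <- region$orfs
  pick <- function(trait) orfs$id[orf_has_trait(orfs, trait)]
  sheath <- pick("tail_sheath"); tape <- pick("tail_tape_measure")
  base <- pick("baseplate_or_fiber")
  if (length(sheath)) {
    out <- list(morphology = "myovirus", evidence = sheath)
  } else if (length(tape)) {
    out <- list(morphology = "siphovirus", evidence = tape)
  } else if (length(base)) {
    out <- list(morphology = "podovirus", evidence = base)
  } else {
    out <- list(morphology = "untyped", evidence = character(0))
  }
  structure(out, class = "morphology_call", region = region$name)
}

#' @export
print.morphology_call <- function(x, ...) {
  cat("<morphology_call>", attr(x, "region"), "->", x$morphology,
      if (length(x$evidence)) paste0("(", paste(x$evidence, collapse = ", "), ")") else "",
      "\n")
  invisible(x)
}

#' Geometry of a promoter pair
#'
#' For two score-filtered promoter calls with `p1$position < p2$position`:
#' strands `(-, +)` face away from each other (divergent), `(+, -)` face
#' each other (convergent), equal strands read in series (tandem).
#'
#' @param p1,p2 Lists or one-row data.frames with `position`, `strand`,
#'   `score`; both scores must be at or above `threshold`.
#' @param threshold Minimum admissible score (contract check).
#' @return `"divergent"`, `"convergent"` or `"tandem"`.
#' @export
promoter_pair_geometry <- function(p1, p2, threshold = 0.87) {
  if (p1$score < threshold || p2$score < threshold)
    stop("promoter_pair_geometry: calls must be score-filtered (>= ", threshold, ")")
  if (!(p1$position < p2$position))
    stop("promoter_pair_geometry: p1 must precede p2")
  if (p1$strand == p2$strand) return("tandem")
  if (p1$strand == "-") "divergent" else "convergent"
}

# Geometry of the promoter pair found in the intergenic interval between
# two ORF rows (chromosome coordinates); "none" when fewer than two calls.
.intergenic_geometry <- function(orfs, i, j, promoters) {
  lo <- min(orfs$end[i], orfs$end[j]); hi <- max(orfs$start[i], orfs$start[j])
  if (is.null(promoters) || !nrow(promoters) || hi <= lo) return("none")
  p <- promoters[promoters$position > lo & promoters$position < hi, , drop = FALSE]
  if (nrow(p) < 2L) return("none")
  p <- p[order(p$position), , drop = FALSE]
  promoter_pair_geometry(p[1, ], p[2, ])
}

#' Call the lysogeny-switch system of a region
#'
#' Classifies the lysogeny control architecture by gene synteny in the
#' canonical orientation, with promoter calls (score-filtered) refining the
#' geometry. Systems are evaluated in precedence order:
#' \enumerate{
#' \item `immr_imma` (ICEBs1-like): an ImmA/IrrE-family metallopeptidase
#'   adjacent (at most `adjacency` intervening ORFs) and co-oriented with an
#'   HTH regulator (ImmR), with the next downstream HTH regulator in the
#'   opposite orientation; the intergenic promoter pair may be divergent or
#'   convergent.
#' \item `c_ner` (Mu-like): two divergently transcribed HTH regulators whose
#'   downstream partner is small (at most `ner_max_aa` aa, Mu Ner is 76 aa),
#'   separated by at most `pair_window` ORFs, with a Mu-type transposase
#'   within `transposase_window` ORFs downstream.
#' \item `ci_cro` (lambda-like): two adjacent divergently transcribed ORFs
#'   in the lysogeny-control span, at least one an HTH regulator. A
#'   divergent promoter pair strengthens the call but absent promoter data
#'   does not block it (`promoter_geometry = "none"`).
#' \item otherwise `undetermined`.
#' }
#'
#' @param region A `prophage_region` (canonicalized internally).
#' @param promoters Promoter-call data.frame (any scores; filtered here), or
#'   `NULL`.
#' @param score_threshold Promoter score cut-off.
#' @param adjacency Maximum intervening ORFs for "adjacent".
#' @param ner_max_aa Size bound for the Ner-like partner.
#' @param pair_window Maximum intervening ORFs between the C- and Ner-like
#'   genes (tolerates hypothetical-gene inserts).
#' @param transposase_window Maximum ORFs between the Ner-like gene and the
#'   Mu transposase.
#' @return A `lysogeny_call`: list with `system`, `repressor_orf`,
#'   `partner_orf`, `promoter_geometry`.
#' @export
call_lysogeny <- function(region, promoters = NULL, score_threshold = 0.87,
                          adjacency = 1L, ner_max_aa = 80L,
                          pair_window = 10L, transposase_window = 10L) {
  region <- .canonical(region)
  orfs <- region$orfs
  n <- nrow(orfs)
  if (!is.null(promoters) && nrow(promoters)) {
    promoters <- filter_promoters(promoters, score_threshold)
    promoters <- promoters[promoters$position >= region$start &
                           promoters$position <= region$end, , drop = FALSE]
  }
  res <- function(system, rep_i = NA, par_i = NA, geometry = "none") {
    structure(list(system = system,
                   repressor_orf = if (is.na(rep_i)) NA_character_ else orfs$id[rep_i],
                   partner_orf = if (is.na(par_i)) NA_character_ else orfs$id[par_i],
                   promoter_geometry = geometry),
              class = "lysogeny_call", region = region$name)
  }
  if (!n) return(res("undetermined"))
  hth <- which(orf_has_trait(orfs, "hth_regulator"))
  imma <- which(orf_has_trait(orfs, "imma_metallopeptidase"))
  mu <- which(orf_has_trait(orfs, "transposase_mu"))

  ## (1) ImmR/ImmA-like ----------------------------------------------------
  for (i in imma) {
    cands <- hth[abs(hth - i) <= adjacency + 1L & hth != i &
                 orfs$strand[hth] == orfs$strand[i]]
    for (h in cands) {
      downstream <- hth[hth > max(i, h) & orfs$strand[hth] != orfs$strand[h]]
      if (length(downstream)) {
        j <- downstream[1]
        return(res("immr_imma", h, j, .intergenic_geometry(orfs, h, j, promoters)))
      }
    }
  }

  ## (2) Mu-like C/Ner -----------------------------------------------------
  if (length(mu)) {
    for (i in hth) {
      if (orfs$strand[i] != "-") next
      partners <- hth[hth > i & hth - i - 1L <= pair_window &
                      orfs$strand[hth] == "+" & orfs$length_aa[hth] <= ner_max_aa]
      for (j in partners) {
        if (any(mu > j & mu - j <= transposase_window))
          return(res("c_ner", i, j, .intergenic_geometry(orfs, i, j, promoters)))
      }
    }
  }

  ## (3) lambda-like CI/Cro ------------------------------------------------
  lys_chains <- .qualifying_chains(orfs, "lysogeny_control")
  span <- if (length(lys_chains)) {
    unique(unlist(lapply(lys_chains, function(ch) min(ch):max(ch))))
  } else seq_len(n)
  fam <- .module_families$lysogeny_control
  for (i in sort(span)) {
    j <- i + 1L
    if (j > n) next
    if (length(lys_chains) && !(j %in% span)) next
    if (!(orfs$category[i] %in% fam) || !(orfs$category[j] %in% fam)) next
    if (orfs$strand[i] == "-" && orfs$strand[j] == "+" &&
        (i %in% hth || j %in% hth)) {
      rep_i <- if (i %in% hth) i else j
      par_i <- if (rep_i == i) j else i
      return(res("ci_cro", rep_i, par_i, .intergenic_geometry(orfs, i, j, promoters)))
    }
  }
  res("undetermined")
}

#' @export
print.lysogeny_call <- function(x, ...) {
  cat("<lysogeny_call>", attr(x, "region"), "->", x$system,
      sprintf("(repressor %s, partner %s, promoters %s)\n",
              x$repressor_orf, x$partner_orf, x$promoter_geometry))
  invisible(x)
}

#' Type all regions of a chromosome
#'
#' Convenience wrapper applying [call_morphology] and [call_lysogeny] to a
#' set of regions.
#'
#' @param regions Named list of `prophage_region` objects.
#' @param promoters Promoter-call data.frame with a `region` column (or
#'   `NULL`).
#' @param ... Passed to [call_lysogeny].
#' @return Data.frame: region, morphology, morphology_evidence,
#'   lysogeny_system, repressor_orf, partner_orf, promoter_geometry.
#' @export
type_regions <- function(regions, promoters = NULL, ...) {
  rows <- lapply(regions, function(r) {
    p <- promoters
    if (!is.null(p) && "region" %in% names(p))
      p <- p[p$region == r$name, , drop = FALSE]
    m <- call_morphology(r)
    l <- call_lysogeny(r, p, ...)
    data.frame(region = r$name, morphology = m$morphology,
               morphology_evidence = paste(m$evidence, collapse = ","),
               lysogeny_system = l$system, repressor_orf = l$repressor_orf,
               partner_orf = l$partner_orf,
               promoter_geometry = l$promoter_geometry,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
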