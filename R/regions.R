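#' Length of a 1-based inclusive genomic interval
#'
#' All coordinates in this package are 1-based and inclusive, the convention
#' of GenBank/GFF3 feature tables, so a region spanning positions
#' `start..end` contains `end - start + 1` bases.
#'
#' @param start,end Integer coordinates, `1 <= start <= end`.
#' @return Integer length in bp (vectorized).
#' @examples
#' region_length(194517, 235362) # 40846
#' @export
region_length <- function(start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("invalid interval: non-finite coordinates")
  if (any(start < 1) || any(end < start))
    stop("invalid interval: need 1 <= start <= end")
  as.integer(end - start + 1)
}

#' Construct a prophage region
#'
#' A chromosomal interval owning an ordered set of ORFs, an optional
#' completeness score (0-100, from an upstream AAI-based assessment), defect
#' flags and a viability category.
#'
#' @param name Region name, e.g. `"phi1"`.
#' @param chrom Chromosome/sequence identifier.
#' @param start,end 1-based inclusive chromosome coordinates.
#' @param packaging_strand `"forward"` or `"reverse"` - the strand on which
#'   the phage reads lysogeny-to-lysis.
#' @param orfs An `orf_table`; all ORFs must lie within `[start, end]`.
#' @param completeness Numeric in `[0, 100]`, or `NA` when unassessed.
#' @param defects List of defect flags (see [defect_flag]).
#' @param category One of `"functional"`, `"unknown"`, `"defective"`,
#'   `"unclassified"`, or `NA` before categorization.
#' @return An object of class `prophage_region`.
#' @export
prophage_region <- function(name, chrom, start, end,
                            packaging_strand = "forward",
                            orfs = empty_orf_table(),
                            completeness = NA_real_,
                            defects = list(),
                            category = NA_character_) {
  stopifnot(length(name) == 1L, length(start) == 1L, length(end) == 1L)
  region_length(start, end) # validates the interval
  if (!packaging_strand %in% c("forward", "reverse"))
    stop("packaging_strand must be 'forward' or 'reverse'")
  orfs <- validate_orf_table(as.data.frame(orfs))
  if (nrow(orfs) && (any(orfs$start < start) || any(orfs$end > end)))
    stop("region ", name, ": ORFs extend outside [start, end]")
  if (!is.na(completeness) && (completeness < 0 || completeness > 100))
    stop("completeness must lie in [0, 100]")
  structure(
    list(name = as.character(name), chrom = as.character(chrom),
         start = as.integer(start), end = as.integer(end),
         packaging_strand = packaging_strand, orfs = orfs,
         completeness = as.numeric(completeness), defects = defects,
         category = category, canonical = FALSE),
    class = "prophage_region"
  )
}

#' @export
print.prophage_region <- function(x, ...) {
  cat(sprintf("<prophage_region> %s  %s:%s-%s (%s bp, %s strand)\n",
              x$name, x$chrom, format(x$start, big.mark = ","),
              format(x$end, big.mark = ","),
              format(region_length(x$start, x$end), big.mark = ","),
              x$packaging_strand))
  cat(sprintf("  %d ORFs; completeness %s; category %s; %d defect flag(s)\n",
              nrow(x$orfs),
              ifelse(is.na(x$completeness), "NA", format(x$completeness)),
              ifelse(is.na(x$category), "<uncalled>", x$category),
              length(x$defects)))
  invisible(x)
}

#' Construct a defect flag
#'
#' @param kind One of `split_integrase`, `truncated_integrase`,
#'   `missing_terminase_or_portal`, `intron_split_gene`,
#'   `misoriented_late_orf`, `mosaic_region`.
#' @param evidence Non-empty character vector of supporting ORF ids.
#' @return A list with class `defect_flag`.
#' @export
defect_flag <- function(kind, evidence) {
  kinds <- c("split_integrase", "truncated_integrase",
             "missing_terminase_or_portal", "intron_split_gene",
             "misoriented_late_orf", "mosaic_region")
  if (!kind %in% kinds) stop("unknown defect kind: ", kind)
  evidence <- as.character(evidence)
  if (!length(evidence)) stop("defect flag requires non-empty evidence")
  structure(list(kind = kind, evidence = evidence), class = "defect_flag")
}

#' Kinds of a list of defect flags
#' @param defects List of `defect_flag` objects.
#' @return Character vector of kinds (possibly empty).
#' @export
defect_kinds <- function(defects) {
  vapply(defects, function(d) d$kind, character(1))
}

#' Orient a region so its modules read lysogeny-to-lysis left-to-right
#'
#' Regions packaged on the reverse strand carry their gene grammar mirrored
#' on the chromosome. Canonicalization reverses the ORF order and flips ORF
#' strands (chromosome coordinates are preserved) so that downstream pattern
#' matching can always read the canonical module order. Forward regions are
#' returned unchanged; the operation is idempotent.
#'
#' @param region A `prophage_region`.
#' @return The canonicalized `prophage_region` (with `canonical = TRUE`).
#' @export
canonicalize_orientation <- function(region) {
  stopifnot(inherits(region, "prophage_region"))
  if (isTRUE(region$canonical) || region$packaging_strand == "forward") {
    region$canonical <- TRUE
    return(region)
  }
  orfs <- region$orfs
  if (nrow(orfs)) {
    orfs <- orfs[rev(seq_len(nrow(orfs))), , drop = FALSE]
    orfs$strand <- ifelse(orfs$strand == "+", "-", "+")
    rownames(orfs) <- NULL
  }
  region$orfs <- orfs
  region$canonical <- TRUE
  region
}

# Internal: ensure a region is canonical before grammar matching.
.canonical <- function(region) {
  if (isTRUE(region$canonical)) region else canonicalize_orientation(region)
}
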