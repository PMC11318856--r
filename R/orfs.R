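#' Functional categories recognized for annotated ORFs
#'
#' The per-ORF functional vocabulary follows the PHROG-style grouping used
#' for temperate-phage genome maps: integration/excision, transcription
#' regulation, DNA replication, packaging and capsid, head-tail connector,
#' tail, lysis, accessory (moron), other, unknown.
#'
#' @format Character vector of valid `category` tokens.
#' @export
orf_categories <- c(
  "integration_excision", "transcription_regulation", "replication",
  "packaging_capsid", "connector", "tail", "lysis",
  "moron_accessory", "other", "unknown"
)

#' Trait flags recognized for annotated ORFs
#'
#' Traits mark gene products that drive downstream calls: integrase and
#' recombinase fragments for defect detection, tail sheath / tape measure /
#' baseplate for morphology, HTH regulators, ImmA-family metallopeptidases
#' and Mu transposases for lysogeny-switch typing, and the accessory-gene
#' repertoire (RM subunits, TA components, anti-CRISPRs, diversity
#' generators, host-adaptation enzymes).
#'
#' @format Character vector of valid trait tokens.
#' @export
orf_traits <- c(
  "integrase", "recombinase", "transposase_mu", "hth_regulator",
  "imma_metallopeptidase", "terminase_large", "portal", "major_capsid",
  "tail_tape_measure", "tail_sheath", "baseplate_or_fiber",
  "reverse_transcriptase_maturase", "avd_dgr", "anti_crispr",
  "rm_hsdR", "rm_hsdM", "rm_hsdS", "rm_type3",
  "ta_toxin", "ta_antitoxin", "restriction_alleviation", "mom_modification",
  "darB_antirestriction", "amidoligase", "haemolysin", "ggct",
  "paps_reductase", "dextransucrase", "cm_phosphotransferase",
  "helicase", "dna_polymerase"
)

# Traits whose presence forces the ORF category.
.forced_category <- c(
  tail_tape_measure  = "tail",
  tail_sheath        = "tail",
  baseplate_or_fiber = "tail",
  terminase_large    = "packaging_capsid",
  portal             = "packaging_capsid",
  major_capsid       = "packaging_capsid",
  integrase          = "integration_excision",
  recombinase        = "integration_excision",
  hth_regulator      = "transcription_regulation",
  helicase           = "replication",
  dna_polymerase     = "replication"
)

.split_traits <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

.join_traits <- function(x) paste(x, collapse = ";")

#' Construct a validated ORF table
#'
#' Builds the per-ORF annotation table used throughout the package. One row
#' per coding feature; coordinates are 1-based inclusive chromosome
#' positions; `traits` is a semicolon-separated set of trait tokens.
#'
#' @param id Character, unique ORF identifiers.
#' @param start,end Integer chromosome coordinates (1-based, inclusive,
#'   `end >= start`).
#' @param strand `"+"` or `"-"`.
#' @param category Functional category token (see [orf_categories]).
#' @param traits Semicolon-separated trait tokens (see [orf_traits]);
#'   `""` for none.
#' @param product Free-text product description.
#' @param length_aa Protein length in amino acids (`>= 1`).
#' @return A `data.frame` with class `orf_table`, ordered by `start`
#'   (ties by `end`, then `id`).
#' @export
orf_table <- function(id, start, end, strand, category = "unknown",
                      traits = "", product = "", length_aa = NULL) {
  n <- length(id)
  if (is.null(length_aa)) length_aa <- pmax(1L, (as.integer(end) - as.integer(start) + 1L) %/% 3L - 1L)
  df <- data.frame(
    id = as.character(id),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    category = rep_len(as.character(category), n),
    traits = rep_len(as.character(traits), n),
    product = rep_len(as.character(product), n),
    length_aa = rep_len(as.integer(length_aa), n),
    stringsAsFactors = FALSE
  )
  validate_orf_table(df)
}

#' Validate an ORF table
#'
#' Checks coordinate sanity, strand symbols, category/trait vocabulary and
#' the forced trait-to-category constraints (e.g. a tail-sheath gene must be
#' in the tail category). Returns the table ordered by start coordinate.
#'
#' @param df A data.frame with the `orf_table` columns.
#' @return The validated, ordered `orf_table`.
#' @export
validate_orf_table <- function(df) {
  req <- c("id", "start", "end", "strand", "category", "traits", "product", "length_aa")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("orf table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicate ORF ids: ",
                                 paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  bad <- which(!is.finite(df$start) | !is.finite(df$end) | df$start < 1L | df$end < df$start)
  if (length(bad)) stop("invalid coordinates (need 1 <= start <= end) for ORF ",
                        df$id[bad[1]])
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) stop("invalid strand symbol for ORF ", df$id[bad[1]],
                        ": '", df$strand[bad[1]], "'")
  bad <- which(!df$category %in% orf_categories)
  if (length(bad)) stop("unknown category token for ORF ", df$id[bad[1]],
                        ": '", df$category[bad[1]], "'")
  bad <- which(df$length_aa < 1L)
  if (length(bad)) stop("length_aa must be >= 1 for ORF ", df$id[bad[1]])
  for (i in seq_len(nrow(df))) {
    tr <- .split_traits(df$traits[i])
    unk <- setdiff(tr, orf_traits)
    if (length(unk)) stop("unknown trait token for ORF ", df$id[i], ": '", unk[1], "'")
    forced <- unique(stats::na.omit(.forced_category[tr]))
    if (length(forced) == 1L && df$category[i] != forced)
      stop("ORF ", df$id[i], ": trait(s) ", .join_traits(tr),
           " force category '", forced, "' but category is '", df$category[i], "'")
  }
  df <- df[order(df$start, df$end, df$id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- unique(c("orf_table", class(df)))
  df
}

#' Which ORFs carry a given trait
#'
#' @param orfs An `orf_table`.
#' @param trait A single trait token.
#' @return Logical vector over the rows of `orfs`.
#' @export
orf_has_trait <- function(orfs, trait) {
  vapply(orfs$traits, function(x) trait %in% .split_traits(x), logical(1),
         USE.NAMES = FALSE)
}

#' Empty ORF table
#' @return A zero-row `orf_table`.
#' @export
empty_orf_table <- function() {
  validate_orf_table(data.frame(
    id = character(0), start = integer(0), end = integer(0),
    strand = character(0), category = character(0), traits = character(0),
    product = character(0), length_aa = integer(0), stringsAsFactors = FALSE
  ))
}
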