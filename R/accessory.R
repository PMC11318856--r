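## Accessory-gene screen: vocabulary-driven classification of prophage
## cargo (RM systems, TA systems, diversity generators, defence and
## anti-defence factors, host-adaptation genes).

#' Load the default accessory-gene vocabulary
#'
#' The vocabulary ships as an editable TSV (`trait`, `accessory_class`,
#' `defence_side`, `putative_function`) so functional assignments can be
#' revised without code changes. Vocabulary edits never affect curation or
#' typing, which do not consult it.
#'
#' @param path Optional path to an alternative vocabulary TSV.
#' @return Data.frame vocabulary.
#' @export
default_accessory_vocab <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "accessory_vocab.tsv", package = "prophager")
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
}

#' Screen a region for accessory genes
#'
#' Maps ORF traits to accessory classes through the vocabulary. Two rules
#' are applied on top of the lookup: an antitoxin with no toxin partner in
#' the same region is reported as `anti_phage_defence` (possibly a
#' degenerate TA system, possibly a counter-defence factor); and an
#' unusually large ORF (> `large_orf_bp` bp) with no functional category is
#' reported as `large_polyvalent_like`.
#'
#' @param region A confirmed `prophage_region`.
#' @param vocab Vocabulary data.frame (default [default_accessory_vocab]).
#' @param large_orf_bp Span threshold for the large-polyvalent-like rule.
#' @return Data.frame of `accessory_record`s: region, orf_id, product,
#'   accessory_class, putative_function (class-`none` ORFs are suppressed).
#' @export
screen_accessory <- function(region, vocab = default_accessory_vocab(),
                             large_orf_bp = 5000L) {
  orfs <- region$orfs
  has_toxin <- any(orf_has_trait(orfs, "ta_toxin"))
  rows <- list()
  for (i in seq_len(nrow(orfs))) {
    traits <- .split_traits(orfs$traits[i])
    hit <- vocab[vocab$trait %in% traits, , drop = FALSE]
    cls <- NA_character_; fun <- NA_character_
    if (nrow(hit)) {
      cls <- hit$accessory_class[1]; fun <- hit$putative_function[1]
      if (cls == "ta_system" && "ta_antitoxin" %in% traits && !has_toxin) {
        cls <- "anti_phage_defence"
        fun <- paste0(fun, " (solitary; possibly degenerate TA or counter-defence)")
      }
    } else if (orfs$end[i] - orfs$start[i] + 1L > large_orf_bp &&
               orfs$category[i] %in% c("unknown", "other")) {
      cls <- "large_polyvalent_like"
      fun <- "Hypothetical protein with similarity to large polyvalent proteins"
    }
    if (!is.na(cls)) {
      rows[[length(rows) + 1L]] <- data.frame(
        region = region$name, orf_id = orfs$id[i], product = orfs$product[i],
        accessory_class = cls, putative_function = fun,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(region = character(0), orf_id = character(0),
                      product = character(0), accessory_class = character(0),
                      putative_function = character(0)))
  do.call(rbind, rows)
}

#' Summarize defence and anti-defence cargo across regions
#'
#' @param records Row-bound output of [screen_accessory] over all regions.
#' @return Data.frame of per-region counts by accessory class (zero rows
#'   for empty input), with attribute `no_classical_morons` set to `TRUE`
#'   when no classical moron product (exotoxin, immune evasion factor)
#'   appears in any record.
#' @export
summarize_defence <- function(records) {
  if (!nrow(records)) {
    out <- data.frame(region = character(0), accessory_class = character(0),
                      n = integer(0))
    attr(out, "no_classical_morons") <- TRUE
    return(out)
  }
  tab <- stats::aggregate(list(n = records$orf_id),
                          by = list(region = records$region,
                                    accessory_class = records$accessory_class),
                          FUN = length)
  tab <- tab[order(tab$region, tab$accessory_class), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "no_classical_morons") <-
    !any(grepl("exotoxin|immune evasion", records$putative_function,
               ignore.case = TRUE))
  tab
}
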