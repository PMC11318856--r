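## Pipeline orchestration: curate -> type -> screen -> qpcr with combined
## reporting, plus a chromosome map figure.

#' Assemble a pipeline configuration
#'
#' @param annotations Path to the annotated chromosome file.
#' @param format Annotation format (`feature_table`, `gff3`, `genbank`).
#' @param hits Path to the candidate-hit TSV (columns chrom/start/end), or
#'   `NULL` to treat every labelled region as a hit.
#' @param completeness Path to the completeness TSV, or `NULL`.
#' @param promoters Path to the promoter-call TSV, or `NULL`.
#' @param qpcr Path to the qPCR replicate CSV, or `NULL`.
#' @param out_dir Output directory.
#' @param stages Stages to run, subset of `curate`, `type`, `screen`,
#'   `qpcr`.
#' @param max_gap Hit-merging gap (bp).
#' @param truncation_aa Integrase truncation threshold (aa).
#' @param score_threshold Promoter score threshold.
#' @param housekeeper qPCR housekeeper target id.
#' @param cq_cap qPCR cycle cap.
#' @param vocab Accessory vocabulary path (`NULL` for the packaged one).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(annotations = NULL, format = "feature_table",
                            hits = NULL, completeness = NULL, promoters = NULL,
                            qpcr = NULL, out_dir = tempfile("prophager_run_"),
                            stages = c("curate", "type", "screen", "qpcr"),
                            max_gap = 1000, truncation_aa = 200L,
                            score_threshold = 0.87, housekeeper = "s10p",
                            cq_cap = 40, vocab = NULL) {
  stages <- match.arg(stages, c("curate", "type", "screen", "qpcr"),
                      several.ok = TRUE)
  cfg <- list(annotations = annotations, format = format, hits = hits,
              completeness = completeness, promoters = promoters, qpcr = qpcr,
              out_dir = out_dir, stages = stages, max_gap = max_gap,
              truncation_aa = truncation_aa, score_threshold = score_threshold,
              housekeeper = housekeeper, cq_cap = cq_cap, vocab = vocab)
  needs_ann <- any(c("curate", "type", "screen") %in% stages)
  if (needs_ann && is.null(annotations))
    stop("configuration error: enabled stages need 'annotations'")
  if ("qpcr" %in% stages && is.null(qpcr))
    stop("configuration error: qpcr stage needs 'qpcr' input")
  for (f in c("annotations", "hits", "completeness", "promoters", "qpcr",
              "vocab")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configuration error: missing input file for '", f, "': ", cfg[[f]])
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the characterization pipeline
#'
#' Executes the enabled stages against the configured inputs and writes
#' per-stage TSV reports plus a combined per-region summary (including
#' delineated sub-regions of mosaic regions) and a JSON run log.
#'
#' @param config A [pipeline_config].
#' @return Invisible list with the in-memory stage outputs (`curation`,
#'   `typing`, `accessory`, `qpcr`, `summary`, `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(files = character(0))
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    out$files <<- c(out$files, path)
    path
  }

  chrom <- NULL; promoters <- NULL
  if (any(c("curate", "type", "screen") %in% config$stages)) {
    chrom <- read_chromosome(config$annotations, config$format)
    if (!is.null(config$promoters)) promoters <- read_promoters(config$promoters)
  }

  regions <- list()
  if ("curate" %in% config$stages) {
    hits <- if (!is.null(config$hits)) {
      utils::read.table(config$hits, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(chrom$regions, function(r)
        data.frame(chrom = r$chrom, start = r$start, end = r$end,
                   source = "region", stringsAsFactors = FALSE)))
    }
    comp <- if (!is.null(config$completeness))
      utils::read.table(config$completeness, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE) else NULL
    cur <- curate(chrom, hits, comp, max_gap = config$max_gap,
                  truncation_aa = config$truncation_aa)
    out$curation <- cur$report
    regions <- cur$regions
    emit(cur$report, "curation.tsv")
    # delineate mosaics into sub-region rows
    subs <- list()
    for (r in regions) {
      if ("mosaic_region" %in% defect_kinds(r$defects)) {
        for (s in delineate_mosaic(r)) {
          s$completeness <- if (!is.null(comp) && s$name %in% comp$region)
            comp$completeness[match(s$name, comp$region)] else NA_real_
          s$defects <- detect_defects(s, truncation_aa = config$truncation_aa)
          s$category <- categorize(s$completeness, s$defects)
          subs[[s$name]] <- s
        }
      }
    }
    out$subregions <- subs
    regions <- c(regions, subs)
  } else {
    regions <- chrom$regions
  }

  if ("type" %in% config$stages && length(regions)) {
    out$typing <- type_regions(regions, promoters,
                               score_threshold = config$score_threshold)
    emit(out$typing, "typing.tsv")
  }

  if ("screen" %in% config$stages && length(regions)) {
    vocab <- default_accessory_vocab(config$vocab)
    recs <- do.call(rbind, lapply(regions, screen_accessory, vocab = vocab))
    if (is.null(recs))
      recs <- data.frame(region = character(0), orf_id = character(0),
                         product = character(0), accessory_class = character(0),
                         putative_function = character(0))
    out$accessory <- recs
    out$defence_summary <- summarize_defence(recs)
    emit(recs, "accessory.tsv")
    emit(out$defence_summary, "defence_summary.tsv")
  }

  if ("qpcr" %in% config$stages) {
    panel <- read_qpcr(config$qpcr)
    out$qpcr <- analyze_qpcr(panel, housekeeper = config$housekeeper,
                             cq_cap = config$cq_cap)
    emit(as.data.frame(out$qpcr), "qpcr.tsv")
  }

  # combined per-region summary
  if (length(regions)) {
    sumrows <- lapply(regions, function(r) {
      data.frame(region = r$name, chrom = r$chrom, start = r$start,
                 end = r$end, length = region_length(r$start, r$end),
                 modules = paste(modules_present(assign_modules(r)),
                                 collapse = ","),
                 completeness = r$completeness,
                 defects = paste(defect_kinds(r$defects), collapse = ","),
                 category = if (is.na(r$category)) "unclassified" else r$category,
                 stringsAsFactors = FALSE)
    })
    summary <- do.call(rbind, sumrows)
    rownames(summary) <- NULL
    if (!is.null(out$typing)) {
      summary <- merge(summary, out$typing[, c("region", "morphology",
                                               "lysogeny_system",
                                               "promoter_geometry")],
                       by = "region", all.x = TRUE, sort = FALSE)
    }
    summary <- summary[order(summary$start, summary$end), , drop = FALSE]
    rownames(summary) <- NULL
    out$summary <- summary
    emit(summary, "summary.tsv")
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }

  log <- list(stages = config$stages,
              parameters = config[c("max_gap", "truncation_aa",
                                    "score_threshold", "housekeeper",
                                    "cq_cap")],
              version = as.character(utils::packageVersion("prophager")))
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE)
  invisible(out)
}

#' Draw a chromosome map of the characterized regions
#'
#' Regions are positioned by coordinate and coloured by category
#' (functional red, defective black, unknown yellow, unclassified grey),
#' labelled with their morphology and lysogeny-switch calls when present.
#'
#' @param summary Combined summary data.frame (from [run_pipeline]).
#' @param path Output figure path (`.svg` or `.pdf`).
#' @param genome_size Chromosome length in bp (defaults to the maximum
#'   region end).
#' @return The path, invisibly.
#' @export
render_region_map <- function(summary, path, genome_size = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") grDevices::svg(path, width = 10, height = 4)
  else grDevices::pdf(path, width = 10, height = 4)
  on.exit(grDevices::dev.off())
  cols <- c(functional = "red", defective = "black", unknown = "gold",
            unclassified = "grey70")
  if (is.null(summary) || !nrow(summary)) {
    warning("render_region_map: empty summary; drawing an empty canvas")
    graphics::plot.new()
    graphics::title("chromosome map (no regions)")
    return(invisible(path))
  }
  gs <- if (is.null(genome_size)) max(summary$end) * 1.02 else genome_size
  graphics::plot(NULL, xlim = c(0, gs), ylim = c(0, 2), axes = FALSE,
                 xlab = "chromosome position (bp)", ylab = "")
  graphics::axis(1, at = pretty(c(0, gs)),
                 labels = format(pretty(c(0, gs)), big.mark = ","))
  graphics::rect(0, 0.9, gs, 1.1, col = "grey90", border = NA)
  for (i in seq_len(nrow(summary))) {
    cat_i <- summary$category[i]
    graphics::rect(summary$start[i], 0.85, summary$end[i], 1.15,
                   col = cols[[ifelse(cat_i %in% names(cols), cat_i,
                                      "unclassified")]],
                   border = "black")
    lab <- summary$region[i]
    if (!is.null(summary$morphology) && !is.na(summary$morphology[i]))
      lab <- paste0(lab, "\n", substr(summary$morphology[i], 1, 4))
    graphics::text((summary$start[i] + summary$end[i]) / 2,
                   ifelse(i %% 2 == 0, 1.45, 0.55), lab, cex = 0.55, srt = 45)
  }
  graphics::legend("topleft", legend = names(cols), fill = unname(cols),
                   bty = "n", cex = 0.7, ncol = 4)
  invisible(path)
}
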