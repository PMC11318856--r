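#' Construct an annotated chromosome
#'
#' The container consumed by the curation pipeline: a flat ORF table in
#' chromosome coordinates (with a `region` label column; `""` marks
#' background/decoy genes outside named prophage regions is allowed too) and
#' a list of [prophage_region] objects.
#'
#' @param seqid Sequence identifier.
#' @param orfs An `orf_table` with an additional `region` character column.
#' @param regions Named list of `prophage_region` objects.
#' @param length Chromosome length in bp (`NA` if unknown).
#' @return An object of class `annotated_chromosome`.
#' @export
annotated_chromosome <- function(seqid, orfs, regions = list(), length = NA_integer_) {
  if (is.null(orfs$region)) orfs$region <- ""
  reg_col <- orfs$region
  core <- validate_orf_table(orfs[setdiff(names(orfs), "region")])
  core$region <- reg_col[match(core$id, orfs$id)]
  if (length(regions) && is.null(names(regions)))
    names(regions) <- vapply(regions, function(r) r$name, character(1))
  structure(list(seqid = as.character(seqid), length = as.integer(length),
                 orfs = core, regions = regions),
            class = "annotated_chromosome")
}

#' @export
print.annotated_chromosome <- function(x, ...) {
  cat(sprintf("<annotated_chromosome> %s: %d ORFs, %d regions\n",
              x$seqid, nrow(x$orfs), length(x$regions)))
  invisible(x)
}

# Infer the packaging strand of a region from the majority strand of its
# ORFs (phage operons are predominantly co-oriented with packaging; only
# the repressor side of the lysogeny switch runs antisense). Ties resolve
# to forward.
.infer_packaging_strand <- function(orfs) {
  if (!nrow(orfs)) return("forward")
  if (sum(orfs$strand == "-") > sum(orfs$strand == "+")) "reverse" else "forward"
}

# Assemble regions from a flat labelled ORF table. Span defaults to the ORF
# envelope unless `spans` (named list/data.frame of start/end/packaging
# strand) provides explicit coordinates.
.regions_from_orfs <- function(seqid, orfs, spans = NULL) {
  labs <- setdiff(unique(orfs$region), "")
  regions <- list()
  for (lab in labs) {
    sub <- orfs[orfs$region == lab, setdiff(names(orfs), "region"), drop = FALSE]
    sub <- validate_orf_table(sub)
    if (!is.null(spans) && lab %in% spans$region) {
      i <- match(lab, spans$region)
      st <- spans$start[i]; en <- spans$end[i]
      ps <- if (!is.null(spans$packaging_strand)) spans$packaging_strand[i]
            else .infer_packaging_strand(sub)
    } else {
      st <- min(sub$start); en <- max(sub$end)
      ps <- .infer_packaging_strand(sub)
    }
    regions[[lab]] <- prophage_region(lab, seqid, st, en,
                                      packaging_strand = ps, orfs = sub)
  }
  regions
}

## ---------------------------------------------------------------- formats

#' Write a chromosome as a feature-table TSV
#'
#' Tab-separated dialect with columns
#' `region orf_id start end strand length_aa category traits product`;
#' traits are a semicolon-separated list, `region` is `""` for background
#' genes.
#'
#' @param chrom An `annotated_chromosome`.
#' @param path Output file.
#' @export
write_feature_table <- function(chrom, path) {
  df <- data.frame(region = chrom$orfs$region, orf_id = chrom$orfs$id,
                   start = chrom$orfs$start, end = chrom$orfs$end,
                   strand = chrom$orfs$strand, length_aa = chrom$orfs$length_aa,
                   category = chrom$orfs$category, traits = chrom$orfs$traits,
                   product = chrom$orfs$product, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_feature_table <- function(path, seqid) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  req <- c("region", "orf_id", "start", "end", "strand", "length_aa",
           "category", "traits", "product")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("feature_table ", path, ": missing column(s) ", paste(miss, collapse = ", "))
  start <- suppressWarnings(as.integer(df$start))
  end <- suppressWarnings(as.integer(df$end))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("feature_table ", path, " line ", bad[1] + 1L,
         " (", df$orf_id[bad[1]], "): malformed coordinates")
  bad <- which(end < start)
  if (length(bad))
    stop("feature_table ", path, " line ", bad[1] + 1L,
         " (", df$orf_id[bad[1]], "): end < start")
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    stop("feature_table ", path, " line ", bad[1] + 1L,
         " (", df$orf_id[bad[1]], "): bad strand '", df$strand[bad[1]], "'")
  df$category[is.na(df$category) | !nzchar(df$category)] <- "unknown"
  bad <- which(!df$category %in% orf_categories)
  if (length(bad))
    stop("feature_table ", path, " line ", bad[1] + 1L,
         " (", df$orf_id[bad[1]], "): bad category '", df$category[bad[1]], "'")
  orfs <- data.frame(id = df$orf_id, start = start, end = end,
                     strand = df$strand, category = df$category,
                     traits = df$traits, product = df$product,
                     length_aa = as.integer(df$length_aa),
                     region = df$region, stringsAsFactors = FALSE)
  orfs$traits[is.na(orfs$traits)] <- ""
  orfs$product[is.na(orfs$product)] <- ""
  orfs$region[is.na(orfs$region)] <- ""
  orfs
}

#' Write a chromosome as GFF3
#'
#' Emits one `prophage_region` feature per region (carrying
#' `packaging_strand`) and one `CDS` feature per ORF (carrying `region`,
#' `category`, `traits` and `length_aa` attributes). Trait lists use `,` as
#' the separator inside the GFF3 attribute.
#'
#' @param chrom An `annotated_chromosome`.
#' @param path Output file.
#' @export
write_gff3 <- function(chrom, path) {
  orfs <- chrom$orfs
  n <- nrow(orfs)
  gr_orf <- GenomicRanges::GRanges(
    seqnames = chrom$seqid,
    ranges = IRanges::IRanges(orfs$start, orfs$end),
    strand = orfs$strand
  )
  gr_orf$type <- "CDS"
  gr_orf$phase <- 0L
  gr_orf$ID <- orfs$id
  gr_orf$region <- orfs$region
  gr_orf$category <- orfs$category
  gr_orf$traits <- gsub(";", ",", orfs$traits, fixed = TRUE)
  gr_orf$product <- orfs$product
  gr_orf$length_aa <- as.character(orfs$length_aa)
  if (length(chrom$regions)) {
    rs <- chrom$regions
    gr_reg <- GenomicRanges::GRanges(
      seqnames = chrom$seqid,
      ranges = IRanges::IRanges(vapply(rs, `[[`, integer(1), "start"),
                                vapply(rs, `[[`, integer(1), "end")),
      strand = "*"
    )
    gr_reg$type <- "prophage_region"
    gr_reg$ID <- names(rs)
    gr_reg$region <- names(rs)
    gr_reg$category <- NA_character_
    gr_reg$traits <- NA_character_
    gr_reg$product <- NA_character_
    gr_reg$length_aa <- NA_character_
    gr_reg$packaging_strand <- vapply(rs, `[[`, character(1), "packaging_strand")
    gr_orf$packaging_strand <- NA_character_
    gr <- c(gr_reg, gr_orf)
  } else {
    gr <- gr_orf
  }
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

.read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  seqid <- as.character(df$seqnames[1])
  is_cds <- df$type == "CDS"
  cds <- df[is_cds, , drop = FALSE]
  bad <- which(!as.character(cds$strand) %in% c("+", "-"))
  if (length(bad)) stop("GFF3 ", path, ": CDS ", cds$ID[bad[1]], " has no strand")
  orfs <- data.frame(id = as.character(cds$ID),
                     start = as.integer(cds$start), end = as.integer(cds$end),
                     strand = as.character(cds$strand),
                     category = as.character(cds$category),
                     traits = gsub(",", ";", as.character(cds$traits), fixed = TRUE),
                     product = as.character(cds$product),
                     length_aa = as.integer(as.character(cds$length_aa)),
                     region = as.character(cds$region), stringsAsFactors = FALSE)
  orfs$traits[is.na(orfs$traits)] <- ""
  orfs$product[is.na(orfs$product)] <- ""
  orfs$region[is.na(orfs$region)] <- ""
  spans <- NULL
  reg <- df[df$type == "prophage_region", , drop = FALSE]
  if (nrow(reg)) {
    spans <- data.frame(region = as.character(reg$ID),
                        start = as.integer(reg$start),
                        end = as.integer(reg$end), stringsAsFactors = FALSE)
    if (!is.null(reg$packaging_strand))
      spans$packaging_strand <- as.character(reg$packaging_strand)
  }
  list(seqid = seqid, orfs = orfs, spans = spans)
}

#' Write a chromosome as a minimal GenBank flat file
#'
#' A sequence-less GenBank record: LOCUS/FEATURES sections with one
#' `misc_feature` per prophage region and one `CDS` per ORF. Annotation is
#' carried in `/locus_tag`, `/product` and a structured `/note`. This writer
#' and [read_chromosome] round-trip each other; it is not a general GenBank
#' implementation.
#'
#' @param chrom An `annotated_chromosome`.
#' @param path Output file.
#' @export
write_genbank <- function(chrom, path) {
  len <- if (is.na(chrom$length)) max(chrom$orfs$end, 0L) else chrom$length
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   UNA", chrom$seqid, len), con)
  writeLines(sprintf("DEFINITION  annotated chromosome %s.", chrom$seqid), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  for (nm in names(chrom$regions)) {
    r <- chrom$regions[[nm]]
    writeLines(sprintf("     misc_feature    %d..%d", r$start, r$end), con)
    writeLines(sprintf("                     /label=\"%s\"", nm), con)
    writeLines(sprintf("                     /note=\"prophage_region packaging_strand=%s\"",
                       r$packaging_strand), con)
  }
  o <- chrom$orfs
  for (i in seq_len(nrow(o))) {
    loc <- sprintf("%d..%d", o$start[i], o$end[i])
    if (o$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf("                     /locus_tag=\"%s\"", o$id[i]), con)
    writeLines(sprintf("                     /product=\"%s\"", o$product[i]), con)
    writeLines(sprintf("                     /note=\"region=%s category=%s traits=%s length_aa=%d\"",
                       o$region[i], o$category[i], o$traits[i], o$length_aa[i]), con)
  }
  writeLines("//", con)
  invisible(path)
}

.gb_field <- function(note, key) {
  m <- regmatches(note, regexec(paste0(key, "=([^ \"]*)"), note))[[1]]
  if (length(m) < 2L) "" else m[2]
}

.read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("GenBank ", path, ": missing LOCUS line")
  toks <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "[[:space:]]+")[[1]]
  seqid <- toks[1]
  len <- suppressWarnings(as.integer(toks[2]))
  feats <- list(); cur <- NULL
  flush <- function(cur, feats) { if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur; feats }
  for (ln in lines) {
    if (grepl("^     [A-Za-z_]+ +", ln) && !grepl("^ {21}", ln)) {
      feats <- flush(cur, feats)
      toks <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      cur <- list(type = toks[1], loc = toks[2], quals = character(0))
    } else if (grepl("^ {21}/", ln) && !is.null(cur)) {
      cur$quals <- c(cur$quals, trimws(ln))
    }
  }
  feats <- flush(cur, feats)
  qual <- function(f, name) {
    hit <- grep(paste0("^/", name, "="), f$quals, value = TRUE)
    if (!length(hit)) return("")
    gsub("^\"|\"$", "", sub(paste0("^/", name, "="), "", hit[1]))
  }
  orf_rows <- list(); spans <- list()
  for (f in feats) {
    if (f$type == "CDS") {
      strand <- if (grepl("^complement\\(", f$loc)) "-" else "+"
      loc <- gsub("^complement\\(|\\)$", "", f$loc)
      m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
      if (length(m) < 3L) stop("GenBank ", path, ": malformed CDS location '", f$loc, "'")
      note <- qual(f, "note")
      orf_rows[[length(orf_rows) + 1L]] <- data.frame(
        id = qual(f, "locus_tag"), start = as.integer(m[2]), end = as.integer(m[3]),
        strand = strand, category = .gb_field(note, "category"),
        traits = .gb_field(note, "traits"), product = qual(f, "product"),
        length_aa = as.integer(.gb_field(note, "length_aa")),
        region = .gb_field(note, "region"), stringsAsFactors = FALSE)
    } else if (f$type == "misc_feature") {
      note <- qual(f, "note")
      if (grepl("prophage_region", note)) {
        m <- regmatches(f$loc, regexec("^(\\d+)\\.\\.(\\d+)$", f$loc))[[1]]
        spans[[length(spans) + 1L]] <- data.frame(
          region = qual(f, "label"), start = as.integer(m[2]), end = as.integer(m[3]),
          packaging_strand = .gb_field(note, "packaging_strand"),
          stringsAsFactors = FALSE)
      }
    }
  }
  orfs <- do.call(rbind, orf_rows)
  list(seqid = seqid, length = len, orfs = orfs,
       spans = if (length(spans)) do.call(rbind, spans) else NULL)
}

#' Read an annotated chromosome
#'
#' @param path Input file.
#' @param format One of `"feature_table"` (the TSV dialect of
#'   [write_feature_table]), `"gff3"`, or `"genbank"`.
#' @param seqid Sequence identifier to use when the format does not carry
#'   one (feature_table).
#' @return An `annotated_chromosome`. Regions are rebuilt from the `region`
#'   labels; when the format carries explicit region features (GFF3,
#'   GenBank) their spans and packaging strands are used, otherwise the span
#'   is the ORF envelope and the packaging strand is inferred from the
#'   majority ORF strand. Unknown product strings map to `category =
#'   "unknown"` with no traits.
#' @export
read_chromosome <- function(path, format = c("feature_table", "gff3", "genbank"),
                            seqid = "chromosome") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  parsed <- switch(format,
    feature_table = list(seqid = seqid, orfs = .read_feature_table(path, seqid),
                         spans = NULL),
    gff3 = .read_gff3(path),
    genbank = .read_genbank(path))
  orfs <- parsed$orfs
  orfs$category[is.na(orfs$category) | !nzchar(orfs$category)] <- "unknown"
  regions <- .regions_from_orfs(parsed$seqid, orfs, parsed$spans)
  annotated_chromosome(parsed$seqid, orfs, regions,
                       length = if (!is.null(parsed$length)) parsed$length else NA_integer_)
}

#' Write an annotated chromosome
#'
#' @param chrom An `annotated_chromosome`.
#' @param path Output file.
#' @param format `"feature_table"`, `"gff3"` or `"genbank"`.
#' @export
write_chromosome <- function(chrom, path,
                             format = c("feature_table", "gff3", "genbank")) {
  format <- match.arg(format)
  switch(format,
    feature_table = write_feature_table(chrom, path),
    gff3 = write_gff3(chrom, path),
    genbank = write_genbank(chrom, path))
}

## ------------------------------------------------------------- promoters

#' Read promoter calls
#'
#' TSV with columns `region position strand score`. Scores must lie in
#' `[0, 1]`.
#'
#' @param path Input TSV.
#' @return A data.frame of promoter calls.
#' @export
read_promoters <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  req <- c("region", "position", "strand", "score")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("promoter table ", path, ": missing column(s) ",
                         paste(miss, collapse = ", "))
  validate_promoters(df)
}

#' Validate a promoter-call table
#' @param df Data.frame with `region`, `position`, `strand`, `score`.
#' @return The validated data.frame.
#' @export
validate_promoters <- function(df) {
  if (any(!df$strand %in% c("+", "-")))
    stop("promoter table: invalid strand symbol")
  if (any(!is.finite(df$score) | df$score < 0 | df$score > 1))
    stop("promoter table: scores must lie in [0, 1]")
  df
}

#' Write promoter calls
#' @param promoters Promoter-call data.frame.
#' @param path Output TSV.
#' @export
write_promoters <- function(promoters, path) {
  utils::write.table(promoters, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Retain promoter calls at or above a score threshold
#'
#' Promoter predictions are used for lysogeny-switch typing only when their
#' score reaches the high-confidence band (default 0.87, the lower edge of
#' the 0.87-1.0 window used in the study design).
#'
#' @param promoters Promoter-call data.frame.
#' @param threshold Minimum score retained.
#' @return Filtered data.frame.
#' @export
filter_promoters <- function(promoters, threshold = 0.87) {
  validate_promoters(promoters)
  promoters[promoters$score >= threshold, , drop = FALSE]
}
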