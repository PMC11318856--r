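## DNase-protection qPCR quantification of spontaneously released phage:
## replicate aggregation, delta-Cq, 2^-ddCq normalization to a housekeeper,
## NTC-based detection calls.

#' Read a qPCR Cq replicate table
#'
#' CSV with columns `target`, `condition` (`treated`/`untreated`/`ntc`),
#' `replicate`, `cq`. Empty or `NA` Cq marks a non-amplifying well.
#'
#' @param path CSV file.
#' @return Data.frame of replicates.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("target", "condition", "replicate", "cq")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("qPCR table ", path, ": missing column(s) ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$condition), c("treated", "untreated", "ntc"))
  if (length(bad)) stop("qPCR table ", path, ": unknown condition '", bad[1], "'")
  df$cq <- suppressWarnings(as.numeric(df$cq))
  df
}

#' Aggregate Cq replicates to a mean
#'
#' Non-amplifying replicates (`NA`) are imputed at the cycle cap before
#' averaging, matching a 40-cycle protocol where a silent well is bounded
#' by the run length.
#'
#' @param replicates Numeric Cq values; `NA` for no amplification.
#' @param cq_cap Cycle cap (default 40).
#' @return Arithmetic mean Cq.
#' @export
aggregate_cq <- function(replicates, cq_cap = 40) {
  if (!length(replicates)) stop("aggregate_cq: empty replicate list")
  replicates[is.na(replicates)] <- cq_cap
  if (any(replicates <= 0 | replicates > cq_cap))
    stop("aggregate_cq: Cq values must lie in (0, cq_cap]")
  mean(replicates)
}

#' Difference in mean Cq between DNase-treated and untreated samples
#'
#' DNase treatment degrades unprotected DNA and raises Cq, so the delta is
#' expected to be non-negative for degradable targets; encapsidated
#' (protected) DNA keeps it small.
#'
#' @param treated_mean,untreated_mean Mean Cq values.
#' @return `treated_mean - untreated_mean`.
#' @export
delta_cq <- function(treated_mean, untreated_mean) {
  if (!is.finite(treated_mean) || !is.finite(untreated_mean))
    stop("delta_cq: means must be finite")
  treated_mean - untreated_mean
}

#' Housekeeper-normalized fold change (2^-ddCq)
#'
#' @param delta_cq_target Delta-Cq of the target.
#' @param delta_cq_housekeeper Delta-Cq of the housekeeper gene.
#' @return `2^-(delta_cq_target - delta_cq_housekeeper)`; strictly
#'   decreasing in the target delta, 1 when the deltas coincide.
#' @export
fold_change <- function(delta_cq_target, delta_cq_housekeeper) {
  if (!is.finite(delta_cq_target) || !is.finite(delta_cq_housekeeper))
    stop("fold_change: deltas must be finite")
  2^(-(delta_cq_target - delta_cq_housekeeper))
}

#' Detection call against the no-template control
#'
#' A target is detected when its treated-sample mean Cq clears the NTC by
#' `margin` cycles; with no NTC no call is made. A housekeeper whose treated
#' mean reaches or exceeds its NTC is fully degraded (complete removal of
#' unprotected bacterial DNA).
#'
#' @param treated_mean Mean treated Cq.
#' @param ntc_cq NTC Cq (or `NA` when absent).
#' @param margin Required clearance in cycles (default 0).
#' @return Logical: detected.
#' @export
detection_call <- function(treated_mean, ntc_cq, margin = 0) {
  if (!is.finite(treated_mean)) stop("detection_call: treated mean must be finite")
  if (is.na(ntc_cq)) return(FALSE)
  treated_mean < ntc_cq - margin
}

#' Analyze a DNase-protection qPCR panel
#'
#' Aggregates replicates per target and condition, computes per-target
#' delta-Cq (treated minus untreated), normalizes to the housekeeper by the
#' 2^-ddCq method, and makes NTC-based detection calls.
#'
#' @param panel Replicate data.frame as from [read_qpcr].
#' @param housekeeper Housekeeper target id (e.g. `"s10p"`).
#' @param cq_cap Cycle cap for non-amplifying wells.
#' @param margin NTC clearance margin (cycles).
#' @return A `qpcr_result` data.frame: target, treated_mean, untreated_mean,
#'   ntc_cq, delta_cq, ddcq, fold_change, detected, housekeeper_degraded
#'   (housekeeper row only), ordered by decreasing fold change with the
#'   housekeeper last.
#' @export
analyze_qpcr <- function(panel, housekeeper = "s10p", cq_cap = 40, margin = 0) {
  targets <- unique(panel$target)
  if (!housekeeper %in% targets)
    stop("housekeeper target '", housekeeper, "' not present in the panel")
  one <- function(tg) {
    sub <- panel[panel$target == tg, , drop = FALSE]
    tr <- sub$cq[sub$condition == "treated"]
    un <- sub$cq[sub$condition == "untreated"]
    if (!length(tr) || !length(un))
      stop("target ", tg, ": need treated and untreated replicates")
    ntc <- sub$cq[sub$condition == "ntc"]
    ntc <- if (length(ntc)) aggregate_cq(ntc, cq_cap) else NA_real_
    tm <- aggregate_cq(tr, cq_cap); um <- aggregate_cq(un, cq_cap)
    data.frame(target = tg, treated_mean = tm, untreated_mean = um,
               ntc_cq = ntc, delta_cq = delta_cq(tm, um),
               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, lapply(targets, one))
  hk <- res[res$target == housekeeper, , drop = FALSE]
  res$ddcq <- res$delta_cq - hk$delta_cq
  res$fold_change <- 2^(-res$ddcq)
  res$detected <- mapply(detection_call, res$treated_mean, res$ntc_cq,
                         MoreArgs = list(margin = margin))
  res$housekeeper_degraded <- res$target == housekeeper &
    !is.na(res$ntc_cq) & res$treated_mean >= res$ntc_cq
  is_hk <- res$target == housekeeper
  res <- rbind(res[!is_hk, , drop = FALSE][order(-res$fold_change[!is_hk]), ,
                                           drop = FALSE],
               res[is_hk, , drop = FALSE])
  rownames(res) <- NULL
  class(res) <- unique(c("qpcr_result", class(res)))
  res
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat("<qpcr_result>", sum(x$target != x$target[nrow(x)]), "targets +",
      "housekeeper; top target:", x$target[1],
      sprintf("(fold change %.3g)\n", x$fold_change[1]))
  print.data.frame(x, digits = 4)
  invisible(x)
}
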