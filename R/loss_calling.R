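#' Convert a staining fraction to an ordinal IHC score
#'
#' Loss of expression is defined as 0--5% of tumor cells with positive
#' nuclear staining in a focus. The default thresholds implement:
#' score 0 if `fraction <= t0` (inclusive), 1 if `t0 < fraction <= t1`,
#' 2 if `fraction > t1`.
#'
#' @param fraction_positive Numeric vector of fractions in \[0,1\].
#' @param t0 Loss threshold (default 0.05, inclusive).
#' @param t1 Strong-positive threshold (default 0.50).
#' @return Integer vector of scores in \{0,1,2\} (NA stays NA).
#' @export
call_score <- function(fraction_positive, t0 = 0.05, t1 = 0.50) {
  f <- as.numeric(fraction_positive)
  if (any(!is.na(f) & (f < 0 | f > 1))) stop("fraction_positive outside [0,1]")
  if (!(t0 >= 0 && t0 < t1 && t1 <= 1)) stop("require 0 <= t0 < t1 <= 1")
  out <- rep(NA_integer_, length(f))
  out[!is.na(f)] <- ifelse(f[!is.na(f)] <= t0, 0L,
                           ifelse(f[!is.na(f)] <= t1, 1L, 2L))
  out
}

#' Fill missing ordinal scores from staining fractions
#'
#' Cells that carry a fraction but no score get [call_score()] applied;
#' existing scores are never overwritten.
#'
#' @param cohort An `ihc_cohort`.
#' @inheritParams call_score
#' @return The cohort with its `score` column completed.
#' @export
apply_score_calls <- function(cohort, t0 = 0.05, t1 = 0.50) {
  s <- cohort$scores
  fill <- is.na(s$score) & !is.na(s$fraction_positive)
  s$score[fill] <- call_score(s$fraction_positive[fill], t0 = t0, t1 = t1)
  cohort$scores <- s
  cohort
}

#' Tumor-level loss call for one marker
#'
#' A tumor has lost a marker if any evaluable focus scores 0; it retains the
#' marker otherwise. With no evaluable focus the call is non-evaluable.
#'
#' @param scores Vector of focus scores for one tumor and one marker
#'   (NAs are non-evaluable foci).
#' @return `"lost"`, `"retained"` or `"non-evaluable"`.
#' @export
tumor_marker_loss <- function(scores) {
  s <- scores[!is.na(scores)]
  if (length(s) == 0L) return("non-evaluable")
  if (any(s == 0L)) "lost" else "retained"
}

#' Focus-level loss status table
#'
#' @param cohort An `ihc_cohort` (scores completed; see
#'   [apply_score_calls()]).
#' @return Long data.frame (tumor_id, stage, focus_id, marker, status) with
#'   status in lost/retained/non-evaluable.
#' @export
focus_loss_table <- function(cohort) {
  cohort <- apply_score_calls(cohort)
  s <- cohort$scores
  status <- ifelse(is.na(s$score), "non-evaluable",
                   ifelse(s$score == 0L, "lost", "retained"))
  data.frame(tumor_id = s$tumor_id, stage = s$stage, focus_id = s$focus_id,
             marker = s$marker, status = status, stringsAsFactors = FALSE)
}

#' Tumor-level loss status table
#'
#' Applies the any-focus rule of [tumor_marker_loss()] to every
#' (tumor, marker) pair.
#'
#' @inheritParams focus_loss_table
#' @return data.frame (tumor_id, stage, marker, status).
#' @export
tumor_loss_table <- function(cohort) {
  cohort <- apply_score_calls(cohort)
  s <- cohort$scores
  agg <- aggregate(score ~ tumor_id + stage + marker, data = s,
                   FUN = tumor_marker_loss, na.action = stats::na.pass)
  names(agg)[names(agg) == "score"] <- "status"
  agg[order(agg$tumor_id, match(agg$marker, cohort$markers)), ]
}

#' Loss prevalence by marker, level and stage
#'
#' At the focus level the denominator counts evaluable foci only; at the
#' tumor level it counts tumors with at least one evaluable focus for the
#' marker. Empty strata yield denominator 0 with proportion NA (flagged).
#'
#' @param cohort An `ihc_cohort`.
#' @param level `"tumor"` or `"focus"`.
#' @param by_stage If TRUE, adds per-stage rows; an `"all"` stratum is always
#'   included.
#' @return data.frame (marker, level, stage, n_lost, n_evaluable,
#'   proportion).
#' @export
prevalence_summary <- function(cohort, level = c("tumor", "focus"),
                               by_stage = FALSE) {
  level <- match.arg(level)
  tab <- if (level == "tumor") tumor_loss_table(cohort) else focus_loss_table(cohort)
  strata <- if (by_stage) c(ROMAN_STAGES, "all") else "all"
  rows <- lapply(strata, function(st) {
    sub <- if (st == "all") tab else tab[tab$stage == stage_to_int(st), ]
    do.call(rbind, lapply(cohort$markers, function(m) {
      x <- sub$status[sub$marker == m]
      den <- sum(x != "non-evaluable")
      num <- sum(x == "lost")
      data.frame(marker = m, level = level, stage = st,
                 n_lost = num, n_evaluable = den,
                 proportion = if (den > 0) num / den else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of tumors losing at least one marker
#'
#' @param cohort An `ihc_cohort`.
#' @param by_stage If TRUE, one row per stage plus an `"all"` row.
#' @return data.frame (stage, n_any_loss, n_tumors, fraction).
#' @export
any_loss_fraction <- function(cohort, by_stage = FALSE) {
  tl <- tumor_loss_table(cohort)
  any_lost <- tapply(tl$status == "lost", tl$tumor_id, any)
  stage <- stage_to_roman(vapply(split(tl$stage, tl$tumor_id), `[`, integer(1), 1L))
  strata <- if (by_stage) c(ROMAN_STAGES, "all") else "all"
  out <- do.call(rbind, lapply(strata, function(st) {
    sel <- if (st == "all") rep(TRUE, length(any_lost)) else stage == st
    data.frame(stage = st, n_any_loss = sum(any_lost[sel]),
               n_tumors = sum(sel),
               fraction = if (sum(sel) > 0) mean(any_lost[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
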