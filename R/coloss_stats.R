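#' 2x2 co-loss contingency table for a marker pair
#'
#' Units (tumors or foci) non-evaluable for either marker are excluded.
#' Cell layout: n11 both lost, n10 only `a` lost, n01 only `b` lost,
#' n00 neither lost.
#'
#' @param cohort An `ihc_cohort`.
#' @param a,b Distinct marker names.
#' @param level `"tumor"` or `"focus"`. Focus-level tables pool foci across
#'   tumors; within-tumor correlation is ignored (deliberately, mirroring
#'   the original procedure).
#' @param stage `"all"` or one of I--IV.
#' @return One-row data.frame (marker_a, marker_b, level, stage, n11, n10,
#'   n01, n00).
#' @export
contingency <- function(cohort, a, b, level = c("tumor", "focus"),
                        stage = "all") {
  level <- match.arg(level)
  if (identical(a, b)) stop("markers must differ")
  if (!all(c(a, b) %in% cohort$markers)) stop("unknown marker")
  tab <- if (level == "tumor") tumor_loss_table(cohort) else focus_loss_table(cohort)
  if (stage != "all") tab <- tab[tab$stage == stage_to_int(stage), ]
  unit <- if (level == "tumor") tab$tumor_id else paste(tab$tumor_id, tab$focus_id)
  ua <- unit[tab$marker == a]; sa <- tab$status[tab$marker == a]
  ub <- unit[tab$marker == b]; sb <- tab$status[tab$marker == b]
  common <- intersect(ua, ub)
  sa <- sa[match(common, ua)]; sb <- sb[match(common, ub)]
  keep <- sa != "non-evaluable" & sb != "non-evaluable"
  la <- sa[keep] == "lost"; lb <- sb[keep] == "lost"
  data.frame(marker_a = a, marker_b = b, level = level, stage = stage,
             n11 = sum(la & lb), n10 = sum(la & !lb),
             n01 = sum(!la & lb), n00 = sum(!la & !lb),
             stringsAsFactors = FALSE)
}

log_factorial <- function(n) lgamma(n + 1)

# log hypergeometric point probability of table [[a, r1-a], [c1-a, ...]]
# with row sums r1, r2 and first-column sum c1
log_hyper_point <- function(a, r1, r2, c1) {
  n <- r1 + r2
  (log_factorial(r1) + log_factorial(r2) + log_factorial(c1) +
     log_factorial(n - c1) - log_factorial(n) -
     log_factorial(a) - log_factorial(r1 - a) - log_factorial(c1 - a) -
     log_factorial(r2 - c1 + a))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p by the point-probability method: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' of tables whose point probability does not exceed that of the observed
#' table (with relative tolerance 1e-7 on the comparison). Computed from
#' log-factorials. When a row or column margin is zero only one table is
#' possible and p = 1 by convention (the result carries a `flagged`
#' attribute).
#'
#' @param n11,n10,n01,n00 Non-negative integer cell counts; alternatively
#'   `n11` may be a 2x2 matrix or a data.frame row as from [contingency()].
#' @return Two-sided p-value in (0, 1\].
#' @export
fisher_two_sided <- function(n11, n10 = NULL, n01 = NULL, n00 = NULL) {
  cells <- as_cells(n11, n10, n01, n00)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(structure(1, flagged = TRUE))
  }
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  ks <- lo:hi
  logp <- log_hyper_point(ks, r1, r2, c1)
  obs <- logp[ks == a]
  p <- sum(exp(logp[logp <= obs + log1p(1e-7)]))
  min(p, 1)
}

as_cells <- function(n11, n10, n01, n00) {
  if (is.matrix(n11)) {
    stopifnot(all(dim(n11) == c(2, 2)))
    return(as.numeric(c(n11[1, 1], n11[1, 2], n11[2, 1], n11[2, 2])))
  }
  if (is.data.frame(n11)) {
    return(as.numeric(c(n11$n11[1], n11$n10[1], n11$n01[1], n11$n00[1])))
  }
  as.numeric(c(n11, n10, n01, n00))
}

#' Odds ratio for a 2x2 table
#'
#' `(n11*n00) / (n10*n01)`; with the Haldane correction 0.5 is added to
#' every cell first, so the result is finite. Without correction a zero
#' denominator yields `Inf` (or `NaN` for the fully degenerate 0/0 case).
#'
#' @inheritParams fisher_two_sided
#' @param haldane Apply the Haldane 0.5 correction (default FALSE).
#' @return Non-negative ratio, possibly infinite.
#' @export
odds_ratio <- function(n11, n10 = NULL, n01 = NULL, n00 = NULL,
                       haldane = FALSE) {
  cells <- as_cells(n11, n10, n01, n00)
  if (haldane) cells <- cells + 0.5
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

#' Conditional co-loss fraction
#'
#' Among units (tumors or foci) that lost the `given` marker, the fraction
#' that also lost `then`.
#'
#' @param cohort An `ihc_cohort`.
#' @param given,then Distinct marker names.
#' @param level `"tumor"` or `"focus"`.
#' @param by_stage If TRUE, per-stage rows plus `"all"`.
#' @return data.frame (stage, n_given_lost, n_both, fraction); zero
#'   denominators yield fraction NA (flagged).
#' @export
conditional_coloss <- function(cohort, given, then,
                               level = c("tumor", "focus"), by_stage = FALSE) {
  level <- match.arg(level)
  strata <- if (by_stage) c(ROMAN_STAGES, "all") else "all"
  out <- do.call(rbind, lapply(strata, function(st) {
    ct <- contingency(cohort, given, then, level = level, stage = st)
    den <- ct$n11 + ct$n10
    data.frame(stage = st, n_given_lost = den, n_both = ct$n11,
               fraction = if (den > 0) ct$n11 / den else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' All-pairs co-loss analysis
#'
#' One row per unordered marker pair and level, with the 2x2 cells, the
#' exact two-sided p, Benjamini-Hochberg q over all rows, the
#' Haldane-corrected odds ratio, and conditional co-loss fractions in both
#' directions. Raw p-values replicate the original analysis; q-values are a
#' companion adjustment, never a substitute.
#'
#' @param cohort An `ihc_cohort` with at least 2 markers scored.
#' @param levels Levels to analyse (default both tumor and focus).
#' @param stage Stage stratum (default `"all"`).
#' @return data.frame, `choose(n_markers, 2) * length(levels)` rows.
#' @export
all_pairs <- function(cohort, levels = c("tumor", "focus"), stage = "all") {
  mk <- cohort$markers
  if (length(mk) < 2L) stop("need at least 2 markers")
  pairs <- utils::combn(mk, 2L)
  rows <- list()
  for (lv in levels) {
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      ct <- contingency(cohort, a, b, level = lv, stage = stage)
      p <- fisher_two_sided(ct)
      ct$p_two_sided <- as.numeric(p)
      ct$degenerate <- isTRUE(attr(p, "flagged"))
      ct$odds_ratio <- odds_ratio(ct, haldane = TRUE)
      ct$frac_b_given_a <- if (ct$n11 + ct$n10 > 0) ct$n11 / (ct$n11 + ct$n10) else NA_real_
      ct$frac_a_given_b <- if (ct$n11 + ct$n01 > 0) ct$n11 / (ct$n11 + ct$n01) else NA_real_
      rows[[length(rows) + 1L]] <- ct
    }
  }
  out <- do.call(rbind, rows)
  out$q_bh <- stats::p.adjust(out$p_two_sided, method = "BH")
  rownames(out) <- NULL
  out
}
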