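#' Run the full ITH analysis pipeline
#'
#' Executes loss calling, clonal tree construction and co-loss statistics
#' on an input score table and writes all result tables: prevalence by
#' marker/level/stage, any-loss fractions, per-tumor Newick trees and shape
#' summary, and the all-pairs co-loss table. The configuration is echoed to
#' the output directory for provenance.
#'
#' @param config Named list or path to a YAML file with fields: `input`
#'   (path), `dialect` (see [read_cohort()]), `t0`, `t1` (score
#'   thresholds), `tau`, `denominator` (truncal rule), `policy` (conflict
#'   policy), `out_dir`. All but `input` and `out_dir` have defaults.
#' @param quiet Suppress per-stage record-count logging.
#' @return Manifest data.frame from [write_results()], plus the run's
#'   tables as attribute `tables`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(dialect = "long-csv", t0 = 0.05, t1 = 0.50, tau = 0.75,
                   denominator = "evaluable", policy = "split")
  config <- utils::modifyList(defaults, config)
  if (is.null(config$input) || is.null(config$out_dir)) {
    stop("config must provide 'input' and 'out_dir'")
  }
  log <- function(...) if (!quiet) message(sprintf(...))

  cohort <- read_cohort(config$input, dialect = config$dialect)
  cohort <- apply_score_calls(cohort, t0 = config$t0, t1 = config$t1)
  log("read %d records, %d tumors [loss_calling]",
      nrow(cohort$scores), n_tumors(cohort))

  prev_tumor <- prevalence_summary(cohort, "tumor", by_stage = TRUE)
  prev_focus <- prevalence_summary(cohort, "focus", by_stage = TRUE)
  anyloss <- any_loss_fraction(cohort, by_stage = TRUE)
  log("prevalence: %d rows [loss_calling]", nrow(prev_tumor) + nrow(prev_focus))

  ts <- cohort_tree_summary(cohort, tau = config$tau,
                            denominator = config$denominator,
                            policy = config$policy)
  log("trees: %d tumors [clonal_phylogeny]", nrow(ts$per_tumor))

  pairs <- all_pairs(cohort)
  log("co-loss: %d pair tables [coloss_stats]", nrow(pairs))

  tables <- list(prevalence_tumor = prev_tumor, prevalence_focus = prev_focus,
                 any_loss = anyloss, tree_per_tumor = ts$per_tumor,
                 tree_by_stage = ts$by_stage, marker_events = ts$marker_events,
                 coloss_pairs = pairs,
                 run_config = config)
  manifest <- write_results(tables, config$out_dir)
  # one Newick file per tumor
  tree_dir <- file.path(config$out_dir, "trees")
  dir.create(tree_dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(ts$trees)) {
    writeLines(to_newick(ts$trees[[id]]), file.path(tree_dir, paste0(id, ".nwk")))
  }
  manifest <- rbind(manifest,
                    data.frame(file = file.path("trees", paste0(names(ts$trees), ".nwk")),
                               rows = 1L, stringsAsFactors = FALSE))
  log("wrote %d files to %s [cli_report]", nrow(manifest), config$out_dir)
  attr(manifest, "tables") <- tables
  manifest
}

#' Reproduce the study's summary numbers from its score table
#'
#' Runs the pipeline on the study's supplementary focus-level score table
#' and emits a side-by-side comparison of computed against published
#' values: tumor-level loss counts, focus-level percentages, stage-IV PBRM1
#' prevalence, per-stage any-loss fractions, and the maximum two-sided
#' Fisher p over the 20 marker-pair tables.
#'
#' @param s1_path Path to the study's focus-level score workbook
#'   (supplementary file pone.0164554.s003.xls) or an equivalent CSV.
#' @param dialect Input dialect (default `"s1-xls"`).
#' @param out_dir Optional output directory for full pipeline results.
#' @return data.frame (quantity, computed, published, match) with one row
#'   per checked value; attribute `note` flags a cohort of unexpected size.
#' @export
reproduce_study <- function(s1_path, dialect = "s1-xls", out_dir = NULL) {
  if (!file.exists(s1_path)) {
    stop("score table not found: ", s1_path,
         "\nThis is the study's supplementary file pone.0164554.s003.xls ",
         "(focus-level IHC scores); download it from the journal and pass ",
         "its path.")
  }
  cohort <- read_cohort(s1_path, dialect = dialect)
  published <- list(
    tumor_counts = c(PBRM1 = 49, ARID1A = 81, SETD2 = 23, BRG1 = 24, BRM = 61),
    tumor_denominator = 160,
    focus_pct = c(PBRM1 = 17, ARID1A = 32, SETD2 = 6.1, BRG1 = 6.9, BRM = 22),
    stage4_pbrm1_pct = 50,
    any_loss_pct = c(I = 58, II = 58, III = 65, IV = 75),
    max_fisher_p = 0.0019)

  prev_t <- prevalence_summary(cohort, "tumor", by_stage = TRUE)
  prev_f <- prevalence_summary(cohort, "focus", by_stage = TRUE)
  anyl <- any_loss_fraction(cohort, by_stage = TRUE)
  pairs <- all_pairs(cohort)
  if (!is.null(out_dir)) {
    write_results(list(prevalence_tumor = prev_t, prevalence_focus = prev_f,
                       any_loss = anyl, coloss_pairs = pairs), out_dir)
  }

  rows <- list()
  add <- function(quantity, computed, pub, digits = 0) {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, computed = computed, published = pub,
      match = !is.na(computed) && round(computed, digits) == pub,
      stringsAsFactors = FALSE)
  }
  for (m in names(published$tumor_counts)) {
    r <- prev_t[prev_t$marker == m & prev_t$stage == "all", ]
    add(paste0("tumor_losses_", m), r$n_lost, published$tumor_counts[[m]])
  }
  for (m in names(published$focus_pct)) {
    r <- prev_f[prev_f$marker == m & prev_f$stage == "all", ]
    digits <- if (published$focus_pct[[m]] %% 1 > 0) 1 else 0
    add(paste0("focus_pct_", m), 100 * r$proportion,
        published$focus_pct[[m]], digits)
  }
  r <- prev_t[prev_t$marker == "PBRM1" & prev_t$stage == "IV", ]
  add("stage_IV_PBRM1_pct", 100 * r$proportion, published$stage4_pbrm1_pct)
  for (st in names(published$any_loss_pct)) {
    add(paste0("any_loss_pct_", st),
        100 * anyl$fraction[anyl$stage == st], published$any_loss_pct[[st]])
  }
  add("max_fisher_p", max(pairs$p_two_sided), published$max_fisher_p, 4)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n <- n_tumors(cohort)
  attr(out, "note") <- if (n != published$tumor_denominator) {
    sprintf("cohort has %d tumors, published denominator is %d", n,
            published$tumor_denominator)
  } else NA_character_
  out
}
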