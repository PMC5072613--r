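#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions: 40 tumors in each of stages
#' I--IV, four foci per tumor (one stage-I tumor contributing only two
#' foci), five markers, marker-loss rates and stage trends plugged in from
#' the study's printed per-stage prevalences, and two co-loss bundles
#' (PBRM1+ARID1A, BRG1+BRM) reproducing the strong observed co-losses.
#'
#' @param n_per_stage Tumors per stage (default 40).
#' @param n_foci Foci per tumor (default 4; must be >= 2).
#' @param two_focus_tumor If TRUE (default) the first stage-I tumor has only
#'   2 foci.
#' @param markers Marker registry.
#' @param p_truncal,p_branch Named per-marker probabilities that the marker
#'   (outside a bundle) is lost as a truncal / branch event.
#' @param bundles List of co-loss bundles, each `list(markers=, prob=)`:
#'   the member markers co-occur as a single loss event with the given
#'   probability.
#' @param bundle_truncal_frac Probability a sampled bundle event is truncal.
#' @param stage_multiplier markers x 4 matrix of per-stage multipliers
#'   applied to all loss probabilities (default derived from the study's
#'   per-stage prevalences, normalised to mean 1 per marker).
#' @param clone_fraction Function n -> n sampled branch clone fractions in
#'   (0,1) (default Beta(2,2)).
#' @param score_noise Probability an expressed focus scores 1 instead of 2.
#' @param missing_rate Probability a cell is non-evaluable.
#' @param require_all_sampled If TRUE, focus-to-clone assignment guarantees
#'   every planted clone is sampled by at least one focus (branch clones in
#'   excess of the focus count are dropped); used for identifiability
#'   checks.
#' @param seed Mandatory RNG seed.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_stage = 40L,
                       n_foci = 4L,
                       two_focus_tumor = TRUE,
                       markers = ith_markers(),
                       p_truncal = c(PBRM1 = 0.038, ARID1A = 0.172,
                                     SETD2 = 0.073, BRG1 = 0.013, BRM = 0.145),
                       p_branch = c(PBRM1 = 0.053, ARID1A = 0.276,
                                    SETD2 = 0.104, BRG1 = 0.018, BRM = 0.226),
                       bundles = list(
                         list(markers = c("PBRM1", "ARID1A"), prob = 0.286),
                         list(markers = c("BRG1", "BRM"), prob = 0.149)),
                       bundle_truncal_frac = 0.5,
                       stage_multiplier = default_stage_multiplier(),
                       clone_fraction = function(n) stats::rbeta(n, 2, 2),
                       score_noise = 0.10,
                       missing_rate = 0.02,
                       require_all_sampled = FALSE,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (n_foci < 2L) stop("n_foci must be >= 2")
  probs <- c(p_truncal, p_branch, bundle_truncal_frac, score_noise,
             missing_rate, vapply(bundles, `[[`, numeric(1), "prob"))
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0,1]")
  if (!all(markers %in% names(p_truncal)) || !all(markers %in% names(p_branch))) {
    stop("p_truncal/p_branch must name every marker")
  }
  for (b in bundles) {
    if (!all(b$markers %in% markers)) stop("bundle marker outside registry")
  }
  if (!all(markers %in% rownames(stage_multiplier)) ||
      ncol(stage_multiplier) != 4L) {
    stop("stage_multiplier must be a markers x 4 matrix")
  }
  structure(list(n_per_stage = as.integer(n_per_stage),
                 n_foci = as.integer(n_foci),
                 two_focus_tumor = two_focus_tumor, markers = markers,
                 p_truncal = p_truncal, p_branch = p_branch,
                 bundles = bundles, bundle_truncal_frac = bundle_truncal_frac,
                 stage_multiplier = stage_multiplier,
                 clone_fraction = clone_fraction, score_noise = score_noise,
                 missing_rate = missing_rate,
                 require_all_sampled = require_all_sampled,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default per-stage loss-rate multipliers
#'
#' Derived from the study's per-stage tumor-level prevalences (for
#' instance PBRM1 25/30/18/50% across stages I--IV), normalised so each
#' marker's multipliers average 1; stage thereby shifts configured
#' probabilities without changing the cohort-wide mean.
#'
#' @return 5 x 4 numeric matrix (markers x stages).
#' @export
default_stage_multiplier <- function() {
  raw <- rbind(
    PBRM1  = c(0.25, 0.30, 0.18, 0.50),
    ARID1A = c(0.40, 0.50, 0.55, 0.58),
    SETD2  = c(0.05, 0.13, 0.15, 0.25),
    BRG1   = c(0.15, 0.25, 0.08, 0.13),
    BRM    = c(0.48, 0.45, 0.25, 0.35))
  sweep(raw, 1, rowMeans(raw), "/")
}

clip01 <- function(p) pmin(pmax(p, 0), 1)

resample <- function(x, ...) x[sample.int(length(x), ...)]

#' Simulate a cohort with planted clone trees
#'
#' Per tumor: truncal events (including sampled bundles) are carried by a
#' trunk clone present in all foci; each branch event forms its own clone
#' attached below the trunk (or to the root when no trunk exists, which can
#' produce multi-trunk tumors). Every focus is assigned to exactly one
#' clone; a marker is truly lost in a focus iff an ancestor-or-self clone
#' carries its loss event. Scores are 0 where lost, otherwise 2 (or 1 with
#' the score-noise rate); cells are blanked at the missing-cell rate.
#'
#' @param config A [sim_config()].
#' @return `list(cohort=, truth=)`: the `ihc_cohort` and per-tumor ground
#'   truth (planted events with supports, clone tree, focus-to-clone
#'   assignment, true expression matrix, and the observable `clone_tree`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mk <- config$markers
  score_rows <- list()
  truth <- list()
  for (s in 1:4) {
    for (t in seq_len(config$n_per_stage)) {
      tumor_id <- sprintf("S%s_T%02d", ROMAN_STAGES[s], t)
      nf <- if (config$two_focus_tumor && s == 1L && t == 1L) 2L else config$n_foci
      foci <- sprintf("F%d", seq_len(nf))
      mult <- config$stage_multiplier[mk, s]
      names(mult) <- mk

      # --- plant events -------------------------------------------------
      events <- list()   # list(markers=, type=)
      used <- character(0)
      for (b in config$bundles) {
        pb <- clip01(b$prob * mean(mult[b$markers]))
        if (stats::runif(1) < pb) {
          type <- if (stats::runif(1) < config$bundle_truncal_frac) "truncal" else "branch"
          events <- c(events, list(list(markers = b$markers, type = type)))
          used <- c(used, b$markers)
        }
      }
      for (m in setdiff(mk, used)) {
        if (stats::runif(1) < clip01(config$p_truncal[[m]] * mult[[m]])) {
          events <- c(events, list(list(markers = m, type = "truncal")))
        } else if (stats::runif(1) < clip01(config$p_branch[[m]] * mult[[m]])) {
          events <- c(events, list(list(markers = m, type = "branch")))
        }
      }

      # --- clone tree: 1 = root (WT); trunk clone holds all truncal events
      types <- vapply(events, `[[`, character(1), "type")
      has_trunk <- any(types == "truncal")
      clone_parent <- NA_integer_              # root
      event_clone <- integer(length(events))
      if (has_trunk) {
        clone_parent <- c(clone_parent, 1L)    # trunk clone = 2
        event_clone[types == "truncal"] <- 2L
      }
      branch_idx <- which(types == "branch")
      for (i in branch_idx) {
        existing <- seq_along(clone_parent)
        pool <- if (has_trunk) setdiff(existing, 1L) else existing
        par <- resample(pool, 1L)
        clone_parent <- c(clone_parent, par)
        event_clone[i] <- length(clone_parent)
      }

      # drop excess branch clones when every clone must receive a focus
      if (config$require_all_sampled) {
        while (length(clone_parent) - 1L > nf) {
          drop <- length(clone_parent)
          events <- events[event_clone != drop]
          types <- types[event_clone != drop]
          event_clone <- event_clone[event_clone != drop]
          clone_parent <- clone_parent[-drop]
        }
      }
      n_clones <- length(clone_parent)

      # --- focus-to-clone assignment ------------------------------------
      eligible <- if (has_trunk) setdiff(seq_len(n_clones), 1L) else seq_len(n_clones)
      if (length(eligible) == 0L) eligible <- 1L
      w <- numeric(n_clones)
      w[eligible] <- 1
      bc <- setdiff(eligible, c(1L, if (has_trunk) 2L))
      if (length(bc)) w[bc] <- config$clone_fraction(length(bc))
      assign_clone <- integer(nf)
      if (config$require_all_sampled) {
        must <- setdiff(seq_len(n_clones), 1L)
        seats <- resample(seq_len(nf), length(must))
        assign_clone[seats] <- must
        free <- which(assign_clone == 0L)
        if (length(free)) {
          assign_clone[free] <- resample(eligible, length(free),
                                         replace = TRUE, prob = w[eligible])
        }
      } else {
        assign_clone <- resample(eligible, nf, replace = TRUE,
                                 prob = w[eligible])
      }
      names(assign_clone) <- foci

      # --- supports and true expression ---------------------------------
      desc <- lapply(seq_len(n_clones), function(cl) {
        out <- cl
        repeat {
          add <- which(clone_parent %in% out & !(seq_len(n_clones) %in% out))
          if (!length(add)) break
          out <- c(out, add)
        }
        out
      })
      events <- lapply(seq_along(events), function(i) {
        e <- events[[i]]
        e$clone <- event_clone[i]
        e$support <- foci[assign_clone %in% desc[[event_clone[i]]]]
        e
      })
      lost <- matrix(FALSE, nrow = nf, ncol = length(mk),
                     dimnames = list(foci, mk))
      for (e in events) lost[e$support, e$markers] <- TRUE

      # --- observable truth tree (events grouped by shared support) -----
      obs <- Filter(function(e) length(e$support) > 0L, events)
      obs_events <- list()
      if (length(obs)) {
        key <- vapply(obs, function(e) paste(sort(e$support), collapse = "\r"),
                      character(1))
        for (k in unique(key)) {
          ms <- unique(unlist(lapply(obs[key == k], `[[`, "markers")))
          obs_events <- c(obs_events, list(list(
            markers = ms[order(match(ms, mk))],
            support = obs[key == k][[1]]$support)))
        }
      }
      truth_tree <- build_tree(obs_events, foci, tumor_id = tumor_id,
                               markers = mk)

      # --- emit scores ---------------------------------------------------
      score <- ifelse(lost, 0L,
                      ifelse(matrix(stats::runif(nf * length(mk)) < config$score_noise,
                                    nf, length(mk)), 1L, 2L))
      miss <- matrix(stats::runif(nf * length(mk)) < config$missing_rate,
                     nf, length(mk))
      score[miss] <- NA_integer_
      score_rows[[tumor_id]] <- data.frame(
        tumor_id = tumor_id, stage = ROMAN_STAGES[s],
        focus_id = rep(foci, times = length(mk)),
        marker = rep(mk, each = nf),
        score = as.integer(score), stringsAsFactors = FALSE)
      truth[[tumor_id]] <- list(
        tumor_id = tumor_id, stage = s, foci = foci, events = events,
        clone_parent = clone_parent, clone_assignment = assign_clone,
        expression_lost = lost, tree = truth_tree)
    }
  }
  scores <- do.call(rbind, score_rows)
  rownames(scores) <- NULL
  cohort <- suppressWarnings(as_cohort(
    scores, markers = mk,
    provenance = sprintf("simulated (seed %d)", config$seed)))
  list(cohort = cohort, truth = truth, config = config)
}

canonical_newick <- function(tree) {
  ser <- function(i) {
    kids <- tree_children(tree, i)
    if (!length(kids)) return(tree$labels[i])
    parts <- sort(vapply(kids, ser, character(1)))
    paste0("(", paste(parts, collapse = ","), ")", tree$labels[i])
  }
  paste0(ser(1L), ";")
}

#' Compare reconstructed trees against simulation ground truth
#'
#' Topology match uses a canonical label-preserving serialization (children
#' sorted lexicographically), so it is invariant to sibling order.
#' Truncal/branch ground-truth labels are positional: the classification
#' rule applied to the planted tree. Planted events sampled by no focus are
#' counted as sampling misses, not errors.
#'
#' @param trees Named list of reconstructed `clone_tree`s (see
#'   [build_cohort_trees()]).
#' @param truth Ground truth from [simulate_cohort()].
#' @param tau,denominator Passed to [classify_events()] on both trees.
#' @return `list(per_tumor=, summary=)`; per-tumor columns: topology_match,
#'   label_accuracy, support_jaccard, n_events_true, n_unsampled.
#' @export
recovery_report <- function(trees, truth, tau = 0.75,
                            denominator = "evaluable") {
  ids <- names(truth)
  if (!all(ids %in% names(trees))) {
    stop("mismatched tumor ids between trees and truth")
  }
  rows <- lapply(ids, function(id) {
    tt <- truth[[id]]
    rec <- trees[[id]]
    match_top <- identical(canonical_newick(rec), canonical_newick(tt$tree))
    lab_t <- marker_labels(tt$tree, tau, denominator)
    lab_r <- marker_labels(rec, tau, denominator)
    acc <- if (length(lab_t)) {
      mean(vapply(names(lab_t), function(m) {
        identical(lab_r[[m]], lab_t[[m]])
      }, logical(1)))
    } else NA_real_
    jac <- if (length(lab_t)) {
      mean(vapply(names(lab_t), function(m) {
        st <- true_marker_support(tt, m)
        sr <- rec_marker_support(rec, m)
        length(intersect(st, sr)) / length(union(st, sr))
      }, numeric(1)))
    } else NA_real_
    data.frame(tumor_id = id, topology_match = match_top,
               label_accuracy = acc, support_jaccard = jac,
               n_events_true = length(tt$events),
               n_unsampled = sum(vapply(tt$events, function(e) {
                 length(e$support) == 0L
               }, logical(1))),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  list(per_tumor = per,
       summary = list(
         topology_match_rate = mean(per$topology_match),
         label_accuracy = mean(per$label_accuracy, na.rm = TRUE),
         mean_support_jaccard = mean(per$support_jaccard, na.rm = TRUE),
         n_tumors = nrow(per),
         n_unsampled_events = sum(per$n_unsampled)))
}

# marker -> truncal/branch label (possibly multiple labels if the marker
# appears in several convergent events; collapsed to unique)
marker_labels <- function(tree, tau, denominator) {
  cls <- classify_events(tree, tau = tau, denominator = denominator)
  out <- list()
  for (k in seq_len(nrow(cls))) {
    for (m in tree$markers[[cls$node[k]]]) {
      out[[m]] <- sort(unique(c(out[[m]], cls$label[k])))
    }
  }
  out
}

true_marker_support <- function(tt, m) {
  sort(unique(unlist(lapply(tt$events, function(e) {
    if (m %in% e$markers) e$support else character(0)
  }))))
}

rec_marker_support <- function(tree, m) {
  idx <- which(vapply(tree$markers, function(ms) m %in% ms, logical(1)))
  sort(unique(unlist(tree$supports[idx])))
}
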