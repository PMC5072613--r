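#' Per-tumor binary loss matrix
#'
#' @param cohort An `ihc_cohort`.
#' @param tumor_id Tumor to extract.
#' @return Logical matrix foci x markers: TRUE = lost, FALSE = retained,
#'   NA = non-evaluable cell.
#' @export
loss_matrix <- function(cohort, tumor_id) {
  fl <- focus_loss_table(cohort)
  fl <- fl[fl$tumor_id == tumor_id, ]
  if (nrow(fl) == 0L) stop("unknown tumor: ", tumor_id)
  foci <- unique(fl$focus_id)
  mk <- cohort$markers
  mat <- matrix(NA, nrow = length(foci), ncol = length(mk),
                dimnames = list(foci, mk))
  idx <- cbind(match(fl$focus_id, foci), match(fl$marker, mk))
  mat[idx] <- ifelse(fl$status == "non-evaluable", NA, fl$status == "lost")
  mat
}

#' Group lost markers into loss events by shared focus support
#'
#' Markers lost in exactly the same set of foci are interpreted as one
#' clonal event. Markers never lost produce no event. Events are ordered by
#' descending support size, ties broken by the fixed marker registry order;
#' markers within an event follow registry order.
#'
#' @param mat Logical loss matrix (foci x markers) as from [loss_matrix()].
#' @param markers Marker registry giving the tie-break order (defaults to
#'   the matrix column order).
#' @return List of events, each `list(markers=, support=)` with `support` a
#'   character vector of focus ids.
#' @export
extract_events <- function(mat, markers = colnames(mat)) {
  evaluable_foci <- rownames(mat)[rowSums(!is.na(mat)) > 0L]
  if (length(evaluable_foci) == 0L) stop("no evaluable focus")
  supports <- lapply(markers, function(m) {
    col <- mat[, m]
    rownames(mat)[!is.na(col) & col]
  })
  names(supports) <- markers
  supports <- supports[vapply(supports, length, integer(1)) > 0L]
  if (length(supports) == 0L) return(list())
  key <- vapply(supports, function(s) paste(sort(s), collapse = "\r"), character(1))
  groups <- split(names(supports), key)
  events <- lapply(groups, function(ms) {
    list(markers = ms[order(match(ms, markers))],
         support = supports[[ms[1]]])
  })
  order_events(unname(events), markers)
}

order_events <- function(events, markers) {
  if (length(events) <= 1L) return(events)
  size <- vapply(events, function(e) length(e$support), integer(1))
  first <- vapply(events, function(e) min(match(e$markers, markers)), integer(1))
  events[order(-size, first)]
}

#' Relation between two focus support sets
#'
#' @param s1,s2 Non-empty character vectors of focus ids.
#' @return `"equal"`, `"nested"` (one strictly contains the other),
#'   `"disjoint"`, or `"conflict"` (overlapping but non-nested).
#' @export
pair_relation <- function(s1, s2) {
  if (length(s1) == 0L || length(s2) == 0L) stop("empty support set")
  s1 <- unique(s1); s2 <- unique(s2)
  inter <- length(intersect(s1, s2))
  if (inter == 0L) return("disjoint")
  if (inter == length(s1) && inter == length(s2)) return("equal")
  if (inter == length(s1) || inter == length(s2)) return("nested")
  "conflict"
}

is_laminar <- function(events) {
  n <- length(events)
  if (n <= 1L) return(TRUE)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- pair_relation(events[[i]]$support, events[[j]]$support)
    if (r %in% c("conflict", "equal")) return(FALSE)
  }
  TRUE
}

#' Resolve support conflicts into a laminar event family
#'
#' Two events conflict when their supports overlap but neither contains the
#' other; a rooted clone tree cannot represent both as single events. Under
#' the `split` policy the later event (in the deterministic descending-
#' support order) is split on the intersection and difference with the
#' event it conflicts with, and the pieces are treated as parallel,
#' convergent occurrences of the same marker loss. A piece whose support
#' coincides with an existing event is merged into it. The `strict` policy
#' raises an error naming the first conflicting pair.
#'
#' @param events Event list from [extract_events()].
#' @param policy `"split"` (default) or `"strict"`.
#' @param markers Marker registry for deterministic ordering.
#' @return `list(events=, log=)` where `log` is a data.frame recording each
#'   split/merge (empty when the input was already laminar).
#' @export
resolve_conflicts <- function(events, policy = c("split", "strict"),
                              markers = ith_markers()) {
  policy <- match.arg(policy)
  events <- order_events(events, markers)
  log <- data.frame(markers = character(0), action = character(0),
                    with = character(0), support = character(0),
                    stringsAsFactors = FALSE)
  accepted <- list()
  for (ev in events) {
    pieces <- list(ev$support)
    # split repeatedly until every piece is nested in / disjoint from all
    # accepted supports
    repeat {
      changed <- FALSE
      new_pieces <- list()
      for (p in pieces) {
        hit <- NULL
        for (a in accepted) {
          if (pair_relation(p, a$support) == "conflict") { hit <- a; break }
        }
        if (is.null(hit)) {
          new_pieces <- c(new_pieces, list(p))
        } else {
          if (policy == "strict") {
            stop(sprintf("conflicting support sets: (%s) vs (%s)",
                         paste(ev$markers, collapse = "+"),
                         paste(hit$markers, collapse = "+")))
          }
          inter <- intersect(p, hit$support)
          diff <- setdiff(p, hit$support)
          log <- rbind(log, data.frame(
            markers = paste(ev$markers, collapse = "+"), action = "split",
            with = paste(hit$markers, collapse = "+"),
            support = paste(sort(p), collapse = ","),
            stringsAsFactors = FALSE))
          new_pieces <- c(new_pieces, list(inter), list(diff))
          changed <- TRUE
        }
      }
      pieces <- new_pieces
      if (!changed) break
    }
    # deterministic piece order: largest first, then by focus ids
    pieces <- pieces[order(-vapply(pieces, length, integer(1)),
                           vapply(pieces, function(p) paste(sort(p), collapse = ","),
                                  character(1)))]
    for (p in pieces) {
      same <- which(vapply(accepted, function(a) {
        setequal(a$support, p)
      }, logical(1)))
      if (length(same)) {
        ms <- union(accepted[[same[1]]]$markers, ev$markers)
        accepted[[same[1]]]$markers <- ms[order(match(ms, markers))]
        log <- rbind(log, data.frame(
          markers = paste(ev$markers, collapse = "+"), action = "merge",
          with = paste(accepted[[same[1]]]$markers, collapse = "+"),
          support = paste(sort(p), collapse = ","),
          stringsAsFactors = FALSE))
      } else {
        accepted <- c(accepted, list(list(markers = ev$markers, support = p)))
      }
    }
  }
  list(events = order_events(accepted, markers), log = log)
}

#' Build a clonal tree from a laminar event family
#'
#' The root is the loss-free founder (WT) supported by every evaluable
#' focus. Each event becomes one node whose parent is the event with the
#' smallest support strictly containing it (the root if none). Siblings are
#' ordered by descending support size then marker registry order.
#'
#' @param events Laminar event list (run [resolve_conflicts()] first if the
#'   family may conflict).
#' @param evaluable_foci Character vector of the tumor's evaluable foci.
#' @param tumor_id Optional id carried on the tree.
#' @param markers Marker registry for deterministic ordering.
#' @return Object of class `clone_tree`: list with `tumor_id`, `labels`,
#'   `markers` (list), `supports` (list), `parent` (integer vector, NA at
#'   the root, node 1 = root).
#' @export
build_tree <- function(events, evaluable_foci, tumor_id = NULL,
                       markers = ith_markers()) {
  if (length(evaluable_foci) == 0L) stop("no evaluable focus")
  events <- order_events(events, markers)
  if (!is_laminar(events)) {
    stop("events do not form a laminar family; run resolve_conflicts() first")
  }
  n <- length(events)
  supports <- c(list(sort(unique(evaluable_foci))),
                lapply(events, function(e) sort(unique(e$support))))
  labels <- c("WT", vapply(events, function(e) paste(e$markers, collapse = "+"),
                           character(1)))
  mks <- c(list(character(0)), lapply(events, `[[`, "markers"))
  parent <- rep(NA_integer_, n + 1L)
  if (n > 0L) {
    sizes <- vapply(supports, length, integer(1))
    for (i in seq_len(n) + 1L) {
      if (!all(supports[[i]] %in% supports[[1]])) {
        stop("event support outside evaluable foci")
      }
      candidates <- which(vapply(seq_len(n) + 1L, function(j) {
        j != i && all(supports[[i]] %in% supports[[j]]) &&
          sizes[j] > sizes[i]
      }, logical(1))) + 1L
      parent[i] <- if (length(candidates)) {
        candidates[which.min(sizes[candidates])]
      } else 1L
    }
  }
  structure(list(tumor_id = tumor_id, labels = labels, markers = mks,
                 supports = supports, parent = parent),
            class = "clone_tree")
}

tree_children <- function(tree, i) which(!is.na(tree$parent) & tree$parent == i)

tree_depths <- function(tree) {
  d <- rep(0L, length(tree$labels))
  for (i in seq_along(d)[-1]) {
    j <- i; k <- 0L
    while (!is.na(tree$parent[j])) { j <- tree$parent[j]; k <- k + 1L }
    d[i] <- k
  }
  d
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("clone_tree%s: %d event(s)\n",
              if (!is.null(x$tumor_id)) paste0(" [", x$tumor_id, "]") else "",
              length(x$labels) - 1L))
  cat(" ", to_newick(x), "\n")
  invisible(x)
}

#' Classify loss events as truncal or branch
#'
#' An event attached directly to the root is truncal when its support covers
#' at least `tau` of the denominator foci; everything else is a branch
#' event. Root-attached events below the threshold are labelled branch and
#' flagged, since topologically they head a trunk.
#'
#' @param tree A `clone_tree`.
#' @param tau Truncal prevalence threshold in (0,1\]; default 0.75 ("all or
#'   most" regions).
#' @param denominator `"evaluable"` (all evaluable foci, the root support)
#'   or `"any-loss"` (foci carrying at least one loss).
#' @return data.frame (node, label_markers, n_support, label, flagged).
#' @export
classify_events <- function(tree, tau = 0.75,
                            denominator = c("evaluable", "any-loss")) {
  denominator <- match.arg(denominator)
  if (!(tau > 0 && tau <= 1)) stop("tau must lie in (0, 1]")
  n <- length(tree$labels)
  if (n == 1L) {
    return(data.frame(node = integer(0), label_markers = character(0),
                      n_support = integer(0), label = character(0),
                      flagged = logical(0), stringsAsFactors = FALSE))
  }
  den <- if (denominator == "evaluable") {
    length(tree$supports[[1]])
  } else {
    length(unique(unlist(tree$supports[-1])))
  }
  idx <- 2:n
  root_child <- tree$parent[idx] == 1L
  frac <- vapply(tree$supports[idx], length, integer(1)) / den
  label <- ifelse(root_child & frac >= tau, "truncal", "branch")
  data.frame(node = idx, label_markers = tree$labels[idx],
             n_support = vapply(tree$supports[idx], length, integer(1)),
             label = label, flagged = root_child & frac < tau,
             stringsAsFactors = FALSE)
}

TREE_SHAPES <- c("NO_LOSS", "TRUNK_ONLY", "BRANCHED", "BIFURCATED", "MULTI_TRUNK")

#' Classify the shape of a clonal tree
#'
#' `NO_LOSS` root-only; `MULTI_TRUNK` the root has two or more immediate
#' lineages; `BIFURCATED` some non-root node has two or more children;
#' otherwise the tree is a chain: `TRUNK_ONLY` at depth 1, `BRANCHED` at
#' depth two or more.
#'
#' @param tree A `clone_tree`.
#' @return One of NO_LOSS, TRUNK_ONLY, BRANCHED, BIFURCATED, MULTI_TRUNK.
#' @export
classify_shape <- function(tree) {
  n <- length(tree$labels)
  if (n == 1L) return("NO_LOSS")
  if (length(tree_children(tree, 1L)) >= 2L) return("MULTI_TRUNK")
  inner_deg <- vapply(2:n, function(i) length(tree_children(tree, i)), integer(1))
  if (any(inner_deg >= 2L)) return("BIFURCATED")
  if (max(tree_depths(tree)) == 1L) "TRUNK_ONLY" else "BRANCHED"
}

#' Serialize a clonal tree to Newick
#'
#' Node labels are marker names joined by `+` in registry order; the root is
#' labelled `WT`; no branch lengths. Children are emitted in the
#' deterministic sibling order (descending support size, then marker order).
#'
#' @param tree A `clone_tree`.
#' @return Single Newick string ending in `;`.
#' @export
to_newick <- function(tree) {
  sizes <- vapply(tree$supports, length, integer(1))
  first <- vapply(tree$markers, function(m) {
    idx <- match(m, ith_markers())
    if (length(idx) && any(!is.na(idx))) min(idx, na.rm = TRUE) else .Machine$integer.max
  }, double(1))
  ser <- function(i) {
    kids <- tree_children(tree, i)
    if (length(kids)) {
      kids <- kids[order(-sizes[kids], first[kids], tree$labels[kids])]
      paste0("(", paste(vapply(kids, ser, character(1)), collapse = ","), ")",
             tree$labels[i])
    } else {
      tree$labels[i]
    }
  }
  paste0(ser(1L), ";")
}

#' Reconstruct clonal trees for every tumor of a cohort
#'
#' Runs extract -> resolve -> build per tumor.
#'
#' @param cohort An `ihc_cohort`.
#' @param policy Conflict policy for [resolve_conflicts()].
#' @return Named list of `clone_tree` objects, one per tumor.
#' @export
build_cohort_trees <- function(cohort, policy = "split") {
  ids <- unique(cohort$scores$tumor_id)
  out <- lapply(ids, function(id) {
    mat <- loss_matrix(cohort, id)
    evaluable <- rownames(mat)[rowSums(!is.na(mat)) > 0L]
    if (length(evaluable) == 0L) return(NULL)
    ev <- extract_events(mat, markers = cohort$markers)
    res <- resolve_conflicts(ev, policy = policy, markers = cohort$markers)
    tr <- build_tree(res$events, evaluable, tumor_id = id,
                     markers = cohort$markers)
    attr(tr, "conflict_log") <- res$log
    tr
  })
  names(out) <- ids
  out[!vapply(out, is.null, logical(1))]
}

#' Cohort-wide tree summary
#'
#' @param cohort An `ihc_cohort`.
#' @param tau,denominator Passed to [classify_events()].
#' @param policy Conflict policy.
#' @return List with `per_tumor` (tumor_id, stage, shape, n_events,
#'   n_truncal, n_branch, newick), `by_stage` (shape counts, any-event
#'   fraction per stage), `marker_events` (truncal/branch event counts per
#'   marker), and `trees` (the clone_tree list).
#' @export
cohort_tree_summary <- function(cohort, tau = 0.75, denominator = "evaluable",
                                policy = "split") {
  trees <- build_cohort_trees(cohort, policy = policy)
  stages <- tumor_stages(cohort)
  per <- do.call(rbind, lapply(names(trees), function(id) {
    tr <- trees[[id]]
    cls <- classify_events(tr, tau = tau, denominator = denominator)
    data.frame(tumor_id = id, stage = stage_to_roman(stages[[id]]),
               shape = classify_shape(tr), n_events = nrow(cls),
               n_truncal = sum(cls$label == "truncal"),
               n_branch = sum(cls$label == "branch"),
               newick = to_newick(tr), stringsAsFactors = FALSE)
  }))
  per$shape <- factor(per$shape, levels = TREE_SHAPES)
  by_stage <- do.call(rbind, lapply(c(ROMAN_STAGES, "all"), function(st) {
    sel <- if (st == "all") rep(TRUE, nrow(per)) else per$stage == st
    counts <- table(per$shape[sel])
    cbind(data.frame(stage = st, n_tumors = sum(sel),
                     any_event_fraction = if (sum(sel)) {
                       mean(per$n_events[sel] > 0)
                     } else NA_real_,
                     stringsAsFactors = FALSE),
          as.data.frame.matrix(t(as.matrix(counts))))
  }))
  rownames(by_stage) <- NULL
  marker_events <- do.call(rbind, lapply(cohort$markers, function(m) {
    cnt <- c(truncal = 0L, branch = 0L)
    for (tr in trees) {
      cls <- classify_events(tr, tau = tau, denominator = denominator)
      has <- vapply(tr$markers[cls$node], function(ms) m %in% ms, logical(1))
      for (lb in c("truncal", "branch")) {
        cnt[lb] <- cnt[lb] + sum(has & cls$label == lb)
      }
    }
    data.frame(marker = m, n_truncal = cnt[["truncal"]],
               n_branch = cnt[["branch"]], stringsAsFactors = FALSE)
  }))
  list(per_tumor = per, by_stage = by_stage, marker_events = marker_events,
       trees = trees)
}
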