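fig4a_tree <- function() {
  mat <- fig4a_pattern()
  build_tree(extract_events(mat), rownames(mat), tumor_id = "SI_T05")
}

test_that("events group markers by identical focus support, worked example", {
  ev <- extract_events(fig4a_pattern())
  expect_length(ev, 2L)
  expect_equal(ev[[1]]$markers, c("ARID1A", "BRM"))
  expect_setequal(ev[[1]]$support, c("R1", "R2", "R3"))
  expect_equal(ev[[2]]$markers, c("PBRM1", "BRG1"))
  expect_equal(ev[[2]]$support, "R3")
})

test_that("all-retained matrix yields no events; groups equal column classes", {
  mk <- ith_markers()
  none <- matrix(FALSE, 4, 5, dimnames = list(paste0("R", 1:4), mk))
  expect_length(extract_events(none), 0L)

  set.seed(42)
  for (i in 1:100) {
    mat <- random_pattern(4, mk)
    ev <- extract_events(mat)
    # brute-force oracle: group columns by identity
    pat <- apply(mat, 2, function(col) paste(which(col), collapse = ","))
    expected <- split(mk, pat)
    expected <- expected[names(expected) != ""]
    got <- lapply(ev, `[[`, "markers")
    expect_setequal(lapply(got, sort), lapply(unname(expected), sort))
    # deterministic ordering: descending support, then registry order
    sizes <- vapply(ev, function(e) length(e$support), integer(1))
    firsts <- vapply(ev, function(e) min(match(e$markers, mk)), integer(1))
    expect_true(all(diff(sizes) <= 0))
    ties <- which(diff(sizes) == 0)
    expect_true(all(firsts[ties] < firsts[ties + 1L]))
  }
})

test_that("pair_relation covers equal, nested, disjoint, conflict", {
  expect_equal(pair_relation(c("R1", "R2", "R3"), "R3"), "nested")
  expect_equal(pair_relation("R1", "R2"), "disjoint")
  expect_equal(pair_relation(c("R1", "R2"), c("R2", "R3")), "conflict")
  expect_equal(pair_relation(c("R1", "R2"), c("R2", "R1")), "equal")
  expect_error(pair_relation(character(0), "R1"), "empty")
})

test_that("conflict resolution: laminar input unchanged, split is minimal", {
  ev <- extract_events(fig4a_pattern())
  res <- resolve_conflicts(ev)
  expect_equal(res$events, ev)
  expect_equal(nrow(res$log), 0L)

  conflicted <- list(list(markers = "PBRM1", support = c("R1", "R2")),
                     list(markers = "ARID1A", support = c("R2", "R3")))
  err <- tryCatch(resolve_conflicts(conflicted, policy = "strict"),
                  error = conditionMessage)
  expect_match(err, "PBRM1")
  expect_match(err, "ARID1A")
  res <- resolve_conflicts(conflicted, policy = "split")
  pb <- Filter(function(e) "ARID1A" %in% e$markers, res$events)
  expect_length(pb, 2L)
  expect_setequal(lapply(pb, `[[`, "support"), list("R2", "R3"))
  expect_true(any(res$log$action == "split"))
})

test_that("split policy is laminar, conserves evidence, and splits minimally", {
  set.seed(7)
  mk <- ith_markers()[1:4]
  for (i in 1:150) {
    mat <- random_pattern(4, mk, p = 0.4)
    ev <- extract_events(mat, markers = mk)
    res <- resolve_conflicts(ev, markers = mk)
    # laminar output
    sup <- lapply(res$events, `[[`, "support")
    if (length(sup) > 1) {
      for (a in seq_along(sup)[-1]) for (b in seq_len(a - 1)) {
        expect_true(pair_relation(sup[[a]], sup[[b]]) %in% c("nested", "disjoint"))
      }
    }
    # conservation: per-marker union of supports reproduces the column
    for (m in mk) {
      got <- sort(unique(unlist(lapply(res$events, function(e) {
        if (m %in% e$markers) e$support else character(0)
      }))))
      expect_equal(got, sort(rownames(mat)[mat[, m]]))
    }
    # greedy minimality: in deterministic event order, each event is cut into
    # as few pieces as any partition of its support compatible with the
    # laminar family accepted so far (oracle: enumerate all set partitions)
    if (nrow(res$log) > 0) {
      accepted <- list()
      for (e in ev) {
        pieces_sup <- lapply(Filter(function(r) {
          all(e$markers %in% r$markers) && all(r$support %in% e$support)
        }, res$events), `[[`, "support")
        if (length(pieces_sup) > 1) {
          best <- min(vapply(set_partitions(e$support), function(p) {
            if (compatible_with_family(p, accepted)) length(p) else Inf
          }, numeric(1)))
          expect_equal(length(pieces_sup), best)
        }
        accepted <- c(accepted, pieces_sup)
      }
    }
  }
})

test_that("tree construction follows containment; shapes classify correctly", {
  tr <- fig4a_tree()
  expect_equal(tr$labels, c("WT", "ARID1A+BRM", "PBRM1+BRG1"))
  expect_equal(tr$parent, c(NA, 1L, 2L))
  expect_equal(classify_shape(tr), "BRANCHED")
  expect_equal(to_newick(tr), "((PBRM1+BRG1)ARID1A+BRM)WT;")

  foci <- paste0("R", 1:4)
  # two disjoint maximal events -> two trunks
  two <- build_tree(list(list(markers = "PBRM1", support = c("R1", "R2")),
                         list(markers = "BRM", support = c("R3", "R4"))), foci)
  expect_equal(two$parent, c(NA, 1L, 1L))
  expect_equal(classify_shape(two), "MULTI_TRUNK")

  empty <- build_tree(list(), foci)
  expect_equal(classify_shape(empty), "NO_LOSS")
  expect_equal(to_newick(empty), "WT;")

  solo <- build_tree(list(list(markers = "SETD2", support = foci)), foci)
  expect_equal(classify_shape(solo), "TRUNK_ONLY")

  bifurc <- build_tree(list(
    list(markers = "ARID1A", support = foci),
    list(markers = "PBRM1", support = c("R1", "R2")),
    list(markers = "BRM", support = c("R3", "R4"))), foci)
  expect_equal(classify_shape(bifurc), "BIFURCATED")

  expect_error(build_tree(list(list(markers = "PBRM1", support = c("R1", "R2")),
                               list(markers = "BRM", support = c("R2", "R3"))),
                          foci), "laminar")
})

test_that("truncal rule: root children above tau, everything else branch", {
  tr <- fig4a_tree()
  cls <- classify_events(tr, tau = 0.75)
  expect_equal(cls$label[cls$label_markers == "ARID1A+BRM"], "truncal")
  expect_equal(cls$label[cls$label_markers == "PBRM1+BRG1"], "branch")
  expect_false(any(cls$flagged))

  foci <- paste0("R", 1:4)
  full <- build_tree(list(list(markers = "BRM", support = foci)), foci)
  for (tau in c(0.25, 0.75, 1)) {
    expect_equal(classify_events(full, tau = tau)$label, "truncal")
  }
  low <- build_tree(list(list(markers = "BRM", support = "R1")), foci)
  cls <- classify_events(low, tau = 0.75)
  expect_equal(cls$label, "branch")
  expect_true(cls$flagged)
  expect_error(classify_events(full, tau = 0), "tau")
  expect_error(classify_events(full, tau = 1.5), "tau")

  # any-loss denominator: 3 lost foci, event in all 3 -> truncal
  part <- build_tree(list(list(markers = "BRM", support = c("R1", "R2", "R3"))),
                     foci)
  expect_equal(classify_events(part, tau = 1, denominator = "any-loss")$label,
               "truncal")
  expect_equal(classify_events(part, tau = 1, denominator = "evaluable")$label,
               "branch")
})

test_that("newick output parses and round-trips topology", {
  skip_if_not_installed("ape")
  set.seed(19)
  mk <- ith_markers()
  for (i in 1:40) {
    mat <- random_pattern(4, mk, p = 0.35)
    ev <- resolve_conflicts(extract_events(mat))$events
    if (length(ev) == 0) next
    tr <- build_tree(ev, rownames(mat))
    ph <- ape::read.tree(text = to_newick(tr))
    expect_false(is.null(ph))
    labels <- c(ph$tip.label, ph$node.label)
    expect_setequal(labels, tr$labels)
    # node count preserved
    expect_equal(length(labels), length(tr$labels))
  }
})

test_that("cohort tree summary accounts for every tumor", {
  sim <- simulate_cohort(sim_config(seed = 23, n_per_stage = 10))
  ts <- cohort_tree_summary(sim$cohort)
  expect_equal(nrow(ts$per_tumor), n_tumors(sim$cohort))
  counts <- table(ts$per_tumor$shape)
  expect_equal(sum(counts), n_tumors(sim$cohort))
  all_row <- ts$by_stage[ts$by_stage$stage == "all", ]
  expect_equal(sum(all_row[, levels(ts$per_tumor$shape)]), n_tumors(sim$cohort))
  expect_equal(all_row$any_event_fraction,
               any_loss_fraction(sim$cohort)$fraction[1])
})
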