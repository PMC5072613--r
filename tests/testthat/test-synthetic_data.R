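test_that("config validation enforces probabilities, foci, mandatory seed", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, n_foci = 1), "n_foci")
  expect_error(sim_config(seed = 1, score_noise = 1.2), "probabilities")
  expect_error(sim_config(seed = 1, bundles = list(
    list(markers = c("PBRM1", "BAP1"), prob = 0.2))), "registry")
  cfg <- sim_config(seed = 1)
  expect_s3_class(cfg, "sim_config")
})

test_that("simulation is deterministic given config and seed", {
  a <- simulate_cohort(sim_config(seed = 99, n_per_stage = 8))
  b <- simulate_cohort(sim_config(seed = 99, n_per_stage = 8))
  expect_identical(a$cohort$scores, b$cohort$scores)
  expect_identical(lapply(a$truth, `[[`, "clone_assignment"),
                   lapply(b$truth, `[[`, "clone_assignment"))
  c <- simulate_cohort(sim_config(seed = 100, n_per_stage = 8))
  expect_false(identical(a$cohort$scores, c$cohort$scores))
})

test_that("cohort dimensions match the study design", {
  sim <- simulate_cohort(sim_config(seed = 12))
  expect_equal(n_tumors(sim$cohort), 160L)
  st <- table(stage_to_roman(tumor_stages(sim$cohort)))
  expect_equal(as.integer(st), rep(40L, 4))
  nf <- tapply(sim$cohort$scores$focus_id, sim$cohort$scores$tumor_id,
               function(f) length(unique(f)))
  expect_equal(sum(nf == 2L), 1L)  # the single two-focus tumor
  expect_equal(sum(nf == 4L), 159L)
  expect_equal(sum(nf), 638L)
})

test_that("zero loss probabilities give loss-free cohorts", {
  cfg <- sim_config(seed = 4, n_per_stage = 5,
                    p_truncal = setNames(rep(0, 5), ith_markers()),
                    p_branch = setNames(rep(0, 5), ith_markers()),
                    bundles = list(), missing_rate = 0)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$cohort$scores$score %in% 1:2))
  shapes <- vapply(build_cohort_trees(sim$cohort), classify_shape, character(1))
  expect_true(all(shapes == "NO_LOSS"))
})

test_that("truncal-only simulations recover trunk-only trees", {
  cfg <- sim_config(seed = 21, n_per_stage = 15,
                    p_branch = setNames(rep(0, 5), ith_markers()),
                    bundle_truncal_frac = 1, score_noise = 0,
                    missing_rate = 0)
  sim <- simulate_cohort(cfg)
  shapes <- vapply(build_cohort_trees(sim$cohort), classify_shape, character(1))
  expect_true(all(shapes %in% c("NO_LOSS", "TRUNK_ONLY")))
  expect_true(any(shapes == "TRUNK_ONLY"))
})

test_that("configured tumor-level loss probability is recovered", {
  # truncal losses hit every focus, so the tumor-level rate is the binomial
  # parameter exactly; 2000 tumors, plug-in rate 0.31
  cfg <- sim_config(seed = 37, n_per_stage = 500,
                    p_truncal = c(PBRM1 = 0.31, ARID1A = 0, SETD2 = 0,
                                  BRG1 = 0, BRM = 0),
                    p_branch = setNames(rep(0, 5), ith_markers()),
                    bundles = list(), score_noise = 0, missing_rate = 0,
                    stage_multiplier = matrix(1, 5, 4,
                                              dimnames = list(ith_markers(), NULL)))
  sim <- simulate_cohort(cfg)
  pt <- prevalence_summary(sim$cohort, "tumor")
  p_hat <- pt$proportion[pt$marker == "PBRM1"]
  se <- sqrt(0.31 * 0.69 / 2000)
  expect_lt(abs(p_hat - 0.31), 3 * se)
})

test_that("ground truth is internally consistent", {
  sim <- simulate_cohort(sim_config(seed = 44, n_per_stage = 10))
  for (tt in sim$truth[1:40]) {
    # every focus assigned to exactly one clone
    expect_equal(sort(names(tt$clone_assignment)), sort(tt$foci))
    expect_true(all(tt$clone_assignment %in% seq_along(tt$clone_parent)))
    # a marker is lost in a focus iff an ancestor-or-self clone carries it
    for (e in tt$events) {
      ancestors_of <- function(cl) {
        out <- cl
        while (!is.na(tt$clone_parent[cl])) {
          cl <- tt$clone_parent[cl]; out <- c(out, cl)
        }
        out
      }
      carried <- vapply(tt$foci, function(f) {
        e$clone %in% ancestors_of(tt$clone_assignment[[f]])
      }, logical(1))
      expect_equal(tt$foci[carried], e$support)
      for (m in e$markers) {
        expect_true(all(tt$expression_lost[carried, m]))
      }
    }
  }
})

test_that("noiseless fully sampled simulations are recovered exactly", {
  cfg <- sim_config(seed = 55, n_per_stage = 15, score_noise = 0,
                    missing_rate = 0, require_all_sampled = TRUE)
  sim <- simulate_cohort(cfg)
  trees <- build_cohort_trees(sim$cohort)
  rep <- recovery_report(trees, sim$truth)
  expect_equal(rep$summary$topology_match_rate, 1.0)
  expect_equal(rep$summary$label_accuracy, 1.0)
  expect_equal(rep$summary$mean_support_jaccard, 1.0)
  expect_equal(rep$summary$n_unsampled_events, 0L)
})

test_that("recovery degrades monotonically with missing cells", {
  base <- sim_config(seed = 61, n_per_stage = 15, score_noise = 0,
                     missing_rate = 0)
  noisy <- sim_config(seed = 61, n_per_stage = 15, score_noise = 0,
                      missing_rate = 0.5)
  r0 <- recovery_report(build_cohort_trees(simulate_cohort(base)$cohort),
                        simulate_cohort(base)$truth)
  r5 <- recovery_report(build_cohort_trees(simulate_cohort(noisy)$cohort),
                        simulate_cohort(noisy)$truth)
  expect_lte(r5$summary$topology_match_rate, r0$summary$topology_match_rate)
  expect_lte(r5$summary$mean_support_jaccard, r0$summary$mean_support_jaccard)
})

test_that("recovery_report rejects mismatched tumor ids", {
  sim <- simulate_cohort(sim_config(seed = 70, n_per_stage = 3))
  trees <- build_cohort_trees(sim$cohort)
  expect_error(recovery_report(trees[-1], sim$truth), "mismatch")
})
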