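test_that("Holm-Sidak step-down matches hand-computed values", {
  expect_equal(holm_sidak(c(0.01, 0.04)),
               c(1 - (1 - 0.01)^2, 0.04), tolerance = 1e-12)
  # order preserved, monotone along the step-down, never below raw
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(2:12, 1))
    adj <- holm_sidak(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    o <- order(p)
    expect_true(!is.unsorted(adj[o]))
  }
  expect_equal(holm_sidak(0.2), 0.2)
})

test_that("impact assembly forms within-experiment mutant:WT ratios", {
  resp <- expand.grid(variant = c("WT", "A", "B"),
                      experiment_id = c("E1", "E2", "E3"),
                      stringsAsFactors = FALSE)
  resp$assay <- "ca"
  resp$value <- ifelse(resp$variant == "WT", c(10, 20, 40)[
    match(resp$experiment_id, c("E1", "E2", "E3"))],
    ifelse(resp$variant == "A", c(5, 10, 20)[
      match(resp$experiment_id, c("E1", "E2", "E3"))], 0))
  imp <- assemble_impacts(resp)
  expect_equal(imp$mean_ratio[imp$variant == "WT"], 1)
  expect_equal(imp$mean_ratio[imp$variant == "A"], 0.5)
  expect_equal(imp$sem[imp$variant == "A"], 0)
  expect_equal(imp$mean_ratio[imp$variant == "B"], 0)
  # single experiment: SEM is reported missing
  one <- assemble_impacts(resp[resp$experiment_id == "E1", ])
  expect_true(all(is.na(one$sem)))
  # an experiment without WT is excluded with a warning
  resp2 <- resp[!(resp$variant == "WT" & resp$experiment_id == "E3"), ]
  expect_warning(imp2 <- assemble_impacts(resp2), "no WT")
  expect_equal(unique(imp2$n), 2L)
})

test_that("log-ratio ANOVA handles identical groups and detects shifts", {
  same <- data.frame(variant = rep(c("WT", "A", "B"), each = 3),
                     ratio = 1, experiment = rep(1:3, 3))
  an <- log_ratio_anova(same, repeated = TRUE)
  expect_true(all(an$comparisons$adj_p == 1))
  # translation invariance: scaling all ratios by a constant changes nothing
  set.seed(9)
  d <- data.frame(variant = rep(c("WT", "A", "B"), each = 4),
                  ratio = exp(rnorm(12, 0, 0.2)) *
                    rep(c(1, 0.3, 1), each = 4))
  a1 <- log_ratio_anova(d)
  d2 <- d; d2$ratio <- d$ratio * 7.3
  a2 <- log_ratio_anova(d2)
  expect_equal(a1$comparisons$raw_p, a2$comparisons$raw_p,
               tolerance = 1e-9)
  expect_lt(a1$comparisons$adj_p[a1$comparisons$comparison == "A vs WT"],
            0.05)
  expect_error(log_ratio_anova(data.frame(variant = c("WT", "WT", "A"),
                                          ratio = c(1, 1.1, 0.5))),
               "fewer than 2")
  neg <- d; neg$ratio[1] <- -1
  expect_error(log_ratio_anova(neg), "nonpositive")
  unbal <- data.frame(variant = c("WT", "WT", "A"), ratio = c(1, 1, 2),
                      experiment = c(1, 2, 1))
  expect_error(log_ratio_anova(unbal, repeated = TRUE), "balanced")
})

test_that("radar tables keep WT at unity and respect axis permutations", {
  resp <- expand.grid(variant = c("WT", "A"), experiment_id = c("E1", "E2"),
                      assay = c("binding", "ca", "arr3"),
                      stringsAsFactors = FALSE)
  resp$value <- ifelse(resp$variant == "WT", 10, 4)
  imp <- assemble_impacts(resp)
  rad <- radar_table(imp)
  expect_equal(rad$variant[1], "WT")
  expect_equal(unlist(rad[1, c("binding_ratio", "ca_ratio", "arr3_ratio")]),
               c(binding_ratio = 1, ca_ratio = 1, arr3_ratio = 1))
  perm <- radar_table(imp, axis_order = c("A", "WT"))
  expect_equal(perm$variant, c("A", "WT"))
  expect_equal(perm$ca_ratio[perm$variant == "A"],
               rad$ca_ratio[rad$variant == "A"])
  expect_error(radar_table(imp, axis_order = c("A", "Z")), "permutation")
  p <- withr::local_tempfile(fileext = ".svg")
  plot_radar(rad, p)
  expect_true(file.size(p) > 0)
})

test_that("bias index quantifies disproportionate pathway impact", {
  expect_equal(as.numeric(bias_index(0.5, 0.5)), 0)
  expect_equal(as.numeric(bias_index(1.0, 0.1)), 1)
  expect_error(bias_index(-1, 0.5), "positive")
  # generator with a calcium-only knockdown: index equals the planted
  # log-quotient of the two efficacy scales
  expect_equal(as.numeric(bias_index(0.15, 1.3)),
               abs(log10(0.15 / 1.3)), tolerance = 1e-12)
})

test_that("basal activity analysis flags planted constitutive variants", {
  b <- data.frame(variant = c("WT", "CAM", "LOWSURF"),
                  basal_bret = c(0.8, 0.86, 0.8),
                  donor_luminescence = c(30000, 30000, 30000),
                  acceptor_level = c(1, 1, 1),
                  surface_level_eq1 = c(1, 1, 0.3),
                  total_level_lum = c(30000, 30000, 30000))
  out <- basal_activity_analysis(b)
  pv <- out$per_variant
  expect_equal(pv$basal_fold_vs_wt[pv$variant == "WT"], 1)
  expect_gt(pv$basal_fold_vs_wt[pv$variant == "CAM"], 1.05)
  expect_false(pv$intracellular_flag[pv$variant == "CAM"])
  expect_true(pv$intracellular_flag[pv$variant == "LOWSURF"])
  # all-WT table: unit folds, no flags
  ident <- b; ident$basal_bret <- 0.8; ident$surface_level_eq1 <- 1
  out2 <- basal_activity_analysis(ident)
  expect_equal(out2$per_variant$basal_fold_vs_wt, rep(1, 3))
  expect_false(any(out2$per_variant$intracellular_flag))
  expect_error(basal_activity_analysis(b[-1, ]), "WT")
})
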