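# Post-selection refit, restoration percentages, flags, pathway summaries
# and the power computation.

test_that("the refit matches a direct normal-equations solution", {
  for (s in 1:5) {
    cfg <- sim_config(panel = default_panel()[1:6, ],
                      effect_means = c(pkd = -0.3, dose = -0.1, mcat = 0.2,
                                       inter = 0),
                      effect_sd = c(pkd = 0.1, dose = 0.05, mcat = 0.05,
                                    inter = 0.02),
                      noise_sd = 0.1, seed = s)
    sim <- simulate_proteomics(cfg)
    des <- build_design(sim$abundance, sim$panel$protein_id)
    # random penalized support
    set.seed(s)
    support <- sort(sample(which(des$penalized), 12))
    refit <- refit_unpenalized(des, support)
    co <- refit$coefficients
    block <- cbind(1, des$covariates$x_pkd, des$covariates$x_dose,
                   des$covariates$x_mcat, des$covariates$x_mcat_dose)
    for (j in seq_along(des$proteins)) {
      cols_j <- which(des$group == j)
      sel <- sort(unique(c(1L, which(cols_j %in% support))))
      Xj <- block[, sel, drop = FALSE]
      yj <- des$y[des$rows[[j]]]
      est <- ols_normal_equations(Xj, yj)
      got <- co[co$protein == des$proteins[j] & co$selected, "estimate"]
      expect_equal(got, as.numeric(est), tolerance = 1e-10)
      # standard errors against the textbook formula
      s2 <- sum((yj - Xj %*% est)^2) / (length(yj) - ncol(Xj))
      se <- sqrt(diag(s2 * solve(crossprod(Xj))))
      expect_equal(co[co$protein == des$proteins[j] & co$selected, "se"],
                   as.numeric(se), tolerance = 1e-10)
    }
  }
})

test_that("an empty penalized support refits to per-protein grand means", {
  sim <- simulate_proteomics(sim_config(seed = 21,
                                        panel = default_panel()[1:4, ]))
  des <- build_design(sim$abundance, sim$panel$protein_id)
  refit <- refit_unpenalized(des, integer(0))
  co <- refit$coefficients
  for (j in seq_along(des$proteins)) {
    expect_equal(co$estimate[co$protein == des$proteins[j] &
                               co$term == "base"],
                 mean(des$y[des$rows[[j]]]))
    expect_equal(co$estimate[co$protein == des$proteins[j] &
                               co$term != "base"], rep(0, 4))
  }
})

test_that("percent restored follows its defining ratio", {
  expect_equal(percent_restored(-0.5, 0.25), 50)
  expect_equal(percent_restored(-0.3, 0.3), 100)
  # the printed FAO pair: -0.29 suppression, 80.7% restoration
  expect_equal(percent_restored(-0.29, 0.23403), 80.7, tolerance = 1e-10)
  expect_true(is.na(percent_restored(0, 0.2)))
  expect_equal(percent_restored(c(-0.5, 0), c(0.25, 1)), c(50, NA))
})

test_that("flags follow the significance and sign rules", {
  # noiseless-by-construction: strong suppression, modest reversal
  cfg <- sim_config(panel = default_panel()[1:3, ],
                    effect_means = c(pkd = -1, dose = -0.5, mcat = 0.0999,
                                     inter = 0),
                    effect_sd = c(pkd = 0, dose = 0, mcat = 0, inter = 0),
                    noise_sd = 0.001, seed = 30)
  sim <- simulate_proteomics(cfg)
  des <- build_design(sim$abundance, sim$panel$protein_id)
  eff <- protein_effect_table(refit_unpenalized(des, which(des$penalized)))
  expect_true(all(eff$altered))
  expect_true(all(eff$suppressed))
  expect_true(all(eff$dose_prominent))     # same sign as pkd effect
  expect_true(all(eff$ameliorated))        # opposing, significant
  # restoration sits just below the 10% threshold: strictly not reversed
  expect_true(all(eff$percent_restored < 10))
  expect_false(any(eff$reversed_gt10))

  # empty support: no flags
  eff0 <- protein_effect_table(refit_unpenalized(des, integer(0)))
  expect_false(any(eff0$altered | eff0$suppressed | eff0$dose_prominent |
                     eff0$ameliorated | eff0$reversed_gt10))
  expect_error(protein_effect_table(refit_unpenalized(des, integer(0)),
                                    alpha = 1.5), "alpha")
})

test_that("suppressed-and-rescued proteins are flagged in nearly all replicates", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(panel = default_panel()[1:3, ],
                      effect_means = c(pkd = -0.4, dose = 0, mcat = 0.2,
                                       inter = 0),
                      effect_sd = c(pkd = 0, dose = 0, mcat = 0, inter = 0),
                      noise_sd = 0.01, seed = 400 + s)
    sim <- simulate_proteomics(cfg)
    des <- build_design(sim$abundance, sim$panel$protein_id)
    model <- select_model(fit_cmcp_path(des))
    eff <- protein_effect_table(refit_unpenalized(des, model))
    all(eff$altered & eff$suppressed & eff$ameliorated & eff$reversed_gt10)
  }, TRUE)
  expect_gte(sum(hits), 19)
})

test_that("pathway summaries average over the full membership", {
  eff <- data.frame(protein = c("a", "b", "c"),
                    pkd_effect = c(-0.2, -0.4, 0),
                    dose_effect = 0,
                    mcat_effect_rcrc = c(0.1, 0.1, 0),
                    mcat_effect_rcnull = c(0.1, 0.1, 0),
                    percent_restored = c(50, 25, NA),
                    percent_restored_rcrc = c(50, 25, NA),
                    percent_restored_rcnull = c(50, 25, NA),
                    pkd_p = 0.01, dose_p = NA, mcat_p = 0.01,
                    altered = c(TRUE, TRUE, FALSE),
                    suppressed = c(TRUE, TRUE, FALSE),
                    dose_prominent = FALSE,
                    ameliorated = c(TRUE, FALSE, FALSE),
                    reversed_gt10 = c(TRUE, FALSE, FALSE))
  panel <- data.frame(protein_id = c("a", "b", "c"),
                      pathway = c("P1", "P1", "P2"))
  s <- pathway_summary(eff, panel)
  expect_equal(s$mean_pkd_effect[s$pathway == "P1"], -0.3)
  expect_equal(s$mean_percent_restored[s$pathway == "P1"], 37.5)
  expect_equal(s$n_altered[s$pathway == "P1"], 2)
  expect_equal(s$mean_pkd_effect[s$pathway == "P2"], 0)
  expect_equal(s$n_altered[s$pathway == "P2"], 0)
  expect_true(is.na(s$restored_of_means[s$pathway == "P2"]))
  # unassigned protein
  expect_error(pathway_summary(eff, panel[1:2, ]), "c")

  cnt <- significance_counts(eff)
  expect_equal(unname(cnt), c(2L, 2L, 0L, 1L, 1L))
  expect_true(all(cnt["suppressed"] <= cnt["altered"],
                  cnt["reversed_gt10"] <= cnt["ameliorated"]))
  # order invariance
  expect_equal(significance_counts(eff[c(3, 1, 2), ]), cnt)
})

test_that("power equals the level at zero effect and saturates", {
  expect_equal(power_two_sample_t(6, 0, 0.05), 0.05, tolerance = 1e-6)
  expect_gt(power_two_sample_t(6, 10, 0.05), 0.999)
  # monotone in d and n
  d <- seq(0, 2, by = 0.25)
  expect_true(all(diff(vapply(d, function(x)
    power_two_sample_t(6, x, 0.05), 0)) > 0))
  expect_gt(power_two_sample_t(12, 1, 0.05), power_two_sample_t(6, 1, 0.05))
  expect_error(power_two_sample_t(1, 1, 0.05), "n_per_group")
  expect_error(power_two_sample_t(6, 1, 1.2), "alpha")
})

test_that("effect heat-map tables round-trip through CSV", {
  sim <- simulate_proteomics(sim_config(seed = 33,
                                        panel = default_panel()[1:5, ]))
  des <- build_design(sim$abundance, sim$panel$protein_id)
  eff <- protein_effect_table(refit_unpenalized(des, which(des$penalized)))
  summ <- pathway_summary(eff, sim$panel)
  dir <- tempfile()
  paths <- write_effect_heatmap_table(eff, summ, sim$panel, dir)
  back <- read.csv(paths[["protein_effects"]])
  expect_equal(nrow(back), nrow(sim$panel))
  expect_equal(back$pkd_effect, eff$pkd_effect, tolerance = 1e-12)
  expect_equal(back$percent_restored, eff$percent_restored,
               tolerance = 1e-12)
  back2 <- read.csv(paths[["pathway_summary"]])
  expect_equal(back2$mean_pkd_effect, summ$mean_pkd_effect,
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
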