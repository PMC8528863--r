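# Flux-assay arithmetic: phase segmentation, complex activities, enzyme
# kinetics.

make_trace <- function(rates = c(100, 20), per_phase = 5, cycle = 6,
                       protein_ug = 4) {
  times <- (seq_len(per_phase * length(rates)) - 0.5) * cycle
  ocr <- rep(rates, each = per_phase)
  inj <- data.frame(reagent = c("NADH", "rotenone")[seq_along(rates)],
                    label = c("substrate", "inhibitor")[seq_along(rates)],
                    time_min = (seq_along(rates) - 1) * per_phase * cycle)
  ocr_trace(data.frame(time_min = times, ocr_pmol_min = ocr), inj,
            protein_ug)
}

test_that("phase segmentation honors half-open injection bounds", {
  tr <- make_trace()
  rates <- segment_rates(tr)
  expect_equal(unname(rates), c(100, 20), ignore_attr = TRUE)
  expect_equal(names(rates), c("NADH", "rotenone"))
  # single-phase trace: plain average of the last k cycles
  tr1 <- ocr_trace(data.frame(time_min = 1:6, ocr_pmol_min = c(9, 9, 9,
                                                               10, 11, 12)),
                   data.frame(reagent = "NADH", label = "substrate",
                              time_min = 0), 4)
  expect_equal(unname(segment_rates(tr1, last_k = 3)), 11, ignore_attr = TRUE)
  expect_equal(unname(segment_rates(tr1, last_k = 100)), 10, ignore_attr = TRUE)
  # a phase left without measurements errors
  inj_bad <- data.frame(reagent = c("a", "b"), label = c("substrate",
                                                         "inhibitor"),
                        time_min = c(0, 1000))
  expect_error(ocr_trace(data.frame(time_min = 1:5,
                                    ocr_pmol_min = rep(1, 5)),
                         inj_bad, 4) |> segment_rates(), "no measurements")
  # time-offset invariance
  tr2 <- make_trace()
  tr2$measurements$time_min <- tr2$measurements$time_min + 37
  tr2$injections$time_min <- tr2$injections$time_min + 37
  expect_equal(segment_rates(tr2), segment_rates(tr), ignore_attr = TRUE)
})

test_that("complex activity is the protein-normalized phase difference", {
  expect_equal(as.numeric(complex_activity(100, 20, 4)), 20)
  expect_equal(as.numeric(complex_activity(50, 50, 4)), 0)
  expect_warning(neg <- complex_activity(20, 100, 4), "negative")
  expect_equal(as.numeric(neg), -20)
  expect_true(attr(neg, "negative"))
  expect_error(complex_activity(1, 1, 0), "protein_ug")
  # linearity in both phase means
  a <- as.numeric(complex_activity(80, 30, 2))
  expect_equal(as.numeric(complex_activity(160, 60, 2)), 2 * a)
})

test_that("citrate-synthase normalization is a guarded ratio", {
  expect_equal(normalize_to_cs(80, 40), 2)
  expect_equal(normalize_to_cs(0, 40), 0)
  expect_equal(normalize_to_cs(8 * 3, 4 * 3), normalize_to_cs(8, 4))
  expect_error(normalize_to_cs(10, 0), "cs_activity")
  expect_error(normalize_to_cs(10, -2), "cs_activity")
})

test_that("enzyme activity follows the Beer-Lambert unit chain", {
  tr <- enzyme_kinetic_trace(0:5, 0.1 + 0.0136 * (0:5), 412, 13.6,
                             path_cm = 1, volume_mL = 0.2, protein_ug = 15)
  expect_equal(enzyme_activity_from_slope(tr), 200 / 15, tolerance = 1e-9)
  # flat trace
  flat <- enzyme_kinetic_trace(0:5, rep(0.3, 6), 340, 6.22,
                               volume_mL = 0.2, protein_ug = 10)
  expect_equal(enzyme_activity_from_slope(flat), 0)
  # doubling protein halves the specific activity
  tr2 <- enzyme_kinetic_trace(0:5, 0.1 + 0.0136 * (0:5), 412, 13.6,
                              volume_mL = 0.2, protein_ug = 30)
  expect_equal(enzyme_activity_from_slope(tr2),
               enzyme_activity_from_slope(tr) / 2)
  # decreasing absorbance (NADH oxidation) reports a positive magnitude
  tr3 <- enzyme_kinetic_trace(0:5, 1 - 0.02 * (0:5), 340, 6.22,
                              volume_mL = 0.2, protein_ug = 10)
  expect_gt(enzyme_activity_from_slope(tr3), 0)
  # window restriction uses only the linear part
  tr4 <- enzyme_kinetic_trace(0:9, c(0.1 + 0.01 * (0:6), rep(0.17, 3)),
                              412, 13.6, volume_mL = 0.2, protein_ug = 10)
  full <- enzyme_activity_from_slope(tr4)
  lin <- enzyme_activity_from_slope(tr4, window = c(0, 6))
  expect_gt(lin, full)
  expect_equal(lin, 0.01 / 13.6 * 0.2 * 1000 / 0.01, tolerance = 1e-9)
  expect_error(enzyme_kinetic_trace(0:1, c(1, 2), 412, 13.6,
                                    volume_mL = 1, protein_ug = 1), "3")
  expect_error(enzyme_kinetic_trace(c(1, 1, 1), c(1, 2, 3), 412, 13.6,
                                    volume_mL = 1, protein_ug = 1),
               "time span")
})

test_that("randomized unit audits match an independent SI computation", {
  set.seed(17)
  for (i in 1:20) {
    m <- runif(1, 0.001, 0.05) * sample(c(-1, 1), 1)  # dA/min
    eps <- runif(1, 1, 20)                            # mM^-1 cm^-1
    l <- runif(1, 0.2, 1.5)                           # cm
    V <- runif(1, 0.05, 1)                            # mL
    ug <- runif(1, 2, 50)                             # ug protein
    tt <- seq(0, 4, by = 0.5)
    tr <- enzyme_kinetic_trace(tt, 0.5 + m * tt, 340, eps, path_cm = l,
                               volume_mL = V, protein_ug = ug)
    # independent route in SI units: mol/L/min -> mol/min -> nmol/min/mg
    mol_per_L_min <- abs(m) / (eps * l) * 1e-3
    nmol_min <- mol_per_L_min * (V * 1e-3) * 1e9
    expected <- nmol_min / (ug * 1e-3)
    expect_equal(enzyme_activity_from_slope(tr), expected,
                 tolerance = 1e-8)
  }
})

test_that("synthetic traces reproduce constructed activities end to end", {
  tr <- simulate_ocr_trace(c(substrate = 100, inhibitor = 20),
                           n_cycles = 20, noise_sd = 2, seed = 5,
                           protein_ug = 4)
  act <- complex_activity_from_trace(tr, cs_activity = 10)
  se <- 2 / sqrt(3)                      # last-3-cycle phase means
  expect_lt(abs(act$raw - 20), 3 * sqrt(2) * se / 4)
  expect_lt(abs(act$cs_normalized - 2), 3 * sqrt(2) * se / 40)
})
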