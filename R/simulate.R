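# Synthetic-data generator: abundance tables with the generative structure
# the pathway-wise penalized models assume, and piecewise-constant
# oxygen-consumption traces for the flux-assay arithmetic.

#' Default 137-protein panel
#'
#' Eight pathways whose sizes sum to 137, with fatty-acid beta-oxidation
#' (FAO, 22 proteins) and the TCA cycle (26 proteins) at the sizes of the
#' study panel this generator emulates. Catalase appears as the named
#' protein `Cat` in the antioxidant pathway.
#'
#' @return Data frame with columns `protein_id`, `pathway`.
#' @export
default_panel <- function() {
  sizes <- c(TCA = 26, FAO = 22, Respiratory = 30, Antioxidant = 12,
             Glycolysis = 15, AminoAcid = 12, Ketone = 8, Transport = 12)
  ids <- unlist(lapply(names(sizes), function(pw) {
    k <- sizes[[pw]]
    if (pw == "Antioxidant") {
      c("Cat", sprintf("%s_%02d", pw, seq_len(k - 1)))
    } else {
      sprintf("%s_%02d", pw, seq_len(k))
    }
  }), use.names = FALSE)
  data.frame(protein_id = ids,
             pathway = rep(names(sizes), sizes),
             stringsAsFactors = FALSE)
}

# Per-pathway generative defaults. mean_pkd is the mean PKD1 effect among
# affected proteins, chosen so that the full-membership pathway average
# (zeros included) sits at the study-scale values: TCA -0.31, FAO -0.29,
# respiratory complexes -0.28, with per-protein restoration ratios sized so
# the pathway restoration percentages land at 47.8 / 80.7 / 53.7 / 62.1.
# The antioxidant ratio accounts for catalase, whose +0.64 treatment effect
# (with no suppression) contributes to the pathway's mean treatment effect.
default_pathway_params <- function() {
  data.frame(
    pathway = c("TCA", "FAO", "Respiratory", "Antioxidant",
                "Glycolysis", "AminoAcid", "Ketone", "Transport"),
    n_affected = c(19L, 16L, 22L, 9L, 10L, 8L, 6L, 8L),
    mean_pkd = c(-0.424, -0.399, -0.382, -0.320,
                 -0.150, -0.180, -0.200, -0.120),
    sd_pkd = c(0.12, 0.12, 0.12, 0.12, 0.08, 0.08, 0.08, 0.08),
    n_mcat = c(16L, 16L, 13L, 8L, 4L, 3L, 3L, 2L),
    restoration = c(0.568, 0.807, 0.909, 0.45, 0.5, 0.5, 0.5, 0.5),
    stringsAsFactors = FALSE
  )
}

default_groups <- function() {
  data.frame(
    genotype = c("WT", "RC_RC", "RC_RC", "RC_null", "RC_null"),
    treatment = c("vector", "vector", "mCAT", "vector", "mCAT"),
    n = c(4L, 9L, 7L, 4L, 3L),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defines the generative model
#' \eqn{y_{ij} = \alpha_j + \beta_j x_{pkd} + \gamma_j x_{dose} +
#' \delta_j x_{mcat} + \eta_j x_{mcat} x_{dose} + \epsilon_{ij}},
#' \eqn{\epsilon_{ij} \sim N(0, \sigma_j^2)}, on the relative-abundance
#' scale (untreated wild-type baseline near 1, so an effect of -0.31 reads
#' as a 31 percent decrease).
#'
#' Two modes are supported. The default structured mode draws, per pathway,
#' a subset of "affected" proteins whose PKD1 effects \eqn{\beta_j} are
#' Gaussian around the pathway mean, gene-dosage effects tied to
#' \eqn{\beta_j} by `dose_scale`, and a further subset of treatment-
#' responsive proteins whose mCAT effects are
#' \eqn{\delta_j = \rho_g(-\beta_j) +} noise, where \eqn{\rho_g} is the
#' pathway restoration ratio; unaffected proteins have exactly zero
#' effects. Passing `effect_means` switches to a simple mode in which every
#' protein draws all four effects from Gaussians with those means.
#'
#' @param n_per_group Data frame with columns `genotype`, `treatment`, `n`;
#'   default is the study layout 4 WT, 9 RC/RC, 7 RC/RC+mCAT, 4 RC/null,
#'   3 RC/null+mCAT (27 samples).
#' @param panel Protein panel (`protein_id`, `pathway`); default
#'   [default_panel()].
#' @param pathway_params Structured-mode per-pathway parameters; default
#'   `default_pathway_params()` restricted to the panel's pathways.
#' @param effect_means Optional named vector `c(pkd=, dose=, mcat=,
#'   inter=)` enabling the simple mode.
#' @param effect_sd Named vector of between-protein effect SDs
#'   `c(pkd=, dose=, mcat=, inter=)` (simple mode and the mcat/inter noise
#'   of the structured mode).
#' @param dose_scale Structured mode: \eqn{\gamma_j =} `dose_scale`
#'   \eqn{\times \beta_j +} noise.
#' @param noise_sd Residual SD \eqn{\sigma_j}; scalar or one value per
#'   protein.
#' @param baseline Named vector `c(mean=, sd=)` for \eqn{\alpha_j}.
#' @param special Named list of per-protein effect overrides, e.g. the
#'   default `list(Cat = c(mcat = 0.64))` encoding ~64 percent catalase
#'   overexpression under treatment with no PKD1 suppression.
#' @param seed Integer seed; identical configurations produce identical
#'   tables.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = default_groups(),
                       panel = default_panel(),
                       pathway_params = NULL,
                       effect_means = NULL,
                       effect_sd = c(pkd = 0.12, dose = 0.05,
                                     mcat = 0.05, inter = 0.02),
                       dose_scale = 0.5,
                       noise_sd = 0.1,
                       baseline = c(mean = 1, sd = 0.1),
                       special = list(Cat = c(mcat = 0.64)),
                       seed = 1L) {
  stopifnot(is.data.frame(n_per_group),
            all(c("genotype", "treatment", "n") %in% names(n_per_group)),
            is.data.frame(panel),
            all(c("protein_id", "pathway") %in% names(panel)))
  normalize_genotype(n_per_group$genotype)
  normalize_treatment(n_per_group$treatment)
  if (any(!is.finite(n_per_group$n)) || any(n_per_group$n < 0)) {
    stop("group counts must be finite and >= 0", call. = FALSE)
  }
  if (anyDuplicated(panel$protein_id)) {
    stop("panel protein_id values must be unique", call. = FALSE)
  }
  if (any(!is.finite(noise_sd)) || any(noise_sd < 0)) {
    stop("`noise_sd` must be finite and >= 0", call. = FALSE)
  }
  if (!length(noise_sd) %in% c(1L, nrow(panel))) {
    stop("`noise_sd` must be a scalar or one value per protein",
         call. = FALSE)
  }
  if (any(!is.finite(baseline)) || baseline[["sd"]] < 0) {
    stop("`baseline` mean/sd must be finite with sd >= 0", call. = FALSE)
  }
  if (any(!is.finite(effect_sd)) || any(effect_sd < 0)) {
    stop("`effect_sd` must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(effect_means)) {
    req <- c("pkd", "dose", "mcat", "inter")
    if (!all(req %in% names(effect_means)) ||
        any(!is.finite(effect_means[req]))) {
      stop("`effect_means` needs finite entries named pkd, dose, mcat, inter",
           call. = FALSE)
    }
    pathway_params <- NULL
    special <- list()
  } else {
    if (is.null(pathway_params)) {
      pathway_params <- default_pathway_params()
    }
    pathway_params <-
      pathway_params[pathway_params$pathway %in% unique(panel$pathway), ]
    missing_pw <- setdiff(unique(panel$pathway), pathway_params$pathway)
    if (length(missing_pw) > 0) {
      stop("no pathway_params for pathway(s): ",
           paste(missing_pw, collapse = ", "), call. = FALSE)
    }
    if (any(!is.finite(as.matrix(pathway_params[-1])))) {
      stop("pathway_params must be finite", call. = FALSE)
    }
  }
  if (!is.finite(dose_scale)) stop("`dose_scale` must be finite",
                                   call. = FALSE)
  if (!is.finite(seed)) stop("`seed` must be a finite integer",
                             call. = FALSE)
  structure(list(n_per_group = n_per_group, panel = panel,
                 pathway_params = pathway_params,
                 effect_means = effect_means, effect_sd = effect_sd,
                 dose_scale = dose_scale, noise_sd = noise_sd,
                 baseline = baseline, special = special,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a targeted-proteomics abundance table
#'
#' Draws ground-truth per-protein effects per [sim_config()] and generates
#' the samples-by-proteins abundance table under the linear model with the
#' covariate encoding of [encode_sample()]. The returned ground truth is
#' the exact set of values used for generation (for recovery tests) and is
#' never written into the abundance table itself.
#'
#' @param cfg A [sim_config()] object.
#' @return List of class `sim_proteomics` with elements `abundance` (data
#'   frame: `sample_id`, `genotype`, `treatment`, one column per protein),
#'   `panel`, and `truth` (per-protein `alpha`, `beta`, `gamma`, `delta`,
#'   `eta`, `sigma`).
#' @export
simulate_proteomics <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  panel <- cfg$panel
  P <- nrow(panel)
  sigma <- rep(cfg$noise_sd, length.out = P)

  alpha <- rnorm(P, cfg$baseline[["mean"]], cfg$baseline[["sd"]])
  beta <- gamma <- delta <- eta <- numeric(P)

  if (!is.null(cfg$effect_means)) {
    m <- cfg$effect_means; s <- cfg$effect_sd
    beta <- rnorm(P, m[["pkd"]], s[["pkd"]])
    gamma <- rnorm(P, m[["dose"]], s[["dose"]])
    delta <- rnorm(P, m[["mcat"]], s[["mcat"]])
    eta <- rnorm(P, m[["inter"]], s[["inter"]])
  } else {
    pp <- cfg$pathway_params
    s <- cfg$effect_sd
    special_ids <- names(cfg$special)
    for (r in seq_len(nrow(pp))) {
      pw <- pp$pathway[r]
      idx <- which(panel$pathway == pw & !(panel$protein_id %in% special_ids))
      n_aff <- min(pp$n_affected[r], length(idx))
      aff <- idx[seq_len(n_aff)]  # deterministic membership, random effects
      beta[aff] <- rnorm(n_aff, pp$mean_pkd[r], pp$sd_pkd[r])
      gamma[aff] <- cfg$dose_scale * beta[aff] + rnorm(n_aff, 0, s[["dose"]])
      n_mc <- min(pp$n_mcat[r], n_aff)
      mc <- aff[seq_len(n_mc)]
      delta[mc] <- pp$restoration[r] * (-beta[mc]) +
        rnorm(n_mc, 0, s[["mcat"]])
      eta[mc] <- rnorm(n_mc, 0, s[["inter"]])
    }
    for (id in special_ids) {
      j <- match(id, panel$protein_id)
      if (is.na(j)) next
      ov <- cfg$special[[id]]
      if ("pkd" %in% names(ov)) beta[j] <- ov[["pkd"]]
      if ("dose" %in% names(ov)) gamma[j] <- ov[["dose"]]
      if ("mcat" %in% names(ov)) delta[j] <- ov[["mcat"]]
      if ("inter" %in% names(ov)) eta[j] <- ov[["inter"]]
    }
  }

  grp <- cfg$n_per_group
  grp <- grp[grp$n > 0, , drop = FALSE]
  genotype <- rep(normalize_genotype(grp$genotype), grp$n)
  treatment <- rep(normalize_treatment(grp$treatment), grp$n)
  sample_id <- unlist(lapply(seq_len(nrow(grp)), function(r) {
    sprintf("%s_%s_%d", grp$genotype[r], grp$treatment[r],
            seq_len(grp$n[r]))
  }), use.names = FALSE)
  cov <- encode_sample(genotype, treatment)
  ns <- length(sample_id)

  mean_mat <- outer(rep(1, ns), alpha) +
    outer(cov$x_pkd, beta) + outer(cov$x_dose, gamma) +
    outer(cov$x_mcat, delta) + outer(cov$x_mcat * cov$x_dose, eta)
  noise <- matrix(rnorm(ns * P, 0, rep(sigma, each = ns)), ns, P)
  Y <- mean_mat + noise
  colnames(Y) <- panel$protein_id

  abundance <- cbind(
    data.frame(sample_id = sample_id, genotype = genotype,
               treatment = treatment, stringsAsFactors = FALSE),
    as.data.frame(Y)
  )
  truth <- data.frame(protein_id = panel$protein_id,
                      pathway = panel$pathway,
                      alpha = alpha, beta = beta, gamma = gamma,
                      delta = delta, eta = eta, sigma = sigma,
                      stringsAsFactors = FALSE)
  structure(list(abundance = abundance, panel = panel, truth = truth,
                 config = cfg),
            class = "sim_proteomics")
}

#' Simulate an injection-annotated oxygen-consumption trace
#'
#' Piecewise-constant oxygen consumption rate (OCR) plus Gaussian noise,
#' with an injection annotation at the start of each phase (substrate
#' first, inhibitor after, as in a respiratory-complex assay).
#'
#' @param phase_rates Named numeric vector of true per-phase OCR levels
#'   (pmol O2/min); names are the reagent labels.
#' @param n_cycles Measurement cycles per phase (scalar or per phase).
#' @param noise_sd Measurement noise SD.
#' @param seed Optional integer seed.
#' @param protein_ug Protein loaded per well (micrograms).
#' @param cycle_min Minutes per measurement cycle.
#' @param phase_labels `substrate` / `inhibitor` label per phase; defaults
#'   to the `phase_rates` names when those are labels, otherwise the first
#'   phase is `substrate` and the rest `inhibitor`.
#' @return An [ocr_trace()] object.
#' @export
simulate_ocr_trace <- function(phase_rates, n_cycles = 8, noise_sd = 0,
                               seed = NULL, protein_ug = 4, cycle_min = 6,
                               phase_labels = NULL) {
  if (length(phase_rates) < 1 || any(!is.finite(phase_rates))) {
    stop("`phase_rates` must be finite and non-empty", call. = FALSE)
  }
  n_cycles <- rep(as.integer(n_cycles), length.out = length(phase_rates))
  if (any(n_cycles < 1)) stop("`n_cycles` must be >= 1", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be finite and >= 0", call. = FALSE)
  }
  reagents <- names(phase_rates)
  if (is.null(reagents)) reagents <- paste0("phase", seq_along(phase_rates))
  if (is.null(phase_labels)) {
    phase_labels <- if (all(reagents %in% c("substrate", "inhibitor"))) {
      reagents
    } else {
      c("substrate", rep("inhibitor", length(phase_rates) - 1L))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  starts <- cumsum(c(0, n_cycles[-length(n_cycles)])) * cycle_min
  times <- unlist(lapply(seq_along(phase_rates), function(i) {
    starts[i] + (seq_len(n_cycles[i]) - 0.5) * cycle_min
  }), use.names = FALSE)
  ocr <- unlist(lapply(seq_along(phase_rates), function(i) {
    phase_rates[i] + rnorm(n_cycles[i], 0, noise_sd)
  }), use.names = FALSE)
  ocr_trace(
    measurements = data.frame(time_min = times, ocr_pmol_min = ocr),
    injections = data.frame(reagent = reagents, label = phase_labels,
                            time_min = starts, stringsAsFactors = FALSE),
    protein_ug = protein_ug
  )
}

#' Write / read the generator's CSV interchange files
#'
#' Wide abundance CSV (first columns `sample_id`, `genotype`, `treatment`,
#' then one column per protein), two-column panel CSV, and the ground-truth
#' effects CSV; header row, UTF-8, `.` decimal separator.
#'
#' @param x A `sim_proteomics` object or the corresponding data frame.
#' @param path Output file path.
#' @return `path`, invisibly (writers); a data frame (readers).
#' @export
write_abundance_csv <- function(x, path) {
  df <- if (inherits(x, "sim_proteomics")) x$abundance else x
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_abundance_csv
#' @export
write_panel_csv <- function(x, path) {
  df <- if (inherits(x, "sim_proteomics")) x$panel else x
  write.csv(df[c("protein_id", "pathway")], path, row.names = FALSE,
            quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_abundance_csv
#' @export
write_true_effects_csv <- function(x, path) {
  df <- if (inherits(x, "sim_proteomics")) x$truth else x
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_abundance_csv
#' @export
read_abundance_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                 check.names = FALSE)
  req <- c("sample_id", "genotype", "treatment")
  if (!all(req %in% names(df))) {
    stop("abundance CSV must have columns sample_id, genotype, treatment",
         call. = FALSE)
  }
  df
}

#' @rdname write_abundance_csv
#' @export
read_panel_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("protein_id", "pathway") %in% names(df))) {
    stop("panel CSV must have columns protein_id, pathway", call. = FALSE)
  }
  df
}
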