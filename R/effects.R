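# Post-selection inference and study-level summaries: unpenalized refit on
# the selected support, per-protein effect flags, restoration percentages,
# pathway averages and the two-sample t power computation.

#' Unpenalized refit on the selected support
#'
#' Ordinary least squares restricted to the selected effects, fitted per
#' protein (the stacked design is block-diagonal across proteins, so the
#' joint refit decomposes exactly), with the residual variance re-estimated
#' per protein. Effects outside the support are fixed at exactly 0 and
#' carry no standard error or p value.
#'
#' @param design A [build_design()] object.
#' @param model A [select_model()] result, or an integer vector of selected
#'   penalized column indices into the design.
#' @return Object of class `cmcp_refit`: a `coefficients` data frame
#'   (protein, term, estimate, se, t, p, selected) and per-protein
#'   `sigma2` / residual degrees of freedom.
#' @export
refit_unpenalized <- function(design, model) {
  stopifnot(inherits(design, "cmcp_design"))
  support <- if (inherits(model, "cmcp_selected")) {
    model$selected_members
  } else {
    as.integer(model)
  }
  if (any(support < 1 | support > ncol(design$Xs))) {
    stop("support indices out of range", call. = FALSE)
  }
  P <- length(design$proteins)
  ns <- design$n_samples
  block <- cbind(base = 1, pkd = design$covariates$x_pkd,
                 dose = design$covariates$x_dose,
                 mcat = design$covariates$x_mcat,
                 mcat_dose = design$covariates$x_mcat_dose)
  res <- vector("list", P)
  sigma2 <- df_res <- numeric(P)
  for (j in seq_len(P)) {
    cols_j <- which(design$group == j)
    sel_terms <- c(1L, which(cols_j %in% support))  # baseline always in
    sel_terms <- sort(unique(sel_terms))
    Xj <- block[, sel_terms, drop = FALSE]
    yj <- design$y[design$rows[[j]]]
    qr_j <- qr(Xj)
    if (qr_j$rank < ncol(Xj)) {
      stop("rank-deficient refit for protein ", design$proteins[j],
           ": collinear terms ",
           paste(colnames(Xj), collapse = ", "), call. = FALSE)
    }
    est <- qr.coef(qr_j, yj)
    resid <- yj - Xj %*% est
    dfj <- ns - ncol(Xj)
    s2 <- if (dfj > 0) sum(resid^2) / dfj else NA_real_
    XtX_inv <- chol2inv(qr.R(qr_j))
    se <- if (is.na(s2)) rep(NA_real_, ncol(Xj)) else
      sqrt(pmax(s2 * diag(XtX_inv), 0))
    tval <- est / se
    pval <- 2 * pt(-abs(tval), dfj)
    full <- data.frame(protein = design$proteins[j],
                       term = EFFECT_TERMS,
                       estimate = 0, se = NA_real_, t = NA_real_,
                       p = NA_real_, selected = FALSE,
                       stringsAsFactors = FALSE)
    full$estimate[sel_terms] <- est
    full$se[sel_terms] <- se
    full$t[sel_terms] <- tval
    full$p[sel_terms] <- pval
    full$selected[sel_terms] <- TRUE
    res[[j]] <- full
    sigma2[j] <- s2
    df_res[j] <- dfj
  }
  structure(list(coefficients = do.call(rbind, res),
                 sigma2 = setNames(sigma2, design$proteins),
                 df_residual = setNames(df_res, design$proteins),
                 proteins = design$proteins),
            class = "cmcp_refit")
}

#' Percentage of mutation-induced suppression restored by treatment
#'
#' `100 * mcat_effect / (-pkd_effect)`: positive when the treatment effect
#' opposes the mutation effect. Undefined (returned as `NA`) when the
#' mutation effect is 0.
#'
#' @param pkd_effect Mutation (PKD1) effect.
#' @param mcat_effect Treatment (mCAT) effect.
#' @return Percentage(s); `NA` where `pkd_effect == 0`.
#' @export
#' @examples
#' percent_restored(-0.5, 0.25)   # 50
#' percent_restored(-0.3, 0.3)    # 100
percent_restored <- function(pkd_effect, mcat_effect) {
  if (length(pkd_effect) != length(mcat_effect)) {
    stop("effect vectors must have equal length", call. = FALSE)
  }
  out <- ifelse(pkd_effect == 0, NA_real_,
                100 * mcat_effect / (-pkd_effect))
  out
}

#' Per-protein effect table with significance flags
#'
#' Assembles, from a refit, the per-protein mutation (`pkd_effect`),
#' gene-dosage (`dose_effect`) and treatment effects (`mcat_effect_rcrc`
#' for the slowly progressive genotype; `mcat_effect_rcnull` adds the
#' treatment-by-dosage interaction), the restoration percentage, and the
#' significance flags:
#' * `altered` - pkd or dose effect selected with p < alpha;
#' * `suppressed` - altered with a negative pkd effect;
#' * `dose_prominent` - dose effect selected, significant, and of the same
#'   sign as the pkd effect;
#' * `ameliorated` - mCAT effect selected, significant, and opposing the
#'   pkd effect;
#' * `reversed_gt10` - ameliorated with restoration strictly above the
#'   reversal threshold (default 10 percent).
#'
#' @param refit A [refit_unpenalized()] result.
#' @param alpha Two-sided significance level in (0, 1).
#' @param reversal_threshold Restoration percentage a protein must exceed
#'   for `reversed_gt10`.
#' @param restoration Which treatment effect feeds `percent_restored`:
#'   the RC/RC-scale main effect (`"rcrc"`, default) or the RC/null-scale
#'   effect including the interaction (`"rcnull"`). Both variants are
#'   always emitted as columns.
#' @param p_adjust `"none"` (default) or `"BH"` to Benjamini-Hochberg
#'   adjust the selected-coefficient p values before flagging.
#' @return Data frame of class `protein_effects`, one row per protein.
#' @export
protein_effect_table <- function(refit, alpha = 0.05,
                                 reversal_threshold = 10,
                                 restoration = c("rcrc", "rcnull"),
                                 p_adjust = c("none", "BH")) {
  stopifnot(inherits(refit, "cmcp_refit"))
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  restoration <- match.arg(restoration)
  p_adjust <- match.arg(p_adjust)
  co <- refit$coefficients
  if (p_adjust == "BH") {
    sel <- co$selected & co$term != "base" & !is.na(co$p)
    co$p[sel] <- stats::p.adjust(co$p[sel], method = "BH")
  }
  get <- function(term, what) {
    x <- co[co$term == term, ]
    x[[what]][match(refit$proteins, x$protein)]
  }
  pkd <- get("pkd", "estimate")
  dose <- get("dose", "estimate")
  mcat <- get("mcat", "estimate")
  inter <- get("mcat_dose", "estimate")
  sig <- function(term) {
    s <- get(term, "selected")
    p <- get(term, "p")
    s & !is.na(p) & p < alpha
  }
  pkd_sig <- sig("pkd"); dose_sig <- sig("dose"); mcat_sig <- sig("mcat")
  mcat_rcnull <- mcat + inter
  pr_rcrc <- percent_restored(pkd, mcat)
  pr_rcnull <- percent_restored(pkd, mcat_rcnull)
  pr <- if (restoration == "rcrc") pr_rcrc else pr_rcnull

  altered <- pkd_sig | dose_sig
  suppressed <- altered & pkd < 0
  dose_prominent <- dose_sig & pkd != 0 & sign(dose) == sign(pkd)
  ameliorated <- mcat_sig & pkd != 0 & sign(mcat) == -sign(pkd)
  reversed_gt10 <- ameliorated & !is.na(pr) & pr > reversal_threshold

  out <- data.frame(
    protein = refit$proteins,
    pkd_effect = pkd, dose_effect = dose,
    mcat_effect_rcrc = mcat, mcat_effect_rcnull = mcat_rcnull,
    percent_restored = pr,
    percent_restored_rcrc = pr_rcrc, percent_restored_rcnull = pr_rcnull,
    pkd_p = get("pkd", "p"), dose_p = get("dose", "p"),
    mcat_p = get("mcat", "p"),
    altered = altered, suppressed = suppressed,
    dose_prominent = dose_prominent, ameliorated = ameliorated,
    reversed_gt10 = reversed_gt10,
    stringsAsFactors = FALSE
  )
  class(out) <- c("protein_effects", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "reversal_threshold") <- reversal_threshold
  attr(out, "restoration") <- restoration
  out
}

#' Pathway-level averages of protein effects
#'
#' Arithmetic means over the full pathway membership: effects of
#' unselected proteins enter as exact zeros (non-selection means shrunk to
#' zero). `mean_percent_restored` averages the per-protein restoration
#' percentages over the proteins where it is defined (nonzero pkd effect);
#' `restored_of_means` is the ratio-of-means variant
#' `100 * mean_mcat / (-mean_pkd)`.
#'
#' @param effects A [protein_effect_table()] result (possibly row-bound
#'   across pathways).
#' @param panel Panel data frame (`protein_id`, `pathway`) assigning every
#'   protein in `effects` to exactly one pathway.
#' @return Data frame with one row per pathway: effect means, restoration
#'   summaries, protein count and per-flag counts.
#' @export
pathway_summary <- function(effects, panel) {
  stopifnot(inherits(effects, "data.frame"),
            all(c("protein_id", "pathway") %in% names(panel)))
  idx <- match(effects$protein, panel$protein_id)
  if (any(is.na(idx))) {
    stop("protein(s) not assigned to a pathway: ",
         paste(effects$protein[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  pw <- panel$pathway[idx]
  flags <- c("altered", "suppressed", "dose_prominent", "ameliorated",
             "reversed_gt10")
  out <- do.call(rbind, lapply(unique(panel$pathway), function(p) {
    e <- effects[pw == p, , drop = FALSE]
    mean_pkd <- mean(e$pkd_effect)
    mean_mcat <- mean(e$mcat_effect_rcrc)
    pr <- e$percent_restored[!is.na(e$percent_restored)]
    data.frame(
      pathway = p,
      n_proteins = nrow(e),
      mean_pkd_effect = mean_pkd,
      mean_dose_effect = mean(e$dose_effect),
      mean_mcat_effect = mean_mcat,
      mean_percent_restored = if (length(pr)) mean(pr) else NA_real_,
      restored_of_means = if (mean_pkd != 0) 100 * mean_mcat / (-mean_pkd)
                          else NA_real_,
      t(vapply(flags, function(f) sum(e[[f]]), 0)),
      stringsAsFactors = FALSE
    )
  }))
  names(out)[names(out) %in% flags] <- paste0("n_", flags)
  rownames(out) <- NULL
  out
}

#' Counts of significance classes over the panel
#'
#' @param effects A [protein_effect_table()] result.
#' @return Named integer vector: `altered`, `suppressed`, `dose_prominent`,
#'   `ameliorated`, `reversed_gt10`.
#' @export
significance_counts <- function(effects) {
  flags <- c("altered", "suppressed", "dose_prominent", "ameliorated",
             "reversed_gt10")
  vapply(flags, function(f) sum(effects[[f]]), 0L)
}

#' Power of the two-sided two-sample t test
#'
#' Exact power via the noncentral t distribution, with noncentrality
#' \eqn{d\sqrt{n/2}} and \eqn{2n - 2} degrees of freedom for `n` per group
#' and standardized effect `d`.
#'
#' @param n_per_group Samples per group (>= 2).
#' @param standardized_effect_d Standardized mean difference (Cohen's d).
#' @param alpha Two-sided level in (0, 1).
#' @return Power in (0, 1).
#' @export
#' @examples
#' power_two_sample_t(6, 0, 0.05)   # equals the level
power_two_sample_t <- function(n_per_group, standardized_effect_d,
                               alpha = 0.05) {
  if (!is.finite(n_per_group) || n_per_group < 2) {
    stop("`n_per_group` must be >= 2", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  if (!is.finite(standardized_effect_d)) {
    stop("`standardized_effect_d` must be finite", call. = FALSE)
  }
  df <- 2 * n_per_group - 2
  ncp <- standardized_effect_d * sqrt(n_per_group / 2)
  tc <- qt(1 - alpha / 2, df)
  (1 - pt(tc, df, ncp)) + pt(-tc, df, ncp)
}

#' Write the tabular effect heat-map and pathway summary
#'
#' Tidy CSV stand-ins for the study's effect heat map: one row per protein
#' (pathway, effects, restoration, flags) and a pathway-summary CSV.
#'
#' @param effects A [protein_effect_table()] result.
#' @param summaries A [pathway_summary()] result.
#' @param panel Panel data frame (`protein_id`, `pathway`).
#' @param dir Output directory (created if absent).
#' @return Named character vector of the two paths written, invisibly.
#' @export
write_effect_heatmap_table <- function(effects, summaries, panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idx <- match(effects$protein, panel$protein_id)
  out <- cbind(data.frame(pathway = panel$pathway[idx]), effects)
  p1 <- file.path(dir, "protein_effects.csv")
  p2 <- file.path(dir, "pathway_summary.csv")
  write.csv(out, p1, row.names = FALSE, quote = FALSE)
  write.csv(summaries, p2, row.names = FALSE, quote = FALSE)
  invisible(c(protein_effects = p1, pathway_summary = p2))
}
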