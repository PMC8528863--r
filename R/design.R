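# Study design: covariate encoding of genotype/treatment metadata and the
# stacked per-pathway, protein-grouped regression design.

GENOTYPES <- c("WT", "RC_het", "RC_RC", "RC_null")
TREATMENTS <- c("vector", "mCAT")

# Accept both the enum spellings and the slash notation used in data files.
normalize_genotype <- function(genotype) {
  g <- as.character(genotype)
  g[g == "RC/+"] <- "RC_het"
  g[g == "RC/RC"] <- "RC_RC"
  g[g == "RC/null"] <- "RC_null"
  bad <- setdiff(unique(g), GENOTYPES)
  if (length(bad) > 0) {
    stop("unknown genotype value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  g
}

normalize_treatment <- function(treatment) {
  t <- as.character(treatment)
  bad <- setdiff(unique(t), TREATMENTS)
  if (length(bad) > 0) {
    stop("unknown treatment value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  t
}

#' Encode sample metadata into regression covariates
#'
#' Maps genotype and treatment to the four model covariates: `x_pkd`
#' (carries a disease-causing PKD1 genotype: RC/RC or RC/null), `x_dose`
#' (the more severe RC/null genotype, i.e. the gene-dosage contrast),
#' `x_mcat` (received mitochondria-targeted catalase) and their product
#' `x_mcat_dose`. Heterozygous RC/+ animals are phenotypically normal
#' controls and encode as `x_pkd = 0`.
#'
#' @param genotype Character vector in `WT`, `RC_het` (`RC/+`), `RC_RC`
#'   (`RC/RC`), `RC_null` (`RC/null`).
#' @param treatment Character vector in `vector`, `mCAT`.
#' @return Data frame with columns `x_pkd`, `x_dose`, `x_mcat`,
#'   `x_mcat_dose` (0/1 integers).
#' @export
#' @examples
#' encode_sample("WT", "vector")        # all zero
#' encode_sample("RC_null", "mCAT")     # all one
encode_sample <- function(genotype, treatment) {
  g <- normalize_genotype(genotype)
  t <- normalize_treatment(treatment)
  if (length(g) != length(t)) stop("genotype and treatment lengths differ",
                                   call. = FALSE)
  x_pkd <- as.integer(g %in% c("RC_RC", "RC_null"))
  x_dose <- as.integer(g == "RC_null")
  x_mcat <- as.integer(t == "mCAT")
  data.frame(x_pkd = x_pkd, x_dose = x_dose, x_mcat = x_mcat,
             x_mcat_dose = x_mcat * x_dose)
}

EFFECT_TERMS <- c("base", "pkd", "dose", "mcat", "mcat_dose")

#' Build the stacked per-pathway design matrix
#'
#' Stacks one response entry per (sample, protein) and, for each protein, a
#' five-column effect bundle: a baseline indicator plus the four covariates
#' from [encode_sample()] restricted to that protein's rows. Baselines are
#' never penalized; the four effect columns form the protein's cMCP group.
#' Penalized columns are centered and scaled to \eqn{(1/n)x'x = 1}; the
#' recorded transform is inverted exactly when coefficients are reported.
#'
#' @param abundance An abundance table: data frame with columns `sample_id`,
#'   `genotype`, `treatment` followed by one column per protein (see
#'   [simulate_proteomics()] / [read_abundance_csv()]).
#' @param proteins Character vector naming the pathway's proteins, each of
#'   which must be a column of `abundance`.
#' @return An object of class `cmcp_design`: standardized design `Xs`,
#'   stacked response `y`, `group` (protein index per column), `penalized`
#'   mask, standardization record, per-protein row indices and metadata.
#' @export
build_design <- function(abundance, proteins) {
  if (length(proteins) == 0) stop("pathway has no proteins", call. = FALSE)
  meta_cols <- c("sample_id", "genotype", "treatment")
  if (!all(meta_cols %in% names(abundance))) {
    stop("abundance table must have columns sample_id, genotype, treatment",
         call. = FALSE)
  }
  missing_p <- setdiff(proteins, names(abundance))
  if (length(missing_p) > 0) {
    stop("abundance table lacks protein column(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(abundance$sample_id)) {
    stop("sample_id values must be unique", call. = FALSE)
  }
  ns <- nrow(abundance)
  P <- length(proteins)
  cov <- encode_sample(abundance$genotype, abundance$treatment)
  for (p in proteins) {
    vals <- abundance[[p]]
    if (any(!is.finite(vals))) {
      bad <- abundance$sample_id[which(!is.finite(vals))[1]]
      stop("missing abundance for sample ", bad, ", protein ", p,
           call. = FALSE)
    }
  }

  n <- ns * P
  X <- matrix(0, n, 5L * P)
  y <- numeric(n)
  group <- rep(seq_len(P), each = 5L)
  penalized <- rep(c(FALSE, TRUE, TRUE, TRUE, TRUE), P)
  cn <- as.vector(vapply(proteins, function(p) paste(EFFECT_TERMS, p,
                                                     sep = "."),
                         character(5)))
  colnames(X) <- cn
  block <- cbind(1, cov$x_pkd, cov$x_dose, cov$x_mcat, cov$x_mcat_dose)
  rows <- vector("list", P)
  for (j in seq_len(P)) {
    idx <- ((j - 1L) * ns + 1L):(j * ns)
    rows[[j]] <- idx
    X[idx, ((j - 1L) * 5L + 1L):(j * 5L)] <- block
    y[idx] <- abundance[[proteins[j]]]
  }
  st <- standardize_columns(X, penalized)
  structure(list(
    Xs = st$Xs, X = X, y = y, group = group, penalized = penalized,
    center = st$center, scale = st$scale,
    baseline_cols = which(!penalized),
    proteins = proteins, rows = rows, n_samples = ns,
    samples = abundance[meta_cols], covariates = cov,
    terms = rep(EFFECT_TERMS, P)
  ), class = "cmcp_design")
}

#' @export
print.cmcp_design <- function(x, ...) {
  cat("cMCP design:", nrow(x$Xs), "stacked rows (", x$n_samples,
      "samples x", length(x$proteins), "proteins ),", ncol(x$Xs),
      "columns\n")
  invisible(x)
}

# Internal: undo standardization of the design matrix (round-trip check).
destandardize_design <- function(design) {
  X <- design$Xs
  for (k in which(design$penalized)) {
    X[, k] <- X[, k] * design$scale[k] + design$center[k]
  }
  X
}
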