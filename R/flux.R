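# Respiratory-complex activity from oxygen-consumption traces and enzyme
# activity from absorbance kinetics.

#' Injection-annotated oxygen-consumption trace
#'
#' @param measurements Data frame with columns `time_min` (strictly
#'   increasing) and `ocr_pmol_min`.
#' @param injections Data frame with columns `reagent`, `label`
#'   (`substrate`/`inhibitor`) and `time_min`, ordered in time.
#' @param protein_ug Protein loaded per well (micrograms, > 0).
#' @return An object of class `ocr_trace`.
#' @export
ocr_trace <- function(measurements, injections, protein_ug) {
  stopifnot(is.data.frame(measurements),
            all(c("time_min", "ocr_pmol_min") %in% names(measurements)),
            is.data.frame(injections),
            all(c("reagent", "label", "time_min") %in% names(injections)))
  if (any(diff(measurements$time_min) <= 0)) {
    stop("measurement times must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(protein_ug) || protein_ug <= 0) {
    stop("`protein_ug` must be > 0", call. = FALSE)
  }
  bad <- setdiff(unique(injections$label), c("substrate", "inhibitor"))
  if (length(bad) > 0) {
    stop("injection labels must be substrate/inhibitor; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(injections$time_min)) {
    stop("injections must be ordered in time", call. = FALSE)
  }
  structure(list(measurements = measurements, injections = injections,
                 protein_ug = protein_ug),
            class = "ocr_trace")
}

#' Per-phase mean oxygen-consumption rates
#'
#' Phases are bounded by injection times (half-open intervals from one
#' injection up to, but excluding, the next). The phase level is the mean
#' of the last `last_k` measurement cycles of the phase (all cycles when
#' fewer), discarding the equilibration that follows an injection.
#'
#' @param trace An [ocr_trace()] object.
#' @param last_k Number of trailing cycles averaged per phase.
#' @return Named numeric vector of phase means (names are the injected
#'   reagents), with the phase labels in attribute `label`.
#' @export
segment_rates <- function(trace, last_k = 3) {
  stopifnot(inherits(trace, "ocr_trace"), last_k >= 1)
  t_m <- trace$measurements$time_min
  inj <- trace$injections
  bounds <- c(inj$time_min, Inf)
  out <- numeric(nrow(inj))
  n_used <- integer(nrow(inj))
  for (i in seq_len(nrow(inj))) {
    in_phase <- which(t_m >= bounds[i] & t_m < bounds[i + 1])
    if (length(in_phase) == 0) {
      stop("phase ", i, " (", inj$reagent[i], ") has no measurements",
           call. = FALSE)
    }
    use <- utils::tail(in_phase, last_k)
    out[i] <- mean(trace$measurements$ocr_pmol_min[use])
    n_used[i] <- length(use)
  }
  names(out) <- inj$reagent
  attr(out, "label") <- inj$label
  attr(out, "n_used") <- n_used
  out
}

#' Raw respiratory-complex activity
#'
#' Substrate-stimulated minus inhibitor-insensitive OCR, normalized to the
#' protein loaded: `(substrate_mean - inhibitor_mean) / protein_ug`, in
#' pmol O2/min/ug. Negative activities are returned unclipped, flagged via
#' attribute `negative` and a warning.
#'
#' @param substrate_mean,inhibitor_mean Phase mean OCR (pmol O2/min).
#' @param protein_ug Protein per well (micrograms, > 0).
#' @return Numeric activity with attribute `negative`.
#' @export
#' @examples
#' complex_activity(100, 20, 4)  # 20 pmol O2/min/ug
complex_activity <- function(substrate_mean, inhibitor_mean, protein_ug) {
  if (!is.finite(protein_ug) || protein_ug <= 0) {
    stop("`protein_ug` must be > 0", call. = FALSE)
  }
  act <- (substrate_mean - inhibitor_mean) / protein_ug
  neg <- act < 0
  if (any(neg)) {
    warning("negative complex activity (inhibitor phase above substrate ",
            "phase); returned unclipped", call. = FALSE)
  }
  attr(act, "negative") <- neg
  act
}

#' Normalize an activity to citrate synthase
#'
#' Citrate synthase activity proxies mitochondrial mass; the ratio
#' `raw_activity / cs_activity` is the mass-corrected complex activity.
#'
#' @param raw_activity Raw complex activity.
#' @param cs_activity Citrate synthase activity (> 0, same units).
#' @return Dimensionless ratio.
#' @export
normalize_to_cs <- function(raw_activity, cs_activity) {
  if (!is.finite(cs_activity) || cs_activity <= 0) {
    stop("`cs_activity` must be > 0", call. = FALSE)
  }
  as.numeric(raw_activity) / cs_activity
}

#' Complex activity from a trace, end to end
#'
#' Segments the trace, takes the first `substrate` and the following
#' `inhibitor` phase, and returns raw (and, when `cs_activity` is given,
#' citrate-synthase-normalized) activity.
#'
#' @param trace An [ocr_trace()] object with substrate-then-inhibitor
#'   injections.
#' @param cs_activity Optional citrate synthase activity.
#' @param last_k Trailing cycles averaged per phase.
#' @return List with `phase_means`, `raw` and (optionally) `cs_normalized`.
#' @export
complex_activity_from_trace <- function(trace, cs_activity = NULL,
                                        last_k = 3) {
  rates <- segment_rates(trace, last_k = last_k)
  lab <- attr(rates, "label")
  i_sub <- which(lab == "substrate")[1]
  i_inh <- which(lab == "inhibitor" & seq_along(lab) > i_sub)[1]
  if (is.na(i_sub) || is.na(i_inh)) {
    stop("trace needs a substrate phase followed by an inhibitor phase",
         call. = FALSE)
  }
  raw <- complex_activity(rates[[i_sub]], rates[[i_inh]], trace$protein_ug)
  out <- list(phase_means = rates, raw = raw)
  if (!is.null(cs_activity)) {
    out$cs_normalized <- normalize_to_cs(raw, cs_activity)
  }
  out
}

#' Absorbance kinetics trace for an enzyme assay
#'
#' @param time_min,absorbance Ordered kinetics readings (>= 3 points).
#' @param wavelength_nm Detection wavelength (metadata).
#' @param extinction_mM Extinction coefficient (per mM per cm, > 0);
#'   13.6 for DTNB/TNB at 412 nm, 6.22 for NADH at 340 nm.
#' @param path_cm Optical path length (cm).
#' @param volume_mL Reaction volume (mL).
#' @param protein_ug Protein in the reaction (micrograms, > 0).
#' @return An object of class `enzyme_kinetic_trace`.
#' @export
enzyme_kinetic_trace <- function(time_min, absorbance, wavelength_nm,
                                 extinction_mM, path_cm = 1,
                                 volume_mL, protein_ug) {
  if (length(time_min) < 3 || length(absorbance) != length(time_min)) {
    stop("need >= 3 (time, absorbance) points", call. = FALSE)
  }
  if (diff(range(time_min)) <= 0) {
    stop("zero time span in kinetics trace", call. = FALSE)
  }
  if (!is.finite(extinction_mM) || extinction_mM <= 0) {
    stop("`extinction_mM` must be > 0", call. = FALSE)
  }
  if (!is.finite(path_cm) || path_cm <= 0) {
    stop("`path_cm` must be > 0", call. = FALSE)
  }
  if (!is.finite(volume_mL) || volume_mL <= 0) {
    stop("`volume_mL` must be > 0", call. = FALSE)
  }
  if (!is.finite(protein_ug) || protein_ug <= 0) {
    stop("`protein_ug` must be > 0", call. = FALSE)
  }
  structure(list(time_min = time_min, absorbance = absorbance,
                 wavelength_nm = wavelength_nm,
                 extinction_mM = extinction_mM, path_cm = path_cm,
                 volume_mL = volume_mL, protein_ug = protein_ug),
            class = "enzyme_kinetic_trace")
}

#' Enzyme specific activity from an absorbance slope
#'
#' Least-squares slope of absorbance vs. time over the selected linear
#' window, converted by Beer-Lambert to a concentration rate
#' (`|dA/dt| / (extinction * path)`, mM/min), scaled by the reaction
#' volume to an amount rate (nmol/min), and normalized to protein mass
#' (nmol/min/mg). The sign convention reports a positive magnitude, so
#' both product-accumulation (DTNB/TNB) and substrate-consumption (NADH)
#' assays give positive activities.
#'
#' @param trace An [enzyme_kinetic_trace()] object.
#' @param window Optional `c(start, end)` time window (minutes); default
#'   uses the full trace.
#' @return Specific activity in nmol/min/mg.
#' @export
#' @examples
#' tr <- enzyme_kinetic_trace(0:5, 0.1 + 0.0136 * (0:5), 412, 13.6,
#'                            path_cm = 1, volume_mL = 0.2, protein_ug = 15)
#' enzyme_activity_from_slope(tr)  # ~13.3 nmol/min/mg
enzyme_activity_from_slope <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "enzyme_kinetic_trace"))
  t_m <- trace$time_min
  a <- trace$absorbance
  if (!is.null(window)) {
    keep <- t_m >= window[1] & t_m <= window[2]
    if (sum(keep) < 3) stop("fewer than 3 points in window", call. = FALSE)
    t_m <- t_m[keep]; a <- a[keep]
  }
  slope <- unname(coef(lm(a ~ t_m))[2])          # dA/dt, per min
  rate_mM <- abs(slope) / (trace$extinction_mM * trace$path_cm)
  nmol_min <- rate_mM * trace$volume_mL * 1000   # mM * mL = umol -> nmol
  nmol_min / (trace$protein_ug / 1000)           # per mg protein
}
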