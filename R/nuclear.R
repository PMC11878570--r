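#' Concentration from molecules in the focal volume
#'
#' C = N / (N_A * V_eff): the molar concentration corresponding to a
#' fitted mean molecule count in the calibrated effective volume.
#'
#' @param n_molecules Mean molecules in the focal volume (>= 0).
#' @param v_eff Effective volume in liters, or a `"focal_volume"`
#'   object.
#' @param constants See [fcs_constants()].
#' @return Concentration in mol/l.
#' @examples
#' concentration_from_n(10, 0.35e-15) * 1e9  # ~47.4 nM
#' @export
concentration_from_n <- function(n_molecules, v_eff,
                                 constants = fcs_constants()) {
  if (inherits(v_eff, "focal_volume")) v_eff <- v_eff$v_eff
  if (any(!is.finite(v_eff)) || any(v_eff <= 0)) {
    stop("v_eff must be > 0", call. = FALSE)
  }
  if (any(n_molecules < 0)) stop("n_molecules must be >= 0", call. = FALSE)
  n_molecules / (constants$avogadro * v_eff)
}

#' Molecules per nucleus from a nuclear concentration
#'
#' N_nucleus = C * V_nuc * N_A, with the HeLa nuclear volume
#' (6.90e-13 l = 690 cubic micrometers) as the default.
#'
#' @param c_molar Nuclear concentration in mol/l (>= 0).
#' @param nuclear_volume Nuclear volume in liters.
#' @param constants See [fcs_constants()].
#' @return Molecule count per nucleus (not rounded).
#' @examples
#' molecules_per_nucleus(3.2e-9)  # ~1300
#' @export
molecules_per_nucleus <- function(c_molar,
                                  nuclear_volume =
                                    fcs_constants()$hela_nuclear_volume,
                                  constants = fcs_constants()) {
  if (any(c_molar < 0)) stop("concentration must be >= 0", call. = FALSE)
  c_molar * nuclear_volume * constants$avogadro
}

#' DNA-bound concentration from the fast fraction
#'
#' In the two-component model the slow, anomalously diffusing fraction
#' is the chromatin-bound population, so the default `"complement"`
#' mode computes C_bound = (1 - F_fast) * C. The `"literal"` mode
#' computes C / F_fast instead — an alternative printed form that can
#' exceed the total concentration; when it does, a warning is issued
#' (never silently).
#'
#' @param c_molar Total nuclear concentration, mol/l.
#' @param f_fast Fast (freely diffusing) fraction. In `(0, 1]` for
#'   literal mode; `[0, 1]` for complement mode.
#' @param mode `"complement"` (default) or `"literal"`.
#' @return Bound concentration, mol/l.
#' @export
bound_concentration <- function(c_molar, f_fast,
                                mode = c("complement", "literal")) {
  mode <- match.arg(mode)
  if (any(!is.finite(f_fast)) || any(f_fast < 0) || any(f_fast > 1)) {
    stop("f_fast must lie in [0, 1]", call. = FALSE)
  }
  if (mode == "complement") {
    (1 - f_fast) * c_molar
  } else {
    if (any(f_fast == 0)) {
      stop("literal mode undefined at f_fast = 0", call. = FALSE)
    }
    out <- c_molar / f_fast
    if (any(out > c_molar)) {
      warning("literal-mode C_bound exceeds the total concentration; ",
              "the bound sub-population cannot be larger than the whole",
              call. = FALSE)
    }
    out
  }
}

#' Fraction of the delivered dose found in the nucleus
#'
#' @param n_nucleus Molecules per nucleus (>= 0).
#' @param dose_per_cell Delivered molecules per cell (> 0).
#' @return Dimensionless fraction (multiply by 100 for percent).
#' @examples
#' # ~16000 molecules/nucleus at a 15e7 molecules/cell dose -> ~0.01%
#' per_cell_fraction(molecules_per_nucleus(39e-9), 15e7) * 100
#' @export
per_cell_fraction <- function(n_nucleus, dose_per_cell) {
  if (any(!is.finite(dose_per_cell)) || any(dose_per_cell <= 0)) {
    stop("dose_per_cell must be > 0", call. = FALSE)
  }
  if (any(n_nucleus < 0)) stop("n_nucleus must be >= 0", call. = FALSE)
  n_nucleus / dose_per_cell
}

#' Per-cell nuclear quantification from accepted fits
#'
#' Converts QC-passing fits into a per-cell table of nuclear
#' concentration, molecules per nucleus, and bound concentration.
#'
#' @param fits List of `"fcs_fit"` objects (run [qc_filter()] first;
#'   only fits with `qc_status == "pass"` are used).
#' @param v_eff Effective volume in liters or a `"focal_volume"`.
#' @param nuclear_volume Nuclear volume in liters.
#' @param dose_per_cell Optional delivered dose (molecules/cell); when
#'   given, the nuclear fraction of the dose is reported.
#' @param bound_mode Passed to [bound_concentration()].
#' @param constants See [fcs_constants()].
#' @return A data frame with one row per accepted fit: `condition`,
#'   `cell_id`, `n_molecules`, `concentration_nM`, `n_nucleus`,
#'   `f_fast`, `c_bound_nM`, and (optionally) `nuclear_fraction`.
#' @export
nuclear_quant <- function(fits, v_eff,
                          nuclear_volume =
                            fcs_constants()$hela_nuclear_volume,
                          dose_per_cell = NULL,
                          bound_mode = "complement",
                          constants = fcs_constants()) {
  if (inherits(fits, "fcs_fit")) fits <- list(fits)
  pass <- Filter(function(f) identical(f$qc_status, "pass"), fits)
  if (length(pass) == 0) {
    stop("no fits with qc_status == 'pass'", call. = FALSE)
  }
  rows <- lapply(pass, function(f) {
    cf <- f$coefficients
    conc <- concentration_from_n(cf[["n_molecules"]], v_eff, constants)
    ff <- if ("f_fast" %in% names(cf)) cf[["f_fast"]] else NA_real_
    cb <- if (is.finite(ff)) {
      bound_concentration(conc, ff, mode = bound_mode)
    } else NA_real_
    meta <- f$curve$meta
    data.frame(
      condition = if (is.null(meta$condition)) "all"
                  else as.character(meta$condition),
      cell_id = if (is.null(meta$cell_id)) NA_character_
                else as.character(meta$cell_id),
      n_molecules = cf[["n_molecules"]],
      concentration_nM = conc * 1e9,
      n_nucleus = molecules_per_nucleus(conc, nuclear_volume, constants),
      f_fast = ff,
      c_bound_nM = cb * 1e9,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(dose_per_cell)) {
    out$nuclear_fraction <- per_cell_fraction(out$n_nucleus, dose_per_cell)
  }
  out
}

#' Per-condition summary of nuclear quantification
#'
#' Means and SEMs by condition, with counts printed to two significant
#' figures in the reporting columns (full precision is retained in the
#' numeric columns).
#'
#' @param quant Output of [nuclear_quant()].
#' @return Data frame: one row per condition with `n_cells`,
#'   `mean_conc_nM`, `sem_conc_nM`, `mean_n_nucleus`,
#'   `n_nucleus_2sf` (two-significant-figure count), `mean_c_bound_nM`,
#'   and `mean_nuclear_fraction` when present.
#' @export
nuclear_summary <- function(quant) {
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  out <- lapply(split(quant, quant$condition), function(d) {
    data.frame(
      condition = d$condition[1],
      n_cells = nrow(d),
      mean_conc_nM = mean(d$concentration_nM),
      sem_conc_nM = sem(d$concentration_nM),
      mean_n_nucleus = mean(d$n_nucleus),
      n_nucleus_2sf = signif(mean(d$n_nucleus), 2),
      mean_c_bound_nM = mean(d$c_bound_nM),
      mean_nuclear_fraction = if ("nuclear_fraction" %in% names(d))
        mean(d$nuclear_fraction) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
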