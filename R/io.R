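# Delimited-text I/O for every object the pipeline consumes or emits.
# All writers put a "# fcsquant <version>" comment on the first line;
# all readers skip comment lines and name missing columns explicitly.

.write_header <- function(path) {
  ver <- tryCatch(as.character(utils::packageVersion("fcsquant")),
                  error = function(e) "dev")
  writeLines(paste0("# fcsquant ", ver), path)
}

.read_delim <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", comment.char = "#",
               stringsAsFactors = FALSE),
    error = function(e) {
      stop("could not parse ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop(path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d
}

.append_table <- function(d, path) {
  suppressWarnings(
    write.table(d, path, append = TRUE, sep = "\t", quote = FALSE,
                row.names = FALSE))
}

#' Read / write autocorrelation curves
#'
#' Tab-delimited text with header columns `lag_s`, `g`, and optional
#' `g_se`.
#'
#' @param path File path.
#' @return `read_acf()` returns an [acf_curve()]; `write_acf()`
#'   returns `path` invisibly.
#' @export
read_acf <- function(path) {
  d <- .read_delim(path, c("lag_s", "g"))
  acf_curve(d$lag_s, d$g,
            g_se = if ("g_se" %in% names(d)) d$g_se else NULL,
            meta = list(file = basename(path)))
}

#' @param curve An [acf_curve()].
#' @rdname read_acf
#' @export
write_acf <- function(curve, path) {
  stopifnot(inherits(curve, "acf_curve"))
  d <- data.frame(lag_s = curve$lags, g = curve$g)
  if (!is.null(curve$g_se)) d$g_se <- curve$g_se
  .write_header(path)
  .append_table(d, path)
  invisible(path)
}

#' Read / write photon traces
#'
#' Either a two-column file (`time_s`, `counts`) or a single-column
#' integer file (in which case `bin_time` must be supplied).
#'
#' @param path File path.
#' @param bin_time Bin width in seconds for single-column files.
#' @return `read_photon_trace()` returns a [photon_trace()].
#' @export
read_photon_trace <- function(path, bin_time = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  if (all(c("time_s", "counts") %in% names(d))) {
    bt <- if (nrow(d) > 1) d$time_s[2] - d$time_s[1] else bin_time
    photon_trace(d$counts, bt, meta = list(file = basename(path)))
  } else if (ncol(d) == 1) {
    if (is.null(bin_time)) {
      stop("single-column trace file needs an explicit bin_time",
           call. = FALSE)
    }
    photon_trace(d[[1]], bin_time, meta = list(file = basename(path)))
  } else {
    stop(path, " must have columns time_s and counts, or one column",
         call. = FALSE)
  }
}

#' @param trace A [photon_trace()].
#' @rdname read_photon_trace
#' @export
write_photon_trace <- function(trace, path) {
  stopifnot(inherits(trace, "photon_trace"))
  d <- data.frame(
    time_s = (seq_along(trace$counts) - 1) * trace$bin_time,
    counts = trace$counts)
  .write_header(path)
  .append_table(d, path)
  invisible(path)
}

#' Read / write droplet tables
#'
#' Tab-delimited text with columns `well_id`, `hex_amplitude`,
#' `fam_amplitude`, `is_reference`; one row per droplet.
#'
#' @param path File path.
#' @return `read_droplets()` returns a list of [droplet_well()]
#'   objects, one per distinct `well_id`.
#' @export
read_droplets <- function(path) {
  d <- .read_delim(path, c("well_id", "hex_amplitude", "fam_amplitude",
                           "is_reference"))
  lapply(split(d, d$well_id), function(w) {
    droplet_well(w$hex_amplitude, w$fam_amplitude,
                 well_id = w$well_id[1],
                 is_reference = as.logical(w$is_reference[1]))
  })
}

#' @param wells A [droplet_well()] or list of them.
#' @rdname read_droplets
#' @export
write_droplets <- function(wells, path) {
  if (inherits(wells, "droplet_well")) wells <- list(wells)
  d <- do.call(rbind, lapply(wells, function(w) {
    data.frame(well_id = w$well_id, hex_amplitude = w$hex_amplitude,
               fam_amplitude = w$fam_amplitude,
               is_reference = w$is_reference, stringsAsFactors = FALSE)
  }))
  .write_header(path)
  .append_table(d, path)
  invisible(path)
}

#' Read a dose-response table
#'
#' Columns `dose_per_cell`, `response_pct`, and optionally
#' `condition`, `replicate`.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_dose_table <- function(path) {
  .read_delim(path, c("dose_per_cell", "response_pct"))
}

#' Read a time-course table
#'
#' Columns `time_h`, `value_pct`, optionally `condition` and
#' `dose_per_cell`.
#'
#' @param path File path.
#' @return A [time_course()].
#' @export
read_timecourse <- function(path) {
  d <- .read_delim(path, c("time_h", "value_pct"))
  time_course(d$time_h, d$value_pct,
              condition = if ("condition" %in% names(d))
                d$condition[1] else "all",
              dose_per_cell = if ("dose_per_cell" %in% names(d))
                d$dose_per_cell[1] else NA_real_)
}

#' Fit every ACF file in a batch and tabulate the results
#'
#' For each file: fit the one- and two-component models, select by
#' chi-square, apply the QC filters, and return one row of parameters
#' and QC status per curve — the batch interface for a directory of
#' exported correlation curves.
#'
#' @param paths Character vector of ACF file paths (see [read_acf()]).
#' @param conditions Optional condition label per file.
#' @param s Structure factor; default 0.17.
#' @param thresholds See [qc_thresholds()].
#' @param ... Passed to [fcs_fit()].
#' @return A data frame with one row per file: `file`, `condition`,
#'   `model`, the fitted parameters, `chi2`, `qc_status`,
#'   `qc_reasons` (comma-separated).
#' @export
fit_acf_files <- function(paths, conditions = NULL,
                          s = .default_structure_factor,
                          thresholds = qc_thresholds(), ...) {
  if (is.null(conditions)) conditions <- rep("all", length(paths))
  stopifnot(length(conditions) == length(paths))
  rows <- lapply(seq_along(paths), function(i) {
    curve <- read_acf(paths[i])
    curve$meta$condition <- conditions[i]
    f1 <- fcs_fit(curve, model = "one_component", s = s, ...)
    f2 <- fcs_fit(curve, model = "two_component", s = s, ...)
    fit <- qc_filter(select_model(f1, f2), thresholds)
    cf <- fit$coefficients
    pick <- function(nm) {
      if (!is.null(cf) && nm %in% names(cf)) cf[[nm]] else NA_real_
    }
    data.frame(
      file = basename(paths[i]), condition = conditions[i],
      model = fit$model,
      n_molecules = pick("n_molecules"),
      tau_diff1 = if (!is.null(cf) && "tau_diff1" %in% names(cf))
        cf[["tau_diff1"]] else pick("tau_diff"),
      tau_diff2 = pick("tau_diff2"),
      alpha = pick("alpha"),
      f_fast = pick("f_fast"),
      chi2 = fit$chi2, qc_status = fit$qc_status,
      qc_reasons = paste(fit$qc_reasons, collapse = ","),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
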