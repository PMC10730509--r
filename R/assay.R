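#' Read a long-format plate-reader CSV
#'
#' Expected columns: `well`, `time_s`, `lum` (or `donor` and `acceptor` for
#' BRET plates) plus optional per-well metadata `receptor`, `g_alpha`,
#' `wavelength_nm`, `intensity_uW_cm2`, `ligand_nM`.
#'
#' @param path CSV path.
#' @return A tibble sorted by well and time.
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("Plate CSV not found: %s", path))
  plate <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"well" %in% names(plate) || !"time_s" %in% names(plate)) {
    abort(sprintf("Plate CSV '%s' must have columns well and time_s.", path))
  }
  arrange(plate, .data$well, .data$time_s)
}

#' Normalize luminescence wells to their pre-activation baseline
#'
#' Each well's trace is divided by the mean of its first `baseline_reads`
#' reads, giving a dimensionless fold-change whose baseline mean is 1. The
#' per-well maximum normalized response at or after the stimulus is the RLU
#' maximum ("relative light units"); no smoothing is applied unless a window
#' is requested.
#'
#' @param plate Long-format tibble with columns `well`, `time_s`, `lum`
#'   (plus any metadata, carried through).
#' @param baseline_reads Number of pre-activation reads per well; default 3.
#' @param stimulus_index 1-based index of the first post-stimulus read;
#'   defaults to `baseline_reads + 1`.
#' @param smooth Optional odd window width for a centered running mean
#'   applied before taking the maximum; `NULL` (default) disables smoothing.
#' @return The input tibble with added columns `normalized` and (repeated
#'   per well) `rlu_max`, of class `gsx_normalized`.
#' @examples
#' plate <- tibble::tibble(
#'   well = "A1", time_s = c(0, 30, 60, 90), lum = c(100, 100, 100, 200)
#' )
#' normalize_wells(plate)
#' @export
normalize_wells <- function(plate, baseline_reads = 3L,
                            stimulus_index = baseline_reads + 1L,
                            smooth = NULL) {
  stopifnot(is.data.frame(plate), all(c("well", "time_s", "lum") %in% names(plate)))
  baseline_reads <- as.integer(baseline_reads)
  stimulus_index <- as.integer(stimulus_index)
  if (baseline_reads < 1L) abort("`baseline_reads` must be >= 1.")
  if (stimulus_index < baseline_reads) {
    abort("`stimulus_index` must be at least `baseline_reads`.")
  }
  out <- plate |>
    arrange(.data$well, .data$time_s) |>
    group_by(.data$well) |>
    group_modify(function(d, key) {
      if (nrow(d) < baseline_reads + 1L) {
        abort(sprintf(
          "Well '%s' has %d reads; need at least baseline_reads + 1 = %d.",
          key$well, nrow(d), baseline_reads + 1L
        ))
      }
      f0 <- mean(d$lum[seq_len(baseline_reads)])
      if (!is.finite(f0) || f0 <= 0) {
        abort(sprintf("Well '%s' has a non-positive baseline mean.", key$well))
      }
      v <- d$lum / f0
      vmax <- if (!is.null(smooth)) running_mean(v, smooth) else v
      post <- stimulus_index:nrow(d)
      mutate(d, normalized = v, rlu_max = max(vmax[post]))
    }) |>
    ungroup()
  structure(out, class = c("gsx_normalized", class(tibble())),
            baseline_reads = baseline_reads, stimulus_index = stimulus_index)
}

running_mean <- function(x, window) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) abort("`smooth` must be a positive odd integer.")
  h <- window %/% 2L
  vapply(seq_along(x), function(i) {
    mean(x[max(1L, i - h):min(length(x), i + h)])
  }, numeric(1))
}

#' Per-well RLU maxima of a normalized plate
#'
#' @param normalized Output of [normalize_wells()].
#' @return One row per well with its metadata and `rlu_max`.
#' @export
rlu_summary <- function(normalized) {
  keep <- setdiff(names(normalized), c("time_s", "lum", "normalized"))
  normalized |>
    as_tibble() |>
    select(dplyr::all_of(keep)) |>
    dplyr::distinct()
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `response(d) = bottom + (top - bottom) /
#' (1 + (ec50 / d)^hill)` by Levenberg-Marquardt. Initialization is
#' deterministic: `bottom = min(response)`, `top = max(response)`, `ec50` the
#' dose whose mean response is nearest the half-maximum, `hill = 1`, with
#' `ec50` bounded in `[min(dose)/10, max(dose) * 10]`.
#'
#' @param data Data frame holding dose and response columns.
#' @param dose,response Column names (character) or bare numeric vectors.
#' @return A `dose_response_fit` with fields `bottom`, `top`, `ec50`, `hill`,
#'   `rss`, `converged`, plus `tidy()`, `glance()`, `predict()` and
#'   `autoplot()` methods.
#' @examples
#' d <- tibble::tibble(dose = c(5, 15, 50, 150, 500))
#' d$resp <- 1 + 9 / (1 + (50 / d$dose))
#' fit_dose_response(d, "dose", "resp")
#' @export
fit_dose_response <- function(data, dose = "dose", response = "response") {
  if (is.data.frame(data)) {
    x <- data[[dose]]
    y <- data[[response]]
  } else {
    x <- data
    y <- dose
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("Doses and responses must be finite.")
  if (any(x <= 0)) abort("Doses must be positive.")
  if (length(unique(x)) < 4L) abort("Need at least 4 distinct dose levels.")
  half <- (max(y) + min(y)) / 2
  mu <- tapply(y, x, mean)
  start <- list(
    bottom = min(y), top = max(y),
    ec50 = as.numeric(names(mu))[which.min(abs(mu - half))],
    hill = 1
  )
  lower <- c(bottom = -Inf, top = -Inf, ec50 = min(x) / 10, hill = -Inf)
  upper <- c(bottom = Inf, top = Inf, ec50 = max(x) * 10, hill = Inf)
  df <- data.frame(d = x, r = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ bottom + (top - bottom) / (1 + (ec50 / d)^hill),
      data = df, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) abort(sprintf("Dose-response fit failed: %s", conditionMessage(e)))
  )
  est <- as.list(stats::coef(fit))
  structure(
    list(
      bottom = est$bottom, top = est$top, ec50 = est$ec50, hill = est$hill,
      rss = sum(stats::resid(fit)^2),
      converged = isTRUE(fit$convInfo$isConv),
      n = length(x),
      data = tibble(dose = x, response = y),
      model = fit
    ),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> bottom %.4g, top %.4g, ec50 %.4g, hill %.4g (rss %.4g, %s, n = %d)\n",
    x$bottom, x$top, x$ec50, x$hill, x$rss,
    if (x$converged) "converged" else "NOT converged", x$n
  ))
  invisible(x)
}

#' Predict from a fitted dose-response curve
#'
#' @param object A `dose_response_fit`.
#' @param newdata Numeric doses, or a data frame with a `dose` column.
#' @param ... Unused.
#' @return Numeric predicted responses.
#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$dose
  else if (is.data.frame(newdata)) newdata$dose
  else newdata
  object$bottom + (object$top - object$bottom) / (1 + (object$ec50 / d)^object$hill)
}

#' Summarize the activation wavelength profile of a plate
#'
#' Groups wells by their activation wavelength, averages the per-well RLU
#' maxima, and reports the peak wavelength (the smallest wavelength achieving
#' the maximum mean, so ties resolve deterministically).
#'
#' @inheritParams normalize_wells
#' @return A tibble `wavelength_nm`, `mean_rlu`, `sd_rlu`, `n` of class
#'   `action_spectrum`, with attribute `peak_wavelength_nm`.
#' @export
action_spectrum <- function(plate, baseline_reads = 3L,
                            stimulus_index = baseline_reads + 1L) {
  if (!"wavelength_nm" %in% names(plate) || all(is.na(plate$wavelength_nm))) {
    abort("Plate has no wavelength metadata.")
  }
  rlu <- rlu_summary(normalize_wells(plate, baseline_reads, stimulus_index))
  if (length(unique(rlu$wavelength_nm)) < 2L) {
    abort("Action spectrum needs at least 2 distinct wavelengths.")
  }
  spec <- rlu |>
    group_by(.data$wavelength_nm) |>
    summarise(
      mean_rlu = mean(.data$rlu_max),
      sd_rlu = stats::sd(.data$rlu_max),
      n = dplyr::n(), .groups = "drop"
    ) |>
    arrange(.data$wavelength_nm)
  peak <- spec$wavelength_nm[which.max(spec$mean_rlu)]  # first max = smallest wavelength
  structure(spec, class = c("action_spectrum", class(tibble())),
            peak_wavelength_nm = peak)
}

#' Peak wavelength of an action spectrum
#'
#' @param spectrum Output of [action_spectrum()].
#' @return Numeric wavelength in nm.
#' @export
peak_wavelength <- function(spectrum) attr(spectrum, "peak_wavelength_nm")

#' BRET2 ratio and baseline-corrected ratio change
#'
#' For each read the BRET ratio is acceptor (GFP2) emission over donor
#' (RLuc8) emission; the ratio change subtracts the mean ratio of the first
#' `baseline_reads` reads, so the baseline of the corrected series is 0 by
#' construction.
#'
#' @param trace Tibble with columns `time_s`, `donor`, `acceptor` (a `well`
#'   column, if present, is handled per well).
#' @param baseline_reads Number of pre-stimulus reads; default 3.
#' @return The input with added columns `ratio` and `delta_bret`.
#' @export
bret_ratio <- function(trace, baseline_reads = 3L) {
  stopifnot(is.data.frame(trace), all(c("time_s", "donor", "acceptor") %in% names(trace)))
  baseline_reads <- as.integer(baseline_reads)
  one <- function(d, key) {
    if (any(!is.finite(d$donor) | d$donor <= 0)) {
      abort(sprintf(
        "Donor emission must be strictly positive%s.",
        if (!is.null(key)) sprintf(" (well '%s')", key$well) else ""
      ))
    }
    if (nrow(d) < baseline_reads) {
      abort("Trace shorter than `baseline_reads`.")
    }
    ratio <- d$acceptor / d$donor
    mutate(d, ratio = ratio, delta_bret = ratio - mean(ratio[seq_len(baseline_reads)]))
  }
  if ("well" %in% names(trace)) {
    trace |>
      arrange(.data$well, .data$time_s) |>
      group_by(.data$well) |>
      group_modify(one) |>
      ungroup()
  } else {
    one(arrange(trace, .data$time_s), NULL)
  }
}
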