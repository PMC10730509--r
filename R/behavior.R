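#' Odor preference index
#'
#' `(n_odor - n_blank) / n_total`: larvae on the odor side minus larvae on
#' the blank side, over all larvae. Animals in the mid-zone count toward
#' `n_total` but toward neither side. Vectorized.
#'
#' @param n_odor,n_blank Non-negative counts per side.
#' @param n_total Positive total count (`>= n_odor + n_blank`).
#' @return Numeric in `[-1, 1]`.
#' @examples
#' preference_index(15, 5, 20)
#' @export
preference_index <- function(n_odor, n_blank, n_total) {
  check_counts(n_odor, n_blank, n_total)
  (n_odor - n_blank) / n_total
}

check_counts <- function(a, b, total) {
  if (any(total <= 0)) abort("`n_total` must be positive.")
  if (any(a < 0) || any(b < 0)) abort("Counts must be non-negative.")
  if (any(a + b > total)) abort("Side counts exceed `n_total`.")
  invisible(TRUE)
}

#' Learning index from reciprocal paired/unpaired preferences
#'
#' `LI = (pref_paired - pref_unpaired) / 2`, where the paired group received
#' odor together with the reward during training and the unpaired group
#' received them separately. Vectorized.
#'
#' @param pref_paired,pref_unpaired Odor preferences in `[-1, 1]`.
#' @return Numeric in `[-1, 1]`.
#' @examples
#' learning_index(0.6, 0.2)
#' @export
learning_index <- function(pref_paired, pref_unpaired) {
  if (any(abs(pref_paired) > 1) || any(abs(pref_unpaired) > 1)) {
    abort("Preferences must lie in [-1, 1].")
  }
  (pref_paired - pref_unpaired) / 2
}

#' T-maze performance index
#'
#' `PI = (n_cs_plus - n_cs_minus) / n_total`. When the counts of the
#' reciprocal experiment (odors interchanged as CS+) are supplied, the two
#' indices are averaged, as one PI per reciprocal pair.
#'
#' @param n_cs_plus,n_cs_minus Flies choosing the CS+ / CS- arm.
#' @param n_total Total flies.
#' @param reciprocal Optional list or data frame with fields `n_cs_plus`,
#'   `n_cs_minus`, `n_total` of the reciprocal experiment.
#' @return Numeric in `[-1, 1]`.
#' @examples
#' performance_index(30, 10, 40)
#' performance_index(30, 10, 40, reciprocal = list(n_cs_plus = 24, n_cs_minus = 16, n_total = 40))
#' @export
performance_index <- function(n_cs_plus, n_cs_minus, n_total, reciprocal = NULL) {
  check_counts(n_cs_plus, n_cs_minus, n_total)
  pi1 <- (n_cs_plus - n_cs_minus) / n_total
  if (is.null(reciprocal)) return(pi1)
  pi2 <- performance_index(reciprocal$n_cs_plus, reciprocal$n_cs_minus, reciprocal$n_total)
  (pi1 + pi2) / 2
}

#' Fraction of animals categorized as rolling, with Wilson 95% CI
#'
#' Escape responses are categorized per animal as rolling (a full 360-degree
#' rotation along the body axis) or not; this summarizes the contingency as
#' a fraction with a Wilson score interval (well behaved at small n and at
#' 0/1 fractions).
#'
#' @param n_rolling Number of rolling animals.
#' @param n_total Total animals (>= 1).
#' @param conf_level Confidence level; default 0.95.
#' @return A one-row tibble: `fraction`, `ci_lower`, `ci_upper`, `n_rolling`,
#'   `n_total`.
#' @examples
#' rolling_fraction(7, 20)
#' @export
rolling_fraction <- function(n_rolling, n_total, conf_level = 0.95) {
  if (n_total < 1) abort("`n_total` must be >= 1.")
  if (n_rolling < 0 || n_rolling > n_total) {
    abort("`n_rolling` must lie in [0, n_total].")
  }
  ci <- stats::prop.test(n_rolling, n_total, conf.level = conf_level, correct = FALSE)$conf.int
  tibble(
    fraction = n_rolling / n_total,
    ci_lower = ci[1], ci_upper = ci[2],
    n_rolling = n_rolling, n_total = n_total
  )
}

#' Per-animal locomotion summaries from a track table
#'
#' For each animal, over the first `window_s` seconds: the mean velocity
#' (mean Euclidean centroid displacement between consecutive frames times
#' the frame rate, mm/s, unsmoothed) and the cumulative bending (sum of
#' absolute bending angles, degrees).
#'
#' @param tracks Tibble with columns `animal_id`, `frame`, `x_mm`, `y_mm`,
#'   `bending_deg`; frames must be strictly increasing per animal.
#' @param window_s Analysis window from the start of the track; default 30 s.
#' @param frame_rate_hz Acquisition rate; default 10 frames/s.
#' @return One row per animal: `animal_id`, `mean_velocity_mm_s`,
#'   `cumulative_bending_deg`, `n_frames`.
#' @export
locomotion_summary <- function(tracks, window_s = 30, frame_rate_hz = 10) {
  stopifnot(is.data.frame(tracks),
            all(c("animal_id", "frame", "x_mm", "y_mm", "bending_deg") %in% names(tracks)))
  tracks |>
    group_by(.data$animal_id) |>
    group_modify(function(d, key) {
      if (is.unsorted(d$frame, strictly = TRUE)) {
        abort(sprintf("Frames not strictly increasing for animal '%s'.", key$animal_id))
      }
      t_s <- d$frame / frame_rate_hz
      d <- d[t_s - min(t_s) <= window_s, ]
      if (nrow(d) < 2L) {
        abort(sprintf("Animal '%s' has fewer than 2 frames inside the window.", key$animal_id))
      }
      step <- sqrt(diff(d$x_mm)^2 + diff(d$y_mm)^2)
      tibble(
        mean_velocity_mm_s = mean(step) * frame_rate_hz,
        cumulative_bending_deg = sum(abs(d$bending_deg)),
        n_frames = nrow(d)
      )
    }) |>
    ungroup()
}

#' Baseline-normalized fluorescence change (dF/F)
#'
#' `F0` is the mean of the first `baseline_frames` values; the series is
#' `(F - F0) / F0` and `dff_max` is its maximum over the post-stimulus
#' frames. The default 95-frame baseline matches confocal cAMP/calcium
#' recordings; use `baseline_frames = 50` for the intact-larva two-photon
#' protocol.
#'
#' @param trace Numeric fluorescence values, or a data frame with a column
#'   `F` (and optionally `frame`).
#' @param baseline_frames Number of pre-stimulus frames averaged into `F0`.
#' @param stimulus_frame First post-stimulus frame; defaults to
#'   `baseline_frames + 1`.
#' @return A tibble `frame`, `F`, `dff` of class `dff_trace`, with
#'   attributes `f0` and `dff_max` (see [dff_max()]).
#' @examples
#' tr <- c(rep(100, 95), 150, 120, 110)
#' dff_max(dff_trace(tr))
#' @export
dff_trace <- function(trace, baseline_frames = 95L,
                      stimulus_frame = baseline_frames + 1L) {
  f <- if (is.data.frame(trace)) trace[["F"]] else trace
  if (is.null(f)) abort("`trace` must be numeric or have a column `F`.")
  baseline_frames <- as.integer(baseline_frames)
  if (baseline_frames < 1L || baseline_frames >= length(f)) {
    abort("`baseline_frames` must be positive and smaller than the trace length.")
  }
  f0 <- mean(f[seq_len(baseline_frames)])
  if (!is.finite(f0) || f0 <= 0) abort("Baseline mean must be positive.")
  dff <- (f - f0) / f0
  post <- stimulus_frame:length(f)
  structure(
    tibble(frame = seq_along(f), F = f, dff = dff),
    class = c("dff_trace", class(tibble())),
    f0 = f0, dff_max = max(dff[post]), baseline_frames = baseline_frames
  )
}

#' Maximum post-stimulus dF/F of a trace
#'
#' @param x Output of [dff_trace()].
#' @return Numeric scalar.
#' @export
dff_max <- function(x) attr(x, "dff_max")
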