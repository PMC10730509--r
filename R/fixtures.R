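#' Default toy receptor segment lengths
#'
#' A small but fully canonical class-A topology (all seven TMs, three
#' loops each side, H8) used by the toy receptor generator.
#'
#' @return Named integer vector of segment lengths in canonical order.
#' @export
toy_segment_lengths <- function() {
  c(
    NTERM = 8L, TM1 = 18L, ICL1 = 6L, TM2 = 18L, ECL1 = 5L, TM3 = 18L,
    ICL2 = 8L, TM4 = 18L, ECL2 = 8L, TM5 = 18L, ICL3 = 12L, TM6 = 18L,
    ECL3 = 5L, TM7 = 18L, H8 = 8L, CTERM = 12L
  )
}

# hydrophobic-biased pool for TM segments; uniform 20-letter pool for loops
TM_POOL <- c("A", "C", "F", "G", "I", "L", "M", "S", "T", "V", "W", "Y")
LOOP_POOL <- setdiff(AA_ALPHABET, "X")

#' Generate a toy GPCR with known topology
#'
#' Draws a random receptor whose sequence is the concatenation of segments
#' of the requested lengths, TM segments from a hydrophobic-biased residue
#' pool so toy alignments behave like real topologies, loops and termini
#' from the full 20-letter alphabet. Deterministic for a given seed.
#'
#' @param segment_lengths Named lengths in canonical order (H8 optional);
#'   default [toy_segment_lengths()].
#' @param seed Integer seed.
#' @param id Sequence identifier.
#' @return A list with elements `sequence` (`protein_seq`) and `topology`
#'   (`gpcr_topology`).
#' @examples
#' toy <- make_toy_gpcr(seed = 1)
#' toy$topology
#' @export
make_toy_gpcr <- function(segment_lengths = toy_segment_lengths(), seed = 1L,
                          id = paste0("toy", seed)) {
  segment_lengths <- segment_lengths[order(match(names(segment_lengths), SEGMENT_ORDER))]
  if (anyNA(match(names(segment_lengths), SEGMENT_ORDER))) {
    abort("Unknown segment name in `segment_lengths`.")
  }
  if (any(segment_lengths < 1L)) abort("Zero-length mandatory segment.")
  if (sum(segment_lengths) < 15L) abort("Toy receptor must have at least 15 residues.")
  res <- withr::with_seed(as.integer(seed), {
    unlist(imap(as.list(segment_lengths), function(len, seg) {
      pool <- if (grepl("^TM", seg)) TM_POOL else LOOP_POOL
      sample(pool, len, replace = TRUE)
    }))
  })
  seqn <- protein_seq(id, paste(res, collapse = ""))
  ends <- cumsum(segment_lengths)
  topo <- topology(
    tibble(
      segment = names(segment_lengths),
      start = as.integer(ends - segment_lengths + 1L),
      end = as.integer(ends)
    ),
    seqn
  )
  list(sequence = seqn, topology = topo)
}

# four-parameter logistic response
four_pl <- function(d, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / d)^hill)
}

#' Simulate a luminescent G-protein-coupling plate
#'
#' Generates long-format plate traces whose post-stimulus fold-change over
#' baseline follows a four-parameter logistic curve of the dose (ligand
#' concentration or light intensity). Baseline reads are drawn around
#' `baseline_level` with coefficient of variation `noise_sd` (reflected at
#' zero to stay positive); post-stimulus reads scale the baseline by the 4PL
#' fold-change at the well's dose, with the same relative noise. With
#' `noise_sd = 0` normalization recovers the 4PL fold-changes exactly.
#'
#' @param doses Positive dose levels; the default spans the nanomolar
#'   dopamine range used in the coupling assays.
#' @param bottom,top,ec50,hill 4PL truth on the fold-change scale; defaults
#'   `bottom = 1` (no response at zero dose), `top = 6`, `ec50 = 50`,
#'   `hill = 1`.
#' @param noise_sd Relative noise (CV); default 0.05.
#' @param baseline_level Raw baseline luminescence counts; default 1000.
#' @param baseline_reads Pre-stimulus reads per well; default 3.
#' @param n_post Post-stimulus reads per well; default 10.
#' @param n_replicates Wells per dose; default 2 (technical duplicates).
#' @param dt_s Read interval in seconds; default 30.
#' @param dose_var Metadata column to store the dose in: `"ligand_nM"` or
#'   `"intensity_uW_cm2"`.
#' @param seed Integer seed.
#' @return A long-format plate tibble (`well`, `time_s`, `lum`, dose
#'   metadata) ready for [normalize_wells()] / [fit_dose_response()].
#' @export
simulate_plate <- function(doses = c(1, 3, 10, 30, 100, 300, 1000),
                           bottom = 1, top = 6, ec50 = 50, hill = 1,
                           noise_sd = 0.05, baseline_level = 1000,
                           baseline_reads = 3L, n_post = 10L,
                           n_replicates = 2L, dt_s = 30,
                           dose_var = c("ligand_nM", "intensity_uW_cm2"),
                           seed = 1L) {
  dose_var <- match.arg(dose_var)
  if (any(doses <= 0)) abort("Doses must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (ec50 < min(doses) || ec50 > max(doses)) {
    abort("`ec50` must lie within the dose range.")
  }
  n_reads <- baseline_reads + n_post
  times <- (seq_len(n_reads) - 1L) * dt_s
  withr::with_seed(as.integer(seed), {
    grid <- tidyr::expand_grid(dose = doses, rep = seq_len(n_replicates))
    traces <- pmap(grid, function(dose, rep) {
      fc <- four_pl(dose, bottom, top, ec50, hill)
      mu <- c(rep(baseline_level, baseline_reads), rep(baseline_level * fc, n_post))
      lum <- abs(rnorm(n_reads, mu, noise_sd * mu))
      tibble(
        well = sprintf("d%g_r%d", dose, rep),
        time_s = times, lum = lum, !!dose_var := dose
      )
    })
    bind_rows(traces)
  })
}

#' Simulate an action-spectrum plate
#'
#' One group of wells per activation wavelength, each with a prescribed mean
#' RLU fold-change; used to exercise [action_spectrum()].
#'
#' @param wavelengths Wavelengths in nm; default the LED set
#'   385/425/470/525/595 nm.
#' @param mean_rlu Mean fold-change per wavelength (same length); the default
#'   profile peaks at 470 nm.
#' @inheritParams simulate_plate
#' @return A long-format plate tibble with `wavelength_nm` metadata.
#' @export
simulate_action_plate <- function(wavelengths = c(385, 425, 470, 525, 595),
                                  mean_rlu = c(2.5, 4.0, 6.0, 4.5, 1.8),
                                  noise_sd = 0.05, baseline_level = 1000,
                                  baseline_reads = 3L, n_post = 10L,
                                  n_replicates = 3L, dt_s = 30, seed = 1L) {
  stopifnot(length(wavelengths) == length(mean_rlu))
  n_reads <- baseline_reads + n_post
  times <- (seq_len(n_reads) - 1L) * dt_s
  withr::with_seed(as.integer(seed), {
    grid <- tidyr::expand_grid(i = seq_along(wavelengths), rep = seq_len(n_replicates))
    bind_rows(pmap(grid, function(i, rep) {
      mu <- c(rep(baseline_level, baseline_reads), rep(baseline_level * mean_rlu[i], n_post))
      tibble(
        well = sprintf("w%g_r%d", wavelengths[i], rep),
        time_s = times,
        lum = abs(rnorm(n_reads, mu, noise_sd * mu)),
        wavelength_nm = wavelengths[i]
      )
    }))
  })
}

#' Simulate larval side-choice counts
#'
#' Multinomial draw of (odor side, blank side, mid-zone) occupancies.
#'
#' @param p_odor,p_blank Per-animal probabilities of ending on each side
#'   (`p_odor + p_blank <= 1`; the remainder is the mid-zone).
#' @param n Number of animals; default 20 per trial.
#' @param seed Integer seed.
#' @return A one-row tibble `n_odor`, `n_blank`, `n_total`.
#' @export
simulate_behavior_counts <- function(p_odor, p_blank, n = 20L, seed = 1L) {
  if (p_odor < 0 || p_blank < 0 || p_odor + p_blank > 1) {
    abort("Require p_odor, p_blank >= 0 and p_odor + p_blank <= 1.")
  }
  if (n < 1) abort("`n` must be >= 1.")
  draw <- withr::with_seed(as.integer(seed), {
    rmultinom(1, n, c(p_odor, p_blank, 1 - p_odor - p_blank))
  })
  tibble(n_odor = draw[1, 1], n_blank = draw[2, 1], n_total = as.integer(n))
}

#' Simulate a fluorescence trace with known peak dF/F
#'
#' Flat baseline at `f0`, then an instantaneous rise to `peak_dff` at the
#' first post-stimulus frame followed by exponential decay with time
#' constant `decay_tau_s` (signals decay back to background within about a
#' minute after a brief blue-light stimulus). In the noiseless limit
#' [dff_trace()] recovers `peak_dff` exactly.
#'
#' @param f0 Baseline fluorescence; default 100.
#' @param peak_dff Peak relative change; default 0.5.
#' @param decay_tau_s Decay time constant; default 10 s.
#' @param baseline_frames Pre-stimulus frames; default 95 (confocal
#'   protocol; use 50 for the intact-larva variant).
#' @param frame_rate_hz Frames per second; default 7.5.
#' @param n_frames Total frames; default 600.
#' @param noise_sd Relative Gaussian noise on F; default 0.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A tibble `frame`, `F` suitable for [dff_trace()].
#' @export
simulate_fluorescence <- function(f0 = 100, peak_dff = 0.5, decay_tau_s = 10,
                                  baseline_frames = 95L, frame_rate_hz = 7.5,
                                  n_frames = 600L, noise_sd = 0, seed = 1L) {
  if (f0 <= 0 || decay_tau_s <= 0 || frame_rate_hz <= 0) {
    abort("`f0`, `decay_tau_s` and `frame_rate_hz` must be positive.")
  }
  if (baseline_frames >= n_frames) abort("`baseline_frames` must be < `n_frames`.")
  frames <- seq_len(n_frames)
  t_after <- pmax(0, (frames - (baseline_frames + 1L)) / frame_rate_hz)
  dff <- ifelse(frames <= baseline_frames, 0, peak_dff * exp(-t_after / decay_tau_s))
  f <- f0 * (1 + dff)
  if (noise_sd > 0) {
    f <- withr::with_seed(as.integer(seed), abs(rnorm(n_frames, f, noise_sd * f0)))
  }
  tibble(frame = frames, F = f)
}

#' Simulate larval centroid tracks
#'
#' Constant-speed random-heading walks with Gaussian bending angles, in the
#' format produced by video tracking (one row per animal per frame).
#'
#' @param n_animals Number of animals; default 5 (one trial).
#' @param duration_s Track length; default 60 s.
#' @param frame_rate_hz Frames per second; default 10.
#' @param speed_mm_s Centroid speed; default 1 mm/s.
#' @param bending_sd_deg SD of per-frame bending angles; default 15.
#' @param seed Integer seed.
#' @return A tibble `animal_id`, `frame`, `time_s`, `x_mm`, `y_mm`,
#'   `bending_deg`.
#' @export
simulate_tracks <- function(n_animals = 5L, duration_s = 60, frame_rate_hz = 10,
                            speed_mm_s = 1, bending_sd_deg = 15, seed = 1L) {
  n_frames <- as.integer(duration_s * frame_rate_hz)
  step <- speed_mm_s / frame_rate_hz
  withr::with_seed(as.integer(seed), {
    bind_rows(map(seq_len(n_animals), function(a) {
      heading <- cumsum(c(stats::runif(1, 0, 2 * pi), rnorm(n_frames - 1, 0, 0.15)))
      tibble(
        animal_id = sprintf("larva%02d", a),
        frame = seq_len(n_frames),
        time_s = seq_len(n_frames) / frame_rate_hz,
        x_mm = cumsum(step * cos(heading)),
        y_mm = cumsum(step * sin(heading)),
        bending_deg = rnorm(n_frames, 0, bending_sd_deg)
      )
    }))
  })
}
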