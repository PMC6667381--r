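# Synthetic data generators.
#
# Every input the pipeline consumes can be generated with the statistical
# structure the analysis assumes, so all stages are testable without
# instrument data. The generators define the package's "stated world":
# their defaults reproduce the X-ray worked example (sparse 6.1 µmol/L at
# 160 µm^-1, total ~11.3 µmol/L at 32 Gy) and the standard measurement
# protocols (10-concentration DMPO series, 11-point decay series starting
# 3 min after exposure, 0-980 µmol/L H2O2 standards).

#' The standard DMPO dilution series, mmol/L
#' @export
DMPO_SERIES_MM <- c(0.5, 1.6, 3.3, 7.7, 13.3, 26.0, 61.6, 208, 600, 1685)

#' Generative truth for a titration curve
#'
#' Two localized radical populations with distinct site densities: a sparse
#' one (amount `A_s` µmol/L saturating at density `d_s` µm^-1) and a dense
#' one (`A_d` µmol/L saturating at `d_d` >= 1000 µm^-1). The response at
#' trap density x is
#' `y(x) = A_s min(x/d_s, 1) + A_d min(x/d_d, 1) + noise`.
#' Defaults are calibrated so the noiseless end-to-end analysis reproduces
#' the X-ray worked example (sparse 160 µm^-1 / 6.8 mM, total ~11.3 µmol/L).
#'
#' @param A_s,d_s sparse amount (µmol/L) and saturation density (µm^-1).
#' @param A_d,d_d dense amount (µmol/L) and saturation density (µm^-1,
#'   >= 1000).
#' @param noise_sd additive Gaussian noise on DMPO-OH, µmol/L.
#' @return a validated `titration_truth` list.
#' @export
titration_truth <- function(A_s = 6.1, d_s = 160, A_d = 51.7, d_d = 1e4,
                            noise_sd = 0) {
  check_scalar(A_s, "A_s", min = 0)
  check_scalar(A_d, "A_d", min = 0)
  check_scalar(d_s, "d_s", min = 0, strict_min = TRUE)
  check_scalar(d_d, "d_d", min = 1000)
  if (d_d <= d_s) stop_domain("`d_d` must exceed `d_s`")
  check_scalar(noise_sd, "noise_sd", min = 0)
  structure(list(A_s = A_s, d_s = d_s, A_d = A_d, d_d = d_d,
                 noise_sd = noise_sd),
            class = "titration_truth")
}

#' Generate a synthetic titration curve
#'
#' @param truth a [titration_truth()] (or a list of overrides for its
#'   defaults).
#' @param dmpo_mM DMPO concentration grid in mmol/L; defaults to the
#'   standard 10-concentration series [DMPO_SERIES_MM].
#' @param dose_Gy,modality,let_keV_um metadata passed to
#'   [titration_curve()].
#' @param seed optional integer making the noise reproducible; the caller's
#'   RNG stream is left untouched.
#' @return a [titration_curve()] with responses clamped at 0.
#' @export
generate_titration <- function(truth = titration_truth(),
                               dmpo_mM = DMPO_SERIES_MM,
                               dose_Gy = 32, modality = "xray",
                               let_keV_um = NULL, seed = NULL) {
  if (!inherits(truth, "titration_truth")) {
    truth <- do.call(titration_truth, as.list(truth))
  }
  check_numeric_vec(dmpo_mM, "dmpo_mM", min = 0, strict_min = TRUE,
                    min_len = 6L)
  x <- concentration_to_linear_density(dmpo_mM, "mmol/L")
  y <- truth$A_s * pmin(x / truth$d_s, 1) + truth$A_d * pmin(x / truth$d_d, 1)
  if (truth$noise_sd > 0) {
    y <- y + with_seed(seed, rnorm(length(y), sd = truth$noise_sd))
  }
  titration_curve(dmpo_mM, pmax(y, 0), dose_Gy, modality, let_keV_um)
}

#' Generate a post-irradiation decay series
#'
#' Default timing follows the X-ray protocol: measurements start 3 min after
#' the end of irradiation and repeat every minute, 11 points in total.
#' Noise is multiplicative, `c0 e^(-k t) (1 + eps)`, as EPR intensity errors
#' scale with the signal.
#'
#' @param c0 concentration at the end of irradiation (µmol/L or a.u.).
#' @param k first-order decay rate, min^-1 (>= 0).
#' @param t_start first measurement time, minutes.
#' @param n number of measurements.
#' @param dt measurement interval, minutes.
#' @param noise_sd relative noise standard deviation.
#' @param seed optional integer seed.
#' @return a [decay_series()].
#' @export
generate_decay_series <- function(c0 = 10, k = 0.05, t_start = 3, n = 11L,
                                  dt = 1, noise_sd = 0, seed = NULL) {
  check_scalar(c0, "c0", min = 0, strict_min = TRUE)
  check_scalar(k, "k", min = 0)
  check_scalar(noise_sd, "noise_sd", min = 0)
  if (n < 3L) stop_domain("`n` must be at least 3")
  t <- t_start + dt * (seq_len(n) - 1L)
  y <- c0 * exp(-k * t)
  if (noise_sd > 0) {
    y <- y * (1 + with_seed(seed, rnorm(n, sd = noise_sd)))
  }
  decay_series(t, pmax(y, .Machine$double.eps))
}

#' Generate an H2O2 calibration-standard table
#'
#' @param slope,intercept true linear response (signal per µmol/L, signal).
#' @param conc_uM standard concentrations; default 8 equal steps over the
#'   0-980 µmol/L standard series.
#' @param noise_sd additive Gaussian noise on the signal.
#' @param seed optional integer seed.
#' @return data frame with columns `conc_uM`, `signal`.
#' @export
generate_calibration <- function(slope = 0.01, intercept = 0,
                                 conc_uM = seq(0, 980, length.out = 8),
                                 noise_sd = 0, seed = NULL) {
  check_scalar(slope, "slope", min = 0, strict_min = TRUE)
  check_scalar(noise_sd, "noise_sd", min = 0)
  check_numeric_vec(conc_uM, "conc_uM", min = 0, min_len = 3L)
  signal <- slope * conc_uM + intercept
  if (noise_sd > 0) {
    signal <- signal + with_seed(seed, rnorm(length(signal), sd = noise_sd))
  }
  data.frame(conc_uM = conc_uM, signal = signal)
}

#' Generate a full LET budget scan with hypoxic and depth companions
#'
#' Emulates the qualitative structure of the measured budget: per-Gy yields
#' decreasing with LET, hypoxic total oxidation on a line through the knot
#' `(plateau_onset, plateau_level)` below the onset and flat above it, and a
#' toy monotone depth-to-LET map whose Bragg-like dose-rate profile peaks in
#' the 146-148 mm window. The depth map is a stand-in for the beam-transport
#' table the analysis treats as an external input; it is synthetic by
#' construction and suitable only for exercising the pipeline.
#'
#' @param let_grid LETs of the simulated beam conditions, keV/µm.
#' @param plateau_level,plateau_onset knot of the hydroxyl contribution
#'   curve (µmol/L/Gy, keV/µm).
#' @param hypoxic_slope slope of the hypoxic total-oxidation line below the
#'   onset, µmol/L/Gy per keV/µm.
#' @param depth_mm depth grid, mm water-equivalent.
#' @param noise_sd additive Gaussian noise on every generated yield.
#' @param seed optional integer seed.
#' @return list with elements `budget` (per-LET yields), `hypoxic`
#'   (`let_keV_um`, `total_oxidation`) and `depth` (`depth_mm`,
#'   `let_keV_um`, `dose_rate_Gy_min`).
#' @export
generate_budget_scan <- function(let_grid = c(20, 40, 60, 80, 100, 160),
                                 plateau_level = 0.35, plateau_onset = 70,
                                 hypoxic_slope = 0.002,
                                 depth_mm = seq(2, 150, by = 2),
                                 noise_sd = 0, seed = NULL) {
  check_numeric_vec(let_grid, "let_grid", min = 0, strict_min = TRUE,
                    min_len = 2L)
  check_scalar(noise_sd, "noise_sd", min = 0)
  with_seed(seed, {
    jitter <- function(n) if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
    n <- length(let_grid)
    budget <- data.frame(
      let_keV_um = let_grid,
      total_oh = pmax(0.35 - 4e-4 * let_grid + jitter(n), 0),
      sparse_oh = pmax(0.17 - 5e-4 * let_grid + jitter(n), 0),
      h2o2 = pmax(0.22 - 4e-4 * let_grid + jitter(n), 0),
      o2_consumption = pmax(0.45 - 2.5e-3 * let_grid + jitter(n), 0.01),
      total_oxidation = pmax(1.6 * exp(-let_grid / 40) + 0.3 + jitter(n), 0))
    hyp_let <- sort(unique(c(let_grid, 13, 30, 55)))
    hypoxic <- data.frame(
      let_keV_um = hyp_let,
      total_oxidation = pmax(
        ifelse(hyp_let < plateau_onset,
               plateau_level + hypoxic_slope * (hyp_let - plateau_onset),
               plateau_level) + jitter(length(hyp_let)), 0))
    # toy monotone depth -> LET map with a Bragg-like dose-rate peak at 147 mm
    let_at_depth <- pmin(13 + 177 * (depth_mm / 148)^6, 190)
    dose_rate <- 3 + 0.05 * depth_mm + 20 * exp(-((depth_mm - 147) / 5)^2)
    depth <- data.frame(depth_mm = depth_mm, let_keV_um = let_at_depth,
                        dose_rate_Gy_min = dose_rate)
    list(budget = budget, hypoxic = hypoxic, depth = depth)
  })
}
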