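# Per-condition ROS budget across LET.
#
# Every yield is expressed per unit absorbed dose (µmol/L/Gy, a G-value-like
# radiation-chemical yield). The budget table collects, per irradiation
# condition (X-ray or carbon beam at a given LET): total and sparse hydroxyl
# radical generation, sparse density and local concentration, H2O2
# generation, O2 consumption, their ratio, and total oxidation. Total
# oxidation splits into a hydroxyl-radical contribution (constant
# 0.35 µmol/L/Gy above 70 keV/µm, a fitted sloped line below) and a
# hydroperoxyl-radical remainder.

.budget_columns <- c(
  "condition", "let_keV_um",
  "total_oh", "total_oh_sd", "sparse_oh", "sparse_oh_sd",
  "sparse_density", "sparse_density_sd", "sparse_conc_mM", "sparse_conc_sd",
  "h2o2", "h2o2_sd", "o2_consumption", "o2_consumption_sd",
  "ratio_h2o2_o2", "total_oxidation", "total_oxidation_sd")

#' Load the bundled six-condition ROS budget table
#'
#' Returns the reference breakdown of ROS generation by X-ray and carbon-ion
#' beam irradiation (X-ray plus carbon at 20, 40, 60, 80 and >100 keV/µm):
#' per-Gy total and sparse hydroxyl-radical generation, sparse density and
#' concentration, H2O2 generation, O2 consumption, their ratio, and total
#' oxidation, each with its reported spread. The fixture is validated on
#' load: 6 rows, the full column set, non-negative yields, and the stored
#' ratio row must equal `h2o2 / o2_consumption` to the printed 2 decimals —
#' any mismatch raises a fixture-integrity error.
#'
#' @param path fixture path; defaults to the copy shipped with the package.
#' @return a `ros_budget` data frame with one row per condition.
#' @export
load_table1 <- function(path = system.file("extdata", "table1_ros_budget.csv",
                                           package = "rostrack")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop_rostrack("budget fixture not found", class = "rostrack_fixture_error")
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.budget_columns, names(tab))
  if (nrow(tab) != 6L || length(missing_cols) > 0L) {
    stop_rostrack(sprintf(
      "budget fixture integrity check failed (rows = %d, missing columns: %s)",
      nrow(tab), paste(missing_cols, collapse = ", ")),
      class = "rostrack_fixture_error")
  }
  yields <- c("total_oh", "sparse_oh", "h2o2", "o2_consumption",
              "total_oxidation", "sparse_density", "sparse_conc_mM")
  if (any(as.matrix(tab[yields]) < 0)) {
    stop_rostrack("budget fixture integrity check failed (negative yields)",
                  class = "rostrack_fixture_error")
  }
  recomputed <- round(tab$h2o2 / tab$o2_consumption, 2L)
  if (any(abs(recomputed - tab$ratio_h2o2_o2) > 1e-9)) {
    stop_rostrack(
      "budget fixture integrity check failed (stored ratio row does not match h2o2/o2)",
      class = "rostrack_fixture_error")
  }
  structure(tab, class = c("ros_budget", "data.frame"))
}

#' Normalize an amount by absorbed dose
#'
#' A yield of 6.1 µmol/L at 32 Gy is 0.19 µmol/L/Gy when rounded to the
#' 2-decimal display convention; the returned value carries full precision —
#' rounding is for display only (see [display_round()]).
#'
#' @param amount_uM amount(s) in µmol/L.
#' @param dose_Gy absorbed dose in Gy (> 0).
#' @return yield(s) in µmol/L/Gy.
#' @export
per_gray <- function(amount_uM, dose_Gy) {
  check_numeric_vec(amount_uM, "amount_uM", min = 0)
  check_scalar(dose_Gy, "dose_Gy", min = 0, strict_min = TRUE)
  amount_uM / dose_Gy
}

#' Round for display following the 2-decimal convention
#'
#' Per-Gy yields and ratios are conventionally printed with 2 decimals;
#' internal computation always keeps full precision.
#'
#' @param x numeric.
#' @param digits decimals (default 2).
#' @export
display_round <- function(x, digits = 2L) round(x, digits)

#' Ratio of H2O2 generation to O2 consumption
#'
#' Dimensionless since both are per-Gy yields. A non-positive O2 consumption
#' makes the ratio undefined: in batch use this yields `NA` with a warning
#' rather than an error (O2-consumption measurements carry large
#' uncertainty); negative inputs are rejected outright.
#'
#' @param h2o2 H2O2 yield(s), µmol/L/Gy.
#' @param o2_consumption O2 consumption yield(s), µmol/L/Gy.
#' @return ratio(s), full precision.
#' @export
h2o2_o2_ratio <- function(h2o2, o2_consumption) {
  check_numeric_vec(h2o2, "h2o2", min = 0)
  check_numeric_vec(o2_consumption, "o2_consumption", min = 0)
  ratio <- h2o2 / o2_consumption
  undefined <- o2_consumption <= 0
  if (any(undefined)) {
    warn_rostrack("ratio undefined where O2 consumption is 0; returning NA")
    ratio[undefined] <- NA_real_
  }
  ratio
}

#' Mean and sample SD over the carbon-beam conditions
#'
#' Aggregates one budget field over the carbon rows only (the X-ray row is
#' excluded), using the arithmetic mean and the sample (n-1) standard
#' deviation.
#'
#' @param budget a `ros_budget` (or compatible data frame with `condition`).
#' @param field name of a numeric column, e.g. `"total_oh"`.
#' @return named numeric `c(mean = , sd = )`.
#' @export
aggregate_carbon <- function(budget, field) {
  if (!is.data.frame(budget) || is.null(budget$condition)) {
    stop_domain("`budget` must be a data frame with a `condition` column")
  }
  if (!field %in% names(budget)) {
    stop_domain(sprintf("unknown budget field '%s'", field))
  }
  carbon <- budget[!grepl("^x[- ]?ray$", budget$condition, ignore.case = TRUE), ]
  if (nrow(carbon) < 2L) stop_domain("need at least 2 carbon-beam rows")
  x <- carbon[[field]]
  check_numeric_vec(x, field, min_len = 2L)
  c(mean = mean(x), sd = sd(x))
}

#' Hydroxyl-radical contribution to total oxidation as a function of LET
#'
#' Above the onset LET the contribution is a constant plateau
#' (0.35 µmol/L/Gy at and above 70 keV/µm by default). Below the onset it is
#' a least-squares line through the hypoxic total-oxidation points,
#' constrained to pass through the knot `(plateau_onset, plateau_level)` so
#' the curve is continuous. With no hypoxic data below the onset the
#' constant is used throughout, with a warning.
#'
#' @param hypoxic data frame with columns `let_keV_um` and `total_oxidation`
#'   (per-Gy totals measured under hypoxia), or `NULL` for the plateau-only
#'   curve.
#' @param plateau_level plateau contribution, µmol/L/Gy.
#' @param plateau_onset LET knot, keV/µm.
#' @return an `oh_curve`: a vectorized function of LET returning µmol/L/Gy,
#'   with the fitted below-onset `slope` as an attribute. `NA` LET values
#'   (conditions without a single defined LET, e.g. X-ray) evaluate to the
#'   plateau level.
#' @export
oh_contribution_curve <- function(hypoxic = NULL, plateau_level = 0.35,
                                  plateau_onset = 70) {
  check_scalar(plateau_level, "plateau_level", min = 0)
  check_scalar(plateau_onset, "plateau_onset", min = 0, strict_min = TRUE)
  slope <- 0
  if (is.null(hypoxic) || nrow(hypoxic) == 0L) {
    warn_rostrack("no hypoxic data below the onset; using the constant plateau throughout")
  } else {
    if (is.null(hypoxic$let_keV_um) || is.null(hypoxic$total_oxidation)) {
      stop_domain("`hypoxic` needs columns let_keV_um and total_oxidation")
    }
    below <- hypoxic$let_keV_um < plateau_onset
    if (!any(below)) {
      warn_rostrack("no hypoxic data below the onset; using the constant plateau throughout")
    } else {
      x <- hypoxic$let_keV_um[below] - plateau_onset
      y <- hypoxic$total_oxidation[below] - plateau_level
      slope <- sum(x * y) / sum(x * x)  # origin-constrained at the knot
    }
  }
  f <- function(let) {
    out <- rep.int(plateau_level, length(let))
    low <- !is.na(let) & let < plateau_onset
    out[low] <- plateau_level + slope * (let[low] - plateau_onset)
    pmax(out, 0)
  }
  structure(f, class = c("oh_curve", "function"),
            slope = slope, plateau_level = plateau_level,
            plateau_onset = plateau_onset)
}

#' Partition total oxidation into hydroxyl and hydroperoxyl contributions
#'
#' For each condition, the hydroxyl contribution is read off `oh_curve` at
#' the condition's LET and the remainder is attributed to the hydroperoxyl
#' radical: `ho2 = total - oh`. If the curve exceeds the measured total the
#' hydroxyl contribution is clamped to the total (with a warning) so the sum
#' identity `oh + ho2 = total` holds exactly in the returned table.
#'
#' @param total_oxidation total oxidation yield(s), µmol/L/Gy.
#' @param let_keV_um LET(s); `NA` uses the plateau contribution.
#' @param oh_curve an [oh_contribution_curve()].
#' @return data frame with columns `let_keV_um`, `total`, `oh_contribution`,
#'   `ho2_contribution`, `clamped`.
#' @export
partition_oxidation <- function(total_oxidation, let_keV_um, oh_curve) {
  check_numeric_vec(total_oxidation, "total_oxidation", min = 0)
  if (!inherits(oh_curve, "oh_curve")) {
    stop_domain("`oh_curve` must come from oh_contribution_curve()")
  }
  if (length(let_keV_um) != length(total_oxidation)) {
    stop_domain("`total_oxidation` and `let_keV_um` must have the same length")
  }
  oh <- oh_curve(let_keV_um)
  clamped <- oh > total_oxidation
  if (any(clamped)) {
    warn_rostrack("hydroxyl contribution exceeds total oxidation; clamped to the total")
    oh[clamped] <- total_oxidation[clamped]
  }
  data.frame(let_keV_um = let_keV_um, total = total_oxidation,
             oh_contribution = oh,
             ho2_contribution = total_oxidation - oh,
             clamped = clamped)
}
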