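# Three-phase titration analysis of DMPO-OH vs DMPO density.
#
# A dilution series of the spin trap is irradiated at a fixed dose and the
# adduct (DMPO-OH) concentration is plotted against the trap's linear
# density. The curve shows three phases:
#   1. linear through the origin  — traps undersample the sparse radicals;
#   2. plateau-like               — sparse radicals saturated;
#   3. linear through the origin  — dense (track-core) radicals being sampled.
# The phase-1/phase-2 intersection gives the density and amount of sparse
# hydroxyl-radical generation; the phase-3 line evaluated at a reference
# density of 1,000 µm^-1 gives total generation.

#' Construct a titration curve
#'
#' @param dmpo_mM DMPO concentrations in mmol/L (at least 6, distinct).
#' @param dmpoh_uM measured DMPO-OH concentrations in µmol/L (same length,
#'   non-negative).
#' @param dose_Gy absorbed dose in Gy (> 0).
#' @param modality `"xray"` or `"carbon"`.
#' @param let_keV_um LET in keV/µm for carbon beams; `NULL` for X-rays.
#' @return a `titration_curve`: a data frame with columns `dmpo_mM`,
#'   `dmpoh_uM`, sorted by increasing DMPO concentration, carrying dose and
#'   beam metadata as attributes. Row order of the inputs is irrelevant.
#' @export
titration_curve <- function(dmpo_mM, dmpoh_uM, dose_Gy,
                            modality = c("xray", "carbon"),
                            let_keV_um = NULL) {
  modality <- match.arg(modality)
  check_numeric_vec(dmpo_mM, "dmpo_mM", min = 0, strict_min = TRUE, min_len = 6L)
  check_numeric_vec(dmpoh_uM, "dmpoh_uM", min = 0, min_len = 6L)
  if (length(dmpo_mM) != length(dmpoh_uM)) {
    stop_domain("`dmpo_mM` and `dmpoh_uM` must have the same length")
  }
  check_scalar(dose_Gy, "dose_Gy", min = 0, strict_min = TRUE)
  if (!is.null(let_keV_um)) check_scalar(let_keV_um, "let_keV_um", min = 0)
  ord <- order(dmpo_mM)
  dmpo_mM <- dmpo_mM[ord]
  dmpoh_uM <- dmpoh_uM[ord]
  if (any(diff(dmpo_mM) <= 0)) {
    stop_domain("DMPO concentrations must be distinct (strictly increasing after sorting)")
  }
  structure(
    data.frame(dmpo_mM = dmpo_mM, dmpoh_uM = dmpoh_uM),
    dose_Gy = dose_Gy, modality = modality, let_keV_um = let_keV_um,
    class = c("titration_curve", "data.frame")
  )
}

#' @export
print.titration_curve <- function(x, ...) {
  let <- attr(x, "let_keV_um")
  cat(sprintf("<titration_curve> %d points, %g Gy, %s%s\n",
              nrow(x), attr(x, "dose_Gy"), attr(x, "modality"),
              if (is.null(let)) "" else sprintf(" (%g keV/um)", let)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Replace the concentration axis by the linear-density axis
#'
#' Adds a `density_per_um` column computed with the cube-root rule; the
#' original DMPO concentrations and the point order are preserved.
#'
#' @param curve a [titration_curve()].
#' @return the curve with a `density_per_um` column.
#' @export
to_density_axis <- function(curve) {
  if (!inherits(curve, "titration_curve")) {
    stop_domain("`curve` must be a titration_curve")
  }
  curve$density_per_um <- concentration_to_linear_density(curve$dmpo_mM, "mmol/L")
  curve
}

# Origin-constrained least squares: slope = sum(xy)/sum(x^2).
fit_through_origin <- function(x, y) {
  s <- sum(x * y) / sum(x * x)
  list(slope = s, sse = sum((y - s * x)^2))
}

# Free-intercept OLS via lm.fit; returns intercept a, slope b, sse.
fit_free_line <- function(x, y) {
  f <- lm.fit(cbind(1, x), y)
  list(a = unname(f$coefficients[1L]), b = unname(f$coefficients[2L]),
       sse = sum(f$residuals^2))
}

#' Fit the three phase lines for a given assignment
#'
#' Phase 1 and phase 3 are least-squares lines constrained through the origin
#' (slope `sum(xy)/sum(x^2)`), as the first and third phases of the titration
#' profile are linear through the origin by construction. Phase 2 is an
#' ordinary least-squares line with free intercept (a "plateau-like" phase
#' need not be exactly flat); `plateau_flat = TRUE` forces a horizontal
#' plateau. Negative phase-1/phase-3 slopes are clamped to zero with a
#' warning (noise at low signal), and the clamped line's residuals enter the
#' total SSE.
#'
#' @param curve a [titration_curve()] (densities computed if absent).
#' @param assignment integer vector of phase labels (1, 2, 3), one per point,
#'   non-decreasing in density order, each phase holding at least 2 points.
#' @param plateau_flat force the phase-2 slope to zero.
#' @return a `phase_model`: list with slopes `s1`, `s3`, phase-2 intercept
#'   `a2` and slope `b2`, total `sse`, the `assignment`, and the density/
#'   response vectors used.
#' @export
fit_phase_lines <- function(curve, assignment, plateau_flat = FALSE) {
  curve <- if (is.null(curve$density_per_um)) to_density_axis(curve) else curve
  x <- curve$density_per_um
  y <- curve$dmpoh_uM
  if (length(assignment) != length(x)) {
    stop_domain("`assignment` must label every point of the curve")
  }
  if (!all(assignment %in% 1:3)) stop_domain("phase labels must be 1, 2 or 3")
  if (is.unsorted(assignment)) {
    stop_domain("phase assignment must be contiguous in density order")
  }
  counts <- tabulate(assignment, nbins = 3L)
  if (any(counts < 2L)) {
    stop_domain("each phase needs at least 2 points")
  }
  p1 <- fit_through_origin(x[assignment == 1L], y[assignment == 1L])
  p3 <- fit_through_origin(x[assignment == 3L], y[assignment == 3L])
  if (plateau_flat) {
    ybar <- mean(y[assignment == 2L])
    p2 <- list(a = ybar, b = 0,
               sse = sum((y[assignment == 2L] - ybar)^2))
  } else {
    p2 <- fit_free_line(x[assignment == 2L], y[assignment == 2L])
  }
  s1 <- p1$slope
  s3 <- p3$slope
  if (s1 < 0) {
    warn_rostrack("negative phase-1 slope clamped to 0")
    s1 <- 0
    p1$sse <- sum(y[assignment == 1L]^2)
  }
  if (s3 < 0) {
    warn_rostrack("negative phase-3 slope clamped to 0")
    s3 <- 0
    p3$sse <- sum(y[assignment == 3L]^2)
  }
  structure(
    list(s1 = s1, a2 = p2$a, b2 = p2$b, s3 = s3,
         sse = p1$sse + p2$sse + p3$sse,
         assignment = as.integer(assignment),
         density_per_um = x, dmpoh_uM = y),
    class = "phase_model"
  )
}

#' @export
print.phase_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<phase_model> phases n = %s\n",
    "  phase 1: y = %.5g x (through origin)\n",
    "  phase 2: y = %.5g + %.5g x\n",
    "  phase 3: y = %.5g x (through origin)\n  SSE = %.5g\n"),
    paste(tabulate(x$assignment, 3L), collapse = "/"),
    x$s1, x$a2, x$b2, x$s3, x$sse))
  invisible(x)
}

#' Segment a titration curve into its three phases
#'
#' Exhaustively enumerates every contiguous 3-way partition of the
#' density-ordered points with at least `min_per_phase` points per phase,
#' fits the three phase lines for each, and returns the partition with the
#' smallest total sum of squared residuals among partitions admitting a
#' phase-1/phase-2 intersection (`s1 > b2`). Ties (SSE equal to within one
#' part in 1e9) are broken toward the partition with the widest phase-2
#' density span, because identifying the plateau is the purpose of the
#' analysis.
#'
#' @inheritParams fit_phase_lines
#' @param min_per_phase minimum points per phase (default 2).
#' @param phases optional manual override: integer vector of three phase
#'   sizes, e.g. `c(3, 5, 2)`, bypassing the search.
#' @return the best-fitting `phase_model`.
#' @export
segment_phases <- function(curve, min_per_phase = 2L, phases = NULL,
                           plateau_flat = FALSE) {
  curve <- if (is.null(curve$density_per_um)) to_density_axis(curve) else curve
  n <- nrow(curve)
  if (!is.null(phases)) {
    if (length(phases) != 3L || sum(phases) != n || any(phases < min_per_phase)) {
      stop_domain(sprintf(
        "`phases` must be 3 sizes summing to %d with each >= %d", n, min_per_phase))
    }
    return(fit_phase_lines(curve, rep(1:3, times = phases), plateau_flat))
  }
  m <- as.integer(min_per_phase)
  if (n < 3L * m) {
    stop_domain(sprintf("need at least %d points for 3 phases of >= %d", 3L * m, m))
  }
  x <- curve$density_per_um
  best <- NULL
  best_span <- -Inf
  for (i in m:(n - 2L * m)) {          # last index of phase 1
    for (j in (i + m):(n - m)) {       # last index of phase 2
      assignment <- rep.int(3L, n)
      assignment[seq_len(i)] <- 1L
      assignment[(i + 1L):j] <- 2L
      model <- withCallingHandlers(
        fit_phase_lines(curve, assignment, plateau_flat),
        rostrack_warning = function(w) invokeRestart("muffleWarning")
      )
      # require a genuinely steeper phase 1 (relative margin guards against
      # float noise declaring an intersection on single-line inputs)
      if (model$s1 - model$b2 <=
          1e-9 * max(abs(model$s1), abs(model$b2))) next
      span <- x[j] - x[i + 1L]
      if (is.null(best) ||
          model$sse < best$sse * (1 - 1e-9) - 1e-12 ||
          (abs(model$sse - best$sse) <= best$sse * 1e-9 + 1e-12 &&
           span > best_span)) {
        best <- model
        best_span <- span
      }
    }
  }
  if (is.null(best)) {
    stop_domain("no plateau detected: no contiguous partition has phase-1 slope above the phase-2 slope")
  }
  best
}

#' Sparse hydroxyl-radical generation from the phase-1/phase-2 intersection
#'
#' The intersection of the phase-1 line (through the origin) and the phase-2
#' line gives the density at which sparse radical generation saturates
#' (x* = a2 / (s1 - b2)) and the corresponding amount (y* = s1 x*).
#'
#' @param model a `phase_model`.
#' @return list with `sparse_density` (µm^-1) and `sparse_amount` (µmol/L).
#' @export
intersect_sparse <- function(model) {
  if (!inherits(model, "phase_model")) stop_domain("`model` must be a phase_model")
  if (model$s1 <= model$b2) {
    stop_domain("phase-1 and phase-2 lines do not intersect at positive density (s1 <= b2)")
  }
  x_star <- model$a2 / (model$s1 - model$b2)
  list(sparse_density = x_star, sparse_amount = model$s1 * x_star)
}

#' Total hydroxyl-radical generation at the reference density
#'
#' The DMPO-OH concentration read off the phase-3 line at a reference trap
#' density — 1,000 µm^-1 by convention — stands in for total generation,
#' sampling the dense track-core population.
#'
#' @param model a `phase_model`.
#' @param reference_density reference density in µm^-1 (default 1000).
#' @return total generation in µmol/L.
#' @export
total_oh <- function(model, reference_density = 1000) {
  if (!inherits(model, "phase_model")) stop_domain("`model` must be a phase_model")
  check_scalar(reference_density, "reference_density", min = 0)
  model$s3 * reference_density
}

#' Full titration analysis
#'
#' Runs the pipeline density transform -> phase segmentation -> phase-line
#' fits -> sparse intersection -> total generation, and converts the sparse
#' density back to a local concentration. If the sparse amount exceeds the
#' total (possible under noise) a warning is emitted, not an error.
#'
#' @inheritParams segment_phases
#' @param reference_density density at which the phase-3 line is read off
#'   (µm^-1).
#' @return a `sparse_dense_estimate`: list with `sparse_density` (µm^-1),
#'   `sparse_concentration_mM`, `sparse_amount_uM`, `total_amount_uM`,
#'   `dose_Gy`, per-Gy yields `sparse_per_Gy` and `total_per_Gy`, and the
#'   fitted `model`.
#' @examples
#' curve <- generate_titration() # noiseless X-ray-like defaults
#' est <- analyze_titration(curve)
#' round(est$sparse_density)     # 160 per um
#' @export
analyze_titration <- function(curve, min_per_phase = 2L, phases = NULL,
                              plateau_flat = FALSE, reference_density = 1000) {
  curve <- to_density_axis(curve)
  model <- segment_phases(curve, min_per_phase, phases, plateau_flat)
  sparse <- intersect_sparse(model)
  total <- total_oh(model, reference_density)
  if (sparse$sparse_amount > total) {
    warn_rostrack("sparse amount exceeds total generation (noise?)")
  }
  dose <- attr(curve, "dose_Gy")
  structure(
    list(sparse_density = sparse$sparse_density,
         sparse_concentration_mM =
           linear_density_to_concentration(sparse$sparse_density, "mmol/L"),
         sparse_amount_uM = sparse$sparse_amount,
         total_amount_uM = total,
         dose_Gy = dose,
         sparse_per_Gy = per_gray(sparse$sparse_amount, dose),
         total_per_Gy = per_gray(total, dose),
         modality = attr(curve, "modality"),
         let_keV_um = attr(curve, "let_keV_um"),
         model = model),
    class = "sparse_dense_estimate"
  )
}

#' @export
print.sparse_dense_estimate <- function(x, ...) {
  cat(sprintf(paste0(
    "<sparse_dense_estimate> %s%s, %g Gy\n",
    "  sparse: %.1f per um (%.2g mM), %.3g umol/L (%.2f umol/L/Gy)\n",
    "  total:  %.3g umol/L (%.2f umol/L/Gy)\n"),
    x$modality,
    if (is.null(x$let_keV_um)) "" else sprintf(" %g keV/um", x$let_keV_um),
    x$dose_Gy, x$sparse_density, x$sparse_concentration_mM,
    x$sparse_amount_uM, x$sparse_per_Gy, x$total_amount_uM, x$total_per_Gy))
  invisible(x)
}
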