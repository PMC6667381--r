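# Depth profiles: per-Gy yields -> time-standardized amounts.
#
# Per-Gy yields are LET-dependent while the dose rate varies with depth
# along the beam; standardizing by a fixed irradiation time (60 s by
# convention) makes conditions at different depths directly comparable:
# amount = yield[µmol/L/Gy] * dose_rate[Gy/min] * exposure[min].

#' Standardize a per-Gy yield by a fixed irradiation time
#'
#' @param yield_per_Gy yield(s) in µmol/L/Gy (>= 0).
#' @param dose_rate_Gy_min dose rate(s) in Gy/min (> 0).
#' @param exposure_s irradiation time in seconds (> 0, default 60).
#' @return amount(s) in µmol/L produced during the exposure.
#' @examples
#' standardize_by_time(0.33, 8.3) # 2.74 umol/L in 60 s
#' @export
standardize_by_time <- function(yield_per_Gy, dose_rate_Gy_min,
                                exposure_s = 60) {
  check_numeric_vec(yield_per_Gy, "yield_per_Gy", min = 0)
  check_numeric_vec(dose_rate_Gy_min, "dose_rate_Gy_min", min = 0,
                    strict_min = TRUE)
  check_scalar(exposure_s, "exposure_s", min = 0, strict_min = TRUE)
  yield_per_Gy * dose_rate_Gy_min * (exposure_s / 60)
}

#' Build a time-standardized depth profile
#'
#' Resolves a per-Gy yield for each scan point's LET — by linear
#' interpolation over the supplied LET grid (default) or by nearest-LET
#' lookup within a tolerance — then standardizes by the common exposure.
#' Interpolation outside the LET range of `yields` clamps to the boundary
#' value and flags the point as extrapolated (with a warning); a
#' nearest-neighbor lookup with no yield within `tol` is an error naming the
#' offending depth.
#'
#' @param points data frame with columns `depth_mm`, `let_keV_um`,
#'   `dose_rate_Gy_min`.
#' @param yields data frame with columns `let_keV_um` and `yield_per_Gy`
#'   (µmol/L/Gy), or a named numeric vector (names = LET).
#' @param exposure_s common irradiation time in seconds.
#' @param match `"interpolate"` or `"nearest"`.
#' @param tol LET tolerance for nearest matching (keV/µm).
#' @return a `depth_profile` data frame ordered by depth: `depth_mm`,
#'   `let_keV_um`, `dose_rate_Gy_min`, `quantity_uM`, `extrapolated`, with
#'   the exposure as an attribute.
#' @export
build_profile <- function(points, yields, exposure_s = 60,
                          match = c("interpolate", "nearest"), tol = 25) {
  match <- match.arg(match)
  need <- c("depth_mm", "let_keV_um", "dose_rate_Gy_min")
  if (!is.data.frame(points) || !all(need %in% names(points)) ||
      nrow(points) == 0L) {
    stop_domain("`points` must be a non-empty data frame with depth_mm, let_keV_um, dose_rate_Gy_min")
  }
  check_numeric_vec(points$depth_mm, "depth_mm", min = 0)
  check_numeric_vec(points$dose_rate_Gy_min, "dose_rate_Gy_min", min = 0,
                    strict_min = TRUE)
  if (is.numeric(yields) && !is.null(names(yields))) {
    yields <- data.frame(let_keV_um = as.numeric(names(yields)),
                         yield_per_Gy = unname(yields))
  }
  if (!is.data.frame(yields) || nrow(yields) == 0L ||
      !all(c("let_keV_um", "yield_per_Gy") %in% names(yields))) {
    stop_domain("`yields` mapping is empty or lacks let_keV_um / yield_per_Gy")
  }
  yields <- yields[order(yields$let_keV_um), ]
  let <- points$let_keV_um
  extrapolated <- rep.int(FALSE, length(let))
  if (match == "interpolate") {
    extrapolated <- let < min(yields$let_keV_um) | let > max(yields$let_keV_um)
    if (any(extrapolated)) {
      warn_rostrack(sprintf(
        "LET outside the yield grid at depth(s) %s; clamped to boundary yields",
        paste(points$depth_mm[extrapolated], collapse = ", ")))
    }
    y <- if (nrow(yields) == 1L) rep.int(yields$yield_per_Gy, length(let))
         else approx(yields$let_keV_um, yields$yield_per_Gy, xout = let,
                     rule = 2)$y
  } else {
    idx <- vapply(let, function(l) {
      d <- abs(yields$let_keV_um - l)
      i <- which.min(d)
      if (d[i] > tol) NA_integer_ else i
    }, integer(1))
    if (anyNA(idx)) {
      stop_domain(sprintf(
        "no yield within %g keV/um of the LET at depth(s) %s",
        tol, paste(points$depth_mm[is.na(idx)], collapse = ", ")))
    }
    y <- yields$yield_per_Gy[idx]
  }
  out <- data.frame(depth_mm = points$depth_mm, let_keV_um = let,
                    dose_rate_Gy_min = points$dose_rate_Gy_min,
                    quantity_uM = standardize_by_time(
                      y, points$dose_rate_Gy_min, exposure_s),
                    extrapolated = extrapolated)
  out <- out[order(out$depth_mm), ]
  rownames(out) <- NULL
  structure(out, exposure_s = exposure_s,
            class = c("depth_profile", "data.frame"))
}
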