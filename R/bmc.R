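#' Four-parameter logistic viability curve
#'
#' \code{bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - log10(ec50))))}.
#' With a positive Hill slope viability decreases with concentration.
#'
#' @param conc Concentrations (> 0).
#' @param top,bottom Upper/lower plateaus (% viability).
#' @param ec50 Half-maximal concentration.
#' @param hill Hill slope.
#' @return Predicted viability (%).
#' @export
four_pl <- function(conc, top, bottom, ec50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - log10(ec50))))
}

#' Normalize raw fluorescence to percent viability
#'
#' Subtracts the mean blank (resazurin background) fluorescence and scales
#' so the mean vehicle control is 100%.
#'
#' @param plate Data.frame with columns \code{well}, \code{concentration},
#'   \code{role} (\code{treated}/\code{vehicle_control}/\code{blank}) and
#'   \code{fluorescence}; treated wells need a numeric concentration.
#' @return Data.frame of treated wells with columns \code{concentration},
#'   \code{viability} (%), sorted by concentration.
#' @export
normalize_viability <- function(plate) {
  need <- c("role", "fluorescence")
  miss <- setdiff(need, colnames(plate))
  if (length(miss)) stop("plate table missing column(s): ", paste(miss, collapse = ", "))
  blank <- plate$fluorescence[plate$role == "blank"]
  vehicle <- plate$fluorescence[plate$role == "vehicle_control"]
  if (!length(blank) || !length(vehicle)) {
    stop("plate must contain at least one blank and one vehicle_control well")
  }
  b <- mean(blank); v <- mean(vehicle)
  if (v <= b) stop("assay failure: vehicle signal does not exceed blank")
  tr <- plate[plate$role == "treated", , drop = FALSE]
  conc <- as.numeric(tr$concentration)
  if (anyNA(conc) || any(conc <= 0)) {
    stop("treated wells need positive numeric concentrations")
  }
  out <- data.frame(concentration = conc,
                    viability = 100 * (tr$fluorescence - b) / (v - b))
  out[order(out$concentration), , drop = FALSE]
}

#' Fit a sigmoidal dose-response (4PL) curve to a viability series
#'
#' Least-squares 4PL fit on log10 concentration via Levenberg-Marquardt,
#' with the top plateau initialized at 100 and bounded in [80, 120] and the
#' bottom bounded in [0, 50]. Technical replicates at the same concentration
#' should be averaged beforehand (\code{\link{normalize_viability}} output
#' can be aggregated with \code{aggregate}). A series that never leaves the
#' top plateau is flagged degenerate and carries no EC50.
#'
#' @param curve Data.frame with columns \code{concentration},
#'   \code{viability}, >= 4 distinct concentrations.
#' @return List with \code{converged}, \code{degenerate}, \code{par}
#'   (named: top, bottom, ec50, hill; NULL if not converged) and
#'   \code{data}.
#' @export
fit_dose_response <- function(curve) {
  conc <- curve$concentration
  if (length(unique(conc)) < 4L) stop("need at least 4 concentrations")
  if (any(conc <= 0)) stop("concentrations must be positive")
  v <- curve$viability
  if (max(v) - min(v) < 5) {
    return(list(converged = FALSE, degenerate = TRUE, par = NULL, data = curve))
  }
  starts <- list(
    list(top = 100, bottom = 0, lec50 = stats::median(log10(conc)), hill = 1),
    list(top = 100, bottom = min(max(0, min(v) * 0.9), 50),
         lec50 = stats::median(log10(conc)), hill = 1.5),
    list(top = 100, bottom = 25, lec50 = mean(range(log10(conc))), hill = 2))
  fit <- NULL
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        viability ~ bottom + (top - bottom) / (1 + 10^(hill * (log10(concentration) - lec50))),
        data = curve, start = start,
        lower = c(top = 80, bottom = 0, lec50 = min(log10(conc)) - 3, hill = 0.1),
        upper = c(top = 120, bottom = 50, lec50 = max(log10(conc)) + 3, hill = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    warning("dose-response fit did not converge; replicate excluded")
    return(list(converged = FALSE, degenerate = FALSE, par = NULL, data = curve))
  }
  cf <- stats::coef(fit)
  list(converged = TRUE, degenerate = FALSE,
       par = c(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
               ec50 = 10^unname(cf["lec50"]), hill = unname(cf["hill"])),
       data = curve)
}

#' BMC10 from averaged dose-response curves
#'
#' Averages the fitted curves of the biological replicates pointwise on a
#' shared log10 grid, finds where the averaged curve crosses 90% viability,
#' and reads the benchmark concentration off as the last measured
#' concentration at or below the crossing (the "last real data point left"
#' rule); the interpolated crossing is reported alongside. If the averaged
#' curve never drops below 90% within the tested range the result is
#' "above tested range".
#'
#' @param fits List of fits from \code{\link{fit_dose_response}} (one per
#'   biological replicate); non-converged or degenerate fits are skipped.
#' @param concentrations Measured concentrations (the dilution series).
#' @param grid_points Resolution of the shared log10 grid.
#' @return List of class \code{bmc_result}: \code{bmc10} (numeric or NA),
#'   \code{above_range} (logical), \code{method} ("interpolated" when the
#'   crossing coincides with a measured point, else "last_data_point"),
#'   \code{crossing} (interpolated concentration), \code{curve}
#'   (data.frame \code{concentration}, \code{viability} of the average).
#' @export
bmc10 <- function(fits, concentrations, grid_points = 400) {
  ok <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(ok)) stop("no converged dose-response fit available")
  conc <- sort(unique(concentrations))
  grid <- 10^seq(log10(min(conc)), log10(max(conc)), length.out = grid_points)
  preds <- vapply(ok, function(f)
    four_pl(grid, f$par["top"], f$par["bottom"], f$par["ec50"], f$par["hill"]),
    numeric(length(grid)))
  avg <- rowMeans(preds)
  below <- which(avg < 90)
  if (!length(below)) {
    return(structure(list(bmc10 = NA_real_, above_range = TRUE,
                          method = NA_character_, crossing = NA_real_,
                          curve = data.frame(concentration = grid, viability = avg)),
                     class = "bmc_result"))
  }
  i <- below[1L]
  crossing <- if (i == 1L) grid[1L] else {
    # linear interpolation in log10 space between the bracketing grid points
    l0 <- log10(grid[i - 1L]); l1 <- log10(grid[i])
    v0 <- avg[i - 1L]; v1 <- avg[i]
    10^(l0 + (90 - v0) * (l1 - l0) / (v1 - v0))
  }
  # a measured point whose averaged viability sits within read-off precision
  # (0.25 percentage points) of 90% is taken as the 90% data point itself
  avg_at_meas <- vapply(ok, function(f)
    four_pl(conc, f$par["top"], f$par["bottom"], f$par["ec50"], f$par["hill"]),
    numeric(length(conc)))
  avg_at_meas <- if (is.matrix(avg_at_meas)) rowMeans(avg_at_meas) else avg_at_meas
  at_crossing <- abs(avg_at_meas - 90) <= 0.25
  eligible <- conc[conc <= crossing * (1 + 1e-5) | at_crossing]
  bmc <- if (length(eligible)) max(eligible) else min(conc)
  method <- if (any(at_crossing & conc == bmc)) "interpolated"
            else "last_data_point"
  structure(list(bmc10 = bmc, above_range = FALSE, method = method,
                 crossing = crossing,
                 curve = data.frame(concentration = grid, viability = avg)),
            class = "bmc_result")
}

#' @export
print.bmc_result <- function(x, ...) {
  if (x$above_range) cat("BMC10: above tested range\n")
  else cat(sprintf("BMC10 = %g (%s; interpolated crossing %.4g)\n",
                   x$bmc10, x$method, x$crossing))
  invisible(x)
}
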