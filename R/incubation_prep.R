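#' Incubation curve: mean cumulative mineralization with variances
#'
#' The fitting target produced by preprocessing: per observation day the
#' mean (across replicates) cumulative mineralization as a fraction of the
#' added carbon, and the total variance at that day (sample variance of
#' the replicate cumulative values, ddof = 1, plus the control-fit
#' prediction variance).
#'
#' @param times Observation days, strictly increasing, >= 0.
#' @param values Mean cumulative mineralized fraction at each day.
#'   Raw curves may dip (noise is not clipped), but values must lie in
#'   `[-0.5, 1]`; monotonicity is enforced only on model output.
#' @param variances Total variance at each day (>= 0).
#' @param n_rep Number of replicates behind each mean (used downstream to
#'   convert replicate variance into variance of the mean).
#' @param bgr_id,soil_id Optional labels carried along the pipeline.
#' @return An object of class `"incubation_curve"` (a list).
#' @export
incubation_curve <- function(times, values, variances = rep(NA_real_, length(times)),
                             n_rep = NA_integer_, bgr_id = NA_character_,
                             soil_id = NA_character_) {
  if (length(times) != length(values) || length(times) != length(variances))
    stop("times, values and variances must have equal length", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0) || any(diff(times) <= 0))
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  if (any(!is.finite(values)) || any(values > 1) || any(values < -0.5))
    stop("values must be fractions of added C (<= 1)", call. = FALSE)
  if (any(variances < 0, na.rm = TRUE))
    stop("variances must be >= 0", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 variances = as.numeric(variances), n_rep = as.integer(n_rep),
                 bgr_id = bgr_id, soil_id = soil_id),
            class = "incubation_curve")
}

#' @export
print.incubation_curve <- function(x, ...) {
  cat(sprintf("Incubation curve %s / %s: %d observations, days %g-%g, final %.4f\n",
              x$bgr_id, x$soil_id, length(x$times), min(x$times), max(x$times),
              x$values[length(x$values)]))
  invisible(x)
}

#' Least-squares polynomial fit of a control series
#'
#' Fits a polynomial of the given degree to control observations by
#' ordinary least squares and evaluates it (with prediction variance of
#' the fitted mean) at the requested days. Extrapolation beyond the
#' observed control range by more than one scheduled control interval is
#' refused.
#'
#' @param days Observed control days (>= degree + 1 distinct values).
#' @param values Control values at those days (any consistent unit).
#' @param target_days Days at which to evaluate the fit.
#' @param degree Polynomial degree (>= 1); default 3.
#' @return A data.frame with columns `day`, `fit`, `var` (variance of the
#'   fitted mean value at that day).
#' @examples
#' d <- c(2, 6, 10, 14, 18)
#' fit_control_polynomial(d, 0.001 * d^2, target_days = 8, degree = 2)
#' @export
fit_control_polynomial <- function(days, values, target_days, degree = 3) {
  if (degree < 1) stop("degree must be >= 1", call. = FALSE)
  ud <- unique(days)
  if (length(ud) < degree + 1)
    stop(sprintf("need at least %d distinct control days for degree %d",
                 degree + 1, degree), call. = FALSE)
  step <- max(diff(sort(ud)))
  lo <- min(ud) - step; hi <- max(ud) + step
  if (any(target_days < lo | target_days > hi))
    stop("target days extrapolate beyond the control range by more than one interval",
         call. = FALSE)
  df <- data.frame(day = days, y = values)
  fit <- stats::lm(y ~ poly(day, degree, raw = TRUE), data = df)
  pr <- stats::predict(fit, newdata = data.frame(day = target_days), se.fit = TRUE)
  data.frame(day = target_days, fit = unname(pr$fit), var = unname(pr$se.fit^2))
}

#' Interpolate control respiration onto a sample day grid
#'
#' Controls are measured on a sparser schedule than amended samples, so
#' the missing days are filled by a least-squares polynomial. Replicate
#' control series are averaged per day, their per-step CO2 amounts are
#' cumulated (per-step amounts on schedules with unequal step lengths are
#' not directly comparable; cumulative amounts are), the polynomial is
#' fitted to the cumulative control mean, and fitted cumulative values
#' are returned at `target_days`.
#'
#' @param controls A data.frame of raw control series with columns
#'   `replicate`, `day`, `co2` (CO2-C evolved per time step).
#' @param target_days Days to evaluate at (the sample schedule).
#' @param degree Polynomial degree; default 3.
#' @return A data.frame `day`, `fit` (cumulative control CO2), `var`.
#' @export
interpolate_control <- function(controls, target_days, degree = 3) {
  need <- c("replicate", "day", "co2")
  if (!all(need %in% names(controls)))
    stop("controls must have columns replicate, day, co2", call. = FALSE)
  if (any(!is.finite(controls$co2)))
    stop("control co2 values must be finite", call. = FALSE)
  # cumulative per replicate, then mean per day
  sp <- split(controls, controls$replicate)
  cums <- lapply(sp, function(d) {
    d <- d[order(d$day), ]
    if (any(diff(d$day) <= 0)) stop("control days must be strictly increasing per replicate",
                                    call. = FALSE)
    data.frame(day = d$day, cum = cumsum(d$co2))
  })
  all <- do.call(rbind, cums)
  mean_cum <- stats::aggregate(cum ~ day, data = all, FUN = mean)
  fit_control_polynomial(mean_cum$day, mean_cum$cum, target_days, degree = degree)
}

#' Net mineralization: sample minus control, per time step
#'
#' Subtracts the control contribution from an amended sample's per-step
#' CO2 amounts on an aligned day grid. Negative differences are retained:
#' they are honest noise, and zeroing them would bias the cumulative
#' curve upward.
#'
#' @param sample A data.frame with columns `day`, `co2` for one replicate.
#' @param control_at_days Control per-step values aligned to `sample$day`
#'   (e.g. differences of the fitted cumulative control).
#' @return Numeric vector of per-step net CO2 amounts.
#' @export
net_mineralization <- function(sample, control_at_days) {
  if (length(control_at_days) != nrow(sample))
    stop("misaligned day grids: control values must match sample rows",
         call. = FALSE)
  sample$co2 - control_at_days
}

#' Aggregate replicate net series into an incubation curve
#'
#' Per replicate, net per-step amounts are cumulated and normalized by the
#' added carbon; per observation day the replicate mean and the sample
#' variance (ddof = 1) are computed, and the control-fit prediction
#' variance (normalized the same way) is added to give the total variance.
#'
#' @param net_series A list of data.frames (`day`, `net`), one per
#'   replicate, on a common day grid.
#' @param added_carbon Added FOM carbon per jar, same unit as the CO2
#'   amounts (> 0). Use 1 if the series are already fractions of added C.
#' @param control_var Optional control-fit variance at each day (same raw
#'   unit squared); added to the replicate variance after normalization.
#' @param bgr_id,soil_id Labels for the resulting curve.
#' @return An [incubation_curve].
#' @export
aggregate_replicates <- function(net_series, added_carbon = 1,
                                 control_var = NULL,
                                 bgr_id = NA_character_, soil_id = NA_character_) {
  if (length(net_series) < 2)
    stop("variance undefined: need at least 2 replicates", call. = FALSE)
  if (!is.finite(added_carbon) || added_carbon <= 0)
    stop("added_carbon must be > 0", call. = FALSE)
  days <- net_series[[1]]$day
  for (d in net_series) if (!identical(as.numeric(d$day), as.numeric(days)))
    stop("misaligned day grids across replicates", call. = FALSE)
  cum <- sapply(net_series, function(d) cumsum(d$net) / added_carbon)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
  v <- apply(cum, 1, stats::var)
  if (!is.null(control_var)) v <- v + control_var / added_carbon^2
  incubation_curve(times = days, values = rowMeans(cum), variances = v,
                   n_rep = length(net_series), bgr_id = bgr_id, soil_id = soil_id)
}

#' Truncate an incubation curve to an observation window
#'
#' Keeps observations with `day <= max_day`. The default window of 20
#' days retains only the daily-measurement phase of the schedule.
#'
#' @param curve An [incubation_curve].
#' @param max_day Last day to keep (default 20).
#' @return The truncated [incubation_curve].
#' @export
truncate_to_window <- function(curve, max_day = 20) {
  keep <- curve$times <= max_day
  if (!any(keep)) stop("empty window: no observations at or before max_day",
                       call. = FALSE)
  incubation_curve(curve$times[keep], curve$values[keep], curve$variances[keep],
                   n_rep = curve$n_rep, bgr_id = curve$bgr_id,
                   soil_id = curve$soil_id)
}

#' Preprocess raw incubation data into per-treatment curves
#'
#' Full preprocessing pipeline for a tidy raw table: for each soil the
#' control series are polynomial-interpolated onto the sample schedule;
#' for each BGR-soil treatment the control is subtracted per time step
#' from each replicate, replicates are cumulated, normalized by the added
#' carbon and aggregated into a mean curve with total variances; the
#' curve is truncated to the daily-measurement window.
#'
#' @param raw Tidy data.frame with columns `bgr`, `soil`, `replicate`,
#'   `day`, `co2`, `is_control`. `co2` is CO2-C evolved per time step,
#'   either as a fraction of added C (`units = "fraction"`) or in mass
#'   units matching `added_carbon`.
#' @param added_carbon Added carbon per jar (1 for fractional units).
#' @param degree Control polynomial degree (default 3).
#' @param max_day Observation window (default 20); `Inf` keeps all days.
#' @param units `"fraction"` or `"mass"` (declarative; both paths divide
#'   by `added_carbon`).
#' @return A named list of [incubation_curve] objects, one per
#'   `bgr:soil` treatment.
#' @export
prepare_incubation <- function(raw, added_carbon = 1, degree = 3,
                               max_day = 20, units = c("fraction", "mass")) {
  units <- match.arg(units)
  need <- c("bgr", "soil", "replicate", "day", "co2", "is_control")
  if (!all(need %in% names(raw)))
    stop("raw table must have columns bgr, soil, replicate, day, co2, is_control",
         call. = FALSE)
  out <- list()
  for (soil in unique(raw$soil)) {
    rs <- raw[raw$soil == soil, ]
    ctrl <- rs[rs$is_control, ]
    samples <- rs[!rs$is_control, ]
    if (nrow(ctrl) == 0) stop(sprintf("no control series for soil %s", soil),
                              call. = FALSE)
    for (bgr in unique(samples$bgr)) {
      sb <- samples[samples$bgr == bgr, ]
      days <- sort(unique(sb$day))
      cfit <- interpolate_control(ctrl, target_days = days, degree = degree)
      ctrl_step <- diff(c(0, cfit$fit))      # cumulative fit -> per-step
      nets <- lapply(split(sb, sb$replicate), function(d) {
        d <- d[order(d$day), ]
        if (!identical(as.numeric(d$day), as.numeric(days)))
          stop("misaligned day grids within treatment", call. = FALSE)
        data.frame(day = days, net = net_mineralization(d, ctrl_step))
      })
      curve <- aggregate_replicates(nets, added_carbon = added_carbon,
                                    control_var = cfit$var,
                                    bgr_id = bgr, soil_id = soil)
      out[[paste(bgr, soil, sep = ":")]] <- truncate_to_window(curve, max_day)
    }
  }
  out
}

#' Write prepared curves to a tidy CSV
#'
#' @param curves A list of [incubation_curve] objects.
#' @param path Output CSV path.
#' @return The written data.frame, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cu) {
    data.frame(bgr = cu$bgr_id, soil = cu$soil_id, day = cu$times,
               mean_cum_fraction = cu$values, variance = cu$variances,
               n_rep = cu$n_rep)
  }))
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
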