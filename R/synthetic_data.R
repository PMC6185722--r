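# default observation schedule: daily for 20 days, then sparser
INCUBATION_SCHEDULE <- c(1:20, 22, 24, 27, 30, 34, 36, 41)

#' Specification of a synthetic incubation experiment
#'
#' Describes the experiment the generator emulates: one or more amended
#' treatments per soil, four replicates each, measured daily for 20 days
#' and then on days 22, 24, 27, 30, 34, 36 and 41, with unamended
#' control jars measured on a sparser schedule. The noise model attaches
#' Gaussian measurement error to each cumulative CO2 observation of each
#' replicate (independent across observation days), so the reported
#' per-step amounts are differences of noisy cumulative totals; see the
#' methods vignette for why this is the error structure the downstream
#' uncertainty analysis assumes.
#'
#' @param params A data.frame with columns `bgr`, `k`, `eta`: the true
#'   parameters per treatment.
#' @param soils A data.frame with columns `soil`, `bat_factor`.
#' @param schedule Observation days for amended jars (strictly
#'   increasing).
#' @param control_every Control jars are measured every this many days
#'   (default 4).
#' @param replicates Jars per treatment (default 4).
#' @param noise_sd Measurement noise sd per cumulative observation, as a
#'   fraction of added C (default 0.005).
#' @param control_coef Coefficients (intercept upward) of the basal
#'   respiration polynomial: cumulative control CO2 as a function of
#'   day, fraction of added C.
#' @param added_c Added FOM carbon per jar (1 = values are fractions).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(params,
                           soils = data.frame(soil = c("silty", "sandy"),
                                              bat_factor = c(1, 1)),
                           schedule = INCUBATION_SCHEDULE,
                           control_every = 4,
                           replicates = 4,
                           noise_sd = 0.005,
                           control_coef = c(0, 0.004, -4e-5),
                           added_c = 1,
                           seed = 1L) {
  if (any(diff(schedule) <= 0)) stop("schedule must be strictly increasing",
                                     call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!all(c("bgr", "k", "eta") %in% names(params)))
    stop("params needs columns bgr, k, eta", call. = FALSE)
  structure(list(params = params, soils = soils, schedule = schedule,
                 control_every = control_every, replicates = replicates,
                 noise_sd = noise_sd, control_coef = control_coef,
                 added_c = added_c, seed = as.integer(seed)),
            class = "synthetic_spec")
}

basal_cumulative <- function(day, coef) {
  drop(outer(day, seq_along(coef) - 1, `^`) %*% coef)
}

#' Generate a synthetic incubation dataset
#'
#' Produces a tidy raw table in the format [prepare_incubation] ingests.
#' Per replicate jar, the true cumulative CO2 curve (forward model for
#' amended jars, plus the basal control polynomial for all jars) receives
#' iid Gaussian noise at every observation day; the emitted `co2` column
#' holds the per-step differences of that noisy cumulative series.
#' Controls are measured every `control_every` days only.
#'
#' @param spec A [synthetic_spec].
#' @return A data.frame `bgr, soil, replicate, day, co2, is_control`,
#'   deterministic under `spec$seed`.
#' @export
generate_incubation <- function(spec) {
  set.seed(spec$seed)
  sched <- spec$schedule
  ctrl_days <- seq(spec$control_every, max(sched) - 1, by = spec$control_every)
  rows <- list()
  emit <- function(bgr, soil, rep, days, true_cum, is_control) {
    noisy <- true_cum + stats::rnorm(length(days), 0, spec$noise_sd) *
      spec$added_c
    data.frame(bgr = bgr, soil = soil, replicate = rep, day = days,
               co2 = diff(c(0, noisy)), is_control = is_control)
  }
  for (si in seq_len(nrow(spec$soils))) {
    soil <- spec$soils$soil[si]
    sc <- soil_context(soil, spec$soils$bat_factor[si])
    basal_s <- basal_cumulative(sched, spec$control_coef) * spec$added_c
    basal_c <- basal_cumulative(ctrl_days, spec$control_coef) * spec$added_c
    for (pi in seq_len(nrow(spec$params))) {
      p <- turnover_params(spec$params$k[pi], spec$params$eta[pi])
      model_cum <- cumulative_mineralization(p, sched, sc) * spec$added_c
      for (r in seq_len(spec$replicates)) {
        rows[[length(rows) + 1L]] <-
          emit(spec$params$bgr[pi], soil, r, sched, model_cum + basal_s, FALSE)
      }
    }
    for (r in seq_len(spec$replicates)) {
      rows[[length(rows) + 1L]] <-
        emit("control", soil, r, ctrl_days, basal_c, TRUE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic digestate panel with known regression structure
#'
#' Draws digestate chemical properties uniformly within plausible ranges
#' and generates true turnover parameters from the stated linear
#' relations (`k` on pH, `eta` on C_t/N_org) plus Gaussian residuals, so
#' the regression stage can be validated against known truth. The
#' internally consistent chemistry is constructed from `ct`, `ct_norg`
#' and `nh4n`: `norg = ct / ct_norg`, `nt = norg + nh4n`.
#'
#' @param n Number of digestates.
#' @param property_ranges Named list of `c(min, max)` ranges for `ph`,
#'   `ct_norg`, `ct`, `nh4n`, `dm`, `dm_org`. The default pH range
#'   (7.2-8.3) spans the study panel and keeps the generating relation
#'   for k positive; pass a wider range (the literature spans up to pH
#'   9.3) at your own risk of clipping.
#' @param regression_truth List with `k = c(intercept, slope)` on pH and
#'   `eta = c(intercept, slope)` on C_t/N_org.
#' @param residual_sd Named vector `c(k = ..., eta = ...)` of residual
#'   sds around the generating relations.
#' @param seed Integer seed.
#' @return A list: `props` (data.frame with full chemistry incl. derived
#'   ratios) and `params` (data.frame `bgr`, `k`, `eta`).
#' @export
generate_bgr_panel <- function(n = 6,
                               property_ranges = list(
                                 ph = c(7.2, 8.3), ct_norg = c(5.9, 26.4),
                                 ct = c(38, 44), nh4n = c(2, 5.5),
                                 dm = c(5, 10), dm_org = c(27, 35)),
                               regression_truth = list(
                                 k = c(intercept = 5.996, slope = -0.710),
                                 eta = c(intercept = 1.016, slope = -0.013)),
                               residual_sd = c(k = 0.04, eta = 0.02),
                               seed = 1L) {
  set.seed(as.integer(seed))
  rng <- function(name) {
    r <- property_ranges[[name]]
    if (is.null(r) || r[2] < r[1]) stop(sprintf("bad range for %s", name),
                                        call. = FALSE)
    stats::runif(n, r[1], r[2])
  }
  ph <- rng("ph"); ct_norg <- rng("ct_norg"); ct <- rng("ct")
  nh4n <- rng("nh4n")
  norg <- ct / ct_norg
  props <- data.frame(bgr = sprintf("S%02d", seq_len(n)),
                      dm = rng("dm"), dm_org = rng("dm_org"), ph = ph,
                      ct = ct, nh4n = nh4n, nt = norg + nh4n)
  props <- derive_ratios(props)
  k <- regression_truth$k[["intercept"]] +
    regression_truth$k[["slope"]] * ph +
    stats::rnorm(n, 0, residual_sd[["k"]])
  eta <- regression_truth$eta[["intercept"]] +
    regression_truth$eta[["slope"]] * ct_norg +
    stats::rnorm(n, 0, residual_sd[["eta"]])
  if (any(k <= 0))
    stop("generated k <= 0; narrow the pH range or the residual sd",
         call. = FALSE)
  params <- data.frame(bgr = props$bgr, k = k, eta = pmin(pmax(eta, 0), 1))
  list(props = props, params = params)
}
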