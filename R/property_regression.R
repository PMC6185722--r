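# Canonical property order used for screening and tie-breaking (the
# order of the published property table).
BGR_PROPERTIES <- c("dm", "dm_org", "ct", "nh4n", "norg", "nt",
                    "ct_nt", "ct_norg", "ph")

#' Derive chemical ratios for a BGR property table
#'
#' Completes a digestate chemistry table with the derived quantities used
#' as regression predictors: organic nitrogen `norg = nt - nh4n`, and the
#' ratios `ct_nt = ct/nt` and `ct_norg = ct/norg`.
#'
#' @param props A data.frame with at least columns `ct`, `nt`, `nh4n`
#'   (percent of dry matter), typically also `bgr`, `dm`, `dm_org`, `ph`.
#' @return The data.frame with columns `norg`, `ct_nt`, `ct_norg` added
#'   (overwritten if present).
#' @export
derive_ratios <- function(props) {
  need <- c("ct", "nt", "nh4n")
  if (!all(need %in% names(props)))
    stop("props must contain ct, nt and nh4n", call. = FALSE)
  if (any(props$ct < 0 | props$nt < 0 | props$nh4n < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  if ("ph" %in% names(props) && any(props$ph <= 0 | props$ph >= 14))
    stop("ph must lie in (0, 14)", call. = FALSE)
  norg <- props$nt - props$nh4n
  if (any(norg <= 0))
    stop("invalid chemistry: nt must exceed nh4n (norg <= 0)", call. = FALSE)
  props$norg <- norg
  props$ct_nt <- props$ct / props$nt
  props$ct_norg <- props$ct / norg
  props
}

#' Simple linear regression of a parameter on one property
#'
#' Ordinary least squares fit of `y = m x + n` with the coefficient of
#' determination and a two-sided t-test p-value for the slope.
#'
#' @param x Predictor values (not constant).
#' @param y Response values, same length (>= 3).
#' @param predictor_name Label stored with the result.
#' @return An object of class `"bgr_regression"`: `predictor`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n_points`, plus the summaries
#'   needed for prediction intervals (`x_mean`, `sxx`, `sigma2`,
#'   `x_range`).
#' @export
fit_simple_regression <- function(x, y, predictor_name = "x") {
  if (length(x) != length(y) || length(x) < 3)
    stop("need >= 3 paired points", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("singular design: predictor is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    # exact fits are expected for synthetic round trips
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  structure(list(predictor = predictor_name,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n_points = length(x),
                 x_mean = mean(x),
                 sxx = sum((x - mean(x))^2),
                 sigma2 = sm$sigma^2,
                 x_range = range(x)),
            class = "bgr_regression")
}

#' @export
print.bgr_regression <- function(x, ...) {
  cat(sprintf("y = %.4g * %s + %.4g   (R2 = %.3f, p = %.3g, n = %d)\n",
              x$slope, x$predictor, x$intercept, x$r_squared, x$p_value,
              x$n_points))
  invisible(x)
}

#' Screen single-property predictors of the turnover parameters
#'
#' Regresses each turnover parameter (`k` and `eta`) on each chemical
#' property in the canonical order (DM, DM_org, C_t, NH4-N, N_org, N_t,
#' C_t/N_t, C_t/N_org, pH) and ranks the fits by R-squared.
#'
#' @param props A property table; [derive_ratios] is applied if the
#'   derived columns are missing.
#' @param params A data.frame with columns `bgr`, `k`, `eta` aligned to
#'   `props$bgr` (merged by `bgr` when both have it, else by row order).
#' @param properties Character vector of predictor columns to screen.
#' @return A data.frame (`parameter`, `predictor`, `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n_points`) sorted within parameter by
#'   decreasing R-squared; ties keep the canonical property order.
#' @export
screen_predictors <- function(props, params, properties = BGR_PROPERTIES) {
  if (!all(c("ct_norg", "norg", "ct_nt") %in% names(props)))
    props <- derive_ratios(props)
  missing <- setdiff(properties, names(props))
  if (length(missing))
    stop(sprintf("missing property column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if ("bgr" %in% names(props) && "bgr" %in% names(params)) {
    merged <- merge(props, params[, c("bgr", "k", "eta")], by = "bgr",
                    sort = FALSE)
  } else {
    if (nrow(props) != nrow(params))
      stop("props and params must align", call. = FALSE)
    merged <- cbind(props, params[, c("k", "eta")])
  }
  if (nrow(merged) < 3)
    stop("need >= 3 BGRs with complete chemistry and parameters",
         call. = FALSE)
  rows <- list()
  for (param in c("k", "eta")) {
    for (prop in properties) {
      r <- fit_simple_regression(merged[[prop]], merged[[param]], prop)
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = param, predictor = prop, slope = r$slope,
                   intercept = r$intercept, r_squared = r$r_squared,
                   p_value = r$p_value, n_points = r$n_points)
    }
  }
  out <- do.call(rbind, rows)
  # stable sort: canonical order preserved among R2 ties
  out <- out[order(match(out$parameter, c("k", "eta")), -out$r_squared), ]
  rownames(out) <- NULL
  out
}

#' Select the pedotransfer model per parameter
#'
#' Picks the highest-R-squared single predictor for each parameter (ties
#' go to the predictor earlier in the canonical order). A multiple
#' regression combining the per-parameter top predictors is only offered
#' when all pairwise predictor correlations satisfy `|r| < threshold`;
#' otherwise it is refused and the offending correlations are reported.
#'
#' @param screen Output of [screen_predictors].
#' @param props The property table the screen was computed on (used for
#'   predictor correlations and for refitting the chosen models).
#' @param params The parameter table (`bgr`, `k`, `eta`).
#' @param collinearity_threshold Maximum tolerated absolute pairwise
#'   predictor correlation (default 0.4).
#' @return A list: `k_model` and `eta_model` ([fit_simple_regression]
#'   objects), `multiple_allowed` (logical), `collinearity` (data.frame
#'   of offending predictor pairs and their `r`, empty when allowed).
#' @export
select_model <- function(screen, props, params, collinearity_threshold = 0.4) {
  if (!all(c("ct_norg", "norg", "ct_nt") %in% names(props)))
    props <- derive_ratios(props)
  if ("bgr" %in% names(props) && "bgr" %in% names(params)) {
    merged <- merge(props, params[, c("bgr", "k", "eta")], by = "bgr",
                    sort = FALSE)
  } else merged <- cbind(props, params[, c("k", "eta")])
  top <- function(param) {
    s <- screen[screen$parameter == param, ]
    s$predictor[which.max(s$r_squared)]  # screen is sorted; first max wins
  }
  best <- c(k = top("k"), eta = top("eta"))
  models <- lapply(c(k = "k", eta = "eta"), function(param) {
    fit_simple_regression(merged[[best[[param]]]], merged[[param]],
                          best[[param]])
  })
  cand <- unique(unname(best))
  offending <- data.frame(predictor_1 = character(), predictor_2 = character(),
                          r = numeric())
  if (length(cand) > 1) {
    for (i in seq_len(length(cand) - 1)) for (j in seq(i + 1, length(cand))) {
      r <- stats::cor(merged[[cand[i]]], merged[[cand[j]]])
      if (abs(r) >= collinearity_threshold)
        offending <- rbind(offending,
                           data.frame(predictor_1 = cand[i],
                                      predictor_2 = cand[j], r = r))
    }
  }
  list(k_model = models$k, eta_model = models$eta,
       multiple_allowed = length(cand) > 1 && nrow(offending) == 0,
       collinearity = offending)
}

#' Predict turnover parameters from chemical properties
#'
#' Evaluates the fitted pedotransfer equations for new digestates:
#' `k* = m x + n` from the k-model's predictor, `eta*` likewise. The
#' prediction standard error uses the OLS prediction-interval formula
#' `s * sqrt(1 + 1/n + (x - xbar)^2 / Sxx)`. `eta*` is clamped to
#' `[0, 1]` and `k*` floored at `k_min`; predictors outside the
#' calibration range are flagged as extrapolation (not an error).
#'
#' @param props New property table; [derive_ratios] applied if needed.
#' @param k_model,eta_model Fitted [fit_simple_regression] objects (e.g.
#'   from [select_model]).
#' @param k_min Lower floor on predicted k (default 0.01 per BAT-day).
#' @return A data.frame: `bgr` (if present), `k_star`, `sd_k_star`,
#'   `eta_star`, `sd_eta_star`, `extrapolation` (logical).
#' @export
predict_parameters <- function(props, k_model, eta_model, k_min = 0.01) {
  if (!all(c("ct_norg", "norg", "ct_nt") %in% names(props)) &&
      all(c("ct", "nt", "nh4n") %in% names(props)))
    props <- derive_ratios(props)
  pred_one <- function(model, x) {
    se <- sqrt(model$sigma2 *
                 (1 + 1 / model$n_points + (x - model$x_mean)^2 / model$sxx))
    list(fit = model$slope * x + model$intercept, se = se,
         extra = x < model$x_range[1] | x > model$x_range[2])
  }
  xk <- props[[k_model$predictor]]
  xe <- props[[eta_model$predictor]]
  if (is.null(xk) || is.null(xe))
    stop("props lacks the model predictor column(s)", call. = FALSE)
  pk <- pred_one(k_model, xk)
  pe <- pred_one(eta_model, xe)
  out <- data.frame(k_star = pmax(pk$fit, k_min), sd_k_star = pk$se,
                    eta_star = pmin(pmax(pe$fit, 0), 1), sd_eta_star = pe$se,
                    extrapolation = pk$extra | pe$extra)
  if ("bgr" %in% names(props)) out <- cbind(bgr = props$bgr, out)
  out
}

#' Range coverage of the study panel against a literature range
#'
#' Fraction of a literature reference range spanned by the study's
#' values: `(max(study) - min(study)) / (ref_max - ref_min)`, as percent.
#'
#' @param study_values Non-empty numeric vector.
#' @param reference_min,reference_max Bounds of the reference range
#'   (`reference_max > reference_min`).
#' @return Coverage in percent.
#' @export
range_coverage <- function(study_values, reference_min, reference_max) {
  if (length(study_values) == 0)
    stop("study values must be non-empty", call. = FALSE)
  if (!(reference_max > reference_min))
    stop("zero or inverted reference range", call. = FALSE)
  100 * (max(study_values) - min(study_values)) /
    (reference_max - reference_min)
}
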