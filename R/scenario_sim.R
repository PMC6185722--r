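#' Site configuration for the long-term scenario
#'
#' Climate, texture and soil state of the simulated site. The defaults
#' describe a loess Chernozem site in Central Germany. Site conditions
#' enter the carbon model only through `bat_year`, the effective
#' Biological Active Time per calendar year (BAT-days yr^-1); all pool
#' rates are expressed per BAT-day.
#'
#' @param mat Mean annual temperature, degrees C.
#' @param map Mean annual precipitation, mm.
#' @param clay,silt,sand Texture fractions (must sum to 1 within 0.01).
#' @param depth Topsoil depth, m.
#' @param bulk_density Bulk density, g cm^-3 (= t m^-3).
#' @param initial_corg Initial soil organic carbon, percent w/w.
#' @param bat_year Effective BAT-days per year (> 0).
#' @return An object of class `"site_config"`.
#' @export
site_config <- function(mat = 8.5, map = 480, clay = 0.21, silt = 0.68,
                        sand = 0.11, depth = 0.3, bulk_density = 1.35,
                        initial_corg = 2, bat_year = 25) {
  if (abs(clay + silt + sand - 1) > 0.01)
    stop("texture fractions must sum to 1 (+/- 0.01)", call. = FALSE)
  if (depth <= 0 || bulk_density <= 0 || bat_year <= 0)
    stop("depth, bulk_density and bat_year must be > 0", call. = FALSE)
  structure(list(mat = mat, map = map, clay = clay, silt = silt, sand = sand,
                 depth = depth, bulk_density = bulk_density,
                 initial_corg = initial_corg, bat_year = bat_year),
            class = "site_config")
}

# topsoil mass, t ha^-1
soil_mass <- function(site) site$depth * site$bulk_density * 1e4

# carbon stock (t C ha^-1) <-> C_org (% w/w)
stock_to_corg <- function(stock, site) 100 * stock / soil_mass(site)
corg_to_stock <- function(corg, site) corg / 100 * soil_mass(site)

#' Management plan for the scenario
#'
#' @param crop Crop label.
#' @param yield Annual yield, dt ha^-1.
#' @param residue_c Crop residue carbon coefficient, t C ha^-1 per dt of
#'   yield (roots and stubble left in the field; default 0.0024, about
#'   1.2 t C ha^-1 at 500 dt ha^-1 whole-plant silage maize).
#' @param residue_params [turnover_params] of the crop residue FOM
#'   (default k = 0.1, eta = 0.62, a straw-like material).
#' @param n_dose Annual BGR nitrogen dose, kg N ha^-1 yr^-1.
#' @return An object of class `"management_plan"`.
#' @export
management_plan <- function(crop = "maize", yield = 500, residue_c = 0.0024,
                            residue_params = turnover_params(0.1, 0.62),
                            n_dose = 170) {
  if (yield < 0 || residue_c < 0 || n_dose < 0)
    stop("yield, residue_c and n_dose must be >= 0", call. = FALSE)
  structure(list(crop = crop, yield = yield, residue_c = residue_c,
                 residue_params = residue_params, n_dose = n_dose),
            class = "management_plan")
}

#' Pool rate configuration for the three-pool SOM model
#'
#' Surrogate rate constants for the soil organic matter pool dynamics
#' (active pool decay, active-to-stabilized partition, stabilized-to-
#' active return), all per BAT-day, plus the initial partition of the
#' soil carbon stock over the pools. Defaults were fixed once by
#' steady-state algebra so that a 2 percent C_org topsoil is close to
#' equilibrium under the mean digestate treatment of the bundled panel
#' (see the methods vignette); they are deliberately configurable
#' because they stand in for a full site-calibrated SOM model.
#'
#' @param active_decay First-order decay rate of the active pool,
#'   BAT-day^-1.
#' @param partition Fraction of decayed active-pool carbon transferred
#'   to the stabilized pool (the rest is respired).
#' @param stab_return First-order return rate stabilized -> active,
#'   BAT-day^-1.
#' @param active_frac,stab_frac Initial fractions of the carbon stock in
#'   the active and stabilized pools; the remainder is inert.
#' @return An object of class `"pool_config"`.
#' @export
pool_config <- function(active_decay = 0.0087, partition = 0.35,
                        stab_return = 0.0007, active_frac = 0.074,
                        stab_frac = 0.326) {
  if (active_decay < 0 || stab_return < 0)
    stop("rates must be >= 0", call. = FALSE)
  if (partition < 0 || partition > 1)
    stop("partition must lie in [0, 1]", call. = FALSE)
  if (active_frac < 0 || stab_frac < 0 || active_frac + stab_frac > 1)
    stop("initial pool fractions must be >= 0 and sum to <= 1", call. = FALSE)
  structure(list(active_decay = active_decay, partition = partition,
                 stab_return = stab_return, active_frac = active_frac,
                 stab_frac = stab_frac),
            class = "pool_config")
}

#' Pool state of the simulated soil
#'
#' @param active,stabilized,inert Pool sizes, t C ha^-1 (>= 0).
#' @param fom Carried-over fresh organic matter cohorts: a data.frame
#'   with columns `carbon` (t C ha^-1), `k`, `eta`.
#' @param year Year index.
#' @return An object of class `"pool_state"`.
#' @export
pool_state <- function(active, stabilized, inert,
                       fom = data.frame(carbon = numeric(), k = numeric(),
                                        eta = numeric()),
                       year = 0L) {
  if (any(c(active, stabilized, inert) < 0))
    stop("pools must be >= 0", call. = FALSE)
  structure(list(active = active, stabilized = stabilized, inert = inert,
                 fom = fom, year = as.integer(year)),
            class = "pool_state")
}

total_carbon <- function(state) {
  state$active + state$stabilized + state$inert + sum(state$fom$carbon)
}

#' Annual BGR carbon input from an application dose
#'
#' Converts a nitrogen-based application dose into the fresh organic
#' carbon input: applied dry matter = dose / (N_t as fraction of DM),
#' carbon = dry matter x (C_t as fraction of DM).
#'
#' @param props A one-row BGR property table (or list) with `nt` and
#'   `ct` in percent of dry matter.
#' @param n_dose Nitrogen dose, kg N ha^-1 yr^-1.
#' @return Annual FOM carbon input, t C ha^-1.
#' @examples
#' bgr_carbon_input(list(nt = 6.3, ct = 38.4), n_dose = 170)
#' @export
bgr_carbon_input <- function(props, n_dose = 170) {
  if (is.null(props$nt) || props$nt <= 0)
    stop("nt must be > 0 to convert a nitrogen dose", call. = FALSE)
  dm_kg <- n_dose / (props$nt / 100)
  dm_kg * (props$ct / 100) / 1000
}

# Build the generator matrix of the within-year linear carbon dynamics.
# State order: (F_1 .. F_n, active, stabilized, co2); columns sum to 0,
# so total carbon (pools + cumulative CO2) is conserved exactly.
pool_generator <- function(fom, pools) {
  n <- nrow(fom)
  dim <- n + 3
  M <- matrix(0, dim, dim)
  iA <- n + 1; iS <- n + 2; iC <- n + 3
  for (i in seq_len(n)) {
    M[i, i] <- -fom$k[i]
    M[iA, i] <- fom$eta[i] * fom$k[i]
    M[iC, i] <- (1 - fom$eta[i]) * fom$k[i]
  }
  M[iA, iA] <- -pools$active_decay
  M[iS, iA] <- pools$partition * pools$active_decay
  M[iC, iA] <- (1 - pools$partition) * pools$active_decay
  M[iA, iS] <- pools$stab_return
  M[iS, iS] <- -pools$stab_return
  M
}

# merge FOM cohorts with identical parameters (tolerance 1e-12)
merge_cohorts <- function(fom) {
  if (nrow(fom) < 2) return(fom)
  key <- paste(signif(fom$k, 12), signif(fom$eta, 12))
  if (!anyDuplicated(key)) return(fom)
  agg <- stats::aggregate(carbon ~ key, data = cbind(fom, key = key), FUN = sum)
  first <- fom[!duplicated(key), c("k", "eta")]
  first <- first[match(agg$key, unique(key)), ]
  data.frame(carbon = agg$carbon, k = first$k, eta = first$eta)
}

#' Advance the soil carbon pools by one year
#'
#' Adds this year's fresh organic matter inputs and integrates the
#' coupled linear dynamics over one year of Biological Active Time: each
#' FOM cohort decays first-order at its own `k`, a fraction `eta` of the
#' decayed carbon enters the active pool (the carbon reproduction flux)
#' and the rest is respired; the active pool decays with a fraction
#' partitioned to the stabilized pool, which slowly returns carbon to
#' the active pool; the inert pool is constant. The default method uses
#' the exact matrix-exponential solution; `method = "euler"` sub-steps
#' the year explicitly (for oracle comparisons).
#'
#' @param state A [pool_state].
#' @param fom_inputs List of inputs, each a list with `carbon` (t C
#'   ha^-1) and `params` ([turnover_params]); may be empty.
#' @param site A [site_config] (supplies `bat_year`).
#' @param pools A [pool_config].
#' @param method `"closed"` (matrix exponential) or `"euler"`.
#' @param n_sub Sub-steps per year for `method = "euler"` (default 365).
#' @param propagator Optional precomputed matrix exponential (advanced;
#'   see [run_scenario]).
#' @return A list: `state` (new [pool_state]), `co2` (annual CO2-C,
#'   t C ha^-1), `balance_error` (inputs - delta C - CO2).
#' @export
step_year <- function(state, fom_inputs = list(), site = site_config(),
                      pools = pool_config(),
                      method = c("closed", "euler"), n_sub = 365,
                      propagator = NULL) {
  method <- match.arg(method)
  fom <- state$fom
  input_c <- 0
  for (inp in fom_inputs) {
    p <- as_turnover_params(inp$params)
    if (inp$carbon < 0) stop("FOM input carbon must be >= 0", call. = FALSE)
    if (inp$carbon > 0) {
      fom <- rbind(fom, data.frame(carbon = inp$carbon, k = p$k, eta = p$eta))
      input_c <- input_c + inp$carbon
    }
  }
  fom <- merge_cohorts(fom)
  total_before <- state$active + state$stabilized + state$inert +
    sum(fom$carbon)
  x0 <- c(fom$carbon, state$active, state$stabilized, 0)
  t_bat <- site$bat_year
  if (method == "closed") {
    P <- propagator
    if (is.null(P)) {
      M <- pool_generator(fom, pools)
      P <- as.matrix(Matrix::expm(M * t_bat))
    }
    x1 <- as.numeric(P %*% x0)
  } else {
    M <- pool_generator(fom, pools)
    dt <- t_bat / n_sub
    x1 <- x0
    for (i in seq_len(n_sub)) x1 <- x1 + dt * as.numeric(M %*% x1)
  }
  n <- nrow(fom)
  fom$carbon <- x1[seq_len(n)]
  fom <- fom[fom$carbon > 1e-12, , drop = FALSE]
  new_active <- x1[n + 1]; new_stab <- x1[n + 2]; co2 <- x1[n + 3]
  if (min(new_active, new_stab, co2) < -1e-9)
    stop("numerical inconsistency: negative pool after step", call. = FALSE)
  new_state <- pool_state(max(new_active, 0), max(new_stab, 0), state$inert,
                          fom = fom, year = state$year + 1L)
  balance <- total_before - (total_carbon(new_state) + co2)
  list(state = new_state, co2 = co2, balance_error = balance)
}

#' Run a long-term soil organic carbon scenario
#'
#' Simulates `years` of constant management (annual BGR fertilization
#' plus crop residue return) for one treatment. Parameter uncertainty is
#' propagated by running three variants: `mean` (the point estimates),
#' `min` (`mean - sd` for both parameters) and `max` (`mean + sd`),
#' requiring `sd_k`/`sd_eta` on `params` for the latter two.
#'
#' @param site A [site_config].
#' @param mgmt A [management_plan].
#' @param props A one-row BGR property table (needs `nt`, `ct`).
#' @param params A [turnover_params] (with sds for the min/max variants).
#' @param years Number of simulated years (default 100).
#' @param pools A [pool_config].
#' @param variants Subset of `c("mean", "min", "max")`.
#' @param treatment Label for the result.
#' @return An object of class `"scenario_result"`: `treatment`,
#'   `trajectory` (data.frame `variant`, `year`, `corg_percent` with
#'   `years + 1` rows per variant), `final` (named final C_org per
#'   variant), `final_mean`, `final_sd`, `max_balance_error`.
#' @export
run_scenario <- function(site, mgmt, props, params, years = 100,
                         pools = pool_config(),
                         variants = c("mean", "min", "max"),
                         treatment = if (!is.null(props$bgr)) as.character(props$bgr) else "treatment") {
  params <- as_turnover_params(params)
  variants <- match.arg(variants, c("mean", "min", "max"), several.ok = TRUE)
  if (any(variants != "mean") && (is.na(params$sd_k) || is.na(params$sd_eta)))
    stop("min/max variants require sd_k and sd_eta", call. = FALSE)
  bgr_c <- bgr_carbon_input(props, mgmt$n_dose)
  res_c <- mgmt$yield * mgmt$residue_c
  stock0 <- corg_to_stock(site$initial_corg, site)
  traj <- list(); finals <- c(); max_bal <- 0
  for (v in variants) {
    pv <- switch(v,
      mean = turnover_params(params$k, params$eta),
      min  = turnover_params(max(params$k - params$sd_k, 1e-6),
                             min(max(params$eta - params$sd_eta, 0), 1)),
      max  = turnover_params(params$k + params$sd_k,
                             min(max(params$eta + params$sd_eta, 0), 1)))
    state <- pool_state(active = pools$active_frac * stock0,
                        stabilized = pools$stab_frac * stock0,
                        inert = (1 - pools$active_frac - pools$stab_frac) * stock0)
    inputs <- list()
    if (bgr_c > 0) inputs <- list(list(carbon = bgr_c, params = pv))
    if (res_c > 0)
      inputs <- c(inputs, list(list(carbon = res_c,
                                    params = mgmt$residue_params)))
    corg <- numeric(years + 1)
    corg[1] <- stock_to_corg(state$active + state$stabilized + state$inert,
                             site)
    prop_cache <- NULL; cache_sig <- NULL
    for (y in seq_len(years)) {
      # cohort parameter set is constant after the first year, so the
      # matrix exponential can be reused
      fom_try <- merge_cohorts(rbind(state$fom,
        do.call(rbind, lapply(inputs, function(i) {
          p <- as_turnover_params(i$params)
          data.frame(carbon = i$carbon, k = p$k, eta = p$eta)
        }))))
      sig <- paste(signif(fom_try$k, 12), signif(fom_try$eta, 12),
                   collapse = ";")
      if (is.null(cache_sig) || !identical(sig, cache_sig)) {
        M <- pool_generator(fom_try, pools)
        prop_cache <- as.matrix(Matrix::expm(M * site$bat_year))
        cache_sig <- sig
      }
      st <- step_year(state, inputs, site, pools, propagator = prop_cache)
      state <- st$state
      max_bal <- max(max_bal, abs(st$balance_error))
      corg[y + 1] <- stock_to_corg(state$active + state$stabilized +
                                     state$inert, site)
    }
    traj[[v]] <- data.frame(variant = v, year = 0:years, corg_percent = corg)
    finals[v] <- corg[years + 1]
  }
  structure(list(treatment = treatment,
                 trajectory = do.call(rbind, traj),
                 final = finals,
                 final_mean = mean(finals),
                 final_sd = if (length(finals) > 1) stats::sd(finals) else NA_real_,
                 max_balance_error = max_bal),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario %s: final C_org %.3f%% w/w (sd %.3g over %d variants)\n",
              x$treatment, x$final_mean, x$final_sd, length(x$final)))
  invisible(x)
}

# compact letter display for LSD groups: means sorted descending; runs of
# mutually non-significant treatments (an interval structure under a
# single LSD threshold) get one letter each
lsd_letters <- function(means, lsd) {
  ord <- order(-means)
  m <- means[ord]
  t_n <- length(m)
  intervals <- list()
  for (i in seq_len(t_n)) {
    j <- i
    while (j < t_n && (m[i] - m[j + 1]) < lsd) j <- j + 1
    intervals[[i]] <- c(i, j)
  }
  # keep maximal intervals only
  keep <- vapply(seq_along(intervals), function(i) {
    !any(vapply(seq_along(intervals), function(l) {
      l != i && intervals[[l]][1] <= intervals[[i]][1] &&
        intervals[[l]][2] >= intervals[[i]][2]
    }, logical(1)))
  }, logical(1))
  intervals <- unique(intervals[keep])
  letters_out <- rep("", t_n)
  for (g in seq_along(intervals)) {
    rng <- intervals[[g]][1]:intervals[[g]][2]
    letters_out[rng] <- paste0(letters_out[rng], letters[g])
  }
  res <- character(t_n)
  res[ord] <- letters_out
  res
}

#' Compare scenario treatments by ANOVA and LSD letters
#'
#' One-way ANOVA of the final C_org across treatments (the parameter
#' variants within a treatment act as the replicates), followed by
#' pairwise least-significant-difference comparisons at `alpha`
#' summarized as a compact letter display (treatments sharing a letter
#' are not significantly different).
#'
#' @param results List of [run_scenario] results (>= 2 treatments, each
#'   with >= 2 variants).
#' @param alpha Significance level (default 0.05).
#' @return A list: `anova` (data.frame with df, SS, MS, F, p),
#'   `lsd` (the least significant difference), `groups` (data.frame
#'   `treatment`, `mean_corg`, `letters`).
#' @export
compare_treatments <- function(results, alpha = 0.05) {
  if (length(results) < 2) stop("need >= 2 treatments", call. = FALSE)
  df <- do.call(rbind, lapply(results, function(r) {
    if (length(r$final) < 2)
      stop("no within-treatment variance: need >= 2 variants per treatment",
           call. = FALSE)
    data.frame(treatment = r$treatment, final = unname(r$final))
  }))
  df$treatment <- factor(df$treatment, levels = unique(df$treatment))
  fit <- stats::aov(final ~ treatment, data = df)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  n_per <- table(df$treatment)
  if (length(unique(n_per)) != 1)
    warning("unbalanced design; LSD uses the harmonic mean group size")
  n_h <- length(n_per) / sum(1 / as.numeric(n_per))
  lsd <- stats::qt(1 - alpha / 2, dfe) * sqrt(2 * mse / n_h)
  means <- tapply(df$final, df$treatment, mean)
  grp <- lsd_letters(as.numeric(means), lsd)
  list(anova = data.frame(term = rownames(an), df = an$Df, sum_sq = an$`Sum Sq`,
                          mean_sq = an$`Mean Sq`, f_value = an$`F value`,
                          p_value = an$`Pr(>F)`),
       lsd = lsd,
       groups = data.frame(treatment = names(means),
                           mean_corg = as.numeric(means),
                           letters = grp))
}
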