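# The in-silico experiments: baseline calibration against measured tissue
# concentrations, secretion-rate scans of the angiogenic ratio, Monte Carlo
# secretion sampling, cHSPG x PF4 response grids, and the pulsed PF4
# controlled-release protocol.

#' Measured tissue-concentration calibration targets
#'
#' The observable aims and experimental ranges used to tune baseline
#' production rates: unbound VEGF and PF4, total TSP1, FGF2, MMP3 and MMP9
#' (pro + active), each controlled by its own production rate.
#'
#' @return Tibble with `observable`, `control` (production target), `aim`,
#'   `low`, `high` (all molar, interstitial fluid).
#' @export
table1_targets <- function() {
  tibble(
    observable = c("VEGF_unbound", "TSP1_total", "PF4_unbound",
                   "FGF2_total", "MMP3_total", "MMP9_total"),
    control = c("VEGF", "TSP1", "PF4", "FGF2", "MMP3", "proMMP9"),
    aim = c(180.2e-12, 3.0e-9, 4.7e-9, 3.9e-9, 5.0e-9, 9.2e-9),
    low = c(8.0e-12, 1.0e-9, 1.0e-9, 0.2e-9, 1.8e-9, 1.0e-9),
    high = c(389e-12, 6.2e-9, 11.3e-9, 11.1e-9, 65.1e-9, 287.8e-9)
  )
}

obs_fluid <- function(state, weights, geom) {
  x <- eval_observables(state, weights)
  x / geom$interstitial_fluid_fraction * 1000  # molar, interstitial fluid
}

#' Calibrate baseline production rates against concentration targets
#'
#' Coordinate-wise root finding in log space, iterated jointly: each
#' production control starts with proportional probes (clipped to a 50-fold
#' move per pass); once a control's observable brackets its aim the update
#' switches to a log-log secant step safeguarded by bisection of the bracket.
#' The loop stops when every aim is met within `tol` (relative). Steady-state
#' observables are monotone in their own production rate, which this scheme
#' requires.
#'
#' @param net Expanded `angio_network`.
#' @param params Starting `angio_params`.
#' @param geom An `angio_geometry`.
#' @param targets Tibble as [table1_targets()].
#' @param tol Relative tolerance on each aim (default 0.05).
#' @param max_pass Outer-loop cap (default 15).
#' @return List with `params` (calibrated), `multipliers`, `history`
#'   (per-pass predictions), `converged`.
#' @export
calibrate_baseline <- function(net, params, geom = geometry(),
                               targets = table1_targets(), tol = 0.05,
                               max_pass = 15L) {
  W <- observable_weights(net)
  nt <- nrow(targets)
  mult <- rep(1, nt)
  lo <- rep(NA_real_, nt); hi <- rep(NA_real_, nt)   # bracket (log-multipliers)
  prev_m <- rep(NA_real_, nt); prev_o <- rep(NA_real_, nt)
  hist <- list()
  state <- NULL
  converged <- FALSE
  for (pass in seq_len(max_pass)) {
    p2 <- scale_parameters(params,
                           production = stats::setNames(mult, targets$control))
    sys <- assemble_odes(net, p2, geom)
    ss <- run_to_steady_state(sys, x0 = state)
    state <- unname(ss$state)
    obs <- obs_fluid(ss$state, W[targets$observable], geom)
    err <- obs / targets$aim - 1
    hist[[pass]] <- tibble(pass = pass, observable = targets$observable,
                           predicted = obs, aim = targets$aim,
                           rel_err = err, multiplier = mult)
    if (all(abs(err) < tol)) { converged <- TRUE; break }
    new_mult <- mult
    for (i in seq_len(nt)) {
      if (abs(err[[i]]) < tol) next
      lm <- log(mult[[i]])
      if (obs[[i]] < targets$aim[[i]]) {
        lo[[i]] <- max(lo[[i]], lm, na.rm = TRUE)
      } else {
        hi[[i]] <- min(hi[[i]], lm, na.rm = TRUE)
      }
      prop <- lm + log(pmin(pmax(targets$aim[[i]] / obs[[i]], 1 / 50), 50))
      cand <- prop
      if (!is.na(prev_o[[i]]) && prev_o[[i]] > 0 && obs[[i]] > 0 &&
          abs(log(obs[[i]]) - log(prev_o[[i]])) > 1e-12) {
        slope <- (lm - prev_m[[i]]) / (log(obs[[i]]) - log(prev_o[[i]]))
        cand <- lm + slope * (log(targets$aim[[i]]) - log(obs[[i]]))
      }
      if (!is.na(lo[[i]]) && !is.na(hi[[i]])) {
        # bisection safeguard inside the bracket
        if (cand <= lo[[i]] || cand >= hi[[i]]) cand <- (lo[[i]] + hi[[i]]) / 2
      }
      prev_m[[i]] <- lm; prev_o[[i]] <- obs[[i]]
      new_mult[[i]] <- exp(cand)
    }
    mult <- new_mult
  }
  if (!converged) warn("calibration did not meet every aim within the pass cap")
  mult <- stats::setNames(mult, targets$control)
  list(params = scale_parameters(params, production = mult),
       multipliers = mult, history = bind_rows(hist), converged = converged)
}

# ---- secretion scans --------------------------------------------------------

default_scan_multipliers <- function(n = 13L) 10^seq(-2, 1, length.out = n)

scan_point <- function(net, params, geom, W, state0) {
  sys <- assemble_odes(net, params, geom)
  ss <- run_to_steady_state(sys, x0 = state0)
  obs <- eval_observables(ss$state, W)
  rat <- angiogenic_ratio(ss$state, net)
  list(obs = obs, ratio = rat$ratio, converged = ss$converged,
       state = unname(ss$state))
}

#' Two-factor secretion scan of the angiogenic state
#'
#' Varies the secretion rates of a pro/anti factor pair over multipliers of
#' baseline (default 13 log-spaced points over 0.01-10x), records the
#' steady-state angiogenic ratio and the per-pathway signaling-complex
#' totals, and normalizes all outputs to the (1, 1) baseline grid point.
#'
#' @param net Expanded `angio_network`.
#' @param params Baseline (calibrated) `angio_params`.
#' @param geom An `angio_geometry`.
#' @param factor_pair Character pair, e.g. `c("VEGF", "TSP1")`.
#' @param multipliers Multiplier grid (must contain 1).
#' @return Tibble of class `angio_scan`: one row per grid point with
#'   `m1`, `m2`, `ratio`, `log10_ratio`, per-pathway signaling totals and
#'   their baseline-normalized values, `converged`.
#' @export
secretion_scan_2d <- function(net, params, geom = geometry(),
                              factor_pair = c("VEGF", "TSP1"),
                              multipliers = default_scan_multipliers()) {
  stopifnot(length(factor_pair) == 2L)
  if (!any(abs(multipliers - 1) < 1e-12)) {
    abort("multiplier grid must contain the baseline point 1")
  }
  W <- observable_weights(net)
  sigs <- c("VEGF_signaling", "FGF2_signaling", "TSP1_signaling", "PF4_signaling")
  rows <- list()
  state0 <- NULL
  for (a in multipliers) {
    for (b in multipliers) {
      pr <- stats::setNames(c(a, b), factor_pair)
      pt <- scan_point(net, scale_parameters(params, production = pr), geom,
                       W[sigs], state0)
      state0 <- pt$state
      rows[[length(rows) + 1L]] <- tibble(
        m1 = a, m2 = b, ratio = pt$ratio, converged = pt$converged,
        !!!stats::setNames(as.list(pt$obs[sigs]), sigs))
    }
  }
  out <- bind_rows(rows)
  base <- out[abs(out$m1 - 1) < 1e-12 & abs(out$m2 - 1) < 1e-12, ]
  for (s in sigs) {
    out[[paste0(s, "_norm")]] <- out[[s]] / base[[s]][[1L]]
  }
  out$ratio_norm <- out$ratio / base$ratio[[1L]]
  out$log10_ratio <- log10(out$ratio)
  structure(out, factor_pair = factor_pair,
            class = c("angio_scan", class(out)))
}

# ---- Monte Carlo secretion sampling ----------------------------------------

#' Log-uniform secretion multiplier sample
#'
#' @param n Number of samples.
#' @param seed Integer seed (mandatory; all randomness flows through it).
#' @param factors Factor names to sample.
#' @param range Multiplier range (default 0.01-10x baseline).
#' @return Tibble with `sample` and one column per factor.
#' @export
sample_secretion_multipliers <- function(n, seed,
                                         factors = c("VEGF", "TSP1", "PF4",
                                                     "FGF2", "MMP3", "proMMP9"),
                                         range = c(0.01, 10)) {
  if (missing(seed) || is.null(seed)) abort("an explicit seed is required")
  stopifnot(n >= 1)
  out <- withr::with_seed(seed, {
    m <- 10^matrix(stats::runif(n * length(factors), log10(range[[1L]]),
                                log10(range[[2L]])),
                   nrow = n)
    colnames(m) <- factors
    as_tibble(m)
  })
  dplyr::bind_cols(tibble(sample = seq_len(n)), out)
}

#' Monte Carlo robustness of the distribution profile
#'
#' Samples secretion-rate multipliers log-uniformly over 0.01-10x baseline
#' for the six secreted species, recomputes the steady state for each sample,
#' and summarises the distribution profile and angiogenic ratio across
#' samples.
#'
#' @param net Expanded `angio_network`.
#' @param params Baseline `angio_params`.
#' @param geom An `angio_geometry`.
#' @param n Number of samples (default 1000).
#' @param seed Integer seed (mandatory).
#' @return Tibble of class `angio_mc`: per sample, the multipliers, the
#'   surface-bound and interstitial percentages per factor, and the ratio.
#' @export
monte_carlo_secretion <- function(net, params, geom = geometry(), n = 1000L,
                                  seed) {
  samples <- sample_secretion_multipliers(n, seed)
  factors <- setdiff(names(samples), "sample")
  rows <- list()
  state0 <- NULL
  for (i in seq_len(n)) {
    pr <- unlist(samples[i, factors])
    p2 <- scale_parameters(params, production = pr)
    sys <- assemble_odes(net, p2, geom)
    ss <- run_to_steady_state(sys, x0 = state0)
    state0 <- unname(ss$state)
    prof <- distribution_profile(ss$state, net)
    surf <- prof %>%
      filter(grepl("^surface", .data$category)) %>%
      group_by(factor) %>% summarise(surface_pct = sum(percent), .groups = "drop")
    rat <- angiogenic_ratio(ss$state, net)
    rows[[i]] <- dplyr::bind_cols(
      samples[i, ],
      tidyr::pivot_wider(surf, names_from = "factor", values_from = "surface_pct",
                         names_glue = "{factor}_surface_pct"),
      tibble(ratio = rat$ratio, converged = ss$converged))
  }
  structure(bind_rows(rows), class = c("angio_mc", class(samples)))
}

# ---- cHSPG x PF4 grids ------------------------------------------------------

#' cHSPG level x PF4 secretion response grid
#'
#' Sweeps the cell-surface HSPG level (default multipliers 0.01, 0.1, 0.5,
#' 1, 2, 10 of baseline) against the PF4 secretion rate (log-spaced over
#' 0.01-10x), recording steady-state observables for every grid point.
#' Fold-changes are normalized per cHSPG level to the smallest PF4 multiplier
#' (the 100-fold-below-baseline reference).
#'
#' @param net Expanded `angio_network`.
#' @param params Baseline `angio_params`.
#' @param geom An `angio_geometry`.
#' @param chspg_multipliers,pf4_multipliers Sweep grids.
#' @param observables Names from [observable_weights()] to record.
#' @return Tibble of class `angio_grid`: `chspg`, `pf4`, observables, their
#'   `_fold` columns, `ratio`, `converged`.
#' @export
chspg_pf4_grid <- function(net, params, geom = geometry(),
                           chspg_multipliers = c(0.01, 0.1, 0.5, 1, 2, 10),
                           pf4_multipliers = default_scan_multipliers(),
                           observables = c("VEGF_signaling", "FGF2_signaling",
                                           "TSP1_signaling", "PF4_signaling",
                                           "VEGF_unbound", "V165_unbound",
                                           "V121_unbound", "FGF2_unbound",
                                           "VEGF_R1", "VEGF_R2", "VEGF_NRP1",
                                           "FGF2_dimer", "FGF2_trimer",
                                           "FGF2_FGFR1_monomer")) {
  W <- observable_weights(net)[observables]
  rows <- list()
  for (cm in chspg_multipliers) {
    pc <- scale_parameters(params, densities = c(cHSPG = cm))
    state0 <- NULL
    for (pm in sort(pf4_multipliers)) {
      pp <- scale_parameters(pc, production = c(PF4 = pm))
      pt <- scan_point(net, pp, geom, W, state0)
      state0 <- pt$state
      rows[[length(rows) + 1L]] <- tibble(
        chspg = cm, pf4 = pm, ratio = pt$ratio, converged = pt$converged,
        !!!stats::setNames(as.list(pt$obs), observables))
    }
  }
  out <- bind_rows(rows)
  ref <- out %>% group_by(chspg) %>% filter(pf4 == min(pf4)) %>% ungroup()
  for (s in observables) {
    refv <- stats::setNames(ref[[s]], as.character(ref$chspg))
    out[[paste0(s, "_fold")]] <- unname(out[[s]] / refv[as.character(out$chspg)])
  }
  structure(out, class = c("angio_grid", class(out)))
}

#' Interior-maximum (biphasic) flag along the cHSPG axis
#'
#' For each PF4 multiplier, tests whether the maximum of an observable over
#' the cHSPG sweep occurs at an interior multiplier (the biphasic VEGF
#' signaling response), rather than at either endpoint.
#'
#' @param grid An `angio_grid`.
#' @param observable Column to test (default `"VEGF_signaling"`).
#' @return Tibble with `pf4`, `argmax_chspg`, `interior`.
#' @export
biphasic_flag <- function(grid, observable = "VEGF_signaling") {
  grid %>%
    group_by(pf4) %>%
    summarise(argmax_chspg = chspg[which.max(.data[[observable]])],
              interior = argmax_chspg > min(chspg) & argmax_chspg < max(chspg),
              .groups = "drop")
}

# ---- pulsed PF4 release -----------------------------------------------------

#' Quasi-steady analytic estimate of the peak depot-driven concentration
#'
#' With release much slower than degradation, the free concentration tracks
#' `amount(t) * k_rel / (k_deg * V_fluid)`; the peak is attained essentially
#' at the start of release.
#'
#' @param d An [dose()].
#' @param k_deg First-order degradation rate of the released species (1/s).
#' @param geom An `angio_geometry`.
#' @return Peak concentration (M, interstitial fluid).
#' @export
pulse_peak_analytic <- function(d = dose(), k_deg = kdeg_from_half_life(300),
                                geom = geometry()) {
  dose_to_moles(d) * d$release_rate_constant /
    (k_deg * interstitial_fluid_volume(geom))
}

#' Pulsed PF4 controlled-release protocol
#'
#' Brings the system to steady state at the given cHSPG level, then releases
#' two depot doses of PF4 (default 5 mg each at days 1 and 3.5, first-order
#' release constant 2.8e-5 1/s) into the tumor interstitium and follows the
#' VEGF- and FGF2-axis species for a week. The depot itself is not subject to
#' degradation; released PF4 enters the free interstitial PF4 pool.
#'
#' @param net Expanded `angio_network`.
#' @param params Baseline `angio_params`.
#' @param geom An `angio_geometry`.
#' @param chspg_level cHSPG multiplier (0.1, 1, 10 for the low / medium /
#'   high microenvironments).
#' @param d An [dose()]: mass, molecular weight, release constant.
#' @param pulse_days Release start times (days).
#' @param duration_days Simulated span (days).
#' @return Object of class `angio_pulse`: `trajectory` (tidy tibble: time,
#'   observable, concentration in pM fluid), `peak_pf4_nM`, `fold_changes`
#'   (peak-vs-pre for increases, pre-vs-trough for decreases),
#'   `chspg_level`.
#' @export
pf4_pulse <- function(net, params, geom = geometry(), chspg_level = 1,
                      d = dose(), pulse_days = c(1, 3.5),
                      duration_days = 7) {
  pc <- scale_parameters(params, densities = c(cHSPG = chspg_level))
  sys <- assemble_odes(net, pc, geom)
  ss <- run_to_steady_state(sys)
  if (!ss$converged) abort("failed to reach the pre-pulse steady state")

  pulse_s <- pulse_days * 86400
  # dense output after each pulse (the free-PF4 peak follows release onset
  # on the 5-minute degradation timescale), hourly elsewhere
  times <- sort(unique(c(
    seq(0, duration_days * 86400, by = 3600),
    unlist(lapply(pulse_s, function(t0) seq(t0, min(t0 + 12 * 3600,
                                                    duration_days * 86400), by = 300)))
  )))
  depot <- list(list(target = "PF4@interstitium",
                     k_rel = d$release_rate_constant,
                     doses = tibble(time = pulse_s,
                                    amount_mol = dose_to_moles(d))))
  traj <- integrate_network(sys, times, x0 = unname(ss$state), depots = depot)

  W <- observable_weights(net)
  tracked <- c("PF4_unbound", "VEGF_unbound", "V165_unbound", "V121_unbound",
               "VEGF_R1", "VEGF_R2", "VEGF_NRP1",
               "FGF2_unbound", "FGF2_FGFR1_monomer", "FGF2_trimer", "FGF2_dimer")
  obs <- eval_observables(traj$state, W[tracked])
  to_pM <- 1e12 * 1000 / geom$interstitial_fluid_fraction
  tidy_traj <- as_tibble(obs * to_pM) %>%
    mutate(time_days = traj$times / 86400) %>%
    tidyr::pivot_longer(-time_days, names_to = "observable",
                        values_to = "conc_pM")

  pre <- unname(obs[1L, ])
  peak <- unname(apply(obs, 2L, max))
  trough <- unname(apply(obs, 2L, min))
  eps <- 1e-300
  fold <- tibble(
    observable = tracked,
    pre_pM = pre * to_pM,
    peak_pM = peak * to_pM,
    trough_pM = trough * to_pM,
    direction = ifelse(peak - pre >= pre - trough, "increase", "decrease"),
    fold = ifelse(peak - pre >= pre - trough,
                  peak / pmax(pre, eps), pmax(pre, eps) / pmax(trough, eps))
  )
  structure(list(
    trajectory = tidy_traj,
    peak_pf4_nM = max(obs[, "PF4_unbound"]) * to_pM / 1000,
    fold_changes = fold,
    chspg_level = chspg_level,
    pre_pulse = stats::setNames(pre, tracked),
    geom = geom
  ), class = "angio_pulse")
}

#' @export
print.angio_pulse <- function(x, ...) {
  cat(sprintf("<angio_pulse> cHSPG x%g: peak free PF4 %.0f nM\n",
              x$chspg_level, x$peak_pf4_nM))
  invisible(x)
}
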