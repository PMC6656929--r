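# Mass-action ODE assembly and stiff integration. Internal state is in
# mol/cm^3 tissue; bimolecular rate constants (1/(M s)) are converted to
# tissue units with the interstitial fluid fraction (fluid-equivalent
# convention, see the methods vignette). Depot sources model first-order
# controlled release of an injected reservoir into the interstitium.

resolve_production <- function(name, value, geom) {
  if (grepl("_ec$", name)) return(value * geom$cells_ec_per_cm3 / AVOGADRO)
  if (grepl("_tc$", name)) return(value * geom$cells_tc_per_cm3 / AVOGADRO)
  value / AVOGADRO  # generic tissue-level source, molecules/cm^3/s
}

resolve_init <- function(init, params, geom) {
  vapply(init, function(spec) {
    if (identical(spec, "zero")) return(0)
    parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
    if (parts[[1L]] != "density") abort(paste0("unknown init spec '", spec, "'"))
    hit <- params$densities$species == parts[[2L]] & params$densities$side == parts[[3L]]
    if (!any(hit)) abort(paste0("no density entry for ", parts[[2L]], ":", parts[[3L]]))
    val <- params$densities$value[hit][[1L]]
    switch(parts[[3L]],
           ec = receptors_per_cell_to_tissue_conc(val, geom$cells_ec_per_cm3),
           tc = receptors_per_cell_to_tissue_conc(val, geom$cells_tc_per_cm3),
           matrix = val / AVOGADRO,
           abort(paste0("unknown density side '", parts[[3L]], "'")))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Assemble the mass-action ODE system for a reaction network
#'
#' Each reaction contributes `k * prod(reactants)` with the correct
#' stoichiometric signs; production reactions contribute constant source
#' terms; internalization reactions destroy soluble cargo and return
#' receptors and cHSPG to their free surface pools, so receptor totals are
#' conserved by construction.
#'
#' @param net An `angio_network`.
#' @param params An `angio_params`; every rate name referenced by the network
#'   must resolve.
#' @param geom An `angio_geometry`.
#' @return Object of class `angio_ode` with the initial state, resolved rate
#'   vector and sparse stoichiometry.
#' @export
assemble_odes <- function(net, params, geom = geometry()) {
  rates <- param_rates(params)
  lookup <- stats::setNames(rates$value, rates$name)
  kind <- stats::setNames(rates$kind, rates$name)
  rx <- net$reactions
  miss <- setdiff(unique(rx$rate), rates$name)
  if (length(miss)) abort(paste0("unresolved rate name(s): ", paste(miss, collapse = ", ")))
  if (any(rates$value < 0)) abort("negative rate constant in parameter set")

  n <- length(net$ids)
  m <- nrow(rx)
  f <- geom$interstitial_fluid_fraction
  one <- n + 1L  # sentinel index holding constant 1

  i1 <- ifelse(is.na(rx$reactant1), one, rx$reactant1)
  i2 <- ifelse(is.na(rx$reactant2), one, rx$reactant2)
  arity <- (!is.na(rx$reactant1)) + (!is.na(rx$reactant2))
  k <- numeric(m)
  for (j in seq_len(m)) {
    nm <- rx$rate[[j]]
    val <- lookup[[nm]]
    k[[j]] <- switch(kind[[nm]],
      production = {
        if (arity[[j]] != 0L) abort(paste0("production rate on reaction with reactants: ", nm))
        resolve_production(nm, val, geom)
      },
      bimolecular = {
        if (arity[[j]] != 2L) abort(paste0("bimolecular rate on unimolecular reaction: ", nm))
        val * 1000 / f
      },
      unimolecular = {
        if (arity[[j]] != 1L) abort(paste0("unimolecular rate on reaction of arity ",
                                           arity[[j]], ": ", nm))
        val
      })
    k[[j]] <- k[[j]] * rx$mult[[j]]
  }

  # sparse stoichiometry
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(m)) {
    for (r in stats::na.omit(c(rx$reactant1[[j]], rx$reactant2[[j]]))) {
      ii <- c(ii, r); jj <- c(jj, j); xx <- c(xx, -1)
    }
    for (p in rx$products[[j]]) {
      ii <- c(ii, p); jj <- c(jj, j); xx <- c(xx, 1)
    }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, m))

  structure(list(
    net = net, params = params, geom = geom,
    x0 = resolve_init(net$init, params, geom),
    k = k, i1 = i1, i2 = i2, S = S, n = n
  ), class = "angio_ode")
}

#' @export
print.angio_ode <- function(x, ...) {
  cat(sprintf("<angio_ode> %d states, %d reactions\n", x$n, length(x$k)))
  invisible(x)
}

ode_rhs <- function(sys, n_depot = 0L, depot_target = integer(0),
                    depot_krel = numeric(0)) {
  S <- sys$S; k <- sys$k; i1 <- sys$i1; i2 <- sys$i2; n <- sys$n
  V <- sys$geom$tumor_volume_cm3
  function(t, x, parms) {
    xs <- c(pmax(x[seq_len(n)], 0), 1)
    v <- k * xs[i1] * xs[i2]
    dx <- as.numeric(S %*% v)
    if (n_depot > 0L) {
      d <- x[n + seq_len(n_depot)]
      rel <- depot_krel * d
      dd <- -rel
      for (q in seq_len(n_depot)) {
        dx[depot_target[[q]]] <- dx[depot_target[[q]]] + rel[[q]] / V
      }
      return(list(c(dx, dd)))
    }
    list(dx)
  }
}

# default solver tolerances: relative 1e-8; absolute 1e-3 pmol/L fluid,
# converted to tissue units
ode_atol <- function(geom) 1e-15 * geom$interstitial_fluid_fraction / 1000

#' Integrate a system over a time grid
#'
#' @param sys An `angio_ode`.
#' @param times Strictly increasing time grid (s); must start at the initial
#'   time.
#' @param x0 Initial state (defaults to the assembled seed state).
#' @param depots Optional list of depot sources; each a list with `target`
#'   (species canonical id), `k_rel` (1/s) and `doses` (data frame with
#'   `time` (s) and `amount_mol`): instantaneous additions to the depot.
#' @param rtol,atol Solver tolerances.
#' @return Object of class `angio_traj`: `times`, `state` matrix
#'   (rows = times, columns = species; depot columns appended as
#'   `depot_<i>`), and the system.
#' @export
integrate_network <- function(sys, times, x0 = NULL, depots = NULL,
                              rtol = 1e-8, atol = ode_atol(sys$geom)) {
  stopifnot(length(times) >= 2L, !is.unsorted(times, strictly = TRUE))
  x0 <- x0 %||% sys$x0
  if (any(x0 < 0)) abort("negative initial state")
  n <- sys$n
  nd <- length(depots)
  tgt <- integer(0); krel <- numeric(0); ev <- NULL
  if (nd > 0L) {
    tgt <- vapply(depots, function(d) {
      i <- match(d$target, sys$net$ids)
      if (is.na(i)) abort(paste0("depot target not in network: ", d$target))
      i
    }, integer(1))
    krel <- vapply(depots, function(d) d$k_rel, numeric(1))
    ev <- bind_rows(lapply(seq_len(nd), function(q) {
      tibble(var = paste0("depot_", q), time = depots[[q]]$doses$time,
             value = depots[[q]]$doses$amount_mol, method = "add")
    }))
    times <- sort(unique(c(times, ev$time)))
  }
  y0 <- c(x0, rep(0, nd))
  names(y0) <- c(sys$net$ids, if (nd) paste0("depot_", seq_len(nd)))
  rhs <- ode_rhs(sys, nd, tgt, krel)
  out <- deSolve::lsoda(y = y0, times = times, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000,
                        events = if (!is.null(ev)) list(data = as.data.frame(ev)))
  if (attr(out, "istate")[[1L]] < 0) {
    abort("ODE solver failed (stiffness or step-size underflow); see diagnostics")
  }
  state <- unname(as.matrix(out[, -1L, drop = FALSE]))
  colnames(state) <- names(y0)
  low <- min(state)
  if (low < -1e-15) abort(sprintf("state went negative beyond tolerance (min %.3e)", low))
  state[state < 0] <- 0
  structure(list(times = out[, 1L], state = state, sys = sys),
            class = "angio_traj")
}

#' @export
print.angio_traj <- function(x, ...) {
  cat(sprintf("<angio_traj> %d time points over %.3g s, %d states\n",
              length(x$times), max(x$times) - min(x$times), ncol(x$state)))
  invisible(x)
}

#' Run a system to steady state
#'
#' Integrates in windows and declares steady state when every tracked output
#' changes by less than `tol` (relative) over a full assessment window
#' (default one simulated hour, strict relative to the fastest half-life in
#' the model). Non-convergence within the hard cap is flagged, not silent.
#'
#' @param sys An `angio_ode`.
#' @param x0 Optional initial state.
#' @param tol Relative tolerance (default 1e-4, i.e. 0.01%).
#' @param window Assessment window (s).
#' @param max_time Hard cap on simulated time (s).
#' @param tracked Optional integer/character vector of species to monitor
#'   (default: all species above the reporting floor).
#' @return Object of class `angio_ss`: `state` (named), `time`, `converged`,
#'   `sys`.
#' @export
run_to_steady_state <- function(sys, x0 = NULL, tol = 1e-4, window = 3600,
                                max_time = 50 * 86400, tracked = NULL) {
  x <- x0 %||% sys$x0
  floor_ <- ode_atol(sys$geom) * 1e3   # ignore species below ~1 fpmol/L
  if (!is.null(tracked) && is.character(tracked)) {
    tracked <- match(tracked, sys$net$ids)
  }
  t_now <- 0
  batch <- 48 * window
  while (t_now < max_time) {
    t_end <- min(t_now + batch, max_time)
    times <- seq(t_now, t_end, by = window)
    if (length(times) < 2L) break
    traj <- integrate_network(sys, times, x0 = x)
    st <- traj$state[, seq_len(sys$n), drop = FALSE]
    for (r in 2:nrow(st)) {
      a <- st[r - 1L, ]; b <- st[r, ]
      sel <- tracked %||% seq_len(sys$n)
      keep <- pmax(abs(a[sel]), abs(b[sel])) > floor_
      rel <- if (any(keep)) {
        max(abs(b[sel][keep] - a[sel][keep]) / pmax(abs(a[sel][keep]), floor_))
      } else 0
      if (rel < tol) {
        return(structure(list(state = stats::setNames(b, sys$net$ids),
                              time = traj$times[[r]], converged = TRUE,
                              sys = sys),
                         class = "angio_ss"))
      }
    }
    x <- st[nrow(st), ]
    t_now <- t_end
  }
  warn("steady state not reached within the hard cap; returning flagged state")
  structure(list(state = stats::setNames(x, sys$net$ids), time = t_now,
                 converged = FALSE, sys = sys),
            class = "angio_ss")
}

#' @export
print.angio_ss <- function(x, ...) {
  cat(sprintf("<angio_ss> t = %.3g s, converged = %s\n", x$time, x$converged))
  invisible(x)
}

# ---- conservation -----------------------------------------------------------

# instances of each conserved (surface/matrix-fixed) monomer type per species
conserved_weight_matrix <- function(net) {
  if (is.null(net$species)) abort("conservation requires a structured network")
  M <- net$spec$monomers
  fixed <- names(M)[vapply(M, function(m) m$mobility != "soluble", logical(1))]
  keys <- list()
  for (s in seq_along(net$species)) {
    cpx <- net$species[[s]]
    for (t in cpx$types) {
      if (!t %in% fixed) next
      key <- paste0(t, "@", cpx$compartment)
      if (is.null(keys[[key]])) keys[[key]] <- numeric(length(net$ids))
      keys[[key]][[s]] <- keys[[key]][[s]] + 1
    }
  }
  keys
}

#' Conservation report for receptors and HSPG pools
#'
#' Receptors are recycled on internalization and iHSPG is neither produced
#' nor degraded, so the total of each fixed monomer type (free + in all
#' complexes) must stay constant along any trajectory. Reports the maximum
#' relative drift per pool.
#'
#' @param traj An `angio_traj`.
#' @param net The `angio_network` the trajectory was simulated from.
#' @return Tibble with `pool`, `total_initial`, `max_rel_drift`.
#' @export
conservation_report <- function(traj, net = traj$sys$net) {
  W <- conserved_weight_matrix(net)
  st <- traj$state[, seq_along(net$ids), drop = FALSE]
  bind_rows(lapply(names(W), function(key) {
    tot <- as.numeric(st %*% W[[key]])
    t0 <- tot[[1L]]
    drift <- if (t0 > 0) max(abs(tot - t0)) / t0 else max(abs(tot))
    tibble(pool = key, total_initial = t0, max_rel_drift = drift)
  }))
}

# table of isolated reversible binding pairs A + B <-> C in a network,
# used by the equilibrium-fidelity checks
binding_pair_table <- function(net) {
  rx <- net$reactions
  fw <- rx[!is.na(rx$reactant2), ]
  out <- list()
  for (j in seq_len(nrow(fw))) {
    if (length(fw$products[[j]]) != 1L) next
    ia <- fw$reactant1[[j]]; ib <- fw$reactant2[[j]]; ic <- fw$products[[j]][[1L]]
    rev_hit <- which(rx$rule == fw$rule[[j]] & rx$reactant1 == ic &
                       is.na(rx$reactant2))
    if (!length(rev_hit)) next
    out[[length(out) + 1L]] <- tibble(
      rule = fw$rule[[j]], A = ia, B = ib, C = ic,
      kon = fw$rate[[j]], koff = rx$rate[[rev_hit[[1L]]]])
  }
  bind_rows(out)
}
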