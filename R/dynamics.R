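#' Continuous (mass-action) interpretation of a Petri net
#'
#' Reading a place/transition net as a continuous Petri net assigns every
#' transition the mass-action rate `k * prod(state[pre]^weight)`, where the
#' product runs over the consumed places and the read-arc side conditions;
#' each dynamic place then obeys `d m(p)/dt = sum_t C[p, t] * rate(t)`.
#' Fixed places (side conditions such as oxygen) are held constant; they
#' must have an all-zero incidence row.
#'
#' @param net A [petri_net()] (logical places merged).
#' @param rate_constants Named vector transition id -> rate constant;
#'   default: the constants stored on the transitions.
#' @param initial_marking Named vector place id -> concentration; default:
#'   the markings stored on the places.
#' @param fixed_places Place ids held constant during integration.
#' @return An object of class `pn_cmodel`.
#' @export
continuous_model <- function(net, rate_constants = NULL, initial_marking = NULL,
                             fixed_places = character()) {
  tid <- transition_ids(net); pid <- place_ids(net)
  k <- stats::setNames(vapply(net$transitions, `[[`, numeric(1), "rate"), tid)
  if (!is.null(rate_constants)) {
    bad <- setdiff(names(rate_constants), tid)
    if (length(bad) > 0L) stop("unknown transition(s): ", paste(bad, collapse = ", "))
    k[names(rate_constants)] <- rate_constants
  }
  if (any(k < 0)) stop("rate constants must be non-negative")
  m0 <- initial_marking(net)
  if (!is.null(initial_marking)) {
    bad <- setdiff(names(initial_marking), pid)
    if (length(bad) > 0L) stop("unknown place(s): ", paste(bad, collapse = ", "))
    m0[names(initial_marking)] <- initial_marking
  }
  if (any(m0 < 0)) stop("initial concentrations must be non-negative")
  bad <- setdiff(fixed_places, pid)
  if (length(bad) > 0L) stop("unknown fixed place(s): ", paste(bad, collapse = ", "))
  C <- incidence_matrix(net)
  nz <- fixed_places[vapply(fixed_places, function(p) any(C[p, ] != 0), logical(1))]
  if (length(nz) > 0L) {
    stop("fixed place(s) with non-zero incidence row: ", paste(nz, collapse = ", "))
  }
  # precompute per-transition rate factors (indices and powers)
  factors <- lapply(net$transitions, function(tr) {
    pre <- -tr$stoich[tr$stoich < 0]
    f <- c(pre, tr$read)
    list(idx = match(names(f), pid), pow = unname(f))
  })
  structure(list(net = net, rate_constants = k, initial = m0,
                 fixed_places = fixed_places, C = C, factors = factors),
            class = "pn_cmodel")
}

#' @export
print.pn_cmodel <- function(x, ...) {
  cat(sprintf("continuous mass-action model: %d species, %d reactions",
              length(x$initial), length(x$rate_constants)))
  if (length(x$fixed_places) > 0L) {
    cat(sprintf(" (fixed: %s)", paste(x$fixed_places, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Transition rates and state derivative
#'
#' @param model A [continuous_model()].
#' @param state Named non-negative state vector (place order of the net).
#' @return For `transition_rates()`, the named vector of mass-action rates;
#'   for `vector_field()`, the named derivative vector (zero on fixed
#'   places).
#' @export
vector_field <- function(model, state) {
  state <- state[place_ids(model$net)]
  if (any(state < -1e-9) || anyNA(state)) {
    stop("state must be non-negative over all places")
  }
  d <- as.numeric(model$C %*% transition_rates(model, state))
  names(d) <- rownames(model$C)
  d[model$fixed_places] <- 0
  d
}

#' @rdname vector_field
#' @export
transition_rates <- function(model, state) {
  state <- pmax(as.numeric(state[place_ids(model$net)]), 0)
  v <- model$rate_constants
  for (j in seq_along(v)) {
    f <- model$factors[[j]]
    if (length(f$idx) > 0L) v[j] <- v[j] * prod(state[f$idx]^f$pow)
  }
  v
}

.deriv_fn <- function(model) {
  fixed_idx <- match(model$fixed_places, place_ids(model$net))
  function(t, s, parms) {
    v <- model$rate_constants
    sp <- pmax(s, 0)
    for (j in seq_along(v)) {
      f <- model$factors[[j]]
      if (length(f$idx) > 0L) v[j] <- v[j] * prod(sp[f$idx]^f$pow)
    }
    d <- as.numeric(model$C %*% v)
    if (length(fixed_idx) > 0L) d[fixed_idx] <- 0
    list(d)
  }
}

#' Integrate a model to its steady state
#'
#' Stiff variable-step integration ([deSolve::lsodar()]) with a root
#' function that stops as soon as the maximum absolute derivative falls
#' below `dnorm_tol`; if the horizon `t_max` is reached first the
#' trajectory is returned with `converged = FALSE` (never silently).
#'
#' @param model A [continuous_model()].
#' @param t_max Integration horizon.
#' @param abs_tol,rel_tol Integrator error tolerances.
#' @param dnorm_tol Steady-state criterion on `max |dm/dt|`.
#' @param times Optional explicit output times (default: logarithmic grid).
#' @param seed Unused (the dynamics are deterministic); accepted for API
#'   uniformity with the stochastic entry points of related tools.
#' @return An object of class `pn_trajectory`: `times`, `states` (matrix
#'   places x times), `converged`, `final_derivative_norm`.
#' @export
simulate_to_steady_state <- function(model, t_max = 1e6, abs_tol = 1e-10,
                                     rel_tol = 1e-8, dnorm_tol = 1e-9,
                                     times = NULL, seed = NULL) {
  f <- .deriv_fn(model)
  y0 <- model$initial
  if (is.null(times)) {
    times <- unique(c(0, 10^seq(-2, log10(t_max), length.out = 120)))
  }
  root <- function(t, s, parms) max(abs(f(t, s, parms)[[1]])) - dnorm_tol
  if (root(0, y0, NULL) <= 0) {
    states <- matrix(y0, ncol = 1, dimnames = list(names(y0), NULL))
    return(structure(list(times = 0, states = states, converged = TRUE,
                          final_derivative_norm = max(abs(f(0, y0, NULL)[[1]]))),
                     class = "pn_trajectory"))
  }
  out <- deSolve::lsodar(y0, times = times, func = f, parms = NULL,
                         rootfunc = root, atol = abs_tol, rtol = rel_tol)
  tms <- out[, 1]
  states <- t(out[, -1, drop = FALSE])
  if (min(states) < -1e-6) {
    stop("integration produced negative concentrations beyond tolerance (min ",
         format(min(states)), ")")
  }
  states[states < 0] <- 0
  fin <- max(abs(f(tms[length(tms)], states[, ncol(states)], NULL)[[1]]))
  structure(list(times = tms, states = states,
                 converged = fin <= dnorm_tol * (1 + 1e-6),
                 final_derivative_norm = fin),
            class = "pn_trajectory")
}

#' @export
print.pn_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d species, %d time points, t in [%g, %g]\n",
              nrow(x$states), length(x$times), min(x$times), max(x$times)))
  cat(sprintf("converged: %s (max |dm/dt| = %.3g)\n",
              if (x$converged) "yes" else "NO",
              x$final_derivative_norm))
  invisible(x)
}

#' @export
as.data.frame.pn_trajectory <- function(x, ...) {
  data.frame(time = rep(x$times, each = nrow(x$states)),
             place = rep(rownames(x$states), times = length(x$times)),
             value = as.numeric(x$states), stringsAsFactors = FALSE)
}

#' Final (steady) state of a trajectory
#' @param traj A `pn_trajectory`.
#' @return Named state vector at the last time point.
#' @export
final_state <- function(traj) traj$states[, ncol(traj$states)]

#' Steady-state dose-response scan
#'
#' For each grid value the scanned (fixed) place is set to that
#' concentration, the model is integrated to steady state from its initial
#' marking, and the steady-state values (SSV) of the watched places are
#' recorded.
#'
#' @param model A [continuous_model()]; `scan_place` must be fixed.
#' @param scan_place Fixed place to titrate (e.g. oxygen).
#' @param grid Numeric vector of concentrations.
#' @param watch_places Places whose SSVs to record (default: all).
#' @param ... Passed to [simulate_to_steady_state()].
#' @return An object of class `pn_scan`: data.frame `values` (one row per
#'   grid point with a column per watched place and a `converged` flag),
#'   plus the model and scan metadata for later refinement.
#' @export
dose_response_scan <- function(model, scan_place, grid,
                               watch_places = place_ids(model$net), ...) {
  if (!(scan_place %in% model$fixed_places)) {
    stop("scan_place must be one of the model's fixed places")
  }
  bad <- setdiff(watch_places, place_ids(model$net))
  if (length(bad) > 0L) stop("unknown watch place(s): ", paste(bad, collapse = ", "))
  rows <- lapply(grid, function(g) {
    m <- model; m$initial[scan_place] <- g
    tr <- simulate_to_steady_state(m, ...)
    fs <- final_state(tr)
    c(stats::setNames(g, scan_place), fs[watch_places],
      converged = as.numeric(tr$converged))
  })
  values <- as.data.frame(do.call(rbind, rows))
  if (any(values$converged == 0)) {
    warning(sum(values$converged == 0), " grid point(s) did not converge")
  }
  structure(list(values = values, model = model, scan_place = scan_place,
                 watch_places = watch_places, sim_args = list(...)),
            class = "pn_scan")
}

#' @export
print.pn_scan <- function(x, ...) {
  cat(sprintf("dose-response scan over %s (%d points, watching %s)\n",
              x$scan_place, nrow(x$values),
              paste(x$watch_places, collapse = ", ")))
  invisible(x)
}

#' Critical concentration of a scanned side condition
#'
#' The smallest scan value at which the steady-state value of `place` falls
#' below `threshold` ("complete degradation"), refined by bisection between
#' the bracketing grid points. The hypoxic plateau of the packaged case
#' study is of order 1e2, hence the default threshold 1 (two orders of
#' magnitude below); the result is insensitive to the threshold across
#' roughly [0.5, 2.5] because the response collapses sharply at the switch.
#'
#' @param scan A [dose_response_scan()] result.
#' @param place Watched place.
#' @param threshold Absolute SSV threshold.
#' @param refine_tol Bisection stops when the bracket is narrower than this.
#' @return The critical concentration, or `NA` (no-switch sentinel) when
#'   the SSV never falls below `threshold` on the grid — the signature of a
#'   disabled switch (e.g. a PHD knock-out in the hypoxia net).
#' @export
critical_concentration <- function(scan, place, threshold = 1,
                                   refine_tol = 1e-3) {
  stopifnot(inherits(scan, "pn_scan"))
  if (!(place %in% scan$watch_places)) stop("place not watched in this scan")
  v <- scan$values
  below <- which(v[[place]] < threshold)
  if (length(below) == 0L) return(NA_real_)
  i <- min(below)
  if (i == 1L) return(v[[scan$scan_place]][1])
  lo <- v[[scan$scan_place]][i - 1L]; hi <- v[[scan$scan_place]][i]
  ssv_at <- function(g) {
    m <- scan$model; m$initial[scan$scan_place] <- g
    final_state(do.call(simulate_to_steady_state, c(list(m), scan$sim_args)))[[place]]
  }
  while (hi - lo > refine_tol) {
    mid <- (lo + hi) / 2
    if (ssv_at(mid) < threshold) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Perturb a continuous model
#'
#' Builds a new model (the input is untouched) implementing the knock-out
#' and titration experiments used to probe the network:
#' \describe{
#'   \item{`silence_transitions`}{set the rate constants of the given
#'     transitions to zero;}
#'   \item{`set_initial`}{named vector of new initial concentrations;}
#'   \item{`restrict_to_invariant`}{keep only the transitions in the support
#'     of the given T-invariant (all other rates zeroed), isolating one
#'     pathway;}
#'   \item{`set_pinvariant_mass_zero`}{zero the initial concentration of
#'     every place in the support of the given P-invariant, switching that
#'     conserved pool off.}
#' }
#' Invariants may be passed as a support character vector, or as
#' `list(invs, index)`.
#'
#' @param model A [continuous_model()].
#' @param silence_transitions Transition ids, or `NULL`.
#' @param set_initial Named numeric vector, or `NULL`.
#' @param restrict_to_invariant T-invariant support (see above), or `NULL`.
#' @param set_pinvariant_mass_zero P-invariant support, or `NULL`.
#' @return A new `pn_cmodel`.
#' @export
apply_perturbation <- function(model, silence_transitions = NULL,
                               set_initial = NULL,
                               restrict_to_invariant = NULL,
                               set_pinvariant_mass_zero = NULL) {
  stopifnot(inherits(model, "pn_cmodel"))
  tid <- names(model$rate_constants); pid <- names(model$initial)
  if (!is.null(silence_transitions)) {
    bad <- setdiff(silence_transitions, tid)
    if (length(bad) > 0L) stop("unknown transition(s): ", paste(bad, collapse = ", "))
    model$rate_constants[silence_transitions] <- 0
  }
  if (!is.null(restrict_to_invariant)) {
    supp <- .support_arg(restrict_to_invariant)
    bad <- setdiff(supp, tid)
    if (length(bad) > 0L) stop("unknown transition(s): ", paste(bad, collapse = ", "))
    model$rate_constants[setdiff(tid, supp)] <- 0
  }
  if (!is.null(set_pinvariant_mass_zero)) {
    supp <- .support_arg(set_pinvariant_mass_zero)
    bad <- setdiff(supp, pid)
    if (length(bad) > 0L) stop("unknown place(s): ", paste(bad, collapse = ", "))
    model$initial[supp] <- 0
  }
  if (!is.null(set_initial)) {
    bad <- setdiff(names(set_initial), pid)
    if (length(bad) > 0L) stop("unknown place(s): ", paste(bad, collapse = ", "))
    model$initial[names(set_initial)] <- set_initial
  }
  model
}

.support_arg <- function(x) {
  if (is.character(x)) return(x)
  if (is.list(x) && inherits(x$invs, "pn_invariant_set")) {
    W <- x$invs$weights
    return(colnames(W)[W[x$index, ] > 0])
  }
  stop("invariant argument must be a support character vector or list(invs, index)")
}
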