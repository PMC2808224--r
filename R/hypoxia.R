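#' The hypoxia-response network fixture
#'
#' The packaged case study: the HIF degradation switch. HIF is produced
#' constitutively and degraded through three routes — a slow
#' oxygen-independent route, and two oxygen-dependent routes in which HIF
#' (directly, or bound to its nuclear partner ARNT) is captured by the
#' prolyl hydroxylase PHD, hydroxylated in the presence of oxygen, and
#' finally ubiquitinated by VHL. Below a critical oxygen concentration HIF
#' accumulates (hypoxia); above it HIF is completely degraded (normoxia).
#'
#' `hypoxia_reactions()` returns the 12-reaction list (7 reversible),
#' `hypoxia_parameters()` the rate-constant/initial-marking file,
#' `build_full_hypoxia_net()` the expanded 14-place / 19-transition net,
#' and `hypoxia_model()` the continuous mass-action model with oxygen as a
#' fixed side condition.
#'
#' @param hif0 Initial HIF concentration, 5 by default; 0 yields the same
#'   steady states (HIF is not covered by any P-invariant and sits in no
#'   structural deadlock among the initially empty places).
#' @param o2 Fixed oxygen concentration for [hypoxia_model()].
#' @return See above.
#' @name hypoxia_case
NULL

.hypoxia_file <- function(which) {
  system.file("extdata", which, package = "petristruct", mustWork = TRUE)
}

#' @rdname hypoxia_case
#' @export
hypoxia_reactions <- function() {
  parse_net(.hypoxia_file("hypoxia_reactions.txt"), format = "dsl")
}

#' @rdname hypoxia_case
#' @export
hypoxia_parameters <- function() {
  read_params(.hypoxia_file("hypoxia_params.toml"))
}

#' @rdname hypoxia_case
#' @export
build_full_hypoxia_net <- function(hif0 = 5) {
  pars <- hypoxia_parameters()
  net <- expand_reversible(hypoxia_reactions(), provenance = "hypoxia response network")
  # oxygen is referenced only by read arcs; give it an explicit place entry
  stopifnot("O2" %in% place_ids(net))
  init <- unlist(pars$initial)
  init["HIF"] <- hif0
  net <- set_marking(net, init)
  rates <- unlist(pars$rates)
  for (i in seq_along(net$transitions)) {
    id <- net$transitions[[i]]$id
    if (!(id %in% names(rates))) stop("no rate constant mapped for '", id, "'")
    net$transitions[[i]]$rate <- rates[[id]]
  }
  net
}

#' @rdname hypoxia_case
#' @export
hypoxia_model <- function(hif0 = 5, o2 = 0) {
  net <- build_full_hypoxia_net(hif0 = hif0)
  continuous_model(net, initial_marking = c(O2 = o2), fixed_places = "O2")
}

#' Core (reduced) hypoxia model
#'
#' Runs the T-invariant analysis on the full net, removes every transition
#' not covered by a non-trivial invariant (and the places isolated by
#' that), and returns the continuous model of the resulting 10-reaction
#' core.
#'
#' @inheritParams hypoxia_case
#' @return A `pn_cmodel` over the core net.
#' @export
hypoxia_core_model <- function(hif0 = 5, o2 = 0) {
  net <- build_full_hypoxia_net(hif0 = hif0)
  tinv <- classify_t_invariants(net, minimal_invariants(net, "T"))
  core <- reduce_to_core(net, tinv)$core_net
  continuous_model(core, initial_marking = c(O2 = o2), fixed_places = "O2")
}

#' The three degradation pathways of the hypoxia net
#'
#' Support sets of the three non-trivial T-invariants: `P1` the
#' oxygen-independent route, `P2` the direct PHD route, `P3` the
#' ARNT-complexed route.
#'
#' @return Named list of transition-id vectors.
#' @export
hypoxia_pathways <- function() {
  net <- build_full_hypoxia_net()
  tinv <- classify_t_invariants(net, minimal_invariants(net, "T"))
  supp <- invariant_supports(nontrivial(tinv))
  supp <- supp[order(vapply(supp, length, integer(1)))]
  stats::setNames(supp, paste0("P", seq_along(supp)))
}

#' Run one of the five validation experiments
#'
#' Reproduces the numerical experiments that validate the structural
#' reduction of the hypoxia network:
#' \describe{
#'   \item{1}{step-wise silencing from the full model to the core: first
#'     the HRE subsystem (`r6`, `r12`, both directions), then the remaining
#'     backward reactions (`r3_b`; `r5_b` with `r9_f`; `r7_b`; `r10_b`),
#'     scanning oxygen after every stage;}
#'   \item{2}{each pathway `P1`/`P2`/`P3` in isolation;}
#'   \item{3}{pathway `P3` alone while titrating the ARNT pool (5, 10, 100);}
#'   \item{4}{the core model across ARNT pools (0, 5, 1000 ... 4500) plus
#'     the full model for comparison;}
#'   \item{5}{the core model across PHD pools including the knock-out 0.}
#' }
#'
#' @param n Experiment number 1-5.
#' @param grid Oxygen grid for the scans; experiments probing the less
#'   efficient ARNT pathway default to an extended grid internally when
#'   `grid` is `NULL`.
#' @param threshold Complete-degradation threshold for the critical oxygen
#'   concentration (see [critical_concentration()]).
#' @param hif0 Initial HIF concentration.
#' @param ... Passed to [simulate_to_steady_state()].
#' @return An object of class `pn_experiment`: `experiment`, a named list
#'   of `pn_scan`s (`scans`), and a `summary` data.frame with one row per
#'   condition (`ssv_at_zero`, `critical`, `switch_present`).
#' @export
run_experiment <- function(n, grid = NULL, threshold = 1, hif0 = 5, ...) {
  stopifnot(n %in% 1:5)
  full <- hypoxia_model(hif0 = hif0)
  paths <- hypoxia_pathways()
  default_grid <- if (is.null(grid)) seq(0, 1, by = 0.01) else grid
  wide_grid <- if (is.null(grid)) seq(0, 2.5, by = 0.025) else grid
  scans <- list()
  if (n == 1L) {
    stages <- list(
      full = character(0),
      no_HRE = c("r6_f", "r6_b", "r12_f", "r12_b"),
      no_r3b = c("r3_b"),
      no_ARNT_back = c("r5_b", "r9_f"),
      no_r7b = c("r7_b"),
      core = c("r10_b"))
    silenced <- character(0)
    for (s in names(stages)) {
      silenced <- c(silenced, stages[[s]])
      m <- apply_perturbation(full, silence_transitions = silenced)
      scans[[s]] <- dose_response_scan(m, "O2", default_grid, "HIF", ...)
    }
  } else if (n == 2L) {
    for (p in names(paths)) {
      m <- apply_perturbation(full, restrict_to_invariant = paths[[p]])
      scans[[p]] <- dose_response_scan(m, "O2", wide_grid, "HIF", ...)
    }
  } else if (n == 3L) {
    for (a in c(5, 10, 100)) {
      m <- apply_perturbation(full, restrict_to_invariant = paths$P3,
                              set_initial = c(ARNT = a))
      scans[[paste0("ARNT_", a)]] <- dose_response_scan(m, "O2", wide_grid, "HIF", ...)
    }
  } else if (n == 4L) {
    core <- hypoxia_core_model(hif0 = hif0)
    for (a in c(0, 5, 1000, 2000, 3000, 4500)) {
      m <- apply_perturbation(core, set_initial = c(ARNT = a))
      scans[[paste0("core_ARNT_", a)]] <- dose_response_scan(m, "O2", default_grid, "HIF", ...)
    }
    scans[["full"]] <- dose_response_scan(full, "O2", default_grid, "HIF", ...)
  } else {
    core <- hypoxia_core_model(hif0 = hif0)
    for (p in c(0, 5, 10, 20)) {
      m <- apply_perturbation(core, set_initial = c(PHD = p))
      scans[[paste0("PHD_", p)]] <- dose_response_scan(m, "O2", wide_grid, "HIF", ...)
    }
  }
  summary <- do.call(rbind, lapply(names(scans), function(nm) {
    sc <- scans[[nm]]
    crit <- critical_concentration(sc, "HIF", threshold = threshold)
    data.frame(condition = nm,
               ssv_at_zero = sc$values$HIF[which.min(sc$values$O2)],
               critical = crit, switch_present = !is.na(crit),
               stringsAsFactors = FALSE)
  }))
  structure(list(experiment = n, scans = scans, summary = summary),
            class = "pn_experiment")
}

#' @export
print.pn_experiment <- function(x, ...) {
  cat("hypoxia validation experiment", x$experiment, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
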