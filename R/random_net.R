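#' Random mass-action Petri net
#'
#' Reproducible generator for property tests and oracle comparisons: a
#' bipartite net with the stated numbers of places and transitions, arc
#' weights in {1, 2}, optional reversible pairs (mirrored stoichiometry,
#' linked through `reverse_of`) and optional read arcs, plus uniform random
#' rate constants. The same seed always yields the same net; the global RNG
#' state is left untouched.
#'
#' @param n_places,n_transitions Positive sizes; `n_transitions` counts all
#'   transitions (a reversible twin is only added while it fits).
#' @param seed Integer seed.
#' @param p_reversible Probability that a transition spawns its reverse.
#' @param p_read Probability of adding a read arc to a transition.
#' @param max_arcs Maximal number of consumed and of produced places per
#'   transition.
#' @return A [petri_net()].
#' @export
random_massaction_net <- function(n_places, n_transitions, seed,
                                  p_reversible = 0.3, p_read = 0.15,
                                  max_arcs = 2L) {
  stopifnot(n_places >= 1L, n_transitions >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  pid <- paste0("p", seq_len(n_places))
  places <- lapply(pid, function(p) place(p, initial_marking = stats::runif(1, 0, 5)))
  transitions <- list(); i <- 0L
  while (length(transitions) < n_transitions) {
    i <- i + 1L
    id <- paste0("t", i)
    npre <- sample.int(max_arcs, 1L)
    npost <- sample.int(max_arcs, 1L)
    pre <- sample(pid, min(npre, n_places))
    post <- sample(pid, min(npost, n_places))
    st <- stats::setNames(numeric(0), character(0))
    for (p in pre) st[p] <- (if (p %in% names(st)) st[[p]] else 0) - sample(1:2, 1L)
    for (p in post) st[p] <- (if (p %in% names(st)) st[[p]] else 0) + sample(1:2, 1L)
    st <- st[st != 0]
    rd <- stats::setNames(numeric(0), character(0))
    free <- setdiff(pid, names(st))
    if (length(free) > 0L && stats::runif(1) < p_read) {
      rd[sample(free, 1L)] <- 1
    }
    if (length(st) == 0L && length(rd) == 0L) next
    k1 <- stats::runif(1, 0.01, 1)
    if (stats::runif(1) < p_reversible && length(transitions) + 2L <= n_transitions &&
        length(st) > 0L) {
      k2 <- stats::runif(1, 0.01, 1)
      fid <- paste0(id, "_f"); bid <- paste0(id, "_b")
      transitions <- c(transitions, list(
        transition(fid, st, rd, reverse_of = bid, rate_constant = k1),
        transition(bid, -st, rd, reverse_of = fid, rate_constant = k2)))
    } else {
      transitions <- c(transitions, list(transition(id, st, rd, rate_constant = k1)))
    }
  }
  petri_net(places, transitions,
            provenance = sprintf("random net (seed %d)", seed))
}
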