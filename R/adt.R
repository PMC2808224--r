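#' Abstract dependent transition (ADT) partition
#'
#' Two transitions depend on each other when they occur together in every
#' invariant of the chosen T-invariant basis; the relation is an equivalence
#' on the transition set. Each transition's signature is the set of basis
#' invariants containing it; the ADT classes are the fibres of the signature
#' map. Transitions occurring in no basis invariant share the
#' empty-signature class.
#'
#' @param net A [petri_net()].
#' @param t_invs A `pn_invariant_set` of kind `"T"` (the basis), e.g. the
#'   non-trivial subset obtained with [nontrivial()].
#' @return An object of class `pn_adt_partition`: list of classes, each
#'   `list(transitions, signature)`, in canonical order (signature size
#'   descending, then lexicographic first member); plus the basis indices.
#' @export
adt_partition <- function(net, t_invs) {
  stopifnot(inherits(t_invs, "pn_invariant_set"), t_invs$kind == "T")
  tid <- transition_ids(net)
  if (length(tid) == 0L) stop("net has no transitions")
  W <- t_invs$weights
  sig <- lapply(tid, function(t) {
    if (nrow(W) == 0L || !(t %in% colnames(W))) return(integer(0))
    which(W[, t] > 0)
  })
  key <- vapply(sig, function(s) paste(s, collapse = ","), character(1))
  classes <- lapply(split(seq_along(tid), key), function(ix) {
    list(transitions = tid[ix], signature = sig[[ix[1]]])
  })
  nsig <- vapply(classes, function(cl) length(cl$signature), integer(1))
  first <- vapply(classes, function(cl) cl$transitions[1], character(1))
  classes <- classes[order(-nsig, first)]
  names(classes) <- NULL
  structure(list(classes = classes, basis = t_invs),
            class = "pn_adt_partition")
}

#' Subset an invariant set to its non-trivial members
#' @param t_invs A classified T-invariant set.
#' @return A `pn_invariant_set` holding the non-trivial invariants only.
#' @export
nontrivial <- function(t_invs) {
  stopifnot(inherits(t_invs, "pn_invariant_set"), t_invs$kind == "T")
  if (anyNA(t_invs$trivial)) stop("classify_t_invariants() first")
  keep <- !t_invs$trivial
  structure(list(kind = "T", weights = t_invs$weights[keep, , drop = FALSE],
                 trivial = t_invs$trivial[keep]),
            class = "pn_invariant_set")
}

#' @export
print.pn_adt_partition <- function(x, ...) {
  cat(sprintf("ADT partition: %d class(es) over %d basis invariant(s)\n",
              length(x$classes), nrow(x$basis$weights)))
  for (i in seq_along(x$classes)) {
    cl <- x$classes[[i]]
    cat(sprintf("  [%d] {%s}  signature {%s}\n", i,
                paste(cl$transitions, collapse = ", "),
                paste(cl$signature, collapse = ",")))
  }
  invisible(x)
}

#' Direct pairwise dependency test
#'
#' Decides whether two transitions co-occur in every T-invariant without
#' enumerating the minimal invariants: the pair is dependent iff neither of
#' the two one-sided systems `{C x = 0, x >= 0, x[t1] >= 1, x[t2] = 0}` and
#' its mirror is feasible. Feasibility is decided exactly over the
#' rationals: a fraction-free Gaussian elimination yields an integer basis
#' of the kernel of `C` (with the `t2` column removed), and Fourier-Motzkin
#' elimination settles whether the non-negativity cone of that kernel
#' contains a point with `x[t1] >= 1`. Because the feasibility systems
#' range over all T-invariants, this is a full-basis test; restriction to
#' the non-trivial basis goes through [adt_partition()] signatures.
#'
#' @param C Incidence matrix (places x transitions) with column names, or a
#'   [petri_net()].
#' @param t1,t2 Distinct transition ids.
#' @return `TRUE` if the two transitions depend on each other over the full
#'   minimal T-invariant basis.
#' @export
pair_dependent_direct <- function(C, t1, t2) {
  if (inherits(C, "petri_net")) C <- incidence_matrix(C)
  if (t1 == t2) stop("t1 and t2 must be distinct")
  tid <- colnames(C)
  if (!all(c(t1, t2) %in% tid)) stop("unknown transition id")
  !.one_sided_feasible(C, t1, t2) && !.one_sided_feasible(C, t2, t1)
}

# feasibility of {C x = 0, x >= 0, x[a] >= 1, x[b] = 0}
.one_sided_feasible <- function(C, a, b) {
  keep <- setdiff(colnames(C), b)        # x[b] = 0: drop the variable
  Cr <- unname(C[, keep, drop = FALSE])
  N <- .int_nullspace(Cr)                # x = N %*% z spans {Cr x = 0}
  if (ncol(N) == 0L) return(FALSE)       # kernel is {0}: x[a] >= 1 impossible
  ia <- match(a, keep)
  # rows of N z >= 0 (componentwise), plus (N z)[a] >= 1
  A <- rbind(N, N[ia, , drop = FALSE])
  bvec <- c(rep(0, nrow(N)), 1)
  .fm_feasible(A, bvec)
}

# Integer basis of {x : M x = 0} by fraction-free (Bareiss-style) Gaussian
# elimination; columns of the result span the kernel over the rationals.
.int_nullspace <- function(M) {
  A <- as.matrix(M); n <- ncol(A)
  r <- 0L; pivcols <- integer(0)
  for (col in seq_len(n)) {
    piv <- which(A[, col] != 0)
    piv <- piv[piv > r]
    if (length(piv) == 0L) next
    r <- r + 1L
    if (piv[1] != r) { tmp <- A[r, ]; A[r, ] <- A[piv[1], ]; A[piv[1], ] <- tmp }
    pivcols <- c(pivcols, col)
    for (i in seq_len(nrow(A))) {
      if (i != r && A[i, col] != 0) {
        A[i, ] <- A[i, ] * A[r, col] - A[r, ] * A[i, col]
        g <- .gcd_vec(A[i, ])
        if (g > 1) A[i, ] <- A[i, ] / g
      }
    }
  }
  free <- setdiff(seq_len(n), pivcols)
  if (length(free) == 0L) return(matrix(0, nrow = n, ncol = 0))
  N <- matrix(0, nrow = n, ncol = length(free))
  for (fi in seq_along(free)) {
    f <- free[fi]
    pivvals <- vapply(seq_along(pivcols), function(j) A[j, pivcols[j]], numeric(1))
    L <- Reduce(function(a, b) a * b / .gcd2(a, b), abs(pivvals), accumulate = FALSE)
    if (length(pivcols) == 0L) L <- 1
    N[f, fi] <- L
    for (j in seq_along(pivcols)) {
      N[pivcols[j], fi] <- -A[j, f] * L / A[j, pivcols[j]]
    }
    g <- .gcd_vec(N[, fi])
    if (g > 1) N[, fi] <- N[, fi] / g
  }
  N
}

# Is {z : A z >= b} non-empty?  Exact integer Fourier-Motzkin elimination.
.fm_feasible <- function(A, b, max_rows = 1e5) {
  rows <- cbind(A, b)
  k <- ncol(A)
  norm_rows <- function(R) {
    if (nrow(R) == 0L) return(R)
    g <- apply(R, 1L, .gcd_vec)
    g[g == 0] <- 1
    unique(R / g)
  }
  rows <- norm_rows(rows)
  for (j in seq_len(k)) {
    cj <- rows[, j]
    zer <- rows[cj == 0, , drop = FALSE]
    pos <- rows[cj > 0, , drop = FALSE]    # lower bounds on z_j
    neg <- rows[cj < 0, , drop = FALSE]    # upper bounds on z_j
    new <- zer
    if (nrow(pos) > 0L && nrow(neg) > 0L) {
      if (nrow(zer) + nrow(pos) * nrow(neg) > max_rows) {
        stop("Fourier-Motzkin feasibility test exceeded ", max_rows, " rows")
      }
      for (u in seq_len(nrow(pos))) {
        p <- pos[u, j]
        for (l in seq_len(nrow(neg))) {
          q <- -neg[l, j]
          g <- .gcd2(p, q)
          new <- rbind(new, (q / g) * pos[u, ] + (p / g) * neg[l, ])
        }
      }
    }
    rows <- norm_rows(new)
    if (nrow(rows) == 0L) return(TRUE)     # no constraints left
  }
  all(rows[, k + 1] <= 0)                  # rows now read 0 >= b'
}

#' Decompose ADT classes into connected classes
#'
#' Maximal ADT sets need not induce connected subnets; coarsening requires
#' connected ones. Each class is split into the connected components of the
#' subnet induced by its transitions (the transitions, all adjacent places
#' including read-arc neighbours, and the arcs between them).
#'
#' @param net A [petri_net()].
#' @param partition A `pn_adt_partition` of this net.
#' @return A `pn_adt_partition` whose classes all induce connected subnets.
#' @export
connected_adt_decomposition <- function(net, partition) {
  stopifnot(inherits(partition, "pn_adt_partition"))
  tid <- transition_ids(net)
  adj <- stats::setNames(lapply(net$transitions, function(tr)
    c(names(tr$stoich), names(tr$read))), tid)
  out <- list()
  for (cl in partition$classes) {
    comps <- .connected_components(cl$transitions, adj)
    for (cc in comps) {
      out[[length(out) + 1L]] <- list(transitions = cc, signature = cl$signature)
    }
  }
  nsig <- vapply(out, function(cl) length(cl$signature), integer(1))
  first <- vapply(out, function(cl) cl$transitions[1], character(1))
  out <- out[order(-nsig, first)]
  structure(list(classes = out, basis = partition$basis),
            class = "pn_adt_partition")
}

# connected components of a transition set under shared-place adjacency
.connected_components <- function(ts, adj) {
  comps <- list(); left <- ts
  while (length(left) > 0L) {
    comp <- left[1]; frontier <- comp
    repeat {
      pls <- unique(unlist(adj[frontier]))
      nxt <- setdiff(left[vapply(adj[left], function(a) any(a %in% pls), logical(1))],
                     comp)
      if (length(nxt) == 0L) break
      comp <- c(comp, nxt); frontier <- nxt
    }
    comps[[length(comps) + 1L]] <- ts[ts %in% comp]
    left <- setdiff(left, comp)
  }
  comps
}
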