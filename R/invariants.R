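#' Minimal semi-positive P- and T-invariants
#'
#' A P-invariant is a non-zero, non-negative integer place vector `y` with
#' `t(y) %*% C = 0`; a T-invariant a non-zero, non-negative integer
#' transition vector `x` with `C %*% x = 0`, where `C` is the incidence
#' matrix. The set of minimal invariants (support containing no other
#' invariant's support, entries with gcd 1) is unique and generates every
#' semi-positive invariant by non-negative combination.
#'
#' The computation is exact integer Fourier-Motzkin (Farkas) elimination on
#' the tableau `[Cᵀ | I]` (P) or `[C | I]` (T): constraint rows are
#' eliminated one at a time by non-negative combination of oppositely signed
#' tableau rows; rows whose annotation support strictly contains another
#' row's support are discarded at every step; results are divided by their
#' gcd and returned in canonical order (sorted by support).
#'
#' @param net A [petri_net()] or an incidence matrix with dimnames.
#' @param kind `"P"` for place invariants, `"T"` for transition invariants.
#' @param max_rows Guard against intermediate tableau blow-up (the number of
#'   minimal invariants is exponential in the worst case); exceeding it is
#'   an error.
#' @return An object of class `pn_invariant_set`: a list with `kind`, the
#'   integer `weights` matrix (one row per invariant, columns = node ids in
#'   net order), and for T-invariants a `trivial` flag vector (filled by
#'   [classify_t_invariants()]). `as.data.frame()` gives a one-row-per-
#'   invariant table.
#' @export
minimal_invariants <- function(net, kind = c("P", "T"), max_rows = 1e6) {
  kind <- match.arg(kind)
  C <- if (inherits(net, "petri_net")) incidence_matrix(net) else as.matrix(net)
  if (is.null(dimnames(C))) {
    dimnames(C) <- list(paste0("p", seq_len(nrow(C))), paste0("t", seq_len(ncol(C))))
  }
  M <- if (kind == "P") t(C) else C      # constraints x variables
  ids <- if (kind == "P") rownames(C) else colnames(C)
  W <- .farkas_minimal(M, max_rows = max_rows)
  colnames(W) <- ids
  structure(list(kind = kind, weights = W,
                 trivial = rep(NA, nrow(W))),
            class = "pn_invariant_set")
}

# Minimal-support non-negative integer solutions of M %*% x == 0 (exact
# integer arithmetic; rows are annotation vectors of the identity part).
.farkas_minimal <- function(M, max_rows = 1e6) {
  n <- ncol(M); k <- nrow(M)
  if (n == 0L) return(matrix(numeric(0), nrow = 0, ncol = 0))
  tab <- cbind(t(M), diag(n))            # n rows: [constraint values | e_i]
  remaining <- seq_len(k)
  while (length(remaining) > 0L) {
    # heuristic: eliminate the constraint creating fewest new rows
    npos <- colSums(tab[, remaining, drop = FALSE] > 0)
    nneg <- colSums(tab[, remaining, drop = FALSE] < 0)
    j <- remaining[which.min(npos * nneg)]
    col <- tab[, j]
    zero <- which(col == 0); pos <- which(col > 0); neg <- which(col < 0)
    new <- tab[zero, , drop = FALSE]
    if (length(pos) > 0L && length(neg) > 0L) {
      if (nrow(new) + length(pos) * length(neg) > max_rows) {
        stop("invariant computation exceeded max_rows = ", max_rows,
             " intermediate rows; the minimal generating set may be ",
             "exponentially large for this net")
      }
      combs <- matrix(0, nrow = length(pos) * length(neg), ncol = ncol(tab))
      r <- 0L
      for (a in pos) for (b in neg) {
        g <- .gcd2(col[a], -col[b])
        r <- r + 1L
        combs[r, ] <- (-col[b] / g) * tab[a, ] + (col[a] / g) * tab[b, ]
      }
      new <- rbind(new, combs)
    }
    # normalize by gcd and prune rows with non-minimal annotation support
    if (nrow(new) > 0L) {
      g <- apply(new, 1L, .gcd_vec)
      new <- new / g
      new <- .prune_support(new, new[, k + seq_len(n), drop = FALSE])
    }
    tab <- new
    remaining <- setdiff(remaining, j)
    if (nrow(tab) == 0L) break
  }
  if (nrow(tab) == 0L) return(matrix(numeric(0), nrow = 0, ncol = n))
  W <- tab[, k + seq_len(n), drop = FALSE]
  W <- unique(W)
  # canonical order: by support pattern, most significant = first node
  ord <- do.call(order, c(as.data.frame(-(W > 0)), as.data.frame(W)))
  W[ord, , drop = FALSE]
}

# drop rows whose support strictly contains another row's support,
# and duplicate rows (equal after gcd normalization)
.prune_support <- function(rows, ann) {
  if (nrow(rows) <= 1L) return(rows)
  supp <- (ann > 0) * 1
  sz <- rowSums(supp)
  # containment: supp_j subset of supp_i  <=>  (supp %*% t(supp))[i,j] == sz[j]
  inter <- tcrossprod(supp)
  keep <- rep(TRUE, nrow(rows))
  o <- order(sz)
  for (jj in seq_along(o)) {
    j <- o[jj]
    if (!keep[j]) next
    dominated <- which(keep & inter[, j] == sz[j])
    dominated <- dominated[dominated != j]
    for (i in dominated) {
      if (sz[i] > sz[j]) {
        keep[i] <- FALSE
      } else if (sz[i] == sz[j] && i > j && all(rows[i, ] == rows[j, ])) {
        keep[i] <- FALSE    # exact duplicate
      }
    }
  }
  rows[keep, , drop = FALSE]
}

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { tmp <- a %% b; a <- b; b <- tmp }
  a
}

.gcd_vec <- function(v) {
  v <- abs(v[v != 0])
  if (length(v) == 0L) return(1)
  Reduce(.gcd2, v)
}

#' @export
print.pn_invariant_set <- function(x, ...) {
  cat(sprintf("%d minimal %s-invariant(s)\n", nrow(x$weights), x$kind))
  if (nrow(x$weights) > 0L) print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.pn_invariant_set <- function(x, ...) {
  W <- x$weights
  if (nrow(W) == 0L) {
    return(data.frame(id = character(0), trivial = logical(0),
                      size = integer(0), support = character(0)))
  }
  supp <- apply(W, 1L, function(w) paste(colnames(W)[w > 0], collapse = ","))
  wtxt <- apply(W, 1L, function(w) {
    nz <- which(w > 0)
    paste(sprintf("%s:%d", colnames(W)[nz], as.integer(w[nz])), collapse = " ")
  })
  data.frame(id = paste0(tolower(x$kind), seq_len(nrow(W))),
             trivial = x$trivial, size = as.integer(rowSums(W > 0)),
             support = supp, weights = wtxt, stringsAsFactors = FALSE)
}

#' Supports of an invariant set
#' @param invs A `pn_invariant_set`.
#' @return List of character vectors (node ids with positive weight).
#' @export
invariant_supports <- function(invs) {
  W <- invs$weights
  lapply(seq_len(nrow(W)), function(i) colnames(W)[W[i, ] > 0])
}

#' Classify T-invariants as trivial or non-trivial
#'
#' A trivial T-invariant is the pair of transitions modeling the two
#' directions of one reversible reaction, with weights (1, 1). The decision
#' is purely structural (via the `reverse_of` links). A reverse pair whose
#' dissociation direction additionally occurs inside a non-trivial invariant
#' contributes to the net's I/O behavior; such pairs are reported in the
#' `io_contributing_pairs` attribute rather than by changing the count,
#' since reduction semantics depend only on non-trivial coverage.
#'
#' @param net The [petri_net()] the invariants were computed from.
#' @param invs A `pn_invariant_set` of kind `"T"`.
#' @return `invs` with the `trivial` flags filled in.
#' @export
classify_t_invariants <- function(net, invs) {
  if (!inherits(invs, "pn_invariant_set") || invs$kind != "T") {
    stop("classify_t_invariants() expects a T-invariant set")
  }
  W <- invs$weights
  tid <- transition_ids(net)
  rev <- stats::setNames(vapply(net$transitions, `[[`, character(1), "reverse_of"), tid)
  trivial <- vapply(seq_len(nrow(W)), function(i) {
    s <- colnames(W)[W[i, ] > 0]
    length(s) == 2L && all(W[i, s] == 1) &&
      !is.na(rev[[s[1]]]) && rev[[s[1]]] == s[2]
  }, logical(1))
  invs$trivial <- trivial
  # annotation: trivial pairs with a member inside some non-trivial support
  nontriv_support <- colnames(W)[colSums(W[!trivial, , drop = FALSE] > 0) > 0]
  io <- vapply(seq_len(nrow(W)), function(i) {
    trivial[i] && any(colnames(W)[W[i, ] > 0] %in% nontriv_support)
  }, logical(1))
  attr(invs, "io_contributing_pairs") <- which(io)
  invs
}

#' Coverage report (CPI / CTI / SCTI)
#'
#' A net is covered by P-invariants (CPI) if every place belongs to some
#' P-invariant, covered by T-invariants (CTI) if every transition belongs to
#' some T-invariant, and strongly covered (SCTI) if every transition belongs
#' to a non-trivial T-invariant.
#'
#' @param net A [petri_net()].
#' @param p_invs,t_invs Invariant sets of the net; `t_invs` must have been
#'   through [classify_t_invariants()].
#' @return An object of class `pn_coverage` with fields `cpi`, `cti`,
#'   `scti`, `uncovered_places`, `uncovered_transitions`,
#'   `uncovered_by_nontrivial`.
#' @export
coverage_report <- function(net, p_invs, t_invs) {
  stopifnot(p_invs$kind == "P", t_invs$kind == "T")
  if (anyNA(t_invs$trivial)) t_invs <- classify_t_invariants(net, t_invs)
  pid <- place_ids(net); tid <- transition_ids(net)
  pcov <- colnames(p_invs$weights)[colSums(p_invs$weights > 0) > 0]
  tcov <- colnames(t_invs$weights)[colSums(t_invs$weights > 0) > 0]
  Wn <- t_invs$weights[!t_invs$trivial, , drop = FALSE]
  ncov <- colnames(Wn)[colSums(Wn > 0) > 0]
  up <- setdiff(pid, pcov); ut <- setdiff(tid, tcov); un <- setdiff(tid, ncov)
  structure(list(cpi = length(up) == 0L, cti = length(ut) == 0L,
                 scti = length(un) == 0L,
                 uncovered_places = up, uncovered_transitions = ut,
                 uncovered_by_nontrivial = un),
            class = "pn_coverage")
}

#' @export
print.pn_coverage <- function(x, ...) {
  yn <- function(b) if (b) "yes" else "no"
  cat("covered by P-invariants (CPI): ", yn(x$cpi), "\n", sep = "")
  if (!x$cpi) cat("  uncovered places: ", paste(x$uncovered_places, collapse = ", "), "\n", sep = "")
  cat("covered by T-invariants (CTI): ", yn(x$cti), "\n", sep = "")
  if (!x$cti) cat("  uncovered transitions: ", paste(x$uncovered_transitions, collapse = ", "), "\n", sep = "")
  cat("strongly covered (SCTI):       ", yn(x$scti), "\n", sep = "")
  if (!x$scti) cat("  not in any non-trivial T-invariant: ",
                   paste(x$uncovered_by_nontrivial, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Largest structural deadlock within a place set
#'
#' A non-empty place set is a structural deadlock (siphon) if every
#' transition producing into the set also consumes from it; once such a set
#' is empty it can never be marked again. This computes the greatest
#' fixpoint inside `place_set`: any place with a producing transition that
#' does not consume from the current set is deleted until stable. Read arcs
#' make a transition both producer and consumer of the place.
#'
#' @param net A [petri_net()].
#' @param place_set Character vector of place ids (default: all places).
#' @return Character vector: the largest deadlock contained in `place_set`
#'   (possibly empty).
#' @export
largest_structural_deadlock <- function(net, place_set = place_ids(net)) {
  pid <- place_ids(net)
  bad <- setdiff(place_set, pid)
  if (length(bad) > 0L) stop("unknown place(s): ", paste(bad, collapse = ", "))
  S <- unique(place_set)
  repeat {
    # transitions consuming from S (post-transitions of S); read arcs count
    consumes_from_S <- vapply(net$transitions, function(tr) {
      any(.pre_places(tr) %in% S) || any(names(tr$read) %in% S)
    }, logical(1))
    drop <- vapply(S, function(p) {
      producers <- vapply(net$transitions, function(tr) {
        p %in% .post_places(tr) || p %in% names(tr$read)
      }, logical(1))
      any(producers & !consumes_from_S)
    }, logical(1))
    if (!any(drop)) return(S)
    S <- S[!drop]
    if (length(S) == 0L) return(character(0))
  }
}

#' Is a place contained in a proper structural deadlock?
#'
#' Answers the question the analysis actually asks of an uncovered place:
#' may its initial concentration be set to zero without permanently starving
#' part of the net? That is the case unless the place lies in a non-empty
#' structural deadlock consisting entirely of places that start empty. The
#' candidate set is therefore the zero-marked places plus the queried place
#' itself (override with `within`). Pure side conditions — places with an
#' all-zero incidence row, touched by read arcs only, such as oxygen — are
#' external inputs rather than species and are excluded from the default
#' candidate set.
#'
#' @param net A [petri_net()].
#' @param place A place id.
#' @param within Candidate place set; default: zero-marked places plus
#'   `place`.
#' @return `TRUE` if the place is inside a non-empty structural deadlock
#'   within the candidate set.
#' @export
is_in_proper_deadlock <- function(net, place, within = NULL) {
  pid <- place_ids(net)
  if (!(place %in% pid)) stop("unknown place: ", place)
  if (is.null(within)) {
    m <- initial_marking(net)
    C <- incidence_matrix(net)
    side <- rownames(C)[rowSums(C != 0) == 0]
    within <- union(setdiff(names(m)[m == 0], side), place)
  }
  dl <- largest_structural_deadlock(net, within)
  place %in% dl
}

#' Reduce a net to its steady-state core
#'
#' Transitions carrying zero weight in every non-trivial T-invariant do not
#' contribute to the input/output behavior in a steady state; they are
#' removed, along with every place left without an adjacent transition
#' (read arcs count as adjacency).
#'
#' @param net A [petri_net()].
#' @param t_invs Classified T-invariant set of this net.
#' @return An object of class `pn_core_reduction` with fields
#'   `removed_transitions`, `removed_places`, `core_net`.
#' @export
reduce_to_core <- function(net, t_invs) {
  if (anyNA(t_invs$trivial)) t_invs <- classify_t_invariants(net, t_invs)
  Wn <- t_invs$weights[!t_invs$trivial, , drop = FALSE]
  if (nrow(Wn) == 0L) {
    stop("nothing to preserve: the net has no non-trivial T-invariant")
  }
  keep <- colnames(Wn)[colSums(Wn > 0) > 0]
  tid <- transition_ids(net)
  removed_t <- setdiff(tid, keep)
  core <- subnet(net, keep, drop_isolated_places = TRUE)
  removed_p <- setdiff(place_ids(net), place_ids(core))
  structure(list(removed_transitions = removed_t, removed_places = removed_p,
                 core_net = core),
            class = "pn_core_reduction")
}

#' @export
print.pn_core_reduction <- function(x, ...) {
  cat("core reduction:\n")
  cat("  removed transitions (", length(x$removed_transitions), "): ",
      paste(x$removed_transitions, collapse = ", "), "\n", sep = "")
  cat("  removed places (", length(x$removed_places), "): ",
      paste(x$removed_places, collapse = ", "), "\n", sep = "")
  cat("  core: ", length(x$core_net$places), " places, ",
      length(x$core_net$transitions), " transitions\n", sep = "")
  invisible(x)
}
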