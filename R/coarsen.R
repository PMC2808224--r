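#' Coarsen a net along its connected ADT classes
#'
#' Each connected ADT class is abstracted into a macro transition wrapping
#' its member subnet. Places whose every adjacent transition lies inside a
#' single macro become internal to that macro; the remaining places are the
#' top-level interface between the subnets (and the environment). Macro ids
#' are letters `A`, `B`, ... assigned by the net-order position of each
#' class's first member transition, so that pathway labels are stable.
#'
#' @param net A [petri_net()].
#' @param partition A connected `pn_adt_partition` of this net (see
#'   [connected_adt_decomposition()]).
#' @param scope `"covered_only"` (default) builds macros only for classes
#'   with a non-empty signature, matching a coarse drawing of the covered
#'   core; `"all"` wraps every class including the empty-signature one.
#' @return An object of class `pn_hierarchy`: `macros` (id, member
#'   transitions, internal places), `interface_places`, `coarse_arcs`
#'   (data.frame macro/place/direction), and the underlying flat `net`.
#' @export
coarsen <- function(net, partition, scope = c("covered_only", "all")) {
  scope <- match.arg(scope)
  stopifnot(inherits(partition, "pn_adt_partition"))
  classes <- partition$classes
  if (scope == "covered_only") {
    classes <- Filter(function(cl) length(cl$signature) > 0L, classes)
    covered <- unique(unlist(lapply(classes, `[[`, "transitions")))
    net <- subnet(net, covered, drop_isolated_places = TRUE)
  }
  if (length(classes) == 0L) stop("no ADT classes in scope")
  tid <- transition_ids(net)
  first_pos <- vapply(classes, function(cl) min(match(cl$transitions, tid)),
                      numeric(1))
  classes <- classes[order(first_pos)]
  ids <- .macro_labels(length(classes))
  macro_of <- stats::setNames(rep(NA_character_, length(tid)), tid)
  for (i in seq_along(classes)) macro_of[classes[[i]]$transitions] <- ids[i]
  pid <- place_ids(net)
  adj_macros <- lapply(pid, function(p) {
    unique(stats::na.omit(macro_of[vapply(net$transitions, function(tr)
      p %in% c(names(tr$stoich), names(tr$read)), logical(1))]))
  })
  names(adj_macros) <- pid
  # a place is internal iff all its adjacent transitions sit in one macro
  fully_inside <- vapply(pid, function(p) {
    touching <- vapply(net$transitions, function(tr)
      p %in% c(names(tr$stoich), names(tr$read)), logical(1))
    ms <- macro_of[touching]
    length(ms) > 0L && !anyNA(ms) && length(unique(ms)) == 1L
  }, logical(1))
  interface <- pid[!fully_inside]
  macros <- lapply(seq_along(classes), function(i) {
    members <- classes[[i]]$transitions
    internal <- pid[fully_inside &
                      vapply(adj_macros, function(a) identical(a, ids[i]), logical(1))]
    list(id = ids[i], member_transitions = members, internal_places = internal,
         signature = classes[[i]]$signature)
  })
  arcs <- do.call(rbind, lapply(net$transitions, function(tr) {
    m <- macro_of[[tr$id]]
    if (is.na(m)) return(NULL)
    pl <- c(names(tr$stoich), names(tr$read))
    dir <- c(ifelse(tr$stoich < 0, "in", "out"), rep("read", length(tr$read)))
    keep <- pl %in% interface
    if (!any(keep)) return(NULL)
    data.frame(macro = m, place = pl[keep], direction = dir[keep],
               stringsAsFactors = FALSE)
  }))
  if (is.null(arcs)) {
    arcs <- data.frame(macro = character(0), place = character(0),
                       direction = character(0))
  } else {
    arcs <- unique(arcs); rownames(arcs) <- NULL
  }
  structure(list(macros = macros, interface_places = interface,
                 coarse_arcs = arcs, net = net),
            class = "pn_hierarchy")
}

.macro_labels <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)]
  else paste0("M", seq_len(n))
}

#' @export
print.pn_hierarchy <- function(x, ...) {
  cat(sprintf("hierarchical net: %d macro transition(s), %d interface place(s)\n",
              length(x$macros), length(x$interface_places)))
  for (m in x$macros) {
    cat(sprintf("  %s = {%s}", m$id, paste(m$member_transitions, collapse = ", ")))
    if (length(m$internal_places) > 0L) {
      cat(sprintf("  internal: {%s}", paste(m$internal_places, collapse = ", ")))
    }
    cat("\n")
  }
  cat("  interface:", paste(x$interface_places, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a hierarchical net
#'
#' Inverse of [coarsen()]: returns the flat net the hierarchy wraps;
#' flattening after coarsening reproduces the source net exactly.
#'
#' @param hnet A `pn_hierarchy`.
#' @return The underlying [petri_net()].
#' @export
flatten_hierarchy <- function(hnet) {
  stopifnot(inherits(hnet, "pn_hierarchy"))
  hnet$net
}

#' Enumerate pathways through the coarse net
#'
#' Every non-trivial T-invariant corresponds to a set of macro transitions;
#' when the macro-level connection structure of that set is a simple chain,
#' the invariant reads as a linear pathway from the input macro to the
#' output macro. The sequence starts at a macro containing a source
#' transition (no pre-places) or, failing that, one with no incoming
#' macro-level edge (ties broken lexicographically); invariants whose macro
#' set is not a chain are flagged non-linear with members still reported.
#'
#' @param hnet A [coarsen()] result.
#' @param t_invs The classified T-invariant set the coarsening is based on.
#' @return A data.frame with one row per non-trivial invariant: `invariant`,
#'   `pathway` (macro ids in order, comma separated), `linear`, `macros`.
#' @export
enumerate_pathways <- function(hnet, t_invs) {
  stopifnot(inherits(hnet, "pn_hierarchy"))
  if (anyNA(t_invs$trivial)) stop("classify_t_invariants() first")
  W <- t_invs$weights[!t_invs$trivial, , drop = FALSE]
  net <- hnet$net
  member_sets <- lapply(hnet$macros, `[[`, "member_transitions")
  names(member_sets) <- vapply(hnet$macros, `[[`, character(1), "id")
  trs <- stats::setNames(net$transitions, transition_ids(net))
  rows <- lapply(seq_len(nrow(W)), function(i) {
    supp <- colnames(W)[W[i, ] > 0]
    inset <- vapply(member_sets, function(ms) all(ms %in% supp), logical(1))
    macros <- names(member_sets)[inset]
    covered <- sort(unique(unlist(member_sets[macros])))
    if (!setequal(covered, supp)) {
      return(data.frame(invariant = i, pathway = NA_character_, linear = FALSE,
                        macros = paste(sort(macros), collapse = ","),
                        stringsAsFactors = FALSE))
    }
    seqn <- .order_macros(macros, member_sets, trs)
    data.frame(invariant = i,
               pathway = if (is.null(seqn)) NA_character_ else paste(seqn, collapse = ","),
               linear = !is.null(seqn),
               macros = paste(sort(macros), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# order a macro set into a chain along produced->consumed interface places
.order_macros <- function(macros, member_sets, trs) {
  if (length(macros) == 1L) return(macros)
  prod_pl <- lapply(macros, function(m)
    unique(unlist(lapply(member_sets[[m]], function(t) .post_places(trs[[t]])))))
  cons_pl <- lapply(macros, function(m)
    unique(unlist(lapply(member_sets[[m]], function(t) .pre_places(trs[[t]])))))
  names(prod_pl) <- names(cons_pl) <- macros
  edge <- sapply(macros, function(a) sapply(macros, function(b)
    a != b && length(intersect(prod_pl[[a]], cons_pl[[b]])) > 0L))
  edge <- matrix(edge, length(macros), dimnames = list(macros, macros))
  # edge[b, a] TRUE means a -> b (sapply fills column-wise: rows = b)
  edge <- t(edge)
  has_source_t <- vapply(macros, function(m)
    any(vapply(member_sets[[m]], function(t)
      length(.pre_places(trs[[t]])) == 0L, logical(1))), logical(1))
  no_incoming <- colSums(edge) == 0
  start <- macros[has_source_t]
  if (length(start) == 0L) start <- macros[no_incoming]
  if (length(start) == 0L) return(NULL)
  start <- sort(start)[1]
  path <- start; cur <- start
  while (length(path) < length(macros)) {
    nxt <- macros[edge[cur, ] & !(macros %in% path)]
    if (length(nxt) != 1L) return(NULL)    # branch or dead end: not a chain
    path <- c(path, nxt); cur <- nxt
  }
  path
}
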