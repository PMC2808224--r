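#' Create a place
#'
#' A place is a passive node of a Petri net and models a molecular species;
#' its marking is read as a (dimensionless, non-negative real) concentration.
#'
#' @param id Short unique token identifying the place.
#' @param name Free-text name; defaults to `id`. Logical (fusion) copies of
#'   the same species share a `name`.
#' @param initial_marking Non-negative initial concentration.
#' @param is_logical Is this node a logical (fusion) copy? All logical places
#'   with the same name denote one species and can be merged with
#'   [merge_logical_places()].
#' @return An object of class `pn_place`.
#' @seealso [petri_net()], [merge_logical_places()]
#' @export
place <- function(id, name = id, initial_marking = 0, is_logical = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(initial_marking) || length(initial_marking) != 1L ||
      is.na(initial_marking) || initial_marking < 0) {
    stop("initial_marking of place '", id, "' must be a non-negative number")
  }
  structure(
    list(id = id, name = name, initial_marking = as.numeric(initial_marking),
         is_logical = isTRUE(is_logical)),
    class = "pn_place"
  )
}

#' Create a transition
#'
#' A transition is an active node of a Petri net and models one reaction
#' direction. Its net token change is the signed integer `stoichiometry`
#' (negative entries are consumed, positive produced); `read_set` holds side
#' conditions connected by read arcs, which gate the rate but are never
#' changed by firing.
#'
#' @param id Short unique token.
#' @param stoichiometry Named integer vector, names are place ids; negative =
#'   consumed, positive = produced.
#' @param read_set Named positive integer vector of side-condition weights;
#'   names must be disjoint from `stoichiometry` names.
#' @param reverse_of For the member of an expanded reversible pair: the id of
#'   the opposite direction, otherwise `NA`.
#' @param rate_constant Non-negative mass-action rate constant.
#' @return An object of class `pn_transition`.
#' @export
transition <- function(id, stoichiometry = numeric(), read_set = numeric(),
                       reverse_of = NA_character_, rate_constant = 0) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stoichiometry <- .named_int(stoichiometry, "stoichiometry", id)
  read_set <- .named_int(read_set, "read_set", id)
  if (any(read_set <= 0)) stop("read_set weights of '", id, "' must be positive")
  if (length(intersect(names(stoichiometry), names(read_set))) > 0L) {
    stop("stoichiometry and read_set of '", id, "' must use disjoint places")
  }
  if (!is.numeric(rate_constant) || length(rate_constant) != 1L ||
      is.na(rate_constant) || rate_constant < 0) {
    stop("rate_constant of '", id, "' must be a non-negative number")
  }
  structure(
    list(id = id, stoich = stoichiometry, read = read_set,
         reverse_of = as.character(reverse_of), rate = as.numeric(rate_constant)),
    class = "pn_transition"
  )
}

.named_int <- function(x, what, id) {
  if (length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop(what, " of '", id, "' must be a named vector of place ids")
  }
  if (any(x != round(x))) stop(what, " of '", id, "' must be integer-valued")
  x <- x[x != 0]
  stats::setNames(as.numeric(x), names(x))
}

#' Create a reaction
#'
#' A reaction is the chemical-level description from which transitions are
#' derived: an irreversible reaction yields one transition, a reversible one
#' two opposite transitions (see [expand_reversible()]). Modifiers are side
#' conditions (read arcs) required by both directions.
#'
#' @param id Reaction identifier.
#' @param reactants,products,modifiers Named positive integer vectors
#'   (species id -> stoichiometric coefficient); the three key sets must be
#'   pairwise disjoint.
#' @param reversible Does the reaction run in both directions?
#' @param k_forward Non-negative forward rate constant.
#' @param k_backward Backward rate constant; required iff `reversible`.
#' @return An object of class `pn_reaction`.
#' @export
reaction <- function(id, reactants = numeric(), products = numeric(),
                     modifiers = numeric(), reversible = FALSE,
                     k_forward = 0, k_backward = NULL) {
  reactants <- .named_int(reactants, "reactants", id)
  products  <- .named_int(products, "products", id)
  modifiers <- .named_int(modifiers, "modifiers", id)
  keys <- c(names(reactants), names(products), names(modifiers))
  if (anyDuplicated(keys)) {
    stop("reactant/product/modifier species of reaction '", id,
         "' must be pairwise disjoint")
  }
  if (isTRUE(reversible) && is.null(k_backward)) {
    stop("reversible reaction '", id, "' needs k_backward")
  }
  structure(
    list(id = id, reactants = reactants, products = products,
         modifiers = modifiers, reversible = isTRUE(reversible),
         k_forward = as.numeric(k_forward),
         k_backward = if (is.null(k_backward)) NA_real_ else as.numeric(k_backward)),
    class = "pn_reaction"
  )
}

#' Assemble a Petri net
#'
#' A Petri net is a weighted, directed, bipartite graph of places and
#' transitions. Node order is significant and stable: the incidence matrix
#' and all invariant vectors index against it.
#'
#' @param places List of [place()] objects.
#' @param transitions List of [transition()] objects.
#' @param provenance Free-text origin note.
#' @return An object of class `petri_net`.
#' @export
petri_net <- function(places, transitions, provenance = "") {
  if (inherits(places, "pn_place")) places <- list(places)
  if (inherits(transitions, "pn_transition")) transitions <- list(transitions)
  pid <- vapply(places, `[[`, character(1), "id")
  tid <- vapply(transitions, `[[`, character(1), "id")
  if (anyDuplicated(pid)) stop("duplicate place ids: ",
                               paste(pid[duplicated(pid)], collapse = ", "))
  if (anyDuplicated(tid)) stop("duplicate transition ids: ",
                               paste(tid[duplicated(tid)], collapse = ", "))
  for (tr in transitions) {
    ref <- c(names(tr$stoich), names(tr$read))
    bad <- setdiff(ref, pid)
    if (length(bad) > 0L) {
      stop("transition '", tr$id, "' references unknown place(s): ",
           paste(bad, collapse = ", "))
    }
    if (!is.na(tr$reverse_of) && !(tr$reverse_of %in% tid)) {
      stop("transition '", tr$id, "' reverse_of points to unknown transition '",
           tr$reverse_of, "'")
    }
  }
  # reverse_of must be symmetric
  rev <- stats::setNames(vapply(transitions, `[[`, character(1), "reverse_of"), tid)
  for (id in tid) {
    r <- rev[[id]]
    if (!is.na(r) && (is.na(rev[[r]]) || rev[[r]] != id)) {
      stop("reverse_of is not symmetric between '", id, "' and '", r, "'")
    }
  }
  net <- structure(
    list(places = places, transitions = transitions,
         provenance = as.character(provenance)),
    class = "petri_net"
  )
  net
}

#' @export
print.petri_net <- function(x, ...) {
  nl <- sum(vapply(x$places, `[[`, logical(1), "is_logical"))
  nr <- sum(!is.na(vapply(x$transitions, `[[`, character(1), "reverse_of")))
  cat(sprintf("Petri net: %d places, %d transitions", length(x$places),
              length(x$transitions)))
  if (nl > 0) cat(sprintf(" (%d logical places)", nl))
  if (nr > 0) cat(sprintf(" (%d reversible-pair members)", nr))
  cat("\n")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Place and transition ids of a net (in net order)
#' @param net A [petri_net()].
#' @return Character vector of ids.
#' @export
place_ids <- function(net) vapply(net$places, `[[`, character(1), "id")

#' @rdname place_ids
#' @export
transition_ids <- function(net) vapply(net$transitions, `[[`, character(1), "id")

#' Initial marking of a net
#' @param net A [petri_net()].
#' @return Named numeric vector of initial concentrations, in place order.
#' @export
initial_marking <- function(net) {
  stats::setNames(vapply(net$places, `[[`, numeric(1), "initial_marking"),
                  place_ids(net))
}

#' Set initial markings
#' @param net A [petri_net()].
#' @param values Named numeric vector (place id -> concentration); places not
#'   mentioned keep their marking.
#' @return The modified net.
#' @export
set_marking <- function(net, values) {
  bad <- setdiff(names(values), place_ids(net))
  if (length(bad) > 0L) stop("unknown place(s): ", paste(bad, collapse = ", "))
  for (i in seq_along(net$places)) {
    id <- net$places[[i]]$id
    if (id %in% names(values)) {
      if (values[[id]] < 0) stop("negative marking for '", id, "'")
      net$places[[i]]$initial_marking <- as.numeric(values[[id]])
    }
  }
  net
}

#' Expand a reaction list into a Petri net
#'
#' Each irreversible reaction becomes one transition; each reversible
#' reaction becomes two opposite transitions `<id>_f` / `<id>_b` with
#' mirrored stoichiometry, cross-linked through `reverse_of`. Modifiers
#' become read arcs on both directions. Places appear in order of first
#' appearance (reactants, then products, then modifiers, per reaction).
#'
#' @param reactions List of [reaction()] objects.
#' @param provenance Provenance note for the new net.
#' @return A [petri_net()].
#' @export
expand_reversible <- function(reactions, provenance = "") {
  if (inherits(reactions, "pn_reaction")) reactions <- list(reactions)
  seen <- character(0)
  for (r in reactions) {
    seen <- union(seen, c(names(r$reactants), names(r$products), names(r$modifiers)))
  }
  places <- lapply(seen, place)
  transitions <- list()
  for (r in reactions) {
    st <- stats::setNames(numeric(length(seen)), seen)
    st[names(r$reactants)] <- st[names(r$reactants)] - r$reactants
    st[names(r$products)]  <- st[names(r$products)] + r$products
    st <- st[st != 0]
    if (r$reversible) {
      fid <- paste0(r$id, "_f"); bid <- paste0(r$id, "_b")
      transitions <- c(transitions, list(
        transition(fid, st, r$modifiers, reverse_of = bid, rate_constant = r$k_forward),
        transition(bid, -st, r$modifiers, reverse_of = fid, rate_constant = r$k_backward)
      ))
    } else {
      transitions <- c(transitions, list(
        transition(r$id, st, r$modifiers, rate_constant = r$k_forward)
      ))
    }
  }
  petri_net(places, transitions, provenance = provenance)
}

#' Collapse expanded reversible pairs back into reactions
#'
#' Inverse of [expand_reversible()] up to the information a net carries: the
#' forward direction is taken to be the `_f` member (or the lexicographically
#' first member when the ids do not follow that convention). Net
#' stoichiometries with mixed production/consumption map back to
#' reactant/product sets.
#'
#' @param net A [petri_net()].
#' @return List of [reaction()] objects.
#' @export
collapse_reversible <- function(net) {
  done <- character(0)
  out <- list()
  for (tr in net$transitions) {
    if (tr$id %in% done) next
    st <- tr$stoich
    reac <- -st[st < 0]; prod <- st[st > 0]
    if (!is.na(tr$reverse_of)) {
      other <- net$transitions[[match(tr$reverse_of, transition_ids(net))]]
      done <- c(done, tr$id, other$id)
      # prefer the `_f` member as the written direction
      if (grepl("_b$", tr$id) && grepl("_f$", other$id)) {
        tmp <- tr; tr <- other; other <- tmp
        st <- tr$stoich; reac <- -st[st < 0]; prod <- st[st > 0]
      }
      rid <- sub("_f$", "", tr$id)
      out <- c(out, list(reaction(rid, reac, prod, tr$read, reversible = TRUE,
                                  k_forward = tr$rate, k_backward = other$rate)))
    } else {
      done <- c(done, tr$id)
      out <- c(out, list(reaction(tr$id, reac, prod, tr$read,
                                  k_forward = tr$rate)))
    }
  }
  out
}

#' Merge logical (fusion) places
#'
#' All logical places sharing one name are identical from the analysis point
#' of view; this fuses them into a single place (the first copy in net
#' order), re-attaching every arc. Non-logical places are untouched.
#'
#' @param net A [petri_net()].
#' @return A [petri_net()] without duplicate logical copies.
#' @export
merge_logical_places <- function(net) {
  pid <- place_ids(net)
  logical <- vapply(net$places, `[[`, logical(1), "is_logical")
  nms <- vapply(net$places, `[[`, character(1), "name")
  remap <- stats::setNames(pid, pid)
  keep <- rep(TRUE, length(pid))
  for (nm in unique(nms[logical])) {
    grp <- which(logical & nms == nm)
    if (length(grp) < 2L) next
    inits <- vapply(net$places[grp], `[[`, numeric(1), "initial_marking")
    if (length(unique(inits)) > 1L) {
      stop("logical places named '", nm, "' have conflicting initial markings: ",
           paste(inits, collapse = ", "))
    }
    remap[pid[grp[-1]]] <- pid[grp[1]]
    keep[grp[-1]] <- FALSE
  }
  if (all(keep)) return(net)
  relabel <- function(v) {
    if (length(v) == 0L) return(v)
    names(v) <- unname(remap[names(v)])
    # fuse arcs that now hit the same place
    tapply_sum <- tapply(v, names(v), sum)
    out <- stats::setNames(as.numeric(tapply_sum), names(tapply_sum))
    out[out != 0]
  }
  transitions <- lapply(net$transitions, function(tr) {
    tr$stoich <- relabel(tr$stoich)
    tr$read <- relabel(tr$read)
    both <- intersect(names(tr$stoich), names(tr$read))
    if (length(both) > 0L) {
      stop("merging logical places puts '", paste(both, collapse = ", "),
           "' into both stoichiometry and read set of '", tr$id, "'")
    }
    tr
  })
  petri_net(net$places[keep], transitions, provenance = net$provenance)
}

#' Incidence (stoichiometric) matrix
#'
#' Integer matrix with one row per place and one column per transition; the
#' entry is the token change of the place when the transition fires
#' (produced minus consumed). Read arcs contribute zero, so the row of a
#' pure side-condition place (oxygen in the hypoxia net) is all-zero.
#'
#' @param net A [petri_net()]; logical places should already be merged.
#' @return Integer matrix with `dimnames` = list(place ids, transition ids).
#' @export
incidence_matrix <- function(net) {
  pid <- place_ids(net); tid <- transition_ids(net)
  C <- matrix(0, nrow = length(pid), ncol = length(tid),
              dimnames = list(pid, tid))
  for (j in seq_along(net$transitions)) {
    st <- net$transitions[[j]]$stoich
    C[names(st), j] <- st
  }
  C
}

# places consumed / produced / read by a transition (internal helpers)
.pre_places <- function(tr) names(tr$stoich)[tr$stoich < 0]
.post_places <- function(tr) names(tr$stoich)[tr$stoich > 0]

#' Restrict a net to a subset of its transitions
#'
#' Keeps the given transitions and afterwards drops every place left without
#' an adjacent transition (read arcs count as adjacency). `reverse_of` links
#' pointing outside the kept set are cleared.
#'
#' @param net A [petri_net()].
#' @param keep_transitions Character vector of transition ids to keep.
#' @param drop_isolated_places Drop places with no remaining adjacent
#'   transition? Default `TRUE`.
#' @return A [petri_net()].
#' @export
subnet <- function(net, keep_transitions, drop_isolated_places = TRUE) {
  tid <- transition_ids(net)
  bad <- setdiff(keep_transitions, tid)
  if (length(bad) > 0L) stop("unknown transition(s): ", paste(bad, collapse = ", "))
  trs <- net$transitions[tid %in% keep_transitions]
  trs <- lapply(trs, function(tr) {
    if (!is.na(tr$reverse_of) && !(tr$reverse_of %in% keep_transitions)) {
      tr$reverse_of <- NA_character_
    }
    tr
  })
  places <- net$places
  if (drop_isolated_places) {
    touched <- unique(unlist(lapply(trs, function(tr) c(names(tr$stoich), names(tr$read)))))
    places <- places[place_ids(net) %in% touched]
  }
  petri_net(places, trs, provenance = net$provenance)
}
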