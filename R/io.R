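#' Parse a network file
#'
#' Three input formats are supported:
#' \describe{
#'   \item{`dsl`}{Plain-text reaction list, one reaction per line:
#'     `id: 2 A + B + M(read) -> C ; kf=0.1` or `id: A <-> B ; kf=0.1, kb=0.2`.
#'     Either side may be empty (pure production/consumption), `#` starts a
#'     comment. Returns a list of [reaction()] objects.}
#'   \item{`pnml`}{PNML place/transition nets (arc inscriptions are weights);
#'     pairs of opposite arcs of equal weight between a place and a
#'     transition are collapsed into read arcs. Returns a [petri_net()].}
#'   \item{`sbml`}{SBML (level 2/3) import of species, reactions,
#'     stoichiometry and modifiers; the `reversible` flag is honoured, rate
#'     constants are not imported. Returns a list of [reaction()] objects.}
#' }
#'
#' @param path File to read.
#' @param format One of `"dsl"`, `"pnml"`, `"sbml"`; default guesses from
#'   the file extension.
#' @return A list of reactions (`dsl`, `sbml`) or a [petri_net()] (`pnml`).
#' @export
parse_net <- function(path, format = c("auto", "dsl", "pnml", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     pnml = "pnml", xml = "pnml", sbml = "sbml",
                     "dsl")
  }
  switch(format,
         dsl = .parse_dsl(path),
         pnml = .parse_pnml(path),
         sbml = .parse_sbml(path))
}

.dsl_term_rx <- "^(\\d+)?\\s*([A-Za-z_][A-Za-z0-9_.:-]*)\\s*(\\(read\\))?$"

.parse_dsl_side <- function(txt, line) {
  txt <- trimws(txt)
  species <- numeric(0); mods <- numeric(0)
  if (!nzchar(txt)) return(list(species = species, modifiers = mods))
  for (term in trimws(strsplit(txt, "+", fixed = TRUE)[[1]])) {
    m <- regmatches(term, regexec(.dsl_term_rx, term))[[1]]
    if (length(m) == 0L) stop("line ", line, ": cannot parse term '", term, "'")
    w <- if (nzchar(m[2])) as.numeric(m[2]) else 1
    id <- m[3]
    if (nzchar(m[4])) {
      mods[id] <- w + if (id %in% names(mods)) mods[[id]] else 0
    } else {
      species[id] <- w + if (id %in% names(species)) species[[id]] else 0
    }
  }
  list(species = species, modifiers = mods)
}

.parse_dsl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec(
      "^\\s*([A-Za-z0-9_.:-]+)\\s*:\\s*(.*?)\\s*(<->|->)\\s*(.*?)\\s*;\\s*(.*?)\\s*$", ln,
      perl = TRUE))[[1]]
    if (length(m) == 0L) stop("line ", i, ": malformed reaction line")
    id <- m[2]; rev <- m[4] == "<->"
    lhs <- .parse_dsl_side(m[3], i)
    rhs <- .parse_dsl_side(m[5], i)
    if (length(rhs$modifiers) > 0L) {
      stop("line ", i, ": modifiers belong on the left-hand side")
    }
    kin <- m[6]
    kf <- .dsl_kin(kin, "kf", i)
    kb <- .dsl_kin(kin, "kb", i, required = FALSE)
    if (rev && is.null(kb)) stop("line ", i, ": reversible reaction '", id,
                                 "' is missing kb")
    out[[length(out) + 1L]] <- reaction(
      id, reactants = lhs$species, products = rhs$species,
      modifiers = lhs$modifiers, reversible = rev,
      k_forward = kf, k_backward = kb)
  }
  out
}

.dsl_kin <- function(txt, key, line, required = TRUE) {
  m <- regmatches(txt, regexec(paste0("\\b", key,
                                      "\\s*=\\s*([0-9.eE+-]+)"), txt))[[1]]
  if (length(m) == 0L) {
    if (required) stop("line ", line, ": missing ", key, "=<value>")
    return(NULL)
  }
  as.numeric(m[2])
}

#' Write a flat net as PNML
#'
#' Writes the standard PNML place/transition dialect. Read arcs are written
#' as a pair of opposite arcs of equal weight (the structural convention for
#' test arcs); rate constants, `reverse_of` links and logical-place flags go
#' into `toolspecific` elements so that a parse round-trip is lossless.
#'
#' @param net A [petri_net()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pnml <- function(net, path) {
  doc <- xml2::xml_new_root("pnml",
                            xmlns = "http://www.pnml.org/version-2009/grammar/pnml")
  nd <- xml2::xml_add_child(doc, "net", id = "net0",
                            type = "http://www.pnml.org/version-2009/grammar/ptnet")
  pg <- xml2::xml_add_child(nd, "page", id = "page0")
  for (p in net$places) {
    pe <- xml2::xml_add_child(pg, "place", id = p$id)
    ne <- xml2::xml_add_child(pe, "name")
    xml2::xml_add_child(ne, "text", p$name)
    me <- xml2::xml_add_child(pe, "initialMarking")
    xml2::xml_add_child(me, "text", format(p$initial_marking, digits = 15))
    if (p$is_logical) {
      ts <- xml2::xml_add_child(pe, "toolspecific", tool = "petristruct", version = "1")
      xml2::xml_add_child(ts, "logical", "true")
    }
  }
  arc_n <- 0L
  add_arc <- function(from, to, w) {
    arc_n <<- arc_n + 1L
    ae <- xml2::xml_add_child(pg, "arc", id = paste0("a", arc_n),
                              source = from, target = to)
    if (w != 1) {
      ie <- xml2::xml_add_child(ae, "inscription")
      xml2::xml_add_child(ie, "text", format(w))
    }
  }
  for (tr in net$transitions) {
    te <- xml2::xml_add_child(pg, "transition", id = tr$id)
    ts <- xml2::xml_add_child(te, "toolspecific", tool = "petristruct", version = "1")
    xml2::xml_add_child(ts, "rate", format(tr$rate, digits = 15))
    if (!is.na(tr$reverse_of)) xml2::xml_add_child(ts, "reverseOf", tr$reverse_of)
  }
  for (tr in net$transitions) {
    for (p in names(tr$stoich)) {
      w <- tr$stoich[[p]]
      if (w < 0) add_arc(p, tr$id, -w) else add_arc(tr$id, p, w)
    }
    for (p in names(tr$read)) {
      add_arc(p, tr$id, tr$read[[p]])
      add_arc(tr$id, p, tr$read[[p]])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.xml_all <- function(doc, name) {
  xml2::xml_find_all(doc, paste0(".//*[local-name()='", name, "']"))
}

.parse_pnml <- function(path) {
  doc <- xml2::read_xml(path)
  pl <- .xml_all(doc, "place")
  places <- lapply(pl, function(pe) {
    id <- xml2::xml_attr(pe, "id")
    if (is.na(id)) stop("PNML place without id")
    nm <- xml2::xml_text(xml2::xml_find_first(
      pe, "./*[local-name()='name']/*[local-name()='text']"))
    mk <- xml2::xml_text(xml2::xml_find_first(
      pe, "./*[local-name()='initialMarking']/*[local-name()='text']"))
    lg <- xml2::xml_text(xml2::xml_find_first(
      pe, "./*[local-name()='toolspecific']/*[local-name()='logical']"))
    place(id, name = if (is.na(nm)) id else nm,
          initial_marking = if (is.na(mk)) 0 else as.numeric(mk),
          is_logical = identical(lg, "true"))
  })
  pid <- vapply(places, `[[`, character(1), "id")
  tl <- .xml_all(doc, "transition")
  tmeta <- lapply(tl, function(te) {
    id <- xml2::xml_attr(te, "id")
    if (is.na(id)) stop("PNML transition without id")
    rt <- xml2::xml_text(xml2::xml_find_first(
      te, "./*[local-name()='toolspecific']/*[local-name()='rate']"))
    ro <- xml2::xml_text(xml2::xml_find_first(
      te, "./*[local-name()='toolspecific']/*[local-name()='reverseOf']"))
    list(id = id, rate = if (is.na(rt)) 0 else as.numeric(rt),
         reverse_of = if (is.na(ro)) NA_character_ else ro)
  })
  tid <- vapply(tmeta, `[[`, character(1), "id")
  into <- lapply(tid, function(i) numeric(0))   # transition -> place weights
  from <- lapply(tid, function(i) numeric(0))   # place -> transition weights
  names(into) <- names(from) <- tid
  for (ae in .xml_all(doc, "arc")) {
    s <- xml2::xml_attr(ae, "source"); t <- xml2::xml_attr(ae, "target")
    wtxt <- xml2::xml_text(xml2::xml_find_first(
      ae, "./*[local-name()='inscription']/*[local-name()='text']"))
    w <- if (is.na(wtxt)) 1 else as.numeric(wtxt)
    if (s %in% pid && t %in% tid) {
      from[[t]][s] <- w + if (s %in% names(from[[t]])) from[[t]][[s]] else 0
    } else if (s %in% tid && t %in% pid) {
      into[[s]][t] <- w + if (t %in% names(into[[s]])) into[[s]][[t]] else 0
    } else {
      stop("PNML arc '", xml2::xml_attr(ae, "id"),
           "' does not connect a known place with a known transition")
    }
  }
  transitions <- lapply(tmeta, function(tm) {
    cons <- from[[tm$id]]; prod <- into[[tm$id]]
    both <- intersect(names(cons), names(prod))
    read <- numeric(0)
    for (p in both) {
      w <- min(cons[[p]], prod[[p]])   # opposite pair of equal weight = read arc
      if (cons[[p]] == prod[[p]]) {
        read[p] <- w
        cons <- cons[names(cons) != p]; prod <- prod[names(prod) != p]
      }
    }
    st <- stats::setNames(numeric(0), character(0))
    for (p in names(cons)) st[p] <- -cons[[p]]
    for (p in names(prod)) st[p] <- (if (p %in% names(st)) st[[p]] else 0) + prod[[p]]
    transition(tm$id, st[st != 0], read, reverse_of = tm$reverse_of,
               rate_constant = tm$rate)
  })
  petri_net(places, transitions, provenance = paste("pnml:", path))
}

.parse_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  sp <- .xml_all(doc, "species")
  sids <- xml2::xml_attr(sp, "id")
  refs <- function(re, what) {
    nodes <- xml2::xml_find_all(re, paste0(
      "./*[local-name()='listOf", what, "']/*[local-name()='",
      if (what == "Modifiers") "modifierSpeciesReference" else "speciesReference",
      "']"))
    if (length(nodes) == 0L) return(numeric(0))
    ids <- xml2::xml_attr(nodes, "species")
    st <- xml2::xml_attr(nodes, "stoichiometry")
    st <- ifelse(is.na(st), 1, as.numeric(st))
    bad <- setdiff(ids, sids)
    if (length(bad) > 0L) stop("SBML reaction references unknown species: ",
                               paste(bad, collapse = ", "))
    v <- tapply(st, ids, sum)
    stats::setNames(as.numeric(v), names(v))
  }
  out <- list()
  for (re in .xml_all(doc, "reaction")) {
    id <- xml2::xml_attr(re, "id")
    revflag <- !identical(xml2::xml_attr(re, "reversible"), "false")
    out[[length(out) + 1L]] <- reaction(
      id,
      reactants = refs(re, "Reactants"),
      products  = refs(re, "Products"),
      modifiers = refs(re, "Modifiers"),
      reversible = revflag,
      k_forward = 0, k_backward = if (revflag) 0 else NULL)
  }
  out
}

#' Write a hierarchical (coarse) net as JSON
#'
#' PNML has no standard macro-transition dialect, so the hierarchy is
#' serialized as JSON: a list of macros, each with its member transitions
#' and internal places, plus the top-level interface places.
#'
#' @param hnet A [coarsen()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(hnet, path) {
  stopifnot(inherits(hnet, "pn_hierarchy"))
  macros <- lapply(hnet$macros, function(m) {
    list(macro_id = m$id,
         member_transition_ids = m$member_transitions,
         internal_place_ids = m$internal_places)
  })
  jsonlite::write_json(
    list(macros = macros, interface_place_ids = hnet$interface_places),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a flat-TOML parameter file
#'
#' Reads the subset of TOML used by the packaged parameter files:
#' `[section]` headers, `key = value` lines and `#` comments. Values are
#' numbers or quoted strings.
#'
#' @param path File to read.
#' @return Named list of sections, each a named list of values.
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); section <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[i]))
    if (!nzchar(ln)) next
    if (grepl("^\\[[^]]+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.:-]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) == 0L) stop("line ", i, ": cannot parse '", ln, "'")
    val <- trimws(m[3])
    val <- if (grepl('^".*"$', val)) gsub('^"|"$', "", val) else as.numeric(val)
    if (is.null(section)) out[[m[2]]] <- val else out[[section]][[m[2]]] <- val
  }
  out
}
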