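# Shared fixtures and independent oracles, built in code.

# --- small nets -------------------------------------------------------------

chain_net <- function() {
  # A -> B, single irreversible step
  petri_net(list(place("A", initial_marking = 1), place("B")),
            list(transition("t1", c(A = -1, B = 1), rate_constant = 0.5)))
}

cycle_net <- function() {
  # closed two-step cycle A -> B -> A
  petri_net(list(place("A", initial_marking = 1), place("B")),
            list(transition("t1", c(A = -1, B = 1), rate_constant = 1),
                 transition("t2", c(B = -1, A = 1), rate_constant = 1)))
}

source_net <- function() {
  # isolated production with no consumer
  petri_net(list(place("A")),
            list(transition("t1", c(A = 1), rate_constant = 1)))
}

enzyme_reactions <- function() {
  # single enzymatic reaction E + S <-> ES -> E + P
  list(reaction("bind", c(E = 1, S = 1), c(ES = 1), reversible = TRUE,
                k_forward = 1, k_backward = 0.5),
       reaction("cat", c(ES = 1), c(E = 1, P = 1), k_forward = 0.2))
}

# --- brute-force invariant oracle -------------------------------------------

# All support-minimal, gcd-normalized non-negative integer solutions of
# M %*% x == 0 with entries bounded by `maxw`, by exhaustive enumeration.
brute_force_kernel <- function(M, maxw = 4) {
  n <- ncol(M)
  grids <- rep(list(0:maxw), n)
  X <- as.matrix(expand.grid(grids))
  colnames(X) <- colnames(M)
  keep <- rowSums(X) > 0 & colSums(abs(M %*% t(X))) == 0
  X <- X[keep, , drop = FALSE]
  if (nrow(X) == 0L) return(X)
  g <- apply(X, 1, function(v) Reduce(function(a, b) {
    while (b > 0) { tmp <- a %% b; a <- b; b <- tmp }; a
  }, abs(v[v != 0])))
  X <- unique(X / g)
  supp <- (X > 0) * 1
  sz <- rowSums(supp)
  inter <- tcrossprod(supp)
  keep <- rep(TRUE, nrow(X))
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(nrow(X))) {
      if (i != j && keep[i] && inter[i, j] == sz[j] && sz[i] > sz[j]) keep[i] <- FALSE
    }
  }
  X[keep, , drop = FALSE]
}

brute_force_invariants <- function(C, kind, maxw = 4) {
  M <- if (kind == "P") t(C) else C
  brute_force_kernel(M, maxw = maxw)
}

# canonical string form of a weight matrix for set comparison
weight_set <- function(W) {
  if (nrow(W) == 0L) return(character(0))
  unname(sort(apply(W, 1, function(v) paste(colnames(W)[v > 0],
                                            as.integer(v[v > 0]),
                                            sep = ":", collapse = ","))))
}

expect_same_invariants <- function(invs, oracle) {
  expect_setequal(weight_set(invs$weights), weight_set(oracle))
}

# Two-sided comparison against the bounded brute-force oracle. The
# enumeration bound `maxw` cannot see minimal invariants with larger
# entries, so the comparison is made bound-aware:
#  * every enumerated result with entries <= maxw must appear verbatim in
#    the oracle set;
#  * every oracle vector must either be such a result, or be a non-minimal
#    kernel vector whose support strictly contains the support of a result
#    with an entry beyond the bound (the witness the bounded oracle missed);
#  * results must satisfy their kernel equation exactly and be pairwise
#    support-minimal with gcd 1.
expect_matches_bounded_oracle <- function(invs, C, kind, maxw = 4) {
  W <- invs$weights
  M <- if (kind == "P") t(C) else C
  if (nrow(W) > 0L) {
    expect_true(all(M %*% t(W) == 0))
    expect_true(all(apply(W, 1, function(v) {
      g <- Reduce(function(a, b) { while (b > 0) { t <- a %% b; a <- b; b <- t }; a },
                  abs(v[v != 0]))
      g == 1
    })))
    supp <- (W > 0) * 1
    if (nrow(W) > 1L) {
      inter <- tcrossprod(supp); sz <- rowSums(supp)
      for (i in seq_len(nrow(W))) for (j in seq_len(nrow(W))) {
        if (i != j) expect_false(inter[i, j] == sz[j] && sz[i] > sz[j])
      }
    }
  }
  B <- brute_force_invariants(C, kind, maxw = maxw)
  small <- W[apply(W, 1, function(v) max(v, 0)) <= maxw, , drop = FALSE]
  big <- W[apply(W, 1, function(v) max(v, 0)) > maxw, , drop = FALSE]
  expect_true(all(weight_set(small) %in% weight_set(B)))
  extra <- setdiff(weight_set(B), weight_set(small))
  for (e in extra) {
    ids <- vapply(strsplit(strsplit(e, ",")[[1]], ":"), `[[`, character(1), 1)
    witnessed <- nrow(big) > 0L && any(apply(big, 1, function(v) {
      s <- colnames(W)[v > 0]
      all(s %in% ids) && length(s) < length(ids)
    }))
    expect_true(witnessed)
  }
}

# SBML fixture written in code (two reactions, one reversible, one modifier)
write_sbml_fixture <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    '<model id="toy">',
    '<listOfSpecies>',
    '<species id="A" initialConcentration="2"/>',
    '<species id="B" initialConcentration="0"/>',
    '<species id="Enz" initialConcentration="1"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="conv" reversible="false">',
    '<listOfReactants><speciesReference species="A" stoichiometry="2"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B"/></listOfProducts>',
    '<listOfModifiers><modifierSpeciesReference species="Enz"/></listOfModifiers>',
    '</reaction>',
    '<reaction id="iso" reversible="true">',
    '<listOfReactants><speciesReference species="B"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A"/></listOfProducts>',
    '</reaction>',
    '</listOfReactions>',
    '</model>',
    '</sbml>'), path)
  path
}
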