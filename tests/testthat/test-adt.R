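hypoxia_with_invariants <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- build_full_hypoxia_net()
      tin <- classify_t_invariants(net, minimal_invariants(net, "T"))
      cache <<- list(net = net, tin = tin)
    }
    cache
  }
})

test_that("the hypoxia ADT partition over the non-trivial basis has 6 classes", {
  hx <- hypoxia_with_invariants()
  part <- adt_partition(hx$net, nontrivial(hx$tin))
  expect_length(part$classes, 6L)
  sizes <- sort(vapply(part$classes, function(cl) length(cl$transitions), integer(1)))
  expect_equal(sizes, c(1L, 1L, 2L, 2L, 4L, 9L))
  by_members <- lapply(part$classes, `[[`, "transitions")
  expect_true(any(vapply(by_members, function(m) setequal(m, "r1"), logical(1))))
  expect_true(any(vapply(by_members, function(m) setequal(m, "r2"), logical(1))))
  expect_true(any(vapply(by_members, function(m) setequal(m, c("r3_f", "r4")), logical(1))))
  expect_true(any(vapply(by_members, function(m)
    setequal(m, c("r5_f", "r7_f", "r8", "r9_b")), logical(1))))
  expect_true(any(vapply(by_members, function(m) setequal(m, c("r10_f", "r11")), logical(1))))
  # classes are the fibres of the signature map
  for (cl in part$classes) {
    W <- nontrivial(hx$tin)$weights
    for (t in cl$transitions) {
      expect_equal(which(W[, t] > 0), cl$signature, ignore_attr = TRUE)
    }
  }
})

test_that("a single-invariant basis splits support from everything else", {
  hx <- hypoxia_with_invariants()
  nt <- nontrivial(hx$tin)
  one <- structure(list(kind = "T", weights = nt$weights[1, , drop = FALSE],
                        trivial = FALSE), class = "pn_invariant_set")
  part <- adt_partition(hx$net, one)
  expect_length(part$classes, 2L)
  expect_setequal(part$classes[[1]]$transitions,
                  colnames(nt$weights)[nt$weights[1, ] > 0])
})

test_that("the full-basis partition refines the non-trivial-basis partition", {
  check_refines <- function(net, tin) {
    fine <- adt_partition(net, tin)
    coarse <- adt_partition(net, nontrivial(tin))
    for (cl in fine$classes) {
      holders <- vapply(coarse$classes, function(cc)
        all(cl$transitions %in% cc$transitions), logical(1))
      expect_equal(sum(holders), 1L)
    }
  }
  hx <- hypoxia_with_invariants()
  check_refines(hx$net, hx$tin)
  for (s in 1:10) {
    net <- random_massaction_net(3 + (s %% 4), 3 + ((s * 3) %% 4), seed = 3000 + s)
    tin <- classify_t_invariants(net, minimal_invariants(net, "T"))
    check_refines(net, tin)
  }
})

test_that("direct pairwise dependency matches known hypoxia facts", {
  hx <- hypoxia_with_invariants()
  C <- incidence_matrix(hx$net)
  # production occurs in P1 without the final VHL degradation step
  expect_false(pair_dependent_direct(C, "r1", "r11"))
  # the two hydroxylations never co-occur in one minimal invariant
  expect_false(pair_dependent_direct(C, "r4", "r8"))
  # an isolated reversible reaction: the pair is the only invariant
  pair <- expand_reversible(list(reaction("r", c(A = 1), c(B = 1),
                                          reversible = TRUE, k_forward = 1,
                                          k_backward = 1)))
  expect_true(pair_dependent_direct(incidence_matrix(pair), "r_f", "r_b"))
  expect_error(pair_dependent_direct(C, "r1", "r1"), "distinct")
})

test_that("direct dependency equals full-basis class co-membership on random nets", {
  for (s in 1:40) {
    net <- random_massaction_net(2 + (s %% 5), 2 + ((s * 7) %% 5), seed = s)
    C <- incidence_matrix(net)
    part <- adt_partition(net, minimal_invariants(net, "T"))
    cls <- integer(0)
    for (i in seq_along(part$classes)) cls[part$classes[[i]]$transitions] <- i
    tid <- transition_ids(net)
    prs <- utils::combn(tid, 2)
    for (k in seq_len(ncol(prs))) {
      expect_equal(pair_dependent_direct(C, prs[1, k], prs[2, k]),
                   cls[[prs[1, k]]] == cls[[prs[2, k]]])
    }
  }
})

test_that("disconnected classes are split, connected and singleton ones kept", {
  # two transitions sharing no place but the same signature
  net <- petri_net(
    list(place("A"), place("B"), place("C"), place("D")),
    list(transition("t1", c(A = -1, B = 1)), transition("t2", c(C = -1, D = 1))))
  fake_basis <- structure(list(
    kind = "T",
    weights = matrix(1, 1, 2, dimnames = list(NULL, c("t1", "t2"))),
    trivial = FALSE), class = "pn_invariant_set")
  part <- adt_partition(net, fake_basis)
  expect_length(part$classes, 1L)
  dec <- connected_adt_decomposition(net, part)
  expect_length(dec$classes, 2L)
  # hypoxia classes already induce connected subnets: decomposition is a no-op
  hx <- hypoxia_with_invariants()
  part2 <- adt_partition(hx$net, nontrivial(hx$tin))
  dec2 <- connected_adt_decomposition(hx$net, part2)
  expect_equal(lapply(dec2$classes, `[[`, "transitions"),
               lapply(part2$classes, `[[`, "transitions"))
})

test_that("coarsening the hypoxia core yields macros A-E with the known interface", {
  hx <- hypoxia_with_invariants()
  part <- connected_adt_decomposition(hx$net, adt_partition(hx$net, nontrivial(hx$tin)))
  h <- coarsen(hx$net, part, scope = "covered_only")
  expect_length(h$macros, 5L)
  members <- lapply(h$macros, `[[`, "member_transitions")
  names(members) <- vapply(h$macros, `[[`, character(1), "id")
  expect_equal(members$A, "r1")
  expect_equal(members$B, "r2")
  expect_setequal(members$C, c("r3_f", "r4"))
  expect_setequal(members$D, c("r5_f", "r7_f", "r8", "r9_b"))
  expect_setequal(members$E, c("r10_f", "r11"))
  expect_setequal(h$interface_places, c("HIF", "PHD", "HIFOH", "O2"))
  # PHD bridges the two oxygen-dependent macros
  phd <- unique(h$coarse_arcs$macro[h$coarse_arcs$place == "PHD"])
  expect_setequal(phd, c("C", "D"))
  # flattening returns the wrapped core net
  flat <- flatten_hierarchy(h)
  expect_setequal(transition_ids(flat), unlist(members))
  # scope = "all" wraps the empty-signature class too
  h_all <- coarsen(hx$net, part, scope = "all")
  expect_length(h_all$macros, 6L)
  expect_equal(incidence_matrix(flatten_hierarchy(h_all)),
               incidence_matrix(hx$net))
})

test_that("a one-class net coarsens to a single macro with boundary interface", {
  cyc <- cycle_net()
  tin <- classify_t_invariants(cyc, minimal_invariants(cyc, "T"))
  part <- connected_adt_decomposition(cyc, adt_partition(cyc, tin))
  h <- coarsen(cyc, part)
  expect_length(h$macros, 1L)
  expect_length(h$interface_places, 0L)   # fully internal cycle
})

test_that("pathway enumeration recovers (A,B), (A,C,E), (A,D,E)", {
  hx <- hypoxia_with_invariants()
  part <- connected_adt_decomposition(hx$net, adt_partition(hx$net, nontrivial(hx$tin)))
  h <- coarsen(hx$net, part)
  pw <- enumerate_pathways(h, hx$tin)
  expect_true(all(pw$linear))
  expect_setequal(pw$pathway, c("A,B", "A,C,E", "A,D,E"))
  # union of pathway members = transitions covered by non-trivial invariants
  members <- lapply(h$macros, `[[`, "member_transitions")
  names(members) <- vapply(h$macros, `[[`, character(1), "id")
  used <- unique(unlist(members[unlist(strsplit(pw$pathway, ","))]))
  expect_setequal(used, unique(unlist(invariant_supports(nontrivial(hx$tin)))))
})

test_that("a branched invariant is flagged non-linear with members reported", {
  # Y-shaped support: s -> m, then m -> a and m -> b, collected by a sink
  net <- petri_net(
    list(place("S"), place("M"), place("A"), place("B")),
    list(transition("t_in", c(M = 1)),
         transition("t_a", c(M = -1, A = 1)),
         transition("t_b", c(M = -1, B = 1)),
         transition("t_outa", c(A = -1)),
         transition("t_outb", c(B = -1))))
  ids <- transition_ids(net)
  # macros come from the two arms separately ...
  arms <- structure(list(
    kind = "T",
    weights = matrix(c(1, 1, 0, 1, 0,
                       1, 0, 1, 0, 1), 2, 5, byrow = TRUE,
                     dimnames = list(NULL, ids)),
    trivial = c(FALSE, FALSE)), class = "pn_invariant_set")
  # ... while the queried invariant uses both arms at once (Y shape)
  both <- structure(list(
    kind = "T",
    weights = matrix(c(2, 1, 1, 1, 1), 1, 5, dimnames = list(NULL, ids)),
    trivial = FALSE), class = "pn_invariant_set")
  part <- connected_adt_decomposition(net, adt_partition(net, arms))
  h <- coarsen(net, part)
  pw <- enumerate_pathways(h, both)
  expect_false(any(pw$linear))
  expect_true(nzchar(pw$macros[1]))
})
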