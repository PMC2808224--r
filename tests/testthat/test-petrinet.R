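test_that("expand_reversible mirrors reversible reactions into linked pairs", {
  net <- expand_reversible(list(
    reaction("r", c(A = 1), c(B = 1), reversible = TRUE,
             k_forward = 2, k_backward = 3)))
  expect_length(net$transitions, 2L)
  C <- incidence_matrix(net)
  expect_equal(unname(C[, "r_f"]), c(-1, 1))
  expect_equal(unname(C[, "r_b"]), -unname(C[, "r_f"]))
  expect_equal(net$transitions[[1]]$reverse_of, "r_b")
  expect_equal(net$transitions[[2]]$reverse_of, "r_f")
  expect_equal(net$transitions[[1]]$rate, 2)
  expect_equal(net$transitions[[2]]$rate, 3)
})

test_that("a single enzymatic reaction expands to 3 transitions over 4 places", {
  net <- expand_reversible(enzyme_reactions())
  expect_length(net$places, 4L)
  expect_length(net$transitions, 3L)
  expect_setequal(transition_ids(net), c("bind_f", "bind_b", "cat"))
})

test_that("a reversible reaction without k_backward is a configuration error", {
  expect_error(reaction("r", c(A = 1), c(B = 1), reversible = TRUE, k_forward = 1),
               "k_backward")
})

test_that("modifiers become read arcs on both directions of a reversible pair", {
  net <- expand_reversible(list(
    reaction("r", c(A = 1), c(B = 1), modifiers = c(M = 1), reversible = TRUE,
             k_forward = 1, k_backward = 1)))
  expect_equal(net$transitions[[1]]$read, c(M = 1))
  expect_equal(net$transitions[[2]]$read, c(M = 1))
  C <- incidence_matrix(net)
  expect_true(all(C["M", ] == 0))
})

test_that("collapsing expanded pairs recovers the reaction list", {
  rx <- hypoxia_reactions()
  back <- collapse_reversible(expand_reversible(rx))
  expect_length(back, length(rx))
  for (i in seq_along(rx)) {
    expect_equal(back[[i]]$id, rx[[i]]$id)
    for (slot in c("reactants", "products", "modifiers")) {
      a <- back[[i]][[slot]]; b <- rx[[i]][[slot]]
      expect_equal(a[sort(names(a))], b[sort(names(b))])
    }
    expect_equal(back[[i]]$reversible, rx[[i]]$reversible)
    expect_equal(back[[i]]$k_forward, rx[[i]]$k_forward)
    expect_equal(back[[i]]$k_backward, rx[[i]]$k_backward)
  }
})

test_that("merge_logical_places fuses same-named logical copies and keeps arcs", {
  net <- petri_net(
    list(place("X", initial_marking = 2),
         place("O2a", name = "O2", initial_marking = 1, is_logical = TRUE),
         place("O2b", name = "O2", initial_marking = 1, is_logical = TRUE)),
    list(transition("t1", c(X = -1), c(O2a = 1), rate_constant = 1),
         transition("t2", c(X = 1), c(O2b = 1), rate_constant = 1)))
  merged <- merge_logical_places(net)
  expect_length(merged$places, 2L)
  expect_equal(merged$transitions[[1]]$read, c(O2a = 1))
  expect_equal(merged$transitions[[2]]$read, c(O2a = 1))
  # three equal copies fuse to one with the shared marking
  net3 <- petri_net(
    lapply(c("a", "b", "c"), function(s)
      place(paste0("L", s), name = "L", initial_marking = 1, is_logical = TRUE)),
    list(transition("t", c(La = 1))))
  m3 <- merge_logical_places(net3)
  expect_length(m3$places, 1L)
  expect_equal(m3$places[[1]]$initial_marking, 1)
})

test_that("merge_logical_places is the identity without logical places", {
  net <- expand_reversible(enzyme_reactions())
  expect_identical(merge_logical_places(net), net)
})

test_that("conflicting initial markings on logical copies are an error", {
  net <- petri_net(
    list(place("A1", name = "A", initial_marking = 1, is_logical = TRUE),
         place("A2", name = "A", initial_marking = 2, is_logical = TRUE)),
    list(transition("t", c(A1 = 1))))
  expect_error(merge_logical_places(net), "conflicting")
})

test_that("incidence matrix entries are net token changes", {
  expect_equal(unname(incidence_matrix(chain_net())), matrix(c(-1, 1), ncol = 1))
  # stoichiometric cancellation: 2A -> A has net entry -1
  net <- petri_net(list(place("A")), list(transition("t", c(A = -1))))
  expect_equal(unname(incidence_matrix(net)[1, 1]), -1)
})

test_that("read arcs never change incidence entries", {
  rx <- hypoxia_reactions()
  net <- expand_reversible(rx)
  stripped <- net
  stripped$transitions <- lapply(stripped$transitions, function(tr) {
    tr$read <- stats::setNames(numeric(0), character(0)); tr
  })
  # oxygen only appears in read sets, so it is dropped when stripping
  C <- incidence_matrix(net)
  C2 <- incidence_matrix(stripped)
  expect_equal(C[rownames(C2), ], C2)
  expect_true(all(C["O2", ] == 0))
})

test_that("nets validate referential integrity", {
  expect_error(petri_net(list(place("A")),
                         list(transition("t", c(B = 1)))), "unknown place")
  expect_error(petri_net(list(place("A"), place("A"))
                         , list()), "duplicate place")
  expect_error(transition("t", c(A = -1), c(A = 1)), "disjoint")
  expect_error(transition("t", c(A = -1), rate_constant = -1), "non-negative")
  # reverse_of must be symmetric
  expect_error(petri_net(
    list(place("A"), place("B")),
    list(transition("t1", c(A = -1, B = 1), reverse_of = "t2"),
         transition("t2", c(A = 1, B = -1)))), "symmetric")
})

test_that("subnet keeps reverse links inside the kept set and drops isolated places", {
  net <- expand_reversible(enzyme_reactions())
  s <- subnet(net, c("bind_f", "cat"))
  expect_setequal(transition_ids(s), c("bind_f", "cat"))
  expect_true(is.na(s$transitions[[1]]$reverse_of))
  s2 <- subnet(net, "cat")
  expect_setequal(place_ids(s2), c("E", "ES", "P"))
})
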