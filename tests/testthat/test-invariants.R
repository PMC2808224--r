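test_that("minimal invariants of elementary nets are exact", {
  # single irreversible A -> B: no T-invariant, one P-invariant {A, B}
  net <- chain_net()
  expect_equal(nrow(minimal_invariants(net, "T")$weights), 0L)
  P <- minimal_invariants(net, "P")
  expect_equal(unname(P$weights), matrix(c(1, 1), nrow = 1))
  # closed cycle: one T-invariant (1,1) and one P-invariant (1,1)
  cyc <- cycle_net()
  expect_equal(unname(minimal_invariants(cyc, "T")$weights),
               matrix(c(1, 1), nrow = 1))
  expect_equal(unname(minimal_invariants(cyc, "P")$weights),
               matrix(c(1, 1), nrow = 1))
})

test_that("hypoxia P-invariants reproduce the five conservation pools", {
  net <- build_full_hypoxia_net()
  P <- minimal_invariants(net, "P")
  expect_equal(nrow(P$weights), 5L)
  expect_true(all(P$weights %in% c(0, 1)))
  supports <- invariant_supports(P)
  expect_true(list("O2") %in% lapply(supports, as.list) ||
                any(vapply(supports, function(s) setequal(s, "O2"), logical(1))))
  expected <- list(
    c("O2"),
    c("PHD", "HIF_PHD", "HIF_ARNT_PHD"),
    c("ARNT", "HIF_ARNT", "HIF_ARNT_HRE", "HIF_ARNT_PHD", "HIFOH_ARNT",
      "HIFOH_ARNT_HRE"),
    c("VHL", "HIFOH_VHL"),
    c("HRE", "HIF_ARNT_HRE", "HIFOH_ARNT_HRE"))
  for (e in expected) {
    expect_true(any(vapply(supports, function(s) setequal(s, e), logical(1))))
  }
})

test_that("hypoxia T-invariants are the 7 reverse pairs plus 3 pathways", {
  net <- build_full_hypoxia_net()
  Tset <- classify_t_invariants(net, minimal_invariants(net, "T"))
  expect_equal(nrow(Tset$weights), 10L)
  expect_equal(sum(Tset$trivial), 7L)
  nt <- nontrivial(Tset)
  sizes <- sort(unname(rowSums(nt$weights > 0)))
  expect_equal(sizes, c(2L, 5L, 7L))
  supports <- invariant_supports(nt)
  expect_true(any(vapply(supports, function(s) setequal(s, c("r1", "r2")), logical(1))))
  expect_true(any(vapply(supports, function(s)
    setequal(s, c("r1", "r3_f", "r4", "r10_f", "r11")), logical(1))))
  expect_true(any(vapply(supports, function(s)
    setequal(s, c("r1", "r5_f", "r7_f", "r8", "r9_b", "r10_f", "r11")), logical(1))))
  # the HIFOH/ARNT pair is structurally trivial but its dissociation
  # direction also carries I/O flux; it must appear in the annotation
  io <- attr(Tset, "io_contributing_pairs")
  r9pair <- which(vapply(seq_len(nrow(Tset$weights)), function(i) {
    s <- colnames(Tset$weights)[Tset$weights[i, ] > 0]
    setequal(s, c("r9_f", "r9_b"))
  }, logical(1)))
  expect_true(r9pair %in% io)
})

test_that("triviality is structural and type-checked", {
  net <- expand_reversible(list(reaction("a", c(X = 1), c(Y = 1), k_forward = 1),
                                reaction("b", c(Y = 1), c(X = 1), k_forward = 1)))
  Tset <- classify_t_invariants(net, minimal_invariants(net, "T"))
  expect_equal(sum(Tset$trivial), 0L)   # a/b are not an expanded pair
  expect_error(classify_t_invariants(net, minimal_invariants(net, "P")),
               "T-invariant")
})

test_that("coverage flags behave on covered, uncovered and hypoxia nets", {
  cyc <- cycle_net()
  cov <- coverage_report(cyc, minimal_invariants(cyc, "P"),
                         classify_t_invariants(cyc, minimal_invariants(cyc, "T")))
  expect_true(cov$cpi); expect_true(cov$cti)
  src <- source_net()
  cov2 <- coverage_report(src, minimal_invariants(src, "P"),
                          classify_t_invariants(src, minimal_invariants(src, "T")))
  expect_false(cov2$cti)
  net <- build_full_hypoxia_net()
  cov3 <- coverage_report(net, minimal_invariants(net, "P"),
                          classify_t_invariants(net, minimal_invariants(net, "T")))
  expect_false(cov3$cpi)
  expect_setequal(cov3$uncovered_places, c("HIF", "HIFOH"))
  expect_true(cov3$cti)
  expect_false(cov3$scti)
  expect_length(cov3$uncovered_by_nontrivial, 9L)
})

test_that("scaling arc weights rescales invariants but keeps supports", {
  for (s in 1:20) {
    net <- random_massaction_net(2 + (s %% 5), 2 + ((s * 3) %% 5), seed = 1000 + s)
    C <- incidence_matrix(net)
    for (kind in c("P", "T")) {
      a <- minimal_invariants(C, kind)
      b <- minimal_invariants(3 * C, kind)
      expect_setequal(weight_set(a$weights), weight_set(b$weights))
    }
  }
})

test_that("every returned invariant satisfies its kernel equation exactly", {
  for (s in 1:25) {
    net <- random_massaction_net(2 + (s %% 5), 2 + ((s * 3) %% 5), seed = 2000 + s)
    C <- incidence_matrix(net)
    P <- minimal_invariants(net, "P")$weights
    Tw <- minimal_invariants(net, "T")$weights
    if (nrow(P) > 0L) expect_true(all(t(C) %*% t(P) == 0))
    if (nrow(Tw) > 0L) expect_true(all(C %*% t(Tw) == 0))
  }
})

test_that("the intermediate-row guard triggers with a clear diagnostic", {
  net <- build_full_hypoxia_net()
  expect_error(minimal_invariants(net, "T", max_rows = 3), "max_rows")
})

test_that("structural deadlock fixpoints match the theory", {
  # a self-loop (read arc) keeps {A} as its own deadlock
  loop <- petri_net(list(place("A")),
                    list(transition("t", read_set = c(A = 1))))
  expect_equal(largest_structural_deadlock(loop, "A"), "A")
  expect_true(is_in_proper_deadlock(loop, "A"))
  # the support of every hypoxia P-invariant is a deadlock (fixed point)
  net <- build_full_hypoxia_net()
  for (s in invariant_supports(minimal_invariants(net, "P"))) {
    expect_setequal(largest_structural_deadlock(net, s), s)
  }
  # the uncovered input/output species are in no proper deadlock: their
  # initial concentrations may be zero
  expect_false(is_in_proper_deadlock(net, "HIF"))
  expect_false(is_in_proper_deadlock(net, "HIFOH"))
  expect_error(largest_structural_deadlock(net, "nope"), "unknown")
})

test_that("core reduction removes exactly the uncovered transitions", {
  net <- build_full_hypoxia_net()
  Tset <- classify_t_invariants(net, minimal_invariants(net, "T"))
  red <- reduce_to_core(net, Tset)
  expect_length(transition_ids(red$core_net), 10L)
  expect_setequal(red$removed_transitions,
                  c("r3_b", "r5_b", "r6_f", "r6_b", "r7_b", "r9_f",
                    "r10_b", "r12_f", "r12_b"))
  expect_setequal(red$removed_places,
                  c("HRE", "HIF_ARNT_HRE", "HIFOH_ARNT_HRE"))
  # core transition set = union of non-trivial supports
  nt <- nontrivial(Tset)
  expect_setequal(transition_ids(red$core_net),
                  unique(unlist(invariant_supports(nt))))
  # re-analysis of the core: same 3 non-trivial invariants, now SCTI
  core <- red$core_net
  Tcore <- classify_t_invariants(core, minimal_invariants(core, "T"))
  expect_equal(nrow(Tcore$weights), 3L)
  expect_equal(sum(Tcore$trivial), 0L)
  covc <- coverage_report(core, minimal_invariants(core, "P"), Tcore)
  expect_true(covc$cti); expect_true(covc$scti)
  expect_setequal(weight_set(nontrivial(Tcore)$weights), weight_set(nt$weights))
})

test_that("an already strongly covered net reduces to itself", {
  cyc <- cycle_net()
  Tset <- classify_t_invariants(cyc, minimal_invariants(cyc, "T"))
  red <- reduce_to_core(cyc, Tset)
  expect_length(red$removed_transitions, 0L)
  expect_length(red$removed_places, 0L)
  # with no non-trivial invariant the reduction is undefined
  pair <- expand_reversible(list(reaction("r", c(A = 1), c(B = 1),
                                          reversible = TRUE, k_forward = 1,
                                          k_backward = 1)))
  Tp <- classify_t_invariants(pair, minimal_invariants(pair, "T"))
  expect_error(reduce_to_core(pair, Tp), "nothing to preserve")
})
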