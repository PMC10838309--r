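# A small clean tandem fixture where every mined probe has binding_prop 1.
selection_fixture <- function(seed = 110, copies = 15L) {
  fx <- generate_fixture(fixture_spec(monomer_length = 120L, copies = copies,
                                      divergence = 0, flank_length = 2000L,
                                      seed = seed))
  tab <- count_kmers(fx$assembly, 18)
  target <- fx$truth[1, ]
  cands <- deduplicate(mine_candidates(target, fx$assembly))
  scored <- score_candidates(cands, tab, target, fx$assembly)
  ranked <- mer_cutoff_filter(normalized_rank(scored), 0.95, 18)
  list(fx = fx, target = target, ranked = ranked)
}

test_that("selection stops at target_sum with the top candidate alone", {
  sf <- selection_fixture()
  crit <- selection_criteria(target_sum = 5, min_on_target = 1,
                             max_probe_return = 10)
  ps <- select_probes(sf$ranked, sf$fx$assembly, sf$target, crit,
                      thermo_model())
  expect_equal(nrow(ps$accepted), 1L)
  expect_equal(ps$termination_reason, "target_sum_met")
  expect_gte(ps$aggregate_on_t, 5)
})

test_that("an exact duplicate of an accepted probe is rejected as redundant", {
  sf <- selection_fixture()
  dup_stream <- rbind(sf$ranked[1, ], sf$ranked[1, ], sf$ranked[2, ])
  crit <- selection_criteria(target_sum = 1e6, min_on_target = 1,
                             max_probe_return = 3, max_pdups_binding = 0.9)
  ps <- select_probes(dup_stream, sf$fx$assembly, sf$target, crit,
                      thermo_model())
  expect_equal(ps$log$decision, c("accept", "reject", "accept"))
  expect_equal(ps$log$reason[2], "max_pdups_binding")
})

test_that("accepted probes respect all per-probe criteria", {
  sf <- selection_fixture(111)
  crit <- selection_criteria(target_sum = 1e6, min_on_target = 2,
                             max_probe_return = 5, min_binding_prop = 0.9)
  ps <- select_probes(sf$ranked, sf$fx$assembly, sf$target, crit,
                      thermo_model())
  expect_gte(nrow(ps$accepted), 1L)
  expect_true(all(ps$accepted$on_t >= 2))
  expect_true(all(ps$accepted$binding_prop >= 0.9))
  expect_equal(ps$aggregate_on_t, sum(ps$accepted$on_t), tolerance = 1e-9)
  expect_equal(ps$aggregate_off_t, sum(ps$accepted$off_t), tolerance = 1e-9)
})

test_that("selection is deterministic and monotone under criterion relaxation", {
  sf <- selection_fixture(112)
  crit <- selection_criteria(target_sum = 1e6, min_on_target = 5,
                             max_probe_return = 3, max_pdups_binding = 0.3)
  ps1 <- select_probes(sf$ranked, sf$fx$assembly, sf$target, crit,
                       thermo_model())
  ps2 <- select_probes(sf$ranked, sf$fx$assembly, sf$target, crit,
                       thermo_model())
  expect_identical(ps1$accepted, ps2$accepted)

  base_seqs <- ps1$accepted$sequence
  relaxed <- list(
    selection_criteria(target_sum = 1e6, min_on_target = 1,
                       max_probe_return = 3, max_pdups_binding = 0.3),
    selection_criteria(target_sum = 1e6, min_on_target = 5,
                       max_probe_return = 6, max_pdups_binding = 0.3),
    selection_criteria(target_sum = 1e6, min_on_target = 5,
                       max_probe_return = 3, max_pdups_binding = 0.8)
  )
  for (crit_r in relaxed) {
    ps_r <- select_probes(sf$ranked, sf$fx$assembly, sf$target, crit_r,
                          thermo_model())
    expect_gte(nrow(ps_r$accepted), length(base_seqs))
  }
})

test_that("a decoy array drags down binding_prop and can be filtered on", {
  fx <- generate_fixture(fixture_spec(monomer_length = 120L, copies = 12L,
                                      divergence = 0, flank_length = 2000L,
                                      decoy_identity = 1.0, seed = 113))
  # decoy identical to target: every probe binds both arrays equally
  tab <- count_kmers(fx$assembly, 18)
  target <- fx$truth[fx$truth$name == "target", ]
  cands <- deduplicate(mine_candidates(target, fx$assembly))
  scored <- score_candidates(cands, tab, target, fx$assembly)
  ranked <- mer_cutoff_filter(normalized_rank(scored), 0.95, 18)
  crit <- selection_criteria(target_sum = 1e6, min_on_target = 1,
                             max_probe_return = 2, min_binding_prop = 0.9,
                             off_bin_thresh = 1e6)
  ps <- select_probes(ranked, fx$assembly, target, crit, thermo_model())
  expect_true(is.null(ps$accepted))  # all rejected: binding_prop ~ 0.5
  expect_true(all(ps$log$reason == "min_binding_prop"))
  expect_equal(ps$termination_reason, "exhausted")

  crit_loose <- selection_criteria(target_sum = 1e6, min_on_target = 1,
                                   max_probe_return = 2,
                                   min_binding_prop = 0.4,
                                   off_bin_thresh = 1e6)
  ps2 <- select_probes(ranked, fx$assembly, target, crit_loose,
                       thermo_model())
  expect_equal(nrow(ps2$accepted), 2L)
  expect_true(all(abs(ps2$accepted$binding_prop - 0.5) < 0.05))
})
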