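test_that("the classifier is total, single-valued, and matches the case oracle", {
  tri <- all_triplets()
  got <- classify_gene(tri$c1, tri$c2, tri$c3)
  expect_length(got, 27)
  expect_true(all(got %in% TRAJECTORY_CLASSES))
  oracle <- mapply(classify_oracle, tri$c1, tri$c2, tri$c3)
  expect_equal(got, unname(oracle))
  expect_error(classify_gene("up", "sideways", "ns"), "invalid call token")
})

test_that("published archetype examples classify as described", {
  expect_equal(classify_gene("up", "down", "down"), "persistent_reversed")
  expect_equal(classify_gene("up", "ns", "down"), "transient")
  expect_equal(classify_gene("ns", "ns", "ns"), "unchanged")
  expect_equal(classify_gene("ns", "up", "ns"), "deprivation_emergent")
  expect_equal(classify_gene("ns", "ns", "up"), "deprivation_shifted")
  expect_equal(classify_gene("down", "down", "ns"), "persistent_same_sign")
})

test_that("pathology rules implement the persistence criterion", {
  # Th-like pattern: altered at AD vs both baselines -> every rule flags it
  for (r in c("cvsad_or_a20vsad", "cvsad_only", "non_normalized"))
    expect_true(pathology_flag("up", "down", "down", r))
  # fully normalized gene: c1 only -> never flagged
  expect_false(pathology_flag("up", "ns", "ns"))
  # A20-vs-AD-only shift (Grm7-like) -> default rule flags it
  expect_true(pathology_flag("ns", "ns", "up"))
  expect_false(pathology_flag("ns", "ns", "up", "cvsad_only"))
  expect_true(pathology_flag("ns", "ns", "up", "non_normalized"))
  expect_false(pathology_flag("ns", "ns", "ns"))
  expect_error(pathology_flag("up", "ns", "ns", "bogus"))
})

test_that("rule implications hold over all 27 triplets", {
  tri <- all_triplets()
  strict <- pathology_flag(tri$c1, tri$c2, tri$c3, "cvsad_only")
  deflt <- pathology_flag(tri$c1, tri$c2, tri$c3, "cvsad_or_a20vsad")
  nonnorm <- pathology_flag(tri$c1, tri$c2, tri$c3, "non_normalized")
  expect_true(all(deflt[strict]))          # cvsad_only  =>  default
  expect_true(all(deflt[nonnorm]))         # non_normalized  =>  default
  # non_normalized never flags a transient gene
  cls <- classify_gene(tri$c1, tri$c2, tri$c3)
  expect_false(any(nonnorm[cls == "transient"]))
})

test_that("panel summaries reproduce the published per-system counts", {
  calls <- nacc_call_fixture()
  panels <- load_default_panels()

  gaba <- summarize_panel(calls, panels$GABAergic)
  expect_equal(length(gaba$deg_set), 6)
  expect_equal(unname(gaba$category_counts["transient"]), 5L)
  non_transient <- setdiff(gaba$deg_set,
                           calls$gene[classify_gene(calls$call_c1,
                                                    calls$call_c2,
                                                    calls$call_c3) == "transient"])
  expect_equal(non_transient, "Gabra5")

  glut <- summarize_panel(calls, panels$glutamatergic)
  expect_equal(glut$pathology_set,
               sort(c("Grin3a", "Grik4", "Grid1", "Grik5", "Grm2", "Grm5",
                      "Grm7", "Gad1")))
  # subclass composition of the glutamatergic DEG set
  expect_equal(as.integer(glut$subclass_counts[c("metabotropic_receptor",
                                                 "ionotropic_receptor",
                                                 "decarboxylase",
                                                 "transporter")]),
               c(7L, 12L, 2L, 2L))

  opi <- summarize_panel(calls, panels$opioidergic_cannabinoidergic)
  expect_equal(opi$pathology_set, c("Oprk1", "Pdyn", "Penk"))

  ca <- summarize_panel(calls, panels$catecholaminergic)
  expect_equal(length(ca$tested), 14)
  expect_equal(unname(ca$updown_counts["up", "c1"]), 4L)
  expect_equal(unname(ca$updown_counts["down", "c1"]), 6L)
  # the six-gene published CAergic pathology list is recovered by the
  # strict control-vs-deprived rule
  ca_strict <- summarize_panel(calls, panels$catecholaminergic, "cvsad_only")
  expect_equal(ca_strict$pathology_set,
               sort(c("Th", "Drd1", "Drd2", "Adra2c", "Ppp1r1b", "Maoa")))
})

test_that("empty inputs behave per contract", {
  empty <- call_table(data.frame(gene = character(), system = character(),
                                 call_c1 = character(), call_c2 = character(),
                                 call_c3 = character()))
  s <- summarize_panel(empty, load_default_panels()$GABAergic)
  expect_equal(sum(s$category_counts), 0L)
  expect_equal(length(s$untested), 23)
  expect_equal(length(s$deg_set), 0)
  expect_error(summarize_panel(empty, gene_panel("x", character())), "empty panel")
})

test_that("classify_trajectories annotates a call table end to end", {
  calls <- nacc_call_fixture()
  traj <- classify_trajectories(calls, rule = "cvsad_or_a20vsad")
  expect_equal(nrow(traj), nrow(calls))
  expect_true(all(traj$category %in% TRAJECTORY_CLASSES))
  expect_equal(traj$category[traj$gene == "Th"], "persistent_reversed")
  expect_true(traj$pathology[traj$gene == "Th"])
  expect_false(traj$pathology[traj$gene == "Slc6a3"])
  expect_equal(unique(traj$rule_id), "cvsad_or_a20vsad")
})

test_that("pipeline recovery: summaries from diffexpr match summaries from truth", {
  counts <- setNames(c(60, 10, 10, 5, 10, 5), TRAJECTORY_CLASSES)
  sim <- generate_dataset(simulation_spec(class_counts = counts, seed = 13))
  res <- run_comparisons(sim$expression)
  got <- calls_from_results(res)
  want <- truth_to_expected_calls(sim$truth)
  got_cls <- classify_gene(got$call_c1, got$call_c2, got$call_c3)
  want_cls <- classify_gene(want$call_c1, want$call_c2, want$call_c3)
  expect_gte(mean(got_cls == want_cls), 0.9)
})
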