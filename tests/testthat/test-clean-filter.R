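# The cleaning ladder: filters, frequency strategies, dedup and splits.

test_that("reactions without reactants or products are dropped", {
  x <- role_table(
    reactants = list(character(0), "CCO", "CC"),
    products = list("CC=O", "CC=O", character(0))
  )
  out <- drop_empty(start_funnel(x))
  expect_equal(nrow(out), 1)
  expect_identical(out$record_id, "r002")
  expect_equal(nrow(drop_empty(x[0, ])), 0)
  expect_identical(utils::tail(get_funnel(out)$step, 1), "no reactants/products")
})

test_that("component counting splits top-level fragments (binary salts count per ion)", {
  expect_equal(count_components("[Na+].[Cl-]"), 2)
  expect_equal(count_components(c("CCO", "O")), 2)
  expect_equal(count_components(character(0)), 0)
  expect_equal(count_components("CC(C)C"), 1)  # branch parens are not fragments
})

test_that("component-count maxima apply per role in funnel order", {
  x <- role_table(
    reactants = list("CCO", c("CCO", "CC", "CCC"), "CC"),
    products = list(c("CC=O", "C=O"), "CC=O", "CC=O"),
    agents = list("[Na+].[Cl-]", character(0), "[Pd]")
  )
  cfg <- cleaning_config(max_reactants = 2, max_products = 1, max_agents = 1)
  out <- filter_component_counts(start_funnel(x), cfg)
  # r001: 2 products out; r002: 3 reactants out; r003 survives ([Pd] = 1)
  expect_identical(out$record_id, "r003")
  steps <- get_funnel(out)$step
  expect_identical(steps, c("full data set", "too many reactants",
                            "too many products", "too many agents"))
  # the binary salt counts as two agents
  cfg2 <- cleaning_config(max_agents = 1)
  out2 <- filter_component_counts(x, cfg2)
  expect_false("r001" %in% out2$record_id)
  # all-unlimited config is the identity
  expect_equal(nrow(filter_component_counts(x, cleaning_config())), 3)
})

test_that("yield sanitization nulls violating yields but keeps the reaction", {
  x <- role_table(
    reactants = list("C", "C", "C"), products = list("CO", "CO", "CO"),
    yields = list(c(50, 60), -5, 88)
  )
  off <- sanitize_yields(x, FALSE)
  expect_equal(off$yields_percent, x$yields_percent)
  on <- sanitize_yields(x, TRUE)
  expect_equal(nrow(on), 3)
  expect_length(on$yields_percent[[1]], 0)  # sum 110 -> nulled
  expect_length(on$yields_percent[[2]], 0)  # negative -> nulled
  expect_equal(on$yields_percent[[3]], 88)
})

test_that("spectator frequencies are per-occurrence and per-role", {
  x <- role_table(
    reactants = list("C", "C", "C"), products = list("CO", "CO", "CO"),
    solvents = list("O", "O", character(0)),
    agents = list("O", "[Pd]", "[Pd]")
  )
  f <- spectator_frequencies(x)
  expect_equal(f$n[f$role == "solvent" & f$smiles == "O"], 2)
  expect_equal(f$n[f$role == "agent" & f$smiles == "O"], 1)
  expect_equal(f$n[f$role == "agent" & f$smiles == "[Pd]"], 2)
  expect_equal(nrow(spectator_frequencies(x[0, ])), 0)
})

test_that("frequency filtering honours both rare strategies and threshold edge cases", {
  fx <- generate_fixtures(fixture_spec(n_reactions = 40, seed = 13))
  roles <- assign_roles(fx$records, "rxn_string", test_lexicon)
  roles <- inject_rare_agents_roles(roles, 4)
  for (t in c(1, 2, 100)) {
    cfg <- cleaning_config(frequency_threshold = t, rare_strategy = "delete_rxn")
    out <- frequency_filter(roles, cfg)
    pre <- spectator_frequencies(roles)
    retained <- spectator_frequencies(out)
    if (nrow(retained)) {
      pre_counts <- pre$n[match(paste(retained$role, retained$smiles),
                                paste(pre$role, pre$smiles))]
      expect_true(all(pre_counts >= t))
    }
    cfg2 <- cleaning_config(frequency_threshold = t, rare_strategy = "map_to_other")
    out2 <- frequency_filter(roles, cfg2)
    expect_equal(nrow(out2), nrow(roles))
    rare <- pre[pre$n < t, ]
    expect_false(any(unlist(out2$solvents) %in% rare$smiles[rare$role == "solvent"]))
    expect_false(any(unlist(out2$agents) %in% rare$smiles[rare$role == "agent"]))
    n_other <- sum(unlist(out2$agents) == "other") + sum(unlist(out2$solvents) == "other")
    expect_equal(n_other, sum(rare$n))
    # reactants and products are never rewritten
    expect_identical(out2$reactants, roles$reactants)
    expect_identical(out2$products, roles$products)
  }
  # threshold 0 is the identity under both strategies
  for (s in c("delete_rxn", "map_to_other")) {
    cfg0 <- cleaning_config(frequency_threshold = 0, rare_strategy = s)
    expect_equal(nrow(frequency_filter(roles, cfg0)), nrow(roles))
    expect_false(any(unlist(frequency_filter(roles, cfg0)$agents) == "other"))
  }
})

test_that("deduplication keys on sorted component sets only and is idempotent", {
  x <- role_table(
    reactants = list(c("CCO", "CC"), c("CC", "CCO"), "CCO"),
    products = list("CC=O", "CC=O", "CC=O"),
    agents = list("[Pd]", "[Pd]", "[Ni]")
  )
  x$procedure_details <- c("run one", "run two", "run three")
  out <- drop_duplicates(x)
  expect_identical(out$record_id, c("r001", "r003"))  # stable: first kept
  expect_identical(drop_duplicates(out)$record_id, out$record_id)
})

test_that("grouped splits are reproducible, leakage-free and near the target fractions", {
  # 1000 distinct single-member keys: greedy fill is exact to +/- 2 groups
  x <- role_table(
    reactants = lapply(1:1000, function(i) sprintf("C%d", i)),
    products = lapply(1:1000, function(i) sprintf("P%d", i))
  )
  keys <- sprintf("k%04d", 1:1000)
  cfg <- cleaning_config(seed = 7)
  s1 <- grouped_random_split(x, cfg, key = keys)
  s2 <- grouped_random_split(x, cfg, key = keys)
  expect_identical(s1$split, s2$split)
  sizes <- table(s1$split)
  expect_lte(abs(sizes[["train"]] - 800), 2)
  expect_lte(abs(sizes[["val"]] - 100), 2)
  expect_lte(abs(sizes[["test"]] - 100), 2)
  expect_equal(split_leakage(s1), 0)

  # reactions sharing a key are co-located
  y <- role_table(
    reactants = lapply(1:10, function(i) "CCO"),
    products = lapply(1:10, function(i) sprintf("P%d", i))
  )
  shared <- c("g1", "g1", sprintf("g%d", 2:9))
  sp <- grouped_random_split(y, cleaning_config(seed = 3), key = shared)
  expect_equal(length(unique(sp$split[shared == "g1"])), 1)
  expect_equal(split_leakage(sp), 0)

  expect_error(
    grouped_random_split(y[1:2, ], cleaning_config(seed = 1), key = c("a", "a")),
    "fewer distinct")
})

test_that("cleaning config validates its invariants", {
  expect_error(cleaning_config(split_fractions = c(0.8, 0.1, 0.2)))
  expect_error(cleaning_config(frequency_threshold = -1))
  expect_error(cleaning_config(rare_strategy = "nope"))
  cfg <- cleaning_config(max_products = 1)
  expect_s3_class(cfg, "cleaning_config")
})
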