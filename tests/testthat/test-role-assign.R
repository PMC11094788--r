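# Reaction parsing and role assignment from atom maps and from labels.

test_that("reaction strings parse into sided fragments with heavy-atom maps", {
  p <- parse_mapped_reaction("[CH3:1][OH:2]>>[CH3:1][Cl:3]")
  expect_identical(p$fragments$side, c("left", "right"))
  expect_equal(p$fragments$map_ids[[1]], c(1L, 2L))
  expect_equal(p$fragments$map_ids[[2]], c(1L, 3L))

  p2 <- parse_mapped_reaction("C.CC>CO>CCO")
  expect_equal(sum(p2$fragments$side == "left"), 2)
  expect_equal(sum(p2$fragments$side == "middle"), 1)

  # map indices on hydrogens are not heavy-atom contributions
  p3 <- parse_mapped_reaction("[H:9][H:10].[CH2:1]=[CH2:2]>>[CH3:1][CH3:2]")
  expect_equal(p3$fragments$map_ids[[1]], integer(0))

  expect_error(parse_mapped_reaction("CCO>CC"), "exactly two")
  expect_error(parse_mapped_reaction("CCO>C>C>O"), "exactly two")
  expect_error(parse_mapped_reaction("C1CC>>C"), "unparsable fragment")
})

test_that("map bookkeeping assigns reactants, solvents and agents", {
  # esterification: acid and alcohol contribute heavy atoms, the unmapped
  # sulfuric acid does not
  p <- parse_mapped_reaction(
    "[CH3:1][C:2](=[O:3])[OH:4].[CH3:5][OH:6].OS(=O)(=O)O>>[CH3:5][O:6][C:2](=[O:3])[CH3:1]")
  r <- assign_roles_from_rxn_string(p, test_lexicon)
  expect_setequal(r$reactants, c("CC(=O)O", "CO"))
  expect_identical(r$products, "COC(=O)C")
  expect_identical(r$agents, "OS(=O)(=O)O")
  expect_identical(r$solvents, character(0))

  # partition: every fragment lands in exactly one role list
  expect_equal(length(r$reactants) + length(r$products) +
                 length(r$solvents) + length(r$agents),
               nrow(p$fragments))

  # a lexicon solvent on the left side is a solvent, not an agent
  p2 <- parse_mapped_reaction(
    "[CH3:1][C:2](=[O:3])[OH:4].[CH3:5][OH:6].C1CCOC1>>[CH3:5][O:6][C:2](=[O:3])[CH3:1]")
  r2 <- assign_roles_from_rxn_string(p2, test_lexicon)
  expect_identical(r2$solvents, canonicalize_smiles("C1CCOC1"))

  expect_error(
    assign_roles_from_rxn_string(parse_mapped_reaction("CCO.[Pd]>>"), test_lexicon),
    "empty product side")
})

test_that("molecular hydrogen is a reactant despite contributing no heavy atom", {
  p <- parse_mapped_reaction("[CH2:1]=[CH2:2].[H][H]>[Pd]>[CH3:1][CH3:2]")
  r <- assign_roles_from_rxn_string(p, test_lexicon)
  expect_setequal(r$reactants, c("C=C", "[H][H]"))
  expect_identical(r$agents, "[Pd]")
  expect_false("[H][H]" %in% r$agents)
})

test_that("atom-map contribution overrides middle-segment position", {
  # the methanol sits in the agent slot of the string but maps into the product
  p <- parse_mapped_reaction(
    "[CH3:1][C:2](=[O:3])[OH:4]>[CH3:5][OH:6]>[CH3:5][O:6][C:2](=[O:3])[CH3:1]")
  r <- assign_roles_from_rxn_string(p, test_lexicon)
  expect_true("CO" %in% r$reactants)
})

test_that("a molecule unchanged on both sides is one agent, not reactant+product", {
  p <- parse_mapped_reaction(
    "[CH3:1][OH:2].[CH3:3][CH3:4]>>[CH3:1][Cl:5].[CH3:3][CH3:4]")
  r <- assign_roles_from_rxn_string(p, test_lexicon)
  expect_identical(r$agents, "CC")
  expect_identical(r$products, canonicalize_smiles("CCl"))
  expect_false("CC" %in% r$reactants)
})

test_that("role assignment is invariant under joint fragment permutation", {
  base <- c("[CH3:1][C:2](=[O:3])[OH:4]", "[CH3:5][OH:6]", "OS(=O)(=O)O", "C1CCOC1")
  prod <- "[CH3:5][O:6][C:2](=[O:3])[CH3:1]"
  ref <- NULL
  set.seed(11)
  for (i in 1:6) {
    rxn <- paste0(paste(sample(base), collapse = "."), ">>", prod)
    r <- assign_roles_from_rxn_string(parse_mapped_reaction(rxn), test_lexicon)
    key <- lapply(r[c("reactants", "products", "solvents", "agents")], sort)
    if (is.null(ref)) ref <- key else expect_identical(key, ref)
  }
})

test_that("classify_spectator is pure lexicon membership", {
  expect_identical(classify_spectator("O", test_lexicon), "solvent")
  expect_identical(classify_spectator("[Pd]", test_lexicon), "agent")
  empty_lex <- structure(character(0), class = c("solvent_lexicon", "character"))
  expect_identical(classify_spectator(c("O", "[Pd]"), empty_lex),
                   c("agent", "agent"))
})

test_that("labeling provenance relabels components and keeps contamination", {
  fx <- generate_fixtures(fixture_spec(n_reactions = 12, seed = 5,
                                       mislabel_agent_as_reactant = 1))
  lab <- assign_roles(fx$records, "labeling", test_lexicon, test_name_table)
  rxn <- assign_roles(fx$records, "rxn_string", test_lexicon)
  expect_true(all(is.na(lab$error)))
  # every record was injected: labeling sees more reactants than the string
  cmp <- compare_role_provenances(rxn, lab)
  expect_true(all(cmp$delta_reactants >= 1))
  # the mislabeled molecule stays an agent under rxn-string provenance
  i <- 1
  moved <- setdiff(lab$reactants[[i]], rxn$reactants[[i]])
  expect_true(all(moved %in% rxn$agents[[i]]))
})

test_that("labeling fails records without any labeled reactants or products", {
  rec <- generate_fixtures(fixture_spec(n_reactions = 1, seed = 1))$records
  rec$labeled_reactants[[1]] <- character(0)
  rec$labeled_products[[1]] <- character(0)
  lab <- assign_roles(rec, "labeling", test_lexicon, test_name_table)
  expect_match(lab$error[[1]], "neither labeled reactants nor")
})

test_that("provenance comparison reports symmetric differences", {
  fx <- generate_fixtures(fixture_spec(n_reactions = 6, seed = 9))
  a <- assign_roles(fx$records, "rxn_string", test_lexicon)
  cmp <- compare_role_provenances(a, a)
  expect_true(all(cmp$n_disagreements == 0))
  expect_true(all(cmp$delta_reactants == 0))
  b <- a
  b$reactants[[2]] <- c(b$reactants[[2]], b$agents[[2]][1])
  b$agents[[2]] <- b$agents[[2]][-1]
  cmp2 <- compare_role_provenances(a, b)
  expect_equal(cmp2$delta_reactants[2], 1)
  expect_equal(cmp2$n_disagreements[2], 2)  # one per role touched
  expect_error(compare_role_provenances(a, b[-1, ]), "different record_id")
})

test_that("noise-free fixtures recover ground truth exactly", {
  fx <- generate_fixtures(fixture_spec(n_reactions = 60, seed = 21))
  roles <- assign_roles(fx$records, "rxn_string", test_lexicon)
  expect_true(all(is.na(roles$error)))
  expect_true(all(roles_match_truth(roles, fx$truth)))
  # partition property against the source string
  n_frag <- vapply(seq_len(nrow(roles)), function(i) {
    length(roles$reactants[[i]]) + length(roles$products[[i]]) +
      length(roles$solvents[[i]]) + length(roles$agents[[i]])
  }, integer(1))
  expect_identical(n_frag, roles$n_fragments)
})
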