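# Shared fixtures, computed once when the helpers are sourced.

test_lexicon <- read_solvent_lexicon()
test_name_table <- name_resolution_table()

# does a role assignment row match the generator's ground truth?
roles_match_truth <- function(roles, truth) {
  vapply(seq_len(nrow(roles)), function(i) {
    j <- match(roles$record_id[[i]], truth$record_id)
    setequal(roles$reactants[[i]], truth$reactants[[j]]) &&
      setequal(roles$products[[i]], truth$products[[j]]) &&
      setequal(roles$solvents[[i]], truth$solvents[[j]]) &&
      setequal(roles$agents[[i]], truth$agents[[j]])
  }, logical(1))
}

# minimal role tibble for cleaning tests, built directly from component lists
role_table <- function(reactants, products, solvents = NULL, agents = NULL,
                       yields = NULL) {
  n <- length(reactants)
  solvents <- solvents %||% rep(list(character(0)), n)
  agents <- agents %||% rep(list(character(0)), n)
  out <- tibble::tibble(
    record_id = sprintf("r%03d", seq_len(n)),
    reactants = reactants, products = products,
    solvents = solvents, agents = agents,
    n_fragments = lengths(reactants) + lengths(products) +
      lengths(solvents) + lengths(agents),
    provenance = "rxn_string", error = NA_character_
  )
  if (!is.null(yields)) out$yields_percent <- yields
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# append one unique frequency-one agent to each of the first n_rare rows of
# a role table (role-level analogue of inject_rare_agents())
inject_rare_agents_roles <- function(roles, n_rare) {
  for (j in seq_len(n_rare)) {
    roles$agents[[j]] <- c(roles$agents[[j]],
                           paste0("FC(F)(F)", strrep("C", j), "Br"))
  }
  roles
}
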