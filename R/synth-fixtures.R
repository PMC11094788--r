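# Synthetic reaction fixtures. Four hard-coded template chemistries
# (Fischer esterification, amide coupling, aryl cross-coupling, alkene
# hydrogenation) are instantiated with parameterizable alkyl R-groups and
# exact atom-map bookkeeping: every heavy atom that persists carries the
# same map index on both sides. Ground-truth roles are known by
# construction, and controllable noise channels (agent-as-reactant
# mislabeling, rare-agent injection, duplicates, invalid yields, map
# stripping, name-only components) exercise every cleaning path without
# any external data.

#' Fixture generation specification
#'
#' @param n_reactions Number of base reactions to generate.
#' @param seed Integer seed; generation is byte-identical under it.
#' @param template_weights Named non-negative weights over the four
#'   templates `esterification`, `amide`, `coupling`, `hydrogenation`.
#' @param mislabel_agent_as_reactant Fraction of records whose labels move
#'   one agent into the labeled reactants (the reaction string is left
#'   correct), emulating label contamination in curated databases.
#' @param rare_agent_injection Fraction of records receiving one unique
#'   (frequency-one) agent molecule.
#' @param duplicate_rate Fraction of extra exact component-copies appended
#'   after the base records.
#' @param invalid_yield_rate Fraction of records with out-of-range or
#'   inconsistent yields.
#' @param unmapped_rate Fraction of records whose reaction string is
#'   stripped of atom maps (`is_mapped = FALSE`).
#' @param name_only_rate Fraction of records in which one labeled solvent
#'   is replaced by a molecule name instead of SMILES.
#' @param name_unresolvable_frac Among name-only replacements, the share
#'   of names absent from the packaged resolution dictionary.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_reactions = 100L, seed = 1L,
                         template_weights = c(esterification = 1, amide = 1,
                                              coupling = 1, hydrogenation = 1),
                         mislabel_agent_as_reactant = 0,
                         rare_agent_injection = 0,
                         duplicate_rate = 0,
                         invalid_yield_rate = 0,
                         unmapped_rate = 0,
                         name_only_rate = 0,
                         name_unresolvable_frac = 0.5) {
  rates <- c(mislabel_agent_as_reactant, rare_agent_injection, duplicate_rate,
             invalid_yield_rate, unmapped_rate, name_only_rate,
             name_unresolvable_frac)
  stopifnot(n_reactions >= 1, all(rates >= 0 & rates <= 1),
            all(template_weights >= 0), sum(template_weights) > 0)
  tmpl <- c("esterification", "amide", "coupling", "hydrogenation")
  w <- setNames(rep(0, 4), tmpl)
  w[names(template_weights)] <- template_weights
  structure(list(
    n_reactions = as.integer(n_reactions), seed = as.integer(seed),
    template_weights = w,
    mislabel_agent_as_reactant = mislabel_agent_as_reactant,
    rare_agent_injection = rare_agent_injection,
    duplicate_rate = duplicate_rate,
    invalid_yield_rate = invalid_yield_rate,
    unmapped_rate = unmapped_rate,
    name_only_rate = name_only_rate,
    name_unresolvable_frac = name_unresolvable_frac
  ), class = "fixture_spec")
}

# ---- mapped fragment builders -----------------------------------------

# linear alkyl chain CH3-(CH2)n-1 with the open valence on the LAST atom
alkyl_frag <- function(n, m0) {
  fmt <- c("[CH3:%d]", rep("[CH2:%d]", n - 1L))
  paste(sprintf(fmt, m0 + seq_len(n) - 1L), collapse = "")
}

# same chain written from the open-valence end
rev_alkyl_frag <- function(n, m0) {
  if (n == 1L) return(sprintf("[CH3:%d]", m0))
  paste0(paste(sprintf("[CH2:%d]", (m0 + n - 1L):(m0 + 1L)), collapse = ""),
         sprintf("[CH3:%d]", m0))
}

aryl_ring <- function(m0, tail) {
  sprintf("[cH:%d]1[cH:%d][cH:%d][cH:%d][cH:%d][c:%d]1%s",
          m0, m0 + 1L, m0 + 2L, m0 + 3L, m0 + 4L, m0 + 5L, tail)
}

# template instantiation: returns mapped fragments for reactants/products
# plus the spectator SMILES; `cfg` is one row of the config grid
instantiate_template <- function(template, a, b, solvent, agent_extra) {
  switch(template,
    esterification = {
      acid <- paste0(alkyl_frag(a, 1L),
                     sprintf("[C:%d](=[O:%d])[OH:%d]", a + 1L, a + 2L, a + 3L))
      m1 <- a + 4L
      alcohol <- paste0(alkyl_frag(b, m1), sprintf("[OH:%d]", m1 + b))
      ester <- paste0(alkyl_frag(a, 1L),
                      sprintf("[C:%d](=[O:%d])[O:%d]", a + 1L, a + 2L, m1 + b),
                      rev_alkyl_frag(b, m1))
      list(reactants = c(acid, alcohol), products = ester,
           solvents = solvent, agents = agent_extra)
    },
    amide = {
      acid <- paste0(alkyl_frag(a, 1L),
                     sprintf("[C:%d](=[O:%d])[OH:%d]", a + 1L, a + 2L, a + 3L))
      m1 <- a + 4L
      amine <- paste0(alkyl_frag(b, m1), sprintf("[NH2:%d]", m1 + b))
      amide <- paste0(alkyl_frag(a, 1L),
                      sprintf("[C:%d](=[O:%d])[NH:%d]", a + 1L, a + 2L, m1 + b),
                      rev_alkyl_frag(b, m1))
      list(reactants = c(acid, amine), products = amide,
           solvents = solvent, agents = agent_extra)
    },
    coupling = {
      ar_br <- aryl_ring(1L, "Br")
      boronic <- paste0(alkyl_frag(b, 7L), "B(O)O")
      biaryl <- aryl_ring(1L, rev_alkyl_frag(b, 7L))
      list(reactants = c(ar_br, boronic), products = biaryl,
           solvents = solvent, agents = c("[Pd]", agent_extra))
    },
    hydrogenation = {
      alkene <- paste0(sprintf("[CH2:%d]=[CH:%d]", 1L, 2L), rev_alkyl_frag(a, 3L))
      alkane <- paste0(sprintf("[CH3:%d][CH2:%d]", 1L, 2L), rev_alkyl_frag(a, 3L))
      list(reactants = c(alkene, "[H][H]"), products = alkane,
           solvents = solvent, agents = "[Pd]")
    }
  )
}

# full configuration grid per template; sampling without replacement over
# this grid keeps base reactions pairwise distinct when n allows it
fixture_config_grid <- function() {
  solvents <- list(
    esterification = c("C1CCOC1", "ClCCl", "CC#N", "Cc1ccccc1"),
    amide = c("ClCCl", "CC#N", "CN(C)C=O", "C1CCOC1"),
    coupling = c("C1CCOC1", "O", "COCCOC", "C1COCCO1"),
    hydrogenation = c("CCO", "CO", "CC(=O)O", "CCOC(C)=O")
  )
  agents <- list(
    esterification = c("OS(=O)(=O)O", "Cc1ccc(cc1)S(=O)(=O)O"),
    amide = c("CCN=C=NCC", "c1ccncc1"),
    coupling = c("O=C([O-])[O-]", "CC(C)(C)[O-]"),
    hydrogenation = "[Pd]"  # fixed; placeholder column
  )
  grids <- lapply(names(solvents), function(tm) {
    g <- expand.grid(
      a = 1:12,
      b = if (tm %in% c("esterification", "amide")) 1:12 else 1:12,
      solvent = solvents[[tm]],
      agent_extra = agents[[tm]],
      stringsAsFactors = FALSE
    )
    if (tm %in% c("coupling", "hydrogenation")) {
      # only one chain length parameter is live for these templates
      g <- g[g$a == g$b, ]
    }
    g$template <- tm
    g
  })
  do.call(rbind, grids)
}

.fixture_solvent_names <- c(
  "O" = "water", "C1CCOC1" = "tetrahydrofuran", "ClCCl" = "dichloromethane",
  "CC#N" = "acetonitrile", "CCO" = "ethanol", "CO" = "methanol",
  "Cc1ccccc1" = "toluene", "CN(C)C=O" = "n,n-dimethylformamide",
  "CC(=O)O" = "acetic acid", "COCCOC" = "1,2-dimethoxyethane",
  "C1COCCO1" = "1,4-dioxane", "CCOC(C)=O" = "ethyl acetate"
)

#' Generate synthetic reaction records with known ground truth
#'
#' Instantiates the template grid under the spec's weights, assembles
#' atom-mapped reaction strings (spectators placed in the middle segment
#' or on the left side at random, fragment order shuffled), fills in
#' labeled components, conditions and metadata, then applies the spec's
#' noise channels. Generation is deterministic under the seed.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `records` (reaction-record tibble as read by
#'   [read_reaction_records()]) and `truth` (tibble `record_id`,
#'   `template`, plus list-columns `reactants`, `products`, `solvents`,
#'   `agents` of canonical SMILES -- the roles the reaction string
#'   encodes).
#' @export
generate_fixtures <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, generate_fixtures_impl(spec))
}

generate_fixtures_impl <- function(spec) {
  n <- spec$n_reactions
  grid <- fixture_config_grid()
  # weights apply to templates, not cells: normalize by template grid size
  cells_per_template <- table(grid$template)
  w <- spec$template_weights[grid$template] /
    as.numeric(cells_per_template[grid$template])
  # weighted sampling without replacement while configurations last;
  # recycle with replacement only once the grid is exhausted
  n_wo <- min(n, nrow(grid))
  idx <- sample.int(nrow(grid), n_wo, replace = FALSE, prob = w)
  if (n > n_wo) {
    idx <- c(idx, sample.int(nrow(grid), n - n_wo, replace = TRUE, prob = w))
  }
  cfgs <- grid[idx, ]

  recs <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    cf <- cfgs[i, ]
    tm <- instantiate_template(cf$template, cf$a, cf$b, cf$solvent, cf$agent_extra)
    spectators <- c(tm$solvents, tm$agents)
    in_middle <- runif(1) < 0.5
    left <- if (in_middle) tm$reactants else c(tm$reactants, spectators)
    middle <- if (in_middle) spectators else character(0)
    left <- if (length(left) > 1) sample(left) else left
    if (length(middle) > 1) middle <- sample(middle)
    mapped_rxn <- paste0(paste(left, collapse = "."), ">",
                         paste(middle, collapse = "."), ">",
                         paste(tm$products, collapse = "."))
    raw <- lapply(tm, strip_atom_maps)
    rid <- sprintf("rxn-%05d", i)
    recs[[i]] <- tibble(
      record_id = rid,
      mapped_rxn = mapped_rxn,
      is_mapped = TRUE,
      labeled_reactants = list(raw$reactants),
      labeled_products = list(raw$products),
      labeled_solvents = list(raw$solvents),
      labeled_catalysts = list(raw$agents[raw$agents == "[Pd]"]),
      labeled_reagents = list(raw$agents[raw$agents != "[Pd]"]),
      temperature_celsius = round(runif(1, -10, 120), 1),
      time_hours = round(runif(1, 0.5, 48), 2),
      yields_percent = list(round(runif(1, 5, 99), 1)),
      procedure_details = sprintf("%s of substrate %d under standard conditions.",
                                  cf$template, i),
      grant_date = sprintf("%04d-%02d-%02d", sample(1990:2015, 1),
                           sample(1:12, 1), sample(1:28, 1)),
      experiment_date = NA_character_,
      source_file = "synthetic-fixture-000"
    )
    truths[[i]] <- tibble(
      record_id = rid,
      template = cf$template,
      reactants = list(sort(canonicalize_smiles(raw$reactants))),
      products = list(sort(canonicalize_smiles(raw$products))),
      solvents = list(sort(canonicalize_smiles(raw$solvents))),
      agents = list(sort(canonicalize_smiles(raw$agents)))
    )
  }
  records <- dplyr::bind_rows(recs)
  truth <- dplyr::bind_rows(truths)

  # -- noise channels ----------------------------------------------------
  pick <- function(rate) which(runif(n) < rate)

  mis <- pick(spec$mislabel_agent_as_reactant)
  for (i in mis) {
    ags <- c(records$labeled_catalysts[[i]], records$labeled_reagents[[i]])
    if (!length(ags)) next
    moved <- ags[[1]]
    records$labeled_reactants[[i]] <- c(records$labeled_reactants[[i]], moved)
    if (length(records$labeled_catalysts[[i]]) &&
        records$labeled_catalysts[[i]][1] == moved) {
      records$labeled_catalysts[[i]] <- records$labeled_catalysts[[i]][-1]
    } else {
      records$labeled_reagents[[i]] <-
        records$labeled_reagents[[i]][-match(moved, records$labeled_reagents[[i]])]
    }
  }
  attr(records, "mislabeled_ids") <- records$record_id[mis]

  bad_yield <- pick(spec$invalid_yield_rate)
  for (i in bad_yield) {
    records$yields_percent[[i]] <-
      switch(sample(3, 1), c(150), c(-5), c(60, 60))
  }

  unmapped <- pick(spec$unmapped_rate)
  if (length(unmapped)) {
    records$mapped_rxn[unmapped] <- strip_atom_maps(records$mapped_rxn[unmapped])
    records$is_mapped[unmapped] <- FALSE
  }

  named <- pick(spec$name_only_rate)
  for (i in named) {
    solv <- records$labeled_solvents[[i]]
    if (!length(solv)) next
    nm <- if (runif(1) < spec$name_unresolvable_frac) {
      sprintf("proprietary solvent blend %d", i)
    } else {
      .fixture_solvent_names[[solv[[1]]]] %||% "water"
    }
    solv[[1]] <- nm
    records$labeled_solvents[[i]] <- solv
  }

  n_rare <- round(spec$rare_agent_injection * n)
  if (n_rare > 0) {
    records <- inject_rare_agents(records, n_rare,
                                  seed = sample.int(2^30, 1), .update_truth = truth)
    truth <- attr(records, "truth_updated") %||% truth
    attr(records, "truth_updated") <- NULL
  }

  n_dup <- round(spec$duplicate_rate * n)
  if (n_dup > 0) {
    dup_idx <- sample.int(n, n_dup, replace = n_dup > n)
    dups <- records[dup_idx, ]
    dups$record_id <- sprintf("rxn-dup-%05d", seq_len(n_dup))
    dups$procedure_details <- paste(dups$procedure_details, "(repeat run)")
    dup_truth <- truth[dup_idx, ]
    dup_truth$record_id <- dups$record_id
    mis_ids <- attr(records, "mislabeled_ids")
    records <- dplyr::bind_rows(records, dups)
    truth <- dplyr::bind_rows(truth, dup_truth)
    attr(records, "mislabeled_ids") <- mis_ids
  }

  list(records = records, truth = truth)
}

#' Inject unique rare agents into records
#'
#' Gives each of `n_rare` randomly chosen records one unique agent SMILES
#' used nowhere else (occurrence frequency exactly one), appended to both
#' the reaction string's spectator segment and the labeled reagents. Used
#' to exercise the frequency filter: under `delete_rxn` exactly these
#' reactions disappear; under `map_to_other` exactly `n_rare` `"other"`
#' tokens appear.
#'
#' @param records Reaction-record tibble.
#' @param n_rare Number of records to modify (`<= nrow(records)`).
#' @param seed Seed for choosing the records.
#' @param .update_truth Internal: ground-truth tibble to keep in sync.
#' @return The modified records (attribute `"rare_ids"` lists the modified
#'   record ids).
#' @export
inject_rare_agents <- function(records, n_rare, seed = 1L, .update_truth = NULL) {
  stopifnot(n_rare <= nrow(records))
  if (n_rare == 0L) return(records)
  sel <- withr::with_seed(seed, sample.int(nrow(records), n_rare))
  rare_smiles <- paste0("FC(F)(F)", strrep("C", seq_len(n_rare)), "I")
  for (j in seq_along(sel)) {
    i <- sel[[j]]
    rxn <- records$mapped_rxn[[i]]
    if (!is.na(rxn) && nzchar(rxn)) {
      parts <- strsplit(rxn, ">", fixed = TRUE)[[1]]
      length(parts) <- 3L
      parts[is.na(parts)] <- ""
      parts[2] <- if (nzchar(parts[2])) paste(parts[2], rare_smiles[[j]], sep = ".") else
        rare_smiles[[j]]
      records$mapped_rxn[[i]] <- paste(parts, collapse = ">")
    }
    records$labeled_reagents[[i]] <- c(records$labeled_reagents[[i]], rare_smiles[[j]])
    if (!is.null(.update_truth)) {
      k <- match(records$record_id[[i]], .update_truth$record_id)
      .update_truth$agents[[k]] <-
        sort(c(.update_truth$agents[[k]], canonicalize_smiles(rare_smiles[[j]])))
    }
  }
  attr(records, "rare_ids") <- records$record_id[sel]
  if (!is.null(.update_truth)) attr(records, "truth_updated") <- .update_truth
  records
}

#' Write fixture records and ground truth to disk
#'
#' @param fixtures A [generate_fixtures()] result.
#' @param records_path JSONL output path for the records.
#' @param truth_path JSON output path for the ground truth.
#' @return The two paths, invisibly.
#' @export
write_fixtures <- function(fixtures, records_path, truth_path = NULL) {
  write_reaction_records(fixtures$records, records_path)
  if (!is.null(truth_path)) {
    tr <- fixtures$truth
    obj <- setNames(lapply(seq_len(nrow(tr)), function(i) {
      list(reactants = tr$reactants[[i]], products = tr$products[[i]],
           solvents = tr$solvents[[i]], agents = tr$agents[[i]])
    }), tr$record_id)
    jsonlite::write_json(obj, truth_path, auto_unbox = FALSE)
  }
  invisible(c(records_path, truth_path))
}
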