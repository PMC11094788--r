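# Reaction role assignment. Roles (reactant / product / solvent / agent)
# are derived either from the atom-mapped reaction string -- a reactant is
# a molecule contributing at least one heavy (non-hydrogen) atom to a
# product, with an explicit exception for molecular hydrogen -- or taken
# from the record's component labels. The two provenances can be compared
# to diagnose label contamination (agents mislabeled as reactants).

# split a SMILES side into top-level dot-separated fragments, honouring
# brackets and unwrapping "(A.B)" component grouping
split_fragments <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_bracket <- FALSE
  frags <- character(0)
  cur <- character(0)
  for (ch in chars) {
    if (ch == "[") in_bracket <- TRUE else if (ch == "]") in_bracket <- FALSE
    if (!in_bracket) {
      if (ch == "(") depth <- depth + 1L
      else if (ch == ")") depth <- depth - 1L
      else if (ch == "." && depth == 0L) {
        frags <- c(frags, paste(cur, collapse = ""))
        cur <- character(0)
        next
      }
    }
    cur <- c(cur, ch)
  }
  frags <- c(frags, paste(cur, collapse = ""))
  # unwrap component grouping: "(A.B)" where the outer parens span the fragment
  unlist(lapply(frags, function(f) {
    if (startsWith(f, "(") && endsWith(f, ")")) {
      inner <- substr(f, 2L, nchar(f) - 1L)
      if (grepl(".", inner, fixed = TRUE) && paren_balanced(inner)) {
        return(split_fragments(inner))
      }
    }
    f
  }))
}

paren_balanced <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  d <- cumsum((chars == "(") - (chars == ")"))
  length(d) == 0L || (all(d >= 0L) && d[length(d)] == 0L)
}

# heavy-atom map indices of one fragment: map indices carried by bracket
# atoms whose element is not hydrogen (isotopic hydrogens included)
heavy_map_ids <- function(fragment) {
  contents <- regmatches(fragment, gregexpr("\\[([^\\]]+)\\]", fragment, perl = TRUE))[[1]]
  if (!length(contents)) return(integer(0))
  contents <- substr(contents, 2L, nchar(contents) - 1L)
  maps <- suppressWarnings(as.integer(sub("^.*:([0-9]+)$", "\\1", contents)))
  has_map <- grepl(":[0-9]+$", contents)
  # hydrogen: optional isotope digits then H not followed by a lowercase letter
  is_h <- grepl("^[0-9]*H($|[^a-z])", contents)
  sort(unique(maps[has_map & !is_h]))
}

#' Parse an atom-mapped reaction SMILES string
#'
#' Splits a `left>middle>right` reaction string into its dot-separated
#' top-level molecule fragments and collects the heavy-atom (non-hydrogen)
#' map indices of each fragment. Exactly two `>` separators are required;
#' an empty middle segment is allowed.
#'
#' @param rxn A reaction SMILES string.
#' @return An object of class `parsed_reaction`: a list with `fragments`
#'   (tibble with columns `side`, `smiles`, `map_ids` (list of integer))
#'   and `source` (the input string).
#' @export
parse_mapped_reaction <- function(rxn) {
  stopifnot(is.character(rxn), length(rxn) == 1L)
  if (is.na(rxn)) abort("reaction string is NA")
  n_sep <- lengths(regmatches(rxn, gregexpr(">", rxn, fixed = TRUE)))
  if (n_sep != 2L) {
    abort(sprintf("reaction string must contain exactly two '>' separators, found %d: \"%s\"",
                  n_sep, rxn))
  }
  sides <- strsplit(rxn, ">", fixed = TRUE)[[1]]
  length(sides) <- 3L
  sides[is.na(sides)] <- ""
  frag_tbl <- purrr::map2_dfr(sides, c("left", "middle", "right"), function(s, nm) {
    fr <- split_fragments(s)
    if (!length(fr)) return(NULL)
    tibble(side = nm, smiles = fr, map_ids = lapply(fr, heavy_map_ids))
  })
  if (nrow(frag_tbl)) {
    bad <- !smiles_valid(strip_atom_maps(frag_tbl$smiles))
    if (any(bad)) {
      abort(sprintf("unparsable fragment(s): %s",
                    paste(frag_tbl$smiles[bad], collapse = ", ")))
    }
  }
  structure(list(fragments = frag_tbl, source = rxn), class = "parsed_reaction")
}

#' @export
print.parsed_reaction <- function(x, ...) {
  cat(sprintf("<parsed_reaction> %s\n", x$source))
  print(x$fragments)
  invisible(x)
}

#' Assign reaction roles from an atom-mapped reaction string
#'
#' Implements map-driven role logic: right-side molecules are products; any
#' other molecule sharing at least one heavy-atom map index with a product
#' is a reactant (atom-map contribution overrides position in the string,
#' so a mapped middle-segment molecule is still a reactant); molecular
#' hydrogen on the non-product side is a reactant even though it contributes
#' no heavy atom (hydrogens are usually implicit, so its contribution is
#' undetectable from the maps); every remaining molecule is a spectator,
#' split into solvents (lexicon members) and agents (everything else). A
#' molecule appearing unchanged on both sides (same map-stripped structure,
#' maps only to itself) is classified as a single agent rather than
#' reactant + product.
#'
#' @param parsed A [parse_mapped_reaction()] result.
#' @param lexicon A [read_solvent_lexicon()] solvent set.
#' @return A list with character vectors `reactants`, `products`,
#'   `solvents`, `agents` (map-stripped canonical SMILES) and
#'   `provenance = "rxn_string"`.
#' @export
assign_roles_from_rxn_string <- function(parsed, lexicon) {
  stopifnot(inherits(parsed, "parsed_reaction"))
  fr <- parsed$fragments
  fr$canonical <- canonicalize_smiles(strip_atom_maps(fr$smiles))
  right <- which(fr$side == "right")
  if (!length(right)) abort("reaction has an empty product side", class = "rxncurate_role_error")
  other <- which(fr$side != "right")

  # both-sides-unchanged molecules collapse to one agent entry
  self_agent <- logical(nrow(fr))
  consumed_right <- logical(nrow(fr))
  for (i in other) {
    cand <- right[!consumed_right[right] & fr$canonical[right] == fr$canonical[i]]
    for (j in cand) {
      same_maps <- setequal(fr$map_ids[[i]], fr$map_ids[[j]])
      other_prod_maps <- unlist(fr$map_ids[setdiff(right, j)])
      only_self <- !length(intersect(fr$map_ids[[i]], other_prod_maps))
      if (same_maps && only_self) {
        self_agent[i] <- TRUE
        consumed_right[j] <- TRUE
        break
      }
    }
  }
  prod_idx <- right[!consumed_right[right]]
  if (!length(prod_idx)) {
    abort("reaction has an empty product side (all products unchanged spectators)",
          class = "rxncurate_role_error")
  }
  prod_maps <- unique(unlist(fr$map_ids[prod_idx]))

  reactants <- character(0); solvents <- character(0); agents <- character(0)
  for (i in other) {
    if (self_agent[i]) {
      agents <- c(agents, fr$canonical[i])
    } else if (length(intersect(fr$map_ids[[i]], prod_maps))) {
      reactants <- c(reactants, fr$canonical[i])
    } else if (is_molecular_hydrogen(fr$canonical[i])) {
      reactants <- c(reactants, fr$canonical[i])
    } else if (fr$canonical[i] %in% lexicon) {
      solvents <- c(solvents, fr$canonical[i])
    } else {
      agents <- c(agents, fr$canonical[i])
    }
  }
  list(reactants = reactants, products = fr$canonical[prod_idx],
       solvents = solvents, agents = agents, provenance = "rxn_string")
}

#' Classify a spectator molecule as solvent or agent
#'
#' @param smiles Character vector of canonical SMILES.
#' @param lexicon A [read_solvent_lexicon()] solvent set.
#' @return Character vector, `"solvent"` where the molecule is a lexicon
#'   member, `"agent"` otherwise.
#' @export
classify_spectator <- function(smiles, lexicon) {
  ifelse(smiles %in% lexicon, "solvent", "agent")
}

#' Assign reaction roles for a table of records
#'
#' Table-level driver over [assign_roles_from_rxn_string()] (provenance
#' `"rxn_string"`) or the record labels (provenance `"labeling"`, in which
#' case labeled solvents stay solvents and labeled catalysts and reagents
#' are merged into agents). Component strings are resolved to canonical
#' SMILES first; with `strict = TRUE` (default) a reaction containing any
#' unresolved or invalid component is marked failed, with `strict = FALSE`
#' unresolved spectators are dropped individually and only unresolved
#' reactants/products fail the reaction.
#'
#' Per-record failures (missing mapped string, empty product side,
#' unresolved components) are captured in the `error` column rather than
#' aborting the run; failed rows carry empty role lists.
#'
#' @param records A tibble of reaction records ([read_reaction_records()]).
#' @param provenance `"rxn_string"` or `"labeling"`.
#' @param lexicon A [read_solvent_lexicon()] solvent set.
#' @param table A [name_resolution_table()]; used for labeling provenance.
#' @param strict Drop whole reactions on unresolved components (default)?
#' @return A tibble with columns `record_id`, list-columns `reactants`,
#'   `products`, `solvents`, `agents` (canonical SMILES), `n_fragments`,
#'   `provenance`, `error`, plus the record's condition metadata
#'   (`temperature_celsius`, `time_hours`, `yields_percent`,
#'   `procedure_details`, dates, `source_file`).
#' @export
assign_roles <- function(records, provenance = c("rxn_string", "labeling"),
                         lexicon = read_solvent_lexicon(),
                         table = name_resolution_table(),
                         strict = TRUE) {
  provenance <- match.arg(provenance)
  n <- nrow(records)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[[i]] <- if (provenance == "rxn_string") {
      role_one_rxn_string(records$mapped_rxn[i], lexicon)
    } else {
      role_one_labeling(records[i, ], table, lexicon, strict)
    }
  }
  out <- tibble(
    record_id = records$record_id,
    reactants = lapply(res, `[[`, "reactants"),
    products = lapply(res, `[[`, "products"),
    solvents = lapply(res, `[[`, "solvents"),
    agents = lapply(res, `[[`, "agents"),
    n_fragments = vapply(res, `[[`, integer(1), "n_fragments"),
    provenance = provenance,
    error = vapply(res, `[[`, character(1), "error")
  )
  meta <- intersect(c("temperature_celsius", "time_hours", "yields_percent",
                      "procedure_details", "grant_date", "experiment_date",
                      "source_file", "is_mapped", "mapped_rxn"),
                    names(records))
  dplyr::bind_cols(out, records[, meta, drop = FALSE])
}

role_failure <- function(msg) {
  list(reactants = character(0), products = character(0),
       solvents = character(0), agents = character(0),
       n_fragments = 0L, error = msg)
}

role_one_rxn_string <- function(mapped_rxn, lexicon) {
  if (is.na(mapped_rxn) || !nzchar(mapped_rxn)) {
    return(role_failure("no mapped reaction string"))
  }
  tryCatch({
    parsed <- parse_mapped_reaction(mapped_rxn)
    roles <- assign_roles_from_rxn_string(parsed, lexicon)
    c(roles[c("reactants", "products", "solvents", "agents")],
      list(n_fragments = nrow(parsed$fragments), error = NA_character_))
  }, error = function(e) role_failure(conditionMessage(e)))
}

role_one_labeling <- function(rec, table, lexicon, strict) {
  comps <- list(
    reactants = rec$labeled_reactants[[1]],
    products = rec$labeled_products[[1]],
    solvents = rec$labeled_solvents[[1]],
    agents = c(rec$labeled_catalysts[[1]], rec$labeled_reagents[[1]])
  )
  if (!length(comps$reactants) && !length(comps$products)) {
    return(role_failure("record has neither labeled reactants nor labeled products"))
  }
  out <- list()
  for (role in names(comps)) {
    raw <- comps[[role]]
    if (!length(raw)) { out[[role]] <- character(0); next }
    resolved <- resolve_molecules(raw, table)
    bad <- !resolved$resolution %in% c("smiles_ok", "name_resolved")
    if (any(bad)) {
      mandatory <- role %in% c("reactants", "products")
      if (strict || mandatory) {
        return(role_failure(sprintf("unresolved %s component(s): %s", role,
                                    paste(raw[bad], collapse = ", "))))
      }
      resolved <- resolved[!bad, ]
    }
    out[[role]] <- unify_catalyst(resolved$canonical_smiles, table)
  }
  list(reactants = out$reactants, products = out$products,
       solvents = out$solvents, agents = out$agents,
       n_fragments = sum(lengths(out)), error = NA_character_)
}

#' Compare role assignments from two provenances
#'
#' Computes per-record, per-role symmetric differences between two role
#' assignments of the same records (typically rxn-string vs labeling) plus
#' the reactant-count delta. On fixtures with injected label contamination
#' this reproduces the characteristic shift of the reactant-count
#' distribution caused by agents mislabeled as reactants.
#'
#' @param a,b Role tibbles from [assign_roles()] covering the same
#'   `record_id`s.
#' @return A `role_comparison` tibble with one row per record: columns
#'   `record_id`, `n_reactants_a`, `n_reactants_b`, `delta_reactants`
#'   (b minus a), `n_disagreements` (total symmetric-difference size over
#'   all four roles) and list-column `diffs` (per-role tibbles with
#'   `only_in_a` / `only_in_b`).
#' @export
compare_role_provenances <- function(a, b) {
  if (!setequal(a$record_id, b$record_id)) {
    abort("role tables cover different record_id sets")
  }
  b <- b[match(a$record_id, b$record_id), ]
  roles <- c("reactants", "products", "solvents", "agents")
  rows <- lapply(seq_len(nrow(a)), function(i) {
    diffs <- purrr::map_dfr(roles, function(role) {
      xa <- a[[role]][[i]]; xb <- b[[role]][[i]]
      tibble(role = role,
             only_in_a = list(setdiff(xa, xb)),
             only_in_b = list(setdiff(xb, xa)))
    })
    tibble(
      record_id = a$record_id[i],
      n_reactants_a = length(a$reactants[[i]]),
      n_reactants_b = length(b$reactants[[i]]),
      delta_reactants = length(b$reactants[[i]]) - length(a$reactants[[i]]),
      n_disagreements = sum(lengths(diffs$only_in_a)) + sum(lengths(diffs$only_in_b)),
      diffs = list(diffs)
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("role_comparison", class(out)),
            provenance_a = unique(a$provenance), provenance_b = unique(b$provenance))
}

#' @rdname autoplot-rxncurate
#' @method autoplot role_comparison
#' @export
autoplot.role_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("record_id", "n_reactants_a", "n_reactants_b")],
    cols = c("n_reactants_a", "n_reactants_b"),
    names_to = "provenance", values_to = "n_reactants"
  )
  df$provenance <- ifelse(df$provenance == "n_reactants_a",
                          attr(object, "provenance_a") %||% "a",
                          attr(object, "provenance_b") %||% "b")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_reactants, fill = .data$provenance)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "reactants per reaction", y = "reactions",
                  title = "Reactant count by role-assignment provenance") +
    ggplot2::theme_minimal()
}
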