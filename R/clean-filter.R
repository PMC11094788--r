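# The cleaning ladder: degenerate-reaction removal, component-count
# limits, yield sanitization, frequency filtering of rare spectators
# (delete-reaction or map-to-"other"), stable deduplication and
# leakage-aware grouped random splits. Each verb takes and returns a role
# tibble and threads a funnel audit through the attribute "funnel" so
# ladders compose with the pipe.

#' Cleaning configuration
#'
#' Bundles the tunable parameters of the cleaning ladder. Component maxima
#' use fragment-count semantics (see [count_components()]): a binary salt
#' written `[Na+].[Cl-]` counts as two components. The frequency threshold
#' defaults to 100 occurrences; spectators seen fewer times are "rare" and
#' handled by `rare_strategy`: `"delete_rxn"` removes the whole reaction,
#' `"map_to_other"` keeps it and replaces the rare molecule by the literal
#' token `"other"`. Yield sanitization is off by default: yield data is far
#' noisier than structural data and irrelevant to structure-related tasks.
#'
#' @param max_reactants,max_products,max_solvents,max_agents Per-role
#'   component maxima; `Inf` = unlimited.
#' @param sanitize_yields Check each yield and the yield sum against
#'   0--100%?
#' @param frequency_threshold Minimum spectator occurrence count.
#' @param rare_strategy `"delete_rxn"` or `"map_to_other"`.
#' @param split_fractions Named numeric `(train, val, test)`; must sum to 1.
#' @param seed Integer seed driving the grouped split shuffle.
#' @return A `cleaning_config` list.
#' @export
cleaning_config <- function(max_reactants = Inf, max_products = Inf,
                            max_solvents = Inf, max_agents = Inf,
                            sanitize_yields = FALSE,
                            frequency_threshold = 100L,
                            rare_strategy = c("delete_rxn", "map_to_other"),
                            split_fractions = c(train = 0.8, val = 0.1, test = 0.1),
                            seed = 1L) {
  rare_strategy <- match.arg(rare_strategy)
  stopifnot(length(split_fractions) == 3L, all(split_fractions > 0),
            abs(sum(split_fractions) - 1) < 1e-9,
            frequency_threshold >= 0,
            max_reactants >= 0, max_products >= 0,
            max_solvents >= 0, max_agents >= 0)
  structure(list(
    max_reactants = max_reactants, max_products = max_products,
    max_solvents = max_solvents, max_agents = max_agents,
    sanitize_yields = isTRUE(sanitize_yields),
    frequency_threshold = as.integer(frequency_threshold),
    rare_strategy = rare_strategy,
    split_fractions = setNames(as.numeric(split_fractions), c("train", "val", "test")),
    seed = as.integer(seed)
  ), class = "cleaning_config")
}

#' @export
print.cleaning_config <- function(x, ...) {
  cat("<cleaning_config>\n")
  cat(sprintf("  maxima: %s reactants, %s products, %s solvents, %s agents\n",
              x$max_reactants, x$max_products, x$max_solvents, x$max_agents))
  cat(sprintf("  frequency threshold %d (%s), sanitize yields: %s\n",
              x$frequency_threshold, x$rare_strategy, x$sanitize_yields))
  cat(sprintf("  split %g/%g/%g, seed %d\n",
              x$split_fractions[1], x$split_fractions[2], x$split_fractions[3], x$seed))
  invisible(x)
}

# ---- funnel threading --------------------------------------------------

#' Attach a funnel audit to a role table
#'
#' @param rxns Role tibble.
#' @param step Name of the initial step.
#' @return `rxns` with a [funnel_audit()] in attribute `"funnel"`.
#' @export
start_funnel <- function(rxns, step = "full data set") {
  attr(rxns, "funnel") <- funnel_audit(step, nrow(rxns))
  rxns
}

#' Funnel audit of a cleaned table
#'
#' @param rxns Role tibble that passed through the cleaning verbs.
#' @return A [funnel_audit()] or `NULL`.
#' @export
get_funnel <- function(rxns) attr(rxns, "funnel")

log_step <- function(out, rxns, step, size_class = "shrink") {
  audit <- attr(rxns, "funnel")
  if (!is.null(audit)) {
    attr(out, "funnel") <- record_funnel(audit, step, nrow(out), size_class)
  }
  out
}

# ---- ladder steps ------------------------------------------------------

#' Remove reactions without reactants or products
#'
#' A reaction with no reactants or no products does not make sense; such
#' rows (including rows whose role assignment failed) are removed.
#'
#' @param rxns Role tibble.
#' @return Filtered tibble (funnel step `"no reactants/products"`).
#' @export
drop_empty <- function(rxns) {
  keep <- lengths(rxns$reactants) > 0L & lengths(rxns$products) > 0L
  log_step(rxns[keep, ], rxns, "no reactants/products")
}

#' Count components of a molecule list
#'
#' Components are dot-separated top-level SMILES fragments summed over the
#' list, so a binary salt written as one string (`[Na+].[Cl-]`) counts as
#' two components.
#'
#' @param molecules Character vector of SMILES.
#' @return Integer count.
#' @export
count_components <- function(molecules) {
  if (!length(molecules)) return(0L)
  sum(vapply(molecules, function(m) length(split_fragments(m)), integer(1)))
}

#' Enforce per-role component-count maxima
#'
#' Applies the configured maxima in the fixed order reactants, products,
#' solvents, agents (mirroring the funnel reporting order), under
#' [count_components()] semantics. Roles with an infinite maximum are
#' skipped and produce no funnel step.
#'
#' @param rxns Role tibble.
#' @param cfg A [cleaning_config()].
#' @return Filtered tibble (funnel steps `"too many <role>"`).
#' @export
filter_component_counts <- function(rxns, cfg) {
  stopifnot(inherits(cfg, "cleaning_config"))
  steps <- list(
    c("reactants", "too many reactants"),
    c("products", "too many products"),
    c("solvents", "too many solvents"),
    c("agents", "too many agents")
  )
  out <- rxns
  for (s in steps) {
    maxv <- cfg[[paste0("max_", s[1])]]
    if (!is.finite(maxv)) next
    counts <- vapply(out[[s[1]]], count_components, integer(1))
    out <- log_step(out[counts <= maxv, ], out, s[2])
  }
  out
}

#' Sanitize reaction yields
#'
#' When enabled, reactions whose yields violate the consistency check
#' (each yield and the yield sum within 0--100%) keep their row but have
#' all yields set to missing. Disabled by default.
#'
#' @param rxns Role tibble with list-column `yields_percent`.
#' @param enabled Apply the check?
#' @return Tibble of identical length (funnel step `"yield sanitization"`,
#'   size-preserving).
#' @export
sanitize_yields <- function(rxns, enabled = FALSE) {
  if (!enabled || !"yields_percent" %in% names(rxns)) {
    return(log_step(rxns, rxns, "yield sanitization", "preserve"))
  }
  bad <- vapply(rxns$yields_percent, function(y) {
    y <- y[!is.na(y)]
    length(y) > 0 && (any(y < 0) || any(y > 100) || sum(y) > 100)
  }, logical(1))
  out <- rxns
  out$yields_percent[bad] <- list(numeric(0))
  log_step(out, rxns, "yield sanitization", "preserve")
}

#' Spectator occurrence frequencies
#'
#' Counts occurrences of each spectator molecule over the whole input,
#' separately per role: the same molecule used as a solvent and as an
#' agent yields two independent counts, because the two roles feed
#' separate prediction targets.
#'
#' @param rxns Role tibble.
#' @return Tibble with columns `role`, `smiles`, `n`.
#' @export
spectator_frequencies <- function(rxns) {
  counts <- function(col, role) {
    v <- unlist(rxns[[col]])
    if (!length(v)) return(NULL)
    tibble(role = role, smiles = v) |>
      dplyr::count(.data$role, .data$smiles, name = "n")
  }
  out <- dplyr::bind_rows(counts("solvents", "solvent"), counts("agents", "agent"))
  if (is.null(out) || !nrow(out)) {
    out <- tibble(role = character(0), smiles = character(0), n = integer(0))
  }
  out
}

#' Frequency-filter rare spectator molecules
#'
#' Spectators occurring fewer than `cfg$frequency_threshold` times in the
#' input (counted once, on the pre-filter set, per role) are rare. Under
#' `"delete_rxn"` every reaction containing a rare spectator is removed;
#' under `"map_to_other"` the reaction count is preserved and each rare
#' spectator is replaced by the literal token `"other"`. Reactant and
#' product lists are never touched.
#'
#' @param rxns Role tibble.
#' @param cfg A [cleaning_config()].
#' @return Filtered or rewritten tibble (funnel step
#'   `"frequency filtering"`).
#' @export
frequency_filter <- function(rxns, cfg) {
  stopifnot(inherits(cfg, "cleaning_config"))
  freqs <- spectator_frequencies(rxns)
  rare <- freqs[freqs$n < cfg$frequency_threshold, ]
  rare_by_role <- split(rare$smiles, rare$role)
  rare_solv <- rare_by_role$solvent %||% character(0)
  rare_ag <- rare_by_role$agent %||% character(0)
  if (cfg$rare_strategy == "delete_rxn") {
    keep <- !vapply(seq_len(nrow(rxns)), function(i) {
      any(rxns$solvents[[i]] %in% rare_solv) || any(rxns$agents[[i]] %in% rare_ag)
    }, logical(1))
    log_step(rxns[keep, ], rxns, "frequency filtering")
  } else {
    out <- rxns
    out$solvents <- lapply(out$solvents, function(v) replace(v, v %in% rare_solv, "other"))
    out$agents <- lapply(out$agents, function(v) replace(v, v %in% rare_ag, "other"))
    log_step(out, rxns, "frequency filtering", "preserve")
  }
}

reaction_key <- function(rxns) {
  vapply(seq_len(nrow(rxns)), function(i) {
    paste(
      paste(sort(rxns$reactants[[i]]), collapse = "."),
      paste(sort(rxns$products[[i]]), collapse = "."),
      paste(sort(rxns$solvents[[i]]), collapse = "."),
      paste(sort(rxns$agents[[i]]), collapse = "."),
      sep = " >> "
    )
  }, character(1))
}

#' Drop duplicate reactions
#'
#' Two reactions are duplicates when their sorted reactant, product,
#' solvent and agent sets all agree; temperature, time, yields, dates and
#' procedure text are deliberately excluded from the key (metadata-
#' differing repeats of one reaction are duplicates for structure-and-
#' condition tasks). The first occurrence is kept (stable).
#'
#' @param rxns Role tibble with canonical components.
#' @return Deduplicated tibble (funnel step `"dropping duplicates"`).
#' @export
drop_duplicates <- function(rxns) {
  keep <- !duplicated(reaction_key(rxns))
  log_step(rxns[keep, ], rxns, "dropping duplicates")
}

#' Leakage-free grouped random split
#'
#' Splits reactions into train/val/test so that all reactions sharing a
#' grouping-key value (by default the model-input tuple: sorted reactants
#' plus products) land in the same partition -- the same input never
#' appears on both sides of a train/test boundary. Distinct keys are
#' shuffled with the configured seed and partitions are filled greedily to
#' their target reaction counts, which is exact in the
#' one-reaction-per-group limit.
#'
#' @param rxns Role tibble.
#' @param cfg A [cleaning_config()] (fractions and seed).
#' @param key Either `NULL` (default input-tuple key), a function
#'   `rxns -> character`, or a character vector of keys.
#' @return `rxns` with an added factor column `split` and the key stored in
#'   attribute `"split_key"`.
#' @export
grouped_random_split <- function(rxns, cfg, key = NULL) {
  stopifnot(inherits(cfg, "cleaning_config"))
  keys <- if (is.null(key)) {
    vapply(seq_len(nrow(rxns)), function(i) {
      paste(paste(sort(rxns$reactants[[i]]), collapse = "."),
            paste(sort(rxns$products[[i]]), collapse = "."), sep = ">>")
    }, character(1))
  } else if (is.function(key)) {
    key(rxns)
  } else {
    as.character(key)
  }
  stopifnot(length(keys) == nrow(rxns))
  distinct_keys <- unique(keys)
  if (length(distinct_keys) < 3L) {
    abort("fewer distinct grouping keys than partitions")
  }
  shuffled <- withr::with_seed(cfg$seed, sample(distinct_keys))
  sizes <- table(keys)[shuffled]
  lag_cum <- cumsum(as.numeric(sizes)) - as.numeric(sizes)
  n <- nrow(rxns)
  t_train <- cfg$split_fractions[["train"]] * n
  t_val <- t_train + cfg$split_fractions[["val"]] * n
  part <- ifelse(lag_cum < t_train, "train", ifelse(lag_cum < t_val, "val", "test"))
  assignment <- setNames(part, shuffled)
  out <- rxns
  out$split <- factor(assignment[keys], levels = c("train", "val", "test"))
  attr(out, "split_key") <- keys
  attr(out, "funnel") <- attr(rxns, "funnel")
  out
}

#' Split leakage count
#'
#' Number of grouping-key values shared between any two partitions of a
#' [grouped_random_split()] result; zero means no input leaks across the
#' train/val/test boundaries.
#'
#' @param rxns A split role tibble (column `split`, attribute
#'   `"split_key"`).
#' @return Non-negative integer.
#' @export
split_leakage <- function(rxns) {
  keys <- attr(rxns, "split_key")
  stopifnot(!is.null(keys), "split" %in% names(rxns))
  by_part <- split(keys, rxns$split)
  combos <- utils::combn(names(by_part), 2, simplify = FALSE)
  sum(vapply(combos, function(p) {
    length(intersect(unique(by_part[[p[1]]]), unique(by_part[[p[2]]])))
  }, integer(1)))
}

#' Partition a split table into a list
#'
#' @param rxns A [grouped_random_split()] result.
#' @return Named list of tibbles `train`, `val`, `test`.
#' @export
split_partitions <- function(rxns) {
  stopifnot("split" %in% names(rxns))
  lapply(split(seq_len(nrow(rxns)), rxns$split), function(ix) rxns[ix, ])
}
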