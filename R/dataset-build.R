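# Benchmark assembly: the three shipped recipes (condition / forward /
# retro), sequence-model input formatting (mixed vs separated), random
# equivalent-SMILES augmentation and flat-row export.

#' Benchmark recipes
#'
#' Returns the cleaning recipe of one of the three shipped benchmarks:
#'
#' * `condition`: one product, up to two reactants, two solvents and three
#'   agents; spectator frequency threshold 100 with a configurable rare
#'   strategy (default `delete_rxn`); split grouped on the input tuple
#'   (reactants + product).
#' * `forward`: up to two products and three each of reactants, solvents
#'   and agents; no frequency filtering; split grouped on the source side
#'   (reactants + spectators).
#' * `retro`: one product, up to two reactants, no solvent/agent limits,
#'   no frequency filtering; split grouped on the product.
#'
#' @param name `"condition"`, `"forward"` or `"retro"`.
#' @param rare_strategy Rare-spectator strategy for the condition recipe.
#' @param split_fractions Train/val/test fractions (default 80/10/10).
#' @param seed Split seed.
#' @param frequency_threshold Spectator frequency threshold for the
#'   condition recipe.
#' @return A `benchmark_recipe` list with fields `name`, `cfg`
#'   (a [cleaning_config()]), `use_frequency_filter` and `key_description`.
#' @export
benchmark_recipe <- function(name = c("condition", "forward", "retro"),
                             rare_strategy = "delete_rxn",
                             split_fractions = c(train = 0.8, val = 0.1, test = 0.1),
                             seed = 1L,
                             frequency_threshold = 100L) {
  name <- match.arg(name)
  cfg <- switch(name,
    condition = cleaning_config(
      max_reactants = 2, max_products = 1, max_solvents = 2, max_agents = 3,
      frequency_threshold = frequency_threshold, rare_strategy = rare_strategy,
      split_fractions = split_fractions, seed = seed),
    forward = cleaning_config(
      max_reactants = 3, max_products = 2, max_solvents = 3, max_agents = 3,
      split_fractions = split_fractions, seed = seed),
    retro = cleaning_config(
      max_reactants = 2, max_products = 1,
      split_fractions = split_fractions, seed = seed)
  )
  structure(list(
    name = name,
    cfg = cfg,
    use_frequency_filter = name == "condition",
    key_description = switch(name,
      condition = "sorted reactants + products",
      forward = "sorted reactants + solvents + agents",
      retro = "sorted products")
  ), class = "benchmark_recipe")
}

recipe_split_key <- function(recipe) {
  switch(recipe$name,
    condition = NULL,  # default input-tuple key
    forward = function(rxns) {
      vapply(seq_len(nrow(rxns)), function(i) {
        paste(sort(c(rxns$reactants[[i]], rxns$solvents[[i]], rxns$agents[[i]])),
              collapse = ".")
      }, character(1))
    },
    retro = function(rxns) {
      vapply(rxns$products, function(p) paste(sort(p), collapse = "."), character(1))
    }
  )
}

#' Build a benchmark dataset
#'
#' Runs the full cleaning ladder on role-assigned reactions in the
#' canonical funnel order -- too many reactants, products, solvents,
#' agents; no reactants/products; dropping duplicates; frequency filtering
#' (condition recipe only) -- then applies the recipe's grouped 80/10/10
#' split. The funnel audit logs the reactions remaining after every step.
#'
#' @param roles Role tibble from [assign_roles()].
#' @param recipe A [benchmark_recipe()].
#' @param source_tag Optional value of `source_file` to filter on before
#'   cleaning (e.g. to build an out-of-distribution evaluation set from a
#'   differently-tagged record source).
#' @return A `reaction_benchmark`: list with `data` (split role tibble),
#'   `audit` (the [funnel_audit()]) and `recipe`.
#' @export
build_benchmark <- function(roles, recipe, source_tag = NULL) {
  stopifnot(inherits(recipe, "benchmark_recipe"))
  x <- roles
  if (!is.null(source_tag)) x <- x[x$source_file %in% source_tag, ]
  x <- start_funnel(x, "full data set")
  prev_step <- function(x) utils::tail(get_funnel(x)$step, 1)
  check_nonempty <- function(x) {
    if (!nrow(x)) abort(sprintf("no reactions left after step '%s'", prev_step(x)))
    x
  }
  x <- check_nonempty(filter_component_counts(x, recipe$cfg))
  x <- check_nonempty(drop_empty(x))
  if (recipe$cfg$sanitize_yields) x <- sanitize_yields(x, TRUE)
  x <- check_nonempty(drop_duplicates(x))
  if (recipe$use_frequency_filter) {
    x <- check_nonempty(frequency_filter(x, recipe$cfg))
  }
  x <- grouped_random_split(x, recipe$cfg, key = recipe_split_key(recipe))
  structure(list(data = x, audit = get_funnel(x), recipe = recipe),
            class = "reaction_benchmark")
}

#' @export
print.reaction_benchmark <- function(x, ...) {
  sizes <- table(x$data$split)
  cat(sprintf("<reaction_benchmark> %s: %d reactions (train %d / val %d / test %d)\n",
              x$recipe$name, nrow(x$data), sizes[["train"]], sizes[["val"]],
              sizes[["test"]]))
  print(x$audit)
  invisible(x)
}

#' @rdname glance
#' @method glance reaction_benchmark
#' @export
glance.reaction_benchmark <- function(x, ...) {
  sizes <- table(x$data$split)
  tibble(
    benchmark = x$recipe$name,
    n_reactions = nrow(x$data),
    n_train = as.integer(sizes[["train"]]),
    n_val = as.integer(sizes[["val"]]),
    n_test = as.integer(sizes[["test"]]),
    leakage = split_leakage(x$data)
  )
}

#' Flatten a benchmark to fixed-width dataset rows
#'
#' Expands the role list-columns into the flat column layout of the
#' on-disk datasets (reaction SMILES + is_mapped; reactant/product
#' columns; solvent/agent columns; temperature, time, yield; procedure;
#' dates and file name), suitable for [write_dataset()].
#'
#' @param bench A [build_benchmark()] result (or a role tibble).
#' @return A flat tibble, one row per reaction.
#' @export
benchmark_rows <- function(bench) {
  x <- if (inherits(bench, "reaction_benchmark")) bench$data else bench
  widen <- function(col, prefix) {
    width <- max(1L, if (nrow(x)) max(lengths(x[[col]])) else 1L)
    cols <- lapply(seq_len(width), function(j) {
      vapply(x[[col]], function(v) if (length(v) >= j) v[[j]] else NA_character_,
             character(1))
    })
    setNames(as_tibble(cols, .name_repair = "minimal"),
             paste0(prefix, "_", seq_len(width)))
  }
  out <- tibble(record_id = x$record_id)
  if ("mapped_rxn" %in% names(x)) out$rxn_str <- x$mapped_rxn
  if ("is_mapped" %in% names(x)) out$is_mapped <- x$is_mapped
  out <- dplyr::bind_cols(out, widen("reactants", "reactant"),
                          widen("products", "product"),
                          widen("solvents", "solvent"), widen("agents", "agent"))
  if ("temperature_celsius" %in% names(x)) out$temperature_celsius <- x$temperature_celsius
  if ("time_hours" %in% names(x)) out$time_hours <- x$time_hours
  if ("yields_percent" %in% names(x)) {
    out$yield_percent <- vapply(x$yields_percent,
                                function(y) if (length(y)) y[[1]] else NA_real_,
                                numeric(1))
  }
  for (f in c("procedure_details", "grant_date", "experiment_date", "source_file")) {
    if (f %in% names(x)) out[[f]] <- x[[f]]
  }
  if ("split" %in% names(x)) out$split <- as.character(x$split)
  out
}

#' Format sequence-model examples
#'
#' Turns role-assigned reactions into untokenized source/target string
#' pairs:
#'
#' * `forward_mixed`: source is the dot-join of reactants, solvents and
#'   agents in randomized order (no `>`); target is the dot-join of
#'   products.
#' * `forward_separated`: source is `reactants>spectators`, the reactant
#'   block weakly separated from the solvent+agent block by a single `>`
#'   token (solvents before agents, each block internally shuffled). An
#'   empty spectator block keeps the trailing `>` so the positional
#'   contract stays parseable.
#' * `retro`: source is the product; target is the dot-join of reactants.
#'
#' @param rxns Role tibble (rows satisfying the recipe's maxima).
#' @param mode `"forward_mixed"`, `"forward_separated"` or `"retro"`.
#' @param seed Seed for the molecule-order randomization.
#' @return A tibble with columns `record_id`, `source`, `target`, `mode`.
#' @export
format_seq_examples <- function(rxns,
                                mode = c("forward_mixed", "forward_separated", "retro"),
                                seed = 1L) {
  mode <- match.arg(mode)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(rxns)), function(i) {
      re <- rxns$reactants[[i]]; pr <- rxns$products[[i]]
      so <- rxns$solvents[[i]]; ag <- rxns$agents[[i]]
      shuf <- function(v) if (length(v) > 1) sample(v) else v
      switch(mode,
        forward_mixed = list(source = paste(shuf(c(re, so, ag)), collapse = "."),
                             target = paste(shuf(pr), collapse = ".")),
        forward_separated = list(
          source = paste0(paste(shuf(re), collapse = "."), ">",
                          paste(c(shuf(so), shuf(ag)), collapse = ".")),
          target = paste(shuf(pr), collapse = ".")),
        retro = list(source = paste(shuf(pr), collapse = "."),
                     target = paste(shuf(re), collapse = "."))
      )
    })
    tibble(
      record_id = rxns$record_id,
      source = vapply(rows, `[[`, character(1), "source"),
      target = vapply(rows, `[[`, character(1), "target"),
      mode = mode
    )
  })
}

# rewrite one source/target string: random equivalent SMILES per fragment,
# molecule order re-randomized within each ">"-delimited block
rewrite_examples <- function(strings) {
  blocks <- strsplit(strings, ">", fixed = TRUE)
  # pad trailing empty blocks lost by strsplit
  n_sep <- lengths(regmatches(strings, gregexpr(">", strings, fixed = TRUE)))
  blocks <- purrr::map2(blocks, n_sep, function(b, k) {
    length(b) <- k + 1L
    b[is.na(b)] <- ""
    b
  })
  frag_lists <- lapply(blocks, function(b) lapply(b, split_fragments))
  all_frags <- unlist(frag_lists)
  if (is.null(all_frags)) all_frags <- character(0)
  rewritten <- random_equivalent_smiles(all_frags)
  k <- 0L
  vapply(frag_lists, function(fl) {
    new_blocks <- vapply(fl, function(frags) {
      m <- length(frags)
      if (!m) return("")
      repl <- rewritten[k + seq_len(m)]
      k <<- k + m
      paste(if (m > 1) sample(repl) else repl, collapse = ".")
    }, character(1))
    paste(new_blocks, collapse = ">")
  }, character(1))
}

#' Augment sequence examples with random equivalent SMILES
#'
#' Doubles the example set: each example gains one augmented copy in which
#' every SMILES fragment is replaced by a random equivalent SMILES string
#' and the molecule order within each block is re-randomized. Augmented
#' fragments canonicalize to the same canonical SMILES as their originals,
#' so the chemistry of every example is untouched.
#'
#' @param examples Tibble from [format_seq_examples()].
#' @param seed Seed for the rewrites and reshuffles.
#' @return A tibble of exactly `2 * nrow(examples)` rows (originals first,
#'   column `augmented` marking the copies).
#' @export
augment_equivalent_smiles <- function(examples, seed = 1L) {
  aug <- examples
  withr::with_seed(seed, {
    aug$source <- rewrite_examples(examples$source)
    aug$target <- rewrite_examples(examples$target)
  })
  out <- dplyr::bind_rows(
    dplyr::mutate(examples, augmented = FALSE),
    dplyr::mutate(aug, augmented = TRUE)
  )
  out
}

#' Write sequence examples as plain-text source/target files
#'
#' One example per line, the layout consumed by sequence-to-sequence
#' training scripts.
#'
#' @param examples Tibble with `source` and `target` columns.
#' @param dir Output directory.
#' @param prefix File-name prefix (`<prefix>.source` / `<prefix>.target`).
#' @return The two paths, invisibly.
#' @export
write_seq_files <- function(examples, dir, prefix = "examples") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  src <- file.path(dir, paste0(prefix, ".source"))
  tgt <- file.path(dir, paste0(prefix, ".target"))
  writeLines(examples$source, src)
  writeLines(examples$target, tgt)
  invisible(c(src, tgt))
}
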