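# Order-invariant evaluation. Condition predictions are five-slot targets
# (two solvents, three agents) compared as multisets -- slot order and
# null padding never matter. Top-k accuracy asks whether any of the first
# k beam entries matches; the frequency-informed baseline predicts the
# most common train-set combinations; AIB normalizes the model's gain
# over that baseline.

.solvent_slots <- c("solvent_1", "solvent_2")
.agent_slots <- c("agent_1", "agent_2", "agent_3")
.all_slots <- c(.solvent_slots, .agent_slots)

#' Construct a condition target
#'
#' A condition target holds up to two solvents and three agents in fixed
#' slots; the comparison semantics ([combo_match()]) ignore slot order and
#' null padding. The literal token `"other"` (produced by the
#' map-to-other rare strategy) participates as an ordinary value.
#'
#' @param solvents Character vector, length <= 2.
#' @param agents Character vector, length <= 3.
#' @return One-row tibble with columns `solvent_1`, `solvent_2`,
#'   `agent_1`, `agent_2`, `agent_3`.
#' @export
condition_target <- function(solvents = character(0), agents = character(0)) {
  solvents <- solvents[!is.na(solvents)]
  agents <- agents[!is.na(agents)]
  if (length(solvents) > 2L) abort("at most two solvent slots")
  if (length(agents) > 3L) abort("at most three agent slots")
  length(solvents) <- 2L
  length(agents) <- 3L
  tibble(solvent_1 = solvents[1], solvent_2 = solvents[2],
         agent_1 = agents[1], agent_2 = agents[2], agent_3 = agents[3])
}

#' Condition targets of a role table
#'
#' @param rxns Role tibble whose rows satisfy the condition recipe maxima.
#' @return Tibble of condition targets, one row per reaction.
#' @export
condition_targets <- function(rxns) {
  purrr::map_dfr(seq_len(nrow(rxns)), function(i) {
    condition_target(rxns$solvents[[i]], rxns$agents[[i]])
  })
}

group_slots <- function(group = c("both", "solvents", "agents")) {
  switch(match.arg(group),
    solvents = .solvent_slots,
    agents = .agent_slots,
    both = .all_slots
  )
}

# multiset key of the non-null entries in the group slots, per row
slot_key <- function(targets, group = "both") {
  cols <- group_slots(group)
  missing_cols <- setdiff(cols, names(targets))
  for (mc in missing_cols) targets[[mc]] <- NA_character_
  mat <- as.matrix(targets[, cols, drop = FALSE])
  apply(mat, 1L, function(v) {
    v <- v[!is.na(v) & nzchar(v)]
    paste(sort(v), collapse = " | ")
  })
}

#' Order-invariant exact match of condition targets
#'
#' Two targets match on a component group iff the multisets of their
#' non-null entries in that group are equal; slot order and null placement
#' are irrelevant, and duplicate molecules are compared as multisets (two
#' slots holding the same species must match two slots holding it).
#'
#' @param pred,truth Condition-target tibbles of equal height.
#' @param group `"solvents"`, `"agents"` or `"both"`.
#' @return Logical vector, one element per row.
#' @export
combo_match <- function(pred, truth, group = c("both", "solvents", "agents")) {
  group <- match.arg(group)
  stopifnot(nrow(pred) == nrow(truth))
  slot_key(pred, group) == slot_key(truth, group)
}

normalize_beams <- function(beams, n_examples) {
  if (is.data.frame(beams)) {
    if (!"rank" %in% names(beams)) beams$rank <- seq_len(nrow(beams))
    beams <- rep(list(beams), n_examples)
  }
  stopifnot(length(beams) == n_examples)
  beams
}

#' Top-k exact-match combination accuracy
#'
#' Percentage of examples for which any of the first `k` entries of the
#' prediction beam matches the true condition target under
#' [combo_match()]. Monotone non-decreasing in `k`.
#'
#' @param beams Ranked predictions: either one beam tibble (rows ordered by
#'   rank, slot columns as in [condition_target()]) shared by all examples
#'   -- the frequency-baseline case -- or a list of such tibbles, one per
#'   example.
#' @param truths Condition-target tibble, one row per example.
#' @param k Rank cutoff.
#' @param group Component group to compare.
#' @return Accuracy in percent.
#' @export
topk_accuracy <- function(beams, truths, k = 3L,
                          group = c("both", "solvents", "agents")) {
  group <- match.arg(group)
  if (!nrow(truths)) abort("empty truth list")
  beams <- normalize_beams(beams, nrow(truths))
  truth_keys <- slot_key(truths, group)
  hits <- vapply(seq_len(nrow(truths)), function(i) {
    beam <- utils::head(beams[[i]], k)
    if (!nrow(beam)) return(FALSE)
    any(slot_key(beam, group) == truth_keys[i])
  }, logical(1))
  100 * mean(hits)
}

#' Frequency-informed baseline beam
#'
#' Predicts, for every test example, the `k` most frequent complete
#' condition combinations of the train set for the requested component
#' group, ranked by count with ties broken lexicographically on the sorted
#' canonical SMILES key. Fewer than `k` distinct combinations yield a
#' shorter beam.
#'
#' @param train_targets Condition-target tibble of the train split.
#' @param k Beam width.
#' @param group Component group the baseline predicts.
#' @return A beam tibble (`rank`, `n`, slot columns) shared by all test
#'   examples.
#' @export
frequency_baseline <- function(train_targets, k = 3L,
                               group = c("both", "solvents", "agents")) {
  group <- match.arg(group)
  if (!nrow(train_targets)) abort("empty train set")
  cols <- group_slots(group)
  key <- slot_key(train_targets, group)
  counts <- tibble(key = key) |>
    dplyr::count(.data$key, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$key)
  top <- utils::head(counts, k)
  first_idx <- match(top$key, key)
  beam <- train_targets[first_idx, cols, drop = FALSE]
  for (mc in setdiff(.all_slots, cols)) beam[[mc]] <- NA_character_
  beam <- beam[, .all_slots]
  beam$rank <- seq_len(nrow(beam))
  beam$n <- top$n
  beam[, c("rank", "n", .all_slots)]
}

#' Average improvement over baseline (AIB)
#'
#' Normalized gain of the model's exact-match combination accuracy over
#' the frequency-informed baseline. The default convention is
#' `100 * (A_m - A_b) / (100 - A_b)`: 0 when the model only matches the
#' baseline, 100 when the model is perfect. The convention is a named,
#' swappable policy; `"difference"` reports the raw gap `A_m - A_b`.
#'
#' @param a_model Model accuracy in percent (0--100).
#' @param a_baseline Baseline accuracy in percent (0 <= A_b < 100 for the
#'   normalized convention).
#' @param convention `"normalized_gain"` (default) or `"difference"`.
#' @return AIB in percent.
#' @export
aib <- function(a_model, a_baseline,
                convention = c("normalized_gain", "difference")) {
  convention <- match.arg(convention)
  stopifnot(all(a_model >= 0 & a_model <= 100), all(a_baseline >= 0))
  if (convention == "difference") return(a_model - a_baseline)
  if (any(a_baseline >= 100)) {
    abort("AIB is undefined at a baseline accuracy of 100%")
  }
  100 * (a_model - a_baseline) / (100 - a_baseline)
}

#' Evaluate condition predictions against a truth set
#'
#' Computes, per component group (solvents, agents, both), the model's
#' top-k exact-match combination accuracy, the frequency-informed baseline
#' accuracy derived from the train targets, and the AIB.
#'
#' @param beams Model predictions as in [topk_accuracy()].
#' @param truths Test-set condition targets.
#' @param train_targets Train-set condition targets (for the baseline).
#' @param k Rank cutoff (default top-3).
#' @param aib_convention Passed to [aib()].
#' @return A `condition_metrics` tibble with columns `group`,
#'   `a_baseline`, `a_model`, `aib_percent`; attributes `k` and
#'   `n_examples`.
#' @export
evaluate_condition_predictions <- function(beams, truths, train_targets,
                                           k = 3L,
                                           aib_convention = "normalized_gain") {
  groups <- c("solvents", "agents", "both")
  rows <- lapply(groups, function(g) {
    a_m <- topk_accuracy(beams, truths, k, g)
    a_b <- topk_accuracy(frequency_baseline(train_targets, k, g), truths, k, g)
    tibble(group = g, a_baseline = a_b, a_model = a_m,
           # AIB is undefined at a saturated baseline
           aib_percent = if (a_b < 100) aib(a_m, a_b, aib_convention) else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("condition_metrics", class(out)),
            k = k, n_examples = nrow(truths))
}

#' @export
print.condition_metrics <- function(x, ...) {
  cat(sprintf("<condition_metrics> top-%d on %d examples (baseline//model//AIB)\n",
              attr(x, "k"), attr(x, "n_examples")))
  lab <- c(solvents = "solvents", agents = "agents", both = "S + A")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-8s %2.0f//%2.0f//%2.0f%%\n", lab[[x$group[i]]],
                x$a_baseline[i], x$a_model[i], x$aib_percent[i]))
  }
  invisible(x)
}

#' Tidy and summarize metric objects
#'
#' `tidy()` returns the per-group metric rows; `glance()` returns a
#' one-row summary (the all-components row).
#'
#' @param x A `condition_metrics` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy
#' @method tidy condition_metrics
#' @export
tidy.condition_metrics <- function(x, ...) {
  as_tibble(x)
}

#' @rdname glance
#' @method glance condition_metrics
#' @export
glance.condition_metrics <- function(x, ...) {
  both <- x[x$group == "both", ]
  tibble(k = attr(x, "k"), n_examples = attr(x, "n_examples"),
         a_baseline = both$a_baseline, a_model = both$a_model,
         aib_percent = both$aib_percent)
}

#' @rdname glance
#' @name glance
NULL

#' Autoplot methods
#'
#' ggplot2 visualizations of the package's result objects: cleaning
#' funnels, reactant-count provenance comparisons and condition metrics.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-rxncurate
NULL

#' @rdname autoplot-rxncurate
#' @method autoplot condition_metrics
#' @export
autoplot.condition_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            cols = c("a_baseline", "a_model"),
                            names_to = "which", values_to = "accuracy")
  df$which <- ifelse(df$which == "a_baseline", "baseline", "model")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$accuracy,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = sprintf("top-%d accuracy (%%)", attr(object, "k")),
                  fill = NULL, title = "Condition prediction accuracy") +
    ggplot2::theme_minimal()
}

#' Invalid-SMILES rate of sequence predictions
#'
#' Share of predicted SMILES strings that fail sanitization, in percent.
#'
#' @param predictions Character vector of predicted SMILES.
#' @return Percent invalid.
#' @export
invalid_smiles_rate <- function(predictions) {
  if (!length(predictions)) abort("empty prediction list")
  100 * mean(!smiles_valid(predictions))
}

seq_match_key <- function(smiles, stereo = c("with", "without")) {
  stereo <- match.arg(stereo)
  vapply(smiles, function(s) {
    frags <- split_fragments(s)
    if (stereo == "without") frags <- strip_stereo(frags)
    canon <- canonicalize_smiles(frags)
    if (!length(canon) || anyNA(canon)) return(NA_character_)
    paste(sort(canon), collapse = ".")
  }, character(1), USE.NAMES = FALSE)
}

#' Top-1 accuracy of sequence predictions
#'
#' A prediction matches its truth iff the canonical forms of their
#' dot-separated fragment multisets agree. With `stereo = "without"` both
#' sides are stripped of stereochemical marks and re-canonicalized first,
#' so the stereo-blind accuracy is never below the stereo-aware one.
#' Invalid predictions never match.
#'
#' @param preds,truths Character vectors of equal length.
#' @param stereo `"with"` or `"without"` stereochemistry.
#' @return Accuracy in percent.
#' @export
top1_accuracy_seq <- function(preds, truths, stereo = c("with", "without")) {
  stereo <- match.arg(stereo)
  if (length(preds) != length(truths)) abort("preds and truths differ in length")
  pk <- seq_match_key(preds, stereo)
  tk <- seq_match_key(truths, stereo)
  100 * mean(!is.na(pk) & !is.na(tk) & pk == tk)
}

#' Evaluate sequence-model predictions
#'
#' Bundles the invalid-SMILES rate and the top-1 accuracies with and
#' without stereochemistry.
#'
#' @param preds,truths Character vectors of equal length.
#' @return A one-row `seq_eval` tibble with columns
#'   `invalid_smiles_percent`, `top1_accuracy_with_sc`,
#'   `top1_accuracy_without_sc`.
#' @export
evaluate_seq_predictions <- function(preds, truths) {
  out <- tibble(
    invalid_smiles_percent = invalid_smiles_rate(preds),
    top1_accuracy_with_sc = top1_accuracy_seq(preds, truths, "with"),
    top1_accuracy_without_sc = top1_accuracy_seq(preds, truths, "without")
  )
  structure(out, class = c("seq_eval", class(out)))
}
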