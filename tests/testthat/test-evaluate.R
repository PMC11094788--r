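# Order-invariant condition metrics and sequence-prediction evaluation.

test_that("combo matching ignores slot order, null padding and compares multisets", {
  thf <- "C1CCOC1"; dmf <- "CN(C)C=O"
  p <- condition_target(c(thf, dmf), c("[Pd]"))
  q <- condition_target(c(dmf, thf), c("[Pd]"))
  expect_true(combo_match(p, q, "solvents"))
  expect_true(combo_match(p, q, "both"))
  expect_true(combo_match(condition_target(thf), condition_target(c(thf))))
  # missing one truth agent is a miss
  r <- condition_target(c(thf, dmf), character(0))
  expect_false(combo_match(p, r, "agents"))
  # duplicates are multisets, not sets
  expect_false(combo_match(condition_target(c(thf, thf)), condition_target(thf),
                           "solvents"))
  # symmetric
  expect_identical(combo_match(p, r, "agents"), combo_match(r, p, "agents"))
})

test_that("combo matching survives randomized slot permutations and null placement", {
  set.seed(101)
  vocab <- c("O", "CCO", "C1CCOC1", "[Pd]", "CN(C)C=O", "other")
  n_cases <- 2500  # x4 checks per case
  for (i in seq_len(n_cases)) {
    ns <- sample(0:2, 1); na <- sample(0:3, 1)
    solv <- sample(vocab, ns, replace = TRUE)
    ag <- sample(vocab, na, replace = TRUE)
    a <- condition_target(solv, ag)
    b <- condition_target(sample(solv), sample(ag))
    expect_true(combo_match(a, b, "both"))
    expect_true(combo_match(a, b, "solvents"))
    expect_true(combo_match(a, b, "agents"))
    # perturbation: dropping or adding one agent breaks the match
    if (na > 0) {
      c_ <- condition_target(solv, ag[-1])
      expect_false(combo_match(a, c_, "agents"))
    }
  }
})

# independent brute-force oracle: loop over beam entries, compare sorted
# component vectors directly
oracle_topk <- function(beams, truths, k, group) {
  cols <- switch(group,
    solvents = c("solvent_1", "solvent_2"),
    agents = c("agent_1", "agent_2", "agent_3"),
    both = c("solvent_1", "solvent_2", "agent_1", "agent_2", "agent_3"))
  pull <- function(df, i) sort(na.omit(unlist(df[i, cols], use.names = FALSE)))
  hits <- 0
  for (i in seq_len(nrow(truths))) {
    beam <- if (is.data.frame(beams)) beams else beams[[i]]
    found <- FALSE
    for (r in seq_len(min(k, nrow(beam)))) {
      if (identical(pull(beam, r), pull(truths, i))) found <- TRUE
    }
    hits <- hits + found
  }
  100 * hits / nrow(truths)
}

test_that("top-k accuracy equals brute-force enumeration on toy sets", {
  set.seed(77)
  vocab <- c("O", "CCO", "[Pd]", "CC#N", "other")
  rand_target <- function() {
    condition_target(sample(vocab, sample(0:2, 1), replace = TRUE),
                     sample(vocab, sample(0:3, 1), replace = TRUE))
  }
  for (trial in 1:25) {
    n <- sample(1:6, 1)
    truths <- do.call(rbind, replicate(n, rand_target(), simplify = FALSE))
    beams <- lapply(seq_len(n), function(i) {
      b <- do.call(rbind, replicate(3, rand_target(), simplify = FALSE))
      if (runif(1) < 0.5) b[sample(3, 1), ] <- truths[i, ]  # plant the truth
      b
    })
    for (g in c("solvents", "agents", "both")) {
      for (k in 1:3) {
        expect_equal(topk_accuracy(beams, truths, k, g),
                     oracle_topk(beams, truths, k, g))
      }
    }
  }
})

test_that("top-k accuracy is monotone in k and handles rank semantics", {
  truth <- condition_target("O", "[Pd]")
  decoy <- condition_target("CCO", "other")
  beam <- rbind(decoy, decoy, truth)  # truth at rank 3
  expect_equal(topk_accuracy(beam, truth, k = 3), 100)
  expect_equal(topk_accuracy(beam, truth, k = 1), 0)
  for (k in 1:2) {
    expect_lte(topk_accuracy(beam, truth, k), topk_accuracy(beam, truth, k + 1))
  }
  expect_error(topk_accuracy(beam, truth[0, ], 3), "empty truth")
})

test_that("the frequency baseline ranks by count with lexicographic ties", {
  x <- condition_target("O", "[Pd]")
  y <- condition_target("CCO", "[Pd]")
  z <- condition_target("CC#N", "[Pd]")
  train <- rbind(x, x, x, x, x, y, y, y, z, z, z)  # X:5, Y:3, Z:3
  beam <- frequency_baseline(train, 3)
  expect_equal(nrow(beam), 3)
  expect_identical(beam$solvent_1[1], "O")
  # tie between Y and Z broken lexicographically on the sorted key
  keys23 <- c(beam$solvent_1[2], beam$solvent_1[3])
  expect_identical(keys23, sort(c("CCO", "CC#N")))
  # degenerate train: single combination, shorter beam, perfect top-1
  train1 <- rbind(x, x, x)
  b1 <- frequency_baseline(train1, 3)
  expect_equal(nrow(b1), 1)
  expect_equal(topk_accuracy(b1, rbind(x, x), 1), 100)
})

test_that("AIB normalizes the gain over baseline", {
  expect_equal(aib(57, 57), 0)
  expect_equal(aib(100, 40), 100)
  # frozen by direct evaluation of 100*(70-57)/(100-57)
  expect_equal(aib(70, 57), 30.23256, tolerance = 1e-6)
  expect_error(aib(50, 100), "undefined")
  # strictly increasing in model accuracy at fixed baseline
  grid <- seq(0, 100, by = 5)
  for (ab in c(0, 20, 57, 91)) {
    vals <- aib(grid, ab)
    expect_true(all(diff(vals) > 0))
    expect_equal(aib(ab, ab), 0)
  }
  expect_equal(aib(70, 57, convention = "difference"), 13)
})

test_that("invalid-SMILES rate counts parse failures", {
  expect_equal(invalid_smiles_rate(c("CCO", "C1CC")), 50)
  expect_equal(invalid_smiles_rate(c("CCO", "O.CC")), 0)
  expect_equal(invalid_smiles_rate(c("xx((", "C1CC")), 100)
  expect_error(invalid_smiles_rate(character(0)), "empty")
})

test_that("top-1 sequence accuracy respects stereochemistry flags", {
  preds <- c("C[C@H](N)C(=O)O", "CCO.O", "C1CC", "OCC")
  truths <- c("C[C@@H](N)C(=O)O", "O.CCO", "CCO", "CCO")
  # pred 1 differs only in stereo: miss with SC, hit without
  expect_equal(top1_accuracy_seq(preds[1], truths[1], "with"), 0)
  expect_equal(top1_accuracy_seq(preds[1], truths[1], "without"), 100)
  # invalid prediction misses under both conventions
  expect_equal(top1_accuracy_seq(preds[3], truths[3], "with"), 0)
  expect_equal(top1_accuracy_seq(preds[3], truths[3], "without"), 0)
  # fragment order on either side is irrelevant
  expect_equal(top1_accuracy_seq(preds[2], truths[2], "with"), 100)
  expect_error(top1_accuracy_seq(preds, truths[1:2]), "length")
})

test_that("stereo-blind accuracy dominates stereo-aware accuracy", {
  set.seed(55)
  base <- c("C[C@H](N)C(=O)O", "F/C=C/F", "CC(O)CC", "c1ccccc1C(N)=O",
            "C[C@@H](O)[C@H](N)C", "CCOC(=O)C")
  flip_stereo <- function(s) chartr("/\\", "\\/", gsub("@@", "@", s))
  for (trial in 1:40) {
    n <- sample(3:6, 1)
    truths <- sample(base, n, replace = TRUE)
    preds <- vapply(truths, function(s) {
      r <- runif(1)
      if (r < 0.3) s
      else if (r < 0.6) flip_stereo(s)
      else sample(base, 1)
    }, character(1), USE.NAMES = FALSE)
    with_sc <- top1_accuracy_seq(preds, truths, "with")
    without_sc <- top1_accuracy_seq(preds, truths, "without")
    expect_gte(without_sc, with_sc)
  }
})

test_that("the condition metrics report is tidy and printable", {
  set.seed(9)
  x <- condition_target("O", "[Pd]")
  y <- condition_target("CCO", "other")
  train <- rbind(x, x, x, y)
  truths <- rbind(x, x, y, x)
  beams <- lapply(1:4, function(i) rbind(truths[i, ], y, x))
  m <- evaluate_condition_predictions(beams, truths, train)
  expect_s3_class(m, "condition_metrics")
  td <- tidy(m)
  expect_identical(td$group, c("solvents", "agents", "both"))
  expect_true(all(td$a_model >= 0 & td$a_model <= 100))
  g <- glance(m)
  expect_equal(g$n_examples, 4)
  expect_output(print(m), "baseline//model//AIB")
  expect_s3_class(autoplot(m), "ggplot")
})
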