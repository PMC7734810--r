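# Decisions/citations pair built directly for metric tests.
make_eval_pair <- function(n_true_inc, n_true_exc, outcomes, true_reasons = NULL) {
  n <- n_true_inc + n_true_exc
  cit <- tibble::tibble(
    id = sprintf("e%03d", seq_len(n)),
    title = "", abstract = "x",
    abstract_decision = "include",
    abstract_reason = NA_character_,
    fulltext_decision = c(rep("include", n_true_inc), rep("exclude", n_true_exc)),
    fulltext_reason = c(rep(NA_character_, n_true_inc),
                        true_reasons %||% rep("study_design", n_true_exc)),
    dataset_tag = "eval"
  )
  dec <- tibble::tibble(
    citation_id = cit$id,
    outcome = outcomes,
    reason = ifelse(outcomes == "exclude", "study_design", NA_character_),
    overall_prob = ifelse(outcomes == "include", 0.1, 0.95)
  )
  attr(dec, "threshold") <- 0.9
  list(dec = dec, cit = cit)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("confusion counts use the screening-specific definitions", {
  # 33 true includes, 2 auto-excluded; the rest of the corpus are true excludes
  p <- make_eval_pair(33, 50, c(rep("include", 20), rep("unclassified", 11),
                                rep("exclude", 2), rep("exclude", 40),
                                rep("unclassified", 10)))
  cc <- confusion_counts(p$dec, p$cit)
  expect_equal(cc$tp, 31)  # include or no-decision counts as TP
  expect_equal(cc$fn, 2)
  expect_equal(cc$tn, 40)
  expect_equal(cc$fp, 10)

  all_un <- make_eval_pair(5, 7, rep("unclassified", 12))
  cc2 <- confusion_counts(all_un$dec, all_un$cit)
  expect_equal(unlist(cc2[c("tp", "fn", "tn", "fp")]),
               c(tp = 5, fn = 0, tn = 0, fp = 7))

  bad <- p$dec
  bad$citation_id[1] <- "missing_id"
  expect_error(confusion_counts(bad, p$cit), "unknown citation id")
})

test_that("confusion counts equal a brute-force per-citation tally", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      n_inc <- sample(2:10, 1); n_exc <- sample(2:15, 1)
      outcomes <- sample(c("include", "exclude", "unclassified"),
                         n_inc + n_exc, replace = TRUE)
      p <- make_eval_pair(n_inc, n_exc, outcomes)
      cc <- confusion_counts(p$dec, p$cit)
      tally <- c(tp = 0, fn = 0, tn = 0, fp = 0)
      for (i in seq_len(nrow(p$cit))) {
        truly_inc <- p$cit$fulltext_decision[i] == "include"
        out <- p$dec$outcome[p$dec$citation_id == p$cit$id[i]]
        if (truly_inc && out != "exclude") tally["tp"] <- tally["tp"] + 1
        if (truly_inc && out == "exclude") tally["fn"] <- tally["fn"] + 1
        if (!truly_inc && out == "exclude") tally["tn"] <- tally["tn"] + 1
        if (!truly_inc && out != "exclude") tally["fp"] <- tally["fp"] + 1
      }
      expect_equal(unlist(cc[c("tp", "fn", "tn", "fp")]), tally)
      expect_equal(sum(tally), nrow(p$cit))  # conservation
    }
  })
})

test_that("performance ratios follow the printed formulas and flag undefined cases", {
  m <- performance_metrics(structure(list(tp = 31, fn = 2, tn = 9, fp = 1),
                                     class = "confusion_counts"))
  expect_equal(m$sensitivity, 31 / 33)
  m2 <- performance_metrics(structure(list(tp = 3, fn = 1, tn = 5, fp = 1),
                                      class = "confusion_counts"))
  expect_equal(m2$precision, 0.75)
  expect_equal(m2$accuracy, 0.8)
  expect_equal(m2$sensitivity, 0.75)
  expect_equal(m2$specificity, 5 / 6)
  m3 <- performance_metrics(structure(list(tp = 0, fn = 0, tn = 5, fp = 0),
                                      class = "confusion_counts"))
  expect_true(is.na(m3$sensitivity))   # undefined, not zero
  expect_equal(m3$specificity, 1.0)
})

test_that("reason-level rates match hand counts", {
  cit <- tibble::tibble(
    id = sprintf("r%02d", 1:5), title = "", abstract = "x",
    abstract_decision = "include", abstract_reason = NA_character_,
    fulltext_decision = c("include", rep("exclude", 4)),
    fulltext_reason = c(NA, "population", "outcomes", "time", "population"),
    dataset_tag = "eval"
  )
  dec <- tibble::tibble(
    citation_id = cit$id,
    outcome = c("include", "exclude", "exclude", "exclude", "unclassified"),
    reason = c(NA, "population", "outcomes", "population", NA),
    overall_prob = c(0.2, 0.95, 0.92, 0.99, 0.91),
    reason_prob_population = c(0.1, 0.95, 0.2, 0.96, 0.5),
    reason_prob_outcomes = c(0.1, 0.3, 0.93, 0.2, 0.5),
    reason_prob_time = c(0.1, 0.2, 0.1, 0.3, 0.5)
  )
  attr(dec, "threshold") <- 0.9
  rm_ <- reason_metrics(dec, cit)
  # 4 citations above the overall threshold, 3 received a reason
  expect_equal(rm_$excluded_with_reason_rate, 0.75)
  # of the 3 reasoned excludes: true reasons population (0.95), outcomes
  # (0.93) qualify; r04's true reason time has prob 0.3 -> 2/3
  expect_equal(rm_$correct_reason_rate, 2 / 3)
  # assigned == reviewer reason for r02 and r03 only
  expect_equal(rm_$strict_match_rate, 2 / 3)

  all_match <- dec[c(1, 2, 3), ]
  attr(all_match, "threshold") <- 0.9
  expect_equal(reason_metrics(all_match, cit)$correct_reason_rate, 1.0)
})

test_that("the full factorial grid reproduces the published scenario totals", {
  tags <- c("psoriasis", "lung_cancer", "liver_cancer", "melanoma", "obesity")
  grid <- enumerate_scenarios(tags)
  expect_equal(nrow(grid), 870)
  expect_equal(sum(grid$algorithm == "naive_bayes"), 420)
  expect_equal(sum(grid$algorithm == "svm"), 240)
  expect_equal(sum(grid$algorithm == "bagged_cart"), 210)

  one <- enumerate_scenarios("psoriasis")
  expect_equal(nrow(one), 174)
  expect_equal(sum(one$algorithm == "naive_bayes"), 84)  # 3*2*7*2
  expect_equal(sum(one$algorithm == "svm"), 48)          # 3*2*4*2
  expect_equal(sum(one$algorithm == "bagged_cart"), 42)  # 3*2*7*1

  expect_equal(nrow(enumerate_scenarios(character())), 0)
  # invalid cells are absent
  expect_false(any(grid$algorithm == "svm" & grid$feature_mode == "importance"))
  expect_false(any(grid$algorithm == "bagged_cart" & !is.na(grid$metric)))
})

test_that("restricted grids match their closed-form products", {
  grid <- enumerate_scenarios(c("a", "b"), schemes = "abstract",
                              downsampling = TRUE,
                              frequency_thresholds = c(5, 10),
                              importance_cuts = 50,
                              metrics = "roc")
  # per dataset: nb 3 feats x 1 metric, svm 2 x 1, cart 3 x 1
  expect_equal(nrow(grid), 2 * (3 + 2 + 3))
  expect_equal(sum(grid$algorithm == "naive_bayes"), 6)
})

test_that("paired factor tests reproduce the closed-form t statistic", {
  base <- tibble::tibble(
    dataset_tag = "d", scheme = "abstract",
    feature_mode = "min_frequency", feature_value = rep(c(5, 10, 100), 2),
    algorithm = "svm", metric = "roc",
    downsample = rep(c(TRUE, FALSE), each = 3),
    sensitivity = c(0.9, 0.8, 0.9, 0.8, 0.6, 0.6),  # diffs 0.1, 0.2, 0.3
    specificity = 0.5
  )
  res <- paired_factor_test(base, "downsample", TRUE, FALSE, "sensitivity")
  expect_equal(res$n_pairs, 3)
  expect_equal(res$mean_difference, 0.2)
  expect_equal(res$degrees_of_freedom, 2)
  d <- c(0.1, 0.2, 0.3)
  expect_equal(res$t_statistic, mean(d) / (sd(d) / sqrt(3)), tolerance = 1e-9)
  expect_equal(res$t_statistic, 3.4641016, tolerance = 1e-6)
  expect_equal(res$p_value, 2 * pt(-res$t_statistic, 2), tolerance = 1e-9)

  zero <- base
  zero$sensitivity <- 0.7
  z <- paired_factor_test(zero, "downsample", TRUE, FALSE, "sensitivity")
  expect_equal(z$mean_difference, 0)
  expect_true(z$degenerate)

  expect_error(paired_factor_test(base[c(1, 4), ][0, ], "downsample", TRUE, FALSE),
               "fewer than 2")
})

test_that("a 12-config grid differing in downsampling yields 6 matched pairs", {
  grid <- enumerate_scenarios("d", schemes = c("abstract", "full_text"),
                              frequency_thresholds = c(5, 10, 100),
                              importance_cuts = numeric(),
                              algorithms = "svm", metrics = "roc")
  expect_equal(nrow(grid), 12)
  grid$sensitivity <- seq(0.5, 0.61, length.out = 12)
  grid$specificity <- 0.5
  res <- paired_factor_test(grid, "downsample", TRUE, FALSE, "sensitivity")
  expect_equal(res$n_pairs, 6)
})

test_that("scenario batches run deterministically and survive per-config failures", {
  cit <- generate_corpus(small_spec(n = 300), seed = 4)
  configs <- enumerate_scenarios("synthetic", schemes = "full_text",
                                 downsampling = TRUE,
                                 frequency_thresholds = 5,
                                 importance_cuts = numeric(),
                                 algorithms = "naive_bayes", metrics = "roc")
  configs <- dplyr::bind_rows(configs, dplyr::mutate(configs, dataset_tag = "missing"))
  res <- run_scenarios(list(synthetic = cit), configs, master_seed = 2, folds = 3)
  expect_equal(nrow(res), 2)
  expect_true(is.na(res$error[1]))
  expect_false(is.na(res$sensitivity[1]))
  expect_match(res$error[2], "no corpus")  # failure recorded, batch continued
  expect_true(is.na(res$sensitivity[2]))

  res2 <- run_scenarios(list(synthetic = cit), configs, master_seed = 2, folds = 3)
  expect_equal(res$sensitivity, res2$sensitivity)
  expect_equal(res$specificity, res2$specificity)
})
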