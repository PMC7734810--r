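# Small learnable corpus: 20 includes, 30 population excludes, 10 outcomes
# excludes, each class with its own word pool.
screener_corpus <- function(seed = 6) {
  withr::with_seed(seed, {
    pools <- list(include = c("remission", "efficacy", "response", "benefit"),
                  population = c("pediatric", "infant", "children", "juvenile"),
                  outcomes = c("cost", "budget", "economic", "price"))
    mk <- function(cls, n) {
      replicate(n, paste(sample(pools[[cls]], 8, replace = TRUE), collapse = " "))
    }
    tibble::tibble(
      id = sprintf("sc%03d", 1:60),
      title = "",
      abstract = c(mk("include", 20), mk("population", 30), mk("outcomes", 10)),
      abstract_decision = c(rep("include", 20), rep("exclude", 40)),
      abstract_reason = c(rep(NA, 20), rep("population", 30), rep("outcomes", 10)),
      fulltext_decision = c(rep("include", 20), rep("not_screened", 40)),
      fulltext_reason = NA_character_,
      dataset_tag = "screener_toy"
    )
  })
}

test_that("ROC-optimal threshold selection minimizes distance to the top-left corner", {
  pts <- data.frame(fpr = c(0.2, 0.1), tpr = c(0.9, 0.7), threshold = c(0.6, 0.8))
  expect_equal(select_threshold(pts), 0.6)  # d = 0.224 beats 0.316
  perfect <- rbind(pts, data.frame(fpr = 0, tpr = 1, threshold = 0.7))
  expect_equal(select_threshold(perfect), 0.7)
  ties <- data.frame(fpr = c(0.3, 0.3), tpr = c(0.8, 0.8), threshold = c(0.4, 0.9))
  expect_equal(select_threshold(ties), 0.9)  # tie toward the higher threshold
  expect_error(select_threshold(pts[0, ]), "empty")
  expect_error(select_threshold(data.frame(fpr = 1.2, tpr = 0.5, threshold = 0.5)),
               "0, 1")
})

test_that("decision rules follow the threshold and hierarchy", {
  decide <- picoscreen:::decide_outcomes
  rp <- function(...) {
    v <- c(...)
    matrix(v, 1, length(v), dimnames = list(NULL, names(v)))
  }
  d <- decide(0.95, rp(population = 0.93, outcomes = 0.91), 0.90)
  expect_equal(d$outcome, "exclude")
  expect_equal(d$reason, "population")  # population outranks outcomes

  expect_equal(decide(0.10, rp(population = 0.99), 0.90)$outcome, "include")
  expect_equal(decide(0.95, rp(population = 0.85, outcomes = 0.85), 0.90)$outcome,
               "unclassified")
  # boundary: exactly at threshold qualifies
  b <- decide(0.90, rp(time = 0.90), 0.90)
  expect_equal(b$outcome, "exclude")
  expect_equal(b$reason, "time")
})

test_that("hierarchy resolution is correct for every qualifying subset", {
  decide <- picoscreen:::decide_outcomes
  reasons <- exclusion_reasons()
  for (mask in 0:(2^7 - 1)) {
    qual <- reasons[bitwAnd(mask, 2^(0:6)) > 0]
    probs <- matrix(ifelse(reasons %in% qual, 0.95, 0.5), 1, 7,
                    dimnames = list(NULL, sample(reasons)))  # column order irrelevant
    probs <- probs[, reasons, drop = FALSE]
    probs[1, ] <- ifelse(reasons %in% qual, 0.95, 0.5)
    d <- decide(0.95, probs, 0.90)
    if (length(qual) == 0) {
      expect_equal(d$outcome, "unclassified")
      expect_true(is.na(d$reason))
    } else {
      expect_equal(d$outcome, "exclude")
      expect_equal(d$reason, qual[which.min(match(qual, reasons))])
    }
  }
})

test_that("every citation gets exactly one outcome and excludes carry reasons", {
  decide <- picoscreen:::decide_outcomes
  withr::with_seed(14, {
    n <- 300
    overall <- runif(n)
    rp <- matrix(runif(n * 7), n, 7, dimnames = list(NULL, exclusion_reasons()))
    d <- decide(overall, rp, 0.90)
    expect_true(all(d$outcome %in% c("include", "exclude", "unclassified")))
    expect_equal(is.na(d$reason), d$outcome != "exclude")
    expect_true(all(d$outcome[overall < 0.90] == "include"))
  })
})

test_that("raising the threshold never grows the auto-excluded set", {
  decide <- picoscreen:::decide_outcomes
  withr::with_seed(15, {
    n <- 200
    overall <- runif(n)
    rp <- matrix(runif(n * 7), n, 7, dimnames = list(NULL, exclusion_reasons()))
    thresholds <- c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95)
    prev_excluded <- NULL
    prev_included <- NULL
    for (t in thresholds) {
      d <- decide(overall, rp, t)
      excluded <- which(d$outcome == "exclude")
      included <- which(d$outcome == "include")
      if (!is.null(prev_excluded)) {
        expect_true(all(excluded %in% prev_excluded))  # non-increasing
        expect_true(all(prev_included %in% included))  # includes never flip to exclude
      }
      prev_excluded <- excluded
      prev_included <- included
    }
  })
})

test_that("the cascade fits one pairwise model per reason present in training", {
  cit <- screener_corpus()
  ld <- derive_labels(cit, "abstract")
  cfg <- screening_config("abstract", algorithm = algorithm_spec("naive_bayes"),
                          metric = "roc", downsample = FALSE, folds = 2, seed = 8)
  model <- fit_screening_model(ld, cfg)
  expect_named(model$reason_models, c("population", "outcomes"))
  # pairwise subsets: includes + excludes with that reason (before downsampling)
  expect_equal(model$reason_subset_sizes[["population"]], 50)
  expect_equal(model$reason_subset_sizes[["outcomes"]], 30)
  expect_equal(model$overall$n_train, 60)
  expect_false(model$degenerate)

  dec <- screen(model, ld)
  expect_equal(nrow(dec), 60)
  expect_identical(dec$citation_id, cit$id)  # input order preserved
  expect_true(all(c("reason_prob_population", "reason_prob_outcomes") %in% names(dec)))
})

test_that("a model with no reason models leaves every gated citation unclassified", {
  cit <- screener_corpus()
  ld <- derive_labels(cit, "abstract")
  cfg <- screening_config("abstract", algorithm = algorithm_spec("naive_bayes"),
                          metric = "roc", downsample = FALSE, folds = 2, seed = 8)
  model <- fit_screening_model(ld, cfg)
  model$reason_models <- list()
  model$degenerate <- TRUE
  dec <- screen(model, ld)
  expect_true(all(dec$outcome %in% c("include", "unclassified")))
  expect_true(all(dec$outcome[dec$overall_prob >= model$threshold] == "unclassified"))
})

test_that("screening a well-separated corpus auto-excludes no true include", {
  cit <- generate_corpus(small_spec(), seed = 9)
  ld <- derive_labels(cit, "full_text")
  sp <- stratified_split(ld, 0.75, seed = 9)
  cfg <- screening_config("full_text", algorithm = algorithm_spec("naive_bayes"),
                          metric = "roc", folds = 5, seed = 9)
  model <- fit_screening_model(sp$train, cfg, screening = sp$test)
  dec <- screen(model, sp$test)
  cc <- confusion_counts(dec, sp$test$citations)
  expect_equal(cc$fn, 0)
  expect_equal(cc$tp + cc$fn + cc$tn + cc$fp, n_citations(sp$test))
})

test_that("classify handles a single feature row and invalid configs error", {
  cit <- screener_corpus()
  ld <- derive_labels(cit, "abstract")
  cfg <- screening_config("abstract", algorithm = algorithm_spec("naive_bayes"),
                          metric = "roc", downsample = FALSE, folds = 2, seed = 8)
  model <- fit_screening_model(ld, cfg)
  one <- build_dtm(preprocess_corpus(cit$abstract[21]), cit$id[21])
  d <- classify(model, one)
  expect_equal(nrow(d), 1)
  expect_true(d$outcome %in% c("include", "exclude", "unclassified"))

  expect_error(screening_config("abstract", feature = feature_config("importance"),
                                algorithm = algorithm_spec("svm")),
               "not applicable to the SVM")
  expect_error(screening_config("abstract", algorithm = algorithm_spec("bagged_cart"),
                                metric = "roc"),
               "not applicable to the bagged CART")
  expect_error(screening_config("abstract", threshold = 1.2), "threshold")
})
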