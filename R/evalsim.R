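#' Confusion counts for screening decisions
#'
#' Counts are computed relative to the full-text truth (a citation is truly
#' an include iff its full-text decision is include), with the
#' screening-specific definitions: a true include counts as TP when the
#' cascade returns include *or* unclassified (no decision) and as FN only
#' when auto-excluded with a reason; a true exclude counts as TN when
#' auto-excluded with a reason and as FP otherwise.
#'
#' @param decisions Decision tibble from [screen()].
#' @param citations Citation tibble holding the truth labels.
#' @return A `confusion_counts` list with fields `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(decisions, citations) {
  m <- match(decisions$citation_id, citations$id)
  if (anyNA(m)) {
    fail("decision(s) for unknown citation id(s): %s",
         paste(head(decisions$citation_id[is.na(m)], 5), collapse = ", "))
  }
  truth <- truth_include(citations)[m]
  excluded <- decisions$outcome == "exclude"
  structure(list(
    tp = sum(truth & !excluded),
    fn = sum(truth & excluded),
    tn = sum(!truth & excluded),
    fp = sum(!truth & !excluded)
  ), class = "confusion_counts")
}

#' Performance metrics from confusion counts
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), precision =
#' TP/(TP+FP), accuracy = (TP+TN)/(TP+FP+FN+TN). A zero denominator yields
#' `NA` (undefined), never a silent zero.
#'
#' @param counts A `confusion_counts` list.
#' @return List with `sensitivity`, `specificity`, `precision`, `accuracy`.
#' @export
performance_metrics <- function(counts) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, list(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    precision = ratio(tp, tp + fp),
    accuracy = ratio(tp + tn, tp + fp + fn + tn)
  ))
}

#' Reason-level screening metrics
#'
#' `excluded_with_reason_rate`: among citations whose overall exclusion
#' probability met the threshold (stage-1 excludes), the fraction that also
#' received a qualifying reason. `correct_reason_rate`: among auto-excluded
#' citations that are truly excludes, the fraction whose reviewer-recorded
#' reason had a pairwise exclusion probability at or above the threshold.
#' `strict_match_rate`: same denominator, but requiring the assigned reason
#' to equal the reviewer reason. Empty denominators yield `NA`.
#'
#' @param decisions Decision tibble from [screen()].
#' @param citations Citation tibble holding the truth labels and reasons.
#' @param threshold Probability threshold; defaults to the one the
#'   decisions were made with.
#' @return List with the three rates.
#' @export
reason_metrics <- function(decisions, citations, threshold = attr(decisions, "threshold")) {
  if (is.null(threshold)) fail("threshold missing: supply it or use decisions from screen()")
  m <- match(decisions$citation_id, citations$id)
  if (anyNA(m)) fail("decision(s) for unknown citation id(s)")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den

  gate <- decisions$overall_prob >= threshold
  excluded <- decisions$outcome == "exclude"
  ewr <- ratio(sum(excluded), sum(gate))

  truly_exc <- !truth_include(citations)[m]
  sel <- which(excluded & truly_exc)
  if (length(sel) == 0) {
    return(list(excluded_with_reason_rate = ewr,
                correct_reason_rate = NA_real_,
                strict_match_rate = NA_real_))
  }
  true_r <- truth_reason(citations)[m][sel]
  prob_of_true <- vapply(seq_along(sel), function(k) {
    col <- paste0("reason_prob_", true_r[k])
    if (is.na(true_r[k]) || !col %in% names(decisions)) return(NA_real_)
    decisions[[col]][sel[k]]
  }, numeric(1))
  list(
    excluded_with_reason_rate = ewr,
    correct_reason_rate = ratio(sum(!is.na(prob_of_true) & prob_of_true >= threshold),
                                length(sel)),
    strict_match_rate = ratio(sum(decisions$reason[sel] == true_r, na.rm = TRUE),
                              length(sel))
  )
}

#' Enumerate the factorial scenario grid
#'
#' Full cross product of datasets, decision schemes, downsampling,
#' feature settings (four frequency thresholds plus three importance cuts)
#' and algorithm/metric combinations, with the invalid cells removed:
#' importance filtering never pairs with SVM, and bagged CART takes no
#' tuning metric. With five datasets and the full grid this yields 870
#' scenarios (420 naive Bayes, 240 SVM, 210 bagged CART).
#'
#' @param dataset_tags Character vector of dataset names.
#' @param schemes Decision schemes to cross.
#' @param downsampling Logical levels to cross.
#' @param frequency_thresholds Minimum-frequency feature settings.
#' @param importance_cuts Top-k importance feature settings.
#' @param algorithms Algorithms to cross.
#' @param metrics Tuning metrics for SVM and naive Bayes.
#' @return Tibble of scenario configurations in deterministic order.
#' @export
enumerate_scenarios <- function(dataset_tags,
                                schemes = c("abstract", "full_text", "modified_full_text"),
                                downsampling = c(TRUE, FALSE),
                                frequency_thresholds = c(5, 10, 100, 500),
                                importance_cuts = c(50, 100, 500),
                                algorithms = c("svm", "naive_bayes", "bagged_cart"),
                                metrics = c("roc", "sensitivity")) {
  if (length(dataset_tags) == 0) {
    return(tibble::tibble(dataset_tag = character(), scheme = character(),
                          downsample = logical(), feature_mode = character(),
                          feature_value = numeric(), algorithm = character(),
                          metric = character()))
  }
  features_all <- rbind(
    data.frame(feature_mode = rep("min_frequency", length(frequency_thresholds)),
               feature_value = as.numeric(frequency_thresholds)),
    data.frame(feature_mode = rep("importance", length(importance_cuts)),
               feature_value = as.numeric(importance_cuts))
  )
  rows <- list()
  for (tag in dataset_tags) for (sch in schemes) for (ds in downsampling) {
    for (alg in algorithms) {
      feats <- if (alg == "svm") {
        features_all[features_all$feature_mode == "min_frequency", , drop = FALSE]
      } else features_all
      mets <- if (alg == "bagged_cart") NA_character_ else metrics
      for (f in seq_len(nrow(feats))) for (met in mets) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          dataset_tag = tag, scheme = sch, downsample = ds,
          feature_mode = feats$feature_mode[f], feature_value = feats$feature_value[f],
          algorithm = alg, metric = met
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Run a batch of screening scenarios
#'
#' For each configuration: derive labels under its scheme, split 75/25
#' (stratified), fit the cascade (feature filtering computed across both
#' splits), screen the test set, and record the performance and reason
#' metrics. Per-configuration seeds are derived deterministically from the
#' master seed; a failing configuration is recorded with its diagnostic and
#' the batch continues.
#'
#' @param corpora Named list of citation tibbles, keyed by `dataset_tag`.
#' @param configs Scenario tibble from [enumerate_scenarios()].
#' @param master_seed Master seed.
#' @param train_fraction Training proportion for the split.
#' @param threshold Exclusion-probability threshold.
#' @param folds CV folds.
#' @return `configs` with appended metric columns, `error` and `elapsed`
#'   (seconds).
#' @export
run_scenarios <- function(corpora, configs, master_seed = 1,
                          train_fraction = 0.75, threshold = 0.90, folds = 10) {
  out <- configs
  metric_cols <- c("sensitivity", "specificity", "precision", "accuracy",
                   "excluded_with_reason_rate", "correct_reason_rate")
  for (col in metric_cols) out[[col]] <- NA_real_
  out$error <- NA_character_
  out$elapsed <- NA_real_
  for (i in seq_len(nrow(configs))) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      row <- configs[i, ]
      cit <- corpora[[row$dataset_tag]]
      if (is.null(cit)) fail("no corpus supplied for dataset '%s'", row$dataset_tag)
      seed_i <- derive_seed(master_seed, i)
      # the split is held constant across scenarios of one dataset
      split_seed <- derive_seed(master_seed, 10000 + match(row$dataset_tag, names(corpora)))
      ld <- derive_labels(cit, row$scheme)
      sp <- stratified_split(ld, train_fraction, seed = split_seed)
      feat <- if (row$feature_mode == "min_frequency") {
        feature_config("min_frequency", min_frequency = row$feature_value)
      } else {
        feature_config("importance", importance_k = row$feature_value)
      }
      cfg <- screening_config(
        scheme = row$scheme, feature = feat,
        algorithm = algorithm_spec(row$algorithm),
        metric = if (is.na(row$metric)) NULL else row$metric,
        downsample = row$downsample, threshold = threshold,
        folds = folds, seed = seed_i
      )
      model <- fit_screening_model(sp$train, cfg, screening = sp$test)
      dec <- screen(model, sp$test)
      pm <- performance_metrics(confusion_counts(dec, sp$test$citations))
      rm_ <- reason_metrics(dec, sp$test$citations)
      c(pm, rm_[c("excluded_with_reason_rate", "correct_reason_rate")])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
    } else {
      for (col in metric_cols) out[[col]][i] <- res[[col]]
    }
    out$elapsed[i] <- proc.time()[["elapsed"]] - t0
  }
  out
}

#' Paired comparison of one factor across matched scenarios
#'
#' Pairs scenario results that are identical in every configuration field
#' except the tested factor, then applies a two-sided paired t-test to the
#' response differences (level_a minus level_b). Results lacking a partner
#' (or with a failed run in the pair) are dropped and counted.
#'
#' @param results Result tibble from [run_scenarios()].
#' @param factor Name of the configuration column to test.
#' @param level_a,level_b The two levels to compare.
#' @param response `"sensitivity"` or `"specificity"`.
#' @return A `paired_test_result` list: `factor`, `level_a`, `level_b`,
#'   `n_pairs`, `n_dropped`, `mean_difference`, `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `degenerate`.
#' @export
paired_factor_test <- function(results, factor, level_a, level_b,
                               response = c("sensitivity", "specificity")) {
  response <- match.arg(response)
  config_cols <- intersect(c("dataset_tag", "scheme", "downsample",
                             "feature_mode", "feature_value", "algorithm", "metric"),
                           names(results))
  if (!factor %in% config_cols) fail("unknown factor: %s", factor)
  key_cols <- setdiff(config_cols, factor)
  a <- results[!is.na(results[[factor]]) & results[[factor]] == level_a, , drop = FALSE]
  b <- results[!is.na(results[[factor]]) & results[[factor]] == level_b, , drop = FALSE]
  merged <- dplyr::inner_join(
    a[, c(key_cols, response)], b[, c(key_cols, response)],
    by = key_cols, suffix = c("_a", "_b")
  )
  da <- merged[[paste0(response, "_a")]]
  db <- merged[[paste0(response, "_b")]]
  ok <- !is.na(da) & !is.na(db)
  n_dropped <- (nrow(a) - sum(ok)) + (nrow(b) - sum(ok))
  d <- da[ok] - db[ok]
  n <- length(d)
  if (n < 2) fail("fewer than 2 matched pairs for factor '%s'", factor)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(structure(list(factor = factor, level_a = level_a, level_b = level_b,
                          n_pairs = n, n_dropped = n_dropped, mean_difference = m,
                          t_statistic = NA_real_, degrees_of_freedom = n - 1,
                          p_value = NA_real_, degenerate = TRUE),
                     class = "paired_test_result"))
  }
  tt <- stats::t.test(d, alternative = "two.sided")
  structure(list(factor = factor, level_a = level_a, level_b = level_b,
                 n_pairs = n, n_dropped = n_dropped, mean_difference = m,
                 t_statistic = unname(tt$statistic),
                 degrees_of_freedom = unname(tt$parameter),
                 p_value = tt$p.value, degenerate = FALSE),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<paired_test_result> %s: %s vs %s | n = %d pairs | mean diff = %.4f | t(%d) = %s | p = %s%s\n",
              x$factor, x$level_a, x$level_b, x$n_pairs, x$mean_difference,
              x$degrees_of_freedom,
              if (is.na(x$t_statistic)) "NA" else sprintf("%.3f", x$t_statistic),
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3),
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}
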