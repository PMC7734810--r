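#' Configuration for a screening cascade
#'
#' Bundles every choice that defines one screening model: the label scheme,
#' the feature filter, the algorithm and tuning grid, the tuning metric,
#' whether to downsample, the exclusion-probability threshold (default
#' 0.90), the number of CV folds (default 10) and the master seed.
#'
#' @param scheme Label scheme (see [derive_labels()]).
#' @param feature A [feature_config()].
#' @param algorithm An [algorithm_spec()].
#' @param metric `"roc"`, `"sensitivity"`, or `NULL` (bagged CART only).
#' @param downsample Balance classes 1:1 before tuning?
#' @param threshold Probability of exclusion required to act, in (0, 1).
#' @param folds CV folds.
#' @param seed Master seed; per-model seeds are derived from it.
#' @param include_title Prepend the title to the abstract text before
#'   tokenization? Default `FALSE` (abstract only).
#' @return A `screening_config` list.
#' @export
screening_config <- function(scheme = c("abstract", "full_text", "modified_full_text"),
                             feature = feature_config(),
                             algorithm = algorithm_spec("svm"),
                             metric = "roc",
                             downsample = TRUE,
                             threshold = 0.90,
                             folds = 10,
                             seed = 1,
                             include_title = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(feature, "feature_config"), inherits(algorithm, "algorithm_spec"))
  if (!(threshold > 0 && threshold < 1)) fail("threshold must be in (0, 1)")
  if (algorithm$name == "svm" && feature$mode == "importance") {
    fail("importance-based feature filtering is not applicable to the SVM algorithm")
  }
  if (algorithm$name == "bagged_cart" && !is.null(metric)) {
    fail("a tuning metric is not applicable to the bagged CART algorithm")
  }
  structure(list(scheme = scheme, feature = feature, algorithm = algorithm,
                 metric = metric, downsample = isTRUE(downsample),
                 threshold = threshold, folds = folds, seed = as.integer(seed),
                 include_title = isTRUE(include_title)),
            class = "screening_config")
}

citation_text <- function(citations, include_title = FALSE) {
  if (include_title) {
    trimws(paste(citations$title, citations$abstract))
  } else {
    citations$abstract
  }
}

#' Fit the two-stage screening cascade
#'
#' Runs the shared feature pipeline (tokenization, document-term matrix,
#' frequency or importance filter, zero-variance removal against the
#' screening set when one is supplied), then trains the overall
#' include/exclude classifier and one pairwise include-versus-reason
#' classifier per exclusion reason present in the training labels, each on
#' the subset of includes plus excludes with that reason, each tuned by
#' stratified cross-validation and (optionally) class-balanced by
#' downsampling.
#'
#' @param train A `labelled_dataset` with at least one include and one
#'   exclude.
#' @param config A [screening_config()].
#' @param screening Optional: the citations to be screened later (a
#'   `labelled_dataset` or citation tibble). When given, corpus-wide term
#'   frequencies and the zero-variance rule are computed across both sets,
#'   as the screening set's text is available before any decision is made.
#' @return A `screening_model`.
#' @export
fit_screening_model <- function(train, config, screening = NULL) {
  stopifnot(inherits(train, "labelled_dataset"), inherits(config, "screening_config"))
  overall <- ifelse(train$label == "include", "include", "exclude")
  if (sum(overall == "include") < 1 || sum(overall == "exclude") < 1) {
    fail("training data must contain at least one include and one exclude")
  }

  toks <- preprocess_corpus(citation_text(train$citations, config$include_title))
  dtm_tr <- build_dtm(toks, train$citations$id)
  dtm_scr <- NULL
  if (!is.null(screening)) {
    scr_cit <- if (inherits(screening, "labelled_dataset")) screening$citations else screening
    dtm_scr <- build_dtm(preprocess_corpus(citation_text(scr_cit, config$include_title)),
                         scr_cit$id)
  }

  if (config$feature$mode == "min_frequency") {
    if (!is.null(dtm_scr)) {
      vocab <- sort(union(colnames(dtm_tr), colnames(dtm_scr)))
      totals <- Matrix::colSums(align_dtm(dtm_tr, vocab)) +
        Matrix::colSums(align_dtm(dtm_scr, vocab))
      keep <- vocab[totals >= config$feature$min_frequency]
      dtm_tr <- align_dtm(dtm_tr, keep)
      dtm_scr <- align_dtm(dtm_scr, keep)
    } else {
      dtm_tr <- filter_min_frequency(dtm_tr, config$feature$min_frequency)
    }
  } else {
    dtm_tr <- top_importance(dtm_tr, overall, config$algorithm$name,
                             k = config$feature$importance_k,
                             bags = config$algorithm$cart_bags,
                             seed = derive_seed(config$seed, 99))
    if (!is.null(dtm_scr)) dtm_scr <- align_dtm(dtm_scr, colnames(dtm_tr))
  }

  if (!is.null(dtm_scr)) {
    zv <- remove_zero_variance(dtm_tr, dtm_scr)
    dtm_tr <- zv$train
  } else {
    dtm_tr <- dtm_tr[, !constant_columns(dtm_tr), drop = FALSE]
  }

  train_classifier <- function(x, y, seed) {
    if (config$downsample) {
      ds <- downsample(x, y, seed = derive_seed(seed, 1))
      x <- ds$features; y <- ds$labels
    }
    tune_and_train(x, y, config$algorithm, metric = config$metric,
                   folds = config$folds, seed = derive_seed(seed, 2))
  }

  overall_model <- train_classifier(dtm_tr, overall, derive_seed(config$seed, 0))

  reasons <- intersect(exclusion_reasons(), unique(train$label_reason[overall == "exclude"]))
  reason_models <- list()
  reason_subset_sizes <- integer()
  for (i in seq_along(reasons)) {
    r <- reasons[i]
    rows <- which(overall == "include" | (overall == "exclude" & train$label_reason == r))
    y <- ifelse(overall[rows] == "include", "include", "exclude")
    reason_subset_sizes[[r]] <- length(rows)
    reason_models[[r]] <- train_classifier(dtm_tr[rows, , drop = FALSE], y,
                                           derive_seed(config$seed, 10 + i))
  }

  structure(list(
    overall = overall_model,
    reason_models = reason_models,
    reason_subset_sizes = reason_subset_sizes,
    threshold = config$threshold,
    vocabulary = colnames(dtm_tr),
    config = config,
    degenerate = length(reason_models) == 0
  ), class = "screening_model")
}

#' @export
print.screening_model <- function(x, ...) {
  cat(sprintf("<screening_model> %s/%s | threshold %.2f | %d terms | reason models: %s\n",
              x$config$algorithm$name, x$config$scheme, x$threshold,
              length(x$vocabulary),
              if (x$degenerate) "none (overall-only)" else
                paste(names(x$reason_models), collapse = ", ")))
  invisible(x)
}

# Resolve overall and per-reason exclusion probabilities into decisions.
# reason_probs: n x R matrix with reason-named columns (R may be 0).
decide_outcomes <- function(overall_prob, reason_probs, threshold) {
  n <- length(overall_prob)
  outcome <- rep("include", n)
  reason <- rep(NA_character_, n)
  gate <- overall_prob >= threshold  # boundary inclusive
  outcome[gate] <- "unclassified"
  if (!is.null(reason_probs) && ncol(reason_probs) > 0) {
    ord <- order(match(colnames(reason_probs), exclusion_reasons()))
    rp <- reason_probs[, ord, drop = FALSE]
    for (i in which(gate)) {
      qual <- which(rp[i, ] >= threshold)
      if (length(qual) > 0) {
        outcome[i] <- "exclude"
        reason[i] <- colnames(rp)[qual[1]]  # highest-priority qualifying reason
      }
    }
  }
  list(outcome = outcome, reason = reason)
}

screen_features <- function(model, dtm) {
  overall_prob <- predict_exclusion_prob(model$overall, dtm)
  reason_probs <- NULL
  if (length(model$reason_models) > 0) {
    reason_probs <- vapply(model$reason_models, function(m) {
      predict_exclusion_prob(m, dtm)
    }, numeric(nrow(dtm)))
    reason_probs <- matrix(reason_probs, nrow = nrow(dtm),
                           dimnames = list(rownames(dtm), names(model$reason_models)))
  }
  dec <- decide_outcomes(unname(overall_prob), reason_probs, model$threshold)
  out <- tibble::tibble(
    citation_id = rownames(dtm),
    outcome = dec$outcome,
    reason = dec$reason,
    overall_prob = unname(overall_prob)
  )
  if (!is.null(reason_probs)) {
    for (r in colnames(reason_probs)) {
      out[[paste0("reason_prob_", r)]] <- unname(reason_probs[, r])
    }
  }
  attr(out, "threshold") <- model$threshold
  out
}

#' Screen a set of citations
#'
#' Applies the fitted cascade to every citation: below the overall exclusion
#' threshold the outcome is `include`; at or above it, the pairwise reason
#' models are consulted and the citation is excluded with the
#' highest-priority reason whose probability also meets the threshold, or
#' left `unclassified` (for a human) when none qualifies.
#'
#' @param model A `screening_model`.
#' @param citations A `labelled_dataset` or citation tibble.
#' @return Tibble of decisions (`citation_id`, `outcome`, `reason`,
#'   `overall_prob`, one `reason_prob_*` column per fitted reason model), in
#'   input order, with the threshold as an attribute.
#' @export
screen <- function(model, citations) {
  stopifnot(inherits(model, "screening_model"))
  cit <- if (inherits(citations, "labelled_dataset")) citations$citations else citations
  toks <- preprocess_corpus(citation_text(cit, model$config$include_title))
  dtm <- build_dtm(toks, cit$id)
  screen_features(model, align_dtm(dtm, model$vocabulary))
}

#' Classify a single citation's features
#'
#' @param model A `screening_model`.
#' @param features One-row feature matrix with term colnames.
#' @return One-row decision tibble (see [screen()]).
#' @export
classify <- function(model, features) {
  stopifnot(inherits(model, "screening_model"))
  if (is.null(dim(features))) fail("features must be a one-row matrix with term colnames")
  screen_features(model, align_dtm(features, model$vocabulary))
}

#' Pick the ROC-optimal probability threshold
#'
#' Returns the threshold of the ROC point closest (Euclidean distance) to
#' the upper-left corner (0, 1); ties break toward the higher threshold.
#'
#' @param roc_points Data frame with columns `fpr`, `tpr`, `threshold`.
#' @return The selected threshold.
#' @export
select_threshold <- function(roc_points) {
  if (is.null(roc_points) || nrow(roc_points) == 0) fail("empty ROC point set")
  stopifnot(all(c("fpr", "tpr", "threshold") %in% names(roc_points)))
  if (any(roc_points$fpr < 0 | roc_points$fpr > 1 | roc_points$tpr < 0 | roc_points$tpr > 1)) {
    fail("ROC rates must lie in [0, 1]")
  }
  d <- sqrt(roc_points$fpr^2 + (1 - roc_points$tpr)^2)
  cand <- which(d == min(d))
  roc_points$threshold[cand[which.max(roc_points$threshold[cand])]]
}

#' Export screening decisions as CSV
#'
#' @param decisions Decision tibble from [screen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  out <- decisions
  out$reason[is.na(out$reason)] <- ""
  readr::write_csv(out, path, na = "", quote = "all", progress = FALSE)
  invisible(path)
}
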