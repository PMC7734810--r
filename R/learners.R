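#' Classification algorithm specification and tuning grid
#'
#' Names one of the three classification algorithms together with its
#' candidate tuning grid: SVM cost (0.25, 1, 2, 8, 32, 256; linear kernel),
#' naive Bayes distribution type (kernel / no kernel) crossed with Laplace
#' correction (0, 0.5, 1), or bagged CART with a fixed number of bootstrap
#' bags (25; no tuned parameter).
#'
#' @param name `"svm"`, `"naive_bayes"` or `"bagged_cart"`.
#' @param svm_costs Candidate SVM cost values.
#' @param nb_kernel Candidate distribution types, subset of `c("yes", "no")`.
#' @param nb_laplace Candidate Laplace corrections.
#' @param cart_bags Number of bootstrap bags for bagged CART.
#' @return An `algorithm_spec` list.
#' @export
algorithm_spec <- function(name = c("svm", "naive_bayes", "bagged_cart"),
                           svm_costs = c(0.25, 1, 2, 8, 32, 256),
                           nb_kernel = c("yes", "no"),
                           nb_laplace = c(0, 0.5, 1),
                           cart_bags = 25L) {
  name <- match.arg(name)
  if (name == "svm" && length(svm_costs) == 0) fail("svm grid must be non-empty")
  if (name == "naive_bayes" && (length(nb_kernel) == 0 || length(nb_laplace) == 0)) {
    fail("naive Bayes grid must be non-empty")
  }
  stopifnot(all(nb_kernel %in% c("yes", "no")))
  structure(list(name = name, svm_costs = svm_costs, nb_kernel = nb_kernel,
                 nb_laplace = nb_laplace, cart_bags = as.integer(cart_bags)),
            class = "algorithm_spec")
}

# Candidate grid in declared order (ties in CV break toward the first row).
param_grid <- function(spec) {
  switch(spec$name,
    svm = tibble::tibble(cost = spec$svm_costs),
    naive_bayes = tibble::tibble(
      kernel = rep(spec$nb_kernel, each = length(spec$nb_laplace)),
      laplace = rep(spec$nb_laplace, times = length(spec$nb_kernel))
    ),
    bagged_cart = tibble::tibble(bags = spec$cart_bags)
  )
}

#' Balance classes by downsampling the excludes
#'
#' Retains every include and a seeded uniform random subset (without
#' replacement) of the excludes of equal size, producing an exact 1:1 class
#' ratio. When the include class is the larger one (possible inside pairwise
#' reason subsets) the roles are swapped so that the minority class is kept
#' whole.
#'
#' @param features Feature matrix (rows = citations).
#' @param labels `"include"`/`"exclude"` per row.
#' @param seed Integer seed.
#' @return List with `features`, `labels` and the retained row `index`.
#' @export
downsample <- function(features, labels, seed = 1) {
  labels <- as.character(labels)
  inc <- which(labels == "include")
  exc <- which(labels == "exclude")
  if (length(inc) == 0) fail("cannot downsample: no includes in training labels")
  if (length(exc) == 0) fail("cannot downsample: no excludes in training labels")
  if (length(inc) <= length(exc)) {
    keep_all <- inc; pool <- exc
  } else {
    keep_all <- exc; pool <- inc
  }
  sampled <- with_seed(seed, sample(pool, length(keep_all)))
  idx <- sort(c(keep_all, sampled))
  list(features = features[idx, , drop = FALSE], labels = labels[idx], index = idx)
}

# Stratified fold assignment; every fold receives both classes.
stratified_folds <- function(y, k) {
  tab <- table(y)
  if (any(tab < k)) {
    fail("each class needs at least %d observations for %d-fold CV; use more data or fewer folds",
         k, k)
  }
  fold <- integer(length(y))
  for (cls in names(tab)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_one <- function(spec, params, x, y) {
  y <- factor(as.character(y), levels = c("include", "exclude"))
  fit <- switch(spec$name,
    svm = e1071::svm(x = as.matrix(x), y = y, kernel = "linear",
                     cost = params$cost, probability = TRUE, scale = FALSE),
    naive_bayes = nb_fit(x, y, kernel = params$kernel == "yes",
                         laplace = params$laplace),
    bagged_cart = cart_bag_fit(x, y, bags = params$bags)
  )
  list(algorithm = spec$name, fit = fit)
}

predict_prob_one <- function(fitted, x) {
  switch(fitted$algorithm,
    svm = {
      pr <- attr(predict(fitted$fit, as.matrix(x), probability = TRUE),
                 "probabilities")
      unname(pr[, "exclude"])
    },
    naive_bayes = unname(nb_predict(fitted$fit, x)),
    bagged_cart = cart_bag_predict(fitted$fit, x)
  )
}

cart_bag_fit <- function(x, y, bags = 25) {
  x <- as.data.frame(as.matrix(x))
  safe <- paste0("v", seq_len(ncol(x)))
  vocab <- names(x)
  names(x) <- safe
  x$.cls <- y
  n <- nrow(x)
  fits <- lapply(seq_len(bags), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    rpart::rpart(.cls ~ ., data = x[idx, , drop = FALSE], method = "class",
                 control = rpart::rpart.control(cp = 0, minsplit = 4,
                                                xval = 0, maxsurrogate = 0))
  })
  structure(list(fits = fits, safe = safe, vocabulary = vocab),
            class = "picoscreen_bag")
}

# Probability of exclusion = fraction of bags voting exclude.
cart_bag_predict <- function(fit, x) {
  x <- as.data.frame(as.matrix(x))
  names(x) <- fit$safe
  votes <- vapply(fit$fits, function(f) {
    as.character(predict(f, x, type = "class")) == "exclude"
  }, logical(nrow(x)))
  rowMeans(matrix(votes, nrow = nrow(x)))
}

#' Tune and train a classifier by stratified cross-validation
#'
#' Evaluates every point of the algorithm's tuning grid by stratified k-fold
#' cross-validation (folds randomized per call from `seed`) on the chosen
#' metric — `"roc"` is the fold-mean area under the ROC curve, and
#' `"sensitivity"` the fold-mean include-class sensitivity at the 0.5
#' posterior cut — then refits the arg-max grid point on all data. Ties
#' break toward the earlier grid point in declared order. Bagged CART has no
#' tuned parameter, so no metric may be supplied for it (its recorded CV
#' score is the fold-mean AUC).
#'
#' @param features Feature matrix with term colnames (rows = citations).
#' @param labels `"include"`/`"exclude"` per row.
#' @param spec An [algorithm_spec()].
#' @param metric `"roc"` or `"sensitivity"`; must be `NULL` for bagged CART.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for fold assignment and stochastic fits.
#' @return A `screen_classifier` with the selected parameters, CV score and
#'   vocabulary binding.
#' @export
tune_and_train <- function(features, labels, spec, metric = NULL,
                           folds = 10, seed = 1) {
  stopifnot(inherits(spec, "algorithm_spec"))
  if (nrow(features) != length(labels)) fail("features and labels are not aligned")
  if (folds < 2) fail("folds must be >= 2")
  if (spec$name == "bagged_cart" && !is.null(metric)) {
    fail("a tuning metric is not applicable to the bagged CART algorithm")
  }
  if (spec$name != "bagged_cart") {
    if (is.null(metric)) fail("a tuning metric ('roc' or 'sensitivity') is required for %s", spec$name)
    metric <- match.arg(metric, c("roc", "sensitivity"))
  }
  eval_metric <- metric %||% "roc"
  y <- factor(as.character(labels), levels = c("include", "exclude"))
  grid <- param_grid(spec)

  with_seed(seed, {
    fold_id <- stratified_folds(y, folds)
    scores <- vapply(seq_len(nrow(grid)), function(g) {
      fold_scores <- vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        fitted <- fit_one(spec, grid[g, ], features[tr, , drop = FALSE], y[tr])
        prob <- predict_prob_one(fitted, features[!tr, , drop = FALSE])
        score_fold(y[!tr], prob, eval_metric)
      }, numeric(1))
      mean(fold_scores)
    }, numeric(1))
    best <- which.max(scores)
    final <- fit_one(spec, grid[best, ], features, y)
    structure(list(
      algorithm = spec$name,
      selected_params = as.list(grid[best, ]),
      cv_score = scores[best],
      cv_metric = eval_metric,
      grid_scores = scores,
      vocabulary = colnames(features),
      n_train = nrow(features),
      fitted = final
    ), class = "screen_classifier")
  })
}

score_fold <- function(truth, prob_exclude, metric) {
  if (metric == "roc") {
    as.numeric(pROC::auc(pROC::roc(response = truth, predictor = prob_exclude,
                                   levels = c("include", "exclude"),
                                   direction = "<", quiet = TRUE)))
  } else {
    inc <- truth == "include"
    sum(prob_exclude[inc] < 0.5) / sum(inc)
  }
}

#' @export
print.screen_classifier <- function(x, ...) {
  cat(sprintf("<screen_classifier> %s | params: %s | CV %s = %.4f | %d terms\n",
              x$algorithm,
              paste(names(x$selected_params), unlist(x$selected_params),
                    sep = "=", collapse = ", "),
              x$cv_metric, x$cv_score, length(x$vocabulary)))
  invisible(x)
}

#' Predict the probability of exclusion
#'
#' Returns one exclusion probability in \[0, 1\] per row, with the include
#' probability being its complement. Input features are re-ordered and
#' zero-padded onto the model's vocabulary binding.
#'
#' @param model A `screen_classifier`.
#' @param features Feature matrix with term colnames.
#' @return Numeric vector of exclusion probabilities, input order preserved.
#' @export
predict_exclusion_prob <- function(model, features) {
  stopifnot(inherits(model, "screen_classifier"))
  x <- align_dtm(features, model$vocabulary)
  p <- predict_prob_one(model$fitted, x)
  names(p) <- rownames(features)
  p
}

MODEL_FORMAT <- "picoscreen_model"
MODEL_VERSION <- 1L

#' Serialize / restore a fitted model
#'
#' Writes a self-describing archive (versioned header, algorithm name,
#' selected parameters, vocabulary binding and fitted parameters).
#'
#' @param model A `screen_classifier` or `screening_model`.
#' @param path File path for the archive.
#' @return `path` invisibly (`write_model`); the model (`read_model`).
#' @export
write_model <- function(model, path) {
  saveRDS(list(format = MODEL_FORMAT, version = MODEL_VERSION,
               package_version = as.character(utils::packageVersion("picoscreen")),
               model = model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, MODEL_FORMAT)) fail("not a picoscreen model archive: %s", path)
  if (obj$version > MODEL_VERSION) fail("model archive version %d is newer than supported", obj$version)
  obj$model
}
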