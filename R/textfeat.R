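stopword_cache <- new.env(parent = emptyenv())

#' Pinned English stopword list
#'
#' The stopword list shipped with the package (a snowball-style core English
#' list). Pinned as a data file so tokenization is reproducible across
#' installations.
#'
#' @return Character vector of stopwords.
#' @export
en_stopwords <- function() {
  if (is.null(stopword_cache$words)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "picoscreen")
    stopword_cache$words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  }
  stopword_cache$words
}

#' Tokenize one text for bag-of-words features
#'
#' Lower-cases, splits on any character that is neither a letter nor a
#' digit, and drops pure-number tokens and stopwords. Alphanumeric tokens
#' containing at least one letter (e.g., `"her2"`) survive. Token order and
#' multiplicity are preserved.
#'
#' @param text Character scalar (may be empty or `NA`).
#' @param stopwords Stopword list; defaults to [en_stopwords()].
#' @return Character vector of tokens.
#' @export
#' @examples
#' preprocess_text("Efficacy of 80 mg in adults.")
preprocess_text <- function(text, stopwords = en_stopwords()) {
  if (is.na(text) || !nzchar(text)) return(character())
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- toks[!grepl("^[0-9]+$", toks)]
  toks[!(toks %in% stopwords)]
}

#' Tokenize a corpus
#'
#' @param texts Character vector of documents.
#' @param stopwords Stopword list.
#' @return List of token vectors, one per document.
#' @export
preprocess_corpus <- function(texts, stopwords = en_stopwords()) {
  lapply(texts, preprocess_text, stopwords = stopwords)
}

#' Build a document-term matrix
#'
#' Sparse citations-by-terms count matrix: entry (i, t) is the number of
#' occurrences of term t in document i. The vocabulary is the sorted union
#' of all tokens; the grand total of the matrix equals the total number of
#' tokens supplied.
#'
#' @param tokens List of token vectors, one per document.
#' @param row_ids Unique citation ids, one per document.
#' @return A `dgCMatrix` with `row_ids` as rownames and terms as colnames.
#' @export
build_dtm <- function(tokens, row_ids) {
  if (length(tokens) != length(row_ids)) {
    fail("one token list required per row id (%d vs %d)",
         length(tokens), length(row_ids))
  }
  if (anyDuplicated(row_ids)) fail("duplicate row ids in document-term matrix")
  all_tokens <- unlist(tokens, use.names = FALSE)
  vocab <- sort(unique(all_tokens))
  m <- Matrix::sparseMatrix(
    i = rep(seq_along(tokens), lengths(tokens)),
    j = match(all_tokens, vocab),
    x = 1,
    dims = c(length(tokens), length(vocab)),
    dimnames = list(as.character(row_ids), vocab)
  )
  methods::as(m, "CsparseMatrix")
}

#' Drop rare terms by corpus-wide frequency
#'
#' Removes every term whose total count across all documents is below
#' `min_count`; rows and surviving counts are unchanged.
#'
#' @param dtm Document-term matrix.
#' @param min_count Minimum corpus-wide count to retain a term (>= 1).
#' @return Filtered document-term matrix.
#' @export
filter_min_frequency <- function(dtm, min_count) {
  if (min_count < 1) fail("min_count must be >= 1")
  keep <- Matrix::colSums(dtm) >= min_count
  dtm[, keep, drop = FALSE]
}

# Zero-pad / reorder a DTM onto a target vocabulary.
align_dtm <- function(dtm, vocab) {
  if (is.null(colnames(dtm))) fail("feature matrix lacks term names; cannot align")
  common <- intersect(colnames(dtm), vocab)
  out <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(nrow(dtm), length(vocab)),
                              dimnames = list(rownames(dtm), vocab))
  out <- methods::as(out, "CsparseMatrix")
  if (length(common) > 0) out[, common] <- dtm[, common, drop = FALSE]
  out
}

# Columns constant across all rows (including all-zero columns).
constant_columns <- function(dtm) {
  n <- nrow(dtm)
  nz <- Matrix::colSums(dtm != 0)
  const <- nz == 0
  full <- which(nz == n)  # term present in every row: constant iff max == min
  if (length(full) > 0) {
    sub <- as.matrix(dtm[, full, drop = FALSE])
    const[full] <- apply(sub, 2, max) == apply(sub, 2, min)
  }
  const
}

#' Remove zero-variance predictors across a train/test pair
#'
#' Takes the union vocabulary of both matrices, then removes (from both)
#' every term that is constant across all training rows or that appears
#' exclusively in one of the two sets. The returned matrices share an
#' identical, identically ordered vocabulary.
#'
#' @param train_dtm,test_dtm Document-term matrices.
#' @return List with elements `train` and `test`.
#' @export
remove_zero_variance <- function(train_dtm, test_dtm) {
  if (nrow(train_dtm) == 0 || nrow(test_dtm) == 0) {
    fail("cannot remove zero-variance predictors from an empty matrix")
  }
  vocab <- sort(union(colnames(train_dtm), colnames(test_dtm)))
  tr <- align_dtm(train_dtm, vocab)
  te <- align_dtm(test_dtm, vocab)
  drop <- constant_columns(tr) |
    Matrix::colSums(tr) == 0 |
    Matrix::colSums(te) == 0
  list(train = tr[, !drop, drop = FALSE], test = te[, !drop, drop = FALSE])
}

#' Keep the top-k terms by algorithm-specific variable importance
#'
#' Ranks terms by the importance criterion of the named algorithm and keeps
#' the `min(k, vocabulary size)` highest-scoring ones, ties broken
#' lexicographically. Columns of the result are in rank order.
#'
#' Criteria: `naive_bayes` scores each term by the absolute difference of
#' its Laplace-smoothed class-conditional log-probabilities (multinomial
#' term model); `bagged_cart` aggregates rpart impurity-decrease importance
#' over bootstrap bags. Not applicable to the SVM algorithm.
#'
#' @param dtm Document-term matrix.
#' @param labels Character/factor vector (`"include"`/`"exclude"`) per row.
#' @param algorithm `"naive_bayes"` or `"bagged_cart"`.
#' @param k Number of terms to keep (>= 1).
#' @param bags Number of bootstrap bags for the CART criterion.
#' @param seed Seed for the bootstrap resampling.
#' @return Document-term matrix restricted to the top-k terms.
#' @export
top_importance <- function(dtm, labels, algorithm = c("naive_bayes", "bagged_cart", "svm"),
                           k, bags = 25, seed = 1) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "svm") {
    fail("variable-importance filtering is not applicable to the SVM algorithm")
  }
  if (k < 1) fail("k must be >= 1")
  p <- ncol(dtm)
  if (p == 0) return(dtm)
  score <- if (algorithm == "naive_bayes") {
    nb_term_importance(dtm, labels)
  } else {
    cart_term_importance(dtm, labels, bags = bags, seed = seed)
  }
  ord <- order(-score, colnames(dtm))
  keep <- ord[seq_len(min(k, p))]
  dtm[, keep, drop = FALSE]
}

# |log p(t | include) - log p(t | exclude)| under a Laplace-smoothed
# multinomial term model.
nb_term_importance <- function(dtm, labels) {
  labels <- as.character(labels)
  lp <- function(cls) {
    cnt <- Matrix::colSums(dtm[labels == cls, , drop = FALSE])
    log((cnt + 1) / (sum(cnt) + ncol(dtm)))
  }
  abs(lp("include") - lp("exclude"))
}

cart_term_importance <- function(dtm, labels, bags = 25, seed = 1) {
  x <- as.data.frame(as.matrix(dtm))
  safe <- paste0("v", seq_len(ncol(x)))
  names(x) <- safe
  x$.cls <- factor(as.character(labels), levels = c("include", "exclude"))
  n <- nrow(x)
  imp <- stats::setNames(numeric(ncol(dtm)), safe)
  with_seed(seed, {
    for (b in seq_len(bags)) {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- rpart::rpart(.cls ~ ., data = x[idx, , drop = FALSE], method = "class",
                          control = rpart::rpart.control(cp = 0, minsplit = 4,
                                                         xval = 0, maxsurrogate = 0))
      vi <- fit$variable.importance
      if (!is.null(vi)) imp[names(vi)] <- imp[names(vi)] + vi
    }
  })
  unname(imp / bags)
}

#' Export / import a document-term matrix as MTX
#'
#' Writes `<prefix>.mtx` (sparse coordinate format) plus `<prefix>.terms.txt`
#' and `<prefix>.ids.txt`. `read_dtm()` restores the matrix exactly.
#'
#' @param dtm Document-term matrix.
#' @param prefix Path prefix for the three files.
#' @return `prefix`, invisibly (`write_dtm`); the matrix (`read_dtm`).
#' @export
write_dtm <- function(dtm, prefix) {
  Matrix::writeMM(dtm, paste0(prefix, ".mtx"))
  writeLines(colnames(dtm), paste0(prefix, ".terms.txt"))
  writeLines(rownames(dtm), paste0(prefix, ".ids.txt"))
  invisible(prefix)
}

#' @rdname write_dtm
#' @export
read_dtm <- function(prefix) {
  m <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  dimnames(m) <- list(readLines(paste0(prefix, ".ids.txt")),
                      readLines(paste0(prefix, ".terms.txt")))
  m
}

#' Feature-filter configuration
#'
#' One cell of the feature-generation factor: either a corpus-wide minimum
#' term frequency (5, 10, 100 or 500) or a top-k variable-importance cut
#' (50, 100 or 500; not applicable to the SVM algorithm).
#'
#' @param mode `"min_frequency"` or `"importance"`.
#' @param min_frequency Frequency threshold, one of 5, 10, 100, 500.
#' @param importance_k Importance cut, one of 50, 100, 500.
#' @return A `feature_config` list.
#' @export
feature_config <- function(mode = c("min_frequency", "importance"),
                           min_frequency = 5, importance_k = 50) {
  mode <- match.arg(mode)
  if (mode == "min_frequency") {
    if (!min_frequency %in% c(5, 10, 100, 500)) {
      fail("min_frequency must be one of 5, 10, 100, 500")
    }
    importance_k <- NULL
  } else {
    if (!importance_k %in% c(50, 100, 500)) {
      fail("importance_k must be one of 50, 100, 500")
    }
    min_frequency <- NULL
  }
  structure(list(mode = mode, min_frequency = min_frequency,
                 importance_k = importance_k), class = "feature_config")
}
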