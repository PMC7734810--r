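citation_columns <- function() {
  c("id", "title", "abstract", "abstract_decision", "abstract_reason",
    "fulltext_decision", "fulltext_reason", "dataset_tag")
}

#' Validate a citation table
#'
#' Checks the screening-record invariants: unique ids, decision vocabularies,
#' a reason on every exclude, and full-text decisions only for abstract
#' includes. Reasons are `NA` when absent.
#'
#' @param citations Tibble with the canonical citation columns.
#' @return The validated tibble, invisibly.
#' @export
validate_citations <- function(citations) {
  missing <- setdiff(citation_columns(), names(citations))
  if (length(missing) > 0) {
    fail("missing required column(s): %s", paste(missing, collapse = ", "))
  }
  if (nrow(citations) == 0) return(invisible(citations))
  if (anyDuplicated(citations$id)) {
    fail("citation ids must be unique; duplicated: %s",
         paste(head(unique(citations$id[duplicated(citations$id)]), 5), collapse = ", "))
  }
  bad <- !citations$abstract_decision %in% c("include", "exclude")
  if (any(bad)) fail("invalid abstract_decision for citation(s): %s",
                     paste(head(citations$id[bad], 5), collapse = ", "))
  bad <- !citations$fulltext_decision %in% c("include", "exclude", "not_screened")
  if (any(bad)) fail("invalid fulltext_decision for citation(s): %s",
                     paste(head(citations$id[bad], 5), collapse = ", "))
  assert_reason(citations$abstract_reason, allow_na = TRUE)
  assert_reason(citations$fulltext_reason, allow_na = TRUE)
  bad <- citations$abstract_decision == "exclude" & is.na(citations$abstract_reason)
  if (any(bad)) fail("abstract exclude without a reason for citation(s): %s",
                     paste(head(citations$id[bad], 5), collapse = ", "))
  bad <- citations$fulltext_decision == "exclude" & is.na(citations$fulltext_reason)
  if (any(bad)) fail("full-text exclude without a reason for citation(s): %s",
                     paste(head(citations$id[bad], 5), collapse = ", "))
  bad <- citations$fulltext_decision %in% c("include", "exclude") &
    citations$abstract_decision != "include"
  if (any(bad)) fail("full-text decision present for abstract exclude(s): %s",
                     paste(head(citations$id[bad], 5), collapse = ", "))
  invisible(citations)
}

#' Read a labelled citation corpus
#'
#' Reads screening records from the canonical CSV contract (columns
#' `id, title, abstract, abstract_decision, abstract_reason,
#' fulltext_decision, fulltext_reason, dataset_tag`; empty string encodes an
#' absent reason) or from a RIS file with a sidecar decision CSV keyed on
#' `id`. Row order is preserved and all invariants are validated.
#'
#' @param path Path to the citation file.
#' @param format `"csv"` (default) or `"ris"`.
#' @param decisions For `format = "ris"`, path to a CSV holding the decision
#'   columns (`id` plus the decision/reason/dataset_tag columns).
#' @return Tibble of citations, one row per record.
#' @export
read_citations <- function(path, format = c("csv", "ris"), decisions = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) fail("file not found: %s", path)
  if (format == "csv") {
    cit <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE)
    cit <- tibble::as_tibble(cit)
    missing <- setdiff(citation_columns(), names(cit))
    if (length(missing) > 0) {
      fail("missing required column(s): %s", paste(missing, collapse = ", "))
    }
    cit <- cit[, citation_columns()]
  } else {
    if (is.null(decisions)) fail("RIS import requires a sidecar decision CSV")
    recs <- parse_ris(path)
    dec <- readr::read_csv(decisions, col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE)
    if (!"id" %in% names(dec)) fail("missing required column(s): id")
    cit <- dplyr::left_join(recs, dec, by = "id")
    missing <- setdiff(citation_columns(), names(cit))
    if (length(missing) > 0) {
      fail("missing required column(s): %s", paste(missing, collapse = ", "))
    }
    cit <- cit[, citation_columns()]
  }
  for (col in c("abstract_reason", "fulltext_reason")) {
    cit[[col]][!nzchar(cit[[col]]) | is.na(cit[[col]])] <- NA_character_
  }
  for (col in c("title", "abstract", "dataset_tag")) {
    cit[[col]][is.na(cit[[col]])] <- ""
  }
  validate_citations(cit)
  cit
}

#' Write citations as canonical CSV
#'
#' Emits the canonical UTF-8, comma-delimited, all-fields-quoted CSV; absent
#' reasons are written as empty strings. `write_citations()` then
#' [read_citations()] is the identity, and the writer is idempotent byte
#' for byte.
#'
#' @param citations Citation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_citations <- function(citations, path) {
  validate_citations(citations)
  out <- citations[, citation_columns()]
  out$abstract_reason[is.na(out$abstract_reason)] <- ""
  out$fulltext_reason[is.na(out$fulltext_reason)] <- ""
  readr::write_csv(out, path, na = "", quote = "all", progress = FALSE)
  invisible(path)
}

# Minimal RIS reader: TY..ER records, TI -> title, AB -> abstract, ID -> id.
parse_ris <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  recs <- list()
  cur <- NULL
  n <- 0
  for (line in lines) {
    tag <- substr(line, 1, 2)
    val <- sub("^..\\s*-\\s*", "", line)
    if (tag == "TY") {
      cur <- list(id = NA_character_, title = "", abstract = "")
    } else if (tag == "ER") {
      n <- n + 1
      if (is.na(cur$id)) cur$id <- sprintf("ris_%04d", n)
      recs[[n]] <- cur
      cur <- NULL
    } else if (!is.null(cur)) {
      if (tag == "TI") cur$title <- val
      if (tag == "AB") cur$abstract <- val
      if (tag == "ID") cur$id <- val
    }
  }
  tibble::tibble(
    id = vapply(recs, `[[`, "", "id"),
    title = vapply(recs, `[[`, "", "title"),
    abstract = vapply(recs, `[[`, "", "abstract")
  )
}

#' Remove duplicated citations
#'
#' Two citations are duplicates when their normalized title + abstract key
#' (lower case, whitespace collapsed) coincides; the first occurrence in
#' input order is retained. Idempotent.
#'
#' @param citations Citation tibble.
#' @return Citation tibble with duplicates dropped, input order preserved.
#' @export
deduplicate <- function(citations) {
  if (nrow(citations) == 0) return(citations)
  key <- tolower(paste(citations$title, citations$abstract))
  key <- trimws(gsub("\\s+", " ", key))
  citations[!duplicated(key), , drop = FALSE]
}

new_labelled_dataset <- function(citations, label, label_reason, scheme) {
  structure(list(citations = citations, label = label,
                 label_reason = label_reason, scheme = scheme),
            class = "labelled_dataset")
}

#' @export
print.labelled_dataset <- function(x, ...) {
  cat(sprintf("<labelled_dataset> %d citations, scheme = %s (%d includes, %d excludes)\n",
              nrow(x$citations), x$scheme,
              sum(x$label == "include"), sum(x$label == "exclude")))
  invisible(x)
}

#' Number of citations in a labelled dataset
#' @param dataset A `labelled_dataset`.
#' @return Integer count.
#' @export
n_citations <- function(dataset) nrow(dataset$citations)

subset_labelled <- function(dataset, idx) {
  new_labelled_dataset(dataset$citations[idx, , drop = FALSE],
                       dataset$label[idx], dataset$label_reason[idx],
                       dataset$scheme)
}

#' Derive training labels under a decision scheme
#'
#' Builds one training label (include, or exclude with a reason) per
#' citation under one of three schemes:
#' * `abstract` — abstract-level decisions for everything;
#' * `full_text` — abstract excludes keep their abstract reason, abstract
#'   includes are relabelled by the full-text decision (full-text excludes
#'   take the full-text reason);
#' * `modified_full_text` — abstract-level decisions after removing
#'   citations included at abstract level but excluded at full text.
#'
#' @param citations Citation tibble satisfying [validate_citations()].
#' @param scheme One of `"abstract"`, `"full_text"`, `"modified_full_text"`.
#' @return A `labelled_dataset`.
#' @export
derive_labels <- function(citations, scheme = c("abstract", "full_text", "modified_full_text")) {
  scheme <- match.arg(scheme)
  validate_citations(citations)
  if (scheme != "abstract" &&
      !any(citations$fulltext_decision %in% c("include", "exclude"))) {
    fail("scheme '%s' requires full-text decisions, but none are present", scheme)
  }
  label <- citations$abstract_decision
  reason <- citations$abstract_reason
  if (scheme == "full_text") {
    idx <- which(citations$abstract_decision == "include")
    unscreened <- idx[citations$fulltext_decision[idx] == "not_screened"]
    if (length(unscreened) > 0) {
      fail("abstract include(s) lacking a full-text decision under full_text scheme: %s",
           paste(head(citations$id[unscreened], 5), collapse = ", "))
    }
    label[idx] <- citations$fulltext_decision[idx]
    reason[idx] <- citations$fulltext_reason[idx]
    return(new_labelled_dataset(citations, label, reason, scheme))
  }
  if (scheme == "modified_full_text") {
    drop <- citations$abstract_decision == "include" &
      citations$fulltext_decision == "exclude"
    keep <- which(!drop)
    return(new_labelled_dataset(citations[keep, , drop = FALSE],
                                label[keep], reason[keep], scheme))
  }
  new_labelled_dataset(citations, label, reason, scheme)
}

#' Recode one exclusion reason into another
#'
#' Replaces every occurrence of `from` by `to` in the training labels and in
#' the underlying citation reasons (e.g., folding short-follow-up `time`
#' excludes into `other`). Idempotent after the first application.
#'
#' @param dataset A `labelled_dataset` (or a citation tibble).
#' @param from,to Distinct reason names.
#' @return Object of the same type with reasons recoded.
#' @export
recode_reason <- function(dataset, from, to) {
  assert_reason(c(from, to))
  if (identical(from, to)) fail("`from` and `to` must differ")
  swap <- function(x) ifelse(!is.na(x) & x == from, to, x)
  if (inherits(dataset, "labelled_dataset")) {
    dataset$label_reason <- swap(dataset$label_reason)
    dataset$citations$abstract_reason <- swap(dataset$citations$abstract_reason)
    dataset$citations$fulltext_reason <- swap(dataset$citations$fulltext_reason)
    return(dataset)
  }
  dataset$abstract_reason <- swap(dataset$abstract_reason)
  dataset$fulltext_reason <- swap(dataset$fulltext_reason)
  dataset
}

#' Stratified train/test split
#'
#' Partitions a labelled dataset into training and test subsets by random
#' sampling within the include and exclude strata. Per stratum the training
#' count is `round_half_up(train_fraction * stratum size)`; the same seed
#' always reproduces the same partition, and reasons travel with their
#' citations.
#'
#' @param dataset A `labelled_dataset`.
#' @param train_fraction Proportion assigned to training, in (0, 1]; default
#'   0.75.
#' @param seed Integer seed controlling the partition.
#' @return List with elements `train` and `test`, both `labelled_dataset`s.
#' @export
stratified_split <- function(dataset, train_fraction = 0.75, seed = 1) {
  stopifnot(inherits(dataset, "labelled_dataset"))
  if (n_citations(dataset) == 0) fail("cannot split an empty dataset")
  if (!(train_fraction > 0 && train_fraction <= 1)) {
    fail("train_fraction must be in (0, 1]")
  }
  strata <- list(include = which(dataset$label == "include"),
                 exclude = which(dataset$label == "exclude"))
  train_idx <- with_seed(seed, {
    unlist(lapply(names(strata), function(s) {
      idx <- strata[[s]]
      if (length(idx) == 0) {
        if (train_fraction < 1) {
          warning(sprintf("stratum '%s' is empty; nothing to assign", s),
                  call. = FALSE)
        }
        return(integer())
      }
      n_tr <- round_half_up(train_fraction * length(idx))
      sample(idx)[seq_len(n_tr)]
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n_citations(dataset)), train_idx)
  list(train = subset_labelled(dataset, train_idx),
       test = subset_labelled(dataset, test_idx))
}

# Evaluation truth is always full-text-level inclusion.
truth_include <- function(citations) citations$fulltext_decision == "include"

# Reviewer reason for a truly excluded citation: the full-text reason when
# full-text screened, otherwise the abstract reason.
truth_reason <- function(citations) {
  ifelse(citations$fulltext_decision == "exclude",
         citations$fulltext_reason, citations$abstract_reason)
}
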