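# Ten-citation screening fixture: 3 abstract includes (1 retained at full
# text, 2 excluded there), 7 abstract excludes covering all seven reasons.
fixture_citations <- function() {
  tibble::tibble(
    id = sprintf("c%02d", 1:10),
    title = paste("Trial report", 1:10),
    abstract = c(
      "randomized adults psoriasis biologic therapy outcome improvement",
      "randomized children psoriasis biologic therapy growth",
      "randomized adults psoriasis biologic cost analysis",
      "narrative review skin disease treatments overview",
      "randomized infants eczema emollient trial",
      "randomized adults psoriasis phototherapy different drug",
      "randomized adults psoriasis placebo versus placebo",
      "randomized adults psoriasis quality metrics unrelated endpoints",
      "conference abstract psoriasis biologic early data",
      "randomized adults psoriasis biologic four week followup"
    ),
    abstract_decision = c("include", "include", "include", rep("exclude", 7)),
    abstract_reason = c(NA, NA, NA, "study_design", "population", "intervention",
                        "comparator", "outcomes", "other", "time"),
    fulltext_decision = c("include", "exclude", "exclude", rep("not_screened", 7)),
    fulltext_reason = c(NA, "population", "outcomes", rep(NA, 7)),
    dataset_tag = "fixture"
  )
}

# Linearly separable toy: two disjoint signature vocabularies.
toy_separable <- function(n_per_class = 20, seed = 42) {
  withr::with_seed(seed, {
    inc_words <- c("remission", "response", "efficacy", "benefit")
    exc_words <- c("protocol", "animal", "vitro", "murine")
    docs <- c(
      replicate(n_per_class, paste(sample(inc_words, 6, replace = TRUE), collapse = " ")),
      replicate(n_per_class, paste(sample(exc_words, 6, replace = TRUE), collapse = " "))
    )
    labels <- rep(c("include", "exclude"), each = n_per_class)
    dtm <- build_dtm(preprocess_corpus(docs), sprintf("d%03d", seq_along(docs)))
    list(dtm = dtm, labels = labels)
  })
}

# Scaled-down synthetic corpus spec used by the simulation-harness tests.
small_spec <- function(dataset_tag = "synthetic", n = 450, signature_strength = 0.35) {
  corpus_spec(
    dataset_tag = dataset_tag, n_citations = n,
    abstract_include_rate = 0.138, fulltext_retention_rate = 0.279,
    reason_distribution = c(study_design = 0.3, population = 0.3,
                            intervention = 0, comparator = 0,
                            outcomes = 0.25, other = 0.15, time = 0),
    background_vocab = 120, signature_vocab_per_class = 15,
    signature_strength = signature_strength, mean_abstract_length = 50
  )
}

# Labelled dataset built directly (abstract scheme) from decision vectors.
make_labelled <- function(n_include, n_exclude, reason = "study_design") {
  cit <- tibble::tibble(
    id = sprintf("s%05d", seq_len(n_include + n_exclude)),
    title = "",
    abstract = "text",
    abstract_decision = c(rep("include", n_include), rep("exclude", n_exclude)),
    abstract_reason = c(rep(NA_character_, n_include), rep(reason, n_exclude)),
    fulltext_decision = c(rep("include", n_include), rep("not_screened", n_exclude)),
    fulltext_reason = NA_character_,
    dataset_tag = "direct"
  )
  derive_labels(cit, "abstract")
}
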