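#' Profiles of the five reference screening datasets
#'
#' Published summary counts of the five systematic-review screening datasets
#' the synthetic generator emulates: abstracts screened, abstracts included
#' at abstract screening, and full texts included among those. The real
#' corpora are proprietary; only these counts are public, and
#' [default_specs()] derives its rates from them.
#'
#' @return Tibble with columns `dataset_tag`, `n_abstracts`,
#'   `n_abstract_includes`, `n_fulltext_includes`.
#' @export
slr_profiles <- function() {
  tibble::tibble(
    dataset_tag = c("psoriasis", "lung_cancer", "liver_cancer", "melanoma", "obesity"),
    n_abstracts = c(4442L, 12769L, 8507L, 3089L, 5187L),
    n_abstract_includes = c(613L, 215L, 1141L, 124L, 228L),
    n_fulltext_includes = c(171L, 66L, 294L, 41L, 47L)
  )
}

default_reason_distribution <- function() {
  c(study_design = 0.25, population = 0.25, intervention = 0.12,
    comparator = 0.08, outcomes = 0.12, other = 0.13, time = 0.05)
}

#' Specification for a synthetic citation corpus
#'
#' Defines the statistical shape of a generated corpus: its size, the
#' abstract-level inclusion rate, the full-text retention rate among
#' abstract includes, the distribution of exclusion reasons, and the text
#' model (shared background vocabulary plus a signature vocabulary per
#' class, mixed with probability `signature_strength`).
#'
#' @param dataset_tag Corpus name.
#' @param n_citations Number of citations.
#' @param abstract_include_rate Proportion included at abstract screening.
#' @param fulltext_retention_rate Proportion of abstract includes retained
#'   at full text.
#' @param reason_distribution Probability vector over the seven exclusion
#'   reasons (in [exclusion_reasons()] order, or named); must sum to 1.
#' @param background_vocab Number of shared background terms.
#' @param signature_vocab_per_class Signature terms per class (includes and
#'   each exclusion reason).
#' @param signature_strength Probability mass an abstract draws from its
#'   class signature vocabulary, in \[0, 1\].
#' @param mean_abstract_length Mean content-token count per abstract
#'   (Poisson).
#' @param overinclusion_blend For citations included at abstract level but
#'   excluded at full text: probability that a signature token comes from
#'   the include signature rather than the reason signature (models
#'   over-inclusive abstract screening).
#' @param seed Default seed for [generate_corpus()].
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(dataset_tag = "synthetic",
                        n_citations = 2000,
                        abstract_include_rate = 0.138,
                        fulltext_retention_rate = 0.279,
                        reason_distribution = default_reason_distribution(),
                        background_vocab = 250,
                        signature_vocab_per_class = 20,
                        signature_strength = 0.35,
                        mean_abstract_length = 80,
                        overinclusion_blend = 0.5,
                        seed = 1L) {
  if (length(reason_distribution) != length(exclusion_reasons())) {
    fail("reason_distribution must have one entry per exclusion reason (7)")
  }
  if (!is.null(names(reason_distribution))) {
    if (!setequal(names(reason_distribution), exclusion_reasons())) {
      fail("reason_distribution names must be the seven exclusion reasons")
    }
    reason_distribution <- reason_distribution[exclusion_reasons()]
  } else {
    names(reason_distribution) <- exclusion_reasons()
  }
  if (any(reason_distribution < 0) || abs(sum(reason_distribution) - 1) > 1e-9) {
    fail("reason_distribution must be non-negative and sum to 1 (within 1e-9)")
  }
  stopifnot(abstract_include_rate >= 0, abstract_include_rate <= 1,
            fulltext_retention_rate >= 0, fulltext_retention_rate <= 1,
            signature_strength >= 0, signature_strength <= 1,
            mean_abstract_length > 0)
  structure(list(dataset_tag = dataset_tag, n_citations = as.integer(n_citations),
                 abstract_include_rate = abstract_include_rate,
                 fulltext_retention_rate = fulltext_retention_rate,
                 reason_distribution = reason_distribution,
                 background_vocab = as.integer(background_vocab),
                 signature_vocab_per_class = as.integer(signature_vocab_per_class),
                 signature_strength = signature_strength,
                 mean_abstract_length = mean_abstract_length,
                 overinclusion_blend = overinclusion_blend,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Specifications emulating the five reference datasets
#'
#' Returns one [corpus_spec()] per reference dataset, with sizes and
#' inclusion/retention rates derived from the published counts in
#' [slr_profiles()]; text-model parameters take the package defaults.
#'
#' @param ... Overrides passed to every [corpus_spec()] call (e.g.,
#'   `signature_strength`).
#' @return Named list of five `corpus_spec` objects.
#' @export
default_specs <- function(...) {
  prof <- slr_profiles()
  specs <- lapply(seq_len(nrow(prof)), function(i) {
    corpus_spec(
      dataset_tag = prof$dataset_tag[i],
      n_citations = prof$n_abstracts[i],
      abstract_include_rate = prof$n_abstract_includes[i] / prof$n_abstracts[i],
      fulltext_retention_rate = prof$n_fulltext_includes[i] / prof$n_abstract_includes[i],
      ...
    )
  })
  stats::setNames(specs, prof$dataset_tag)
}

#' Generate a synthetic labelled citation corpus
#'
#' Draws a corpus with exactly `round_half_up(n * abstract_include_rate)`
#' abstract includes, of which exactly `round_half_up(includes *
#' fulltext_retention_rate)` are retained at full text (deterministic
#' counts, randomized assignment). Every exclude carries a reason drawn
#' from the reason distribution. Abstract text is a bag of tokens drawn
#' from the citation's class signature vocabulary with probability
#' `signature_strength` and from the shared background vocabulary
#' otherwise; citations included at abstract level but excluded at full
#' text blend the include and reason signatures. Fully reproducible from
#' the seed.
#'
#' @param spec A [corpus_spec()].
#' @param seed Seed; defaults to the spec's.
#' @return Citation tibble satisfying [validate_citations()].
#' @export
generate_corpus <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "corpus_spec"))
  n <- spec$n_citations
  if (n == 0) {
    return(tibble::tibble(id = character(), title = character(), abstract = character(),
                          abstract_decision = character(), abstract_reason = character(),
                          fulltext_decision = character(), fulltext_reason = character(),
                          dataset_tag = character()))
  }
  reasons <- exclusion_reasons()
  bg <- sprintf("background%04d", seq_len(spec$background_vocab))
  sig <- lapply(c("include", reasons), function(cls) {
    sprintf("sig%s%03d", gsub("_", "", cls), seq_len(spec$signature_vocab_per_class))
  })
  names(sig) <- c("include", reasons)

  with_seed(seed, {
    n_inc <- round_half_up(n * spec$abstract_include_rate)
    n_ft <- round_half_up(n_inc * spec$fulltext_retention_rate)
    abs_inc <- sample.int(n, n_inc)
    ft_inc <- if (n_inc > 0) abs_inc[sample.int(n_inc, n_ft)] else integer()

    abstract_decision <- rep("exclude", n)
    abstract_decision[abs_inc] <- "include"
    fulltext_decision <- rep("not_screened", n)
    fulltext_decision[abs_inc] <- "exclude"
    fulltext_decision[ft_inc] <- "include"

    draw_reason <- function(k) {
      if (k == 0) return(character())
      sample(reasons, k, replace = TRUE, prob = spec$reason_distribution)
    }
    abstract_reason <- rep(NA_character_, n)
    is_abs_exc <- abstract_decision == "exclude"
    abstract_reason[is_abs_exc] <- draw_reason(sum(is_abs_exc))
    fulltext_reason <- rep(NA_character_, n)
    is_ft_exc <- fulltext_decision == "exclude"
    fulltext_reason[is_ft_exc] <- draw_reason(sum(is_ft_exc))

    make_text <- function(i, len) {
      sig_mask <- stats::runif(len) < spec$signature_strength
      toks <- sample(bg, len, replace = TRUE)
      k <- sum(sig_mask)
      if (k > 0) {
        if (fulltext_decision[i] == "include") {
          pool <- sig[["include"]]
          toks[sig_mask] <- sample(pool, k, replace = TRUE)
        } else if (fulltext_decision[i] == "exclude") {
          # over-included: blend of include and reason signatures
          from_inc <- stats::runif(k) < spec$overinclusion_blend
          toks[sig_mask][from_inc] <- sample(sig[["include"]], sum(from_inc), replace = TRUE)
          toks[sig_mask][!from_inc] <- sample(sig[[fulltext_reason[i]]], sum(!from_inc),
                                              replace = TRUE)
        } else {
          toks[sig_mask] <- sample(sig[[abstract_reason[i]]], k, replace = TRUE)
        }
      }
      paste(toks, collapse = " ")
    }
    lens <- pmax(3L, stats::rpois(n, spec$mean_abstract_length))
    title_lens <- pmax(2L, stats::rpois(n, 6))
    abstracts <- vapply(seq_len(n), function(i) make_text(i, lens[i]), character(1))
    titles <- vapply(seq_len(n), function(i) make_text(i, title_lens[i]), character(1))

    cit <- tibble::tibble(
      id = sprintf("%s_%05d", spec$dataset_tag, seq_len(n)),
      title = titles,
      abstract = abstracts,
      abstract_decision = abstract_decision,
      abstract_reason = abstract_reason,
      fulltext_decision = fulltext_decision,
      fulltext_reason = fulltext_reason,
      dataset_tag = spec$dataset_tag
    )
    validate_citations(cit)
    cit
  })
}
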