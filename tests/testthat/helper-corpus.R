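# Corpora are expensive to label (every pair gets an optimized ST), so
# they are built once per test run and shared across test files.
.corpus_cache <- new.env(parent = emptyenv())

cached_corpus <- function(n_train, n_test, seed, ...) {
  key <- paste(n_train, n_test, seed, ..., sep = "|")
  if (is.null(.corpus_cache[[key]])) {
    .corpus_cache[[key]] <- build_corpus(
      corpus_spec(n_train_pairs = n_train, n_test_pairs = n_test,
                  seed = seed, ...))
  }
  .corpus_cache[[key]]
}

# The reference study corpus: 2,000 training pairs and 5,000 held-out
# pairs, 30% perturbation pairs at sigma = 0.05 A.
study_corpus <- function() cached_corpus(2000, 5000, seed = 101)

# A small corpus for unit-level checks.
small_corpus <- function() cached_corpus(120, 120, seed = 7)
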