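# Shared fixtures, built in code. The small fixture backs fast unit tests;
# the learnability fixture (memoised below) backs the slower model tests so
# it is generated and trained at most once per test run.

small_fixture <- function(seed = 7) {
  generate_fixture(synthetic_genome_config(
    n_chromosomes = 2, chromosome_length = 50000, n_transcripts = 20,
    motif = "TATAAAGGCC", motif_noise = 0.05, seed = seed))
}

small_dataset <- function(seed = 7, n_neg = 10) {
  fx <- small_fixture(seed)
  build_dataset(fx$assembly, fx$annotation, window_params(70, 30),
                n_negatives_per_positive = n_neg, seed = seed)
}

# Desk-scale study conditions for the learnability checks: 10 chromosomes,
# 100 transcripts, 10-mer consensus motif at 5% per-base noise, 43-base
# windows (upstream 30 / downstream 10 — short enough that recurrent models
# learn from tens of positives), 1:10 negatives. Train = chromosomes 1-6
# (~660 instances), validation = 9-10, test = 7-8.
learnability_params <- function() window_params(30, 10)

learnability_split <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- generate_fixture(synthetic_genome_config(
        n_chromosomes = 10, chromosome_length = 20000, n_transcripts = 100,
        motif = "TATAAAGGCC", motif_noise = 0.05, seed = 11))
      ds <- build_dataset(fx$assembly, fx$annotation, learnability_params(),
                          n_negatives_per_positive = 10, seed = 11)
      cache <<- split_by_chromosome(ds, validation_chromosomes = c("9", "10"),
                                    test_chromosomes = c("7", "8"))
    }
    cache
  }
})

# Second species: same planted motif, different genome/background (shared
# signal). Null control: motif_noise = 1 randomizes every planted base, so
# the species' TSS neighborhoods are indistinguishable from background — a
# fixed "different" motif would instead be an anti-motif for a positionally
# sharp model and push AUC systematically away from 0.5.
cross_species_dataset <- function(motif = "TATAAAGGCC", motif_noise = 0.05,
                                  seed = 23) {
  fx <- generate_fixture(synthetic_genome_config(
    n_chromosomes = 4, chromosome_length = 20000, n_transcripts = 50,
    motif = motif, motif_noise = motif_noise, seed = seed))
  build_dataset(fx$assembly, fx$annotation, learnability_params(),
                n_negatives_per_positive = 10, seed = seed)
}

# Trained LSTM on the learnability split, memoised across test files.
trained_lstm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      model <- build_architecture("lstm",
                                  input_length = learnability_params()$window_length)
      fit <- train_network(model, learnability_split(),
                           training_config(max_epochs = 60, patience = 10,
                                           seed = 3))
      cache <<- fit
    }
    cache
  }
})

# A deliberately cheap classifier for harness plumbing tests: scores a
# window by its count of motif 8-mers (no training).
motif_count_classifier <- function(motif = "TATAAAGG") {
  classifier_spec(
    name = "motif_count",
    fit = function(train, validation, seed) list(motif = motif),
    predict = function(model, dataset) {
      hits <- vapply(dataset$instances$sequence, function(s) {
        lengths(regmatches(s, gregexpr(model$motif, s, fixed = TRUE)))
      }, integer(1), USE.NAMES = FALSE)
      stats::plogis(hits * 2 - 1)
    }
  )
}
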