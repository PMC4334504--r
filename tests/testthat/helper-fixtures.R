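# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Encode an in-memory synthetic dataset with the full block set; the domain
# vocabulary is derived from the positive annotations with a min-count
# scaled to the positive-set size (the reference rule uses 25 of 410).
encode_synth <- function(ds, min_count) {
  ann <- structure(lapply(ds$profiles, `[[`, "domains"), class = "domain_annotation")
  pos <- names(ds$labels)[ds$labels == "positive"]
  vocab <- build_domain_vocabulary(ann, pos, min_count = min_count)
  blocks <- if (length(vocab) > 0) "all" else
    c("sequence", "physicochemical", "evolutionary", "disorder", "ssi")
  cfg <- encoder_config(blocks, vocabulary = if (length(vocab) > 0) vocab else NULL)
  encode_dataset(ds$records, ds$profiles, cfg, labels = ds$labels)
}

# Strong planted signal: 100 + 100 proteins, signal 1.
planted_fixture <- function() cached("planted", function() {
  encode_synth(simulate_dataset(synth_config(100, 100, signal = 1, seed = 7)),
               min_count = 25)
})

# Null fixture: identical generative process for both classes.
null_fixture <- function() cached("null", function() {
  encode_synth(simulate_dataset(synth_config(100, 100, signal = 0, seed = 7)),
               min_count = 25)
})

# Imbalance fixture for the ratio sweep: moderate signal so the classifier
# is imperfect and the imbalance pathology is visible.
sweep_fixture <- function() cached("sweep", function() {
  encode_synth(simulate_dataset(synth_config(30, 300, signal = 0.3, seed = 5)),
               min_count = 8)
})

# Tiny labeled matrix with planted informative columns, for selection and
# ensemble unit tests that do not need real encodings.
planted_matrix <- function(n_pos = 30, n_neg = 30, d_noise = 15, seed = 3) {
  withr_seed(seed, {
    n <- n_pos + n_neg
    labels <- rep(c("positive", "negative"), c(n_pos, n_neg))
    signal <- ifelse(labels == "positive", 1, -1)
    x <- cbind(
      sig1 = signal + rnorm(n, sd = 0.4),
      sig2 = signal + rnorm(n, sd = 0.6),
      matrix(rnorm(n * d_noise), n, d_noise,
             dimnames = list(NULL, paste0("noise", seq_len(d_noise))))
    )
    rownames(x) <- paste0("s", seq_len(n))
    feature_matrix(x, labels)
  })
}
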