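# Lazily trained toy model ensemble, shared across acceptance tests so the
# three-view training runs exactly once per test session.

.toy_cache <- new.env(parent = emptyenv())

get_toy_experiment <- function() {
  if (!is.null(.toy_cache$exp)) return(.toy_cache$exp)
  sets <- build_toy_sets(n_train = 40L, n_val = 10L, n_test = 10L,
                         grid = 64L, crop_side = 48L, seed = 1L)
  trained <- train_toy_models(sets, seed = 1L)
  .toy_cache$exp <- list(sets = sets, models = trained$models,
                         histories = trained$histories)
  .toy_cache$exp
}
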