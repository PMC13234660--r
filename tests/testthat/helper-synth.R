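# Shared small synthetic configurations so tests stay fast; the acceptance
# tests use the full default study conditions instead.

small_config <- function(...) {
  args <- utils::modifyList(list(n_train = 2, n_test = 1), list(...))
  do.call(synth_config, args)
}

# single cached default dataset for tests that only read it
cached_default_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- generate_dataset(synth_config(seed = 42L))
    ds
  }
})
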