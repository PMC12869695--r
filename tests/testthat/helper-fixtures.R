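# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

small_world <- function() {
  memo_fixture("w_small", synth_world(synth_config(
    n_pathways = 4, genes_per_pathway = 10, n_samples = 20, n_drugs = 12,
    seed = 11)))
}

small_features <- function() {
  memo_fixture("fs_small", synth_features(small_world(), bottleneck = 8,
                                          ae_hidden = 24, ae_epochs = 10))
}

small_triplets <- function() {
  memo_fixture("tt_small", synth_truth(small_world()))
}

default_world <- function() {
  memo_fixture("w_default", synth_world(synth_config(seed = 1)))
}

default_features <- function() {
  memo_fixture("fs_default", synth_features(default_world(), bottleneck = 16,
                                            ae_hidden = 64, ae_epochs = 40))
}

default_triplets <- function() {
  memo_fixture("tt_default", synth_triplets(default_world(), 4000))
}

default_fplib <- function() {
  memo_fixture("fplib_default", fingerprint_library(default_world()$drugs))
}

# desk-scale model configuration used across training tests
desk_cfg <- function(seed = 1, epochs = 20, ...) {
  synergy_net_config(d = 32, chem_hidden = 64, dti_compress = 64,
                     head_widths = c(128, 64), epochs = epochs,
                     batch_size = 128, seed = seed, ...)
}
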