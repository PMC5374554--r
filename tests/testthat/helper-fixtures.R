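# Shared in-code fixtures. Reference sets are deterministic given the seed,
# so repeated calls across test files are cheap and reproducible.

fixture_env <- new.env(parent = emptyenv())

small_refs <- function() {
  if (is.null(fixture_env$small)) {
    fixture_env$small <- make_reference_set(20, 8, rng_seed = 101)
  }
  fixture_env$small
}

big_refs <- function() {
  if (is.null(fixture_env$big)) {
    fixture_env$big <- make_reference_set(50, 20, rng_seed = 202)
  }
  fixture_env$big
}

indexes_for <- function(refs, k = 12L) {
  list(plant = build_index(refs$plant$id, refs$plant$mature, k),
       host = build_index(c(refs$host$id, refs$decoys$id),
                          c(refs$host$mature, refs$decoys$sequence), k,
                          kingdom = c(rep("host", nrow(refs$host)),
                                      rep("decoy", nrow(refs$decoys)))))
}
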