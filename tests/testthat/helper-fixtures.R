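# memoized synthetic fixtures shared across test files
.fixture_env <- new.env()

tiny_ds <- function() {
  if (is.null(.fixture_env$tiny)) {
    .fixture_env$tiny <- generate_dataset(
      synth_config(n_molecules = 40L, seed = 11L, a_state = 1, d0_frac = 1))
  }
  .fixture_env$tiny
}

medium_ds <- function() {
  if (is.null(.fixture_env$medium)) {
    .fixture_env$medium <- generate_dataset(
      synth_config(n_molecules = 80L, seed = 5L))
  }
  .fixture_env$medium
}

badger_ds <- function() {
  if (is.null(.fixture_env$badger)) {
    .fixture_env$badger <- generate_dataset(
      synth_config(n_molecules = 100L, noise_Re = 0, noise_we = 0,
                   seed = 9L, truth = "badger_exact"))
  }
  .fixture_env$badger
}
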