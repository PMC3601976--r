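# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# small fixture (6 background families) for unit tests
small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    sc <- sim_scenario(n_background = 6L, seed = 42L)
    .fixture_cache$small <- make_transcriptome_fixture(sc)
  }
  .fixture_cache$small
}

# full default fixture (50 background families) for the acceptance suite
default_fixture <- function() {
  if (is.null(.fixture_cache$full)) {
    .fixture_cache$full <- make_transcriptome_fixture(sim_scenario(seed = 1L))
  }
  .fixture_cache$full
}

default_screen <- function() {
  if (is.null(.fixture_cache$screen)) {
    fx <- default_fixture()
    .fixture_cache$screen <- run_screen(fx$contigs, fx$references,
                                        fx$taxon_map)
  }
  .fixture_cache$screen
}

random_peptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
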