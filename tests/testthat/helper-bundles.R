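# shared fixtures: the packaged Tanzania bundle (cached per file) and a
# deterministic batch of random synthetic bundles
tz_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- tanzania_fixture()
    cache
  }
})

random_bundles <- function(n, seed_offset = 0) {
  lapply(seq_len(n) + seed_offset, generate_bundle)
}

# small intervention table used across impact tests
toy_interventions <- function() {
  tibble::tibble(
    name = c("alpha", "beta"),
    cause = c("sepsis", "sepsis"),
    effectiveness = c(0.9, 0.5),
    affected_fraction = c(1, 0.8),
    baseline_coverage = c(0.1, 0.2),
    target_coverage = c(0.85, 0.6)
  )
}
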