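# Expensive fixture objects computed once per test session.

.lmwgs_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .lmwgs_cache, inherits = FALSE)) {
    assign(name, expr, envir = .lmwgs_cache)
  }
  get(name, envir = .lmwgs_cache, inherits = FALSE)
}

# designed base sequences + truth of the 39 fixture variants
fixture_variants <- function() {
  cached("variants", lmwgs:::build_variant_sequences(fixture_population_config()))
}

# zero-mutation fixture population (157 accessions)
fixture_pop <- function() {
  cached("pop", make_population(fixture_population_config()))
}

# pairwise global identity matrix of the 39 variant sequences
fixture_idm <- function() {
  cached("idm", identity_matrix(fixture_variants()$sequences))
}

# one full pipeline run on the fixture configuration
fixture_pipeline <- function() {
  cached("pipeline", {
    out <- file.path(tempdir(), "lmwgs-fixture-pipeline")
    cfg <- pipeline_config(out_dir = out, seed = 42)
    suppressMessages(run_pipeline(cfg))
  })
}

fixture_profiles <- function() {
  cached("profiles", population_profiles(fixture_pop()))
}

fixture_calls <- function() {
  cached("calls", call_genotypes(fixture_profiles(), fixture_pop()$sequences))
}
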