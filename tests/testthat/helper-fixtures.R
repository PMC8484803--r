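# One shared synthetic cohort per test run, generated once and memoized.
.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(key = "default", config = fixture_config(seed = 11L)) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, gen_cohort(config, file.path(tempdir(), paste0("fx_", key))),
           envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
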