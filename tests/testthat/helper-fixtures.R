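# Shared fixtures, generated once per test run
.fixture_env <- new.env()

fixtures <- function(seed = 7L) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- make_fixture_suite(seed)
  }
  .fixture_env[[key]]
}

# small long-format CSV written on the fly
write_long_fixture <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("site_id,date,parameter,value", lines), path)
  path
}
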