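# One full default-condition study run, shared (lazily) across test files so
# the expensive simulate -> call -> classify chain executes once per session.
.run_cache <- new.env(parent = emptyenv())

cached_default_report <- function(seed = 101) {
  key <- paste0("report_", seed)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_differential_architecture(default_config(seed))
  .run_cache[[key]]
}
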