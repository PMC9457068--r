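# Shared configuration for the analysis scripts. Each numbered script sources
# this file, regenerates the (deterministic) synthetic study from the seed,
# and writes its tables under results/.

library(subtadscope)

SEED <- 20260927
CONFIG <- default_config(SEED)
RESULTS <- "results"

get_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(CONFIG)
    cache
  }
})

outdir <- function(...) {
  d <- file.path(RESULTS, ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_tsv <- function(df, ...) {
  path <- file.path(...)
  data.table::fwrite(as.data.frame(df), path, sep = "\t")
  message("wrote ", path)
}
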