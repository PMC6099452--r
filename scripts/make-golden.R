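#!/usr/bin/env Rscript
# Regenerate the golden pipeline outputs committed under
# tests/testthat/golden/. Run from the repository root against the
# installed package after any intentional change to the pipeline or the
# generators, and review the diff before committing.

library(rxlines)

seed <- 20180605L
td <- tempfile("golden-run-")
cfg <- write_demo_inputs(td, seed = seed)
run_pipeline(cfg)

dest <- file.path("tests", "testthat", "golden")
dir.create(dest, recursive = TRUE, showWarnings = FALSE)
for (f in list.files(cfg$output_dir)) {
  file.copy(file.path(cfg$output_dir, f), file.path(dest, f), overwrite = TRUE)
}
cat("golden outputs written to", dest, ":\n")
print(file.info(list.files(dest, full.names = TRUE))["size"])
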