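## Shared settings for the analysis scripts. Run the scripts in order from
## the repository root: Rscript analysis/01_simulate.R, 02_..., etc.
suppressMessages({
  library(vanscape)
  library(data.table)
})

PARAMS <- list(
  seed = 1L,
  pipeline_dir = "results/pipeline",
  results_dir = "results"
)
CFG <- sim_config(seed = PARAMS$seed)
dir.create(PARAMS$pipeline_dir, showWarnings = FALSE, recursive = TRUE)

p_pipe <- function(f) file.path(PARAMS$pipeline_dir, f)
p_res <- function(f) file.path(PARAMS$results_dir, f)
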