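#!/usr/bin/env Rscript
# Thin command-line wrapper over thyrosig::run_pipeline().
#
# Examples:
#   Rscript scripts/thyrosig.R --simulate --seed 7 --out results/run7
#   Rscript scripts/thyrosig.R --input cohort.csv --stages indices,endotype \
#       --out results/partial

suppressPackageStartupMessages({
  library(optparse)
  library(thyrosig)
})

parser <- OptionParser(option_list = list(
  make_option("--input", type = "character", default = NULL,
              help = "cohort CSV (omit with --simulate)"),
  make_option("--simulate", action = "store_true", default = FALSE,
              help = "generate the synthetic registry cohort instead"),
  make_option("--seed", type = "integer", default = 1L,
              help = "seed for the generator and bootstrap stages [%default]"),
  make_option("--stages", type = "character",
              default = "indices,endotype,cluster,comparisons,cutoffs,survival,cox,composite",
              help = "comma-separated stage list"),
  make_option("--unit-dialect", type = "character", default = "SI_pmol",
              dest = "unit_dialect", help = "SI_pmol or conventional_ngdl_pgml"),
  make_option("--config", type = "character", default = NULL,
              help = "YAML with constants/ranges/aliases overrides"),
  make_option("--out", type = "character", default = "results",
              help = "output directory [%default]")
))
opt <- parse_args(parser)

if (is.null(opt$input) && !opt$simulate) {
  stop("either --input or --simulate is required", call. = FALSE)
}
cfg <- if (!is.null(opt$config)) read_config(opt$config) else
  list(constants = spina_constants(), ranges = reference_ranges())

res <- run_pipeline(
  input = opt$input,
  simulate = opt$simulate,
  seed = opt$seed,
  stages = strsplit(opt$stages, ",")[[1]],
  constants = cfg$constants,
  ranges = cfg$ranges,
  output_dir = opt$out,
  unit_dialect = opt$unit_dialect
)
print(res)
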