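#!/usr/bin/env Rscript
# Thin command-line wrapper over the package's simulate / profile / report
# functions. The R functions are the primary interface; this script only
# forwards flags.
#
#   Rscript scripts/profile.R simulate --outdir runs/demo --seed 1
#   Rscript scripts/profile.R profile --input runs/demo/cohort.csv \
#       --pairing sedep --group-by sex --seed 1 --outdir runs/demo
#   Rscript scripts/profile.R report --input runs/demo/cohort.csv \
#       --pairing both --group-by age --seed 1 --outdir runs/demo

suppressMessages({
  library(uvsdt)
  library(optparse)
})

parser <- OptionParser(
  usage = "%prog {simulate|profile|report} [options]",
  option_list = list(
    make_option("--input", type = "character", default = NULL,
                help = "cohort CSV (profile/report)"),
    make_option("--pairing", type = "character", default = "both",
                help = "sedep, pcu or both [default %default]"),
    make_option("--group-by", dest = "group_by", type = "character",
                default = "none",
                help = "none, sex, age or laterality [default %default]"),
    make_option("--resampling", type = "character", default = "loo",
                help = "loo or bootstrap [default %default]"),
    make_option("--partitions", action = "store_true", default = FALSE,
                help = "add random-partition rows (72/71, 100 reps)"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--outdir", type = "character", default = "uvsdt-run")))
args <- parse_args2(parser)
cmd <- if (length(args$args) >= 1) args$args[1] else ""
opt <- args$options

pairings <- switch(opt$pairing, both = c("sedep", "pcu"), opt$pairing)

if (cmd == "simulate") {
  paths <- write_simulation(synthetic_config(seed = opt$seed), opt$outdir)
  cat("wrote", paths, sep = "\n")
} else if (cmd %in% c("profile", "report")) {
  if (is.null(opt$input)) stop("--input is required for ", cmd)
  co <- read_cohort(opt$input)
  pr <- profile_cohort(co, pairings = pairings, group_by = opt$group_by,
                       resampling = opt$resampling,
                       partitions = opt$partitions, seed = opt$seed,
                       outdir = opt$outdir)
  if (cmd == "report") {
    path <- file.path(opt$outdir, "report.txt")
    decision_report(pr, co, path = path)
    cat(readLines(path), sep = "\n")
  } else {
    print(pr)
  }
} else {
  stop("unknown command '", cmd, "'; use simulate, profile or report")
}
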