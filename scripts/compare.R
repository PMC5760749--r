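#!/usr/bin/env Rscript
# Thin command-line wrapper over genomepair::compare_genomes().
#
# Usage:
#   Rscript scripts/compare.R --genome-a a.gbff --genome-b b.gbff \
#       [--format genbank|gff3 --gff-a a.gff3 --gff-b b.gff3] \
#       [--out outdir --seed 1 --n-rounds 10 --region-min-run 5 --skip-ani]

suppressMessages({
  library(optparse)
  library(genomepair)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--genome-a", type = "character", dest = "genome_a"),
  make_option("--genome-b", type = "character", dest = "genome_b"),
  make_option("--format", type = "character", default = "genbank"),
  make_option("--gff-a", type = "character", default = NULL, dest = "gff_a"),
  make_option("--gff-b", type = "character", default = NULL, dest = "gff_b"),
  make_option("--out", type = "character", default = "genomepair_out"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--n-rounds", type = "integer", default = 10L, dest = "n_rounds"),
  make_option("--region-min-run", type = "integer", default = 5L,
              dest = "region_min_run"),
  make_option("--skip-ani", action = "store_true", default = FALSE,
              dest = "skip_ani")
)))

if (is.null(opts$genome_a) || is.null(opts$genome_b)) {
  stop("--genome-a and --genome-b are required")
}

a <- load_genome(opts$genome_a, format = opts$format, gff_path = opts$gff_a)
b <- load_genome(opts$genome_b, format = opts$format, gff_path = opts$gff_b)

report <- compare_genomes(
  a, b,
  region_params = list(min_nonbbh_run = opts$region_min_run),
  n_rounds = opts$n_rounds, seed = opts$seed, skip_ani = opts$skip_ani
)
write_comparison_report(report, opts$out, a = a, b = b)
print(report)
cat("report written to", opts$out, "\n")
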