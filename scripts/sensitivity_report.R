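#!/usr/bin/env Rscript
# Post-hoc robustness report over a power table produced by run_study()
# (or the simulate-study CLI verb): for each method, the spread of power
# across scenarios is classified as sensitive (spread > 0.1), slightly
# sensitive (0.05-0.1) or non-sensitive (< 0.05). This is bookkeeping
# over an existing table, not a tested operation.
#
# Usage: Rscript scripts/sensitivity_report.R --table results/power_table.tsv

suppressPackageStartupMessages(library(optparse))

opts <- parse_args(OptionParser(option_list = list(
  make_option("--table", type = "character", default = "results/power_table.tsv"),
  make_option("--out", type = "character", default = "")
)))

tab <- read.delim(opts$table, stringsAsFactors = FALSE)
stopifnot(all(c("scenario", "method", "power") %in% names(tab)))

classify <- function(d) {
  if (d > 0.1) "sensitive" else if (d >= 0.05) "slightly sensitive" else "non-sensitive"
}
rep_ <- do.call(rbind, lapply(split(tab, tab$method), function(g) {
  d <- max(g$power) - min(g$power)
  data.frame(method = g$method[1], n_scenarios = nrow(g),
             min_power = min(g$power), max_power = max(g$power),
             spread = d, class = classify(d), stringsAsFactors = FALSE)
}))
rep_ <- rep_[order(rep_$spread), ]
rownames(rep_) <- NULL

print(rep_, digits = 3)
if (nzchar(opts$out)) {
  write.table(rep_, opts$out, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", opts$out)
}
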