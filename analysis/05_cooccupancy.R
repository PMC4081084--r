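#!/usr/bin/env Rscript
# Co-occupancy of the six peak classes with the external mark sets: the
# percentage of class peaks with a mark peak within 150 nt.

suppressPackageStartupMessages(library(peakscape))

dir <- "results/simdata"
peaks <- read_peaks(file.path(dir, "tf_peaks.narrowPeak"), "narrowPeak")
genes <- read_gene_models(file.path(dir, "genes.tsv"))
expr <- read_expression(file.path(dir, "expression.tsv"))
mark_files <- list.files(dir, pattern = "^mark_.*\\.narrowPeak$",
                         full.names = TRUE)
names(mark_files) <- sub("^mark_", "", sub("\\.narrowPeak$", "",
                                           basename(mark_files)))

rep <- run_analysis(pipeline_config(peaks = peaks, genes = genes,
                                    expression = expr, marks = mark_files),
                    out = "results/cooccupancy")

cat("overlap matrix (% of class peaks with a mark within 150 nt):\n")
pct <- do.call(rbind, lapply(rep$cooccupancy$percent, unlist))
print(round(pct, 1))
cat("class sizes:", paste(names(rep$cooccupancy$n_class),
                          unlist(rep$cooccupancy$n_class), sep = "=",
                          collapse = " "), "\n")
cat("tables written to results/cooccupancy\n")
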