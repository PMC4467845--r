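#!/usr/bin/env Rscript
# Estimated daily intake of heavy metals from the bundled survey, with
# non-detect exclusion, screened against the tolerable-daily-intake
# registry.
suppressPackageStartupMessages(library(seadose))

bundle <- load_reference_tables()
metals <- malacca_metals()

edi <- edi_table(metals, bundle)
write_table_csv(edi, "results/metals_edi.csv")

screened <- edi[edi$flag != "no_tdi", ]
cat(sprintf("%d location x element EDI values; %d screened against a TDI\n",
            nrow(edi), nrow(screened)))
cat(sprintf("all screened below TDI: %s (largest ratio %s, EDI/TDI = %.2f)\n",
            all(screened$flag == "below_tdi"),
            screened$element[which.max(screened$ratio)],
            max(screened$ratio)))
cat("elements without a registered TDI:",
    paste(unique(edi$element[edi$flag == "no_tdi"]), collapse = ", "), "\n")
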