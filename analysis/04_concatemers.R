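#!/usr/bin/env Rscript
# Concatemer length spectrum of the branched-synthesis dataset: count fully
# correct products of each length (k triplet incorporations) ending in the 3'
# adapter, for products I and II, and report the longest product and its
# circle coverage.
suppressPackageStartupMessages(library(tripletRCS))

tpls <- load_template_specs()
products <- tpls[c("sc8211_I", "sc8211_II")]
decoded <- read_decoded_tsv("results/branched_decoded.tsv")

tab <- count_correct_products(decoded, products, k_range = 9:30)
readr::write_tsv(tab, "results/concatemer_spectrum.tsv")

s <- spectrum_summary(tab)
print(s$per_product)
cat(sprintf("longest fully correct product: %d triplet incorporations (%d nt), %.2fx circle coverage\n",
            s$overall$max_k, s$overall$length_nt, s$overall$circle_coverage))
cat(sprintf("reads at k = 15: I n = %d, II n = %d\n",
            tab$n[tab$product == "I" & tab$k == 15],
            tab$n[tab$product == "II" & tab$k == 15]))
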