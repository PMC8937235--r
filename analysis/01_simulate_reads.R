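#!/usr/bin/env Rscript
# Generate the synthetic sequencing datasets the downstream analyses run on:
# a one-pot mixture over the four barcoded templates A-D (circular and linear
# variants) and a branched-synthesis dataset over the double-primed 36 nt
# circle (products I and II).  Reads mimic gel-excised longer-than-full-length
# products: every read spans the analysis window and ends in the 3' adapter.
suppressPackageStartupMessages(library(tripletRCS))

SEED <- 20260924L
N_PER_TEMPLATE <- 2500L
dir.create("results", showWarnings = FALSE)

tpls <- load_template_specs()

# Non-templated (terminal-transferase) appending rarely inserts the GAA
# triplet that the repeat expects next, which is what makes the linear
# templates' beyond-full-length fidelity collapse; the circular templates
# stay templated throughout.
alph <- triplet_alphabet()
tt <- stats::setNames(ifelse(alph == "GAA", 0.09, 1), alph)

simulate_group <- function(names, label, seed0) {
  sims <- lapply(seq_along(names), function(i) {
    spec <- tpls[[names[i]]]
    cfg <- sim_config(spec, N_PER_TEMPLATE, seed = seed0 + i,
                      p_correct = default_fidelity_profile(spec, 18),
                      termination = 18, tt_model = tt)
    simulate_dataset(cfg)
  })
  reads <- do.call(rbind, lapply(sims, function(s) s$reads))
  truth <- do.call(rbind, lapply(sims, function(s) s$truth))
  write_fastq(reads, file.path("results", paste0(label, ".fastq.gz")))
  write_truth_tsv(truth, file.path("results", paste0(label, "_truth.tsv")))
  cat(sprintf("%s: %d reads over %s\n", label, nrow(reads),
              paste(names, collapse = ", ")))
  invisible(NULL)
}

simulate_group(c("A_circ", "B_circ", "C_circ", "D_circ"), "onepot_circular",
               SEED)
simulate_group(c("A_lin", "B_lin", "C_lin", "D_lin"), "onepot_linear",
               SEED + 10L)

# Branched synthesis: double priming sustains strand invasion, so synthesis
# stays templated at a high plateau throughout; product lengths thin out
# geometrically over k = 9..29 triplet incorporations (up to 96 nt).
branched <- lapply(1:2, function(i) {
  spec <- tpls[[c("sc8211_I", "sc8211_II")[i]]]
  term <- stats::setNames(2^(-(9:29 - 9) / 3.3), 9:29)
  cfg <- sim_config(spec, 5000L, seed = SEED + 20L + i,
                    p_correct = rep(0.95, 29),
                    termination = term, tt_model = tt, p_adapter = 0.95)
  simulate_dataset(cfg)
})
reads <- do.call(rbind, lapply(branched, function(s) s$reads))
write_fastq(reads, "results/branched.fastq.gz")
write_truth_tsv(do.call(rbind, lapply(branched, function(s) s$truth)),
                "results/branched_truth.tsv")
cat(sprintf("branched: %d reads over products I and II\n", nrow(reads)))
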