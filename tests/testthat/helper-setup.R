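# Shared fixtures and independent string-level oracles.
#
# The oracles reproduce exact-substring counting directly on the raw read
# strings (trim at the first primer occurrence, then prefix-match a query
# list), independently of the triplet-level decoding path they check.

TPLS <- load_template_specs()
ALPH <- attr(TPLS, "alphabet")
PRIMER <- attr(TPLS, "primer")
ADAPTER <- attr(TPLS, "adapter")

oracle_trim <- function(seqs, primer = PRIMER) {
  pos <- regexpr(primer, seqs, fixed = TRUE)
  ifelse(pos > 0L, substring(seqs, pos + nchar(primer)), NA_character_)
}

# number of reads whose trimmed extension starts with the given triplets
oracle_prefix_count <- function(seqs, triplets, primer = PRIMER) {
  trimmed <- oracle_trim(seqs, primer)
  q <- paste0(triplets, collapse = "")
  sum(startsWith(trimmed[!is.na(trimmed)], q))
}

# reads that are exactly k correct triplets followed by the adapter
oracle_correct_length_count <- function(seqs, expected, k,
                                        primer = PRIMER, adapter = ADAPTER) {
  oracle_prefix_count(seqs, c(expected[seq_len(k)], adapter), primer)
}

# hand-construct a decoded tibble from triplet vectors
make_decoded <- function(trip_lists, adapter_found = TRUE, frame_ok = TRUE) {
  n <- length(trip_lists)
  tibble::tibble(
    read_id = sprintf("r%03d", seq_len(n)),
    sample_id = NA_character_,
    triplets = trip_lists,
    k = lengths(trip_lists),
    adapter_found = rep_len(adapter_found, n),
    frame_ok = rep_len(frame_ok, n),
    trailing_bases = "")
}

# quick simulated one-pot mixture over the four circular or linear templates
sim_one_pot <- function(specs, n_per_template, seed, termination = 18,
                        kmax = 18) {
  sims <- lapply(seq_along(specs), function(i) {
    spec <- specs[[i]]
    cfg <- sim_config(spec, n_per_template, seed = seed + i,
                      p_correct = default_fidelity_profile(spec, kmax),
                      termination = termination)
    simulate_dataset(cfg)
  })
  list(reads = do.call(rbind, lapply(sims, function(s) s$reads)),
       truth = do.call(rbind, lapply(sims, function(s) s$truth)))
}
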