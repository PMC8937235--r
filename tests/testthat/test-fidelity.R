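circ_specs <- TPLS[c("A_circ", "B_circ", "C_circ", "D_circ")]
BCMAP <- barcode_map(circ_specs)

test_that("reads are classified by their position-3 barcode", {
  d <- make_decoded(list(
    c("GAA", "GAA", "ATA", "GAA"),   # template A barcode
    c("GAA", "GAA", "AAA", "GAA"),   # template B
    c("GAA", "GAA", "TTA"),          # template C
    c("GAA", "GAA", "ATC"),          # template D
    c("GAA", "GAA", "GGG", "GAA"),   # GGG is no position-3 barcode
    c("GAA", "GAA")))                # too short
  out <- classify_template(d, BCMAP)
  expect_identical(out$template, c("A", "B", "C", "D", NA, NA))
  expect_error(classify_template(d, c(ATA = "A", ATA = "B")), "distinct")
})

test_that("prefix conditioning counts a read up to its first error only", {
  A <- TPLS[["A_circ"]]
  exp_vec <- expected_triplet(A, 1:6)
  good <- replicate(10, exp_vec[1:5], simplify = FALSE)
  bad4 <- replace(exp_vec[1:5], 4, "CCC")  # wrong at 4, correct elsewhere
  d <- classify_template(make_decoded(c(good, list(bad4))), BCMAP)
  cm <- count_conditional(d, circ_specs, positions = 3:5)
  expect_identical(cm$n_total["5", "A"], 10L)
  expect_identical(cm$counts["5", "GAA", "A"], 10L)
  # the faulty read contributes its error at position 4 and nothing later
  expect_identical(cm$counts["4", "CCC", "A"], 1L)
  expect_identical(cm$n_total["4", "A"], 11L)
})

test_that("fidelity percentages match direct recomputation and sum to 100", {
  A <- TPLS[["A_circ"]]
  exp_vec <- expected_triplet(A, 1:4)
  reads <- c(replicate(90, exp_vec[1:4], simplify = FALSE),
             replicate(10, replace(exp_vec[1:4], 4, "ATA"),
                       simplify = FALSE))
  d <- classify_template(make_decoded(reads), BCMAP)
  fm <- fidelity(count_conditional(d, circ_specs, positions = 3:4))
  expect_equal(fidelity_value(fm, 4, "GAA", "A"), 90)
  expect_equal(fidelity_value(fm, 4, "ATA", "A"), 10)
  expect_equal(sum(fm$F["4", , "A"]), 100)
  expect_equal(sum(fm$F["3", , "A"]), 100)
  # single observed triplet gives 100%
  expect_equal(fidelity_value(fm, 3, "ATA", "A"), 100)
})

test_that("unmasked fidelity rows sum to 100 on random count configurations", {
  set.seed(7)
  A <- TPLS[["A_circ"]]
  exp_vec <- expected_triplet(A, 1:3)
  reads <- lapply(1:200, function(i) c(exp_vec, sample(ALPH, 5, TRUE)))
  d <- classify_template(make_decoded(reads), BCMAP)
  fm <- fidelity(count_conditional(d, circ_specs, positions = 3:8))
  for (a in as.character(3:8)) {
    if (!fm$masked[a, "A"]) {
      expect_equal(sum(fm$F[a, , "A"]), 100, tolerance = 1e-9)
      # each cell matches independent recomputation from raw counts
      cm2 <- count_conditional(d, circ_specs, positions = 3:8)
      expect_equal(fm$F[a, , "A"],
                   100 * cm2$counts[a, , "A"] / sum(cm2$counts[a, , "A"]))
    }
  }
})

test_that("out-of-alphabet triplets are excluded from the denominator", {
  A <- TPLS[["A_circ"]]
  exp_vec <- expected_triplet(A, 1:4)
  reads <- c(replicate(8, exp_vec, simplify = FALSE),
             list(replace(exp_vec, 4, "NNN"), replace(exp_vec, 4, "TGT")))
  d <- classify_template(make_decoded(reads), BCMAP)
  cm <- count_conditional(d, circ_specs, positions = 3:4)
  expect_identical(cm$n_total["4", "A"], 8L)
  expect_identical(cm$other["4", "A"], 2L)
  fm <- fidelity(cm)
  expect_equal(fidelity_value(fm, 4, "GAA", "A"), 100)
})

test_that("low-n cells are masked at the configurable threshold", {
  A <- TPLS[["A_circ"]]
  exp_vec <- expected_triplet(A, 1:6)
  reads <- c(replicate(6, exp_vec[1:3], simplify = FALSE),
             replicate(5, exp_vec[1:5], simplify = FALSE))
  d <- classify_template(make_decoded(reads), BCMAP)
  fm <- fidelity(count_conditional(d, circ_specs, positions = 3:6))
  expect_false(fm$masked["3", "A"])   # n = 11
  expect_true(fm$masked["5", "A"])    # n = 5 <= 5
  expect_true(fm$masked["6", "A"])    # n = 0
  fm0 <- fidelity(count_conditional(d, circ_specs, positions = 3:6),
                  mask_threshold = 0L)
  expect_false(fm0$masked["5", "A"])
})

test_that("cumulative correct-synthesis probability multiplies fidelities", {
  A <- TPLS[["A_circ"]]
  exp_vec <- expected_triplet(A, 1:5)
  # 4 reads: correct through 3; at 4 half fail; at 5 half of survivors fail
  reads <- list(exp_vec,
                replace(exp_vec, 5, "CCC"),
                replace(exp_vec, 4, "CCC")[1:4],
                replace(exp_vec, 4, "CCC")[1:4])
  d <- classify_template(make_decoded(reads), BCMAP)
  fm <- fidelity(count_conditional(d, circ_specs, positions = 3:5),
                 mask_threshold = 0L)
  p <- cumulative_correct(fm, A, 5)
  expect_equal(as.numeric(p), 0.25)  # 1 * 0.5 * 0.5
  expect_true(attr(p, "reliable"))
  expect_equal(as.numeric(cumulative_correct(fm, A, 3)), 1)
  # masked cells propagate the insufficient-n flag
  fm5 <- fidelity(count_conditional(d, circ_specs, positions = 3:5))
  expect_false(attr(cumulative_correct(fm5, A, 5), "reliable"))
})

test_that("prefix-conditioned counts telescope exactly on simulated reads", {
  A <- TPLS[["A_circ"]]
  cfg <- sim_config(A, 2000, seed = 17,
                    p_correct = default_fidelity_profile(A, 18),
                    termination = 18)
  sim <- simulate_dataset(cfg)
  d <- classify_template(decode_reads(sim$reads)$decoded, BCMAP)
  cm <- count_conditional(d, circ_specs, positions = 3:18)
  # integer identity: every read counted at a+1 is a read correct at a
  for (a in 3:17) {
    expect_identical(cm$n_total[as.character(a + 1), "A"],
                     cm$counts[as.character(a), expected_triplet(A, a), "A"])
  }
  fm <- fidelity(cm)
  defined <- (4:18)[cm$n_total[as.character(4:18), "A"] > 0]
  expect_gte(length(defined), 8)
  for (X in defined) {
    direct <- cm$counts[as.character(X), expected_triplet(A, X), "A"] /
      cm$n_total["3", "A"]
    expect_equal(as.numeric(cumulative_correct(fm, A, X)), direct,
                 tolerance = 1e-12)
  }
})

test_that("per-position fidelity equals brute-force grep-style counting", {
  sim <- sim_one_pot(circ_specs, 500, seed = 40)
  d <- classify_template(decode_reads(sim$reads)$decoded, BCMAP)
  cm <- count_conditional(d, circ_specs, positions = 3:12)
  for (Y in c("A", "C")) {
    spec <- circ_specs[[paste0(Y, "_circ")]]
    for (a in c(3L, 4L, 7L, 10L)) {
      prefix <- expected_triplet(spec, seq_len(a - 1))
      for (x in ALPH) {
        n_oracle <- oracle_prefix_count(sim$reads$seq, c(prefix, x))
        if (a == 3L && x != spec$barcode_positions[["3"]]) {
          # at the classification position a non-barcode triplet belongs to
          # another template's tally (or none), not to Y's
          next
        }
        expect_identical(cm$counts[as.character(a), x, Y], n_oracle)
      }
    }
  }
})

test_that("unconditional counting ignores upstream errors", {
  A <- TPLS[["A_circ"]]
  exp_vec <- expected_triplet(A, 1:5)
  reads <- list(exp_vec, replace(exp_vec, 4, "CCC"))
  d <- classify_template(make_decoded(reads), BCMAP)
  cm_u <- count_conditional(d, circ_specs, positions = 3:5,
                            conditioning = "unconditional")
  cm_p <- count_conditional(d, circ_specs, positions = 3:5)
  expect_identical(cm_u$n_total["5", "A"], 2L)  # both reads long enough
  expect_identical(cm_p$n_total["5", "A"], 1L)  # error at 4 blocks one
})

test_that("fold difference handles identities and degenerate denominators", {
  expect_equal(fold_difference(0.2, 0.02), 10)
  expect_equal(fold_difference(0.37, 0.37), 1)
  expect_identical(fold_difference(0.1, 0), Inf)
  expect_identical(fold_difference(0, 0), NaN)
})

test_that("fidelity matrices are written as one labelled TSV per template", {
  sim <- sim_one_pot(circ_specs[1:2], 100, seed = 8, termination = 12,
                     kmax = 12)
  d <- classify_template(decode_reads(sim$reads)$decoded,
                         barcode_map(circ_specs[1:2]))
  fm <- fidelity(count_conditional(d, circ_specs[1:2], positions = 3:12))
  dir <- tempfile(); paths <- write_fidelity_tsv(fm, dir)
  expect_true(all(file.exists(file.path(dir, c("fidelity_A.tsv",
                                               "fidelity_B.tsv")))))
  tab <- readr::read_tsv(file.path(dir, "fidelity_A.tsv"),
                         show_col_types = FALSE)
  expect_identical(names(tab)[1:2], c("triplet", "pos3"))
  expect_identical(tab$triplet, c(ALPH, "n", "masked"))
})
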