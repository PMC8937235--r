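#' Simulation configuration for synthetic sequencing reads
#'
#' Describes the generative model the analysis pipeline assumes: a primer, a
#' template with position-dependent correct-incorporation probability, an
#' error distribution over the triplet alphabet for mis-incorporations, a
#' terminal-transferase (non-templated) triplet distribution for positions
#' beyond a linear template's instruction, a termination distribution over the
#' number of incorporated triplets, and optional sample barcode / 3' adapter.
#'
#' @param template A \code{\link{template_spec}}.
#' @param n_reads Number of reads to generate.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param p_correct Numeric vector of per-position probabilities of inserting
#'   the expected triplet, indexed by 1-based position.  Must cover every
#'   templated position reachable under \code{termination}.
#' @param termination Either a single integer (every read incorporates exactly
#'   that many triplets) or a named numeric vector of probabilities whose
#'   names are triplet counts k >= 0.
#' @param error_model Named probability vector over the alphabet from which
#'   incorrect insertions are drawn; the expected triplet is removed and the
#'   rest renormalized at each position, so \code{p_correct} is exactly the
#'   correct-incorporation probability.  Default: uniform over the alphabet.
#' @param tt_model Named probability vector over the alphabet for non-templated
#'   terminal-transferase appending beyond a linear template's instruction.
#'   Default: uniform over the alphabet.
#' @param p_adapter Probability that a read ends with the 3' adapter.
#' @param sample_barcode Optional sample barcode prefixed to every read.
#' @param adapter_filler Fixed sequence appended after the adapter prefix
#'   (sequencing continues into library scaffold; only the prefix is
#'   diagnostic).
#' @param alphabet Triplet alphabet.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(template, n_reads, seed, p_correct, termination,
                       error_model = NULL, tt_model = NULL, p_adapter = 1,
                       sample_barcode = NULL,
                       adapter_filler = "CTGACGCTGCCGACGA",
                       alphabet = triplet_alphabet()) {
  stopifnot(inherits(template, "template_spec"), n_reads >= 0)
  if (length(termination) == 1L && is.null(names(termination))) {
    termination <- stats::setNames(1, as.character(as.integer(termination)))
  }
  kk <- as.integer(names(termination))
  if (any(is.na(kk)) || any(kk < 0) || any(termination < 0)) {
    stop("termination must be a distribution over counts k >= 0")
  }
  termination <- termination / sum(termination)
  kmax <- max(kk[termination > 0])
  templated_thru <- if (template$topology == "circular") kmax
                    else min(kmax, template$instruction_len)
  if (templated_thru >= 1L &&
      (length(p_correct) < templated_thru || anyNA(p_correct[seq_len(templated_thru)]))) {
    stop("p_correct must be defined for every templated position 1..",
         templated_thru)
  }
  if (any(p_correct < 0 | p_correct > 1, na.rm = TRUE)) {
    stop("p_correct values must lie in [0, 1]")
  }
  norm_dist <- function(d, what) {
    if (is.null(d)) d <- stats::setNames(rep(1, length(alphabet)), alphabet)
    if (is.null(names(d)) || !all(names(d) %in% alphabet) || any(d < 0)) {
      stop(what, " must be a non-negative named vector over the alphabet")
    }
    d / sum(d)
  }
  if (!is.null(sample_barcode)) sample_barcode <- rna_to_dna(sample_barcode)
  structure(
    list(template = template, n_reads = as.integer(n_reads),
         seed = as.integer(seed), p_correct = p_correct,
         termination = termination,
         error_model = norm_dist(error_model, "error_model"),
         tt_model = norm_dist(tt_model, "tt_model"),
         p_adapter = p_adapter, sample_barcode = sample_barcode,
         adapter_seq = ADAPTER_PREFIX,
         adapter_filler = rna_to_dna(adapter_filler),
         alphabet = alphabet),
    class = "sim_config")
}

#' Default per-position fidelity profile
#'
#' The profile the one-pot experiments display: a high plateau up to
#' full-length circle synthesis, a sharp drop at the strand-invasion position
#' (full length + 1), and partial recovery beyond it once invasion has
#' succeeded.  Defaults put the circular plateau at 0.90, the invasion dip at
#' 0.109, and the recovered regime at 0.5; linear templates plateau at 0.79
#' (their beyond-instruction positions are non-templated and ignore
#' \code{p_correct}).
#'
#' @param spec A \code{\link{template_spec}}.
#' @param kmax Highest position the profile must cover.
#' @param plateau,invasion,recovery Probabilities for the three regimes.
#' @return Numeric vector of length \code{kmax}.
#' @export
default_fidelity_profile <- function(spec, kmax,
                                     plateau = if (spec$topology == "circular") 0.90 else 0.79,
                                     invasion = 0.109, recovery = 0.5) {
  fc <- if (spec$topology == "circular") spec_full_circle(spec)
        else spec$instruction_len
  p <- rep(plateau, kmax)
  if (kmax > fc) p[fc + 1L] <- invasion
  if (kmax > fc + 1L) p[(fc + 2L):kmax] <- recovery
  p
}

#' Simulate a synthetic sequencing dataset with ground truth
#'
#' Each read is \code{[sample_barcode] + primer + triplets + [adapter]}: the
#' triplet at templated position a is the template's expected triplet with
#' probability \code{p_correct[a]} and otherwise drawn from the error model
#' (expected triplet excluded); positions beyond a linear template's
#' instruction draw from the terminal-transferase model.  Fully reproducible
#' from the config seed.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list of class \code{sim_dataset} with elements \code{reads}
#'   (tibble: read_id, seq), \code{truth} (tibble: read_id, template, k,
#'   triplets list-column, correct list-column with NA at non-templated
#'   positions, adapter_present) and \code{config}.
#' @export
#' @examples
#' tpl <- load_template_specs()[["A_circ"]]
#' cfg <- sim_config(tpl, n_reads = 5, seed = 1,
#'                   p_correct = rep(1, 12), termination = 12)
#' sim <- simulate_dataset(cfg)
#' sim$reads$seq[1]
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$template
  n <- config$n_reads
  set.seed(config$seed)
  ks <- as.integer(names(config$termination))
  k <- if (length(ks) == 1L) rep(ks, n)
       else sample(ks, n, replace = TRUE, prob = config$termination)
  kmax <- if (n > 0) max(k, 0L) else 0L
  trip <- matrix(NA_character_, nrow = n, ncol = max(kmax, 1L))
  correct <- matrix(NA, nrow = n, ncol = max(kmax, 1L))
  for (a in seq_len(kmax)) {
    idx <- which(k >= a)
    if (!length(idx)) next
    templated <- spec$topology == "circular" ||
      a <= (spec$instruction_len %||% 0L)
    if (templated) {
      exp_a <- expected_triplet(spec, a)
      ok <- stats::runif(length(idx)) < config$p_correct[a]
      trip[idx[ok], a] <- exp_a
      correct[idx[ok], a] <- TRUE
      wrong <- idx[!ok]
      if (length(wrong)) {
        em <- config$error_model[names(config$error_model) != exp_a]
        trip[wrong, a] <- sample(names(em), length(wrong), replace = TRUE,
                                 prob = em)
        correct[wrong, a] <- FALSE
      }
    } else {
      trip[idx, a] <- sample(names(config$tt_model), length(idx),
                             replace = TRUE, prob = config$tt_model)
    }
  }
  has_adapter <- stats::runif(n) < config$p_adapter
  ext <- vapply(seq_len(n), function(i) {
    if (k[i] == 0L) "" else paste0(trip[i, seq_len(k[i])], collapse = "")
  }, character(1))
  read_id <- sprintf("%s_r%06d", gsub("[^A-Za-z0-9]", "_", spec$name),
                     seq_len(n))
  seqs <- paste0(config$sample_barcode %||% "", spec$primer_seq, ext,
                 ifelse(has_adapter,
                        paste0(config$adapter_seq, config$adapter_filler), ""))
  truth <- tibble::tibble(
    read_id = read_id, template = spec$name, k = k,
    triplets = lapply(seq_len(n), function(i) trip[i, seq_len(k[i])]),
    correct = lapply(seq_len(n), function(i) correct[i, seq_len(k[i])]),
    adapter_present = has_adapter)
  structure(list(reads = tibble::tibble(read_id = read_id, seq = seqs),
                 truth = truth, config = config),
            class = "sim_dataset")
}

#' Lane simulation configuration and simulator
#'
#' Emulates a gel lane of a primer-extension ladder on a small circular
#' template whose junction accessibility oscillates with the helical pitch of
#' A-form dsRNA.  Per-junction efficiency is
#' \code{e_b = e0 * (1 - A * (1 + cos(theta_b)) / 2)} with
#' \code{theta_b = 2 * pi * (3 * b + phase_offset_bp) / pitch_bp}; band
#' intensities follow \code{I_b = N * prod(e_1..e_b) * (1 - e_{b+1})} for
#' b < n and \code{I_n = N * prod(e_1..e_n)}, so a noiseless lane conserves
#' the number of loaded molecules across bands.
#'
#' @param n_junctions Number of triplet ligation junctions (bands 1..n; band 0
#'   is the unextended primer).
#' @param e0 Baseline junction efficiency in [0, 1].
#' @param A Modulation amplitude in [0, 1] (0 = unmodulated).
#' @param pitch_bp Helical period in bp (> 2); default A-form dsRNA pitch.
#' @param phase_offset_bp Phase offset in bp.
#' @param n_molecules Total lane intensity (molecule count / fluorescence
#'   scale).
#' @param noise_sd Multiplicative log-normal noise sd on intensities (0 =
#'   noiseless).
#' @param seed Seed used when \code{noise_sd > 0}.
#' @param meta Metadata list stored on the profile.
#' @return A \code{\link{lane_profile}}.
#' @export
#' @examples
#' lane <- simulate_lane(n_junctions = 9, e0 = 0.8, A = 0.5)
#' extension_efficiency(lane)
simulate_lane <- function(n_junctions, e0, A = 0,
                          pitch_bp = RNA_HELICAL_PITCH_BP,
                          phase_offset_bp = 0, n_molecules = 1,
                          noise_sd = 0, seed = NULL, meta = list()) {
  stopifnot(n_junctions >= 1, e0 >= 0, e0 <= 1, A >= 0, A <= 1, pitch_bp > 2,
            noise_sd >= 0, e0 * (1 - A) >= 0)
  b <- seq_len(n_junctions)
  theta <- 2 * pi * (3 * b + phase_offset_bp) / pitch_bp
  e <- e0 * (1 - A * (1 + cos(theta)) / 2)
  surv <- cumprod(e)
  I <- n_molecules * c(1 - e[1L],
                       if (n_junctions > 1L)
                         surv[-n_junctions] * (1 - e[-1L]),
                       surv[n_junctions])
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    I <- I * stats::rlnorm(length(I), 0, noise_sd)
  }
  lane_profile(I, meta = c(meta, list(e0 = e0, A = A, pitch_bp = pitch_bp,
                                      phase_offset_bp = phase_offset_bp,
                                      true_efficiency = e)))
}
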