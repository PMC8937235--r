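#' Classify decoded reads by their position-3 barcode
#'
#' The triplet at position 3 — the first barcode slot — identifies which
#' template a product was synthesized on; by construction the fidelity of the
#' classifying triplet at position 3 is then 100\% for classified reads.
#'
#' @param decoded Decoded-read tibble (see \code{\link{decode_reads}}).
#' @param barcode_map Named character vector mapping barcode triplet to
#'   template name (see \code{\link{barcode_map}}).
#' @param position Classification position (default 3).
#' @return The tibble with a \code{template} column added (\code{NA} for
#'   unclassified reads, including reads shorter than the classification
#'   position).
#' @export
classify_template <- function(decoded, barcode_map, position = 3L) {
  if (anyDuplicated(names(barcode_map))) {
    stop("barcode_map keys must be distinct")
  }
  tr <- vapply(decoded$triplets, function(t) {
    if (length(t) >= position) t[position] else NA_character_
  }, character(1))
  decoded$template <- unname(barcode_map[tr])
  decoded
}

#' Prefix-conditioned triplet counts per position and template
#'
#' For each analysis position a and template Y, counts the observed triplet of
#' every read whose triplets at positions 1..a-1 all equal Y's expected
#' triplets (the template's own barcodes at barcode slots).  This generalizes
#' exact-substring counting with query lists of the form
#' primer + expected(1..a-1) + each alphabet triplet: a read contributes at
#' positions up to and including its first mis-incorporation.  Observed
#' triplets outside the alphabet are tallied separately as "other" and
#' excluded from the fidelity denominator.  Frame-shifted reads (adapter off
#' the triplet boundary) are excluded; reads without adapter participate.
#'
#' @param decoded Classified decoded tibble (must carry \code{template}).
#' @param specs Named list of \code{\link{template_spec}}s; names must match
#'   the \code{template} values.
#' @param positions Integer positions to count (default 3:18).
#' @param alphabet Triplet alphabet defining the denominator.
#' @param conditioning \code{"prefix"} (default) or \code{"unconditional"}
#'   (count every read long enough at each position, regardless of upstream
#'   errors — sensitivity-analysis mode).
#' @return Object of class \code{count_matrix}: 3-d count array
#'   (position x triplet x template), \code{other} and \code{n_total}
#'   matrices (position x template), plus bookkeeping fields.
#' @export
count_conditional <- function(decoded, specs, positions = 3:18,
                              alphabet = triplet_alphabet(),
                              conditioning = c("prefix", "unconditional")) {
  conditioning <- match.arg(conditioning)
  if (!"template" %in% names(decoded)) {
    stop("decoded reads must be classified first (see classify_template)")
  }
  positions <- sort(as.integer(positions))
  templates <- vapply(specs, function(s) s$name, character(1))
  if (is.null(names(specs))) names(specs) <- templates
  missing_specs <- setdiff(stats::setNames(unique(stats::na.omit(decoded$template)), NULL),
                           templates)
  if (length(missing_specs)) {
    stop("no spec for classified template(s): ",
         paste(missing_specs, collapse = ", "))
  }
  pmax_ <- max(positions)
  counts <- array(0L, dim = c(length(positions), length(alphabet),
                              length(templates)),
                  dimnames = list(position = positions, triplet = alphabet,
                                  template = templates))
  other <- matrix(0L, length(positions), length(templates),
                  dimnames = list(positions, templates))
  keep <- !is.na(decoded$template) & !(decoded$adapter_found & !decoded$frame_ok)
  dd <- decoded[keep, , drop = FALSE]
  for (ti in seq_along(templates)) {
    Y <- templates[ti]
    spec <- specs[[which(templates == Y)]]
    exp_vec <- expected_triplet(spec, seq_len(pmax_))
    rows <- which(dd$template == Y)
    for (r in rows) {
      trips <- dd$triplets[[r]]
      k <- length(trips)
      if (k == 0L) next
      limit <- min(k, pmax_)
      if (conditioning == "prefix") {
        cmp_len <- limit
        mism <- which(trips[seq_len(cmp_len)] != exp_vec[seq_len(cmp_len)] |
                        is.na(exp_vec[seq_len(cmp_len)]))
        if (length(mism)) limit <- min(limit, mism[1L])
      }
      for (a in positions[positions <= limit]) {
        obs <- trips[a]
        j <- match(obs, alphabet)
        ai <- match(a, positions)
        if (is.na(j)) other[ai, ti] <- other[ai, ti] + 1L
        else counts[ai, j, ti] <- counts[ai, j, ti] + 1L
      }
    }
  }
  n_total <- apply(counts, c(1, 3), sum)
  structure(list(counts = counts, other = other, n_total = n_total,
                 conditioning = conditioning, positions = positions,
                 alphabet = alphabet, templates = templates),
            class = "count_matrix")
}

#' Per-position incorporation fidelity (percent)
#'
#' Fidelity of triplet xxx at position a on template Y is
#' \code{100 * n(xxx, a, Y) / sum_XXX n(XXX, a, Y)}, the percentage of counted
#' reads carrying xxx at that position; the denominator sums over the
#' configured triplet alphabet.  Cells with denominator at or below the mask
#' threshold are flagged as low-n (default threshold 5).
#'
#' @param cm A \code{\link{count_conditional}} result.
#' @param mask_threshold Mask positions with \code{n_total <= mask_threshold}.
#' @return Object of class \code{fidelity_matrix}: \code{F} (percent array,
#'   position x triplet x template, NA where undefined), \code{n}
#'   (\code{n_total} matrix), \code{masked} (logical matrix), bookkeeping.
#' @export
fidelity <- function(cm, mask_threshold = 5L) {
  stopifnot(inherits(cm, "count_matrix"))
  Fm <- array(NA_real_, dim = dim(cm$counts), dimnames = dimnames(cm$counts))
  for (ti in seq_along(cm$templates)) {
    nt <- cm$n_total[, ti]
    ok <- nt > 0
    Fm[ok, , ti] <- 100 * cm$counts[ok, , ti, drop = FALSE] /
      nt[ok]
  }
  masked <- cm$n_total <= mask_threshold
  structure(list(F = Fm, n = cm$n_total, masked = masked,
                 positions = cm$positions, alphabet = cm$alphabet,
                 templates = cm$templates, mask_threshold = mask_threshold,
                 conditioning = cm$conditioning),
            class = "fidelity_matrix")
}

#' Look up a fidelity value
#'
#' @param fm A \code{\link{fidelity}} result.
#' @param position,triplet,template Cell coordinates.
#' @return Fidelity percentage (NA if undefined).
#' @export
fidelity_value <- function(fm, position, triplet, template) {
  fm$F[as.character(position), triplet, template]
}

#' Cumulative probability of fully templated synthesis through position X
#'
#' Product of the correct-triplet fidelities from the classification position
#' (3, contributing a factor of 1 by construction) through position X.  With
#' prefix-conditioned counts over reads spanning the range this telescopes to
#' the fraction of classified reads fully correct through X.
#'
#' @param fm A \code{\link{fidelity}} result from prefix-conditioned counts.
#' @param spec The template's \code{\link{template_spec}}.
#' @param X Final position.
#' @param from Starting position (default 3).
#' @return Probability in [0, 1] with attribute \code{reliable} (FALSE when
#'   any contributing cell was masked or undefined, the "insufficient n"
#'   flag).
#' @export
cumulative_correct <- function(fm, spec, X, from = 3L) {
  stopifnot(inherits(fm, "fidelity_matrix"), X >= from)
  Y <- spec$name
  reliable <- TRUE
  p <- 1
  for (a in from:X) {
    exp_a <- expected_triplet(spec, a)
    f <- fm$F[as.character(a), exp_a, Y]
    if (is.na(f) || fm$masked[as.character(a), Y]) reliable <- FALSE
    p <- p * ifelse(is.na(f), NA_real_, f / 100)
  }
  structure(p, reliable = reliable)
}

#' Circular-vs-linear fold difference of templated-synthesis probability
#'
#' @param p_circular,p_linear Cumulative correct-synthesis probabilities.
#' @return \code{p_circular / p_linear}; \code{Inf} when the linear
#'   probability is zero (reported as a sentinel, not an error), \code{NA}
#'   when undefined.
#' @export
fold_difference <- function(p_circular, p_linear) {
  pc <- as.numeric(p_circular); pl <- as.numeric(p_linear)
  out <- pc / pl
  out[!is.na(pl) & pl == 0 & !is.na(pc) & pc > 0] <- Inf
  out
}

#' Write fidelity matrices to TSV (one file per template)
#'
#' Rows are the alphabet triplets plus an \code{n} row and a \code{masked}
#' row; columns are 1-based triplet positions.
#'
#' @param fm A \code{\link{fidelity}} result.
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @return Paths written, invisibly.
#' @export
write_fidelity_tsv <- function(fm, dir, prefix = "fidelity") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (Y in fm$templates) {
    m <- t(fm$F[, , Y, drop = TRUE])  # triplet x position
    df <- tibble::as_tibble(round(m, 1), .name_repair = "minimal")
    names(df) <- paste0("pos", fm$positions)
    df <- cbind(tibble::tibble(triplet = fm$alphabet), df)
    extra <- rbind(c("n", fm$n[, Y]), c("masked", as.integer(fm$masked[, Y])))
    extra <- stats::setNames(as.data.frame(extra), names(df))
    out <- rbind(as.data.frame(lapply(df, as.character)), extra)
    p <- file.path(dir, paste0(prefix, "_", gsub("[^A-Za-z0-9]", "_", Y),
                               ".tsv"))
    readr::write_tsv(tibble::as_tibble(out), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
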