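#' The 14-triplet substrate alphabet
#'
#' Ordered set of trinucleotide substrates available to the triplet polymerase
#' ribozyme in the one-pot experiments, in DNA (sequenced cDNA) representation.
#' All fidelity denominators sum over this alphabet.
#'
#' @param members Optional character vector of 3-mers replacing the default
#'   14-member alphabet.
#' @return Character vector of unique uppercase DNA triplets.
#' @export
#' @examples
#' triplet_alphabet()
triplet_alphabet <- function(members = NULL) {
  if (is.null(members)) {
    members <- c("CTG", "ATA", "CCA", "CCC", "AAA", "CAC", "GGG",
                 "TTA", "TCC", "GGC", "ATC", "GAT", "CGC", "GAA")
  }
  members <- rna_to_dna(members)
  bad <- !is_triplet(members)
  if (any(bad)) {
    stop("not valid DNA triplets: ", paste(members[bad], collapse = ", "))
  }
  if (anyDuplicated(members)) {
    stop("alphabet members must be unique")
  }
  members
}

#' Convert RNA sequence notation to the DNA representation used internally
#'
#' Reads are sequenced cDNA; all internal arithmetic is over {A,C,G,T}.
#' The conversion is one-way (U -> T) and upper-cases its input.
#'
#' @param x Character vector of sequences.
#' @return Character vector over the DNA alphabet.
#' @export
rna_to_dna <- function(x) {
  gsub("U", "T", toupper(x), fixed = TRUE)
}

#' @keywords internal
is_triplet <- function(x) {
  nchar(x) == 3L & grepl("^[ACGT]{3}$", x)
}

# Sequence constants of the experimental system: extension primer P9_1 and the
# prefix of the 3' sequencing adapter that marks the end of a genuine product.
#' @rdname decode_reads
#' @export
PRIMER_P9_1 <- "GAAGAACTG"

#' @rdname decode_reads
#' @export
ADAPTER_PREFIX <- "GTCGAATAT"

#' Helical pitch of A-form double-stranded RNA (base pairs per turn)
#'
#' Used as the default period when simulating accessibility-modulated gel
#' lanes; junction accessibility on a small circular template oscillates with
#' this period.
#' @export
RNA_HELICAL_PITCH_BP <- 11.3

#' Template / product specification
#'
#' Describes the expected triplet at every product position for a circular or
#' linear template, the priming frame, and barcode slots.  Positions are
#' 1-based counting from the first extension triplet after the primer.  For a
#' circular template the expected triplets repeat with period
#' \code{circle_len_nt / 3}, and the last \code{nchar(primer_seq)/3} entries of
#' one period are the primer's own triplets (the primer occupies whole triplet
#' slots of the circle).
#'
#' @param name Template identifier (e.g. "A", "sc8211-I").
#' @param topology "circular" or "linear".
#' @param primer_seq Primer sequence (DNA or RNA notation), length a multiple
#'   of 3.
#' @param expected Character vector of expected triplets for positions
#'   \code{1..P}: one period for circular templates, the full reference
#'   extension for linear ones.  May be \code{NULL} for geometry-only specs
#'   (e.g. odd-length circles used only in gel analyses).
#' @param circle_len_nt Circle length in nt (circular topology only).
#' @param barcode_positions Named list/vector mapping position (as character)
#'   to this template's barcode triplet at that position.
#' @param instruction_len For linear templates, the number of positions that
#'   are actually template-instructed; positions beyond it in \code{expected}
#'   are the reference continuation used for fidelity scoring while synthesis
#'   there is non-templated.  Defaults to \code{length(expected)}.
#' @param full_circle_override Explicit full-circle triplet count for circles
#'   whose length is not a multiple of 3 (experimental idiosyncrasy of the
#'   34-58 nt series); such specs carry no \code{expected} triplets.
#' @param alphabet Triplet alphabet the expected/barcode triplets must belong
#'   to.
#' @return An object of class \code{template_spec}.
#' @export
#' @examples
#' tpl <- template_spec("A", "circular", "GAAGAACTG",
#'   expected = c("GAA","GAA","ATA","GAA","GAA","CAC",
#'                "GAA","GAA","GGG","GAA","GAA","CTG"),
#'   circle_len_nt = 36,
#'   barcode_positions = list(`3` = "ATA", `6` = "CAC", `9` = "GGG"))
#' expected_triplet(tpl, 15)  # same as position 3
template_spec <- function(name, topology = c("circular", "linear"),
                          primer_seq, expected = NULL, circle_len_nt = NULL,
                          barcode_positions = list(), instruction_len = NULL,
                          full_circle_override = NULL,
                          alphabet = triplet_alphabet()) {
  topology <- match.arg(topology)
  primer_seq <- rna_to_dna(primer_seq)
  if (nchar(primer_seq) %% 3L != 0L) {
    stop("template_spec '", name, "': primer length must be a multiple of 3")
  }
  if (!is.null(expected)) {
    expected <- rna_to_dna(expected)
    if (!all(is_triplet(expected))) {
      stop("template_spec '", name, "': malformed expected triplets")
    }
    outside <- setdiff(expected, alphabet)
    if (length(outside)) {
      stop("template_spec '", name, "': expected triplets outside alphabet: ",
           paste(outside, collapse = ", "))
    }
  }
  if (topology == "circular") {
    if (is.null(circle_len_nt)) {
      stop("template_spec '", name, "': circular template needs circle_len_nt")
    }
    if (circle_len_nt %% 3L != 0L) {
      if (is.null(full_circle_override)) {
        stop("template_spec '", name, "': circle length ", circle_len_nt,
             " nt is not a multiple of 3; supply full_circle_override")
      }
      if (!is.null(expected)) {
        stop("template_spec '", name,
             "': expected triplets are undefined on a circle whose length ",
             "is not a multiple of 3")
      }
    } else if (!is.null(expected)) {
      period <- circle_len_nt / 3L
      if (length(expected) != period) {
        stop("template_spec '", name, "': expected must hold one period (",
             period, " triplets), got ", length(expected))
      }
      primer_trip <- split_triplets(primer_seq)
      np <- length(primer_trip)
      if (np > 0 &&
          !identical(expected[(period - np + 1L):period], primer_trip)) {
        stop("template_spec '", name, "': the last ", np, " period entries ",
             "must equal the primer's own triplets")
      }
    }
  }
  bp <- lapply(barcode_positions, rna_to_dna)
  if (length(bp)) {
    if (!all(unlist(bp) %in% alphabet)) {
      stop("template_spec '", name, "': barcode triplet outside alphabet")
    }
    pos <- as.integer(names(bp))
    for (i in seq_along(bp)) {
      et <- if (!is.null(expected)) expected_at(expected, topology, pos[i]) else NA
      if (!is.na(et) && et != bp[[i]]) {
        stop("template_spec '", name, "': barcode at position ", pos[i],
             " disagrees with expected triplet")
      }
    }
  }
  structure(
    list(name = name, topology = topology, primer_seq = primer_seq,
         expected = expected, circle_len_nt = circle_len_nt,
         barcode_positions = bp,
         instruction_len = if (topology == "linear")
           instruction_len %||% length(expected) else NULL,
         full_circle_override = full_circle_override,
         alphabet = alphabet),
    class = "template_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.template_spec <- function(x, ...) {
  cat("<template_spec>", x$name, "-", x$topology)
  if (!is.null(x$circle_len_nt)) cat(",", x$circle_len_nt, "nt circle")
  cat("\n  primer:", x$primer_seq, "\n")
  if (!is.null(x$expected)) {
    cat("  expected:", paste(x$expected, collapse = " "), "\n")
  }
  invisible(x)
}

#' @keywords internal
split_triplets <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# position lookup on a plain expected vector (shared by validation and
# expected_triplet)
#' @keywords internal
expected_at <- function(expected, topology, position) {
  P <- length(expected)
  if (P == 0L) return(rep(NA_character_, length(position)))
  if (topology == "circular") {
    expected[((position - 1L) %% P) + 1L]
  } else {
    ifelse(position <= P, expected[pmin(position, P)], NA_character_)
  }
}

#' Expected triplet at a product position
#'
#' For circular templates positions wrap with the circle's triplet period (the
#' triplet expected at position 15 of a 12-period circle is that of position
#' 3); for linear templates positions beyond the reference extension have no
#' template instruction and return \code{NA} (terminal-transferase regime).
#'
#' @param spec A \code{\link{template_spec}}.
#' @param position Integer vector of 1-based triplet positions.
#' @return Character vector of triplets, \code{NA} where undefined.
#' @export
expected_triplet <- function(spec, position) {
  stopifnot(inherits(spec, "template_spec"))
  if (any(position < 1L)) stop("positions are 1-based: got position < 1")
  if (is.null(spec$expected)) {
    stop("template_spec '", spec$name, "' carries no expected triplets")
  }
  expected_at(spec$expected, spec$topology, as.integer(position))
}

#' Number of triplet incorporations completing one full circle
#'
#' @param circle_len_nt Circle length in nt (multiple of 3).
#' @param primer_len_nt Primer length in nt (multiple of 3, shorter than the
#'   circle).
#' @return Integer count of triplet incorporations to full length.
#' @export
#' @examples
#' full_circle_triplets(36, 9)  # 9 bands to full length
full_circle_triplets <- function(circle_len_nt, primer_len_nt) {
  if (circle_len_nt %% 3L != 0L || primer_len_nt %% 3L != 0L) {
    stop("circle and primer lengths must be multiples of 3 nt ",
         "(use a spec-level full_circle_override for odd-length circles)")
  }
  if (primer_len_nt < 0L || circle_len_nt <= primer_len_nt) {
    stop("need circle_len_nt > primer_len_nt >= 0")
  }
  as.integer((circle_len_nt - primer_len_nt) / 3L)
}

#' Full-circle triplet count for a template spec
#'
#' Honors \code{full_circle_override} for circles whose length is not a
#' multiple of 3.
#' @param spec A circular \code{\link{template_spec}}.
#' @return Integer triplet count.
#' @export
spec_full_circle <- function(spec) {
  stopifnot(inherits(spec, "template_spec"))
  if (spec$topology != "circular") stop("not a circular template")
  if (!is.null(spec$full_circle_override)) {
    return(as.integer(spec$full_circle_override))
  }
  full_circle_triplets(spec$circle_len_nt, nchar(spec$primer_seq))
}

#' Product length in nucleotides after k triplet incorporations
#'
#' @param primer_len_nt Primer length in nt.
#' @param k Number of triplet incorporations (k >= 0).
#' @return \code{primer_len_nt + 3 * k}.
#' @export
#' @examples
#' product_length_nt(9, 29)  # 96 nt
product_length_nt <- function(primer_len_nt, k) {
  if (any(k < 0)) stop("k must be >= 0")
  as.integer(primer_len_nt + 3L * as.integer(k))
}

#' Circle coverage of a product
#'
#' Product length divided by circle length: how many times around the circle
#' the product extends (> 1 means beyond-full-length synthesis with strand
#' displacement; e.g. a 96 nt product on a 36 nt circle covers it 2.67 times).
#'
#' @param product_nt Product length in nt.
#' @param circle_nt Circle length in nt (> 0).
#' @return Dimensionless ratio.
#' @export
circle_coverage <- function(product_nt, circle_nt) {
  if (any(circle_nt <= 0)) stop("circle length must be positive")
  product_nt / circle_nt
}
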