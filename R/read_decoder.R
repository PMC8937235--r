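#' Demultiplex reads by exact sample-barcode prefix
#'
#' Assigns each read to the sample whose barcode matches its prefix (0
#' mismatches by default); reads matching no barcode go to the
#' \code{"unmatched"} bin so that read counts are conserved.
#'
#' @param reads Tibble with columns \code{read_id} and \code{seq}.
#' @param barcode_table Named character vector mapping barcode sequence to
#'   sample id; barcodes must be distinct and equal length.
#' @param max_mismatch Hamming tolerance on the barcode prefix (default 0,
#'   exact matching).
#' @return The input tibble with a \code{sample_id} column added
#'   (\code{"unmatched"} where no barcode fits).
#' @export
demultiplex <- function(reads, barcode_table, max_mismatch = 0L) {
  bcs <- rna_to_dna(names(barcode_table))
  if (anyDuplicated(bcs)) stop("duplicate barcodes in barcode_table")
  if (length(unique(nchar(bcs))) != 1L) stop("barcodes must be equal length")
  w <- nchar(bcs[1L])
  prefix <- substr(reads$seq, 1L, w)
  if (max_mismatch == 0L) {
    sample_id <- unname(barcode_table[match(prefix, bcs)])
  } else {
    sample_id <- vapply(prefix, function(p) {
      d <- vapply(bcs, function(b) {
        sum(utf8ToInt(p) != utf8ToInt(b))
      }, numeric(1))
      hits <- which(d <= max_mismatch)
      if (length(hits) == 1L) unname(barcode_table[hits]) else NA_character_
    }, character(1), USE.NAMES = FALSE)
  }
  reads$sample_id <- ifelse(is.na(sample_id), "unmatched", sample_id)
  reads
}

#' Anchor a read at the primer and trim to the extension sequence
#'
#' Locates the first exact occurrence of the primer in each read and returns
#' the subsequence immediately following it; \code{NA} when the primer is
#' absent (such reads are discarded from analysis and counted in the decode
#' summary).
#'
#' @param seqs Character vector of read sequences.
#' @param primer_seq Primer to anchor on (e.g. P9_1 \code{"GAAGAACTG"}).
#' @return Character vector of extension sequences, \code{NA} where the primer
#'   was not found.
#' @export
anchor_and_trim <- function(seqs, primer_seq = PRIMER_P9_1) {
  primer_seq <- rna_to_dna(primer_seq)
  if (nchar(primer_seq) == 0L) stop("primer_seq must be non-empty")
  pos <- regexpr(primer_seq, seqs, fixed = TRUE)
  out <- ifelse(pos > 0L, substring(seqs, pos + nchar(primer_seq)),
                NA_character_)
  out
}

#' Segment an extension sequence into triplets up to the 3' adapter
#'
#' Reads triplets in non-overlapping frame from the first base of the
#' extension sequence up to the first occurrence of the adapter (or the end of
#' the read).  \code{frame_ok} is TRUE when the adapter begins on a triplet
#' boundary; frame-shifted reads keep their complete leading triplets but are
#' excluded from fidelity counting downstream.  Without an adapter, 0-2
#' residual letters are recorded as \code{trailing_bases}.
#'
#' @param ext_seqs Character vector of extension sequences (primer already
#'   trimmed).
#' @param adapter_seq Adapter prefix marking the end of the original RNA
#'   product.
#' @return Tibble with columns \code{triplets} (list of character vectors),
#'   \code{k}, \code{adapter_found}, \code{frame_ok}, \code{trailing_bases}.
#' @export
#' @examples
#' segment_triplets(c("GAAGAAATAGTCGAATATTT", "GAAGA"))
segment_triplets <- function(ext_seqs, adapter_seq = ADAPTER_PREFIX) {
  adapter_seq <- rna_to_dna(adapter_seq)
  apos <- regexpr(adapter_seq, ext_seqs, fixed = TRUE)
  found <- apos > 0L
  body_len <- ifelse(found, apos - 1L, nchar(ext_seqs))
  ntrip <- body_len %/% 3L
  resid <- body_len %% 3L
  frame_ok <- found & resid == 0L
  trailing <- ifelse(found, "",
                     substring(ext_seqs, body_len - resid + 1L, body_len))
  body <- substr(ext_seqs, 1L, ntrip * 3L)
  tibble::tibble(
    triplets = lapply(body, split_triplets),
    k = as.integer(ntrip),
    adapter_found = as.vector(found),
    frame_ok = as.vector(frame_ok),
    trailing_bases = as.vector(trailing))
}

#' Decode raw reads into triplet calls
#'
#' Full decoding pipeline: optional sample demultiplexing, primer anchoring,
#' adapter detection and triplet segmentation.  Matching is exact throughout,
#' mirroring the exact-substring counting the fidelity statistics are defined
#' over.
#'
#' @param reads Tibble with columns \code{read_id}, \code{seq} (e.g. from
#'   \code{\link{read_sequences}} or \code{\link{simulate_dataset}}).
#' @param primer_seq,adapter_seq Anchor sequences.
#' @param barcode_table Optional named vector barcode -> sample id for
#'   demultiplexing before anchoring.
#' @return List of class \code{decoded_reads}: \code{decoded} (tibble:
#'   read_id, sample_id, k, triplets, adapter_found, frame_ok,
#'   trailing_bases; primer-less reads excluded) and \code{summary} (list of
#'   bin counts; assigned + unmatched + no_primer = total).
#' @export
decode_reads <- function(reads, primer_seq = PRIMER_P9_1,
                         adapter_seq = ADAPTER_PREFIX, barcode_table = NULL) {
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  reads$seq <- rna_to_dna(reads$seq)
  if (!is.null(barcode_table)) {
    reads <- demultiplex(reads, barcode_table)
  } else {
    reads$sample_id <- NA_character_
  }
  ext <- anchor_and_trim(reads$seq, primer_seq)
  has_primer <- !is.na(ext)
  seg <- segment_triplets(ext[has_primer], adapter_seq)
  decoded <- tibble::tibble(
    read_id = reads$read_id[has_primer],
    sample_id = reads$sample_id[has_primer])
  decoded <- cbind(decoded, seg)
  decoded <- tibble::as_tibble(decoded)
  per_sample <- if (!is.null(barcode_table)) {
    as.list(table(reads$sample_id))
  } else NULL
  summary <- list(
    total_reads = nrow(reads),
    no_primer = sum(!has_primer),
    decoded = sum(has_primer),
    adapter_found = sum(seg$adapter_found),
    frame_shifted = sum(seg$adapter_found & !seg$frame_ok),
    per_sample = per_sample)
  structure(list(decoded = decoded, summary = summary),
            class = "decoded_reads")
}

#' @export
print.decoded_reads <- function(x, ...) {
  s <- x$summary
  cat("<decoded_reads>", s$decoded, "of", s$total_reads, "reads decoded (",
      s$no_primer, "without primer,", s$frame_shifted, "frame-shifted )\n")
  invisible(x)
}

#' Write decoded reads to a per-sample TSV
#'
#' Columns: read_id, sample_id, k, triplets (comma-joined), adapter_found,
#' frame_ok, trailing_bases.  Triplet positions are 1-based.
#'
#' @param dec A \code{decoded_reads} object or its \code{decoded} tibble.
#' @param path Output TSV path.
#' @export
write_decoded_tsv <- function(dec, path) {
  d <- if (inherits(dec, "decoded_reads")) dec$decoded else dec
  out <- d
  out$triplets <- vapply(d$triplets, paste, character(1), collapse = ",")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read decoded reads back from TSV
#'
#' @param path TSV written by \code{\link{write_decoded_tsv}}.
#' @return Tibble in the \code{decoded} layout (triplets as list-column).
#' @export
read_decoded_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         trailing_bases = readr::col_character(),
                         triplets = readr::col_character()))
  d$trailing_bases[is.na(d$trailing_bases)] <- ""
  d$triplets <- lapply(d$triplets, function(s) {
    if (is.na(s) || s == "") character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
  })
  tibble::as_tibble(d)
}
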