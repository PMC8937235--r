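#' Read sequencing reads from FASTA/FASTQ
#'
#' Format is auto-detected from file content (not the extension); plain and
#' gzip-compressed files are handled transparently and give identical results.
#' FASTQ structure is checked first so that a truncated or malformed record is
#' reported with its record index; parsing itself is delegated to Biostrings.
#'
#' @param path Path to a FASTA or FASTQ file, optionally gzipped.
#' @return Tibble with columns \code{read_id}, \code{seq} (uppercase DNA;
#'   U converted to T).
#' @export
read_sequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) == 0L) {
    return(tibble::tibble(read_id = character(0), seq = character(0)))
  }
  first <- substr(lines[1L], 1L, 1L)
  # parse as raw strings (RNA letters allowed), then normalize to DNA
  if (first == "@") {
    validate_fastq_lines(lines)
    x <- Biostrings::readBStringSet(path, format = "fastq")
  } else if (first == ">") {
    x <- Biostrings::readBStringSet(path, format = "fasta")
  } else {
    stop("cannot detect sequence format of '", path,
         "': first record starts with '", first, "'")
  }
  tibble::tibble(read_id = sub("\\s.*$", "", names(x)),
                 seq = unname(rna_to_dna(as.character(x))))
}

#' @keywords internal
validate_fastq_lines <- function(lines) {
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ parse error at record ", length(lines) %/% 4L + 1L,
         ": truncated record (", length(lines), " lines total)")
  }
  n <- length(lines) %/% 4L
  for (i in seq_len(n)) {
    hdr <- lines[4L * i - 3L]; seq <- lines[4L * i - 2L]
    plus <- lines[4L * i - 1L]; qual <- lines[4L * i]
    if (substr(hdr, 1L, 1L) != "@" || substr(plus, 1L, 1L) != "+" ||
        nchar(seq) != nchar(qual)) {
      stop("FASTQ parse error at record ", i,
           ": malformed record (header/separator/quality mismatch)")
    }
  }
  invisible(TRUE)
}

#' Write reads as FASTQ
#'
#' Quality strings are constant (the analysis is sequence-only); output is
#' gzip-compressed when the path ends in \code{.gz}.  Identical input gives
#' byte-identical output.
#'
#' @param reads Tibble with \code{read_id}, \code{seq}, or a
#'   \code{sim_dataset}.
#' @param path Output path.
#' @param quality Quality character replicated over each read.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path, quality = "I") {
  if (inherits(reads, "sim_dataset")) reads <- reads$reads
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  quals <- Biostrings::BStringSet(strrep(quality, nchar(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Write a ground-truth table as TSV
#'
#' @param sim A \code{sim_dataset} (or its truth tibble).
#' @param path Output path.
#' @export
write_truth_tsv <- function(sim, path) {
  truth <- if (inherits(sim, "sim_dataset")) sim$truth else sim
  out <- truth
  out$triplets <- vapply(truth$triplets, paste, character(1), collapse = ",")
  out$correct <- vapply(truth$correct, function(v) {
    paste(ifelse(is.na(v), "NA", ifelse(v, "1", "0")), collapse = ",")
  }, character(1))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write an analysis summary as JSON
#'
#' @param x Named list of scalars/vectors.
#' @param path Output path.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
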