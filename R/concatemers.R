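#' Length spectrum of fully correct concatemeric products
#'
#' For branched rolling-circle synthesis, counts decoded reads that carry
#' exactly k triplets, every one equal to the product's expected triplet at
#' that position, and end in the 3' adapter on a triplet boundary — the
#' "correct sequence of a specific length ending in the adapter" criterion.
#' Lengths and circle coverages are derived from the product geometry.  A read
#' can only match several products where their expected triplets agree through
#' its whole length (shared prefixes at small k); such reads are counted for
#' each matching product and the total is reported in the
#' \code{multi_matched} attribute.
#'
#' @param decoded Decoded-read tibble (see \code{\link{decode_reads}}).
#' @param products Named list of \code{\link{template_spec}}s for the products
#'   (e.g. the bundled \code{sc8211_I} / \code{sc8211_II}).
#' @param k_range Integer range of triplet incorporations to count
#'   (default 9:30).
#' @param require_adapter Count only adapter-terminated, in-frame reads
#'   (default TRUE; disabling it can only increase counts).
#' @return Tibble of class \code{spectrum_table} with columns \code{product},
#'   \code{k}, \code{n}, \code{length_nt}, \code{circle_coverage}.
#' @export
count_correct_products <- function(decoded, products, k_range = 9:30,
                                   require_adapter = TRUE) {
  k_range <- sort(as.integer(k_range))
  rows <- list()
  match_count <- integer(nrow(decoded))
  for (pp in products) {
    exp_vec <- expected_triplet(pp, seq_len(max(k_range)))
    primer_len <- nchar(pp$primer_seq)
    circ <- pp$circle_len_nt
    n_k <- stats::setNames(integer(length(k_range)), k_range)
    for (r in seq_len(nrow(decoded))) {
      k <- decoded$k[r]
      if (!(k %in% k_range)) next
      if (require_adapter &&
          !(decoded$adapter_found[r] && decoded$frame_ok[r])) next
      trips <- decoded$triplets[[r]]
      if (all(trips == exp_vec[seq_len(k)])) {
        n_k[as.character(k)] <- n_k[as.character(k)] + 1L
        match_count[r] <- match_count[r] + 1L
      }
    }
    len <- product_length_nt(primer_len, k_range)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      product = pp$name, k = k_range, n = unname(n_k), length_nt = len,
      circle_coverage = circle_coverage(len, circ))
  }
  out <- do.call(rbind, rows)
  attr(out, "multi_matched") <- sum(match_count > 1L)
  class(out) <- c("spectrum_table", class(out))
  out
}

#' Summarize a concatemer length spectrum
#'
#' @param table A \code{\link{count_correct_products}} result.
#' @return List with \code{per_product} (tibble: product, max_k, length_nt,
#'   circle_coverage for the longest observed product of each kind) and
#'   \code{overall} (the single longest observed product).
#' @export
spectrum_summary <- function(table) {
  obs <- table[table$n > 0, , drop = FALSE]
  if (nrow(obs) == 0L) stop("no products observed in spectrum table")
  per <- do.call(rbind, lapply(split(obs, obs$product), function(d) {
    d[which.max(d$k), c("product", "k", "length_nt", "circle_coverage")]
  }))
  names(per)[names(per) == "k"] <- "max_k"
  overall <- per[which.max(per$max_k), ]
  list(per_product = tibble::as_tibble(per),
       overall = tibble::as_tibble(overall))
}
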