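#' Load template specifications from a YAML fixture
#'
#' Parses a YAML document describing templates/products (see the bundled
#' \code{templates.yaml}) into a named list of \code{\link{template_spec}}
#' objects.  The bundled fixture carries the four one-pot templates A-D in
#' circular and linear form and the two branched-synthesis products I/II on the
#' double-primed 36 nt circle; barcode slots at positions 6 and 9 are
#' synthetic placeholders (documented in the fixture) and can be edited there.
#'
#' @param path Path to a YAML file; defaults to the bundled fixture.
#' @return Named list of \code{template_spec} objects (names are fixture entry
#'   names, e.g. \code{A_circ}); the list carries \code{alphabet},
#'   \code{primer} and \code{adapter} attributes.
#' @export
#' @examples
#' tpls <- load_template_specs()
#' names(tpls)
load_template_specs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "templates.yaml", package = "tripletRCS",
                        mustWork = TRUE)
  }
  doc <- yaml::read_yaml(path)
  alphabet <- triplet_alphabet(unlist(doc$alphabet))
  specs <- lapply(doc$templates, function(t) {
    template_spec(
      name = t$template %||% t$name,
      topology = t$topology,
      primer_seq = t$primer %||% doc$primer,
      expected = if (!is.null(t$expected)) unlist(t$expected),
      circle_len_nt = t$circle_len_nt,
      barcode_positions = t$barcodes %||% list(),
      instruction_len = t$instruction_len,
      full_circle_override = t$full_circle_override,
      alphabet = alphabet)
  })
  names(specs) <- vapply(doc$templates, function(t) t$name, character(1))
  attr(specs, "alphabet") <- alphabet
  attr(specs, "primer") <- rna_to_dna(doc$primer)
  attr(specs, "adapter") <- rna_to_dna(doc$adapter %||% ADAPTER_PREFIX)
  specs
}

#' Position-3 barcode map for template classification
#'
#' @param specs Named list of \code{template_spec}s (subset to one topology
#'   before calling if both are present).
#' @param position Barcode position used for classification (default 3, the
#'   first barcode slot).
#' @return Named character vector mapping barcode triplet to template name.
#' @export
barcode_map <- function(specs, position = 3L) {
  key <- as.character(position)
  bc <- vapply(specs, function(s) {
    b <- s$barcode_positions[[key]]
    if (is.null(b)) NA_character_ else b
  }, character(1))
  tpl <- vapply(specs, function(s) s$name, character(1))
  keep <- !is.na(bc)
  bc <- bc[keep]; tpl <- tpl[keep]
  if (anyDuplicated(bc)) {
    stop("duplicate barcode triplets at position ", position,
         " across templates")
  }
  stats::setNames(tpl, bc)
}
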