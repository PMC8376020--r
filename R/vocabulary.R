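#' Canonical vocabulary of the synoptic survey design
#'
#' Every other function in the package validates its inputs against these
#' tokens. Solutes are the six dissolved species quantified in the survey;
#' seasons are the three synoptic sampling events; categories are the four
#' land-use/hydrology classes of subwatershed.
#'
#' @return A character vector of canonical tokens.
#' @name vocabulary
NULL

#' @rdname vocabulary
#' @export
watershed_solutes <- function() {
  c("DOC", "TDN", "DIN", "PO4", "Cl", "SO4")
}

#' @rdname vocabulary
#' @export
watershed_seasons <- function() {
  c("Spring", "Summer", "Fall")
}

#' @rdname vocabulary
#' @export
watershed_categories <- function() {
  c("AgriculturalUnregulated", "MixedDammed", "MountainUrban",
    "ValleyTributaries")
}

#' @rdname vocabulary
#' @export
land_cover_classes <- function() {
  c("forest", "developed", "impervious", "herbaceous")
}

# Fold a token for case/punctuation-insensitive matching ("Mixed dammed",
# "mixed_dammed" and "MixedDammed" all normalise to "mixeddammed").
normalize_token <- function(x) {
  gsub("[^a-z0-9]", "", tolower(as.character(x)))
}

# Map raw tokens onto a canonical vocabulary; unknown tokens abort with the
# offending values and the field name.
match_vocabulary <- function(x, vocabulary, field, extra = character()) {
  vocab <- c(vocabulary, extra)
  idx <- match(normalize_token(x), normalize_token(vocab))
  if (anyNA(idx[!is.na(x)])) {
    bad <- unique(x[is.na(idx) & !is.na(x)])
    stop(sprintf(
      "unknown %s token(s): %s (expected one of: %s)",
      field, paste(sQuote(bad), collapse = ", "),
      paste(vocab, collapse = ", ")
    ), call. = FALSE)
  }
  vocab[idx]
}
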