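#' Genetic code table
#'
#' Wraps an NCBI translation table as used for codon classification throughout
#' the package. The default is table 11 (bacterial, archaeal and plant
#' plastid), which is identical to the standard code (table 1) for all
#' internal codons; it differs only in which codons may initiate translation,
#' which plays no role in substitution counting.
#'
#' @param table_id NCBI genetic-code table identifier (integer or string),
#'   e.g. `11` or `1`.
#' @return An object of class `coremk_genetic_code`: a list with `table_id`
#'   and `map`, a named character vector over all 64 DNA codons with `"*"`
#'   marking stop codons.
#' @examples
#' code <- genetic_code(11)
#' code$map[c("ATG", "TAA")]
#' @export
genetic_code <- function(table_id = 11) {
  map <- tryCatch(
    Biostrings::getGeneticCode(as.character(table_id)),
    error = function(e) {
      coremk_abort(
        sprintf("unknown genetic code table id '%s'", table_id),
        "input_error"
      )
    }
  )
  map <- map[order(names(map))]
  structure(
    list(table_id = table_id, map = map),
    class = "coremk_genetic_code"
  )
}

#' @export
print.coremk_genetic_code <- function(x, ...) {
  cat(sprintf(
    "<genetic code: table %s, %d stop codons (%s)>\n",
    x$table_id, sum(x$map == "*"),
    paste(stop_codons(x), collapse = ", ")
  ))
  invisible(x)
}

#' Stop and sense codons of a genetic code
#'
#' @param code A [genetic_code()] object.
#' @return Character vector of codons.
#' @export
stop_codons <- function(code) {
  names(code$map)[code$map == "*"]
}

#' @rdname stop_codons
#' @export
sense_codons <- function(code) {
  names(code$map)[code$map != "*"]
}

#' Translate codons
#'
#' Vectorised codon-to-amino-acid translation. Codons containing characters
#' other than A/C/G/T (gaps, ambiguity codes) translate to `"X"`.
#'
#' @param codons Character vector of 3-letter DNA codons.
#' @param code A [genetic_code()] object.
#' @return Character vector of single-letter amino acids (`"*"` = stop).
#' @export
translate_codons <- function(codons, code = genetic_code(11)) {
  aa <- unname(code$map[codons])
  aa[is.na(aa)] <- "X"
  aa
}
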