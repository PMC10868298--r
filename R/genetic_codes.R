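#' Genetic-code tables and codon state spaces
#'
#' Codon models index their states by the *sense* codons of a genetic code
#' (61 for the universal code, 60 for the vertebrate mitochondrial code).
#' The state-index convention used throughout the package is lexicographic
#' codon order over the nucleotide alphabet (T, C, A, G), i.e. TTT, TTC,
#' TTA, TTG, TCT, ... with stop codons removed.
#'
#' @param code Genetic-code name: `"universal"` (standard nuclear code) or
#'   `"vertebrate_mitochondrial"`.
#' @return `genetic_code()` returns a named character vector mapping all 64
#'   codons (in T/C/A/G lexicographic order) to one-letter amino-acid codes,
#'   with `"*"` marking stop codons. `sense_codons()` returns the character
#'   vector of sense codons in state-index order.
#' @examples
#' length(sense_codons("universal"))                # 61
#' length(sense_codons("vertebrate_mitochondrial")) # 60
#' @export
genetic_code <- function(code = "universal") {
  id <- switch(code,
    universal = "1",
    standard = "1",
    vertebrate_mitochondrial = "2",
    stop("unsupported-code: unknown genetic code '", code, "'")
  )
  tab <- Biostrings::getGeneticCode(id)
  # reorder into T,C,A,G lexicographic codon order (the state convention)
  tab[sort_codons_tcag()]
}

# all 64 codons in lexicographic (T,C,A,G) order, first position slowest
sort_codons_tcag <- function() {
  nts <- c("T", "C", "A", "G")
  out <- character(64)
  k <- 1L
  for (a in nts) for (b in nts) for (d in nts) {
    out[k] <- paste0(a, b, d)
    k <- k + 1L
  }
  out
}

#' @rdname genetic_code
#' @export
sense_codons <- function(code = "universal") {
  tab <- genetic_code(code)
  names(tab)[tab != "*"]
}
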