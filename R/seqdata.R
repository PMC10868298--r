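# ---------------------------------------------------------------------------
# Alignments, site-pattern compression and tip-state encoding.
#
# An alignment stores N equal-length character rows.  `width` is the number
# of characters per state symbol: 1 for nucleotides, 3 for codon alignments
# (rows remain nucleotide text; they are interpreted in frame-aligned
# triplets once translated).
# ---------------------------------------------------------------------------

new_alignment <- function(taxon_names, rows, width = 1L, code_tag = NULL) {
  structure(list(taxon_names = taxon_names, rows = toupper(rows),
                 width = as.integer(width), code_tag = code_tag),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment:", length(x$rows), "taxa x", nchar(x$rows[1]), "characters",
      if (x$width == 3L) "(codon)" else "(nucleotide)", "\n")
  invisible(x)
}

aln_n_columns <- function(aln) nchar(aln$rows[1]) %/% aln$width

#' Read a FASTA alignment
#'
#' All sequences must have equal length; characters are upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return An `alignment` object (nucleotide width).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) pg_stop("input_error", "file-not-found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    pg_stop("parse_error", "parse-error: ", conditionMessage(e)))
  if (length(set) == 0)
    pg_stop("parse_error", "parse-error: empty FASTA file")
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    pg_stop("parse_error", "parse-error: duplicate FASTA header '",
            nm[duplicated(nm)][1], "'")
  lens <- Biostrings::width(set)
  if (length(unique(lens)) != 1)
    pg_stop("alignment_error",
            "alignment-error: sequences have unequal lengths")
  new_alignment(nm, unname(as.character(set)))
}

#' Write an alignment as FASTA
#'
#' @param aln An `alignment`.
#' @param path Output path.
#' @param wrap Line width for sequence wrapping (default 70).
#' @export
write_fasta <- function(aln, path, wrap = 70L) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(aln$rows)) {
    cat(">", aln$taxon_names[i], "\n", sep = "", file = con)
    s <- aln$rows[i]
    starts <- seq(1, nchar(s), by = wrap)
    for (st in starts)
      cat(substr(s, st, min(st + wrap - 1, nchar(s))), "\n",
          sep = "", file = con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# State maps: symbol -> set of compatible state indices
# ---------------------------------------------------------------------------

iupac_nucleotide_sets <- function() {
  list(A = 1L, C = 2L, G = 3L, T = 4L, U = 4L,
       R = c(1L, 3L), Y = c(2L, 4L), S = c(2L, 3L), W = c(1L, 4L),
       K = c(3L, 4L), M = c(1L, 2L),
       B = c(2L, 3L, 4L), D = c(1L, 3L, 4L), H = c(1L, 2L, 4L),
       V = c(1L, 2L, 3L),
       N = 1:4, "-" = 1:4, "?" = 1:4, X = 1:4)
}

#' State maps for tip encoding
#'
#' A state map translates alignment symbols into sets of compatible state
#' indices.  The nucleotide map indexes states (A, C, G, T) = (1, 2, 3, 4)
#' and supports the full IUPAC ambiguity alphabet plus gap (`-`) and `?`
#' as fully ambiguous.  The codon map indexes the sense codons of a
#' genetic code lexicographically over (T, C, A, G); triplets containing
#' ambiguous nucleotides expand to the set of compatible sense codons.
#'
#' @param code Genetic-code name for `codon_state_map`.
#' @return A `state_map` list with fields `kind`, `S` (state count),
#'   `width` (symbol width in characters), and `compat(symbol)` returning
#'   the integer vector of compatible states.
#' @export
nucleotide_state_map <- function() {
  sets <- iupac_nucleotide_sets()
  structure(list(kind = "nucleotide", S = 4L, width = 1L,
                 alphabet = c("A", "C", "G", "T"),
                 compat = function(symbol) {
                   s <- sets[[symbol]]
                   if (is.null(s))
                     pg_stop("encoding_error",
                             "encoding-error: unmappable character '",
                             symbol, "'")
                   s
                 }),
            class = "state_map")
}

#' @rdname nucleotide_state_map
#' @export
codon_state_map <- function(code = "universal") {
  codons <- sense_codons(code)
  S <- length(codons)
  cmat <- do.call(rbind, strsplit(codons, ""))
  nsets <- iupac_nucleotide_sets()
  nts <- c("A", "C", "G", "T")
  compat <- function(symbol) {
    if (nchar(symbol) != 3)
      pg_stop("encoding_error", "encoding-error: codon symbol '", symbol,
              "' is not a triplet")
    letters3 <- strsplit(symbol, "")[[1]]
    ok <- rep(TRUE, S)
    for (p in 1:3) {
      s <- nsets[[letters3[p]]]
      if (is.null(s))
        pg_stop("encoding_error",
                "encoding-error: unmappable character '", letters3[p], "'")
      ok <- ok & cmat[, p] %in% nts[s]
    }
    w <- which(ok)
    if (!length(w))
      pg_stop("encoding_error",
              "encoding-error: codon '", symbol,
              "' matches no sense codon (stop codon?)")
    w
  }
  structure(list(kind = "codon", S = S, width = 3L, alphabet = codons,
                 compat = compat, code_tag = code),
            class = "state_map")
}

# ---------------------------------------------------------------------------
# Pattern compression
# ---------------------------------------------------------------------------

#' Compress an alignment into unique site patterns
#'
#' Identical columns share all downstream computation; each unique pattern
#' carries an integer weight (its column count).  Pattern order is the
#' order of first occurrence, so per-pattern outputs are reproducible.
#'
#' @param aln An `alignment`.
#' @param state_map A `state_map` matching the alignment's symbol width
#'   (default chosen from the width: nucleotide for 1, universal codon for
#'   3 unless the alignment carries a code tag).
#' @return A `pattern_alignment` with fields `pattern_count`, `weights`,
#'   `symbols` (N x C character matrix), `state_map`, `state_count` and
#'   `taxon_names`.
#' @export
compress_patterns <- function(aln, state_map = NULL) {
  if (is.null(state_map)) {
    state_map <- if (aln$width == 3L)
      codon_state_map(if (is.null(aln$code_tag)) "universal" else aln$code_tag)
    else nucleotide_state_map()
  }
  if (state_map$width != aln$width)
    pg_stop("encoding_error", "encoding-error: state-map width ",
            state_map$width, " does not match alignment width ", aln$width)
  N <- length(aln$rows)
  C0 <- aln_n_columns(aln)
  if (C0 < 1) pg_stop("alignment_error", "alignment-error: empty alignment")
  # N x C0 symbol matrix
  sym <- matrix("", N, C0)
  for (n in seq_len(N)) {
    starts <- (seq_len(C0) - 1L) * aln$width + 1L
    sym[n, ] <- substring(aln$rows[n], starts, starts + aln$width - 1L)
  }
  # validate all symbols once (names taxon/column on failure)
  for (n in seq_len(N)) for (c in seq_len(C0)) {
    tryCatch(state_map$compat(sym[n, c]), phylograd_error = function(e)
      pg_stop("encoding_error", conditionMessage(e), " (taxon '",
              aln$taxon_names[n], "', column ", c, ")"))
  }
  keys <- apply(sym, 2, paste, collapse = "\r")
  first <- !duplicated(keys)
  ukeys <- keys[first]
  idx <- match(keys, ukeys)
  weights <- tabulate(idx, nbins = length(ukeys))
  structure(list(pattern_count = length(ukeys),
                 weights = as.integer(weights),
                 symbols = sym[, first, drop = FALSE],
                 pattern_of_column = idx,
                 state_map = state_map,
                 state_count = state_map$S,
                 taxon_names = aln$taxon_names),
            class = "pattern_alignment")
}

#' @export
print.pattern_alignment <- function(x, ...) {
  cat("pattern_alignment:", length(x$taxon_names), "taxa,",
      x$pattern_count, "unique patterns (", sum(x$weights),
      "columns ), S =", x$state_count, "\n")
  invisible(x)
}

#' Translate a nucleotide alignment to codon states
#'
#' Interprets the alignment in frame-aligned, non-overlapping triplets.
#' Triplets containing IUPAC-ambiguous or gap nucleotides become codon
#' ambiguity sets (all compatible sense codons) at encoding time.
#'
#' @param aln A nucleotide `alignment`.
#' @param code Genetic-code name.
#' @param frame 0-based reading-frame offset (default 0); leading
#'   `frame` nucleotides are discarded.
#' @param strict If `TRUE` (default) an unambiguous internal stop codon is
#'   an error; if `FALSE` stop codons become fully ambiguous (`NNN`).
#' @return A codon-width `alignment` tagged with the code.
#' @export
translate_codons <- function(aln, code = "universal", frame = 0L,
                             strict = TRUE) {
  if (aln$width != 1L)
    pg_stop("encoding_error", "encoding-error: alignment is not nucleotide")
  L <- nchar(aln$rows[1])
  if ((L - frame) %% 3 != 0)
    pg_stop("alignment_error",
            "alignment-error: length minus frame offset not divisible by 3")
  tab <- genetic_code(code)
  stops <- names(tab)[tab == "*"]
  rows <- substring(aln$rows, frame + 1L, L)
  Ccod <- (L - frame) %/% 3
  out <- character(length(rows))
  for (n in seq_along(rows)) {
    starts <- (seq_len(Ccod) - 1L) * 3L + 1L
    trip <- substring(rows[n], starts, starts + 2L)
    bad <- trip %in% stops
    if (any(bad)) {
      if (strict)
        pg_stop("encoding_error", "encoding-error: internal stop codon ",
                trip[bad][1], " in taxon '", aln$taxon_names[n],
                "', codon position ", which(bad)[1])
      trip[bad] <- "NNN"
    }
    out[n] <- paste(trip, collapse = "")
  }
  new_alignment(aln$taxon_names, out, width = 3L, code_tag = code)
}

#' Encode tip states for the likelihood engine
#'
#' Per taxon and pattern, an unambiguously observed state is kept as a
#' single integer; ambiguity/gap symbols become indicator vectors with a 1
#' at every compatible state (all-ones for fully unknown).  Both the
#' compressed integer codes and the dense S x C indicator partials are
#' returned; the engine consumes the partials.
#'
#' @param pa A `pattern_alignment`.
#' @return List with `states` (N x C integer matrix, NA where ambiguous)
#'   and `partials` (list of N dense S x C indicator matrices).
#' @export
encode_tips <- function(pa) {
  N <- length(pa$taxon_names)
  C <- pa$pattern_count
  S <- pa$state_count
  states <- matrix(NA_integer_, N, C)
  partials <- vector("list", N)
  cache <- new.env(parent = emptyenv())
  for (n in seq_len(N)) {
    m <- matrix(0, S, C)
    for (c in seq_len(C)) {
      symbol <- pa$symbols[n, c]
      set <- get0(symbol, envir = cache, inherits = FALSE)
      if (is.null(set)) {
        set <- pa$state_map$compat(symbol)
        assign(symbol, set, envir = cache)
      }
      m[set, c] <- 1
      if (length(set) == 1L) states[n, c] <- set
    }
    partials[[n]] <- m
  }
  list(states = states, partials = partials)
}

#' Export unique patterns and weights as TSV
#'
#' Columns: `pattern` (1-based index in first-occurrence order), `weight`,
#' then one symbol column per taxon.
#'
#' @param pa A `pattern_alignment`.
#' @param path Output path.
#' @export
write_patterns_tsv <- function(pa, path) {
  df <- data.frame(pattern = seq_len(pa$pattern_count),
                   weight = pa$weights,
                   t(pa$symbols), check.names = FALSE)
  names(df)[-(1:2)] <- pa$taxon_names
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
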