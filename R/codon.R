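#' Read a codon usage table
#'
#' The TSV has columns `aa`, `codon`, `freq` (relative frequency of each
#' codon within its amino acid). The table is validated: every amino acid
#' needs at least one codon, frequencies per amino acid must sum to 1 within
#' 1e-9, and each codon must translate to its stated amino acid under the
#' standard genetic code.
#'
#' @param path Path to the TSV; defaults to the shipped human usage table.
#' @return A tibble `aa`, `codon`, `freq` of class `codon_table`.
#' @export
read_codon_table <- function(path = codon_table_path()) {
  if (!file.exists(path)) abort(sprintf("Codon table not found: %s", path))
  tab <- readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      aa = readr::col_character(),
      codon = readr::col_character(),
      freq = readr::col_double()
    )
  )
  if (!all(c("aa", "codon", "freq") %in% names(tab))) {
    abort(sprintf("Codon table '%s' must have columns aa, codon, freq.", path))
  }
  tab <- mutate(tab, aa = toupper(.data$aa), codon = toupper(.data$codon))
  code <- Biostrings::GENETIC_CODE
  bad <- which(is.na(code[tab$codon]) | code[tab$codon] != tab$aa)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Codon '%s' does not translate to amino acid '%s' under the standard genetic code.",
      tab$codon[bad[1]], tab$aa[bad[1]]
    ))
  }
  sums <- tapply(tab$freq, tab$aa, sum)
  off <- which(abs(sums - 1) > 1e-9)
  if (length(off) > 0L) {
    abort(sprintf(
      "Codon frequencies for amino acid '%s' sum to %.12f, not 1.",
      names(sums)[off[1]], sums[off[1]]
    ))
  }
  structure(tab, class = c("codon_table", class(tibble())))
}

#' @rdname read_codon_table
#' @export
codon_table_path <- function() {
  system.file("extdata", "codon_usage_human.tsv", package = "optoxr", mustWork = TRUE)
}

#' Back-translate a protein to codon-optimized DNA
#'
#' Produces a DNA coding sequence whose translation under the standard
#' genetic code reproduces the protein exactly. In `most_frequent` mode every
#' residue gets its most frequent codon (ties broken alphabetically), which
#' is fully deterministic; in `weighted` mode codons are sampled
#' proportionally to their usage frequency, deterministically for a given
#' `seed`.
#'
#' @param protein A `protein_seq` (or one-row sequence tibble).
#' @param table A `codon_table` from [read_codon_table()].
#' @param mode `"most_frequent"` or `"weighted"`.
#' @param seed Integer seed, required for `weighted` mode.
#' @param append_stop Append a stop codon (`TAA`) when `TRUE`.
#' @return A character scalar of DNA (length `3 * n` residues, plus 3 for
#'   the stop if requested).
#' @examples
#' back_translate(protein_seq("m", "M"), read_codon_table())
#' @export
back_translate <- function(protein, table = read_codon_table(),
                           mode = c("most_frequent", "weighted"),
                           seed = NULL, append_stop = FALSE) {
  if (is.data.frame(protein) && !inherits(protein, "protein_seq")) {
    protein <- as_protein_list(protein)[[1]]
  }
  mode <- match.arg(mode)
  res <- seq_chars(protein)
  missing <- setdiff(unique(res), unique(table$aa))
  if (length(missing) > 0L) {
    abort(sprintf("Amino acid '%s' absent from the codon table.", missing[1]))
  }
  by_aa <- split(table[, c("codon", "freq")], table$aa)
  if (mode == "most_frequent") {
    best <- map_chr(by_aa, function(d) {
      d <- d[order(-d$freq, d$codon), ]
      d$codon[1]
    })
    codons <- best[res]
  } else {
    if (is.null(seed)) abort("`weighted` mode requires a `seed`.")
    codons <- withr::with_seed(as.integer(seed), {
      map_chr(res, function(r) {
        d <- by_aa[[r]]
        if (nrow(d) == 1L) d$codon else sample(d$codon, 1L, prob = d$freq)
      })
    })
  }
  dna <- paste(codons, collapse = "")
  if (append_stop) dna <- paste0(dna, "TAA")
  dna
}

#' Translate a DNA coding sequence under the standard genetic code
#'
#' @param dna Character scalar whose length is a multiple of 3. A single
#'   terminal stop codon is dropped.
#' @return The protein as a character scalar.
#' @export
translate_dna <- function(dna) {
  dna <- toupper(dna)
  if (nchar(dna) %% 3 != 0) abort("DNA length is not a multiple of 3.")
  codons <- substring(dna, seq(1, nchar(dna), 3), seq(3, nchar(dna), 3))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) abort(sprintf("Unknown codon '%s'.", codons[which(is.na(aa))[1]]))
  if (length(aa) > 1L && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) abort("Internal stop codon in DNA.")
  paste(aa, collapse = "")
}
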