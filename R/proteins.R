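#' Construct a protein sequence record
#'
#' A lightweight container for a single protein: an identifier, its residues
#' (uppercase one-letter codes over the 20 canonical amino acids plus `X`),
#' and a free-text description.
#'
#' @param id Non-empty character scalar identifier.
#' @param residues Character scalar of residues; lowercase input is
#'   uppercased, a single terminal `*` (stop) is stripped.
#' @param description Optional free-text description.
#' @return A list of class `protein_seq` with fields `id`, `residues`,
#'   `description`.
#' @examples
#' protein_seq("r1", "MKT")
#' @export
protein_seq <- function(id, residues, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    abort("`id` must be a non-empty character scalar.")
  }
  if (!is.character(residues) || length(residues) != 1L) {
    abort("`residues` must be a character scalar.")
  }
  residues <- toupper(residues)
  residues <- sub("\\*$", "", residues)
  if (!nzchar(residues)) {
    abort(sprintf("Sequence '%s' is empty.", id))
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Sequence '%s' contains illegal residue '%s' at position %d.",
      id, chars[bad[1]], bad[1]
    ))
  }
  structure(
    list(id = id, residues = residues, description = description),
    class = "protein_seq"
  )
}

#' @export
print.protein_seq <- function(x, ...) {
  cat(sprintf(
    "<protein_seq> %s (%d aa)%s\n", x$id, nchar(x$residues),
    if (nzchar(x$description)) paste0(" - ", x$description) else ""
  ))
  invisible(x)
}

seq_length <- function(p) nchar(p$residues)

seq_chars <- function(p) strsplit(p$residues, "", fixed = TRUE)[[1]]

#' Read protein sequences from a FASTA file
#'
#' Records are validated against the amino-acid alphabet (20 canonical
#' residues plus `X`); residues are uppercased and a terminal `*` stop is
#' stripped. Any input line wrapping is tolerated.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record and columns `id`, `residues`,
#'   `description`; also retrievable as `protein_seq` objects via
#'   [as_protein_list()].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r toy", "MKT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("Failed to parse FASTA '%s': %s", path, conditionMessage(e)))
  )
  if (length(set) == 0L) abort(sprintf("FASTA file is empty: %s", path))
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate record id '%s' in %s", ids[duplicated(ids)][1], path))
  }
  recs <- purrr::pmap(
    list(ids, as.character(set), desc),
    function(i, r, d) protein_seq(i, r, d)
  )
  tibble(
    id = map_chr(recs, "id"),
    residues = map_chr(recs, "residues"),
    description = map_chr(recs, "description")
  )
}

#' Convert a sequence tibble to a list of `protein_seq` records
#'
#' @param x A tibble as returned by [read_fasta()], or a single `protein_seq`.
#' @return A named list of `protein_seq` objects.
#' @export
as_protein_list <- function(x) {
  if (inherits(x, "protein_seq")) return(setNames(list(x), x$id))
  stopifnot(is.data.frame(x), all(c("id", "residues") %in% names(x)))
  desc <- if ("description" %in% names(x)) x$description else rep("", nrow(x))
  out <- purrr::pmap(list(x$id, x$residues, desc), protein_seq)
  setNames(out, x$id)
}

#' Write protein sequences to a FASTA file
#'
#' Output is wrapped at 60 residues per line.
#'
#' @param x A sequence tibble (`id`, `residues`, optional `description`) or a
#'   `protein_seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  recs <- as_protein_list(x)
  set <- Biostrings::BStringSet(map_chr(recs, "residues"))
  desc <- map_chr(recs, "description")
  names(set) <- ifelse(
    nzchar(desc), paste(map_chr(recs, "id"), desc), map_chr(recs, "id")
  )
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
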