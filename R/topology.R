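#' Build and validate a receptor topology
#'
#' A topology is the ordered list of named segments (NTERM, TM1-TM7, ICL1-3,
#' ECL1-3, optional H8, CTERM) covering every residue of a receptor exactly
#' once, with 1-based inclusive coordinates.
#'
#' @param segments A data frame with columns `segment`, `start`, `end`.
#' @param sequence A `protein_seq` (or tibble row) the topology annotates.
#' @return A tibble of class `gpcr_topology` with columns `segment`, `start`,
#'   `end` and attribute `sequence_id`.
#' @export
topology <- function(segments, sequence) {
  seq <- if (is.data.frame(sequence)) as_protein_list(sequence)[[1]] else sequence
  stopifnot(inherits(seq, "protein_seq"))
  stopifnot(is.data.frame(segments), all(c("segment", "start", "end") %in% names(segments)))
  seg <- tibble(
    segment = as.character(segments$segment),
    start = as.integer(segments$start),
    end = as.integer(segments$end)
  )
  validate_topology(seg, seq_length(seq), seq$id)
  structure(seg, class = c("gpcr_topology", class(tibble())), sequence_id = seq$id)
}

validate_topology <- function(seg, L, id) {
  unknown <- setdiff(seg$segment, SEGMENT_ORDER)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown segment name '%s' in topology for '%s'.", unknown[1], id))
  }
  if (anyDuplicated(seg$segment)) {
    abort(sprintf("Duplicated segment name in topology for '%s'.", id))
  }
  ord <- match(seg$segment, SEGMENT_ORDER)
  if (is.unsorted(ord, strictly = TRUE)) {
    abort(sprintf(
      "Segments out of canonical N-to-C order in topology for '%s' (at '%s').",
      id, seg$segment[which(diff(ord) <= 0)[1] + 1L]
    ))
  }
  if (any(seg$start > seg$end) || any(seg$start < 1L)) {
    bad <- seg$segment[which(seg$start > seg$end | seg$start < 1L)[1]]
    abort(sprintf("Invalid coordinates for segment '%s' in topology for '%s'.", bad, id))
  }
  if (seg$start[1] != 1L) {
    abort(sprintf("Topology for '%s' must start at residue 1.", id))
  }
  if (nrow(seg) > 1L) {
    gaps <- which(seg$start[-1] != seg$end[-nrow(seg)] + 1L)
    if (length(gaps) > 0L) {
      abort(sprintf(
        "Gap or overlap between segments '%s' and '%s' in topology for '%s'.",
        seg$segment[gaps[1]], seg$segment[gaps[1] + 1L], id
      ))
    }
  }
  if (seg$end[nrow(seg)] != L) {
    abort(sprintf(
      "Topology for '%s' covers residues 1..%d but the sequence has %d residues.",
      id, seg$end[nrow(seg)], L
    ))
  }
  invisible(seg)
}

#' Load a topology annotation from a TSV file
#'
#' The file has a header `segment<TAB>start<TAB>end` and 1-based inclusive
#' residue ranges. Lines starting with `#` are ignored. The annotation is
#' validated against the supplied sequence: segments must be contiguous,
#' non-overlapping, in canonical N-to-C order and jointly cover the whole
#' sequence.
#'
#' @param path Path to the topology TSV.
#' @param sequence The `protein_seq` (or one-row tibble) the file annotates.
#' @return A `gpcr_topology` tibble.
#' @export
load_topology <- function(path, sequence) {
  if (!file.exists(path)) abort(sprintf("Topology file not found: %s", path))
  seg <- readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      segment = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer()
    )
  )
  if (!identical(names(seg), c("segment", "start", "end"))) {
    abort(sprintf("Topology TSV '%s' must have columns segment, start, end.", path))
  }
  topology(seg, sequence)
}

#' Default backbone topology shipped with the package
#'
#' Returns the path of the implementer-provided topology TSV for the
#' synthetic rhodopsin-like backbone. The exact helix boundaries of the
#' authors' backbone are not published; this file is an editable stand-in
#' that users should replace with their own annotation for real designs.
#'
#' @return Path to the TSV file.
#' @export
default_topology_path <- function() {
  system.file("extdata", "rhodopsin_topology_synthetic.tsv", package = "optoxr", mustWork = TRUE)
}

segment_range <- function(topo, name) {
  i <- match(name, topo$segment)
  if (is.na(i)) return(NULL)
  c(topo$start[i], topo$end[i])
}
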