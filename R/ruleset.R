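#' Build a chimera cut-site rule set
#'
#' A rule set declares, per topology segment, whether the chimera takes its
#' residues from the light-sensitive backbone opsin or from the target
#' receptor, plus the boundary-offset parameters that place the actual cut
#' sites:
#'
#' * `V1` (legacy design): all three intracellular loops (ICL1-3) and the
#'   C-terminus come from the target; all TM helices, extracellular loops and
#'   the N-terminus stay backbone. `cterm_cut_shift` is 0.
#' * `V2` (optimized design): ICL1 is kept from the backbone (its residues do
#'   not contribute to G-protein binding), ICL2, ICL3 and the C-terminus come
#'   from the target, and the C-terminal exchange point is moved
#'   `cterm_cut_shift` residues into TM7 to capture G-protein contact sites.
#' * `custom`: caller supplies the full per-segment source map.
#'
#' `proximal_tm_offset` flanking TM residues on each side of a swapped ICL
#' are taken from the target as well. H8, when annotated, follows the
#' C-terminus. The epitope (default `TETSQVAPA`, the rhodopsin 1D4 tag used
#' for comparative immunolabeling) is appended after the C-terminus.
#'
#' @param version One of `"V1"`, `"V2"`, `"custom"`.
#' @param source_by_segment Named character vector mapping segment names to
#'   `"BACKBONE"`/`"TARGET"`; required for `custom`, must not override the
#'   preset maps for V1/V2.
#' @param proximal_tm_offset Non-negative integer; default 2.
#' @param cterm_cut_shift Non-negative integer; defaults 0 (V1) / 8 (V2).
#' @param epitope Epitope appended at the C-terminus; `""` disables.
#' @param keep_icl1 For V1 only: keep the backbone ICL1 (the published
#'   two-loop V1 variant).
#' @return A list of class `chimera_ruleset`.
#' @examples
#' make_ruleset("V2")
#' @export
make_ruleset <- function(version = c("V1", "V2", "custom"),
                         source_by_segment = NULL,
                         proximal_tm_offset = 2L,
                         cterm_cut_shift = NULL,
                         epitope = "TETSQVAPA",
                         keep_icl1 = FALSE) {
  if (length(version) != 1L || !version %in% c("V1", "V2", "custom")) {
    abort(sprintf("Unknown ruleset version '%s'.", paste(version, collapse = ",")[1]))
  }
  proximal_tm_offset <- as.integer(proximal_tm_offset)
  if (is.na(proximal_tm_offset) || proximal_tm_offset < 0L) {
    abort("`proximal_tm_offset` must be a non-negative integer.")
  }
  base_map <- setNames(rep("BACKBONE", length(SEGMENT_ORDER)), SEGMENT_ORDER)
  if (version == "V1") {
    src <- base_map
    src[c(if (!keep_icl1) "ICL1", "ICL2", "ICL3", "H8", "CTERM")] <- "TARGET"
    shift <- cterm_cut_shift %||% 0L
    if (shift != 0L) abort("V1 fixes `cterm_cut_shift` at 0.")
  } else if (version == "V2") {
    src <- base_map
    src[c("ICL2", "ICL3", "H8", "CTERM")] <- "TARGET"
    shift <- cterm_cut_shift %||% 8L
    if (shift <= 0L) abort("V2 requires `cterm_cut_shift` > 0.")
  } else {
    if (is.null(source_by_segment)) {
      abort("`custom` rule sets require a full `source_by_segment` map.")
    }
    src <- base_map
    src[names(source_by_segment)] <- toupper(source_by_segment)
    shift <- cterm_cut_shift %||% 0L
  }
  if (version != "custom" && !is.null(source_by_segment)) {
    abort(sprintf("Segment sources are fixed by the %s preset; use version = 'custom'.", version))
  }
  if (!all(src %in% c("BACKBONE", "TARGET"))) {
    abort("Segment sources must be 'BACKBONE' or 'TARGET'.")
  }
  # H8 follows the C-terminal exchange group
  src[["H8"]] <- src[["CTERM"]]
  shift <- as.integer(shift)
  if (is.na(shift) || shift < 0L) abort("`cterm_cut_shift` must be a non-negative integer.")
  if (nzchar(epitope)) {
    ep <- strsplit(toupper(epitope), "", fixed = TRUE)[[1]]
    if (!all(ep %in% setdiff(AA_ALPHABET, "X"))) {
      abort("Epitope contains non-alphabet characters.")
    }
    epitope <- paste(ep, collapse = "")
  }
  structure(
    list(
      name = version,
      source_by_segment = src,
      proximal_tm_offset = proximal_tm_offset,
      cterm_cut_shift = shift,
      epitope = epitope
    ),
    class = "chimera_ruleset"
  )
}

#' @export
print.chimera_ruleset <- function(x, ...) {
  tgt <- names(x$source_by_segment)[x$source_by_segment == "TARGET"]
  cat(sprintf(
    "<chimera_ruleset> %s: target-sourced {%s}, proximal_tm_offset %d, cterm_cut_shift %d, epitope '%s'\n",
    x$name, paste(tgt, collapse = ","), x$proximal_tm_offset, x$cterm_cut_shift, x$epitope
  ))
  invisible(x)
}
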