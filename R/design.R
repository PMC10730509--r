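#' Design a chimeric optoXR
#'
#' The core stitching algorithm. The chimera is assembled N- to C-terminally
#' by walking the backbone topology: each segment's residues are copied from
#' its assigned source — backbone coordinates for backbone-sourced segments,
#' alignment-projected target coordinates for target-sourced ones. For a
#' swapped intracellular loop, `proximal_tm_offset` flanking residues on each
#' TM side are taken from the target too; for a target-sourced C-terminus
#' with `cterm_cut_shift = k`, the exchange begins `k` residues before the
#' backbone TM7/C-terminus boundary. The epitope, if any, is appended last.
#'
#' @param backbone Backbone `protein_seq` (or one-row sequence tibble).
#' @param backbone_topology `gpcr_topology` annotating the backbone.
#' @param target Target `protein_seq` (or one-row sequence tibble).
#' @param ruleset A `chimera_ruleset` from [make_ruleset()].
#' @param colmap Optional `alignment_colmap`; computed with [global_align()]
#'   under default scoring when omitted.
#' @param id Identifier for the chimera; a sensible default is derived from
#'   the target id and rule set name.
#' @return A `chimera_design`: list with fields `chimera` (a `protein_seq`),
#'   `provenance` (tibble with one row per chimera residue: `position`,
#'   `source`, `source_id`, `source_index`, `segment`), `ruleset`,
#'   `backbone_source` (per-backbone-residue source mask) and `inputs`
#'   (ids and content checksums).
#' @export
design_chimera <- function(backbone, backbone_topology, target, ruleset,
                           colmap = NULL, id = NULL) {
  if (is.data.frame(backbone)) backbone <- as_protein_list(backbone)[[1]]
  if (is.data.frame(target)) target <- as_protein_list(target)[[1]]
  stopifnot(inherits(ruleset, "chimera_ruleset"))
  L_b <- seq_length(backbone)
  L_t <- seq_length(target)
  if (!identical(attr(backbone_topology, "sequence_id"), backbone$id) ||
      backbone_topology$end[nrow(backbone_topology)] != L_b) {
    abort("`backbone_topology` does not annotate `backbone`.")
  }
  if (is.null(colmap)) colmap <- global_align(backbone, target)
  check_colmap_covers(colmap, L_b, L_t)

  topo <- backbone_topology
  src_map <- ruleset$source_by_segment
  missing <- setdiff(topo$segment, names(src_map))
  if (length(missing) > 0L) {
    abort(sprintf("Rule set has no source assignment for segment '%s'.", missing[1]))
  }

  # per-backbone-residue source mask
  mask <- character(L_b)
  for (k in seq_len(nrow(topo))) {
    mask[topo$start[k]:topo$end[k]] <- src_map[[topo$segment[k]]]
  }
  # proximal TM residues flanking swapped ICLs come from the target
  p <- ruleset$proximal_tm_offset
  if (p > 0L) {
    for (icl in ICL_SEGMENTS) {
      r <- segment_range(topo, icl)
      if (!is.null(r) && src_map[[icl]] == "TARGET") {
        lo <- max(1L, r[1] - p)
        hi <- min(L_b, r[2] + p)
        mask[lo:hi] <- "TARGET"
      }
    }
  }
  # C-terminal exchange point moved into TM7
  cterm_group <- intersect(c("H8", "CTERM"), topo$segment)
  if (length(cterm_group) > 0L && src_map[["CTERM"]] == "TARGET" &&
      ruleset$cterm_cut_shift > 0L) {
    gstart <- min(map_int(cterm_group, ~ segment_range(topo, .x)[1]))
    lo <- max(1L, gstart - ruleset$cterm_cut_shift)
    mask[lo:L_b] <- "TARGET"
  }

  seg_of_backbone <- character(L_b)
  for (k in seq_len(nrow(topo))) {
    seg_of_backbone[topo$start[k]:topo$end[k]] <- topo$segment[k]
  }
  B <- target_boundary_fun(colmap, L_b, L_t)
  # backbone segment context of each target residue (for provenance labels)
  seg_of_target <- seg_of_backbone[findInterval(seq_len(L_t) - 0.5, B[-1]) + 1L]

  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  tchars <- seq_chars(target)
  bchars <- seq_chars(backbone)

  prov <- vector("list", length(runs$values))
  for (k in seq_along(runs$values)) {
    a <- starts[k]; b <- ends[k]
    if (runs$values[k] == "BACKBONE") {
      prov[[k]] <- tibble(
        source = "BACKBONE", source_id = backbone$id,
        source_index = a:b, residue = bchars[a:b],
        segment = seg_of_backbone[a:b]
      )
    } else {
      t_lo <- B[(a - 1L) + 1L] + 1L
      t_hi <- B[b + 1L]
      if (t_lo > t_hi) {
        abort(sprintf(
          "Projected segment '%s' collapses to zero length on the target.",
          seg_of_backbone[a]
        ))
      }
      res <- tchars[t_lo:t_hi]
      if (any(res == "X")) {
        abort(sprintf(
          "Target residues %d..%d selected for exchange (segment '%s') contain 'X'.",
          t_lo, t_hi, seg_of_backbone[a]
        ))
      }
      prov[[k]] <- tibble(
        source = "TARGET", source_id = target$id,
        source_index = t_lo:t_hi, residue = res,
        segment = seg_of_target[t_lo:t_hi]
      )
    }
  }
  prov <- bind_rows(prov)
  if (nzchar(ruleset$epitope)) {
    ep <- strsplit(ruleset$epitope, "", fixed = TRUE)[[1]]
    prov <- bind_rows(prov, tibble(
      source = "EPITOPE", source_id = "1D4",
      source_index = seq_along(ep), residue = ep, segment = "EPITOPE"
    ))
  }
  prov <- mutate(prov, position = dplyr::row_number(), .before = 1)

  chimera_id <- id %||% paste0("opto", target$id, "_", ruleset$name)
  chimera <- protein_seq(
    chimera_id, paste(prov$residue, collapse = ""),
    sprintf("chimera of %s segments on %s backbone (%s rules)", target$id, backbone$id, ruleset$name)
  )
  structure(
    list(
      chimera = chimera,
      provenance = prov,
      ruleset = ruleset,
      backbone_source = mask,
      backbone_segments = seg_of_backbone,
      inputs = list(
        backbone_id = backbone$id, target_id = target$id,
        backbone_checksum = rlang::hash(backbone$residues),
        target_checksum = rlang::hash(target$residues),
        alignment_checksum = rlang::hash(list(colmap$backbone_index, colmap$target_index))
      )
    ),
    class = "chimera_design"
  )
}

#' @export
print.chimera_design <- function(x, ...) {
  nb <- nrow(provenance_blocks(x))
  cat(sprintf(
    "<chimera_design> %s: %d aa, %d provenance blocks (%s rules; %s segments on %s backbone)\n",
    x$chimera$id, seq_length(x$chimera), nb, x$ruleset$name,
    x$inputs$target_id, x$inputs$backbone_id
  ))
  invisible(x)
}

#' Contiguous same-source provenance blocks of a design
#'
#' @param design A `chimera_design`.
#' @return A tibble with one row per maximal run of residues copied
#'   contiguously from one source: `start`, `end` (chimera coordinates),
#'   `source`, `source_id`, `source_start`, `source_end`, `segment` (the
#'   segment at the block start).
#' @export
provenance_blocks <- function(design) {
  p <- design$provenance
  brk <- c(TRUE, p$source[-1] != p$source[-nrow(p)] |
             p$source_id[-1] != p$source_id[-nrow(p)] |
             p$source_index[-1] != p$source_index[-nrow(p)] + 1L)
  grp <- cumsum(brk)
  p |>
    mutate(.block = grp) |>
    group_by(.data$.block) |>
    summarise(
      start = min(.data$position), end = max(.data$position),
      source = .data$source[1], source_id = .data$source_id[1],
      source_start = min(.data$source_index), source_end = max(.data$source_index),
      segment = .data$segment[1], .groups = "drop"
    ) |>
    select(-".block")
}

#' Compare two chimera designs built from the same backbone/target pair
#'
#' Reports the backbone residue ranges whose source assignment differs
#' between the two designs, labelled by backbone segment (e.g. V1 vs V2
#' differ at ICL1 and at the C-terminal junction).
#'
#' @param a,b `chimera_design` objects sharing backbone and target.
#' @return A tibble with columns `start`, `end` (backbone coordinates),
#'   `segment`, `source_a`, `source_b`; zero rows for identical designs.
#' @export
diff_designs <- function(a, b) {
  stopifnot(inherits(a, "chimera_design"), inherits(b, "chimera_design"))
  same <- identical(a$inputs$backbone_checksum, b$inputs$backbone_checksum) &&
    identical(a$inputs$target_checksum, b$inputs$target_checksum)
  if (!same) {
    abort("Designs were not built from the same backbone/target pair (checksum mismatch).")
  }
  ma <- a$backbone_source; mb <- b$backbone_source
  seg_names <- a$backbone_segments
  differs <- ma != mb
  if (!any(differs)) {
    return(tibble(
      start = integer(0), end = integer(0), segment = character(0),
      source_a = character(0), source_b = character(0)
    ))
  }
  r <- rle(paste(differs, seg_names, ma, mb, sep = "\r"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- differs[starts]
  tibble(
    start = starts[keep], end = ends[keep],
    segment = seg_names[starts[keep]],
    source_a = ma[starts[keep]], source_b = mb[starts[keep]]
  )
}

#' Write a chimera design to FASTA and GFF3
#'
#' The chimera goes out as a single FASTA record (60-column wrapping); the
#' per-residue provenance map goes out as GFF3 in protein coordinates
#' (1-based inclusive), one feature per contiguous same-source block, with
#' attributes recording the source sequence id, source coordinates, segment
#' name and rule set.
#'
#' @param design A `chimera_design`.
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_design_outputs <- function(design, fasta_path, gff3_path) {
  stopifnot(inherits(design, "chimera_design"))
  write_fasta(design$chimera, fasta_path)
  blocks <- provenance_blocks(design)
  gr <- GenomicRanges::GRanges(
    seqnames = design$chimera$id,
    ranges = IRanges::IRanges(start = blocks$start, end = blocks$end)
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "optoxr",
    type = "sequence_feature",
    block_source = blocks$source,
    source_seq = blocks$source_id,
    source_start = blocks$source_start,
    source_end = blocks$source_end,
    segment = blocks$segment,
    ruleset = design$ruleset$name
  )
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(list(fasta = fasta_path, gff3 = gff3_path))
}
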