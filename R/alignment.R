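#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-delimited matrix format used by NCBI BLAST
#' (`#` comment lines, a header row of residue codes, one labelled row per
#' residue). The matrix must be symmetric.
#'
#' @param path Path to the matrix file. Defaults to the BLOSUM62 copy shipped
#'   with the package.
#' @return An integer matrix with residue dimnames, class `subst_matrix`.
#' @export
read_substitution_matrix <- function(path = blosum62_path()) {
  if (!file.exists(path)) abort(sprintf("Matrix file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  labs <- map_chr(rows, 1)
  vals <- map(rows, ~ as.integer(.x[-1]))
  if (any(lengths(vals) != length(header))) {
    abort(sprintf("Malformed substitution matrix '%s': ragged rows.", path))
  }
  m <- do.call(rbind, vals)
  dimnames(m) <- list(labs, header)
  if (!identical(rownames(m), colnames(m)) || !isSymmetric(unname(m))) {
    abort(sprintf("Substitution matrix '%s' is not symmetric.", path))
  }
  structure(m, name = sub("\\.[^.]*$", "", basename(path)), class = c("subst_matrix", "matrix", "array"))
}

#' @rdname read_substitution_matrix
#' @export
blosum62_path <- function() {
  system.file("extdata", "BLOSUM62.txt", package = "optoxr", mustWork = TRUE)
}

subst_score <- function(matrix, a, b) {
  missing <- setdiff(unique(c(a, b)), rownames(matrix))
  if (length(missing) > 0L) {
    abort(sprintf("Residue '%s' absent from substitution matrix.", missing[1]))
  }
  matrix[cbind(a, b)]
}

new_colmap <- function(backbone_index, target_index, score, backbone_id, target_id) {
  cm <- tibble(backbone_index = backbone_index, target_index = target_index)
  structure(
    cm, class = c("alignment_colmap", class(tibble())),
    score = score, backbone_id = backbone_id, target_id = target_id
  )
}

#' @export
print.alignment_colmap <- function(x, ...) {
  cat(sprintf(
    "<alignment_colmap> %s vs %s: %d columns, score %g\n",
    attr(x, "backbone_id"), attr(x, "target_id"), nrow(x), attr(x, "score")
  ))
  NextMethod()
}

# gap cost of one gap of length len: open + (len - 1) * extend
gap_cost <- function(len, gap_open, gap_extend) gap_open + (len - 1) * gap_extend

#' Score an alignment column map
#'
#' Recomputes the alignment score of a column map from scratch: the sum of
#' substitution scores over residue-residue columns minus, for every maximal
#' gap run of length `len`, `gap_open + (len - 1) * gap_extend`.
#'
#' @param colmap An `alignment_colmap`.
#' @param a,b The two `protein_seq` records the map aligns (backbone, target).
#' @param matrix Substitution matrix from [read_substitution_matrix()].
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return Numeric scalar score.
#' @export
score_colmap <- function(colmap, a, b, matrix = read_substitution_matrix(),
                         gap_open = 11, gap_extend = 1) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  bi <- colmap$backbone_index; ti <- colmap$target_index
  both <- !is.na(bi) & !is.na(ti)
  s <- sum(subst_score(matrix, ca[bi[both]], cb[ti[both]]))
  for (gap_in in list(is.na(bi), is.na(ti))) {
    r <- rle(gap_in)
    lens <- r$lengths[r$values]
    if (length(lens) > 0L) s <- s - sum(gap_cost(lens, gap_open, gap_extend))
  }
  s
}

#' Global pairwise protein alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment maximizing the sum of substitution
#' scores minus affine gap penalties (a gap of length `len` costs
#' `gap_open + (len - 1) * gap_extend`; terminal gaps are penalized like
#' internal ones). Traceback tie-breaking is fixed: at every cell a
#' substitution is preferred over a gap in the target, which is preferred
#' over a gap in the backbone, so output is bit-stable.
#'
#' @param a Backbone `protein_seq` (or one-row sequence tibble).
#' @param b Target `protein_seq` (or one-row sequence tibble).
#' @param matrix Substitution matrix; defaults to the shipped BLOSUM62.
#' @param gap_open,gap_extend Non-negative penalties, `gap_extend <= gap_open`.
#' @return An `alignment_colmap`: a tibble of aligned index pairs
#'   (`backbone_index`, `target_index`, `NA` = gap) with attributes `score`,
#'   `backbone_id`, `target_id`.
#' @examples
#' a <- protein_seq("a", "ACDE")
#' global_align(a, a)
#' @export
global_align <- function(a, b, matrix = read_substitution_matrix(),
                         gap_open = 11, gap_extend = 1) {
  if (is.data.frame(a)) a <- as_protein_list(a)[[1]]
  if (is.data.frame(b)) b <- as_protein_list(b)[[1]]
  stopifnot(inherits(a, "protein_seq"), inherits(b, "protein_seq"))
  if (gap_open < 0 || gap_extend < 0 || gap_extend > gap_open) {
    abort("Require 0 <= gap_extend <= gap_open.")
  }
  ca <- seq_chars(a); cb <- seq_chars(b)
  n <- length(ca); m <- length(cb)
  missing <- setdiff(unique(c(ca, cb)), rownames(matrix))
  if (length(missing) > 0L) {
    abort(sprintf("Residue '%s' absent from substitution matrix.", missing[1]))
  }
  S <- matrix[ca, cb, drop = FALSE]

  NEG <- -.Machine$double.xmax / 4
  # state matrices: M residue-residue, X gap in target (consumes a),
  # Y gap in backbone (consumes b); (n+1) x (m+1), index 1 = zero prefix
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (n > 0L) X[2L:(n + 1L), 1L] <- -gap_cost(seq_len(n), gap_open, gap_extend)
  if (m > 0L) Y[1L, 2L:(m + 1L)] <- -gap_cost(seq_len(m), gap_open, gap_extend)

  for (i in seq_len(n)) {
    ip <- i; ic <- i + 1L
    js <- 2L:(m + 1L)
    # M and X depend only on the previous row/column block: vectorized
    M[ic, js] <- pmax(M[ip, js - 1L], X[ip, js - 1L], Y[ip, js - 1L]) + S[i, ]
    X[ic, js] <- pmax(M[ip, js] - gap_open, X[ip, js] - gap_extend, Y[ip, js] - gap_open)
    # Y depends on the current row: every Y value is some M/X entry of this
    # row followed by one gap run, so a running maximum closes the recursion
    W <- pmax(M[ic, 1L:m], X[ic, 1L:m])
    k <- 0L:(m - 1L)
    Y[ic, js] <- cummax(W + k * gap_extend) - gap_open - k * gap_extend
  }

  final <- c(M = M[n + 1L, m + 1L], X = X[n + 1L, m + 1L], Y = Y[n + 1L, m + 1L])
  state <- names(final)[which.max(final)]  # which.max takes the first: M > X > Y
  score <- unname(final[state])

  # traceback, preferring M > X > Y at every choice
  bi <- integer(0); ti <- integer(0)
  i <- n; j <- m
  pick <- function(vals) c("M", "X", "Y")[which.max(vals)]
  while (i > 0L || j > 0L) {
    if (state == "M") {
      bi <- c(i, bi); ti <- c(j, ti)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      i <- i - 1L; j <- j - 1L
      if (i == 0L && j == 0L) break
      state <- pick(prev)
    } else if (state == "X") {
      bi <- c(i, bi); ti <- c(NA_integer_, ti)
      prev <- c(M[i, j + 1L] - gap_open, X[i, j + 1L] - gap_extend, Y[i, j + 1L] - gap_open)
      i <- i - 1L
      if (i == 0L && j == 0L) break
      state <- pick(prev)
    } else {
      bi <- c(NA_integer_, bi); ti <- c(j, ti)
      prev <- c(M[i + 1L, j] - gap_open, X[i + 1L, j] - gap_open, Y[i + 1L, j] - gap_extend)
      j <- j - 1L
      if (i == 0L && j == 0L) break
      state <- pick(prev)
    }
  }
  new_colmap(bi, ti, score, a$id, b$id)
}

#' Import an externally computed pairwise alignment
#'
#' Reads an aligned FASTA file (gap character `-`), extracts the two named
#' records and converts them to a column map. The score is recomputed under
#' the supplied matrix and gap parameters, so externally produced alignments
#' (e.g. from an MSA program) are directly comparable to [global_align()].
#'
#' @param path Aligned FASTA file containing at least the two records.
#' @param backbone_id,target_id Record ids to extract.
#' @inheritParams score_colmap
#' @return An `alignment_colmap`.
#' @export
import_alignment <- function(path, backbone_id, target_id,
                             matrix = read_substitution_matrix(),
                             gap_open = 11, gap_extend = 1) {
  if (!file.exists(path)) abort(sprintf("Alignment file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  for (want in c(backbone_id, target_id)) {
    if (!want %in% ids) abort(sprintf("Record '%s' not found in alignment '%s'.", want, path))
  }
  ga <- toupper(as.character(set[[match(backbone_id, ids)]]))
  gb <- toupper(as.character(set[[match(target_id, ids)]]))
  if (nchar(ga) != nchar(gb)) {
    abort(sprintf(
      "Aligned records '%s' (%d) and '%s' (%d) have unequal lengths.",
      backbone_id, nchar(ga), target_id, nchar(gb)
    ))
  }
  cga <- strsplit(ga, "", fixed = TRUE)[[1]]
  cgb <- strsplit(gb, "", fixed = TRUE)[[1]]
  if (any(cga == "-" & cgb == "-")) {
    abort(sprintf("All-gap column at position %d.", which(cga == "-" & cgb == "-")[1]))
  }
  bi <- ifelse(cga == "-", NA_integer_, cumsum(cga != "-"))
  ti <- ifelse(cgb == "-", NA_integer_, cumsum(cgb != "-"))
  a <- protein_seq(backbone_id, gsub("-", "", ga, fixed = TRUE))
  b <- protein_seq(target_id, gsub("-", "", gb, fixed = TRUE))
  cm <- new_colmap(as.integer(bi), as.integer(ti), 0, backbone_id, target_id)
  attr(cm, "score") <- score_colmap(cm, a, b, matrix, gap_open, gap_extend)
  cm
}

check_colmap_covers <- function(colmap, n_backbone, n_target = NULL) {
  bi <- colmap$backbone_index[!is.na(colmap$backbone_index)]
  if (!identical(as.integer(bi), seq_len(n_backbone))) {
    abort("Alignment column map does not cover the backbone sequence exactly once, in order.")
  }
  if (!is.null(n_target)) {
    ti <- colmap$target_index[!is.na(colmap$target_index)]
    if (!identical(as.integer(ti), seq_len(n_target))) {
      abort("Alignment column map does not cover the target sequence exactly once, in order.")
    }
  }
  invisible(colmap)
}

# For each backbone prefix 0..n, the largest target index aligned in any
# column at or before the column of backbone residue e (0 if none). This is
# the boundary projection: a boundary falling on a target gap shifts toward
# the interior of the preceding segment, i.e. the nearest earlier non-gap
# target column.
target_boundary_fun <- function(colmap, n_backbone, n_target) {
  last_t <- 0L
  B <- integer(n_backbone + 1L)  # B[e + 1] = boundary after backbone residue e
  e <- 0L
  for (k in seq_len(nrow(colmap))) {
    ti <- colmap$target_index[k]
    if (!is.na(ti)) last_t <- ti
    bi <- colmap$backbone_index[k]
    if (!is.na(bi)) {
      e <- bi
      B[e + 1L] <- last_t
    }
  }
  B[1L] <- 0L
  B[n_backbone + 1L] <- n_target  # trailing target insertions belong to the last segment
  # boundaries are monotone by construction; enforce cumulative max for safety
  cummax(B)
}

#' Project a backbone topology onto the target via an alignment
#'
#' Each backbone segment boundary is carried across the alignment to the
#' homologous target residue. When the target is gapped at a boundary column
#' the boundary shifts to the nearest non-gap column toward the interior of
#' the preceding segment, so the projected segments always tile the target
#' sequence. A segment whose projection collapses to zero length is an error.
#'
#' @param backbone_topology A `gpcr_topology` for the backbone.
#' @param colmap An `alignment_colmap` covering the backbone.
#' @param target The target `protein_seq` (used for its length and id).
#' @return A `gpcr_topology` on target coordinates.
#' @export
project_topology <- function(backbone_topology, colmap, target) {
  if (is.data.frame(target) && !inherits(target, "protein_seq")) {
    target <- as_protein_list(target)[[1]]
  }
  n_b <- backbone_topology$end[nrow(backbone_topology)]
  n_t <- seq_length(target)
  check_colmap_covers(colmap, n_b, n_t)
  B <- target_boundary_fun(colmap, n_b, n_t)
  t_start <- B[backbone_topology$start - 1L + 1L] + 1L
  t_end <- B[backbone_topology$end + 1L]
  collapsed <- which(t_start > t_end)
  if (length(collapsed) > 0L) {
    abort(sprintf(
      "Projected segment '%s' collapses to zero length on the target.",
      backbone_topology$segment[collapsed[1]]
    ))
  }
  topology(
    tibble(segment = backbone_topology$segment, start = t_start, end = t_end),
    target
  )
}
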