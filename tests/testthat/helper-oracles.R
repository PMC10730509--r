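# Independent exhaustive-enumeration oracle for global affine-gap alignment.
# All monotone alignment paths for sequence lengths (n, m) are enumerated
# once and cached in a vectorized layout: a long index vector of the
# substitution columns of every path plus a per-path gap cost, so scoring a
# concrete sequence pair is a single table lookup + rowsum.

.path_cache <- new.env(parent = emptyenv())

enumerate_paths <- function(n, m) {
  key <- paste(n, m, sep = "_")
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  rec <- function(n, m) {
    if (n == 0 && m == 0) return(list(character(0)))
    out <- list()
    if (n > 0 && m > 0) out <- c(out, lapply(rec(n - 1, m - 1), function(p) c(p, "D")))
    if (n > 0) out <- c(out, lapply(rec(n - 1, m), function(p) c(p, "X")))
    if (m > 0) out <- c(out, lapply(rec(n, m - 1), function(p) c(p, "Y")))
    out
  }
  paths <- rec(n, m)
  pid <- integer(0); iv <- integer(0); jv <- integer(0)
  n_gaps <- numeric(length(paths)); extra <- numeric(length(paths))
  for (k in seq_along(paths)) {
    p <- paths[[k]]
    i <- cumsum(p != "Y")
    j <- cumsum(p != "X")
    sub <- p == "D"
    pid <- c(pid, rep.int(k, sum(sub)))
    iv <- c(iv, i[sub]); jv <- c(jv, j[sub])
    lens <- with(rle(p), lengths[values != "D"])
    n_gaps[k] <- length(lens)
    extra[k] <- sum(lens - 1)
  }
  res <- list(pid = pid, iv = iv, jv = jv, n_gaps = n_gaps, extra = extra,
              n_paths = length(paths))
  .path_cache[[key]] <- res
  res
}

# maximum global alignment score by exhaustive enumeration
brute_align_score <- function(a, b, matrix, gap_open = 11, gap_extend = 1) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  pz <- enumerate_paths(length(ca), length(cb))
  subtot <- numeric(pz$n_paths)
  if (length(pz$pid) > 0) {
    s <- matrix[cbind(ca[pz$iv], cb[pz$jv])]
    agg <- rowsum(s, pz$pid)
    subtot[as.integer(rownames(agg))] <- agg[, 1]
  }
  max(subtot - pz$n_gaps * gap_open - pz$extra * gap_extend)
}

# the worked stitching example: marker blocks WLLLW / YKKKY span the ICL
toy_example <- function() {
  bb <- protein_seq("bb", "MAAAWLLLWAAAC")
  tg <- protein_seq("tg", "MGGGYKKKYGGGD")
  topo <- topology(
    tibble::tibble(
      segment = c("NTERM", "TM1", "ICL1", "TM2", "CTERM"),
      start = c(1, 2, 5, 10, 13),
      end = c(1, 4, 9, 12, 13)
    ),
    bb
  )
  list(backbone = bb, target = tg, topology = topo)
}

# all-backbone ruleset for a given topology (identity design)
identity_ruleset <- function(topo) {
  make_ruleset(
    "custom",
    source_by_segment = setNames(rep("BACKBONE", nrow(topo)), topo$segment),
    proximal_tm_offset = 0L, epitope = ""
  )
}

random_protein <- function(n, seed) {
  withr::with_seed(seed, {
    paste(sample(setdiff(optoxr:::AA_ALPHABET, "X"), n, replace = TRUE), collapse = "")
  })
}
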