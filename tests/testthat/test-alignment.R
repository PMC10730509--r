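mat <- read_substitution_matrix()

test_that("gap-free identity alignments score as the matrix diagonal sum", {
  al <- global_align(protein_seq("a", "ACDE"), protein_seq("b", "ACDE"), mat)
  expect_equal(nrow(al), 4L)
  expect_false(anyNA(al$backbone_index))
  expect_false(anyNA(al$target_index))
  # oracle: diagonal entries A, C, D, E of the shipped matrix
  expect_equal(attr(al, "score"), sum(diag(mat[c("A", "C", "D", "E"), c("A", "C", "D", "E")])))
  expect_equal(attr(al, "score"), 24)

  single <- global_align(protein_seq("m", "M"), protein_seq("m2", "M"), mat)
  expect_equal(nrow(single), 1L)
  expect_equal(attr(single, "score"), mat["M", "M"])
})

test_that("optimal score equals exhaustive enumeration on random short pairs", {
  ab <- c("A", "C", "D", "E")
  withr::with_seed(202, {
    for (k in 1:400) {
      a <- paste(sample(ab, sample(1:5, 1), TRUE), collapse = "")
      b <- paste(sample(ab, sample(1:5, 1), TRUE), collapse = "")
      al <- global_align(protein_seq("a", a), protein_seq("b", b), mat)
      expect_equal(attr(al, "score"), brute_align_score(a, b, mat))
    }
  })
})

test_that("score is symmetric and recomputable from the column list", {
  withr::with_seed(77, {
    aa <- rownames(mat)[1:20]
    for (k in 1:25) {
      a <- protein_seq("a", paste(sample(aa, sample(3:30, 1), TRUE), collapse = ""))
      b <- protein_seq("b", paste(sample(aa, sample(3:30, 1), TRUE), collapse = ""))
      al <- global_align(a, b, mat)
      expect_equal(attr(al, "score"), score_colmap(al, a, b, mat))
      expect_equal(attr(al, "score"),
                   attr(global_align(b, a, mat), "score"))
    }
  })
})

test_that("column maps satisfy their invariants", {
  withr::with_seed(12, {
    aa <- rownames(mat)[1:20]
    for (k in 1:20) {
      na <- sample(2:25, 1); nb <- sample(2:25, 1)
      a <- protein_seq("a", paste(sample(aa, na, TRUE), collapse = ""))
      b <- protein_seq("b", paste(sample(aa, nb, TRUE), collapse = ""))
      al <- global_align(a, b, mat)
      bi <- al$backbone_index[!is.na(al$backbone_index)]
      ti <- al$target_index[!is.na(al$target_index)]
      expect_identical(as.integer(bi), seq_len(na))
      expect_identical(as.integer(ti), seq_len(nb))
      expect_false(any(is.na(al$backbone_index) & is.na(al$target_index)))
    }
  })
})

test_that("aligner agrees with an independent affine-gap implementation", {
  skip_if_not_installed("Biostrings")
  # Biostrings charges gapOpening + len * gapExtension per gap, so its
  # opening penalty maps to ours minus one extension
  data(BLOSUM62, package = "Biostrings", envir = environment())
  withr::with_seed(31, {
    aa <- rownames(mat)[1:20]
    for (k in 1:15) {
      a <- paste(sample(aa, sample(10:60, 1), TRUE), collapse = "")
      b <- paste(sample(aa, sample(10:60, 1), TRUE), collapse = "")
      ours <- attr(global_align(protein_seq("a", a), protein_seq("b", b), mat), "score")
      ref <- Biostrings::score(Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 1, type = "global"
      ))
      expect_equal(ours, ref)
    }
  })
})

test_that("import_alignment parses gapped FASTA and recomputes the score", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bb", "AC-E", ">tg", "ACDE"), fa)
  al <- import_alignment(fa, "bb", "tg", mat)
  expect_equal(al$backbone_index, c(1L, 2L, NA, 3L))
  expect_equal(al$target_index, 1:4)
  expect_equal(
    attr(al, "score"),
    mat["A", "A"] + mat["C", "C"] + mat["E", "E"] - 11
  )

  writeLines(c(">bb", "AC-E", ">tg", "ACDEF"), fa)
  expect_error(import_alignment(fa, "bb", "tg", mat), "unequal lengths")
  writeLines(c(">bb", "AC-E", ">tg", "AC-E"), fa)
  expect_error(import_alignment(fa, "bb", "tg", mat), "All-gap column")
  writeLines(c(">bb", "ACDE"), fa)
  expect_error(import_alignment(fa, "bb", "tg", mat), "'tg' not found")
})

test_that("topology projection: identity, insertion and boundary-gap cases", {
  # identity alignment projects boundaries onto themselves
  toy <- make_toy_gpcr(seed = 4)
  al <- global_align(toy$sequence, toy$sequence, mat)
  proj <- project_topology(toy$topology, al, toy$sequence)
  expect_equal(proj$start, toy$topology$start)
  expect_equal(proj$end, toy$topology$end)

  # one extra target residue inside ICL1 stretches ICL1 and shifts TM2
  bb <- protein_seq("bb", "AAAAWLLWAAAA")
  topo <- topology(
    tibble::tibble(segment = c("TM1", "ICL1", "TM2"),
                   start = c(1, 5, 9), end = c(4, 8, 12)),
    bb
  )
  afa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bb", "AAAAWL-LWAAAA", ">tg", "AAAAWLKLWAAAA"), afa)
  tg <- protein_seq("tg", "AAAAWLKLWAAAA")
  al2 <- import_alignment(afa, "bb", "tg", mat)
  proj2 <- project_topology(topo, al2, tg)
  expect_equal(proj2$start, c(1L, 5L, 10L))
  expect_equal(proj2$end, c(4L, 9L, 13L))

  # boundary column where the target is gapped: boundary shifts to the
  # nearest interior non-gap target residue
  bb3 <- protein_seq("bb", "AAAW")
  topo3 <- topology(
    tibble::tibble(segment = c("TM1", "ICL1"), start = c(1, 4), end = c(3, 4)),
    bb3
  )
  writeLines(c(">bb", "AAAW", ">tg", "AA-W"), afa)
  tg3 <- protein_seq("tg", "AAW")
  proj3 <- project_topology(topo3, import_alignment(afa, "bb", "tg", mat), tg3)
  expect_equal(proj3$end, c(2L, 3L))

  # projection preserves coverage on random pairs whenever nothing collapses
  # (a collapsing segment is a defined error and excluded from the property)
  n_ok <- 0L
  for (k in 1:10) {
    t1 <- make_toy_gpcr(seed = 100 + k)
    t2 <- make_toy_gpcr(seed = 200 + k, id = "t2")
    p <- tryCatch(
      project_topology(t1$topology, global_align(t1$sequence, t2$sequence, mat), t2$sequence),
      error = function(e) NULL
    )
    if (is.null(p)) next
    n_ok <- n_ok + 1L
    expect_equal(p$start[1], 1L)
    expect_equal(p$end[nrow(p)], nchar(t2$sequence$residues))
    expect_true(all(p$start[-1] == p$end[-nrow(p)] + 1L))
  }
  expect_gte(n_ok, 5L)
})

test_that("a projected segment collapsing to zero length is an error", {
  bb <- protein_seq("bb", "AAAWWAAA")
  topo <- topology(
    tibble::tibble(segment = c("TM1", "ICL1", "TM2"),
                   start = c(1, 4, 6), end = c(3, 5, 8)),
    bb
  )
  afa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bb", "AAAWWAAA", ">tg", "AAA--AAA"), afa)
  tg <- protein_seq("tg", "AAAAAA")
  al <- import_alignment(afa, "bb", "tg", read_substitution_matrix())
  expect_error(project_topology(topo, al, tg), "ICL1")
})
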