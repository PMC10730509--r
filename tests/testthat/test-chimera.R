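test_that("rule set presets encode the V1 and V2 cut-site choices", {
  v1 <- make_ruleset("V1")
  expect_equal(unname(v1$source_by_segment[c("ICL1", "ICL2", "ICL3")]),
               rep("TARGET", 3))
  expect_equal(v1$source_by_segment[["CTERM"]], "TARGET")
  expect_equal(v1$cterm_cut_shift, 0L)

  v2 <- make_ruleset("V2")
  expect_equal(v2$source_by_segment[["ICL1"]], "BACKBONE")
  expect_equal(unname(v2$source_by_segment[c("ICL2", "ICL3", "CTERM")]),
               rep("TARGET", 3))
  expect_gt(v2$cterm_cut_shift, 0)

  # two-loop V1 variant keeps the backbone ICL1
  expect_equal(make_ruleset("V1", keep_icl1 = TRUE)$source_by_segment[["ICL1"]],
               "BACKBONE")

  expect_error(make_ruleset("V3"), "Unknown ruleset version")
  expect_error(make_ruleset("V2", cterm_cut_shift = 0), "requires")
  expect_error(make_ruleset("V1", source_by_segment = c(ICL1 = "BACKBONE")),
               "fixed by the V1 preset")
  expect_error(make_ruleset("custom"), "full `source_by_segment`")
  expect_error(make_ruleset("V1", epitope = "TET1"), "non-alphabet")
})

test_that("the worked toy chimera stitches exactly as specified", {
  ex <- toy_example()
  rs <- make_ruleset(
    "custom",
    source_by_segment = c(NTERM = "BACKBONE", TM1 = "BACKBONE", ICL1 = "TARGET",
                          TM2 = "BACKBONE", CTERM = "TARGET"),
    proximal_tm_offset = 1L, epitope = ""
  )
  des <- design_chimera(ex$backbone, ex$topology, ex$target, rs)
  expect_identical(des$chimera$residues, "MAAGYKKKYGAAD")
  # provenance is complete and addresses real source residues
  expect_equal(nrow(des$provenance), 13L)
  rebuilt <- paste(des$provenance$residue, collapse = "")
  expect_identical(rebuilt, des$chimera$residues)
})

test_that("the all-backbone ruleset returns the backbone verbatim", {
  for (seed in c(1, 2, 3)) {
    toy <- make_toy_gpcr(seed = seed)
    des <- design_chimera(toy$sequence, toy$topology, toy$sequence,
                          identity_ruleset(toy$topology))
    expect_identical(des$chimera$residues, toy$sequence$residues)
    expect_true(all(des$provenance$source == "BACKBONE"))
    expect_equal(des$provenance$source_index, seq_len(nchar(toy$sequence$residues)))
  }
})

test_that("the epitope is appended with EPITOPE provenance", {
  toy <- make_toy_gpcr(seed = 10)
  tgt <- make_toy_gpcr(seed = 11, id = "tgt")
  des <- design_chimera(toy$sequence, toy$topology, tgt$sequence, make_ruleset("V2"))
  expect_true(endsWith(des$chimera$residues, "TETSQVAPA"))
  tailp <- utils::tail(des$provenance, 9)
  expect_true(all(tailp$source == "EPITOPE"))
  expect_identical(paste(tailp$residue, collapse = ""), "TETSQVAPA")
})

test_that("provenance concatenation reproduces the chimera for random designs", {
  withr::with_seed(55, {
    for (k in 1:12) {
      bb <- make_toy_gpcr(seed = 300 + k)
      tg <- make_toy_gpcr(seed = 400 + k, id = "tgt")
      segs <- bb$topology$segment
      rs <- make_ruleset(
        "custom",
        source_by_segment = setNames(sample(c("BACKBONE", "TARGET"), length(segs), TRUE), segs),
        proximal_tm_offset = sample(0:3, 1),
        cterm_cut_shift = sample(0:8, 1),
        epitope = if (k %% 2 == 0) "TETSQVAPA" else ""
      )
      des <- design_chimera(bb$sequence, bb$topology, tg$sequence, rs)
      # concatenation invariant
      expect_identical(paste(des$provenance$residue, collapse = ""), des$chimera$residues)
      # addressed residues really come from their source sequences
      bchars <- strsplit(bb$sequence$residues, "")[[1]]
      tchars <- strsplit(tg$sequence$residues, "")[[1]]
      p <- des$provenance
      expect_identical(p$residue[p$source == "BACKBONE"],
                       bchars[p$source_index[p$source == "BACKBONE"]])
      expect_identical(p$residue[p$source == "TARGET"],
                       tchars[p$source_index[p$source == "TARGET"]])
      # block source indices are consecutive
      blocks <- provenance_blocks(des)
      expect_equal(blocks$source_end - blocks$source_start,
                   blocks$end - blocks$start)
    }
  })
})

test_that("V2 keeps the backbone ICL1 and swaps every TARGET block faithfully", {
  for (k in 1:8) {
    bb <- make_toy_gpcr(seed = 500 + k)
    tg <- make_toy_gpcr(seed = 600 + k, id = "tgt")
    des <- design_chimera(bb$sequence, bb$topology, tg$sequence, make_ruleset("V2"))
    icl1 <- des$provenance[des$provenance$segment == "ICL1", ]
    expect_true(all(icl1$source == "BACKBONE"))
    r <- optoxr:::segment_range(bb$topology, "ICL1")
    expect_identical(paste(icl1$residue, collapse = ""),
                     substr(bb$sequence$residues, r[1], r[2]))
    blocks <- provenance_blocks(des)
    for (b in which(blocks$source == "TARGET")) {
      expect_identical(
        substr(des$chimera$residues, blocks$start[b], blocks$end[b]),
        substr(tg$sequence$residues, blocks$source_start[b], blocks$source_end[b])
      )
    }
  }
})

test_that("diff_designs localizes the V1/V2 differences at ICL1 and the C-terminal junction", {
  bb <- make_toy_gpcr(seed = 1)
  tg <- make_toy_gpcr(seed = 2, id = "tgt")
  v1 <- design_chimera(bb$sequence, bb$topology, tg$sequence, make_ruleset("V1"))
  v2 <- design_chimera(bb$sequence, bb$topology, tg$sequence, make_ruleset("V2"))
  d <- diff_designs(v1, v2)
  expect_true("ICL1" %in% d$segment)
  expect_true("TM7" %in% d$segment)  # C-terminal cut moved into TM7
  # ICL1 difference includes both proximal TM flanks
  expect_true(any(d$segment == "TM1"))
  expect_true(any(d$segment == "TM2"))

  expect_equal(nrow(diff_designs(v1, v1)), 0L)

  other <- design_chimera(bb$sequence, bb$topology,
                          make_toy_gpcr(seed = 3, id = "tgt")$sequence,
                          make_ruleset("V1"))
  expect_error(diff_designs(v1, other), "checksum")
})

test_that("X inside an exchanged segment is a design-time error", {
  bb <- make_toy_gpcr(seed = 31)
  tg <- make_toy_gpcr(seed = 32, id = "tgt")
  r <- optoxr:::segment_range(tg$topology, "ICL2")
  res <- tg$sequence$residues
  substr(res, r[1] + 1L, r[1] + 1L) <- "X"
  tgx <- protein_seq("tgt", res)
  expect_error(
    design_chimera(bb$sequence, bb$topology, tgx, make_ruleset("V2")),
    "'X'"
  )
})

test_that("back-translation is exact, deterministic and codon-table driven", {
  tab <- read_codon_table()
  expect_identical(back_translate(protein_seq("m", "M"), tab), "ATG")

  # round trip for 1,000 random proteins
  withr::with_seed(1234, {
    lens <- sample(1:60, 1000, replace = TRUE)
    for (L in lens) {
      p <- paste(sample(setdiff(optoxr:::AA_ALPHABET, "X"), L, TRUE), collapse = "")
      dna <- back_translate(protein_seq("p", p), tab)
      expect_identical(translate_dna(dna), p)
    }
  })

  p <- protein_seq("p", "MKTAYWCDERLISH")
  w1 <- back_translate(p, tab, mode = "weighted", seed = 7)
  w2 <- back_translate(p, tab, mode = "weighted", seed = 7)
  expect_identical(w1, w2)
  expect_identical(translate_dna(w1), p$residues)
  expect_error(back_translate(p, tab, mode = "weighted"), "seed")
  expect_error(back_translate(protein_seq("x", "MX"), tab), "'X' absent")

  dna_stop <- back_translate(p, tab, append_stop = TRUE)
  expect_equal(nchar(dna_stop), 3 * nchar(p$residues) + 3)
  expect_identical(translate_dna(dna_stop), p$residues)
})

test_that("the codon table loader validates sums and the genetic code", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("aa\tcodon\tfreq", "M\tATG\t0.9"), f)
  expect_error(read_codon_table(f), "sum to")
  writeLines(c("aa\tcodon\tfreq", "M\tTTT\t1.0"), f)
  expect_error(read_codon_table(f), "does not translate")
})
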