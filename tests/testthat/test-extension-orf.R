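test_that("an immediately adjacent second stop gives a 1-residue extension", {
  tx <- make_tx(cds = "ATGAAATGA", utr3 = "TAAGGG")
  orf <- find_extension(tx)
  expect_identical(orf$between_stops_codons, 0L)
  expect_identical(orf$extension_aa_length, 1L)
  expect_identical(orf$peptide, "X")
  expect_true(orf$terminated)
  expect_identical(orf$second_stop_codon, "TAA")
})

test_that("extension scan equals a brute-force codon walk on random 3'UTRs", {
  set.seed(41)
  for (i in 1:200) {
    utr <- paste(sample(c("A", "C", "G", "T"), sample(0:80, 1), TRUE),
                 collapse = "")
    tx <- make_tx(cds = "ATGGCCTGA", utr3 = utr, id = paste0("r", i))
    orf <- suppressWarnings(find_extension(tx))
    # oracle: walk codons one at a time
    n_complete <- as.integer(nchar(utr) %/% 3)
    between <- NA_integer_
    for (j in seq_len(n_complete)) {
      cod <- substr(utr, 3 * j - 2, 3 * j)
      if (cod %in% c("TAA", "TAG", "TGA")) { between <- j - 1L; break }
    }
    if (is.na(between)) {
      expect_false(orf$terminated)
      expect_identical(orf$between_stops_codons, n_complete)
    } else {
      expect_true(orf$terminated)
      expect_identical(orf$between_stops_codons, between)
    }
    expect_identical(orf$extension_aa_length, orf$between_stops_codons + 1L)
  }
})

test_that("translating through the recoded stop gives protein + extension", {
  set.seed(43)
  for (i in 1:20) {
    cds <- paste0("ATG", random_sense(10), sample(c("TAA", "TAG", "TGA"), 1))
    utr <- paste0(random_sense(sample(1:20, 1)), "TGA",
                  paste(sample(c("A", "C", "G", "T"), 9, TRUE), collapse = ""))
    tx <- make_tx(cds = cds, utr3 = utr, id = paste0("c", i))
    orf <- find_extension(tx)
    protein <- translate_dna(substr(cds, 1, nchar(cds) - 3))
    # concatenation identity: full translation with the stop recoded as X
    full <- paste0(substr(tx$sequence, tx$cds_start + 1, tx$cds_end - 3),
                   "NNN",  # recoded stop renders as X
                   substr(tx$sequence, tx$cds_end + 1, orf$second_stop_pos))
    expect_identical(translate_dna(full), paste0(protein, orf$peptide))
  }
})

test_that("the scan ignores 3'UTR content beyond the second stop", {
  tx1 <- make_tx(cds = "ATGGCCTGA", utr3 = "GCCGCATAGAAAAAAAAA", id = "a")
  tx2 <- make_tx(cds = "ATGGCCTGA", utr3 = "GCCGCATAGCCCCCCCCC", id = "a")
  o1 <- find_extension(tx1)
  o2 <- find_extension(tx2)
  expect_identical(o1[setdiff(names(o1), "transcript_id")],
                   o2[setdiff(names(o2), "transcript_id")])
})

test_that("a missing second stop is flagged with a warning", {
  tx <- make_tx(cds = "ATGGCCTGA", utr3 = "GCCGCAGCC")
  expect_warning(orf <- find_extension(tx), "no in-frame stop")
  expect_false(orf$terminated)
  expect_identical(orf$between_stops_codons, 3L)
  expect_identical(orf$peptide, "XAAA")
})

test_that("reporter inserts truncate at in-frame stops keeping whole codons", {
  ctx <- extract_stop_context(make_tx(cds = "ATGATCCAGTGA",
                                      utr3 = "CTAGCAGGGTGAAAA"))
  ins <- design_reporter_insert(ctx)
  expect_identical(ins$downstream_len, 9L)
  expect_identical(ins$truncated_reason, "inframe_stop")
  expect_identical(ins$insert_seq, "ATCCAGTGACTAGCAGGG")
  expect_identical(ins$control_seq, "ATCCAGTGGCTAGCAGGG")

  # no in-frame stop in the window: full 12 nt
  ctx2 <- extract_stop_context(make_tx(cds = "ATGATCCAGTGA",
                                       utr3 = "CTAGCAGGGACTGAA"))
  ins2 <- design_reporter_insert(ctx2)
  expect_identical(ins2$downstream_len, 12L)
  expect_identical(ins2$truncated_reason, "none")

  # short 3'UTR without a stop
  ctx3 <- extract_stop_context(make_tx(cds = "ATGATCCAGTGA", utr3 = "CTAGCAG"))
  ins3 <- design_reporter_insert(ctx3)
  expect_identical(ins3$downstream_len, 7L)
  expect_identical(ins3$truncated_reason, "short_utr")
})

test_that("inserts never contain an in-frame stop in the downstream segment", {
  set.seed(47)
  for (i in 1:100) {
    utr <- paste(sample(c("A", "C", "G", "T"), sample(0:15, 1), TRUE),
                 collapse = "")
    ctx <- extract_stop_context(make_tx(cds = "ATGATCCAGTGA", utr3 = utr,
                                        id = paste0("p", i)))
    ins <- design_reporter_insert(ctx)
    ds <- substr(ins$insert_seq, 10, nchar(ins$insert_seq))
    nc <- nchar(ds) %/% 3
    codons <- if (nc > 0) substring(ds, 3 * seq_len(nc) - 2, 3 * seq_len(nc)) else character(0)
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
    if (ins$truncated_reason == "inframe_stop") {
      expect_identical(ins$downstream_len %% 3L, 0L)
    }
  }
})

test_that("extension peptides round-trip through FASTA", {
  tx <- sim_transcriptome(25, seed = 51)
  orfs <- suppressWarnings(find_extension(tx))
  fa <- tempfile(fileext = ".fa")
  written <- export_peptides(orfs, fa)
  back <- Biostrings::readAAStringSet(fa)
  expect_identical(as.character(back), setNames(written$peptide,
                                                written$transcript_id))
  # zero ORFs produce an empty file
  fa0 <- tempfile(fileext = ".fa")
  export_peptides(orfs[orfs$terminated & FALSE, ], fa0)
  expect_identical(length(Biostrings::readAAStringSet(fa0)), 0L)
  # a 1-residue extension writes a 1-residue record
  one <- find_extension(make_tx(cds = "ATGAAATGA", utr3 = "TAAGGG"))
  fa1 <- tempfile(fileext = ".fa")
  export_peptides(one, fa1)
  expect_identical(as.character(Biostrings::readAAStringSet(fa1)[[1]]), "X")
})
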