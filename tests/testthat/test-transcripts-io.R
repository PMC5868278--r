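write_gtf_lines <- function(lines, path) writeLines(lines, path)

test_that("generated transcriptomes round-trip through FASTA/GTF exactly", {
  tx <- sim_transcriptome(60, seed = 5)
  fa <- tempfile(fileext = ".fa")
  gtf <- tempfile(fileext = ".gtf")
  write_transcriptome(tx, fa, gtf)
  lt <- load_transcripts(fa, gtf)
  expect_equal(nrow(lt), nrow(tx))
  lt <- lt[match(tx$transcript_id, lt$transcript_id), ]
  expect_identical(lt$sequence, tx$sequence)
  expect_identical(lt$cds_start, as.integer(tx$cds_start))
  expect_identical(lt$cds_end, as.integer(tx$cds_end))
  expect_identical(lt$stop_codon, tx$stop_codon)
  # round-trip preserves the planted stop codons and post-stop 4-mers
  ctx <- extract_stop_context(lt)
  expect_identical(substring(ctx$downstream, 1, 4),
                   substring(tx$sequence, tx$cds_end + 1, tx$cds_end + 4))
})

test_that("a CDS not ending in a stop codon is excluded with reason no_stop", {
  fa <- tempfile(fileext = ".fa")
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(">t1", "AAATGGCTTGGCCCAAA"), fa)  # CDS ends TGG
  write_gtf_lines(c(
    paste("t1", "x", "exon", 1, 17, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("t1", "x", "CDS", 3, 11, ".", "+", "0",
          'gene_id "g1"; transcript_id "t1";', sep = "\t")
  ), gtf)
  lt <- load_transcripts(gtf = gtf, fasta = fa)
  expect_equal(nrow(lt), 0L)
  sk <- attr(lt, "skipped")
  expect_identical(sk$reason, "no_stop")
})

test_that("minus-strand two-exon CDS matches a brute-force splicing oracle", {
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  set.seed(31)
  # transcript first: 10 nt 5'UTR + 36 nt CDS (ATG..TAA) + 24 nt 3'UTR
  tx_seq <- paste0(paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = ""),
                   "ATG", strrep("GCC", 10), "TAA",
                   paste(sample(c("A", "C", "G", "T"), 24, TRUE), collapse = ""))
  stopifnot(nchar(tx_seq) == 70)
  # lay it on the minus strand of chrZ as exons 11..40 (3' part) and
  # 61..100 (5' part): concat(exonA, exonB) on the + strand = revcomp(tx)
  g <- revcomp(tx_seq)
  genome <- paste0(strrep("N", 10), substr(g, 1, 30), strrep("N", 20),
                   substr(g, 31, 70), strrep("N", 20))
  # transcript offset t (0-based) -> genomic 1-based: exon B first
  t2g <- function(t) ifelse(t < 40, 100 - t, 80 - t)
  fa <- tempfile(fileext = ".fa")
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(">chrZ", genome), fa)
  attrs <- 'gene_id "gZ"; transcript_id "tZ";'
  # CDS excl stop = transcript offsets 10..42, split across the two exons
  write_gtf_lines(c(
    paste("chrZ", "x", "exon", 11, 40, ".", "-", ".", attrs, sep = "\t"),
    paste("chrZ", "x", "exon", 61, 100, ".", "-", ".", attrs, sep = "\t"),
    paste("chrZ", "x", "CDS", t2g(39), t2g(10), ".", "-", "0", attrs, sep = "\t"),
    paste("chrZ", "x", "CDS", t2g(42), t2g(40), ".", "-", "2", attrs, sep = "\t")
  ), gtf)
  lt <- load_transcripts(fa, gtf)
  expect_equal(nrow(lt), 1L)
  # brute-force oracle: exon concatenation in genome order, reverse complement
  oracle <- revcomp(paste0(substr(genome, 11, 40), substr(genome, 61, 100)))
  expect_identical(lt$sequence, oracle)
  expect_identical(lt$sequence, tx_seq)
  expect_identical(lt$cds_start, 10L)
  expect_identical(lt$cds_end, 46L)
  expect_identical(lt$stop_codon, "TAA")
  # first stop nt is transcript offset 43 -> genomic 80-43=37, 0-based 36
  expect_identical(lt$stop_genomic, 36L)
})

test_that("stop contexts are exact string slices of the transcript", {
  tx <- sim_transcriptome(40, seed = 13)
  ctx <- extract_stop_context(tx)
  for (k in seq_len(nrow(tx))) {  # brute-force slicing oracle
    s <- tx$sequence[k]
    e <- tx$cds_end[k]
    expect_identical(ctx$upstream[k], substr(s, e - 8, e - 3))
    expect_identical(ctx$stop_codon[k], substr(s, e - 2, e))
    expect_identical(ctx$downstream[k],
                     substr(s, e + 1, min(nchar(s), e + 12)))
  }
})

test_that("short 3'UTRs truncate the downstream flank and short CDSs flag upstream", {
  tx <- make_tx(cds = "ATGTGA", utr3 = "GGGTT")  # 5-nt 3'UTR, 6-nt CDS
  ctx <- extract_stop_context(tx)
  expect_identical(ctx$downstream, "GGGTT")
  expect_identical(ctx$downstream_len, 5L)
  expect_true(ctx$upstream_short)      # CDS has only 3 nt before the stop
  expect_identical(ctx$upstream, "ATG")
})

test_that("the readthrough-motif context is recovered from a VDR-like toy", {
  tx <- make_tx(cds = paste0("ATG", strrep("GAC", 5), "ATCCAG", "TGA"),
                utr3 = "CTAGCAGGGACTG")
  ctx <- extract_stop_context(tx)
  expect_identical(ctx$stop_codon, "TGA")
  expect_identical(ctx$upstream, "ATCCAG")
  expect_identical(substring(ctx$downstream, 1, 4), "CTAG")
})

test_that("dedupe keeps one context per genomic stop, order-invariantly", {
  tx <- sim_transcriptome(30, seed = 17)
  ctx <- extract_stop_context(tx)
  iso <- ctx[c(1, 1, 2, 3, 3, 3), ]  # isoforms sharing stops
  iso$transcript_id <- paste0("iso", seq_len(nrow(iso)))
  dd <- dedupe_stops(iso)
  expect_equal(nrow(dd), 3L)
  expect_equal(attr(dd, "n_duplicates"), 3L)
  # distinct coordinates are all retained
  dd_all <- dedupe_stops(ctx)
  expect_equal(nrow(dd_all), nrow(ctx))
  # order invariance of the retained key set + idempotence
  set.seed(1)
  shuffled <- dedupe_stops(iso[sample(nrow(iso)), ])
  key <- function(d) sort(paste(d$chrom, d$strand, d$stop_genomic))
  expect_identical(key(shuffled), key(dd))
  expect_identical(dedupe_stops(dd)$transcript_id, dd$transcript_id)
})
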