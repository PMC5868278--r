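# region of K sense codons followed by the second stop at codon K + 1
make_region <- function(K = 20, seed = 1) {
  set.seed(seed)
  codons <- sample(setdiff(sense_codons(), "ATG"), K, replace = TRUE)
  c(codons, "TGA")
}

test_that("a row identical to the reference yields no events", {
  cods <- make_region(10)
  aln <- aln_from_codons(list(human = cods, other = cods))
  ev <- frame_integrity(aln, second_stop_codon_index = 11L)
  expect_identical(nrow(ev), 0L)
})

test_that("a 1-base deletion is localised to the codon where frame is lost", {
  cods <- make_region(50, seed = 2)
  ref <- paste(cods, collapse = "")
  gib <- strsplit(ref, "")[[1]]
  gib[3 * 45 - 1] <- "-"   # delete the middle base of codon 45
  aln <- codon_alignment(c(human = ref, gibbon = paste(gib, collapse = "")),
                         ref = "human")
  ev <- frame_integrity(aln, second_stop_codon_index = 51L)
  fs <- ev[ev$kind == "frameshift_indel", ]
  expect_identical(nrow(fs), 1L)
  expect_identical(fs$species, "gibbon")
  expect_identical(fs$codon_index, 45L)
  expect_identical(fs$detail, "-1")
})

test_that("a substitution at the reference second stop is called as loss", {
  cods <- make_region(12, seed = 3)
  marm <- cods
  marm[13] <- "CGA"  # second stop TGA -> CGA
  aln <- aln_from_codons(list(human = cods, marmoset = marm))
  ev <- frame_integrity(aln, second_stop_codon_index = 13L)
  expect_identical(ev$kind, "second_stop_loss")
  expect_identical(ev$species, "marmoset")
  expect_identical(ev$codon_index, 13L)
  expect_identical(ev$detail, "CGA")
})

test_that("in-frame premature stops are reported, including in the reference", {
  cods <- make_region(8, seed = 4)
  sp <- cods
  sp[4] <- "TAA"
  aln <- aln_from_codons(list(human = cods, monkey = sp))
  ev <- frame_integrity(aln, second_stop_codon_index = 9L)
  expect_identical(ev$kind, "premature_stop")
  expect_identical(ev$codon_index, 4L)
  # reference-row internal stop: reported under the reference species
  refstop <- cods
  refstop[3] <- "TAG"
  aln2 <- aln_from_codons(list(human = refstop, monkey = refstop))
  ev2 <- frame_integrity(aln2, second_stop_codon_index = 9L)
  expect_true(any(ev2$species == "human" & ev2$kind == "premature_stop" &
                    ev2$codon_index == 3L))
})

test_that("whole-codon and compensating indels do not shift the frame", {
  cods <- make_region(15, seed = 5)
  ref <- paste(cods, collapse = "")
  ch <- strsplit(ref, "")[[1]]
  ch[10:12] <- "-"   # clean 3-nt deletion
  aln <- codon_alignment(c(human = ref, sp = paste(ch, collapse = "")),
                         ref = "human")
  ev <- frame_integrity(aln, second_stop_codon_index = 16L)
  expect_false(any(ev$kind == "frameshift_indel"))
  # two deletions of 1 and 2 nt compensate: net 0 mod 3, no event
  ch2 <- strsplit(ref, "")[[1]]
  ch2[7] <- "-"
  ch2[22:23] <- "-"
  aln2 <- codon_alignment(c(human = ref, sp = paste(ch2, collapse = "")),
                          ref = "human")
  ev2 <- frame_integrity(aln2, second_stop_codon_index = 16L)
  expect_false(any(ev2$kind == "frameshift_indel"))
})

test_that("planted indel runs are recovered exactly over random cases", {
  set.seed(91)
  for (i in 1:40) {
    K <- 30
    cods <- make_region(K, seed = 1000 + i)
    ref <- paste(cods, collapse = "")
    len <- sample(1:4, 1)
    codon_at <- sample(2:(K - 1), 1)
    start <- 3 * (codon_at - 1) + sample(0:2, 1) + 1
    ch <- strsplit(ref, "")[[1]]
    ch[start:(start + len - 1)] <- "-"
    aln <- codon_alignment(c(human = ref, sp = paste(ch, collapse = "")),
                           ref = "human")
    ev <- frame_integrity(aln, second_stop_codon_index = K + 1L)
    fs <- ev[ev$kind == "frameshift_indel", ]
    if (len %% 3 == 0) {
      expect_identical(nrow(fs), 0L)
    } else {
      expect_identical(nrow(fs), 1L)
      expect_identical(fs$codon_index, as.integer(ceiling(start / 3)))
      expect_identical(fs$detail, sprintf("%+d", -len))
    }
  }
})

test_that("insertions relative to the reference count toward frame loss", {
  cods <- make_region(10, seed = 6)
  ref_ch <- strsplit(paste(cods, collapse = ""), "")[[1]]
  sp_ch <- ref_ch
  # insert 1 nt after codon 5: gap in reference, base in species
  at <- 15
  ref_g <- c(ref_ch[1:at], "-", ref_ch[(at + 1):length(ref_ch)])
  sp_g <- c(sp_ch[1:at], "G", sp_ch[(at + 1):length(sp_ch)])
  aln <- codon_alignment(c(human = paste(ref_g, collapse = ""),
                           sp = paste(sp_g, collapse = "")), ref = "human")
  ev <- frame_integrity(aln, second_stop_codon_index = 11L)
  fs <- ev[ev$kind == "frameshift_indel", ]
  expect_identical(nrow(fs), 1L)
  expect_identical(fs$detail, "+1")
  expect_identical(fs$codon_index, 6L)
})
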