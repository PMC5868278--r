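#' Default post-stop nucleotide frequencies
#'
#' Position-specific frequencies for the four nucleotides immediately 3' of
#' a stop codon. Real stop-codon contexts are not uniform: the nucleotides
#' of efficient readthrough motifs are over-represented after UGA stops.
#' The default mildly favours the C/T/A/G bases of the CTAG readthrough
#' motif (0.4 at its own position, 0.2 elsewhere), giving the motif a joint
#' null probability of 0.4^4 = 2.56% under independence.
#'
#' @return A 4 x 4 matrix; rows are downstream positions +4..+7, columns
#'   are `A`, `C`, `G`, `T`. Each row sums to 1.
#' @export
default_post_stop_freqs <- function() {
  nt <- c("A", "C", "G", "T")
  f <- matrix(0.2, nrow = 4, ncol = 4, dimnames = list(paste0("pos", 1:4), nt))
  motif <- c("C", "T", "A", "G")
  for (i in 1:4) f[i, motif[i]] <- 0.4
  f
}

#' Simulate a single-isoform transcriptome with a planted stop-context motif
#'
#' Generates `n_transcripts` spliced transcripts, each with a 5' UTR, a CDS
#' beginning with ATG and ending in a stop codon drawn from
#' `stop_codon_mix`, and a 3' UTR whose first four nucleotides follow the
#' position-specific `post_stop_freqs`. For transcripts with a TGA stop the
#' joint probability of the planted `motif` is multiplied by `motif_factor`
#' (values < 1 deplete the motif, > 1 enrich it, 0 forbids it), emulating
#' selection on the stop-codon context. Each transcript lives on its own
#' contig so genomic stop coordinates are well defined.
#'
#' @param n_transcripts Number of transcripts.
#' @param motif_factor Multiplicative factor applied to the joint motif
#'   probability after TGA stops; must be >= 0 and leave the adjusted
#'   probability <= 1.
#' @param motif 4-nt DNA motif planted/depleted immediately after TGA stops.
#' @param stop_codon_mix Named probabilities over `TAA`, `TAG`, `TGA`.
#'   Defaults approximate the human stop-codon usage mix.
#' @param post_stop_freqs 4 x 4 matrix of position-specific nucleotide
#'   frequencies for the 4 nt after the stop (rows = positions, columns
#'   `A`,`C`,`G`,`T`).
#' @param cds_length_range,utr5_length_range,utr3_length_range Integer
#'   ranges (nt) to sample lengths from; CDS lengths are rounded to whole
#'   codons and include the start and stop codons.
#' @param seed Optional integer seed; the same spec and seed give
#'   byte-identical output.
#' @return A tibble of class `transcriptome` with one row per transcript:
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `sequence`,
#'   `cds_start`/`cds_end` (0-based half-open, `cds_end` just past the stop
#'   codon), `stop_codon`, `planted_motif`, `utr3_length`.
#' @examples
#' tx <- sim_transcriptome(20, motif_factor = 1, seed = 1)
#' table(tx$stop_codon)
#' @export
sim_transcriptome <- function(n_transcripts,
                              motif_factor = 1,
                              motif = "CTAG",
                              stop_codon_mix = c(TAA = 0.28, TAG = 0.24, TGA = 0.48),
                              post_stop_freqs = default_post_stop_freqs(),
                              cds_length_range = c(120L, 600L),
                              utr5_length_range = c(10L, 60L),
                              utr3_length_range = c(60L, 240L),
                              seed = NULL) {
  assert_count(n_transcripts, "n_transcripts")
  if (!is.numeric(motif_factor) || length(motif_factor) != 1L || motif_factor < 0) {
    stop_validation("`motif_factor` must be a single number >= 0")
  }
  motif <- toupper(motif)
  if (nchar(motif) != 4L || grepl("[^ACGT]", motif)) {
    stop_validation("`motif` must be a 4-nt DNA string")
  }
  stop_codon_mix <- stop_codon_mix[c("TAA", "TAG", "TGA")]
  assert_prob_vector(stop_codon_mix, "stop_codon_mix")
  if (!is.matrix(post_stop_freqs) || !identical(dim(post_stop_freqs), c(4L, 4L))) {
    stop_validation("`post_stop_freqs` must be a 4 x 4 matrix")
  }
  colnames(post_stop_freqs) <- colnames(post_stop_freqs) %||% c("A", "C", "G", "T")
  for (i in 1:4) assert_prob_vector(post_stop_freqs[i, ], sprintf("post_stop_freqs[%d, ]", i))

  motif_nt <- strsplit(motif, "")[[1]]
  p_motif <- prod(vapply(1:4, function(i) post_stop_freqs[i, motif_nt[i]], 0))
  p_adj <- motif_factor * p_motif
  if (p_adj > 1) {
    stop_validation("adjusted motif probability %.3f exceeds 1; lower `motif_factor`",
                    p_adj)
  }

  nt <- c("A", "C", "G", "T")
  sense <- sense_codons()
  sense <- sense[sense != "ATG"]  # body codons; ATG prepended explicitly

  with_seed_maybe(seed, {
    n <- n_transcripts
    ids <- sprintf("TX%05d", seq_len(n))
    utr5_len <- sample(utr5_length_range[1]:utr5_length_range[2], n, TRUE)
    cds_codons <- pmax(3L, as.integer(
      round(sample(cds_length_range[1]:cds_length_range[2], n, TRUE) / 3L)))
    utr3_len <- sample(utr3_length_range[1]:utr3_length_range[2], n, TRUE)
    stops <- sample(names(stop_codon_mix), n, TRUE, prob = stop_codon_mix)

    # one bulk uniform draw for all UTR sequence, sliced per transcript
    slice_random <- function(lens) {
      big <- paste(sample(nt, sum(lens) + 1L, TRUE), collapse = "")
      ends <- cumsum(lens)
      out <- substring(big, ends - lens + 1L, ends)
      out[lens == 0L] <- ""
      out
    }
    utr5 <- slice_random(utr5_len)
    body <- vapply(cds_codons - 2L,
                   function(k) paste(sample(sense, k, TRUE), collapse = ""), "")

    # the 4 nt after the stop: position-specific draws, motif handled jointly
    post4 <- vapply(1:4, function(i) sample(nt, n, TRUE, post_stop_freqs[i, ]),
                    character(n))
    if (n == 1L) post4 <- matrix(post4, nrow = 1L)
    post4 <- apply(post4, 1, paste, collapse = "")
    tga_full <- stops == "TGA" & utr3_len >= 4L
    planted <- rep(FALSE, n)
    if (any(tga_full)) {
      planted[tga_full] <- runif(sum(tga_full)) < p_adj
      post4[planted] <- motif
      # conditional redraw given "not the motif" for unplanted TGA contexts
      repeat {
        clash <- which(tga_full & !planted & post4 == motif)
        if (length(clash) == 0L) break
        redraw <- vapply(1:4, function(i)
          sample(nt, length(clash), TRUE, post_stop_freqs[i, ]),
          character(length(clash)))
        if (length(clash) == 1L) redraw <- matrix(redraw, nrow = 1L)
        post4[clash] <- apply(redraw, 1, paste, collapse = "")
      }
    }
    rest <- slice_random(pmax(utr3_len - 4L, 0L))
    utr3 <- ifelse(utr3_len >= 4L, paste0(post4, rest),
                   substring(post4, 1L, utr3_len))
    cds <- paste0("ATG", body, stops)
    out <- tibble(
      transcript_id = ids,
      gene_id = sub("^TX", "G", ids),
      chrom = ids,
      strand = "+",
      sequence = paste0(utr5, cds, utr3),
      cds_start = utr5_len,
      cds_end = utr5_len + nchar(cds),
      stop_codon = stops,
      stop_genomic = utr5_len + nchar(cds) - 3L,
      planted_motif = planted,
      utr3_length = utr3_len
    )
    class(out) <- c("transcriptome", class(out))
    attr(out, "p_motif_null") <- p_motif
    attr(out, "p_motif_adjusted") <- p_adj
    out
  })
}

#' Write a transcriptome to FASTA and GTF
#'
#' The FASTA holds spliced transcript sequences (one contig per transcript);
#' the GTF carries `exon` and `CDS` features. By default the CDS feature
#' excludes the stop codon (GENCODE dialect); set `stop_in_cds = TRUE` for
#' the dialect in which the CDS includes it.
#'
#' @param x A `transcriptome` tibble (or any tibble with the same columns).
#' @param fasta,gtf Output paths.
#' @param stop_in_cds Whether the written CDS feature includes the stop.
#' @return Invisibly, the input.
#' @export
write_transcriptome <- function(x, fasta, gtf, stop_in_cds = FALSE) {
  seqs <- Biostrings::DNAStringSet(setNames(x$sequence, x$transcript_id))
  Biostrings::writeXStringSet(seqs, fasta)

  cds_end1 <- if (stop_in_cds) x$cds_end else x$cds_end - 3L
  lines <- character(0)
  for (k in seq_len(nrow(x))) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     x$gene_id[k], x$transcript_id[k])
    lines <- c(
      lines,
      paste(x$chrom[k], "sim", "exon", 1L, nchar(x$sequence[k]), ".",
            x$strand[k], ".", attrs, sep = "\t"),
      paste(x$chrom[k], "sim", "CDS", x$cds_start[k] + 1L, cds_end1[k], ".",
            x$strand[k], "0", attrs, sep = "\t")
    )
  }
  writeLines(lines, gtf)
  invisible(x)
}
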