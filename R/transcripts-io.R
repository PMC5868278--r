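#' Load transcript models from FASTA and GTF
#'
#' Reads contig (or transcript) sequences from `fasta` and transcript models
#' from `gtf`, splices exons (reverse-complementing minus-strand models),
#' maps the CDS into transcript coordinates, and keeps only transcripts whose
#' CDS ends in a valid stop codon. In the default GENCODE dialect the GTF
#' `CDS` features exclude the stop codon, which is taken as the next three
#' transcript nucleotides; with `stop_in_cds = TRUE` the CDS feature already
#' includes it.
#'
#' Transcripts that cannot be retained are skipped with a reason code
#' (`missing_sequence`, `no_exons`, `cds_not_multiple_of_3`, `no_stop`),
#' available via `attr(x, "skipped")`.
#'
#' @param fasta Path to a FASTA of contig/transcript sequences.
#' @param gtf Path to a GTF with `exon` and `CDS` features carrying
#'   `transcript_id` and `gene_id` attributes.
#' @param stop_in_cds Whether CDS features include the stop codon.
#' @return A tibble with one row per retained transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `sequence` (spliced, 5'->3'),
#'   `cds_start`/`cds_end` (0-based half-open transcript coordinates,
#'   `cds_end` just past the stop codon), `stop_codon`, `stop_genomic`
#'   (genomic coordinate, 0-based, of the first stop-codon nucleotide).
#' @export
load_transcripts <- function(fasta, gtf, stop_in_cds = FALSE) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- tryCatch(rtracklayer::import(gtf, format = "gtf"),
                 error = function(e) stop_data("malformed GTF: %s", conditionMessage(e)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (!all(c("type", "transcript_id") %in% names(df))) {
    stop_data("GTF lacks type/transcript_id fields")
  }
  if (is.null(df$gene_id)) df$gene_id <- df$transcript_id

  kept <- list()
  skipped <- list()
  skip <- function(id, reason) {
    skipped[[length(skipped) + 1L]] <<- tibble(transcript_id = id, reason = reason)
  }

  for (id in unique(df$transcript_id[df$type == "CDS"])) {
    sub <- df[df$transcript_id == id, , drop = FALSE]
    chrom <- as.character(sub$seqnames[1])
    strand <- as.character(sub$strand[1])
    if (!chrom %in% names(seqs)) {
      warn(sprintf("transcript %s: sequence %s missing from FASTA; skipped", id, chrom))
      skip(id, "missing_sequence")
      next
    }
    exons <- sub[sub$type == "exon", , drop = FALSE]
    if (nrow(exons) == 0L) {
      skip(id, "no_exons")
      next
    }
    exons <- exons[order(exons$start), , drop = FALSE]
    chromseq <- seqs[[chrom]]
    pieces <- lapply(seq_len(nrow(exons)), function(i) {
      Biostrings::subseq(chromseq, exons$start[i], exons$end[i])
    })
    spliced <- do.call(Biostrings::xscat, pieces)
    if (strand == "-") spliced <- Biostrings::reverseComplement(spliced)
    tx_seq <- as.character(spliced)

    # map a genomic coordinate (1-based) to a 0-based transcript offset
    exon_len <- exons$end - exons$start + 1L
    g2t <- function(gpos) {
      hit <- which(gpos >= exons$start & gpos <= exons$end)
      if (length(hit) != 1L) return(NA_integer_)
      if (strand == "-") {
        before <- if (hit < nrow(exons)) sum(exon_len[(hit + 1L):nrow(exons)]) else 0L
        before + (exons$end[hit] - gpos)
      } else {
        before <- if (hit > 1L) sum(exon_len[seq_len(hit - 1L)]) else 0L
        before + (gpos - exons$start[hit])
      }
    }
    t2g <- function(tpos) {  # 0-based transcript offset -> 1-based genomic
      cum <- cumsum(exon_len)
      if (strand == "-") {
        ord <- rev(seq_len(nrow(exons)))
        cumr <- cumsum(exon_len[ord])
        hit <- which(tpos < cumr)[1]
        prev <- if (hit > 1L) cumr[hit - 1L] else 0L
        exons$end[ord[hit]] - (tpos - prev)
      } else {
        hit <- which(tpos < cum)[1]
        prev <- if (hit > 1L) cum[hit - 1L] else 0L
        exons$start[hit] + (tpos - prev)
      }
    }

    cds <- sub[sub$type == "CDS", , drop = FALSE]
    cds_g_start <- min(cds$start)
    cds_g_end <- max(cds$end)
    first_g <- if (strand == "-") cds_g_end else cds_g_start
    last_g <- if (strand == "-") cds_g_start else cds_g_end
    t_start <- g2t(first_g)
    t_last <- g2t(last_g)
    if (is.na(t_start) || is.na(t_last)) {
      skip(id, "cds_outside_exons")
      next
    }
    cds_end <- t_last + 1L
    if (!stop_in_cds) cds_end <- cds_end + 3L
    if ((cds_end - t_start) %% 3L != 0L) {
      skip(id, "cds_not_multiple_of_3")
      next
    }
    if (cds_end > nchar(tx_seq)) {
      skip(id, "no_stop")
      next
    }
    stop_codon <- toupper(substring(tx_seq, cds_end - 2L, cds_end))
    if (!is_stop_codon(stop_codon)) {
      skip(id, "no_stop")
      next
    }
    stop_genomic <- t2g(cds_end - 3L) - 1L  # 0-based first nt of the stop

    kept[[length(kept) + 1L]] <- tibble(
      transcript_id = id,
      gene_id = sub$gene_id[1],
      chrom = chrom,
      strand = strand,
      sequence = tx_seq,
      cds_start = t_start,
      cds_end = cds_end,
      stop_codon = stop_codon,
      stop_genomic = stop_genomic
    )
  }

  out <- if (length(kept)) bind_rows(kept) else
    tibble(transcript_id = character(), gene_id = character(),
           chrom = character(), strand = character(), sequence = character(),
           cds_start = integer(), cds_end = integer(),
           stop_codon = character(), stop_genomic = integer())
  attr(out, "skipped") <- if (length(skipped)) bind_rows(skipped) else
    tibble(transcript_id = character(), reason = character())
  out
}

#' Extract the stop-codon context of each transcript
#'
#' The context is the stop codon plus `up` nucleotides 5' of it (from the
#' CDS) and up to `down` nucleotides 3' of it (from the 3' UTR, truncated at
#' the transcript end). A CDS shorter than `up` + 3 yields a shortened
#' upstream flank, flagged in `upstream_short`.
#'
#' @param transcripts Tibble from [load_transcripts()] or
#'   [sim_transcriptome()] (needs `sequence`, `cds_start`, `cds_end`).
#' @param up,down Flank widths in nucleotides (defaults 6 and 12, the
#'   reporter-insert design widths).
#' @return A tibble with `transcript_id`, `gene_id`, `stop_codon`,
#'   `upstream`, `downstream`, `downstream_len`, `upstream_short`, and the
#'   genomic dedup key (`chrom`, `strand`, `stop_genomic`).
#' @export
extract_stop_context <- function(transcripts, up = 6L, down = 12L) {
  assert_count(up, "up", min = 0L)
  assert_count(down, "down", min = 0L)
  t <- transcripts
  stop_start <- t$cds_end - 2L        # 1-based first nt of the stop codon
  up_start <- pmax(t$cds_start + 1L, stop_start - up)
  upstream <- toupper(substring(t$sequence, up_start, stop_start - 1L))
  downstream <- toupper(substring(t$sequence, t$cds_end + 1L,
                                  pmin(nchar(t$sequence), t$cds_end + down)))
  tibble(
    transcript_id = t$transcript_id,
    gene_id = if (!is.null(t$gene_id)) t$gene_id else NA_character_,
    stop_codon = toupper(substring(t$sequence, stop_start, t$cds_end)),
    upstream = upstream,
    downstream = downstream,
    downstream_len = nchar(downstream),
    upstream_short = nchar(upstream) < up,
    chrom = if (!is.null(t$chrom)) t$chrom else t$transcript_id,
    strand = if (!is.null(t$strand)) t$strand else "+",
    stop_genomic = if (!is.null(t$stop_genomic)) t$stop_genomic else t$cds_end - 3L
  )
}

#' Deduplicate stop contexts by genomic stop coordinate
#'
#' Isoforms of a gene usually share an annotated stop codon; a census over
#' unique stops must count each genomic stop once. Keeps the first-seen
#' context per (`chrom`, `strand`, `stop_genomic`) key; the number of
#' duplicates dropped is stored in `attr(x, "n_duplicates")`.
#'
#' @param contexts Tibble from [extract_stop_context()].
#' @return Deduplicated tibble.
#' @export
dedupe_stops <- function(contexts) {
  key <- paste(contexts$chrom, contexts$strand, contexts$stop_genomic)
  keep <- !duplicated(key)
  out <- contexts[keep, , drop = FALSE]
  attr(out, "n_duplicates") <- sum(!keep)
  out
}
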