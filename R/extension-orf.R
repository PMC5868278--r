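#' Find the readthrough extension ORF of each transcript
#'
#' Scans in-frame codons 3' of the annotated stop codon until the next stop
#' codon. `between_stops_codons` counts the codons strictly between the two
#' stops (neither stop included); the extension peptide additionally
#' contains the residue decoded at the recoded annotated stop, so
#' `extension_aa_length = between_stops_codons + 1`. Transcripts with no
#' in-frame stop before the transcript end get `terminated = FALSE` and a
#' peptide covering the available complete codons.
#'
#' @param transcripts Tibble from [load_transcripts()] or
#'   [sim_transcriptome()].
#' @param recoded_aa Symbol used for the residue decoded at the recoded
#'   stop codon (default `"X"`: the inserted amino acid is context-dependent
#'   and not determined by the transcript sequence).
#' @return A tibble with `transcript_id`, `between_stops_codons`,
#'   `extension_aa_length`, `peptide`, `terminated`, `second_stop_codon`,
#'   `second_stop_pos` (0-based transcript coordinate of the second stop's
#'   first nucleotide, `NA` if not terminated).
#' @examples
#' tx <- tibble::tibble(transcript_id = "t1",
#'                      sequence = "ATGAAATGACCCGGGTAGAA",
#'                      cds_start = 0L, cds_end = 9L)
#' find_extension(tx)
#' @export
find_extension <- function(transcripts, recoded_aa = "X") {
  t <- transcripts
  rows <- lapply(seq_len(nrow(t)), function(k) {
    utr <- toupper(substring(t$sequence[k], t$cds_end[k] + 1L))
    codons <- split_codons(utr)
    stop_idx <- which(is_stop_codon(codons))
    terminated <- length(stop_idx) > 0L
    if (terminated) {
      j <- stop_idx[1]
      between <- j - 1L
      body <- if (between > 0L) codons[seq_len(between)] else character(0)
      second_stop <- codons[j]
      second_pos <- t$cds_end[k] + 3L * (j - 1L)
    } else {
      if (length(codons) > 0L || nchar(utr) > 0L) {
        warn(sprintf("transcript %s: no in-frame stop before transcript end",
                     t$transcript_id[k]))
      }
      between <- length(codons)
      body <- codons
      second_stop <- NA_character_
      second_pos <- NA_integer_
    }
    peptide <- paste0(recoded_aa, translate_dna(paste(body, collapse = "")))
    tibble(
      transcript_id = t$transcript_id[k],
      between_stops_codons = between,
      extension_aa_length = between + 1L,
      peptide = peptide,
      terminated = terminated,
      second_stop_codon = second_stop,
      second_stop_pos = second_pos
    )
  })
  bind_rows(rows)
}

#' Design dual-luciferase reporter inserts from stop contexts
#'
#' The insert is the `up` nucleotides 5' of the stop, the stop codon, and up
#' to `down` nucleotides 3' of it. The downstream segment is truncated to
#' whole codons ending before the first in-frame stop codon within the
#' window (so the fusion reading frame never terminates inside the insert),
#' and further truncated by the transcript end. A control insert with the
#' stop codon changed to TGG (Trp) is emitted alongside.
#'
#' @param contexts Tibble from [extract_stop_context()].
#' @param down Maximum downstream length in nucleotides (default 12).
#' @return A tibble with `transcript_id`, `insert_seq`, `control_seq`,
#'   `downstream_len`, `truncated_reason` (`none`, `inframe_stop`,
#'   `short_utr`).
#' @export
design_reporter_insert <- function(contexts, down = 12L) {
  c_ <- contexts
  rows <- lapply(seq_len(nrow(c_)), function(k) {
    ds <- toupper(substring(c_$downstream[k], 1L, down))
    codons <- split_codons(ds)
    stop_idx <- which(is_stop_codon(codons))
    if (length(stop_idx) > 0L) {
      len <- 3L * (stop_idx[1] - 1L)
      reason <- "inframe_stop"
    } else if (nchar(ds) < down) {
      len <- nchar(ds)
      reason <- "short_utr"
    } else {
      len <- down
      reason <- "none"
    }
    ds_keep <- substring(ds, 1L, len)
    tibble(
      transcript_id = c_$transcript_id[k],
      insert_seq = paste0(c_$upstream[k], c_$stop_codon[k], ds_keep),
      control_seq = paste0(c_$upstream[k], "TGG", ds_keep),
      downstream_len = len,
      truncated_reason = reason
    )
  })
  bind_rows(rows)
}

#' Write extension peptides to a FASTA file
#'
#' One record per terminated extension ORF, named by transcript id.
#'
#' @param orfs Tibble from [find_extension()].
#' @param path Output FASTA path.
#' @return Invisibly, the tibble of written records.
#' @export
export_peptides <- function(orfs, path) {
  done <- orfs[orfs$terminated, , drop = FALSE]
  aa <- Biostrings::AAStringSet(setNames(done$peptide, done$transcript_id))
  Biostrings::writeXStringSet(aa, path)
  invisible(done)
}
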