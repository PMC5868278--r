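#' Call frame-integrity events per species in a codon alignment
#'
#' For each non-reference row, reports the alignment features that disrupt
#' the putative extended reading frame defined by the reference row:
#'
#' * `frameshift_indel`: the species' cumulative indel length relative to
#'   the reference is not a multiple of 3 over the region; the event is
#'   localised to the reference codon where frame is first lost, with the
#'   signed length of the offending indel run as detail.
#' * `premature_stop`: an in-frame stop codon (read at the reference codon
#'   positions, while the species is in frame) before the reference second
#'   stop.
#' * `second_stop_loss`: a non-stop codon aligned at the reference second
#'   stop position.
#'
#' An in-frame stop in the reference row itself before the second stop is
#' reported (species = reference), not fatal.
#'
#' @param aln A `codon_alignment` that includes the second stop codon.
#' @param second_stop_codon_index 1-based reference codon index of the
#'   second (terminating) stop codon.
#' @return A tibble with `species`, `kind`, `codon_index`, `detail`.
#' @export
frame_integrity <- function(aln, second_stop_codon_index) {
  assert_count(second_stop_codon_index, "second_stop_codon_index")
  cols <- ref_codon_columns(aln)
  K <- length(cols)
  if (second_stop_codon_index > K) {
    stop_data("second_stop_codon_index (%d) exceeds reference codons (%d)",
              second_stop_codon_index, K)
  }
  ssi <- second_stop_codon_index
  cods <- alignment_ref_codons(aln)
  refch <- strsplit(aln$seqs[[aln$ref]], "")[[1]]
  refgap <- refch == "-"
  ref_count <- cumsum(!refgap)
  first_col_of_codon <- vapply(cols, `[`, 0L, 1L)
  # codon an indel event belongs to: for a deletion the codon containing the
  # reference nucleotide; for an insertion the codon starting at/after it
  event_codon <- function(col, insertion) {
    if (insertion) {
      pmin(K, floor(ref_count[col] / 3) + 1L)
    } else {
      pmin(K, pmax(1L, ceiling(ref_count[col] / 3)))
    }
  }

  events <- list()
  add <- function(species, kind, codon_index, detail) {
    events[[length(events) + 1L]] <<- tibble(
      species = species, kind = kind,
      codon_index = as.integer(codon_index), detail = as.character(detail))
  }

  # reference-row internal stops
  for (j in seq_len(ssi - 1L)) {
    if (is_stop_codon(cods[aln$ref, j])) {
      add(aln$ref, "premature_stop", j, cods[aln$ref, j])
    }
  }

  readable <- function(codon) !grepl("[^ACGT]", codon)

  for (sp in setdiff(names(aln$seqs), aln$ref)) {
    spch <- strsplit(aln$seqs[[sp]], "")[[1]]
    code <- integer(length(refch))
    code[refgap & spch != "-"] <- 1L    # insertion relative to reference
    code[!refgap & spch == "-"] <- -1L  # deletion relative to reference

    # indel runs in column order
    r <- rle(code)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cum <- 0L
    first_loss <- NULL
    for (i in seq_along(r$values)) {
      if (r$values[i] == 0L) next
      len <- r$lengths[i] * r$values[i]
      cum <- cum + len
      if (is.null(first_loss) && cum %% 3L != 0L) {
        first_loss <- list(codon = event_codon(starts[i], r$values[i] > 0L),
                           len = len)
      }
    }
    if (cum %% 3L != 0L && !is.null(first_loss)) {
      add(sp, "frameshift_indel", first_loss$codon,
          sprintf("%+d", first_loss$len))
    }

    # frame offset of the species at the start of each reference codon
    cumcode <- cumsum(code)
    offset_at <- function(j) {
      col <- first_col_of_codon[j]
      if (col == 1L) 0L else cumcode[col - 1L]
    }

    for (j in seq_len(ssi - 1L)) {
      codon <- cods[sp, j]
      if (readable(codon) && is_stop_codon(codon) && offset_at(j) %% 3L == 0L) {
        add(sp, "premature_stop", j, codon)
      }
    }

    second <- cods[sp, ssi]
    if (readable(second) && !is_stop_codon(second)) {
      add(sp, "second_stop_loss", ssi, second)
    }
  }

  if (length(events)) bind_rows(events) else
    tibble(species = character(), kind = character(),
           codon_index = integer(), detail = character())
}
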