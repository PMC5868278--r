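#' Reference-framed codon alignment
#'
#' A light container for a gapped multiple alignment of DNA sequences in
#' which one row (the reference) defines the reading frame: reference
#' codons are consecutive triples of alignment columns at which the
#' reference row has nucleotides.
#'
#' @param seqs Named character vector of equal-length gapped DNA strings
#'   (gap = `-`).
#' @param ref Name of the reference row (default: the first).
#' @return A `codon_alignment` object.
#' @export
codon_alignment <- function(seqs, ref = names(seqs)[1]) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop_validation("alignment rows must be named")
  }
  if (anyDuplicated(names(seqs))) stop_validation("row names must be unique")
  if (length(unique(nchar(seqs))) != 1L) {
    stop_data("alignment rows must have equal length")
  }
  if (!ref %in% names(seqs)) stop_validation("reference row %s not in alignment", ref)
  structure(list(seqs = toupper(seqs), ref = ref), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d rows x %d columns, reference %s (%d codons)\n",
              length(x$seqs), nchar(x$seqs[1]), x$ref,
              ncol(alignment_ref_codons(x))))
  invisible(x)
}

#' Read a reference-framed alignment from multi-FASTA
#'
#' @param path Multi-FASTA file of gapped, equal-length rows.
#' @param ref Reference row name; defaults to the first record.
#' @return A `codon_alignment`.
#' @export
read_codon_alignment <- function(path, ref = NULL) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  codon_alignment(seqs, ref = ref %||% names(seqs)[1])
}

#' Write a codon alignment to multi-FASTA
#' @param aln A `codon_alignment`.
#' @param path Output path.
#' @return Invisibly, `aln`.
#' @export
write_codon_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$seqs), path)
  invisible(aln)
}

# columns (indices) of the j-th reference codon, j = 1..K
ref_codon_columns <- function(aln) {
  refchars <- strsplit(aln$seqs[[aln$ref]], "")[[1]]
  nongap <- which(refchars != "-")
  K <- length(nongap) %/% 3L
  if (K == 0L) return(list())
  lapply(seq_len(K), function(j) nongap[(3L * j - 2L):(3L * j)])
}

#' Codons of every row at the reference codon positions
#'
#' @param aln A `codon_alignment`.
#' @return Character matrix, rows = species, columns = reference codons;
#'   entries are 3-character strings that may contain gaps.
#' @export
alignment_ref_codons <- function(aln) {
  cols <- ref_codon_columns(aln)
  K <- length(cols)
  sp <- names(aln$seqs)
  chars <- lapply(aln$seqs, function(s) strsplit(s, "")[[1]])
  out <- matrix("", length(sp), K, dimnames = list(sp, NULL))
  for (i in seq_along(sp)) {
    ch <- chars[[i]]
    out[i, ] <- vapply(cols, function(ix) paste(ch[ix], collapse = ""), "")
  }
  out
}

#' Restrict an alignment (and its tree) to a clade
#'
#' Keeps the requested species' rows, drops columns that become all-gap,
#' and prunes the tree to match. Requested species missing from the
#' alignment are dropped with a warning.
#'
#' @param aln A `codon_alignment`.
#' @param species Character vector of row names to keep.
#' @param tree Optional `phylo` tree to prune consistently.
#' @return If `tree` is `NULL`, the subset `codon_alignment`; otherwise a
#'   list with elements `aln` and `tree`.
#' @export
clade_subset <- function(aln, species, tree = NULL) {
  missing <- setdiff(species, names(aln$seqs))
  if (length(missing)) {
    warn(sprintf("species not in alignment, skipped: %s",
                 paste(missing, collapse = ", ")))
  }
  keep <- intersect(species, names(aln$seqs))
  if (length(keep) < 2L) stop_data("fewer than 2 species remain after subsetting")
  if (!aln$ref %in% keep) {
    stop_validation("reference row %s must be retained in the subset", aln$ref)
  }
  mats <- do.call(rbind, strsplit(unname(aln$seqs[keep]), ""))
  allgap <- apply(mats == "-", 2, all)
  mats <- mats[, !allgap, drop = FALSE]
  seqs <- setNames(apply(mats, 1, paste, collapse = ""), keep)
  out <- codon_alignment(seqs, ref = aln$ref)
  if (is.null(tree)) return(out)
  list(aln = out, tree = ape::keep.tip(tree, keep))
}
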