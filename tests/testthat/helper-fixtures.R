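# shared fixtures and independent oracles

# a toy transcript tibble from explicit parts; cds includes start and stop
make_tx <- function(cds, utr5 = "", utr3 = "", id = "t1") {
  tibble::tibble(
    transcript_id = id,
    gene_id = paste0("g_", id),
    chrom = id,
    strand = "+",
    sequence = paste0(utr5, cds, utr3),
    cds_start = nchar(utr5),
    cds_end = nchar(utr5) + nchar(cds),
    stop_codon = substr(cds, nchar(cds) - 2, nchar(cds)),
    stop_genomic = nchar(utr5) + nchar(cds) - 3L
  )
}

# random non-stop codon string of n codons
random_sense <- function(n) {
  paste(sample(setdiff(sense_codons(), "ATG"), n, replace = TRUE), collapse = "")
}

# exhaustive ancestral-state summation: the independent likelihood oracle.
# All leaf codons must be observable states of the model (no gaps/stops
# outside the state space).
enum_loglik <- function(aln, tree, model) {
  cods <- alignment_ref_codons(aln)
  states <- model$states
  S <- length(states)
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  Ps <- lapply(seq_len(nrow(edges)), function(i) {
    transition_matrix(model, tree$edge.length[i])
  })
  m <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), m)))
  total <- 0
  for (j in seq_len(ncol(cods))) {
    leafstate <- match(cods[tree$tip.label, j], states)
    stopifnot(!anyNA(leafstate))
    val <- unname(model$pi[grid[, 1]])  # root = ntip + 1 is internal node 1
    for (i in seq_len(nrow(edges))) {
      p <- edges[i, 1] - ntip
      ch <- edges[i, 2]
      val <- val * if (ch <= ntip) {
        Ps[[i]][cbind(grid[, p], leafstate[ch])]
      } else {
        Ps[[i]][cbind(grid[, p], grid[, ch - ntip])]
      }
    }
    total <- total + log(sum(val))
  }
  total
}

# type-7 quantile by the direct interpolation formula (independent of
# stats::quantile)
quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# build a gapless codon_alignment from a named list of codon vectors
aln_from_codons <- function(rows, ref = names(rows)[1]) {
  codon_alignment(vapply(rows, paste, "", collapse = ""), ref = ref)
}
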