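#' Simulate a codon alignment down a phylogenetic tree
#'
#' Draws a root sequence of `n_codons` codons from the model's stationary
#' distribution and evolves it along every branch with the model's
#' transition probabilities (branch lengths in expected nucleotide
#' substitutions per site). Optional indels are then planted on terminal
#' branches as deletions of 1-3 nt, with a Poisson number of events per tip
#' of mean `indel_rate * n_codons * branch_length`; the reference row never
#' receives indels, so the alignment stays reference-framed.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param n_codons Number of codon sites.
#' @param model A `codon_model` (its regime decides whether stop codons can
#'   occur as states).
#' @param indel_rate Indel events per codon per unit branch length.
#' @param ref Reference row; defaults to the first tip label.
#' @param seed Optional integer seed (same inputs + seed give identical
#'   alignments).
#' @return A `codon_alignment`. The root codon sequence is kept in
#'   `attr(x, "root_codons")`.
#' @export
sim_codon_alignment <- function(tree, n_codons, model, indel_rate = 0,
                                ref = NULL, seed = NULL) {
  assert_count(n_codons, "n_codons")
  if (!is.numeric(indel_rate) || indel_rate < 0) {
    stop_validation("`indel_rate` must be >= 0")
  }
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop_validation("tree must have non-negative branch lengths")
  }
  states <- model$states
  ref <- ref %||% tree$tip.label[1]

  with_seed_maybe(seed, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    node_seq <- vector("list", ntip + tree$Nnode)
    node_seq[[root]] <- sample(seq_along(states), n_codons, replace = TRUE,
                               prob = model$pi)
    # parents before children: reverse postorder edge traversal
    tr <- ape::reorder.phylo(tree, "postorder")
    for (ei in rev(seq_len(nrow(tr$edge)))) {
      parent <- tr$edge[ei, 1]
      child <- tr$edge[ei, 2]
      P <- transition_matrix(model, tr$edge.length[ei])
      P[P < 0] <- 0
      ps <- node_seq[[parent]]
      cs <- integer(n_codons)
      for (s in unique(ps)) {
        at <- which(ps == s)
        cs[at] <- sample(seq_along(states), length(at), replace = TRUE,
                         prob = P[s, ])
      }
      node_seq[[child]] <- cs
    }

    tipchars <- lapply(seq_len(ntip), function(i) {
      strsplit(paste(states[node_seq[[i]]], collapse = ""), "")[[1]]
    })
    names(tipchars) <- tr$tip.label

    if (indel_rate > 0) {
      term <- match(seq_len(ntip), tr$edge[, 2])
      blen <- tr$edge.length[term]
      L <- 3L * n_codons
      for (i in seq_len(ntip)) {
        if (tr$tip.label[i] == ref) next
        n_ev <- rpois(1, indel_rate * n_codons * blen[i])
        if (n_ev == 0) next
        for (e in seq_len(n_ev)) {
          len <- sample(1:3, 1)
          pos <- sample.int(L - len + 1L, 1)
          tipchars[[i]][pos:(pos + len - 1L)] <- "-"
        }
      }
    }

    aln <- codon_alignment(vapply(tipchars, paste, "", collapse = ""), ref = ref)
    attr(aln, "root_codons") <- states[node_seq[[root]]]
    aln
  })
}

#' Deterministic balanced tree for alignment simulations
#'
#' A balanced bifurcating tree with equal branch lengths, used as the fixed
#' phylogeny of the simulation experiments (a stand-in for the shallow
#' primate clades real alignments come with). With the defaults (8 taxa,
#' 0.15 substitutions/site per branch) the total tree length is 2.1, deep
#' enough for a 66-codon region to carry usable coding signature.
#'
#' @param n_taxa Number of tips (a power of 2).
#' @param branch_length Length of every branch, in expected nucleotide
#'   substitutions per site.
#' @return An [ape::phylo] tree with tips `sp1..spN`.
#' @export
sim_tree <- function(n_taxa = 8L, branch_length = 0.15) {
  assert_count(n_taxa, "n_taxa", min = 2L)
  tree <- ape::stree(n_taxa, "balanced")
  tree$tip.label <- paste0("sp", seq_len(n_taxa))
  tree$edge.length <- rep(branch_length, nrow(tree$edge))
  tree
}
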