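# leaf partial-likelihood matrix (states x columns) for one species:
# unit vector for an observed state, all-ones for gapped/ambiguous/unmodelled
# codons (missing data), and for columns masked as missing
leaf_partials <- function(codons, states, mask = NULL) {
  S <- length(states)
  K <- length(codons)
  m <- matrix(0, S, K)
  ix <- match(codons, states)
  for (j in seq_len(K)) {
    if (is.na(ix[j]) || (!is.null(mask) && mask[j])) m[, j] <- 1 else m[ix[j], j] <- 1
  }
  m
}

#' Phylogenetic log-likelihood of a codon alignment by Felsenstein pruning
#'
#' Computes the log-likelihood (nats) of the reference-frame codon columns
#' of `aln` under a [build_codon_model()] substitution model on `tree`,
#' by post-order accumulation of partial likelihoods with per-column
#' scaling. Codons containing gaps or ambiguity codes — and, under the
#' coding model, stop codons, which are outside its state space — are
#' treated as missing data (all-ones partials). Columns are independent;
#' the total is the sum over codon columns.
#'
#' @param aln A `codon_alignment`.
#' @param tree An [ape::phylo] tree whose tip labels include all alignment
#'   rows; extra tips are pruned. Branch lengths are expected nucleotide
#'   substitutions per site.
#' @param model A `codon_model`.
#' @param missing_mask Optional logical matrix (species x reference codons)
#'   marking additional cells to treat as missing.
#' @return Total log-likelihood in nats, with attribute `"per_column"`.
#' @export
felsenstein_loglik <- function(aln, tree, model, missing_mask = NULL) {
  cods <- alignment_ref_codons(aln)
  K <- ncol(cods)
  if (K == 0L) stop_data("alignment has no complete reference-frame codons")
  sp <- rownames(cods)
  states <- model$states
  pi <- model$pi

  if (length(sp) == 1L) {
    part <- leaf_partials(cods[1, ], states,
                          mask = if (!is.null(missing_mask)) missing_mask[sp, ] else NULL)
    percol <- log(colSums(pi * part))
    total <- sum(percol)
    attr(total, "per_column") <- percol
    return(total)
  }

  absent <- setdiff(sp, tree$tip.label)
  if (length(absent)) {
    stop_data("alignment species absent from tree: %s",
              paste(absent, collapse = ", "))
  }
  if (length(setdiff(tree$tip.label, sp))) tree <- ape::keep.tip(tree, sp)

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  children <- vector("list", nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    children[[p]] <- c(children[[p]], i)
  }

  partials <- vector("list", nnode)
  logscale <- rep(0, K)
  for (i in seq_len(ntip)) {
    nm <- tree$tip.label[i]
    partials[[i]] <- leaf_partials(
      cods[nm, ], states,
      mask = if (!is.null(missing_mask)) missing_mask[nm, ] else NULL)
  }

  visit <- function(node) {
    if (node <= ntip) return(partials[[node]])
    acc <- matrix(1, length(states), K)
    for (ei in children[[node]]) {
      child <- tree$edge[ei, 2]
      P <- transition_matrix(model, tree$edge.length[ei])
      P[P < 0] <- 0  # clip eigendecomposition round-off so log(0) stays -Inf
      acc <- acc * (P %*% visit(child))
    }
    cmax <- apply(acc, 2, max)
    cmax[cmax == 0] <- 1  # impossible column: leave zeros, log(0) surfaces at root
    logscale <<- logscale + log(cmax)
    sweep(acc, 2, cmax, "/")
  }

  root <- ntip + 1L
  rootpart <- visit(root)
  percol <- log(colSums(pi * rootpart)) + logscale
  total <- sum(percol)
  attr(total, "per_column") <- percol
  total
}

#' Coding-potential score of an alignment region
#'
#' The score is the log-likelihood ratio of a coding versus a noncoding
#' phylogenetic codon model over the reference-frame codons of `aln`,
#' expressed in decibans (10 * log10 of the ratio): positive scores favour
#' protein-coding evolution. The scored region is the alignment as given
#' and must already exclude the bounding stop codons. Stop codons inside
#' the region (which the coding model's state space excludes) are masked —
#' treated as missing under both models, so the ratio compares the two
#' regimes on identical effective data; the count of masked reference-row
#' stops is reported.
#'
#' @param aln A `codon_alignment` of the region between the stops.
#' @param tree An [ape::phylo] tree covering the alignment rows.
#' @param coding,noncoding Optional `codon_model`s; by default built with
#'   `kappa`, `omega` and F3x4 frequencies estimated from the alignment.
#' @param kappa,omega Parameters for the default models.
#' @return A `csf_score` object: `score` (decibans), `logL_coding`,
#'   `logL_noncoding` (nats), `n_codons`, `species_used`,
#'   `masked_ref_stops`. Has `tidy()`/`glance()` methods.
#' @export
csf_score <- function(aln, tree, coding = NULL, noncoding = NULL,
                      kappa = 2.5, omega = 0.2) {
  cods <- alignment_ref_codons(aln)
  if (ncol(cods) == 0L) stop_data("empty scored region")
  if (is.null(coding) || is.null(noncoding)) {
    freqs <- alignment_nuc_freqs(aln)
    if (is.null(coding)) coding <- build_codon_model("coding", kappa, omega, freqs)
    if (is.null(noncoding)) noncoding <- build_codon_model("noncoding", kappa,
                                                           nuc_freqs = freqs)
  }
  if (coding$regime != "coding" || noncoding$regime != "noncoding") {
    stop_validation("models must be a coding and a noncoding codon_model")
  }
  # stop codons are outside the coding state space; mask them as missing
  # under BOTH models so the likelihood ratio compares the two regimes on
  # the same effective data rather than rewarding the model that skips a cell
  ref_stops <- is_stop_codon(cods[aln$ref, ])
  stop_cells <- matrix(is_stop_codon(cods), nrow(cods), ncol(cods),
                       dimnames = dimnames(cods))
  mask <- if (any(stop_cells)) stop_cells else NULL
  lc <- felsenstein_loglik(aln, tree, coding, missing_mask = mask)
  ln <- felsenstein_loglik(aln, tree, noncoding, missing_mask = mask)
  structure(
    list(score = (10 / log(10)) * (as.numeric(lc) - as.numeric(ln)),
         logL_coding = as.numeric(lc), logL_noncoding = as.numeric(ln),
         n_codons = ncol(cods), species_used = rownames(cods),
         masked_ref_stops = sum(ref_stops)),
    class = "csf_score"
  )
}

#' @export
print.csf_score <- function(x, ...) {
  cat(sprintf("coding-potential score: %.2f decibans over %d codons, %d species\n",
              x$score, x$n_codons, length(x$species_used)))
  if (x$masked_ref_stops > 0) {
    cat(sprintf("  (%d reference stop codon(s) masked for the coding model)\n",
                x$masked_ref_stops))
  }
  invisible(x)
}

#' @rdname csf_score
#' @param x A `csf_score`.
#' @param ... Unused.
#' @export
tidy.csf_score <- function(x, ...) {
  tibble(score = x$score, logL_coding = x$logL_coding,
         logL_noncoding = x$logL_noncoding, n_codons = x$n_codons,
         n_species = length(x$species_used),
         masked_ref_stops = x$masked_ref_stops)
}

#' @rdname csf_score
#' @export
glance.csf_score <- function(x, ...) {
  tibble(score = x$score, n_codons = x$n_codons,
         n_species = length(x$species_used))
}

#' Percentile of a score against an empirical background
#'
#' Fraction of background scores strictly below `score` — the convention
#' under which a score equal to the background minimum sits at percentile 0
#' and one above every background value at percentile 1.
#'
#' @param score A score in decibans.
#' @param background Numeric vector of background scores.
#' @return Fraction in `[0, 1]`.
#' @export
background_percentile <- function(score, background) {
  if (length(background) == 0L) stop_data("empty background")
  mean(background < score)
}
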