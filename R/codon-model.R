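nt_order <- c("T", "C", "A", "G")

is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

# 4x4 HKY rate matrix, scaled to 1 expected substitution per unit time
hky_matrix <- function(kappa, freqs) {
  freqs <- freqs[nt_order]
  Q <- matrix(0, 4, 4, dimnames = list(nt_order, nt_order))
  for (a in nt_order) for (b in nt_order) {
    if (a == b) next
    Q[a, b] <- freqs[b] * if (is_transition(a, b)) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  rate <- -sum(freqs * diag(Q))
  Q / rate
}

#' Build a phylogenetic codon substitution model
#'
#' Two regimes over the 64-codon state space:
#' * `coding`: a GY94-style model restricted to the 61 sense codons. Single
#'   nucleotide changes get rate `kappa` (transitions) or 1 (transversions)
#'   times the stationary frequency of the target nucleotide at that codon
#'   position, times `omega` when the change is nonsynonymous. Stop codons
#'   carry zero stationary mass and no flow.
#' * `noncoding`: three independent HKY nucleotide processes, one per codon
#'   position, composed onto the codon space (so its transition matrix is
#'   the tensor product of three 4x4 HKY transition matrices); stop codons
#'   are ordinary states.
#'
#' Both models are time-reversible and scaled so one unit of branch length
#' is one expected nucleotide substitution per site (3 per codon).
#'
#' @param regime `"coding"` or `"noncoding"`.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (> 0; coding only).
#' @param nuc_freqs Nucleotide frequencies: either a named length-4 vector
#'   shared by all positions, or a 3 x 4 matrix of per-position frequencies
#'   (F3x4 style), columns named `A`,`C`,`G`,`T`.
#' @return A `codon_model` object with elements `regime`, `states` (codon
#'   names), `pi` (stationary distribution), `Q`, and a cached spectral
#'   decomposition used by [transition_matrix()].
#' @examples
#' m <- build_codon_model("coding", kappa = 2.5, omega = 0.2)
#' sum(m$pi)
#' @export
build_codon_model <- function(regime = c("coding", "noncoding"),
                              kappa = 2.5, omega = 0.2,
                              nuc_freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  regime <- match.arg(regime)
  if (!is.numeric(kappa) || kappa <= 0) stop_validation("`kappa` must be > 0")
  if (regime == "coding" && (!is.numeric(omega) || omega <= 0)) {
    stop_validation("`omega` must be > 0 for the coding regime")
  }
  if (is.matrix(nuc_freqs)) {
    if (!identical(dim(nuc_freqs), c(3L, 4L))) {
      stop_validation("`nuc_freqs` matrix must be 3 x 4")
    }
    fmat <- nuc_freqs[, c("A", "C", "G", "T")]
  } else {
    fmat <- matrix(rep(nuc_freqs[c("A", "C", "G", "T")], each = 3), 3, 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  }
  for (i in 1:3) {
    assert_prob_vector(fmat[i, ], sprintf("nuc_freqs[position %d]", i), tol = 1e-6)
    if (any(fmat[i, ] <= 0)) {
      stop_validation("nucleotide frequencies must all be positive")
    }
    fmat[i, ] <- fmat[i, ] / sum(fmat[i, ])
  }

  codons <- all_codons()
  codon_nt <- do.call(rbind, strsplit(codons, ""))
  tab <- codon_translation_table()

  if (regime == "noncoding") {
    states <- codons
    pi <- fmat[1, codon_nt[, 1]] * fmat[2, codon_nt[, 2]] * fmat[3, codon_nt[, 3]]
    names(pi) <- states
    hkys <- lapply(1:3, function(p) hky_matrix(kappa, fmat[p, ]))
    n <- length(states)
    Q <- matrix(0, n, n, dimnames = list(states, states))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(codon_nt[i, ] != codon_nt[j, ])
      if (length(diff) == 1L) {
        p <- diff
        Q[i, j] <- hkys[[p]][codon_nt[i, p], codon_nt[j, p]]
      }
    }
    diag(Q) <- -rowSums(Q)
  } else {
    states <- codons[tab[codons] != "*"]
    snt <- codon_nt[match(states, codons), ]
    pi <- fmat[1, snt[, 1]] * fmat[2, snt[, 2]] * fmat[3, snt[, 3]]
    pi <- pi / sum(pi)
    names(pi) <- states
    n <- length(states)
    Q <- matrix(0, n, n, dimnames = list(states, states))
    aa <- tab[states]
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(snt[i, ] != snt[j, ])
      if (length(diff) == 1L) {
        p <- diff
        r <- fmat[p, snt[j, p]] *
          (if (is_transition(snt[i, p], snt[j, p])) kappa else 1)
        if (aa[i] != aa[j]) r <- r * omega
        Q[i, j] <- r
      }
    }
    diag(Q) <- -rowSums(Q)
    rate <- -sum(pi * diag(Q))
    Q <- Q * (3 / rate)  # 3 nucleotide sites per codon
  }

  # symmetric-form spectral decomposition of the reversible generator
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)

  structure(
    list(regime = regime, kappa = kappa,
         omega = if (regime == "coding") omega else NA_real_,
         freqs = fmat, states = states, pi = pi, Q = Q,
         eig_values = eig$values,
         eig_left = (1 / sq) * eig$vectors,        # D^{-1/2} U
         eig_right = t(eig$vectors * sq)),         # U' D^{1/2}
    class = "codon_model"
  )
}

#' Transition probability matrix of a codon model
#'
#' Computes `exp(Q t)` via the cached symmetric eigendecomposition of the
#' reversible generator.
#'
#' @param model A `codon_model`.
#' @param t Branch length in expected nucleotide substitutions per site.
#' @return Row-stochastic matrix over the model's states.
#' @export
transition_matrix <- function(model, t) {
  if (!inherits(model, "codon_model")) stop_validation("`model` must be a codon_model")
  if (!is.numeric(t) || t < 0) stop_validation("branch length must be >= 0")
  P <- model$eig_left %*% (exp(model$eig_values * t) * model$eig_right)
  dimnames(P) <- list(model$states, model$states)
  P
}

#' @export
print.codon_model <- function(x, ...) {
  cat(sprintf("codon_model: %s regime, %d states, kappa = %g%s\n",
              x$regime, length(x$states), x$kappa,
              if (x$regime == "coding") sprintf(", omega = %g", x$omega) else ""))
  invisible(x)
}

#' Estimate per-position nucleotide frequencies from an alignment (F3x4)
#'
#' Counts nucleotides at the three codon positions of the reference frame
#' across all rows of the alignment, ignoring gaps and ambiguity codes.
#' A small pseudocount keeps every frequency positive.
#'
#' @param aln A `codon_alignment`.
#' @param pseudocount Added to every cell before normalising.
#' @return 3 x 4 matrix of frequencies, columns `A`,`C`,`G`,`T`.
#' @export
alignment_nuc_freqs <- function(aln, pseudocount = 0.5) {
  cods <- alignment_ref_codons(aln)
  nt <- c("A", "C", "G", "T")
  counts <- matrix(pseudocount, 3, 4, dimnames = list(NULL, nt))
  for (sp in rownames(cods)) {
    for (p in 1:3) {
      ch <- substring(cods[sp, ], p, p)
      tab <- table(factor(ch, levels = nt))
      counts[p, ] <- counts[p, ] + as.numeric(tab)
    }
  }
  counts / rowSums(counts)
}
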