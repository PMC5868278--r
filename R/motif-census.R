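parse_motif <- function(motif) {
  if (is.character(motif) && length(motif) == 1L && grepl(":", motif)) {
    parts <- toupper(strsplit(motif, ":", fixed = TRUE)[[1]])
  } else if (length(motif) == 2L) {
    parts <- toupper(unlist(motif))
  } else {
    stop_validation('`motif` must be "STOP:EXT", e.g. "TGA:CTAG"')
  }
  if (!is_stop_codon(parts[1]) || grepl("[^ACGT]", parts[2])) {
    stop_validation("motif stop must be TAA/TAG/TGA and extension must be DNA")
  }
  list(stop = parts[1], ext = parts[2])
}

#' Scan stop contexts for a stop-codon + downstream motif
#'
#' A context is a hit iff its stop codon equals the motif's stop codon and
#' its downstream sequence begins with the motif's extension (exact,
#' case-insensitive match). Contexts whose downstream flank is shorter than
#' the extension, or contains `N` within it, are ineligible: they join
#' neither the trials nor the hits.
#'
#' @param contexts Tibble from [extract_stop_context()].
#' @param motif Motif as `"STOP:EXT"` (default `"TGA:CTAG"`, the readthrough
#'   motif) or a length-2 vector `c(stop, ext)`.
#' @return The contexts with logical columns `eligible` and `hit` added.
#' @export
scan_motif <- function(contexts, motif = "TGA:CTAG") {
  m <- parse_motif(motif)
  w <- nchar(m$ext)
  head_ext <- toupper(substring(contexts$downstream, 1L, w))
  stop_match <- toupper(contexts$stop_codon) == m$stop
  eligible <- stop_match & nchar(contexts$downstream) >= w & !grepl("[^ACGT]", head_ext)
  mutate(contexts,
         eligible = eligible,
         hit = eligible & head_ext == m$ext)
}

#' Position-specific nucleotide frequencies downstream of a stop codon
#'
#' Empirical frequencies of `A`,`C`,`G`,`T` at each of the first `width`
#' positions 3' of the given stop codon, over contexts with at least `width`
#' unambiguous downstream nucleotides. These are the independence null for
#' the motif expectation.
#'
#' @param contexts Tibble from [extract_stop_context()].
#' @param stop_codon Stop codon to restrict to (default `"TGA"`).
#' @param width Number of downstream positions (default 4).
#' @return `width` x 4 matrix of frequencies; rows sum to 1. The number of
#'   contexts used is in `attr(x, "n_contexts")`.
#' @export
position_freqs <- function(contexts, stop_codon = "TGA", width = 4L) {
  sub <- contexts[toupper(contexts$stop_codon) == toupper(stop_codon), , drop = FALSE]
  head4 <- toupper(substring(sub$downstream, 1L, width))
  ok <- nchar(sub$downstream) >= width & !grepl("[^ACGT]", head4)
  head4 <- head4[ok]
  if (length(head4) == 0L) {
    stop_data("no eligible %s-stop contexts with %d downstream nt", stop_codon, width)
  }
  nt <- c("A", "C", "G", "T")
  f <- t(vapply(seq_len(width), function(i) {
    tab <- table(factor(substring(head4, i, i), levels = nt))
    as.numeric(tab) / length(head4)
  }, numeric(4)))
  dimnames(f) <- list(paste0("pos", seq_len(width)), nt)
  attr(f, "n_contexts") <- length(head4)
  f
}

#' One-sided binomial depletion/enrichment test for a motif count
#'
#' Tests an observed motif count against the independence-null expectation
#' `n_trials * p_motif`. The one-sided direction defaults to whichever tail
#' the data fall in (depletion when observed < expected, enrichment
#' otherwise); the lower-tail p-value is `P(X <= observed)`, the upper tail
#' `P(X >= observed)`. `poisson_limit` mode replaces the binomial by a
#' Poisson with `lambda = n_trials * p_motif`.
#'
#' @param observed Observed motif count.
#' @param n_trials Number of eligible contexts (trials).
#' @param p_motif Null motif probability per trial.
#' @param mode `"exact_binomial"` (default) or `"poisson_limit"`.
#' @param direction `"auto"`, `"depletion"` or `"enrichment"`.
#' @param motif Optional motif label carried into the result.
#' @return A `census_result` object: list with `observed`, `n_trials`,
#'   `p_motif`, `expected`, `p_value`, `direction`, `mode`. Has
#'   [generics::tidy()] and [generics::glance()] methods.
#' @examples
#' depletion_test(23, 10000, 0.0039)
#' depletion_test(23, 10000, 39 / 10000, mode = "poisson_limit")
#' @export
depletion_test <- function(observed, n_trials, p_motif,
                           mode = c("exact_binomial", "poisson_limit"),
                           direction = c("auto", "depletion", "enrichment"),
                           motif = NA_character_) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  assert_count(observed, "observed", min = 0L)
  if (!is.numeric(n_trials) || n_trials < 1) stop_data("`n_trials` must be >= 1")
  assert_fraction(p_motif, "p_motif")
  expected <- n_trials * p_motif
  if (direction == "auto") {
    direction <- if (observed < expected) "depletion" else "enrichment"
  }
  p_value <- switch(
    mode,
    exact_binomial = if (direction == "depletion") {
      pbinom(observed, n_trials, p_motif)
    } else {
      pbinom(observed - 1L, n_trials, p_motif, lower.tail = FALSE)
    },
    poisson_limit = if (direction == "depletion") {
      ppois(observed, expected)
    } else {
      ppois(observed - 1L, expected, lower.tail = FALSE)
    }
  )
  structure(
    list(motif = motif, observed = as.integer(observed),
         n_trials = as.integer(n_trials), p_motif = p_motif,
         expected = expected, p_value = p_value,
         direction = direction, mode = mode, position_freqs = NULL),
    class = "census_result"
  )
}

#' Census of a stop-context motif with depletion/enrichment test
#'
#' Runs the full census on a set of (deduplicated) stop contexts: estimates
#' the position-specific nucleotide frequencies after the motif's stop
#' codon, forms the null motif probability as the product of the marginal
#' frequencies of the motif nucleotides, counts motif hits, and applies the
#' one-sided test.
#'
#' @inheritParams scan_motif
#' @inheritParams depletion_test
#' @return A `census_result` with `position_freqs` attached.
#' @export
census <- function(contexts, motif = "TGA:CTAG",
                   mode = c("exact_binomial", "poisson_limit"),
                   direction = c("auto", "depletion", "enrichment")) {
  m <- parse_motif(motif)
  scanned <- scan_motif(contexts, motif)
  n_trials <- sum(scanned$eligible)
  if (n_trials == 0L) stop_data("no eligible contexts for motif %s:%s", m$stop, m$ext)
  freqs <- position_freqs(contexts, stop_codon = m$stop, width = nchar(m$ext))
  motif_nt <- strsplit(m$ext, "")[[1]]
  p_motif <- prod(vapply(seq_along(motif_nt),
                         function(i) freqs[i, motif_nt[i]], 0))
  res <- depletion_test(sum(scanned$hit), n_trials, p_motif,
                        mode = match.arg(mode), direction = match.arg(direction),
                        motif = paste(m$stop, m$ext, sep = ":"))
  res$position_freqs <- freqs
  res
}

#' @export
print.census_result <- function(x, ...) {
  cat(sprintf("Stop-context motif census (%s)\n", x$motif %||% "?"))
  cat(sprintf("  observed %d of %d trials; expected %.1f (p_motif = %.4g)\n",
              x$observed, x$n_trials, x$expected, x$p_motif))
  cat(sprintf("  one-sided %s p-value (%s): %.4g\n",
              x$direction, x$mode, x$p_value))
  invisible(x)
}

#' @rdname depletion_test
#' @param x A `census_result`.
#' @param ... Unused.
#' @export
tidy.census_result <- function(x, ...) {
  tibble(motif = x$motif, observed = x$observed, n_trials = x$n_trials,
         expected = x$expected, p_motif = x$p_motif,
         p_value = x$p_value, direction = x$direction, mode = x$mode)
}

#' @rdname depletion_test
#' @export
glance.census_result <- function(x, ...) {
  tibble(p_value = x$p_value, direction = x$direction,
         observed = x$observed, expected = x$expected)
}
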