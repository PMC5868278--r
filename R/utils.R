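#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows distinct n left_join across
#' @importFrom stats quantile setNames rbinom rlnorm runif rpois pbinom ppois
#'   median ecdf
NULL

# classed conditions: "validation" = bad arguments/spec, "data" = bad input data
stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "readthrough_validation_error")
}

stop_data <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "readthrough_data_error")
}

# run code with a temporary RNG seed; NULL seed leaves the RNG stream alone
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_validation("`%s` must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

assert_prob_vector <- function(p, name, tol = 1e-9) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0)) {
    stop_validation("`%s` must be non-negative numeric", name)
  }
  if (abs(sum(p) - 1) > tol) {
    stop_validation("`%s` must sum to 1 (got %.12f)", name, sum(p))
  }
  invisible(p)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_validation("`%s` must be a single number in [0, 1]", name)
  }
  invisible(x)
}

is_stop_codon <- function(codon) toupper(codon) %in% c("TAA", "TAG", "TGA")

# split a DNA string into codons, dropping a trailing partial codon
split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

random_dna <- function(n, freqs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}
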