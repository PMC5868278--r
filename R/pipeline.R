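with_stage <- function(stage, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", stage, conditionMessage(e)),
            class = class(e)[1], parent = e)
    }),
    warning = function(w) {
      warn(sprintf("[%s] %s", stage, conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
}

#' Run the stop-context motif census end to end
#'
#' Chains transcript loading (or takes a transcript tibble directly),
#' stop-context extraction, genomic deduplication, motif scanning and the
#' one-sided depletion/enrichment test. Errors are labelled with the stage
#' that raised them.
#'
#' @param transcripts Transcript tibble from [load_transcripts()] or
#'   [sim_transcriptome()]; alternatively give `fasta` and `gtf`.
#' @param fasta,gtf Input paths, used when `transcripts` is `NULL`.
#' @param motif Motif as `"STOP:EXT"` (default `"TGA:CTAG"`).
#' @param mode Test mode, `"exact_binomial"` or `"poisson_limit"`.
#' @param dedupe Count unique genomic stops (default) rather than
#'   transcripts.
#' @param stop_in_cds Passed to [load_transcripts()].
#' @return A list with `result` (the `census_result`), `contexts`,
#'   `n_transcript_hits`/`n_transcript_trials` (transcript-level counts,
#'   before deduplication) and `n_duplicates`.
#' @export
run_census <- function(transcripts = NULL, fasta = NULL, gtf = NULL,
                       motif = "TGA:CTAG",
                       mode = c("exact_binomial", "poisson_limit"),
                       dedupe = TRUE, stop_in_cds = FALSE) {
  mode <- match.arg(mode)
  if (is.null(transcripts)) {
    if (is.null(fasta) || is.null(gtf)) {
      stop_validation("give `transcripts` or both `fasta` and `gtf`")
    }
    transcripts <- with_stage("load_transcripts",
                              load_transcripts(fasta, gtf, stop_in_cds))
  }
  if (nrow(transcripts) == 0L) stop_data("[load_transcripts] empty transcript set")
  contexts <- with_stage("extract_stop_context", extract_stop_context(transcripts))
  tx_scan <- with_stage("scan_motif", scan_motif(contexts, motif))
  deduped <- if (dedupe) with_stage("dedupe_stops", dedupe_stops(contexts)) else contexts
  result <- with_stage("depletion_test", census(deduped, motif = motif, mode = mode))
  list(result = result,
       contexts = deduped,
       n_transcript_hits = sum(tx_scan$hit),
       n_transcript_trials = sum(tx_scan$eligible),
       n_duplicates = attr(deduped, "n_duplicates") %||% 0L)
}

#' Score a readthrough region and call frame-integrity events
#'
#' Chains optional clade subsetting, coding-potential scoring, percentile
#' ranking against a background score distribution, and per-species
#' frame-integrity calling.
#'
#' @param aln A `codon_alignment` of the extension region; when
#'   `second_stop_index` is given the alignment is assumed to include the
#'   second stop at that reference codon index, and scoring excludes it
#'   and everything beyond.
#' @param tree An [ape::phylo] tree.
#' @param species Optional clade to restrict to (see [clade_subset()]).
#' @param background Numeric vector of background scores (decibans); `NULL`
#'   skips the percentile.
#' @param second_stop_index Optional 1-based reference codon index of the
#'   second stop within `aln`; `NULL` skips frame-integrity calling and
#'   scores the full alignment.
#' @param kappa,omega Model parameters for [csf_score()].
#' @return List with `score` (`csf_score`), `percentile` (or `NA`),
#'   `events` (frame-event tibble or `NULL`), `aln`, `tree`.
#' @export
run_score <- function(aln, tree, species = NULL, background = NULL,
                      second_stop_index = NULL, kappa = 2.5, omega = 0.2) {
  if (!is.null(species)) {
    sub <- with_stage("clade_subset", clade_subset(aln, species, tree))
    aln <- sub$aln
    tree <- sub$tree
  }
  events <- NULL
  scored_aln <- aln
  if (!is.null(second_stop_index)) {
    events <- with_stage("frame_integrity", frame_integrity(aln, second_stop_index))
    scored_aln <- with_stage("frame_integrity",
                             trim_to_region(aln, second_stop_index))
  }
  score <- with_stage("csf_score",
                      csf_score(scored_aln, tree, kappa = kappa, omega = omega))
  pct <- if (is.null(background)) NA_real_ else
    with_stage("background_percentile",
               background_percentile(score$score, background))
  list(score = score, percentile = pct, events = events,
       aln = scored_aln, tree = tree)
}

# keep the reference codons strictly before the second stop
trim_to_region <- function(aln, second_stop_index) {
  cols <- ref_codon_columns(aln)
  if (second_stop_index < 2L) stop_data("empty region before the second stop")
  keep_cols <- seq_len(cols[[second_stop_index]][1] - 1L)
  seqs <- vapply(aln$seqs, function(s) substring(s, 1L, length(keep_cols)), "")
  codon_alignment(seqs, ref = aln$ref)
}

#' Run the dual-luciferase readthrough quantification
#'
#' Loads a plate CSV (or takes a plate tibble) and computes per-construct
#' readthrough efficiencies with box-plot summaries.
#'
#' @param plate Plate tibble; alternatively give `csv`.
#' @param csv Path to a CSV with columns `batch`, `construct`, `variant`,
#'   `treatment`, `dose`, `replicate`, `firefly`, `renilla`.
#' @param ... Passed to [readthrough_efficiency()].
#' @return An `efficiency_result` tibble.
#' @export
run_assay <- function(plate = NULL, csv = NULL, ...) {
  if (is.null(plate)) {
    if (is.null(csv)) stop_validation("give `plate` or `csv`")
    plate <- with_stage("load_plate",
                        as_tibble(utils::read.csv(csv, stringsAsFactors = FALSE)))
  }
  with_stage("readthrough_efficiency", readthrough_efficiency(plate, ...))
}
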