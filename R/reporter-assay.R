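#' Relative luciferase activity (firefly / Renilla)
#'
#' Adds a `rel_activity` column. Rows with non-positive firefly or Renilla
#' readings are rejected (removed) with a warning; the rejected rows and
#' reasons are kept in `attr(x, "rejected")`.
#'
#' @param plate A plate tibble with `firefly` and `renilla` columns.
#' @return The plate with `rel_activity` added and bad rows removed.
#' @export
relative_activity <- function(plate) {
  bad <- !(plate$firefly > 0 & plate$renilla > 0) | is.na(plate$firefly) |
    is.na(plate$renilla)
  rejected <- plate[bad, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- ifelse(!(rejected$renilla > 0) | is.na(rejected$renilla),
                              "nonpositive_renilla", "nonpositive_firefly")
    warn(sprintf("%d plate row(s) rejected for non-positive readings",
                 nrow(rejected)))
  }
  out <- plate[!bad, , drop = FALSE]
  out <- mutate(out, rel_activity = .data$firefly / .data$renilla)
  attr(out, "rejected") <- rejected
  out
}

#' Box-plot summary statistics (R type-7 convention)
#'
#' Quartiles use the type-7 empirical quantile convention; whiskers extend
#' to the most extreme values within 1.5 interquartile ranges of the box
#' limits; values beyond are outliers.
#'
#' @param values Numeric vector (at least one value).
#' @return One-row tibble with `n`, `median`, `q25`, `q75`, `whisker_lo`,
#'   `whisker_hi` and a list-column `outliers`.
#' @examples
#' boxplot_stats(1:5)
#' @export
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop_data("no values to summarise")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_lim <- q[1] - 1.5 * iqr
  hi_lim <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_lim & values <= hi_lim]
  tibble(
    n = length(values), median = q[2], q25 = q[1], q75 = q[3],
    whisker_lo = min(inside), whisker_hi = max(inside),
    outliers = list(values[values < lo_lim | values > hi_lim])
  )
}

#' Readthrough efficiency from a dual-luciferase plate
#'
#' Per-replicate readthrough efficiency is 100 times the relative
#' luciferase activity (firefly/Renilla) of a test (stop-codon) well
#' divided by the control (sense-codon) activity of the same construct and
#' batch. The default `control_mean` mode divides by the mean control
#' relative activity of the batch; `paired` mode divides each test
#' replicate by the control replicate with the same index.
#'
#' @param plate Plate tibble (columns `batch`, `construct`, `variant`,
#'   `replicate`, `firefly`, `renilla`).
#' @param test_variant,control_variant Variant labels (defaults `TGA`,
#'   `TGG`).
#' @param mode `"control_mean"` (default) or `"paired"`.
#' @return A tibble of class `efficiency_result`: one row per
#'   (batch, construct) with box-plot summaries of the per-replicate
#'   efficiencies (percent) and a list-column `efficiencies`.
#' @export
readthrough_efficiency <- function(plate, test_variant = "TGA",
                                   control_variant = "TGG",
                                   mode = c("control_mean", "paired")) {
  mode <- match.arg(mode)
  plate <- relative_activity(plate)
  groups <- distinct(plate[plate$variant == test_variant, c("batch", "construct")])
  if (nrow(groups) == 0L) stop_data("no %s test rows in plate", test_variant)
  rows <- lapply(seq_len(nrow(groups)), function(k) {
    b <- groups$batch[k]
    con <- groups$construct[k]
    test <- plate[plate$batch == b & plate$construct == con &
                    plate$variant == test_variant, , drop = FALSE]
    ctrl <- plate[plate$batch == b & plate$construct == con &
                    plate$variant == control_variant, , drop = FALSE]
    if (nrow(ctrl) == 0L) {
      stop_data("no %s control replicates for construct %s (batch %s)",
                control_variant, con, b)
    }
    eff <- if (mode == "control_mean") {
      100 * test$rel_activity / mean(ctrl$rel_activity)
    } else {
      m <- match(test$replicate, ctrl$replicate)
      if (anyNA(m)) stop_data("paired mode: unmatched replicate indices for %s", con)
      100 * test$rel_activity / ctrl$rel_activity[m]
    }
    stats <- boxplot_stats(eff)
    mutate(stats, batch = b, construct = con, efficiencies = list(eff),
           .before = 1)
  })
  out <- bind_rows(rows)
  class(out) <- c("efficiency_result", class(out))
  out
}

#' Transactivation fold-change from stimulated and vehicle wells
#'
#' Fold-change per construct = mean stimulated relative activity divided by
#' mean vehicle relative activity, with a delta-method standard error from
#' the replicate dispersion of both arms.
#'
#' @param plate Plate tibble with a `treatment` column.
#' @param stimulated,vehicle Treatment labels.
#' @param group Grouping columns (default `construct`).
#' @return Tibble with `fold`, `fold_se`, `n_stimulated`, `n_vehicle` per
#'   group.
#' @export
transactivation_fold <- function(plate, stimulated = "stimulated",
                                 vehicle = "vehicle", group = "construct") {
  plate <- relative_activity(plate)
  groups <- distinct(plate[, group, drop = FALSE])
  rows <- lapply(seq_len(nrow(groups)), function(k) {
    sel <- rep(TRUE, nrow(plate))
    for (g in group) sel <- sel & plate[[g]] == groups[[g]][k]
    stim <- plate$rel_activity[sel & plate$treatment == stimulated]
    veh <- plate$rel_activity[sel & plate$treatment == vehicle]
    if (length(veh) == 0L) {
      stop_data("missing vehicle arm for group %s",
                paste(unlist(groups[k, ]), collapse = "/"))
    }
    if (length(stim) == 0L) {
      stop_data("missing stimulated arm for group %s",
                paste(unlist(groups[k, ]), collapse = "/"))
    }
    fold <- mean(stim) / mean(veh)
    rel_var <- stats::var(stim) / (length(stim) * mean(stim)^2) +
      stats::var(veh) / (length(veh) * mean(veh)^2)
    mutate(groups[k, , drop = FALSE],
           fold = fold,
           fold_se = fold * sqrt(pmax(rel_var, 0)),
           n_stimulated = length(stim), n_vehicle = length(veh))
  })
  bind_rows(rows)
}
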