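#' Compare a predicted structure with a trusted one
#'
#' A base pair is a true positive if present in both structures (both
#' endpoints equal), a false positive if only in the prediction, a false
#' negative if only in the trusted structure. Sensitivity is
#' `TP / (TP + FN)`, positive predictive value `TP / (TP + FP)`, F-score
#' `2 TP / (2 TP + FN + FP)`; all are 0 when their denominator is 0.
#'
#' @param predicted,trusted `rna_structure` objects of equal length.
#' @return A list of class `metric_report` with `tp`, `fp`, `fn`,
#'   `sensitivity`, `ppv`, `fscore`.
#' @export
compare_structures <- function(predicted, trusted) {
  if (predicted$length != trusted$length)
    stop("structures have different lengths")
  kp <- paste(predicted$pairs[, 1], predicted$pairs[, 2])
  kt <- paste(trusted$pairs[, 1], trusted$pairs[, 2])
  tp <- length(intersect(kp, kt))
  metric_report(tp, length(kp) - tp, length(kt) - tp)
}

metric_report <- function(tp, fp, fn) {
  rat <- function(num, den) if (den == 0) 0 else num / den
  structure(list(tp = tp, fp = fp, fn = fn,
                 sensitivity = rat(tp, tp + fn),
                 ppv = rat(tp, tp + fp),
                 fscore = rat(2 * tp, 2 * tp + fn + fp)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d fn=%d  sensitivity=%.4f ppv=%.4f F=%.4f\n",
              x$tp, x$fp, x$fn, x$sensitivity, x$ppv, x$fscore))
  invisible(x)
}

#' Mountain metric distance between two structures
#'
#' The mountain profile of a structure assigns to each position `i` the
#' number of pairs (k, l) with `k <= i < l` (the nesting height). The
#' distance is the unnormalised L1 norm between the two profiles — a metric
#' on equal-length structures that is additive across positions.
#'
#' @param s1,s2 `rna_structure` objects of equal length.
#' @return Nonnegative integer-valued distance.
#' @examples
#' mountain_distance(parse_dotbracket("(())"), parse_dotbracket("()()")) # 2
#' @export
mountain_distance <- function(s1, s2) {
  if (s1$length != s2$length) stop("structures have different lengths")
  sum(abs(mountain_profile(s1) - mountain_profile(s2)))
}

mountain_profile <- function(s) {
  h <- numeric(s$length)
  p <- s$pairs
  if (nrow(p) > 0)
    for (a in seq_len(nrow(p)))
      h[p[a, 1]:(p[a, 2] - 1)] <- h[p[a, 1]:(p[a, 2] - 1)] + 1
  h
}

#' Dataset-level metrics (micro-average)
#'
#' Sums true/false positives and false negatives across records before
#' taking ratios, so long structures weigh by their pair counts. With
#' `macro = TRUE` the per-record sensitivity/PPV/F values are averaged
#' instead.
#'
#' @param records list of `structured_seq` (the trusted structures).
#' @param predictions list of `scfg_prediction` (or `rna_structure`),
#'   aligned with `records`. Failed predictions contribute their all-unpaired
#'   structure and so depress sensitivity.
#' @param macro average per-record metrics instead of pooling counts.
#' @return A `metric_report` (for `macro = TRUE`, counts are summed but the
#'   ratio fields are per-record means).
#' @export
aggregate_metrics <- function(records, predictions, macro = FALSE) {
  if (length(records) == 0 || length(records) != length(predictions))
    stop("records and predictions must be non-empty and aligned")
  reps <- mapply(function(rec, pred) {
    ps <- if (inherits(pred, "rna_structure")) pred else pred$structure
    compare_structures(ps, rec$structure)
  }, records, predictions, SIMPLIFY = FALSE)
  tp <- sum(vapply(reps, `[[`, numeric(1), "tp"))
  fp <- sum(vapply(reps, `[[`, numeric(1), "fp"))
  fn <- sum(vapply(reps, `[[`, numeric(1), "fn"))
  out <- metric_report(tp, fp, fn)
  if (macro) {
    out$sensitivity <- mean(vapply(reps, `[[`, numeric(1), "sensitivity"))
    out$ppv <- mean(vapply(reps, `[[`, numeric(1), "ppv"))
    out$fscore <- mean(vapply(reps, `[[`, numeric(1), "fscore"))
  }
  out
}

#' Relative sensitivity and PPV between two prediction sets
#'
#' The relative sensitivity of method A with respect to method B is the
#' sensitivity of A's predictions treating B's predictions as the trusted
#' structures (and likewise for PPV). Swapping the roles of A and B swaps
#' the two values. Used to ask whether two grammars predict the *same*
#' structures, not merely equally accurate ones.
#'
#' @param predictions_a,predictions_b aligned lists of `scfg_prediction` or
#'   `rna_structure` for the same underlying sequences.
#' @return A list with `sensitivity` and `ppv`.
#' @export
relative_metrics <- function(predictions_a, predictions_b) {
  if (length(predictions_a) != length(predictions_b))
    stop("prediction lists must be aligned")
  as_st <- function(p) if (inherits(p, "rna_structure")) p else p$structure
  tp <- fp <- fn <- 0
  for (k in seq_along(predictions_a)) {
    r <- compare_structures(as_st(predictions_a[[k]]),
                            as_st(predictions_b[[k]]))
    tp <- tp + r$tp; fp <- fp + r$fp; fn <- fn + r$fn
  }
  r <- metric_report(tp, fp, fn)
  list(sensitivity = r$sensitivity, ppv = r$ppv)
}

#' Sensitivity/PPV curve over a gamma grid
#'
#' Computes each record's posterior matrix once, decodes it at every gamma in
#' the grid, and micro-averages the metrics per gamma. The default grid runs
#' from 0.05 to 5.00 in increments of 0.05 (100 points).
#'
#' @param grammar an `scfg_grammar`.
#' @param params an `scfg_params`.
#' @param records list of `structured_seq`.
#' @param gamma_grid strictly positive numeric vector.
#' @return A data frame with columns `gamma`, `sensitivity`, `ppv`.
#' @export
gamma_sweep <- function(grammar, params, records,
                        gamma_grid = seq(0.05, 5, by = 0.05)) {
  if (any(gamma_grid <= 0)) stop("gamma grid must be strictly positive")
  posts <- lapply(records, function(r)
    tryCatch(sequence_outside_posteriors(grammar, params, r$sequence),
             error = function(e) NULL))
  rows <- lapply(gamma_grid, function(g) {
    preds <- mapply(function(post, rec) {
      if (is.null(post)) rna_structure(rec$structure$length)
      else mea_from_posterior(post, g)$structure
    }, posts, records, SIMPLIFY = FALSE)
    m <- aggregate_metrics(records, preds)
    data.frame(gamma = g, sensitivity = m$sensitivity, ppv = m$ppv)
  })
  do.call(rbind, rows)
}

#' Combined-best metrics over several prediction sets
#'
#' For each record, picks the prediction with the highest F-score among the
#' given sets (ties go to the first set), then micro-averages. Reports what
#' an oracle that knew which method to trust per structure would achieve.
#'
#' @param records list of `structured_seq`.
#' @param prediction_sets list of prediction lists, each aligned with
#'   `records`.
#' @return A `metric_report`.
#' @export
combined_best <- function(records, prediction_sets) {
  stopifnot(length(prediction_sets) >= 1)
  for (s in prediction_sets)
    if (length(s) != length(records))
      stop("every prediction set must cover every record")
  as_st <- function(p) if (inherits(p, "rna_structure")) p else p$structure
  best <- lapply(seq_along(records), function(k) {
    fs <- vapply(prediction_sets, function(s)
      compare_structures(as_st(s[[k]]), records[[k]]$structure)$fscore,
      numeric(1))
    as_st(prediction_sets[[which.max(fs)]][[k]])
  })
  aggregate_metrics(records, best)
}
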