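# Metric suite for scoring site-level stoichiometry predictions against a
# truth file.
#
# Two views of the data feed the metrics:
#   * position-wise paired vectors over all N reference positions (Y = target
#     frequency, 0 at unmodified positions; Yhat = predicted frequency, 0
#     where nothing was predicted) for RMSE, MAE and median AE, with the
#     max/min deviation restricted to the modified positions;
#   * a tolerance-aware one-to-one matching between truth and prediction
#     sites (prediction within +/- pos_window bases and within
#     Y +/- freq_tol_factor * Y) for TP/TN/FP/FN, accuracy and F1.

#' Tolerance rule for true-positive matching
#'
#' A prediction counts as correct for a modified position with target
#' frequency Y when it lies within `pos_window` bases of the position and its
#' frequency falls within `Y +/- freq_tol_factor * Y`.
#'
#' @param freq_tol_factor relative frequency tolerance (default 0.6).
#' @param pos_window positional tolerance in bases (default 1).
#' @return a list of class `tolerance_rule`.
#' @export
tolerance_rule <- function(freq_tol_factor = 0.6, pos_window = 1L) {
  if (freq_tol_factor < 0) stopf("freq_tol_factor must be >= 0")
  if (!is_count(pos_window) || pos_window < 0)
    stopf("pos_window must be a non-negative integer")
  structure(list(freq_tol_factor = freq_tol_factor,
                 pos_window = as.integer(pos_window)),
            class = "tolerance_rule")
}

#' Frequency acceptance interval around a target frequency
#'
#' `[max(0, Y * (1 - f)), min(1, Y * (1 + f))]` with `f` the rule's relative
#' tolerance. Only defined for modified positions (`Y > 0`); unmodified
#' positions are governed by the exact-zero true-negative rule instead.
#'
#' @param Y target frequency (scalar or vector), all `> 0`.
#' @param rule a [tolerance_rule()].
#' @return for scalar `Y` a length-2 vector `c(lo, hi)`; for vector `Y` a
#'   two-column matrix.
#' @examples
#' acceptance_interval(0.2)  # c(0.08, 0.32)
#' @export
acceptance_interval <- function(Y, rule = tolerance_rule()) {
  if (any(Y <= 0)) stopf("acceptance_interval requires Y > 0")
  f <- rule$freq_tol_factor
  lo <- pmax(0, Y * (1 - f))
  hi <- pmin(1, Y * (1 + f))
  if (length(Y) == 1L) c(lo, hi) else cbind(lo = lo, hi = hi)
}

#' Tolerance-aware one-to-one matching of predictions to truth sites
#'
#' Finds a one-to-one matching between truth sites and prediction sites such
#' that each matched pair is within `pos_window` bases and the predicted
#' frequency lies in the truth site's [acceptance_interval()]. Among feasible
#' matchings one of maximum cardinality is returned (augmenting-path bipartite
#' matching); candidate edges are explored by smallest positional offset, then
#' leftmost truth site, predictions left to right, making the result
#' deterministic and biased toward small total offset.
#'
#' @param truth,pred site-record `data.frame`s sorted by `start`, single
#'   chromosome; truth frequencies must be `> 0`.
#' @param rule a [tolerance_rule()].
#' @return a `data.frame` with columns `truth_idx`, `pred_idx`, `truth_pos`,
#'   `pred_pos`, `offset` (one row per matched pair).
#' @export
match_predictions <- function(truth, pred, rule = tolerance_rule()) {
  if (is.unsorted(truth$start)) stopf("truth sites must be sorted by position")
  if (is.unsorted(pred$start)) stopf("prediction sites must be sorted by position")
  if (any(truth$frequency <= 0))
    stopf("truth sites must have frequency > 0")
  nt <- nrow(truth)
  np <- nrow(pred)
  w <- rule$pos_window
  f <- rule$freq_tol_factor
  lo <- pmax(0, truth$frequency * (1 - f))
  hi <- pmin(1, truth$frequency * (1 + f))

  adj <- vector("list", np)
  for (j in seq_len(np)) {
    cand <- which(abs(truth$start - pred$start[j]) <= w &
                    pred$frequency[j] >= lo & pred$frequency[j] <= hi)
    ord <- order(abs(truth$start[cand] - pred$start[j]), truth$start[cand])
    adj[[j]] <- cand[ord]
  }

  match_of_truth <- rep(NA_integer_, nt)
  visited <- logical(nt)
  augment <- function(j) {
    for (i in adj[[j]]) {
      if (!visited[i]) {
        visited[i] <<- TRUE
        if (is.na(match_of_truth[i]) || augment(match_of_truth[i])) {
          match_of_truth[i] <<- j
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (j in seq_len(np)) {
    visited[] <- FALSE
    augment(j)
  }

  ti <- which(!is.na(match_of_truth))
  pj <- match_of_truth[ti]
  out <- data.frame(truth_idx = ti, pred_idx = pj,
                    truth_pos = truth$start[ti], pred_pos = pred$start[pj],
                    offset = abs(truth$start[ti] - pred$start[pj]))
  out[order(out$truth_idx), , drop = FALSE]
}

#' Confusion counts from a tolerance matching
#'
#' `TP` is the number of matched truth sites; `FN` the unmatched truth sites.
#' A false positive is an unmatched prediction with frequency `> 0` at a
#' position whose target rate is 0 (a prediction of exactly 0 asserts
#' "unmodified" and is never a false positive); `TN` fills the remainder so
#' that `TP + TN + FP + FN = N`.
#'
#' @param matching result of [match_predictions()] over the same `truth` and
#'   `pred`.
#' @param truth,pred the site tables used for the matching.
#' @param n_positions N, the total number of evaluable reference positions.
#' @return a named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(matching, truth, pred, n_positions) {
  N <- as.integer(n_positions)
  if (N < nrow(truth)) stopf("n_positions must be >= number of truth sites")
  TP <- nrow(matching)
  FN <- nrow(truth) - TP
  unmatched <- setdiff(seq_len(nrow(pred)), matching$pred_idx)
  stray <- unmatched[pred$frequency[unmatched] > 0 &
                       !(pred$start[unmatched] %in% truth$start)]
  FP <- length(stray)
  TN <- N - nrow(truth) - FP
  if (TN < 0L) stopf("inconsistent counts: TN < 0")
  c(TP = TP, TN = as.integer(TN), FP = FP, FN = FN)
}

#' Position-wise paired frequency vectors
#'
#' Builds the strict (no positional window) paired vectors over all N
#' reference positions: `Y` holds the target frequency (0 at unmodified
#' positions) and `Yhat` the predicted frequency (0 where no prediction was
#' emitted).
#'
#' @param truth,pred site-record `data.frame`s with distinct positions.
#' @param n_positions N, the total number of evaluable positions.
#' @return a list of class `paired_vectors` with `Y`, `Yhat` (length-N
#'   numeric) and `modified` (1-based indices of modified positions).
#' @export
paired_vectors <- function(truth, pred, n_positions) {
  N <- as.integer(n_positions)
  if (N < 1L) stopf("n_positions must be >= 1")
  for (df in list(truth, pred))
    if (nrow(df) && (anyDuplicated(df$start) || any(df$start >= N)))
      stopf("site positions must be distinct and < n_positions")
  Y <- numeric(N)
  Yhat <- numeric(N)
  Y[truth$start + 1L] <- truth$frequency
  Yhat[pred$start + 1L] <- pred$frequency
  structure(list(Y = Y, Yhat = Yhat, modified = which(Y > 0)),
            class = "paired_vectors")
}

#' Error metrics on paired frequency vectors
#'
#' `rmse` is the root mean squared difference and `mae` the mean absolute
#' difference between target and predicted frequencies over all N positions;
#' `median_ae` is the median absolute difference (lower median for even N).
#' `max_deviation`/`min_deviation` are the largest and smallest absolute
#' differences restricted to the modified positions, giving the error range on
#' the predicted modification frequencies.
#'
#' @param pair a [paired_vectors()] object.
#' @return a single numeric value.
#' @export
rmse <- function(pair) {
  sqrt(mean((pair$Y - pair$Yhat)^2))
}

#' @rdname rmse
#' @export
mae <- function(pair) {
  mean(abs(pair$Y - pair$Yhat))
}

#' @rdname rmse
#' @export
median_ae <- function(pair) {
  ae <- sort(abs(pair$Y - pair$Yhat))
  ae[ceiling(length(ae) / 2)]
}

#' @rdname rmse
#' @export
max_deviation <- function(pair) {
  if (!length(pair$modified)) stopf("no modified positions")
  max(abs(pair$Y[pair$modified] - pair$Yhat[pair$modified]))
}

#' @rdname rmse
#' @export
min_deviation <- function(pair) {
  if (!length(pair$modified)) stopf("no modified positions")
  min(abs(pair$Y[pair$modified] - pair$Yhat[pair$modified]))
}

#' Accuracy and F1 from confusion counts
#'
#' `accuracy = (TP + TN) / N`; `f1_score = 2 TP / (2 TP + FP + FN)`. The F1
#' degenerate cases are fixed explicitly: with `TP = FP = FN = 0` (perfect
#' empty agreement) F1 is 1; with `TP = 0` and `FP + FN > 0` it is 0.
#'
#' @param counts a [confusion_counts()] vector.
#' @param n_positions N, total evaluable positions.
#' @return a single numeric value in `[0, 1]`.
#' @export
accuracy <- function(counts, n_positions) {
  N <- as.integer(n_positions)
  if (N < 1L) stopf("n_positions must be >= 1")
  unname((counts[["TP"]] + counts[["TN"]]) / N)
}

#' @rdname accuracy
#' @export
f1_score <- function(counts) {
  TP <- counts[["TP"]]
  FP <- counts[["FP"]]
  FN <- counts[["FN"]]
  if (TP == 0L) {
    if (FP + FN == 0L) return(1)
    return(0)
  }
  2 * TP / (2 * TP + FP + FN)
}

as_site_table <- function(x, what) {
  if (is.character(x) && length(x) == 1L) x <- parse_bedrmod(x)
  if (is.list(x) && !is.data.frame(x) && !is.null(x$records)) {
    if (any(x$issues$severity == "error"))
      stopf("%s file has parse errors: %s", what,
            paste(utils::head(x$issues$message[x$issues$severity == "error"],
                              3L), collapse = "; "))
    x <- x$records
  }
  if (!is.data.frame(x)) stopf("cannot interpret %s input", what)
  x
}

#' Evaluate a prediction file against a truth file
#'
#' Runs the full metric suite for one truth/prediction pair: position-wise
#' RMSE, MAE and median absolute error over all reference positions, the
#' deviation range over modified positions, and tolerance-matched confusion
#' counts with accuracy and F1. Predictions with frequency exactly 0 are
#' treated as explicit "unmodified" calls.
#'
#' @param truth,prediction bedRMod file paths, parsed `bedrmod_file` lists, or
#'   site-record `data.frame`s. Truth must be non-empty; both must use the
#'   same single chromosome.
#' @param reference_length N, the total number of evaluable reference
#'   positions (e.g. the reference sequence length).
#' @param rule a [tolerance_rule()].
#' @return a list of class `eval_report` with elements `metrics` (rmse, mae,
#'   median_ae, max_deviation, min_deviation, accuracy, f1), `confusion`,
#'   `tolerance`, `n_positions`, `n_truth_sites`, `n_prediction_sites` and the
#'   per-site `matches` table.
#' @export
evaluate_predictions <- function(truth, prediction, reference_length,
                                 rule = tolerance_rule()) {
  truth <- as_site_table(truth, "truth")
  pred <- as_site_table(prediction, "prediction")
  if (nrow(truth) == 0L) stopf("truth must contain at least one site")
  chroms <- unique(c(truth$chrom, pred$chrom))
  if (length(unique(truth$chrom)) > 1L || length(unique(pred$chrom)) > 1L)
    stopf("evaluation operates on a single chromosome")
  if (nrow(pred) && !all(pred$chrom %in% truth$chrom))
    stopf("chromosome mismatch between truth (%s) and prediction (%s)",
          unique(truth$chrom), unique(pred$chrom))
  truth <- truth[order(truth$start), , drop = FALSE]
  pred <- pred[order(pred$start), , drop = FALSE]
  if (anyDuplicated(truth$start)) stopf("duplicate truth positions")
  if (anyDuplicated(pred$start)) stopf("duplicate prediction positions")
  N <- as.integer(reference_length)

  pair <- paired_vectors(truth, pred, N)
  pred_nz <- pred[pred$frequency > 0, , drop = FALSE]
  matching <- match_predictions(truth, pred_nz, rule)
  counts <- confusion_counts(matching, truth, pred_nz, N)

  structure(list(
    metrics = list(
      rmse = rmse(pair),
      mae = mae(pair),
      median_ae = median_ae(pair),
      max_deviation = max_deviation(pair),
      min_deviation = min_deviation(pair),
      accuracy = accuracy(counts, N),
      f1 = f1_score(counts)
    ),
    confusion = as.list(counts),
    tolerance = list(freq_tol_factor = rule$freq_tol_factor,
                     pos_window = rule$pos_window),
    n_positions = N,
    n_truth_sites = nrow(truth),
    n_prediction_sites = nrow(pred),
    matches = matching
  ), class = "eval_report")
}

#' Serialize an evaluation report to JSON
#'
#' @param report an [evaluate_predictions()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d positions (%d truth, %d predicted sites)\n",
              x$n_positions, x$n_truth_sites, x$n_prediction_sites))
  m <- x$metrics
  cat(sprintf("  RMSE %.4g | MAE %.4g | median AE %.4g\n",
              m$rmse, m$mae, m$median_ae))
  cat(sprintf("  deviation range [%.4g, %.4g]\n",
              m$min_deviation, m$max_deviation))
  cat(sprintf("  accuracy %.4g | F1 %.4g  (TP %d TN %d FP %d FN %d)\n",
              m$accuracy, m$f1, x$confusion$TP, x$confusion$TN,
              x$confusion$FP, x$confusion$FN))
  invisible(x)
}
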