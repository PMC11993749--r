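# Independent oracles used to cross-check the implementation. These are
# deliberately naive (explicit loops, exhaustive enumeration) and share no
# code with the package internals.

# exhaustive maximum one-to-one matching size under the tolerance rule
brute_force_max_matching <- function(truth, pred, rule) {
  nt <- nrow(truth)
  np <- nrow(pred)
  if (nt == 0L || np == 0L) return(0L)
  f <- rule$freq_tol_factor
  w <- rule$pos_window
  feasible <- matrix(FALSE, nt, np)
  for (i in seq_len(nt)) {
    lo <- max(0, truth$frequency[i] * (1 - f))
    hi <- min(1, truth$frequency[i] * (1 + f))
    for (j in seq_len(np)) {
      feasible[i, j] <- abs(truth$start[i] - pred$start[j]) <= w &&
        pred$frequency[j] >= lo && pred$frequency[j] <= hi
    }
  }
  rec <- function(i, used) {
    if (i > nt) return(0L)
    best <- rec(i + 1L, used)          # truth i left unmatched
    for (j in seq_len(np)) {
      if (!used[j] && feasible[i, j]) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, logical(np))
}

# straight-line recomputation of the error metrics from first principles
straight_line_metrics <- function(truth, pred, N) {
  Y <- numeric(N)
  Yhat <- numeric(N)
  for (i in seq_len(nrow(truth))) Y[truth$start[i] + 1] <- truth$frequency[i]
  for (j in seq_len(nrow(pred))) Yhat[pred$start[j] + 1] <- pred$frequency[j]
  ae <- numeric(N)
  sq <- 0
  for (p in seq_len(N)) {
    ae[p] <- abs(Y[p] - Yhat[p])
    sq <- sq + (Y[p] - Yhat[p])^2
  }
  mod <- which(Y > 0)
  sorted <- sort(ae)
  list(rmse = sqrt(sq / N),
       mae = sum(ae) / N,
       median_ae = sorted[ceiling(N / 2)],
       max_deviation = if (length(mod)) max(ae[mod]) else NA_real_,
       min_deviation = if (length(mod)) min(ae[mod]) else NA_real_)
}

# per-position membership scan over read spans (half-open)
pileup_scan <- function(reads, L) {
  n_mod <- integer(L)
  n_unmod <- integer(L)
  for (p in 0:(L - 1L)) {
    covers <- reads$start <= p & p < reads$end
    n_mod[p + 1L] <- sum(covers & reads$origin == "modified")
    n_unmod[p + 1L] <- sum(covers & reads$origin == "unmodified")
  }
  data.frame(position = 0:(L - 1L), n_mod = n_mod, n_unmod = n_unmod)
}
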