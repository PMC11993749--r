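# Challenge dataset simulation: per-position modification rate profiles,
# controlled binomial count simulation, transcript read-mixture simulation
# with 5' truncation, train/test read splitting, and truth perturbation for
# exercising the evaluator.
#
# All simulators take an explicit seed and are bit-reproducible under a fixed
# seed and parameter set.

# The three packaged challenge profiles: a single modification type per
# challenge, 243 modified positions on a 2438 nt reference, and the published
# target-frequency range. The modified positions sit at the centres of the
# 5-mer blocks of an all-5-mer core (256 blocks of 5 nt = 1280 nt) flanked by
# 579 nt on each side; 13 evenly spaced blocks carry no target frequency,
# emulating target dropout, which leaves 243 targeted positions.
CHALLENGE_PROFILES <- list(
  challenge1 = list(mod_name = "m5C", central_base = "C",
                    range = c(0.12, 0.33)),
  challenge2 = list(mod_name = "m6A", central_base = "A",
                    range = c(0.01, 0.10)),
  challenge3 = list(mod_name = "psi", central_base = "T",
                    range = c(0.31, 0.50))
)

CHALLENGE_K <- 5L
CHALLENGE_N_BLOCKS <- 256L
CHALLENGE_FLANK <- 579L

#' Layout of a packaged challenge profile
#'
#' Returns the fixed, deterministic geometry of one of the three packaged
#' challenges: reference length 2438 nt, 243 modified positions, modification
#' name, central target base and target-frequency range (`challenge1`: m5C,
#' 0.12-0.33; `challenge2`: m6A, 0.01-0.1; `challenge3`: psi, 0.31-0.5).
#'
#' @param name `"challenge1"`, `"challenge2"` or `"challenge3"`.
#' @return a list with `name`, `mod_name`, `central_base`, `range_min`,
#'   `range_max`, `ref_length`, `positions` (0-based, sorted), `k`,
#'   `flank_5p_len`, `flank_3p_len`.
#' @export
challenge_layout <- function(name = c("challenge1", "challenge2",
                                      "challenge3")) {
  name <- match.arg(name)
  p <- CHALLENGE_PROFILES[[name]]
  block_pos <- CHALLENGE_FLANK + CHALLENGE_K * (0:(CHALLENGE_N_BLOCKS - 1L)) +
    (CHALLENGE_K - 1L) %/% 2L
  dropped <- round(seq(1L, CHALLENGE_N_BLOCKS, length.out = 13L))
  list(name = name,
       mod_name = p$mod_name,
       central_base = p$central_base,
       range_min = p$range[1],
       range_max = p$range[2],
       ref_length = 2L * CHALLENGE_FLANK + CHALLENGE_N_BLOCKS * CHALLENGE_K,
       positions = as.integer(block_pos[-dropped]),
       k = CHALLENGE_K,
       flank_5p_len = CHALLENGE_FLANK,
       flank_3p_len = CHALLENGE_FLANK)
}

#' Build the reference sequence for a packaged challenge
#'
#' Assembles the actual nucleotide sequence matching [challenge_layout()]: the
#' 256 5-mers with the challenge's central base (lexicographic order by
#' default), with deterministic periodic ACGT flanks of 579 nt on each side.
#'
#' @inheritParams challenge_layout
#' @param order_seed optional seed to shuffle the 5-mer block order.
#' @return a [build_reference()] `reference_design` of length 2438.
#' @export
challenge_reference <- function(name = c("challenge1", "challenge2",
                                         "challenge3"), order_seed = NULL) {
  name <- match.arg(name)
  layout <- challenge_layout(name)
  kmers <- enumerate_central_kmers(layout$central_base, layout$k)
  flank <- substr(strrep("ACGT", ceiling(CHALLENGE_FLANK / 4)), 1L,
                  CHALLENGE_FLANK)
  build_reference(kmers, order_seed = order_seed, flank_5p = flank,
                  flank_3p = flank, name = name)
}

#' Create a per-position modification rate profile
#'
#' Assigns each listed position a true modification rate drawn uniformly from
#' `[range_min, range_max]`. With `anchor_endpoints`, the lowest-coordinate
#' position receives exactly `range_min` and the highest-coordinate position
#' exactly `range_max`, so the profile's extremes equal the nominal range
#' endpoints. Positions are sorted; unlisted positions are unmodified (rate 0).
#'
#' @param positions 0-based modified positions (non-empty, distinct).
#' @param range_min,range_max rate range, `0 < range_min <= range_max <= 1`.
#' @param seed integer seed for the uniform draws (NULL: ambient RNG).
#' @param anchor_endpoints logical; pin the first/last position to the range
#'   endpoints.
#' @param length total reference length; defaults to `max(positions) + 1`.
#' @param reference reference name.
#' @param mod_name modification short name carried into truth output.
#' @return an object of class `rate_profile`: list with `reference`,
#'   `mod_name`, `length`, `positions`, `rates`.
#' @export
make_rate_profile <- function(positions, range_min, range_max, seed = NULL,
                              anchor_endpoints = FALSE, length = NULL,
                              reference = "ref", mod_name = "mod") {
  if (!length(positions)) stopf("positions must be non-empty")
  positions <- as.integer(positions)
  if (anyDuplicated(positions)) stopf("positions must be distinct")
  if (any(positions < 0L)) stopf("positions must be non-negative")
  if (!(range_min > 0 && range_min <= range_max && range_max <= 1))
    stopf("require 0 < range_min <= range_max <= 1")
  length <- as.integer(length %||% (max(positions) + 1L))
  if (any(positions >= length)) stopf("positions must be < length")
  positions <- sort(positions)
  n <- base::length(positions)
  rates <- maybe_with_seed(seed, stats::runif(n, range_min, range_max))
  if (anchor_endpoints && n >= 2L) {
    rates[1L] <- range_min
    rates[n] <- range_max
  }
  structure(list(reference = reference, mod_name = mod_name, length = length,
                 positions = positions, rates = rates),
            class = "rate_profile")
}

#' Rate profile for a packaged challenge
#'
#' Convenience wrapper: [challenge_layout()] geometry plus
#' [make_rate_profile()] with endpoint anchoring, so the minimum and maximum
#' true rates equal the challenge's published range endpoints.
#'
#' @inheritParams challenge_layout
#' @param seed integer seed for the rate draws.
#' @return a `rate_profile` over 2438 positions with 243 modified positions.
#' @export
challenge_rate_profile <- function(name = c("challenge1", "challenge2",
                                            "challenge3"), seed = NULL) {
  layout <- challenge_layout(name)
  make_rate_profile(layout$positions, layout$range_min, layout$range_max,
                    seed = seed, anchor_endpoints = TRUE,
                    length = layout$ref_length, reference = layout$name,
                    mod_name = layout$mod_name)
}

#' Truth site records for a rate profile
#'
#' @param profile a `rate_profile`.
#' @param coverage coverage value recorded at each site.
#' @return a [site_records()] table, one row per modified position.
#' @export
profile_truth_records <- function(profile, coverage = 100L) {
  stopifnot(inherits(profile, "rate_profile"))
  site_records(profile$reference, profile$positions, profile$mod_name,
               profile$rates, coverage)
}

#' Simulate per-position counts at controlled rates
#'
#' For every profiled position p the modified-read count is drawn
#' `Binomial(coverage, rate[p])` and the unmodified count is the complement;
#' unprofiled positions get `n_mod = 0`, `n_unmod = coverage`. This controlled
#' mode exercises the rate estimator at a known depth.
#'
#' @param profile a [make_rate_profile()] object.
#' @param coverage reads per position, `>= 1`.
#' @param seed integer seed.
#' @return a `data.frame` with columns `position` (0-based), `n_mod`,
#'   `n_unmod`, one row per reference position.
#' @export
simulate_controlled <- function(profile, coverage, seed = NULL) {
  stopifnot(inherits(profile, "rate_profile"))
  if (!is_count(coverage) || coverage < 1) stopf("coverage must be >= 1")
  coverage <- as.integer(coverage)
  n_mod <- integer(profile$length)
  draws <- maybe_with_seed(seed,
    stats::rbinom(base::length(profile$positions), coverage, profile$rates))
  n_mod[profile$positions + 1L] <- draws
  data.frame(position = 0:(profile$length - 1L),
             n_mod = n_mod,
             n_unmod = coverage - n_mod)
}

#' Simulate a mixed two-pool read table
#'
#' Emulates the challenge mixing experiment at the read/alignment level: one
#' pool of fully modified transcripts and one of unmodified transcripts are
#' drawn from the same reference and mixed. Direct RNA sequencing proceeds
#' 3'->5', so reads keep the full 3' end while the 5' start is truncated by a
#' geometric offset with mean `trunc_mean`; truncation makes the emergent
#' per-position mixing ratio vary along the reference. `trunc_mean = 0` yields
#' full-length reads only.
#'
#' @param reference a `reference_design`, or a single integer reference
#'   length.
#' @param n_mod_reads,n_unmod_reads pool sizes, `>= 0`.
#' @param trunc_mean mean 5' start offset (bases) of the geometric truncation
#'   model; 0 disables truncation.
#' @param seed integer seed.
#' @return a `data.frame` ReadTable with columns `read_id`, `origin`
#'   (`"modified"`/`"unmodified"`), `start`, `end` (0-based half-open spans).
#' @export
simulate_transcript_mixture <- function(reference, n_mod_reads,
                                        n_unmod_reads, trunc_mean = 0,
                                        seed = NULL) {
  L <- if (inherits(reference, "reference_design"))
    nchar(reference$sequence) else as.integer(reference)
  if (is.na(L) || L < 1L) stopf("invalid reference length")
  if (n_mod_reads < 0 || n_unmod_reads < 0) stopf("read counts must be >= 0")
  n <- as.integer(n_mod_reads) + as.integer(n_unmod_reads)
  starts <- maybe_with_seed(seed, {
    if (trunc_mean <= 0) integer(n)
    else pmin(stats::rgeom(n, prob = 1 / (1 + trunc_mean)), L - 1L)
  })
  origin <- rep(c("modified", "unmodified"),
                c(n_mod_reads, n_unmod_reads))
  ids <- c(sprintf("mod_%06d", seq_len(n_mod_reads)),
           sprintf("unmod_%06d", seq_len(n_unmod_reads)))
  data.frame(read_id = ids, origin = origin,
             start = as.integer(starts), end = L,
             stringsAsFactors = FALSE)
}

#' Split a read table into train and test subsets
#'
#' Disjoint, exhaustive, seed-stable partition. The training size is
#' `round(train_frac * n)` with halves rounded away from zero; the remainder
#' goes to the test set. Rows keep their original order within each subset.
#'
#' @param reads a ReadTable `data.frame`.
#' @param train_frac training fraction, strictly between 0 and 1.
#' @param seed integer seed for the shuffle.
#' @return a list with `train` and `test` ReadTables.
#' @export
split_reads <- function(reads, train_frac = 0.8, seed = NULL) {
  if (!(train_frac > 0 && train_frac < 1))
    stopf("train_frac must be in (0, 1)")
  n <- nrow(reads)
  if (n == 0L) return(list(train = reads, test = reads))
  n_train <- as.integer(round_half_up(train_frac * n))
  perm <- maybe_with_seed(seed, sample.int(n))
  train_idx <- sort(perm[seq_len(n_train)])
  test_idx <- sort(perm[setdiff(seq_len(n), seq_len(n_train))])
  train <- reads[train_idx, , drop = FALSE]
  test <- reads[test_idx, , drop = FALSE]
  rownames(train) <- NULL
  rownames(test) <- NULL
  list(train = train, test = test)
}

#' Perturb a truth file into method-like predictions
#'
#' Applies, in order: site dropout (`fn_rate`), +/-1 position jitter
#' (`pos_jitter_prob`, direction symmetric, clamped to the reference),
#' Gaussian frequency noise (`freq_noise_sd`, clipped to `[0, 1]`), and
#' spurious-site injection at unmodified positions (`fp_rate` per position,
#' uniform frequency). With all parameters zero the input is returned
#' unchanged. Scores are recomputed from the perturbed frequencies.
#'
#' @param truth a [site_records()] table (single chromosome).
#' @param pos_jitter_prob,fp_rate,fn_rate probabilities in `[0, 1]`.
#' @param freq_noise_sd Gaussian frequency noise standard deviation, `>= 0`.
#' @param reference_length total reference length (required when
#'   `fp_rate > 0`).
#' @param seed integer seed.
#' @return a site-record `data.frame` sorted by position.
#' @export
perturb_truth <- function(truth, pos_jitter_prob = 0, freq_noise_sd = 0,
                          fp_rate = 0, fn_rate = 0, seed = NULL,
                          reference_length = NULL) {
  for (p in c(pos_jitter_prob, fp_rate, fn_rate))
    if (p < 0 || p > 1) stopf("probabilities must be in [0, 1]")
  if (freq_noise_sd < 0) stopf("freq_noise_sd must be >= 0")
  if (fp_rate > 0 && is.null(reference_length))
    stopf("reference_length is required when fp_rate > 0")
  maybe_with_seed(seed, {
    out <- truth
    n <- nrow(out)
    if (fn_rate > 0 && n > 0L)
      out <- out[stats::runif(n) >= fn_rate, , drop = FALSE]
    m <- nrow(out)
    if (pos_jitter_prob > 0 && m > 0L) {
      jit <- stats::runif(m) < pos_jitter_prob
      shift <- ifelse(stats::runif(m) < 0.5, -1L, 1L)
      L <- reference_length %||% (max(truth$end))
      new_start <- pmin(pmax(out$start + ifelse(jit, shift, 0L), 0L), L - 1L)
      out$start <- as.integer(new_start)
      out$end <- out$start + 1L
      out$thickStart <- out$start
      out$thickEnd <- out$end
    }
    if (freq_noise_sd > 0 && m > 0L) {
      out$frequency <- pmin(pmax(out$frequency +
                                   stats::rnorm(m, 0, freq_noise_sd), 0), 1)
      out$score <- as.integer(round_half_up(1000 * out$frequency))
    }
    if (fp_rate > 0) {
      free <- setdiff(0:(reference_length - 1L), truth$start)
      hit <- free[stats::runif(base::length(free)) < fp_rate]
      if (base::length(hit)) {
        cov <- if (nrow(truth)) as.integer(round(stats::median(truth$coverage)))
               else 30L
        fp <- site_records(
          chrom = if (nrow(truth)) truth$chrom[1] else "ref",
          start = hit,
          mod_name = if (nrow(truth)) truth$mod_name[1] else "mod",
          frequency = stats::runif(base::length(hit)),
          coverage = cov)
        out <- rbind(out, fp)
      }
    }
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' @export
print.rate_profile <- function(x, ...) {
  cat(sprintf(
    "rate_profile '%s' (%s): %d/%d modified positions, rates %.4g-%.4g\n",
    x$reference, x$mod_name, length(x$positions), x$length,
    min(x$rates), max(x$rates)))
  invisible(x)
}
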