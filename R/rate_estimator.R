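# Ground-truth rate estimation from two separately mapped read pools:
# per-position pileup of modified/unmodified coverage and the modification
# ratio n_mod / (n_mod + n_unmod).

#' Per-position pileup of a two-pool read table
#'
#' Counts, at every reference position, the number of modified-origin and
#' unmodified-origin reads whose half-open alignment span covers it. Coverage
#' is computed with run-length encoded interval coverage ([IRanges::coverage]).
#'
#' @param reads a ReadTable `data.frame` with columns `read_id`, `origin`
#'   (`"modified"`/`"unmodified"`), `start`, `end` (0-based half-open).
#' @param reference_length total reference length.
#' @return a `data.frame` with columns `position` (0-based), `n_mod`,
#'   `n_unmod`.
#' @export
pileup <- function(reads, reference_length) {
  L <- as.integer(reference_length)
  if (is.na(L) || L < 1L) stopf("invalid reference length")
  bad <- reads$start < 0L | reads$end > L | reads$start >= reads$end
  if (any(bad))
    stopf("read span outside [0, %d) for: %s", L,
          paste(utils::head(reads$read_id[bad], 5L), collapse = ", "))
  if (!all(reads$origin %in% c("modified", "unmodified")))
    stopf("origin must be 'modified' or 'unmodified'")
  cov_of <- function(df) {
    if (!nrow(df)) return(integer(L))
    as.integer(IRanges::coverage(
      IRanges::IRanges(start = df$start + 1L, end = df$end), width = L))
  }
  data.frame(position = 0:(L - 1L),
             n_mod = cov_of(reads[reads$origin == "modified", , drop = FALSE]),
             n_unmod = cov_of(reads[reads$origin == "unmodified", ,
                                    drop = FALSE]))
}

#' Per-position modification rates from pileup counts
#'
#' The modification ratio at a position is the fraction of covering reads that
#' come from the modified pool, `n_mod / (n_mod + n_unmod)`. Positions with no
#' coverage are absent from the result — "unobserved" is distinct from
#' "unmodified" (rate 0).
#'
#' @param counts a [pileup()] / [simulate_controlled()] `data.frame` with
#'   columns `position`, `n_mod`, `n_unmod`.
#' @return a `data.frame` with columns `position`, `n_mod`, `n_unmod`,
#'   `coverage`, `rate`, restricted to covered positions.
#' @export
compute_rates <- function(counts) {
  stopifnot(all(c("position", "n_mod", "n_unmod") %in% names(counts)))
  total <- counts$n_mod + counts$n_unmod
  keep <- total > 0L
  out <- data.frame(position = counts$position[keep],
                    n_mod = counts$n_mod[keep],
                    n_unmod = counts$n_unmod[keep],
                    coverage = total[keep])
  out$rate <- out$n_mod / out$coverage
  rownames(out) <- NULL
  out
}

#' Convert a rate table to bedRMod site records
#'
#' Emits one record per covered position with `rate > 0` and coverage at least
#' `min_coverage`; the record's frequency is the rate and its coverage the
#' total covering read count.
#'
#' @param rates a [compute_rates()] `data.frame`.
#' @param mod_name modification short name for the records.
#' @param chrom reference name.
#' @param min_coverage minimum total coverage for a site to be reported
#'   (default 10).
#' @return a [site_records()] `data.frame`.
#' @export
rates_to_bedrmod <- function(rates, mod_name, chrom = "ref",
                             min_coverage = 10L) {
  if (min_coverage < 0) stopf("min_coverage must be >= 0")
  keep <- rates$rate > 0 & rates$coverage >= min_coverage
  site_records(chrom, rates$position[keep], mod_name, rates$rate[keep],
               rates$coverage[keep])
}

#' Read or write a ReadTable TSV
#'
#' Plain four-column tab-separated representation of simulated reads
#' (`read_id`, `origin`, `start`, `end`).
#'
#' @param path TSV path.
#' @return for `read_reads_tsv`, the ReadTable `data.frame`.
#' @export
read_reads_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "integer",
                                   "integer"))
}

#' @rdname read_reads_tsv
#' @param reads ReadTable to write.
#' @export
write_reads_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
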