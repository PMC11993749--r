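# bedRMod input/output and validation
#
# bedRMod is a BED-derived tab-delimited text format for site-level RNA
# modification data: a "#key=value" metadata header followed by one row per
# modified site. The dialect used here is an 11-column BED9+2:
#   chrom start end mod_name score strand thickStart thickEnd itemRgb
#   coverage frequency
# Coordinates are 0-based half-open. The frequency column stores a decimal
# fraction in [0, 1] (the parser also accepts the percent representation,
# values in (1, 100], which it divides by 100). The score column mirrors the
# frequency as round(1000 * frequency).

BEDRMOD_COLUMNS <- c("chrom", "start", "end", "mod_name", "score", "strand",
                     "thickStart", "thickEnd", "itemRgb", "coverage",
                     "frequency")

REQUIRED_HEADER_KEYS <- c("fileformat", "modification_type", "assembly")

new_issues <- function(severity = character(), line = integer(),
                       message = character()) {
  data.frame(severity = as.character(severity), line = as.integer(line),
             message = as.character(message), stringsAsFactors = FALSE)
}

add_issue <- function(issues, severity, line, message) {
  rbind(issues, new_issues(severity, line, message))
}

#' Construct site-level modification records
#'
#' Builds the canonical site-record table used throughout the package: one row
#' per modified position, in the 11-column bedRMod dialect. The `score` column
#' is derived from the frequency (`round(1000 * frequency)`, half away from
#' zero), and `thickStart`/`thickEnd`/`itemRgb` are filled with their BED
#' defaults.
#'
#' @param chrom reference (chromosome) name, recycled.
#' @param start 0-based inclusive start position.
#' @param mod_name modification short name, e.g. `"m6A"`, `"m5C"`, `"psi"`.
#' @param frequency modification stoichiometry, fraction in `[0, 1]`.
#' @param coverage non-negative integer read count at the site.
#' @param strand `"+"`, `"-"` or `"."`; single-stranded IVT transcripts are
#'   `"+"` by default.
#' @param end 0-based exclusive end; defaults to `start + 1` (single-base).
#' @return a `data.frame` with the 11 bedRMod columns.
#' @examples
#' site_records("ref1", 11L, "m5C", 0.25, 40L)
#' @export
site_records <- function(chrom, start, mod_name, frequency, coverage,
                         strand = "+", end = start + 1L) {
  n <- length(start)
  df <- data.frame(
    chrom      = rep_len(as.character(chrom), n),
    start      = as.integer(start),
    end        = as.integer(rep_len(end, n)),
    mod_name   = rep_len(as.character(mod_name), n),
    score      = as.integer(round_half_up(1000 * rep_len(as.numeric(frequency), n))),
    strand     = rep_len(as.character(strand), n),
    thickStart = as.integer(start),
    thickEnd   = as.integer(rep_len(end, n)),
    itemRgb    = rep_len("0,0,0", n),
    coverage   = as.integer(rep_len(coverage, n)),
    frequency  = rep_len(as.numeric(frequency), n),
    stringsAsFactors = FALSE
  )
  bad <- check_record_invariants(df)
  if (any(bad$severity == "error"))
    stopf("invalid site records: %s",
          paste(unique(bad$message[bad$severity == "error"]), collapse = "; "))
  df
}

empty_site_records <- function() {
  site_records(character(0), integer(0), character(0), numeric(0), integer(0),
               strand = character(0), end = integer(0))
}

# invariant checks shared by the writer and the validator;
# `line` defaults to the record's row index
check_record_invariants <- function(records, lines = seq_len(nrow(records))) {
  issues <- new_issues()
  if (nrow(records) == 0L) return(issues)
  chk <- function(bad, severity, what) {
    if (any(bad))
      add_issue(issues, severity, lines[bad],
                sprintf("%s", rep(what, sum(bad))))
    else issues
  }
  issues <- chk(records$start < 0L, "error", "negative start coordinate")
  issues <- chk(records$end <= records$start, "error",
                "end must exceed start")
  issues <- chk(records$end != records$start + 1L, "warning",
                "multi-base site (end != start + 1)")
  issues <- chk(!records$strand %in% c("+", "-", "."), "error",
                "strand must be one of +, -, .")
  issues <- chk(records$frequency < 0 | records$frequency > 1, "error",
                "frequency outside [0, 1]")
  issues <- chk(records$coverage < 0L, "error", "negative coverage")
  issues <- chk(records$score !=
                  as.integer(round_half_up(1000 * records$frequency)),
                "error", "score does not equal round(1000 * frequency)")
  issues
}

#' Construct a bedRMod metadata header
#'
#' @param ... further `key = "value"` metadata entries, stored verbatim.
#' @param fileformat format dialect identifier.
#' @param modification_type modification assayed (e.g. `"m6A"`).
#' @param assembly reference/assembly label.
#' @return a named character vector of class `bedrmod_header`.
#' @export
bedrmod_header <- function(..., fileformat = "bedRModv1.8",
                           modification_type = "RNAMod",
                           assembly = "custom") {
  extra <- c(...)
  h <- c(fileformat = fileformat, modification_type = modification_type,
         assembly = assembly, extra)
  h <- vapply(h, as.character, character(1))
  if (anyDuplicated(names(h))) stopf("duplicate header keys")
  structure(h, class = "bedrmod_header")
}

#' Parse a bedRMod file
#'
#' Reads the `#key=value` header and the tab-delimited data section. Parsing is
#' permissive but accounted: every malformed data row produces an error
#' [issue][validate_bedrmod] with its line number and is dropped, so
#' `rows_in == nrow(records) + error issues`; a missing header yields a
#' warning issue and parsing continues. Frequencies in `[0, 1]` are taken as
#' fractions; values in `(1, 100]` are interpreted as percentages and divided
#' by 100.
#'
#' @param x path to a bedRMod file, or a character vector of its lines (a
#'   single string may contain embedded newlines).
#' @return a list of class `bedrmod_file` with elements `header` (named
#'   character), `records` (site-record `data.frame` in file order) and
#'   `issues` (`data.frame` with columns severity, line, message).
#' @export
parse_bedrmod <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) &&
               file.exists(x)) readLines(x)
           else unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  issues <- new_issues()
  header <- character(0)
  rows <- vector("list", length(lines))
  n_rows <- 0L
  seen_data <- FALSE

  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      if (seen_data) {
        issues <- add_issue(issues, "warning", ln,
                            "header line after data section")
      }
      body <- sub("^#", "", line)
      if (!grepl("=", body, fixed = TRUE)) {
        issues <- add_issue(issues, "warning", ln,
                            "header line is not key=value")
        next
      }
      key <- sub("=.*$", "", body)
      val <- sub("^[^=]*=", "", body)
      header[key] <- val
      next
    }
    seen_data <- TRUE
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(BEDRMOD_COLUMNS)) {
      issues <- add_issue(issues, "error", ln,
                          sprintf("expected %d tab-delimited columns, got %d",
                                  length(BEDRMOD_COLUMNS), length(fields)))
      next
    }
    start <- suppressWarnings(as.integer(fields[2]))
    end   <- suppressWarnings(as.integer(fields[3]))
    score <- suppressWarnings(as.integer(fields[5]))
    cov   <- suppressWarnings(as.integer(fields[10]))
    freq  <- suppressWarnings(as.numeric(fields[11]))
    if (is.na(start) || is.na(end)) {
      issues <- add_issue(issues, "error", ln, "non-numeric coordinate")
      next
    }
    if (is.na(score) || is.na(cov) || is.na(freq)) {
      issues <- add_issue(issues, "error", ln,
                          "non-numeric score, coverage or frequency")
      next
    }
    if (freq < 0 || freq > 100) {
      issues <- add_issue(issues, "error", ln,
                          "frequency outside fraction [0,1] / percent (1,100] representation")
      next
    }
    if (freq > 1) freq <- freq / 100
    if (cov < 0L) {
      issues <- add_issue(issues, "error", ln, "negative coverage")
      next
    }
    if (!fields[6] %in% c("+", "-", ".")) {
      issues <- add_issue(issues, "error", ln, "invalid strand symbol")
      next
    }
    n_rows <- n_rows + 1L
    rows[[n_rows]] <- data.frame(
      chrom = fields[1], start = start, end = end, mod_name = fields[4],
      score = score, strand = fields[6],
      thickStart = suppressWarnings(as.integer(fields[7])),
      thickEnd = suppressWarnings(as.integer(fields[8])),
      itemRgb = fields[9], coverage = cov, frequency = freq,
      stringsAsFactors = FALSE
    )
  }

  if (length(header) == 0L)
    issues <- add_issue(issues, "warning", 1L, "missing header section")
  records <- if (n_rows) do.call(rbind, rows[seq_len(n_rows)])
             else empty_site_records()
  rownames(records) <- NULL
  structure(list(header = header, records = records, issues = issues),
            class = "bedrmod_file")
}

fmt_frequency <- function(f) sprintf("%.6g", f)

#' Write a bedRMod file
#'
#' Serializes a header and a site-record table deterministically: header lines
#' first (in the order given), then records sorted by `(chrom, start)`.
#' Records violating the site-record invariants are refused. Output written by
#' this function is canonical: re-parsing and re-writing it reproduces the
#' bytes exactly.
#'
#' @param header named character vector (see [bedrmod_header()]), or a parsed
#'   `bedrmod_file` list (then `records` may be omitted).
#' @param records site-record `data.frame` (see [site_records()]).
#' @param path optional output file path.
#' @return the file text, invisibly (a single string ending in a newline).
#' @export
write_bedrmod <- function(header, records, path = NULL) {
  if (missing(records) && is.list(header) && !is.null(header$records)) {
    records <- header$records
    header <- header$header
  }
  issues <- check_record_invariants(records)
  if (any(issues$severity == "error"))
    stopf("refusing to write invalid records: %s",
          paste(sprintf("row %d: %s",
                        issues$line[issues$severity == "error"],
                        issues$message[issues$severity == "error"]),
                collapse = "; "))
  records <- records[order(records$chrom, records$start), , drop = FALSE]
  hlines <- if (length(header)) paste0("#", names(header), "=",
                                       unname(header)) else character(0)
  dlines <- if (nrow(records)) {
    paste(records$chrom, records$start, records$end, records$mod_name,
          records$score, records$strand, records$thickStart, records$thickEnd,
          records$itemRgb, records$coverage, fmt_frequency(records$frequency),
          sep = "\t")
  } else character(0)
  text <- paste0(paste(c(hlines, dlines), collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(c(hlines, dlines), path)
  invisible(text)
}

#' Validate bedRMod content
#'
#' Collects all consistency violations as issues rather than raising errors:
#' coordinate problems (including positions beyond the reference length when a
#' reference is supplied), frequency/score mismatches, invalid strands, and
#' duplicate `(chrom, start, mod_name, strand)` sites (each duplicate pair is
#' reported naming both rows). When a parsed file is given, missing required
#' header keys are reported too.
#'
#' @param x a site-record `data.frame` or a parsed `bedrmod_file` list.
#' @param reference optional reference to check coordinates against: a single
#'   length, a named numeric vector of lengths, or a
#'   [Biostrings::DNAStringSet].
#' @return an issues `data.frame` (severity, line, message); empty when fully
#'   consistent. Line numbers refer to record row indices.
#' @export
validate_bedrmod <- function(x, reference = NULL) {
  issues <- new_issues()
  records <- x
  if (is.list(x) && !is.data.frame(x) && !is.null(x$records)) {
    records <- x$records
    missing_keys <- setdiff(REQUIRED_HEADER_KEYS, names(x$header))
    if (length(missing_keys))
      issues <- add_issue(issues, "error", 0L,
                          sprintf("missing required header key '%s'",
                                  missing_keys))
  }
  issues <- rbind(issues, check_record_invariants(records))
  if (nrow(records)) {
    key <- paste(records$chrom, records$start, records$mod_name,
                 records$strand, sep = "|")
    for (k in unique(key[duplicated(key)])) {
      rows <- which(key == k)
      issues <- add_issue(issues, "error", rows[1],
                          sprintf("duplicate site rows %s",
                                  paste(rows, collapse = ",")))
    }
    if (!is.null(reference)) {
      ref_len <- reference_lengths(reference)
      for (i in seq_len(nrow(records))) {
        len <- if (is.null(names(ref_len))) ref_len[[1]]
               else ref_len[[records$chrom[i]]]
        if (is.null(len) || is.na(len)) {
          issues <- add_issue(issues, "error", i,
                              sprintf("chrom '%s' not in reference",
                                      records$chrom[i]))
        } else if (records$start[i] >= len || records$end[i] > len) {
          issues <- add_issue(issues, "error", i,
                              "coordinate beyond reference length")
        }
      }
    }
  }
  rownames(issues) <- NULL
  issues
}

reference_lengths <- function(reference) {
  if (methods::is(reference, "DNAStringSet"))
    return(stats::setNames(Biostrings::width(reference), names(reference)))
  if (is.numeric(reference)) return(reference)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    seqs <- Biostrings::readDNAStringSet(reference)
    return(stats::setNames(Biostrings::width(seqs),
                           sub("\\s.*$", "", names(seqs))))
  }
  stopf("cannot interpret reference of class %s", class(reference)[1])
}

#' Export site records as plain 6-column BED
#'
#' Drops coverage and frequency, keeping the 0-1000 score, for genome-browser
#' use.
#'
#' @inheritParams write_bedrmod
#' @param path optional output path.
#' @return the 6-column `data.frame`, invisibly if `path` is given.
#' @export
export_bed <- function(records, path = NULL) {
  bed <- records[order(records$chrom, records$start),
                 c("chrom", "start", "end", "mod_name", "score", "strand")]
  rownames(bed) <- NULL
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}

#' @export
print.bedrmod_file <- function(x, ...) {
  cat(sprintf("bedRMod file: %d header entries, %d records, %d issues\n",
              length(x$header), nrow(x$records), nrow(x$issues)))
  invisible(x)
}
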