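# Programmatic fixtures; everything is generated in code under a seed.

# random small truth/prediction pair on one short reference
random_eval_fixture <- function(seed, L = 40L, max_sites = 6L) {
  withr::with_seed(seed, {
    nt <- sample.int(max_sites, 1L)
    truth <- site_records("ref", sort(sample(0:(L - 1L), nt)), "mod",
                          runif(nt, 0.05, 1), 50L)
    np <- sample(0:max_sites, 1L)
    pred <- site_records("ref", sort(sample(0:(L - 1L), np)), "mod",
                         runif(np), 50L)
    list(truth = truth, pred = pred, L = L)
  })
}

canonical_bedrmod_text <- function(n = 8L, seed = 42L, L = 500L) {
  withr::with_seed(seed, {
    recs <- site_records("ref1", sort(sample(0:(L - 1L), n)), "m6A",
                         round(runif(n, 0.01, 1), 4), sample(20:80, n))
  })
  write_bedrmod(bedrmod_header(modification_type = "m6A", assembly = "ref1"),
                recs)
}

# apply one seeded corruption to a canonical bedRMod file; returns the
# corrupted lines plus the corruption type. All types must be flagged by
# parse + validate (with the reference length supplied).
corrupt_bedrmod_lines <- function(lines, case_seed, ref_length) {
  types <- c("freq_over_percent", "non_numeric_coord", "wrong_column_count",
             "duplicate_row", "beyond_reference", "score_mismatch",
             "negative_coverage")
  withr::with_seed(case_seed, {
    is_data <- !startsWith(lines, "#")
    row <- sample(which(is_data), 1L)
    type <- sample(types, 1L)
    fields <- strsplit(lines[row], "\t", fixed = TRUE)[[1]]
    out <- lines
    if (type == "freq_over_percent") {
      fields[11] <- "250"
      out[row] <- paste(fields, collapse = "\t")
    } else if (type == "non_numeric_coord") {
      fields[2] <- paste0("x", fields[2])
      out[row] <- paste(fields, collapse = "\t")
    } else if (type == "wrong_column_count") {
      out[row] <- paste(fields[-11], collapse = "\t")
    } else if (type == "duplicate_row") {
      out <- append(out, lines[row], after = row)
    } else if (type == "beyond_reference") {
      fields[2] <- as.character(ref_length + 5L)
      fields[3] <- as.character(ref_length + 6L)
      fields[7] <- fields[2]
      fields[8] <- fields[3]
      out[row] <- paste(fields, collapse = "\t")
    } else if (type == "score_mismatch") {
      fields[5] <- as.character(as.integer(fields[5]) + 7L)
      out[row] <- paste(fields, collapse = "\t")
    } else if (type == "negative_coverage") {
      fields[10] <- "-5"
      out[row] <- paste(fields, collapse = "\t")
    }
    list(lines = out, type = type)
  })
}
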