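# Challenge reference design: sequences containing every k-mer with a fixed
# central target base, concatenated gap-free so that one modifiable position
# sits at the centre of each k-mer block.

DNA_BASES <- c("A", "C", "G", "T")

#' Enumerate all k-mers with a fixed central base
#'
#' Generates the `4^(k-1)` distinct k-mers whose central position carries
#' `central_base`, ordered lexicographically by their flanking bases (the
#' concatenation of 5' and 3' flanks). For `k = 5` this is the 256-member set
#' used to design the challenge references, so that every 5-mer context of the
#' target base is represented.
#'
#' @param central_base one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param k odd k-mer length, between 3 and 9.
#' @return character vector of `4^(k-1)` k-mers.
#' @examples
#' length(enumerate_central_kmers("C", 5))  # 256
#' @export
enumerate_central_kmers <- function(central_base, k = 5L) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 3L || k > 9L || k %% 2L == 0L)
    stopf("k must be an odd integer between 3 and 9, got %s", deparse(k))
  if (length(central_base) != 1L || !central_base %in% DNA_BASES)
    stopf("central_base must be one of A, C, G, T")
  nf <- k - 1L                       # number of flanking positions
  half <- nf %/% 2L
  n <- 4L^nf
  digits <- matrix(0L, nrow = n, ncol = nf)
  rem <- 0:(n - 1L)
  for (d in nf:1) {                  # most significant digit first
    digits[, d] <- rem %% 4L
    rem <- rem %/% 4L
  }
  flank_chars <- matrix(DNA_BASES[digits + 1L], nrow = n)
  left  <- do.call(paste0, as.data.frame(flank_chars[, seq_len(half),
                                                     drop = FALSE]))
  right <- do.call(paste0, as.data.frame(flank_chars[, half + seq_len(half),
                                                     drop = FALSE]))
  paste0(left, central_base, right)
}

#' Build a challenge reference design
#'
#' Concatenates the given k-mers without intervening gaps (optionally in a
#' seed-shuffled order), attaches optional flanking sequences, and records the
#' 0-based central position of every k-mer block — the positions at which the
#' target base can carry a modification.
#'
#' @param kmers character vector of distinct, equal-length k-mers sharing the
#'   same central base.
#' @param order_seed optional integer; when given, the k-mer order is a
#'   seed-reproducible shuffle instead of the input order.
#' @param flank_5p,flank_3p DNA strings prepended/appended to the k-mer core
#'   (possibly empty).
#' @param name sequence name used in FASTA/BED output.
#' @return an object of class `reference_design`: a list with `name`,
#'   `sequence`, `k`, `central_base`, `kmers` (in final order),
#'   `block_positions` (0-based central positions), `flank_5p`, `flank_3p`.
#' @export
build_reference <- function(kmers, order_seed = NULL, flank_5p = "",
                            flank_3p = "", name = "design") {
  if (!length(kmers)) stopf("no k-mers supplied")
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stopf("k-mers must all have the same length")
  k <- as.integer(k)
  if (k %% 2L == 0L) stopf("k-mer length must be odd")
  if (anyDuplicated(kmers)) stopf("duplicate k-mers are not allowed")
  if (!all(grepl("^[ACGT]+$", kmers))) stopf("k-mers must be over {A,C,G,T}")
  for (fl in c(flank_5p, flank_3p))
    if (nzchar(fl) && !grepl("^[ACGT]+$", fl))
      stopf("flanks must be DNA strings over {A,C,G,T}")
  centre <- (k + 1L) %/% 2L
  central <- unique(substr(kmers, centre, centre))
  if (length(central) != 1L)
    stopf("k-mers must share a single central base, found: %s",
          paste(central, collapse = ", "))
  kmers <- maybe_with_seed(order_seed, if (is.null(order_seed)) kmers
                           else sample(kmers))
  core <- paste(kmers, collapse = "")
  block_positions <- nchar(flank_5p) + k * (seq_along(kmers) - 1L) +
    (k - 1L) %/% 2L
  structure(list(
    name = name,
    sequence = paste0(flank_5p, core, flank_3p),
    k = k,
    central_base = central,
    kmers = kmers,
    block_positions = as.integer(block_positions),
    flank_5p = flank_5p,
    flank_3p = flank_3p
  ), class = "reference_design")
}

#' Write a reference design to FASTA and a truth-layout BED
#'
#' @param design a [build_reference()] object.
#' @param fasta_path output FASTA path.
#' @param bed_path output BED path; one 0-based half-open row per k-mer block
#'   central position, named by the block's k-mer.
#' @return invisibly, a list with the two paths.
#' @export
write_design <- function(design, fasta_path, bed_path) {
  stopifnot(inherits(design, "reference_design"))
  seqs <- Biostrings::DNAStringSet(stats::setNames(design$sequence,
                                                   design$name))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  bed <- data.frame(chrom = design$name,
                    start = design$block_positions,
                    end = design$block_positions + 1L,
                    name = design$kmers,
                    score = 0L,
                    strand = "+")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(fasta = fasta_path, bed = bed_path))
}

#' @export
print.reference_design <- function(x, ...) {
  cat(sprintf(
    "reference_design '%s': %d nt (%d x %d-mer core, flanks %d/%d), central base %s\n",
    x$name, nchar(x$sequence), length(x$kmers), x$k,
    nchar(x$flank_5p), nchar(x$flank_3p), x$central_base))
  invisible(x)
}
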