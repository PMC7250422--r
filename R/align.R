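## Seed-and-extend alignment against a single amplicon reference. A 15-mer
## exact seed fixes the diagonal; placement is then a gapless comparison with
## a banded affine-gap fallback for indel-bearing reads (src/align.cpp).

#' Build an exact k-mer index of a reference
#'
#' @param ref reference sequence.
#' @param k seed length (default 15).
#' @return named integer vector: k-mer -> first 0-based position.
#' @keywords internal
kmer_index <- function(ref, k = 15L) {
  L <- nchar(ref)
  if (L < k) stop("reference shorter than seed length")
  starts <- seq_len(L - k + 1L)
  kmers <- substring(ref, starts, starts + k - 1L)
  keep <- !duplicated(kmers)
  setNames(starts[keep] - 1L, kmers[keep])
}

## Estimated diagonal (0-based ref position of query base 0) per read, from
## exact seed hits at several query offsets; NA when no seed matches.
seed_diagonals <- function(seqs, index, k = 15L,
                           offsets = c(0L, 15L, 30L, 45L, 60L)) {
  n <- length(seqs)
  lens <- nchar(seqs)
  diags <- matrix(NA_integer_, nrow = n, ncol = length(offsets))
  for (j in seq_along(offsets)) {
    o <- offsets[j]
    ok <- lens >= o + k
    seeds <- substring(seqs[ok], o + 1L, o + k)
    hit <- unname(index[seeds])
    diags[ok, j] <- hit - o
  }
  apply(diags, 1L, function(d) {
    d <- d[!is.na(d)]
    if (!length(d)) NA_integer_ else as.integer(stats::median(d))
  })
}

#' Align short read pairs to a single amplicon reference
#'
#' Seed-and-extend placement: an exact 15-mer seed fixes the diagonal, then
#' a gapless comparison (with banded affine-gap dynamic programming as a
#' fallback for indel-bearing reads) places each mate. Orientation is chosen
#' per mate by seeding the read and its reverse complement. Pairs that do
#' not place with both mates on opposite strands of the same amplicon are
#' discarded and tallied, as are reads with no seed match.
#'
#' @param reads a [read_set()] (quality-filtered upstream).
#' @param amplicon reference sequence the reads derive from.
#' @param amplicon_id reference name used in downstream reports.
#' @param band half-width of the DP band around the seed diagonal.
#' @param require_proper_pair discard fragments without a concordant
#'   forward/reverse mate placement (single-end sets skip this check).
#' @return object of class `read_placements`: data.frame with `id`,
#'   `pair_id`, `mate`, `strand`, `pos` (0-based), `cigar`, `nm`, `seq`,
#'   `qual` (aligned orientation), plus attributes `amplicon`,
#'   `amplicon_id`, `n_discarded`.
#' @export
align_short_reads <- function(reads, amplicon, amplicon_id = "amplicon",
                              band = 12L, require_proper_pair = TRUE) {
  stopifnot(nrow(reads) > 0L)
  idx <- kmer_index(amplicon)
  seqs <- reads$seq
  diag_f <- seed_diagonals(seqs, idx)
  need_rc <- is.na(diag_f)
  rc <- character(length(seqs))
  rc[need_rc] <- revcomp(seqs[need_rc])
  diag_r <- rep(NA_integer_, length(seqs))
  if (any(need_rc)) diag_r[need_rc] <- seed_diagonals(rc[need_rc], idx)
  strand <- ifelse(!is.na(diag_f), "+", ifelse(!is.na(diag_r), "-", NA))
  oriented <- ifelse(!is.na(diag_f), seqs, rc)
  quals <- reads$qual
  quals[strand %in% "-"] <-
    vapply(strsplit(quals[strand %in% "-"], "", fixed = TRUE),
           function(x) paste(rev(x), collapse = ""), character(1))
  diags <- ifelse(!is.na(diag_f), diag_f, diag_r)

  pl <- cpp_place_reads(oriented, amplicon, diags, band = band)
  placed <- !is.na(pl$pos) & !is.na(strand)

  df <- data.frame(id = reads$id, pair_id = reads$pair_id, mate = reads$mate,
                   strand = strand, pos = pl$pos, cigar = pl$cigar,
                   nm = pl$nm, seq = oriented, qual = quals,
                   stringsAsFactors = FALSE)
  paired <- any(reads$mate > 0L)
  if (paired && require_proper_pair) {
    ok_by_pair <- tapply(placed & !is.na(df$strand), df$pair_id, all)
    str_by_pair <- tapply(df$strand, df$pair_id, function(s)
      length(s) == 2L && !anyNA(s) && s[1] != s[2])
    proper <- names(ok_by_pair)[ok_by_pair & str_by_pair]
    keep <- placed & (as.character(df$pair_id) %in% proper)
  } else keep <- placed
  out <- df[keep, , drop = FALSE]
  structure(out, class = c("read_placements", "data.frame"),
            amplicon = amplicon, amplicon_id = amplicon_id,
            n_discarded = nrow(df) - nrow(out))
}

#' @export
print.read_placements <- function(x, ...) {
  cat("Read placements on", attr(x, "amplicon_id"), ":", nrow(x),
      "reads placed,", attr(x, "n_discarded"), "discarded\n")
  invisible(x)
}

#' Banded semi-global alignment of one read against one reference
#'
#' The query is aligned end to end; leading/trailing reference bases are
#' free. Scoring: match +2, mismatch -4, gap open -4, gap extend -2.
#'
#' @param query,ref sequences.
#' @param diag estimated 0-based reference position of the first query base.
#' @param band band half-width around the diagonal.
#' @param ref_match return a per-reference-base match vector (-1 uncovered,
#'   0 covered mismatch/indel, 1 covered match).
#' @return list with `ok`, `score`, `ref_start`, `ref_end` (0-based
#'   half-open), `cigar`, `nm` and optionally `ref_match`.
#' @export
band_align <- function(query, ref, diag = 0L, band = 50L,
                       ref_match = FALSE) {
  cpp_band_align(query, ref, as.integer(diag), as.integer(band),
                 ref_match_vec = ref_match)
}
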