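#' Read/write FASTA
#'
#' @param path file path (plain or gzipped).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read set container
#'
#' Reads are held as a plain `data.frame` of class `read_set` with columns
#' `id`, `pair_id`, `mate` (1/2 for paired data, 0 for single-end long
#' reads), `seq` and `qual` (Phred+33). Simulators may attach extra truth
#' columns (e.g. `truth`) used only by tests.
#'
#' @param id read identifiers.
#' @param seq,qual sequence and quality strings (equal lengths).
#' @param pair_id integer pair index (one per fragment).
#' @param mate 1/2 mate number, or 0 for single-end.
#' @param ... additional columns (recycled by `data.frame`).
#' @return a `read_set`.
#' @export
read_set <- function(id, seq, qual, pair_id = seq_along(id),
                     mate = 0L, ...) {
  if (any(nchar(seq) != nchar(qual)))
    stop("sequence/quality length mismatch")
  df <- data.frame(id = as.character(id), pair_id = as.integer(pair_id),
                   mate = as.integer(mate), seq = as.character(seq),
                   qual = as.character(qual), ...,
                   stringsAsFactors = FALSE)
  class(df) <- c("read_set", "data.frame")
  df
}

#' @export
print.read_set <- function(x, ...) {
  cat("Read set:", nrow(x), "reads")
  if (any(x$mate > 0L)) cat(" (", length(unique(x$pair_id)), "pairs )")
  cat("; lengths", paste(range(nchar(x$seq)), collapse = "-"), "nt\n")
  invisible(x)
}

#' Read/write FASTQ
#'
#' Parsing is done by [Biostrings::readDNAStringSet()]; pair structure is
#' reconstructed from `/1` `/2` id suffixes when present.
#'
#' @param path file path; `.gz` suffix triggers gzip on write and is handled
#'   transparently on read.
#' @return a [read_set()].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  parsed <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    q <- as.character(S4Vectors::mcols(x)$qualities)
    if (any(nchar(q) != Biostrings::width(x)))
      stop("sequence/quality length mismatch")
    list(x = x, q = q)
  }, error = function(e) stop("malformed FASTQ in ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  x <- parsed$x
  ids <- names(x)
  qual <- parsed$q
  mate <- integer(length(ids))
  m <- regmatches(ids, regexpr("/[12]$", ids))
  has_mate <- grepl("/[12]$", ids)
  mate[has_mate] <- as.integer(substring(m, 2))
  base_id <- sub("/[12]$", "", ids)
  pair_id <- match(base_id, unique(base_id))
  read_set(id = ids, seq = as.character(x), qual = qual,
           pair_id = pair_id, mate = mate)
}

#' @rdname read_fastq
#' @param reads a [read_set()].
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Droplet count table
#'
#' Four-class counts of two-channel ddPCR droplets: `n_pp` (FAM+/HEX+),
#' `n_pn` (FAM+/HEX-), `n_np` (FAM-/HEX+), `n_nn` (double-negative).
#'
#' @param n_pp,n_pn,n_np,n_nn non-negative integer counts.
#' @return object of class `droplet_table`.
#' @export
droplet_table <- function(n_pp, n_pn, n_np, n_nn) {
  counts <- c(n_pp = as.integer(n_pp), n_pn = as.integer(n_pn),
              n_np = as.integer(n_np), n_nn = as.integer(n_nn))
  if (any(is.na(counts)) || any(counts < 0L))
    stop("droplet counts must be non-negative integers")
  if (sum(counts) == 0L) stop("droplet table is empty")
  structure(as.list(counts), class = "droplet_table")
}

#' @export
print.droplet_table <- function(x, ...) {
  n <- x$n_pp + x$n_pn + x$n_np + x$n_nn
  cat("Droplet table (", n, " droplets)\n", sep = "")
  cat(sprintf("  FAM+/HEX+ %8d\n  FAM+/HEX- %8d\n  FAM-/HEX+ %8d\n  FAM-/HEX- %8d\n",
              x$n_pp, x$n_pn, x$n_np, x$n_nn))
  invisible(x)
}

#' @rdname droplet_table
#' @param path TSV path with columns n_pp, n_pn, n_np, n_nn.
#' @export
read_droplet_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("n_pp", "n_pn", "n_np", "n_nn")
  if (!all(need %in% names(df)))
    stop("droplet TSV must have columns: ", paste(need, collapse = ", "))
  droplet_table(df$n_pp[1], df$n_pn[1], df$n_np[1], df$n_nn[1])
}

#' @rdname droplet_table
#' @param table a `droplet_table`.
#' @param meta optional named list written as `#key: value` header lines.
#' @export
write_droplet_table <- function(table, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(meta), con)
  writeLines(c(paste(c("n_pp", "n_pn", "n_np", "n_nn"), collapse = "\t"),
               paste(c(table$n_pp, table$n_pn, table$n_np, table$n_nn),
                     collapse = "\t")), con)
  invisible(path)
}

provenance_lines <- function(meta) {
  meta <- c(list(package = paste0("intequant ",
                                  as.character(utils::packageVersion("intequant")))),
            meta)
  paste0("#", names(meta), ": ", vapply(meta, function(v)
    paste(as.character(v), collapse = ","), character(1)))
}

#' Write a TSV report with a provenance header
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta optional named list of provenance values (seed, command, ...).
#' @export
write_report_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a variant table as minimal VCF 4.2
#'
#' `CHROM` is the amplicon id, `POS` is 1-based (internal positions are
#' 0-based), and INFO carries depth, allele frequency and, when present,
#' per-replicate frequencies and the de novo verdict.
#'
#' @param variants a `variant_table` (see [pileup_variants()]) or a de novo
#'   report's candidate table.
#' @param path output path.
#' @param contigs optional named integer vector of amplicon lengths.
#' @param meta optional named list for the header (seed, command line, ...).
#' @export
write_vcf <- function(variants, path, contigs = NULL, meta = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=intequant-",
                  as.character(utils::packageVersion("intequant"))))
  if (!is.null(meta))
    hdr <- c(hdr, paste0("##", names(meta), "=",
                         vapply(meta, function(v)
                           paste(as.character(v), collapse = ","),
                           character(1))))
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contigs), as.integer(contigs)))
  hdr <- c(hdr,
           '##INFO=<ID=DP,Number=1,Type=Integer,Description="Filtered depth">',
           '##INFO=<ID=AF,Number=1,Type=Float,Description="Alt allele frequency">')
  extra <- intersect(c("rep1_af", "rep2_af", "wt_af", "verdict"),
                     names(variants))
  defs <- c(rep1_af = '##INFO=<ID=REP1_AF,Number=1,Type=Float,Description="Replicate 1 frequency">',
            rep2_af = '##INFO=<ID=REP2_AF,Number=1,Type=Float,Description="Replicate 2 frequency">',
            wt_af = '##INFO=<ID=WT_AF,Number=1,Type=Float,Description="WT allele frequency">',
            verdict = '##INFO=<ID=VERDICT,Number=1,Type=String,Description="De novo verdict">')
  hdr <- c(hdr, unname(defs[extra]),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (!is.null(variants) && nrow(variants) > 0) {
    rows <- vapply(seq_len(nrow(variants)), function(i) {
      v <- variants[i, ]
      info <- sprintf("DP=%d;AF=%.6g", v$depth, v$frequency)
      if ("rep1_af" %in% extra) info <- paste0(info, sprintf(";REP1_AF=%.6g", v$rep1_af))
      if ("rep2_af" %in% extra) info <- paste0(info, sprintf(";REP2_AF=%.6g", v$rep2_af))
      if ("wt_af" %in% extra) info <- paste0(info, sprintf(";WT_AF=%.6g", v$wt_af))
      if ("verdict" %in% extra) info <- paste0(info, ";VERDICT=", v$verdict)
      paste(v$amplicon_id, v$pos + 1L, ".", v$ref, v$alt, ".",
            v$filter %||% "PASS", info, sep = "\t")
    }, character(1))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a per-base coverage vector as BedGraph
#'
#' @param coverage numeric vector of per-base depth along the reference.
#' @param refname reference (amplicon) name.
#' @param path output path.
#' @export
write_bedgraph <- function(coverage, refname, path) {
  r <- rle(as.numeric(coverage))
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  gr <- GenomicRanges::GRanges(
    seqnames = refname,
    ranges = IRanges::IRanges(start = starts, end = ends),
    score = r$values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
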