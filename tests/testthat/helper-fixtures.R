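# Shared fixtures and independent brute-force oracles.

# memoized standard example locus (arm lengths 960/911, 7+2 het SNPs)
test_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- example_locus_model(100)
    m
  }
})

# small deterministic locus for fast structural tests
toy_locus <- function(seed = 7L) {
  for (try in 0:9) {
    m <- try(withr::with_seed(seed + try * 13L, {
      dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")
      left_arm <- dna(60); right_arm <- dna(55)
      snps <- data.frame(arm = c("left", "left", "right"),
                         offset = c(15L, 40L, 20L),
                         haplotype = c(1L, 2L, 1L),
                         stringsAsFactors = FALSE)
      snps$ref <- vapply(seq_len(nrow(snps)), function(i) {
        a <- if (snps$arm[i] == "left") left_arm else right_arm
        idx <- snp_arm_index(snps$offset[i], snps$arm[i], nchar(a))
        substr(a, idx + 1L, idx + 1L)
      }, character(1))
      snps$alt <- vapply(snps$ref, function(r)
        setdiff(c("A", "C", "G", "T"), r)[1], character(1))
      locus_model(left_arm, right_arm, payload_seq = dna(40),
                  wt_insert_seq = dna(30), left_flank_seq = dna(40),
                  right_flank_seq = dna(40), itr_d_region_seq = dna(12),
                  snps = snps)
    }), silent = TRUE)
    if (!inherits(m, "try-error")) return(m)
  }
  stop("no valid toy locus")
}

# naive junction counting: per-fragment substring scan, independent of the
# production grepl/rowsum path
brute_force_junction_counts <- function(reads, model, side) {
  jk <- junction_kmers(model)
  k_wt <- jk[[paste0(side, "_wt")]]
  k_ed <- jk[[paste0(side, "_edited")]]
  has <- function(seq, kmer) {
    length(gregexpr(kmer, seq, fixed = TRUE)[[1]]) > 0 &&
      gregexpr(kmer, seq, fixed = TRUE)[[1]][1] != -1 ||
      gregexpr(revcomp(kmer), seq, fixed = TRUE)[[1]][1] != -1
  }
  n_ed <- n_wt <- n_un <- 0L
  for (pid in unique(reads$pair_id)) {
    mates <- reads$seq[reads$pair_id == pid]
    w <- any(vapply(mates, has, logical(1), kmer = k_wt))
    e <- any(vapply(mates, has, logical(1), kmer = k_ed))
    if (w && e) n_un <- n_un + 1L
    else if (e) n_ed <- n_ed + 1L
    else if (w) n_wt <- n_wt + 1L
    else n_un <- n_un + 1L
  }
  list(n_edited = n_ed, n_wt = n_wt, n_uninformative = n_un)
}

# naive pileup of gapless reads with known placements
brute_force_pileup <- function(seqs, quals, starts, ref_len, min_bq = 30) {
  counts <- matrix(0L, 4, ref_len, dimnames = list(c("A", "C", "G", "T"),
                                                   NULL))
  for (i in seq_along(seqs)) {
    s <- strsplit(seqs[i], "")[[1]]
    q <- as.integer(charToRaw(quals[i])) - 33L
    for (j in seq_along(s)) {
      pos <- starts[i] + j
      if (pos >= 1 && pos <= ref_len && q[j] >= min_bq &&
          s[j] %in% rownames(counts))
        counts[s[j], pos] <- counts[s[j], pos] + 1L
    }
  }
  counts
}

# build a minimal variant_table by hand
mk_variant_table <- function(df, amplicon_id = "amp", ref_len = 1000L) {
  need <- c("pos", "type", "ref", "alt", "depth", "alt_count")
  for (nm in setdiff(need, names(df))) {
    val <- switch(nm, type = "snv", ref = "A", depth = 10000L,
                  alt_count = NA_integer_)
    df[[nm]] <- rep(val, nrow(df))
  }
  if (all(is.na(df$alt_count))) df$alt_count <- round(df$frequency * df$depth)
  if (is.null(df$frequency)) df$frequency <- df$alt_count / df$depth
  df$amplicon_id <- rep(amplicon_id, nrow(df))
  df$filter <- rep("PASS", nrow(df))
  class(df) <- c("variant_table", "data.frame")
  attr(df, "amplicon_id") <- amplicon_id
  attr(df, "ref_len") <- ref_len
  df
}
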