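#' Locus model for a targeted-integration site
#'
#' A `locus_model` holds every sequence needed to reason about one
#' homology-directed integration locus: the two homology arms, the payload
#' edge sequences, the wild-type insert that the payload replaces (for the
#' packaged example a SINE-like repeat), genomic flanks outside the arms, and
#' the terminal "d region" of the viral ITR. From these it precomputes the
#' four genotype-discriminating junction k-mers (default k = 12: 6 arm bases
#' plus 6 genotype-specific bases on either side of each junction) and
#' validates that they are unique across all amplicons on both strands.
#'
#' All coordinates are 0-based half-open. SNP annotations use the field
#' convention of "distance to the first payload base" (`offset`, >= 1), which
#' is converted to an arm index internally (see [snp_arm_index()]).
#'
#' @param left_arm_seq,right_arm_seq homology arm sequences (A/C/G/T).
#' @param payload_seq payload edge sequence included in amplicons.
#' @param wt_insert_seq wild-type-specific sequence replaced by the payload.
#' @param left_flank_seq,right_flank_seq genomic sequence outside the arms.
#' @param itr_d_region_seq terminal d-region of the ITR.
#' @param snps `data.frame` with columns `arm` ("left"/"right"), `offset`,
#'   `ref`, `alt`, `haplotype`; may be `NULL` for a SNP-free model.
#' @param junction_k junction k-mer length (even; default 12).
#' @return object of class `locus_model`.
#' @export
locus_model <- function(left_arm_seq, right_arm_seq, payload_seq,
                        wt_insert_seq, left_flank_seq, right_flank_seq,
                        itr_d_region_seq, snps = NULL, junction_k = 12L) {
  seqs <- list(left_arm = left_arm_seq, right_arm = right_arm_seq,
               payload = payload_seq, wt_insert = wt_insert_seq,
               left_flank = left_flank_seq, right_flank = right_flank_seq,
               itr_d_region = itr_d_region_seq)
  seqs <- lapply(seqs, function(s) toupper(as.character(s)))
  junction_k <- as.integer(junction_k)
  if (junction_k < 2L || junction_k %% 2L != 0L)
    stop("junction_k must be a positive even integer")
  h <- junction_k %/% 2L

  ok <- vapply(seqs, is_dna, logical(1), allow_n = TRUE)
  if (!all(ok))
    stop("non-DNA characters in: ", paste(names(seqs)[!ok], collapse = ", "))
  lens <- vapply(seqs, nchar, integer(1))
  need <- c("left_arm", "right_arm", "payload", "wt_insert")
  if (any(lens[need] < junction_k))
    stop("arm/payload/wt_insert sequences must be at least junction_k long")
  if (any(lens[c("left_flank", "right_flank", "itr_d_region")] < 1L))
    stop("flank and ITR d-region sequences must be non-empty")

  ## N is forbidden near any junction: both ends of the arms and the
  ## junction-proximal ends of payload, wt_insert, flanks and d-region.
  near <- c(substr(seqs$left_arm, 1, h),
            substr(seqs$left_arm, lens["left_arm"] - h + 1L, lens["left_arm"]),
            substr(seqs$right_arm, 1, h),
            substr(seqs$right_arm, lens["right_arm"] - h + 1L, lens["right_arm"]),
            substr(seqs$payload, 1, h),
            substr(seqs$payload, lens["payload"] - h + 1L, lens["payload"]),
            substr(seqs$wt_insert, 1, h),
            substr(seqs$wt_insert, lens["wt_insert"] - h + 1L, lens["wt_insert"]),
            substr(seqs$left_flank, lens["left_flank"] - h + 1L, lens["left_flank"]),
            substr(seqs$right_flank, 1, h),
            seqs$itr_d_region)
  if (any(grepl("N", near, fixed = TRUE)))
    stop("ambiguous base (N) within junction_k/2 of a junction")

  model <- structure(
    c(seqs, list(junction_k = junction_k, snps = NULL)),
    class = "locus_model")
  model$snps <- validate_snps(snps, model)

  jk <- compute_junction_kmers(model)
  if (anyDuplicated(unlist(jk)))
    stop("junction k-mers are not pairwise distinct: ",
         paste(unlist(jk)[duplicated(unlist(jk))], collapse = ", "))
  model$junction_kmers <- jk
  validate_kmer_uniqueness(model)
  model
}

compute_junction_kmers <- function(model) {
  h <- model$junction_k %/% 2L
  la <- model$left_arm; ra <- model$right_arm
  tail_la <- substr(la, nchar(la) - h + 1L, nchar(la))
  head_ra <- substr(ra, 1L, h)
  list(
    left_wt      = paste0(tail_la, substr(model$wt_insert, 1L, h)),
    left_edited  = paste0(tail_la, substr(model$payload, 1L, h)),
    right_wt     = paste0(substr(model$wt_insert,
                                 nchar(model$wt_insert) - h + 1L,
                                 nchar(model$wt_insert)), head_ra),
    right_edited = paste0(substr(model$payload,
                                 nchar(model$payload) - h + 1L,
                                 nchar(model$payload)), head_ra))
}

#' Junction k-mers of a locus model
#'
#' @param model a [locus_model()].
#' @return named list with elements `left_wt`, `left_edited`, `right_wt`,
#'   `right_edited`.
#' @export
junction_kmers <- function(model) {
  stopifnot(inherits(model, "locus_model"))
  model$junction_kmers
}

count_occurrences <- function(kmer, seq) {
  Biostrings::countPattern(kmer, Biostrings::DNAString(seq)) +
    Biostrings::countPattern(kmer,
                             Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## Each genotype k-mer must occur exactly once, in its own genotype's
## amplicon, and nowhere else (either strand). The ITR amplicon legitimately
## repeats the edited arm/payload junction and is checked for the foreign
## k-mers only.
validate_kmer_uniqueness <- function(model) {
  jk <- model$junction_kmers
  for (side in c("left", "right")) {
    amp <- build_amplicons(model, side, .validate = FALSE)
    own_wt <- paste0(side, "_wt"); own_ed <- paste0(side, "_edited")
    for (nm in names(jk)) {
      k <- jk[[nm]]
      n_wt <- count_occurrences(k, amp$wt)
      n_ed <- count_occurrences(k, amp$edited)
      n_itr <- count_occurrences(k, amp$itr)
      exp_wt <- if (nm == own_wt) 1L else 0L
      exp_ed <- if (nm == own_ed) 1L else 0L
      if (n_wt != exp_wt || n_ed != exp_ed)
        stop("junction k-mer ", nm, " (", k, ") occurs ", n_wt, "/", n_ed,
             " times in the ", side, " WT/edited amplicons (expected ",
             exp_wt, "/", exp_ed, ")")
      if (nm != own_ed && nm != own_wt && n_itr != 0L)
        stop("junction k-mer ", nm, " (", k, ") collides with the ",
             side, " ITR amplicon")
    }
  }
  invisible(model)
}

validate_snps <- function(snps, model) {
  if (is.null(snps) || nrow(snps) == 0L)
    return(data.frame(arm = character(0), offset = integer(0),
                      ref = character(0), alt = character(0),
                      haplotype = integer(0)))
  need <- c("arm", "offset", "ref", "alt", "haplotype")
  if (!all(need %in% names(snps)))
    stop("SNP table must have columns: ", paste(need, collapse = ", "))
  snps <- snps[, need]
  snps$arm <- as.character(snps$arm)
  snps$offset <- as.integer(snps$offset)
  snps$haplotype <- as.integer(snps$haplotype)
  snps$ref <- toupper(as.character(snps$ref))
  snps$alt <- toupper(as.character(snps$alt))
  if (!all(snps$arm %in% c("left", "right")))
    stop("SNP arm must be 'left' or 'right'")
  for (i in seq_len(nrow(snps))) {
    arm_seq <- if (snps$arm[i] == "left") model$left_arm else model$right_arm
    L <- nchar(arm_seq)
    if (snps$offset[i] < 1L || snps$offset[i] > L)
      stop("SNP offset ", snps$offset[i], " outside ", snps$arm[i],
           " arm (length ", L, ")")
    if (snps$ref[i] == snps$alt[i])
      stop("SNP ref and alt must differ (offset ", snps$offset[i], ")")
    idx <- snp_arm_index(snps$offset[i], snps$arm[i], L)
    have <- substr(arm_seq, idx + 1L, idx + 1L)
    if (have != snps$ref[i])
      stop("SNP ref base ", snps$ref[i], " does not match arm base ", have,
           " at offset ", snps$offset[i], " (", snps$arm[i], " arm)")
  }
  snps
}

#' Convert a SNP offset to a 0-based arm index
#'
#' Offsets count the distance from the SNP to the first payload base, the
#' convention used for "distance to center" in crossover analyses: on the
#' left arm the payload begins immediately after the arm, on the right arm
#' immediately before it.
#'
#' @param offset integer offset (>= 1).
#' @param arm `"left"` or `"right"`.
#' @param arm_len arm length in bases.
#' @return 0-based index into the arm sequence.
#' @export
snp_arm_index <- function(offset, arm, arm_len) {
  n <- max(length(offset), length(arm))
  arm <- rep_len(arm, n)
  offset <- rep_len(as.integer(offset), n)
  ifelse(arm == "left", as.integer(arm_len) - offset, offset - 1L)
}

#' Build the WT, edited and ITR-control amplicons for one side
#'
#' The edited amplicon joins genomic flank, homology arm and payload with no
#' intervening bases; the WT amplicon carries the wild-type insert in place
#' of the payload; the ITR amplicon equals the edited amplicon with the ITR
#' d-region inserted at the arm/genome junction (modelling the documented
#' ITR-remnant integration control).
#'
#' @param model a [locus_model()].
#' @param side `"left"` or `"right"`.
#' @param .validate internal; skip class check during model construction.
#' @return object of class `amplicon_set`: sequences `wt`, `edited`, `itr`
#'   plus 0-based half-open `regions` per amplicon and `lengths`.
#' @export
build_amplicons <- function(model, side = c("left", "right"),
                            .validate = TRUE) {
  side <- match.arg(side)
  if (.validate) stopifnot(inherits(model, "locus_model"))
  d <- model$itr_d_region
  reg <- function(...) {
    parts <- list(...)
    ends <- cumsum(vapply(parts, nchar, integer(1)))
    starts <- c(0L, utils::head(ends, -1L))
    out <- Map(function(s, e) c(start = s, end = e), starts, ends)
    names(out) <- names(parts)
    out
  }
  if (side == "left") {
    wt  <- paste0(model$left_flank, model$left_arm, model$wt_insert)
    ed  <- paste0(model$left_flank, model$left_arm, model$payload)
    itr <- paste0(model$left_flank, d, model$left_arm, model$payload)
    regions <- list(
      wt = reg(flank = model$left_flank, arm = model$left_arm,
               wt_insert = model$wt_insert),
      edited = reg(flank = model$left_flank, arm = model$left_arm,
                   payload = model$payload),
      itr = reg(flank = model$left_flank, d_region = d,
                arm = model$left_arm, payload = model$payload))
  } else {
    wt  <- paste0(model$wt_insert, model$right_arm, model$right_flank)
    ed  <- paste0(model$payload, model$right_arm, model$right_flank)
    itr <- paste0(model$payload, model$right_arm, d, model$right_flank)
    regions <- list(
      wt = reg(wt_insert = model$wt_insert, arm = model$right_arm,
               flank = model$right_flank),
      edited = reg(payload = model$payload, arm = model$right_arm,
                   flank = model$right_flank),
      itr = reg(payload = model$payload, arm = model$right_arm,
                d_region = d, flank = model$right_flank))
  }
  structure(list(side = side, wt = wt, edited = ed, itr = itr,
                 regions = regions,
                 lengths = c(wt = nchar(wt), edited = nchar(ed),
                             itr = nchar(itr))),
            class = "amplicon_set")
}

#' @export
print.locus_model <- function(x, ...) {
  cat("Locus model (junction k =", x$junction_k, ")\n")
  cat(sprintf("  left arm : %d bp   right arm: %d bp\n",
              nchar(x$left_arm), nchar(x$right_arm)))
  cat(sprintf("  payload edge: %d bp   WT insert: %d bp   ITR d-region: %d bp\n",
              nchar(x$payload), nchar(x$wt_insert), nchar(x$itr_d_region)))
  cat(sprintf("  flanks: %d / %d bp\n",
              nchar(x$left_flank), nchar(x$right_flank)))
  cat("  SNPs:", nrow(x$snps), "(",
      sum(x$snps$arm == "left"), "left /", sum(x$snps$arm == "right"),
      "right )\n")
  cat("  junction k-mers:\n")
  for (nm in names(x$junction_kmers))
    cat(sprintf("    %-12s %s\n", nm, x$junction_kmers[[nm]]))
  invisible(x)
}

#' @export
print.amplicon_set <- function(x, ...) {
  cat("Amplicon set (", x$side, " side)\n", sep = "")
  for (nm in c("wt", "edited", "itr"))
    cat(sprintf("  %-7s %5d bp\n", nm, nchar(x[[nm]])))
  invisible(x)
}

# ---- configuration ---------------------------------------------------------

LOCUS_CONFIG_KEYS <- c("sequences", "snps", "junction_k")

#' Read a locus configuration file
#'
#' The configuration is a small YAML file with documented keys:
#' \describe{
#'   \item{sequences}{path (relative to the config file) of a multi-FASTA
#'     with records named `left_arm`, `right_arm`, `payload`, `wt_insert`,
#'     `left_flank`, `right_flank`, `itr_d_region`.}
#'   \item{snps}{path of a TSV with columns `arm`, `offset`, `ref`, `alt`,
#'     `haplotype`.}
#'   \item{junction_k}{optional junction k-mer length (default 12).}
#' }
#' Unknown keys are rejected.
#'
#' @param path path to the YAML config.
#' @return list with elements `sequences` (named character), `snps`
#'   (data.frame), `junction_k`.
#' @export
read_locus_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), LOCUS_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$sequences) || is.null(cfg$snps))
    stop("config must provide 'sequences' and 'snps'")
  base <- dirname(path)
  fa <- read_fasta(file.path(base, cfg$sequences))
  need <- c("left_arm", "right_arm", "payload", "wt_insert",
            "left_flank", "right_flank", "itr_d_region")
  if (!all(need %in% names(fa)))
    stop("sequences FASTA missing records: ",
         paste(setdiff(need, names(fa)), collapse = ", "))
  snps <- utils::read.delim(file.path(base, cfg$snps),
                            stringsAsFactors = FALSE)
  list(sequences = fa[need], snps = snps,
       junction_k = as.integer(cfg$junction_k %||% 12L))
}

#' Build a locus model from a configuration
#'
#' @param config path to a YAML config (see [read_locus_config()]) or a list
#'   as returned by it.
#' @return a [locus_model()].
#' @export
build_locus_model <- function(config) {
  if (is.character(config)) config <- read_locus_config(config)
  s <- config$sequences
  locus_model(left_arm_seq = s[["left_arm"]],
              right_arm_seq = s[["right_arm"]],
              payload_seq = s[["payload"]],
              wt_insert_seq = s[["wt_insert"]],
              left_flank_seq = s[["left_flank"]],
              right_flank_seq = s[["right_flank"]],
              itr_d_region_seq = s[["itr_d_region"]],
              snps = config$snps,
              junction_k = config$junction_k %||% 12L)
}

## AAV2 ITR terminal "d region"
AAV2_D_REGION <- "AGGAACCCCTAGTGATGGAG"

#' Synthetic example locus model
#'
#' Generates a fully synthetic stand-in for a targeted-integration locus with
#' the canonical layout: 960 bp left and 911 bp right homology arms, a 140 bp
#' wild-type insert replaced by the payload, 150 bp genomic flanks, a 250 bp
#' payload edge, the AAV2 ITR d-region, and a donor carrying 7 left-arm plus
#' 2 right-arm heterozygous SNPs split across two haplotypes (six of the
#' seven left-arm SNPs on one haplotype, one on the other). Sequences are
#' random under the given seed; the generator retries deterministically if a
#' draw violates the junction k-mer uniqueness invariant.
#'
#' @param seed integer seed for sequence generation.
#' @return a [locus_model()].
#' @export
example_locus_model <- function(seed = 100L) {
  for (try in 0:19) {
    s <- as.integer(seed) + try * 1000003L
    model <- try(withr::with_seed(s, build_example_locus()), silent = TRUE)
    if (!inherits(model, "try-error")) return(model)
  }
  stop("could not generate a valid example locus from seed ", seed)
}

build_example_locus <- function() {
  left_arm <- random_dna(960)
  right_arm <- random_dna(911)
  payload <- random_dna(250)
  wt_insert <- random_dna(140)
  left_flank <- random_dna(150)
  right_flank <- random_dna(150)

  snp_alt <- function(ref) sample(setdiff(DNA_BASES, ref), 1)
  left_off <- c(47L, 214L, 378L, 521L, 562L, 703L, 886L)
  left_hap <- c(2L, 2L, 2L, 1L, 2L, 2L, 2L)
  right_off <- c(160L, 622L)
  right_hap <- c(1L, 2L)
  snps <- data.frame(
    arm = c(rep("left", 7), rep("right", 2)),
    offset = c(left_off, right_off),
    haplotype = c(left_hap, right_hap),
    stringsAsFactors = FALSE)
  snps$ref <- vapply(seq_len(nrow(snps)), function(i) {
    arm_seq <- if (snps$arm[i] == "left") left_arm else right_arm
    idx <- snp_arm_index(snps$offset[i], snps$arm[i], nchar(arm_seq))
    substr(arm_seq, idx + 1L, idx + 1L)
  }, character(1))
  snps$alt <- vapply(snps$ref, snp_alt, character(1))

  locus_model(left_arm, right_arm, payload, wt_insert,
              left_flank, right_flank, AAV2_D_REGION,
              snps = snps, junction_k = 12L)
}

#' Write an example locus configuration to disk
#'
#' Writes `sequences.fa`, `snps.tsv` and `config.yaml` for the synthetic
#' example locus, so the config-file loading path can be exercised.
#'
#' @param dir output directory (created if missing).
#' @param seed passed to [example_locus_model()].
#' @return path to the written config file, invisibly.
#' @export
write_example_locus <- function(dir, seed = 100L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- example_locus_model(seed)
  seqs <- c(left_arm = model$left_arm, right_arm = model$right_arm,
            payload = model$payload, wt_insert = model$wt_insert,
            left_flank = model$left_flank, right_flank = model$right_flank,
            itr_d_region = model$itr_d_region)
  write_fasta(seqs, file.path(dir, "sequences.fa"))
  utils::write.table(model$snps, file.path(dir, "snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(sequences = "sequences.fa", snps = "snps.tsv",
                        junction_k = model$junction_k), cfg)
  invisible(cfg)
}
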