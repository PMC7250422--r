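## Long-read classification at the integration junction: reads are filtered
## on quality and length, assigned by banded alignment to a three-way
## reference (ITR-containing, seamless, WT), and ITR calls require three
## criteria: full length over the arm with a payload anchor, >= 5 consecutive
## bases matching the payload-facing d-region at the junction, and genomic
## sequence beyond the junction.

#' Filter long reads on accuracy and length
#'
#' Mirrors the two-stage trim: a first pass at `first_pass_min_len`, then
#' the expected-amplicon window `[min_len, max_len]`. Accuracy is the mean
#' per-base correctness implied by the quality string.
#'
#' @param reads a [read_set()].
#' @param min_accuracy minimum mean per-base accuracy (default 0.90).
#' @param min_len,max_len length window for the expected amplicons.
#' @param first_pass_min_len initial minimum length trim.
#' @return list with `kept` (a [read_set()]) and `excluded` (data.frame of
#'   `id`, `reason` in `{low_quality, short, long}`).
#' @export
filter_long_reads <- function(reads, min_accuracy = 0.90,
                              min_len = 1000L, max_len = 2000L,
                              first_pass_min_len = 400L) {
  len <- nchar(reads$seq)
  acc <- 1 - 10^(-mean_qual(reads$qual) / 10)
  reason <- rep("none", nrow(reads))
  reason[acc < min_accuracy] <- "low_quality"
  reason[reason == "none" & (len < first_pass_min_len | len < min_len)] <- "short"
  reason[reason == "none" & len > max_len] <- "long"
  kept <- reads[reason == "none", , drop = FALSE]
  class(kept) <- class(reads)
  list(kept = kept,
       excluded = data.frame(id = reads$id[reason != "none"],
                             reason = reason[reason != "none"],
                             stringsAsFactors = FALSE))
}

## Vectorized seeding: median diagonal and seed-hit count per read against
## one reference index, sampling seeds every `stride` bases.
seed_diag_summary <- function(seqs, ix, k = 15L, stride = 40L,
                              max_seeds = 40L) {
  lens <- nchar(seqs)
  offs <- seq.int(0L, max(0L, max(lens) - k), by = stride)
  if (length(offs) > max_seeds) offs <- offs[seq_len(max_seeds)]
  nm <- names(ix)
  diags <- matrix(NA_integer_, length(seqs), length(offs))
  for (j in seq_along(offs)) {
    o <- offs[j]
    ok <- lens >= o + k
    if (!any(ok)) next
    pos <- unname(ix[match(substring(seqs[ok], o + 1L, o + k), nm)])
    diags[ok, j] <- pos - o
  }
  nh <- rowSums(!is.na(diags))
  diag <- apply(diags, 1L, function(d) {
    d <- d[!is.na(d)]
    if (!length(d)) NA_integer_ else as.integer(stats::median(d))
  })
  list(diag = diag, nhits = nh)
}

## longest run of consecutive matched reference bases within [from, to)
longest_match_run <- function(ref_match, from, to) {
  v <- ref_match[seq.int(from + 1L, to)]
  if (!length(v)) return(0L)
  r <- rle(v == 1L)
  runs <- r$lengths[r$values]
  if (length(runs)) max(runs) else 0L
}

#' Assign long reads to the three-way reference by banded alignment
#'
#' Each read is aligned (semi-global, affine gaps, band 10% of read length
#' around a 15-mer seed diagonal) against the ITR, seamless and WT amplicons
#' of one side; the highest score wins and ties are left unassigned. For the
#' winning reference the alignment span and the longest matched run inside
#' the d-region (ITR reference only) are recorded.
#'
#' @param reads a [read_set()] of filtered long reads.
#' @param amp an [build_amplicons()] result.
#' @param seed_k seed k-mer length.
#' @param seed_stride spacing of seed positions along the read.
#' @return data.frame (class `three_way_alignment`) with per-read scores,
#'   `assigned`, `top_ref`, `strand`, `ref_start`, `ref_end`, `d_match_run`.
#' @export
align_three_way <- function(reads, amp, seed_k = 15L, seed_stride = 40L) {
  stopifnot(inherits(amp, "amplicon_set"))
  refs <- list(itr = amp$itr, seamless = amp$edited, wt = amp$wt)
  idx <- lapply(refs, kmer_index, k = seed_k)
  n <- nrow(reads)
  scores <- matrix(NA_real_, n, 3, dimnames = list(NULL, names(refs)))
  out <- data.frame(id = reads$id, assigned = "unassigned",
                    top_ref = NA_character_, strand = NA_character_,
                    ref_start = NA_integer_, ref_end = NA_integer_,
                    d_match_run = NA_integer_, tie = FALSE,
                    stringsAsFactors = FALSE)
  d_reg <- amp$regions$itr$d_region
  rc_seqs <- revcomp(reads$seq)
  sd_f <- lapply(idx, function(ix)
    seed_diag_summary(reads$seq, ix, seed_k, seed_stride))
  sd_r <- lapply(idx, function(ix)
    seed_diag_summary(rc_seqs, ix, seed_k, seed_stride))
  tot_f <- Reduce(`+`, lapply(sd_f, `[[`, "nhits"))
  tot_r <- Reduce(`+`, lapply(sd_r, `[[`, "nhits"))
  use_rc_all <- tot_r > tot_f
  for (r in seq_len(n)) {
    use_rc <- use_rc_all[r]
    q <- if (use_rc) rc_seqs[r] else reads$seq[r]
    len <- nchar(q)
    band <- max(30L, as.integer(round(0.05 * len)))
    sd <- if (use_rc) sd_r else sd_f
    als <- vector("list", 3)
    names(als) <- names(refs)
    for (ref_nm in names(refs)) {
      diag <- sd[[ref_nm]]$diag[r]
      if (is.na(diag)) next
      al <- cpp_band_align(q, refs[[ref_nm]], diag, band,
                           ref_match_vec = (ref_nm == "itr"))
      if (isTRUE(al$ok)) {
        als[[ref_nm]] <- al
        scores[r, ref_nm] <- al$score
      }
    }
    sc <- scores[r, ]
    if (all(is.na(sc))) next
    top <- which(sc == max(sc, na.rm = TRUE))
    top_nm <- names(refs)[top[1]]
    out$top_ref[r] <- top_nm
    out$strand[r] <- if (use_rc) "-" else "+"
    out$ref_start[r] <- als[[top_nm]]$ref_start
    out$ref_end[r] <- als[[top_nm]]$ref_end
    if (length(top) > 1L) {
      out$tie[r] <- TRUE # ambiguous: never counts toward any reference
    } else {
      out$assigned[r] <- top_nm
    }
    if (!is.null(als$itr) && !is.null(als$itr$ref_match))
      out$d_match_run[r] <- longest_match_run(als$itr$ref_match,
                                              d_reg["start"], d_reg["end"])
  }
  out$score_itr <- scores[, "itr"]
  out$score_seamless <- scores[, "seamless"]
  out$score_wt <- scores[, "wt"]
  class(out) <- c("three_way_alignment", "data.frame")
  attr(out, "side") <- amp$side
  out
}

region_overlap <- function(start, end, region) {
  pmax(0L, pmin(end, region["end"]) - pmax(start, region["start"]))
}

#' Apply the ITR criteria to aligned long reads
#'
#' A read counts as ITR-containing only when assigned to the ITR reference
#' with (a) a full-length alignment covering the entire homology arm and at
#' least one payload base, (b) at least 5 consecutive read bases matching
#' the payload-facing d-region at the junction, and (c) alignment extending
#' into the genomic flank beyond the junction. Reads whose alignment covers
#' payload and arm but no genomic flank are flagged as mispriming products.
#'
#' @param aligned an [align_three_way()] result.
#' @param amp the matching [build_amplicons()] result.
#' @param min_itr_match minimum consecutive d-region matches (default 5).
#' @return `aligned` with logical columns `full_length`, `itr_5nt_match`,
#'   `genomic_beyond_junction`, `is_itr` and a `mispriming` flag.
#' @export
classify_itr <- function(aligned, amp, min_itr_match = 5L) {
  stopifnot(inherits(aligned, "three_way_alignment"))
  n <- nrow(aligned)
  aligned$full_length <- aligned$itr_5nt_match <-
    aligned$genomic_beyond_junction <- rep(NA, n)
  aligned$mispriming <- rep(FALSE, n)
  for (r in seq_len(n)) {
    top <- aligned$top_ref[r]
    if (is.na(top)) next
    reg <- amp$regions[[if (top == "seamless") "edited" else top]]
    st <- aligned$ref_start[r]; en <- aligned$ref_end[r]
    arm_cov <- st <= reg$arm["start"] && en >= reg$arm["end"]
    pay_reg <- if ("payload" %in% names(reg)) reg$payload else reg$wt_insert
    pay_cov <- region_overlap(st, en, pay_reg) >= 1L
    flank_cov <- region_overlap(st, en, reg$flank) >= 1L
    if (pay_cov && arm_cov && !flank_cov && "payload" %in% names(reg))
      aligned$mispriming[r] <- TRUE
    if (aligned$assigned[r] == "itr") {
      aligned$full_length[r] <- arm_cov && pay_cov
      aligned$itr_5nt_match[r] <-
        !is.na(aligned$d_match_run[r]) &&
        aligned$d_match_run[r] >= min_itr_match
      aligned$genomic_beyond_junction[r] <- flank_cov
    }
  }
  aligned$is_itr <- aligned$assigned == "itr" &
    aligned$full_length %in% TRUE &
    aligned$itr_5nt_match %in% TRUE &
    aligned$genomic_beyond_junction %in% TRUE
  aligned
}

#' Remove cross-contaminating reads carrying foreign sample markers
#'
#' @param reads a [read_set()].
#' @param markers named character vector of sample-unique marker
#'   subsequences; reads containing any marker (either strand) are excluded
#'   with reason `contamination`. An empty/NULL marker set passes all reads
#'   through with a warning.
#' @return list with `kept` and `excluded` (data.frame `id`, `reason`,
#'   `marker`).
#' @export
remove_cross_contamination <- function(reads, markers) {
  if (is.null(markers) || length(markers) == 0L) {
    warning("no contamination markers declared; reads passed through")
    return(list(kept = reads,
                excluded = data.frame(id = character(0), reason = character(0),
                                      marker = character(0))))
  }
  hit_marker <- rep(NA_character_, nrow(reads))
  for (nm in names(markers)) {
    m <- markers[[nm]]
    hit <- grepl(m, reads$seq, fixed = TRUE) |
      grepl(revcomp(m), reads$seq, fixed = TRUE)
    hit_marker[hit & is.na(hit_marker)] <- nm
  }
  kept <- reads[is.na(hit_marker), , drop = FALSE]
  class(kept) <- class(reads)
  if (nrow(kept) == 0L)
    warning("all reads removed as cross-contamination")
  list(kept = kept,
       excluded = data.frame(id = reads$id[!is.na(hit_marker)],
                             reason = "contamination",
                             marker = hit_marker[!is.na(hit_marker)],
                             stringsAsFactors = FALSE))
}

#' End-to-end long-read ITR scan
#'
#' Filter, (optionally) decontaminate, align to the three-way reference,
#' apply the ITR criteria, and summarize counts and per-reference coverage.
#'
#' @param reads a [read_set()] of long reads.
#' @param model a [locus_model()].
#' @param side `"left"` or `"right"`.
#' @param markers optional named character vector for
#'   [remove_cross_contamination()]; `NULL` skips decontamination.
#' @param min_accuracy,min_len,max_len read filters
#'   (see [filter_long_reads()]).
#' @return object of class `itr_report`: `per_read` classification table,
#'   `counts` (named vector over final classes and exclusion reasons),
#'   `itr_read_ids`, `coverage` (per-reference depth vectors), `side`.
#' @export
itr_scan <- function(reads, model, side = c("left", "right"), markers = NULL,
                     min_accuracy = 0.90, min_len = 1000L, max_len = 2000L) {
  side <- match.arg(side)
  stopifnot(inherits(model, "locus_model"))
  amp <- build_amplicons(model, side)
  n_input <- nrow(reads)
  flt <- filter_long_reads(reads, min_accuracy, min_len, max_len)
  excluded <- flt$excluded
  kept <- flt$kept
  if (!is.null(markers)) {
    dec <- remove_cross_contamination(kept, markers)
    kept <- dec$kept
    if (nrow(dec$excluded))
      excluded <- rbind(excluded, dec$excluded[, c("id", "reason")])
  }
  if (nrow(kept) == 0L) stop("no reads left after filtering")
  al <- classify_itr(align_three_way(kept, amp), amp)
  final <- al$assigned
  final[al$mispriming] <- "excluded"
  reason <- rep("none", nrow(al))
  reason[al$mispriming] <- "mispriming"
  per_read <- data.frame(id = al$id, final_class = final,
                         exclusion_reason = reason,
                         al[, setdiff(names(al), "id")],
                         stringsAsFactors = FALSE)
  if (nrow(excluded))
    per_read <- rbind(per_read,
                      data.frame(id = excluded$id, final_class = "excluded",
                                 exclusion_reason = excluded$reason,
                                 assigned = NA, top_ref = NA, strand = NA,
                                 ref_start = NA, ref_end = NA,
                                 d_match_run = NA, tie = NA,
                                 score_itr = NA, score_seamless = NA,
                                 score_wt = NA, full_length = NA,
                                 itr_5nt_match = NA,
                                 genomic_beyond_junction = NA,
                                 mispriming = NA, is_itr = FALSE,
                                 stringsAsFactors = FALSE))
  coverage <- lapply(setNames(c("itr", "edited", "wt"),
                              c("itr", "seamless", "wt")), function(a)
                                numeric(nchar(amp[[a]])))
  use <- which(per_read$final_class %in% c("itr", "seamless", "wt"))
  for (r in use) {
    cl <- per_read$final_class[r]
    span <- seq.int(per_read$ref_start[r] + 1L, per_read$ref_end[r])
    coverage[[cl]][span] <- coverage[[cl]][span] + 1
  }
  cls <- factor(per_read$final_class,
                levels = c("itr", "seamless", "wt", "unassigned", "excluded"))
  counts <- c(table(cls),
              n_itr_positive = sum(per_read$is_itr, na.rm = TRUE),
              n_input = n_input)
  structure(list(per_read = per_read, counts = counts,
                 itr_read_ids = per_read$id[per_read$is_itr %in% TRUE],
                 coverage = coverage, side = side),
            class = "itr_report")
}

#' @export
print.itr_report <- function(x, ...) {
  cat("ITR scan (", x$side, " side): ", x$counts[["n_input"]],
      " reads in\n", sep = "")
  for (nm in c("itr", "seamless", "wt", "unassigned", "excluded"))
    cat(sprintf("  %-11s %d\n", nm, x$counts[[nm]]))
  cat("  ITR-positive (all criteria):", x$counts[["n_itr_positive"]], "\n")
  reasons <- table(x$per_read$exclusion_reason[
    x$per_read$final_class == "excluded"])
  if (length(reasons))
    cat("  exclusions:",
        paste(names(reasons), reasons, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
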