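## Low-frequency variant detection across the homology arms: Q30 pileup with
## depth/frequency filters, the two-replicate de novo criteria, and the
## limit-of-detection panel evaluation used to characterize the caller.

#' Pileup of placed reads along an amplicon
#'
#' Accumulates per-position base counts (base quality >= `min_bq`), deletion
#' counts and insertion events from a set of read placements.
#'
#' @param placements an [align_short_reads()] result.
#' @param min_bq minimum base quality for a base to count.
#' @return object of class `amplicon_pileup`: `counts` (4 x L matrix, rows
#'   A/C/G/T), `del` (per-position deletion counts), `ins` (data.frame of
#'   insertion events), `depth` (filtered depth per position), `ref`,
#'   `amplicon_id`.
#' @export
pileup_reads <- function(placements, min_bq = 30L) {
  stopifnot(inherits(placements, "read_placements"))
  if (nrow(placements) == 0L) stop("empty pileup: no placed reads")
  ref <- attr(placements, "amplicon")
  acc <- cpp_pileup_acc(nchar(ref), placements$seq, placements$qual,
                        placements$pos, placements$cigar,
                        min_bq = as.integer(min_bq))
  counts <- acc$counts
  rownames(counts) <- DNA_BASES
  ins <- data.frame(pos = acc$ins_pos, seq = acc$ins_seq,
                    count = acc$ins_count, stringsAsFactors = FALSE)
  structure(list(counts = counts, del = acc$del, ins = ins,
                 depth = colSums(counts) + acc$del,
                 ref = ref, amplicon_id = attr(placements, "amplicon_id")),
            class = "amplicon_pileup")
}

#' @export
print.amplicon_pileup <- function(x, ...) {
  cat("Pileup on", x$amplicon_id, ":", length(x$depth), "positions, median",
      "depth", stats::median(x$depth), "\n")
  invisible(x)
}

#' Call variants from a pileup
#'
#' Emits SNVs (and simple indels) with frequency >= `min_vf` at positions
#' with filtered depth >= `min_depth`; everything else is suppressed. The
#' default filters are frequency 0.0005, base quality 30 and depth 200.
#' Positions within `edge_mask` bases of the amplicon ends are masked
#' against alignment edge artifacts.
#'
#' @param pileup an [pileup_reads()] result, or an [align_short_reads()]
#'   result (piled up with `min_bq`).
#' @param min_bq minimum base quality (applied when `pileup` is placements).
#' @param min_depth minimum filtered depth for a callable position.
#' @param min_vf minimum variant frequency.
#' @param edge_mask bases masked at each amplicon end.
#' @return a `variant_table` data.frame: `amplicon_id`, `pos` (0-based),
#'   `type` (`snv`/`ins`/`del`), `ref`, `alt`, `depth`, `alt_count`,
#'   `frequency`, `filter`.
#' @export
pileup_variants <- function(pileup, min_bq = 30L, min_depth = 200L,
                            min_vf = 0.0005, edge_mask = 12L) {
  if (inherits(pileup, "read_placements"))
    pileup <- pileup_reads(pileup, min_bq = min_bq)
  stopifnot(inherits(pileup, "amplicon_pileup"))
  L <- length(pileup$depth)
  refch <- strsplit(pileup$ref, "", fixed = TRUE)[[1]]
  depth <- pileup$depth
  callable <- depth >= min_depth
  if (edge_mask > 0L) {
    edge <- c(seq_len(min(edge_mask, L)),
              seq.int(max(1L, L - edge_mask + 1L), L))
    callable[edge] <- FALSE
  }
  rows <- list()
  for (b in DNA_BASES) {
    cnt <- pileup$counts[b, ]
    is_alt <- refch != b & callable & cnt > 0 & cnt / depth >= min_vf
    if (any(is_alt)) {
      p <- which(is_alt)
      rows[[b]] <- data.frame(
        amplicon_id = pileup$amplicon_id, pos = p - 1L, type = "snv",
        ref = refch[p], alt = b, depth = depth[p], alt_count = cnt[p],
        frequency = cnt[p] / depth[p], filter = "PASS",
        stringsAsFactors = FALSE)
    }
  }
  isdel <- pileup$del > 0 & callable & pileup$del / depth >= min_vf
  if (any(isdel)) {
    p <- which(isdel)
    rows$del <- data.frame(
      amplicon_id = pileup$amplicon_id, pos = p - 1L, type = "del",
      ref = refch[p], alt = "-", depth = depth[p],
      alt_count = pileup$del[p], frequency = pileup$del[p] / depth[p],
      filter = "PASS", stringsAsFactors = FALSE)
  }
  if (nrow(pileup$ins)) {
    ip <- pileup$ins
    ok <- ip$pos > edge_mask & ip$pos < L - edge_mask &
      depth[pmin(ip$pos + 1L, L)] >= min_depth &
      ip$count / depth[pmin(ip$pos + 1L, L)] >= min_vf
    if (any(ok)) {
      ip <- ip[ok, , drop = FALSE]
      rows$ins <- data.frame(
        amplicon_id = pileup$amplicon_id, pos = ip$pos, type = "ins",
        ref = refch[pmin(ip$pos + 1L, L)], alt = ip$seq,
        depth = depth[pmin(ip$pos + 1L, L)], alt_count = ip$count,
        frequency = ip$count / depth[pmin(ip$pos + 1L, L)],
        filter = "PASS", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(amplicon_id = character(0), pos = integer(0),
               type = character(0), ref = character(0), alt = character(0),
               depth = integer(0), alt_count = integer(0),
               frequency = numeric(0), filter = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  attr(out, "amplicon_id") <- pileup$amplicon_id
  attr(out, "ref_len") <- L
  out
}

#' One-stop variant pipeline for an amplicon read set
#'
#' Quality-filters reads (mean Q30), aligns them to the amplicon, piles up
#' and calls variants with the standard filters.
#'
#' @param reads a [read_set()].
#' @param amplicon reference sequence.
#' @param amplicon_id reference name.
#' @param min_mean_q read-level mean quality filter.
#' @param ... passed to [pileup_variants()].
#' @return a `variant_table`.
#' @export
variant_pipeline <- function(reads, amplicon, amplicon_id = "amplicon",
                             min_mean_q = 30, ...) {
  reads <- filter_reads_meanq(reads, min_mean_q)
  pl <- align_short_reads(reads, amplicon, amplicon_id)
  pileup_variants(pl, ...)
}

variant_key <- function(v) paste(v$pos, v$type, v$alt, sep = ":")

lookup_freq <- function(tab, keys) {
  m <- match(keys, variant_key(tab))
  f <- ifelse(is.na(m), 0, tab$frequency[m])
  f
}

#' Call de novo variants from technical replicates against WT alleles
#'
#' A variant is de novo when it (a) exceeds the reporting threshold and
#' passed the pileup filters, (b) appears above threshold in both technical
#' replicates, and (c) is not observed (frequency below threshold) in the
#' WT alleles. Every candidate present in either replicate receives a
#' verdict with a reason code.
#'
#' @param rep1,rep2 `variant_table`s of the two technical replicates.
#' @param wt `variant_table` of the WT-allele sample.
#' @param threshold reporting threshold (default 0.005, i.e. 0.5%).
#' @return object of class `de_novo_report`: `candidates` data.frame with
#'   per-replicate and WT frequencies and `verdict` in
#'   `{below_threshold, single_replicate, present_in_wt, de_novo}`,
#'   plus `n_de_novo`.
#' @export
call_de_novo <- function(rep1, rep2, wt, threshold = 0.005) {
  ids <- c(attr(rep1, "amplicon_id"), attr(rep2, "amplicon_id"),
           attr(wt, "amplicon_id"))
  if (length(unique(ids)) != 1L)
    stop("variant tables come from different amplicons: ",
         paste(unique(ids), collapse = ", "))
  keys <- unique(c(variant_key(rep1), variant_key(rep2)))
  src <- rbind(as.data.frame(rep1), as.data.frame(rep2))
  m <- match(keys, variant_key(src))
  cand <- data.frame(amplicon_id = ids[1],
                     pos = src$pos[m], type = src$type[m],
                     ref = src$ref[m], alt = src$alt[m],
                     stringsAsFactors = FALSE)
  cand$rep1_af <- lookup_freq(rep1, keys)
  cand$rep2_af <- lookup_freq(rep2, keys)
  cand$wt_af <- lookup_freq(wt, keys)
  hi <- pmax(cand$rep1_af, cand$rep2_af)
  lo <- pmin(cand$rep1_af, cand$rep2_af)
  cand$verdict <- ifelse(hi <= threshold, "below_threshold",
                  ifelse(lo <= threshold, "single_replicate",
                  ifelse(cand$wt_af > threshold, "present_in_wt",
                         "de_novo")))
  cand$mean_af <- (cand$rep1_af + cand$rep2_af) / 2
  cand <- cand[order(cand$pos), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(candidates = cand,
                 n_de_novo = sum(cand$verdict == "de_novo"),
                 threshold = threshold),
            class = "de_novo_report")
}

#' @export
print.de_novo_report <- function(x, ...) {
  cat("De novo variant report (threshold ",
      100 * x$threshold, "%)\n", sep = "")
  tab <- table(x$candidates$verdict)
  for (nm in names(tab)) cat(sprintf("  %-18s %d\n", nm, tab[[nm]]))
  if (x$n_de_novo == 0) cat("  no de novo variants detected\n")
  invisible(x)
}

#' Evaluate a variant caller on a limit-of-detection panel
#'
#' Computes sensitivity and precision at the reporting threshold and the
#' log-log linear fit of observed versus expected frequency over the nonzero
#' panel levels (detection down to the pileup `min_vf` counts toward the
#' regression; reporting uses `threshold`).
#'
#' @param calls_per_level list of `variant_table`s, one per panel member.
#' @param truth data.frame with one row per panel member: `expected_vaf`,
#'   `pos` (0-based), `alt` (NA alt/pos allowed for the 0% member).
#' @param threshold reporting threshold for sensitivity/precision.
#' @return object of class `panel_evaluation`: per-level table, sensitivity,
#'   precision, and `slope`/`intercept`/`r_squared` of the log10-log10 fit.
#' @export
evaluate_panel <- function(calls_per_level, truth, threshold = 0.005) {
  stopifnot(length(calls_per_level) == nrow(truth))
  obs <- numeric(nrow(truth))
  n_fp <- 0L
  for (i in seq_len(nrow(truth))) {
    tab <- calls_per_level[[i]]
    if (!is.na(truth$pos[i])) {
      key <- paste(truth$pos[i], "snv", truth$alt[i], sep = ":")
      obs[i] <- lookup_freq(tab, key)
      fp <- tab$frequency >= threshold &
        !(tab$pos == truth$pos[i] & tab$alt == truth$alt[i])
    } else {
      obs[i] <- NA_real_
      fp <- tab$frequency >= threshold
    }
    n_fp <- n_fp + sum(fp)
  }
  detectable <- !is.na(truth$pos) & truth$expected_vaf >= threshold
  detected <- detectable & obs >= threshold
  sensitivity <- if (any(detectable)) sum(detected) / sum(detectable) else NA
  n_tp <- sum(detected)
  precision <- if (n_tp + n_fp > 0) n_tp / (n_tp + n_fp) else NA
  nz <- !is.na(truth$pos) & truth$expected_vaf > 0 & obs > 0
  slope <- intercept <- r2 <- NA_real_
  if (sum(nz) >= 2L) {
    fit <- lm(log10(obs[nz]) ~ log10(truth$expected_vaf[nz]))
    slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
    r2 <- suppressWarnings(summary(fit)$r.squared)
  }
  levels_tab <- data.frame(expected_vaf = truth$expected_vaf,
                           observed_vaf = obs,
                           detected = !is.na(obs) & obs >= threshold)
  structure(list(levels = levels_tab, sensitivity = sensitivity,
                 precision = precision, n_false_positive = n_fp,
                 slope = slope, intercept = intercept, r_squared = r2,
                 threshold = threshold),
            class = "panel_evaluation")
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat("LoD panel evaluation (threshold ", 100 * x$threshold, "%)\n", sep = "")
  cat(sprintf("  sensitivity %.3f  precision %.3f  (false positives: %d)\n",
              x$sensitivity, x$precision, x$n_false_positive))
  cat(sprintf("  log-log fit: slope %.3f  intercept %.3f  R-squared %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}
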