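## Integration frequency from 3-primer amplicon reads: count genotype
## junction k-mers, fit the dilution-panel standard curve, apply the linear
## correction.

#' Filter reads by mean base quality
#'
#' Reads with mean Phred quality below `min_q` are removed (the Q30 read
#' filter applied before any counting or pileup).
#'
#' @param reads a [read_set()].
#' @param min_q minimum mean Phred quality.
#' @return filtered [read_set()].
#' @export
filter_reads_meanq <- function(reads, min_q = 30) {
  keep <- mean_qual(reads$qual) >= min_q
  out <- reads[keep, , drop = FALSE]
  class(out) <- class(reads)
  out
}

#' Count genotype junction k-mers in a read set
#'
#' A fragment (read pair, or single read) containing the WT junction k-mer on
#' either strand counts as unedited; the edited junction k-mer counts as
#' edited; neither k-mer is uninformative. A fragment matching both k-mers
#' (or a discordant pair) is counted uninformative and tallied separately.
#'
#' @param reads a [read_set()] (quality-filtered; see
#'   [filter_reads_meanq()]).
#' @param model a [locus_model()].
#' @param side `"left"` or `"right"`.
#' @return object of class `junction_counts` with fields `n_edited`, `n_wt`,
#'   `n_uninformative`, `n_conflicting`, `side`.
#' @export
count_junctions <- function(reads, model, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(model, "locus_model"))
  if (is.null(reads) || nrow(reads) == 0L) stop("empty read set")
  jk <- junction_kmers(model)
  k_wt <- jk[[paste0(side, "_wt")]]
  k_ed <- jk[[paste0(side, "_edited")]]
  hit_wt <- grepl(k_wt, reads$seq, fixed = TRUE) |
    grepl(revcomp(k_wt), reads$seq, fixed = TRUE)
  hit_ed <- grepl(k_ed, reads$seq, fixed = TRUE) |
    grepl(revcomp(k_ed), reads$seq, fixed = TRUE)
  pid <- reads$pair_id
  wt_frag <- rowsum(as.integer(hit_wt), pid) > 0L
  ed_frag <- rowsum(as.integer(hit_ed), pid) > 0L
  both <- wt_frag & ed_frag
  n_conflicting <- sum(both)
  structure(list(n_edited = sum(ed_frag & !both),
                 n_wt = sum(wt_frag & !both),
                 n_uninformative = sum(!wt_frag & !ed_frag) + n_conflicting,
                 n_conflicting = n_conflicting,
                 side = side),
            class = "junction_counts")
}

#' @export
print.junction_counts <- function(x, ...) {
  cat("Junction counts (", x$side, " side)\n", sep = "")
  cat(sprintf("  edited: %d  WT: %d  uninformative: %d (of which conflicting: %d)\n",
              x$n_edited, x$n_wt, x$n_uninformative, x$n_conflicting))
  if (x$n_edited + x$n_wt > 0)
    cat(sprintf("  observed: %.4g%%\n", observed_fraction(x)))
  invisible(x)
}

#' Observed integration percentage
#'
#' `100 * n_edited / (n_edited + n_wt)`: the denominator is restricted to
#' junction-informative fragments, since fragments spanning neither junction
#' cannot be assigned a genotype.
#'
#' @param counts a `junction_counts` object (or list with `n_edited`,
#'   `n_wt`).
#' @return observed integration percentage.
#' @export
observed_fraction <- function(counts) {
  tot <- counts$n_edited + counts$n_wt
  if (is.na(tot) || tot <= 0) stop("no junction-informative reads")
  100 * counts$n_edited / tot
}

#' Fit the standard-curve correction model
#'
#' Ordinary least squares of observed on expected integration percentages
#' over the dilution panel, with R-squared and the Pearson correlation
#' p-value.
#'
#' @param observed_percents observed percentages per panel level.
#' @param expected_percents expected (mixed-in) percentages.
#' @return object of class `correction_model` with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `levels_used` and a `usable` flag
#'   (slope > 0).
#' @export
fit_panel_curve <- function(observed_percents, expected_percents) {
  if (length(observed_percents) != length(expected_percents))
    stop("observed and expected must have equal length")
  if (length(expected_percents) < 3L)
    stop("at least 3 panel levels are required")
  if (stats::var(expected_percents) == 0)
    stop("expected percentages have zero variance")
  fit <- lm(observed_percents ~ expected_percents)
  ct <- suppressWarnings(cor.test(observed_percents, expected_percents))
  slope <- unname(coef(fit)[2])
  ## summary.lm warns on an exactly collinear (noise-free) panel
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 p_value = ct$p.value,
                 levels_used = expected_percents,
                 usable = is.finite(slope) && slope > 0),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("Standard-curve correction: observed = %.4g * expected %+.4g\n",
              x$slope, x$intercept))
  cat(sprintf("  R-squared %.4f, Pearson p-value %.3g, %d levels%s\n",
              x$r_squared, x$p_value, length(x$levels_used),
              if (x$usable) "" else "  [UNUSABLE: slope <= 0]"))
  invisible(x)
}

#' Apply the standard-curve correction
#'
#' Inverts the fitted line: `corrected = (observed - intercept) / slope`.
#' Corrected values below zero are returned as-is with a `below_noise`
#' attribute set, signalling a sample at or under the assay noise floor.
#'
#' @param corr_model a [fit_panel_curve()] result.
#' @param observed_percent observed percentage(s).
#' @return numeric corrected percentage(s) with logical attribute
#'   `below_noise`.
#' @export
apply_correction <- function(corr_model, observed_percent) {
  stopifnot(inherits(corr_model, "correction_model"))
  if (!corr_model$usable || corr_model$slope <= 0)
    stop("correction model has non-positive slope")
  corrected <- (observed_percent - corr_model$intercept) / corr_model$slope
  attr(corrected, "below_noise") <- corrected < 0
  corrected
}

#' End-to-end junction quantification
#'
#' Quality-filters sample and panel read sets, counts junction k-mers, fits
#' the panel standard curve and corrects the sample estimate.
#'
#' @param sample_reads a [read_set()] for the test sample.
#' @param panel a named list of [read_set()]s as produced by
#'   [simulate_control_panel()] (each with an `expected_percent` attribute),
#'   or `NULL` to skip correction.
#' @param model a [locus_model()].
#' @param side `"left"` or `"right"`.
#' @param min_mean_q mean-quality read filter.
#' @return list with `counts`, `observed`, `panel_curve`, `corrected`,
#'   `below_noise` and a one-row `report` data.frame.
#' @export
quantify_junctions <- function(sample_reads, panel = NULL, model,
                               side = c("left", "right"), min_mean_q = 30) {
  side <- match.arg(side)
  counts <- count_junctions(filter_reads_meanq(sample_reads, min_mean_q),
                            model, side)
  obs <- observed_fraction(counts)
  curve <- NULL; corrected <- NA_real_; below <- NA
  if (!is.null(panel)) {
    pc <- vapply(panel, function(rs)
      observed_fraction(count_junctions(filter_reads_meanq(rs, min_mean_q),
                                        model, side)), numeric(1))
    exp_pc <- vapply(panel, function(rs)
      attr(rs, "expected_percent"), numeric(1))
    curve <- fit_panel_curve(pc, exp_pc)
    corr <- apply_correction(curve, obs)
    corrected <- as.numeric(corr)
    below <- attr(corr, "below_noise")
  }
  report <- data.frame(side = side, n_edited = counts$n_edited,
                       n_wt = counts$n_wt,
                       n_uninformative = counts$n_uninformative,
                       observed_percent = obs,
                       corrected_percent = corrected,
                       below_noise = below)
  list(counts = counts, observed = obs, panel_curve = curve,
       corrected = corrected, below_noise = below, report = report)
}
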