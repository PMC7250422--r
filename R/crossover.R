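## Localizing homologous-recombination crossovers: inherited heterozygous
## SNPs sit at ~50% frequency in the WT alleles; in integrated alleles each
## donor variant is "corrected" to the vector (reference) base whenever the
## crossover fell beyond it, so its depletion as a function of distance to
## the payload traces where crossovers occur.

#' Per-SNP correction frequencies from WT and integrated variant tables
#'
#' For each annotated SNP, the correction frequency is
#' `1 - vaf_integrated / vaf_wt`, normalizing by the measured WT frequency so
#' donor allele-balance noise cancels. Values are clipped to `[0, 1]` with a
#' flag. SNPs with `vaf_wt` below 10% are excluded with a warning (not
#' credibly heterozygous); a SNP absent from both tables is an error.
#'
#' @param wt_variants,integrated_variants `variant_table`s (see
#'   [pileup_variants()]) for the WT-allele and integrated-allele samples of
#'   one homology arm.
#' @param snps SNP annotation data.frame (`arm`, `offset`, `ref`, `alt`,
#'   `haplotype`) for the corresponding arm.
#' @param arm_len homology arm length (to map offsets to positions).
#' @return object of class `crossover_profile`: one row per retained SNP
#'   with `offset`, `pos`, `haplotype`, `vaf_wt`, `vaf_integrated`,
#'   `correction`, `clipped`, depths.
#' @export
correction_frequencies <- function(wt_variants, integrated_variants, snps,
                                   arm_len) {
  stopifnot(nrow(snps) > 0L)
  pos <- snp_arm_index(snps$offset, snps$arm, arm_len)
  keys <- paste(pos, "snv", snps$alt, sep = ":")
  in_wt <- keys %in% variant_key(wt_variants)
  in_int <- keys %in% variant_key(integrated_variants)
  if (any(!in_wt & !in_int))
    stop("SNP position(s) absent from both variant tables: ",
         paste(pos[!in_wt & !in_int], collapse = ", "))
  vaf_wt <- lookup_freq(wt_variants, keys)
  vaf_int <- lookup_freq(integrated_variants, keys)
  dget <- function(tab, keys) {
    m <- match(keys, variant_key(tab))
    ifelse(is.na(m), NA_integer_, tab$depth[m])
  }
  prof <- data.frame(offset = snps$offset, pos = pos,
                     haplotype = snps$haplotype,
                     vaf_wt = vaf_wt, vaf_integrated = vaf_int,
                     depth_wt = dget(wt_variants, keys),
                     depth_integrated = dget(integrated_variants, keys),
                     stringsAsFactors = FALSE)
  weak <- prof$vaf_wt < 0.10
  if (any(weak)) {
    warning("excluding ", sum(weak),
            " SNP(s) with WT frequency < 10% (not heterozygous): offsets ",
            paste(prof$offset[weak], collapse = ", "))
    prof <- prof[!weak, , drop = FALSE]
  }
  raw <- 1 - prof$vaf_integrated / prof$vaf_wt
  prof$correction <- pmin(1, pmax(0, raw))
  prof$clipped <- raw < 0 | raw > 1
  prof <- prof[order(prof$offset), , drop = FALSE]
  rownames(prof) <- NULL
  class(prof) <- c("crossover_profile", "data.frame")
  attr(prof, "arm_len") <- arm_len
  prof
}

#' Fit the linear correction-versus-distance trend
#'
#' Ordinary least squares of correction frequency on SNP offset (distance to
#' the first payload base), overall and per haplotype where at least two
#' SNPs are available. Under uniform crossovers over an arm of length L the
#' expected line is `correction = 1 - offset / L` (slope `-1/L`).
#'
#' @param profile a [correction_frequencies()] result.
#' @return object of class `trend_fit` with `slope`, `intercept`,
#'   `r_squared` and `by_haplotype` subgroup fits.
#' @export
fit_trend <- function(profile) {
  stopifnot(inherits(profile, "crossover_profile"))
  if (nrow(profile) < 2L) stop("at least 2 SNPs are required for a trend fit")
  fit <- lm(correction ~ offset, data = profile)
  sub <- lapply(split(profile, profile$haplotype), function(p) {
    if (nrow(p) < 2L) return(NULL)
    f <- lm(correction ~ offset, data = p)
    list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
         r_squared = suppressWarnings(summary(f)$r.squared), n = nrow(p))
  })
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n = nrow(profile),
                 by_haplotype = Filter(Negate(is.null), sub)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Crossover trend: correction = %.4g %+.3g * offset (R-squared %.3f, n=%d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  for (h in names(x$by_haplotype)) {
    s <- x$by_haplotype[[h]]
    cat(sprintf("  haplotype %s: slope %+.3g, R-squared %.3f (n=%d)\n",
                h, s$slope, s$r_squared, s$n))
  }
  invisible(x)
}

#' Test for haplotype (allele) specificity of integration
#'
#' The retention of a donor variant in integrated alleles,
#' `vaf_integrated / vaf_wt`, is proportional to the rate at which its
#' haplotype is used for integration. The haplotype with the most SNPs
#' serves as baseline: its retention-versus-offset line predicts the
#' retention expected at the other haplotype's offsets under equal usage,
#' and the mean observed/predicted ratio estimates the relative integration
#' rate. A parametric bootstrap over read counts gives a confidence
#' interval; an interval containing 1 is reported as no detectable
#' specificity.
#'
#' @param profile a [correction_frequencies()] result covering at least two
#'   haplotypes.
#' @param bootstrap bootstrap replicates.
#' @param conf confidence level.
#' @param seed optional RNG seed.
#' @return object of class `allele_specificity`: `ratio` (target versus
#'   baseline haplotype integration rate), `ci`, `haplotypes`,
#'   `no_detectable_specificity`.
#' @export
allele_specificity <- function(profile, bootstrap = 1000L, conf = 0.95,
                               seed = NULL) {
  stopifnot(inherits(profile, "crossover_profile"))
  haps <- sort(unique(profile$haplotype))
  if (length(haps) < 2L)
    stop("allele specificity needs SNPs on at least two haplotypes")
  nh <- table(profile$haplotype)
  base_h <- as.integer(names(nh)[which.max(nh)])
  targ_h <- setdiff(haps, base_h)[1]
  ratio_fun <- function(p) {
    p$retention <- p$vaf_integrated / p$vaf_wt
    b <- p[p$haplotype == base_h, , drop = FALSE]
    t <- p[p$haplotype == targ_h, , drop = FALSE]
    pred <- if (nrow(b) >= 2L) {
      f <- lm(retention ~ offset, data = b)
      pmax(1e-9, predict(f, newdata = t))
    } else rep(mean(b$retention), nrow(t))
    mean(t$retention / pred)
  }
  est <- ratio_fun(profile)
  ci <- with_opt_seed(seed, {
    reps <- vapply(seq_len(bootstrap), function(i) {
      p <- profile
      ok <- !is.na(p$depth_wt) & !is.na(p$depth_integrated)
      p$vaf_wt[ok] <- rbinom(sum(ok), p$depth_wt[ok], p$vaf_wt[ok]) /
        p$depth_wt[ok]
      p$vaf_integrated[ok] <- rbinom(sum(ok), p$depth_integrated[ok],
                                     p$vaf_integrated[ok]) /
        p$depth_integrated[ok]
      p$vaf_wt <- pmax(p$vaf_wt, 1e-9)
      ratio_fun(p)
    }, numeric(1))
    a <- (1 - conf) / 2
    quantile(reps, c(a, 1 - a), na.rm = TRUE)
  })
  structure(list(ratio = est, ci = unname(ci), conf = conf,
                 baseline_haplotype = base_h, target_haplotype = targ_h,
                 no_detectable_specificity = ci[1] <= 1 && ci[2] >= 1),
            class = "allele_specificity")
}

#' @export
print.allele_specificity <- function(x, ...) {
  cat(sprintf("Allele specificity: haplotype %d vs %d integration-rate ratio %.3g (%d%% CI %.3g-%.3g)\n",
              x$target_haplotype, x$baseline_haplotype, x$ratio,
              round(100 * x$conf), x$ci[1], x$ci[2]))
  cat(if (x$no_detectable_specificity)
    "  no detectable allele specificity (CI contains 1)\n"
    else "  allele usage differs from parity\n")
  invisible(x)
}

#' Hotspot diagnostic: largest jump between adjacent SNPs
#'
#' A crossover hotspot between two adjacent SNPs would show as a sharp drop
#' in correction frequency. This diagnostic compares the maximum adjacent
#' jump against a bootstrap null in which corrections follow the fitted
#' linear trend with binomial counting noise.
#'
#' @param profile a [correction_frequencies()] result (>= 3 SNPs).
#' @param bootstrap bootstrap replicates.
#' @param seed optional RNG seed.
#' @return list with `max_jump`, the flanking offsets, and `p_value`.
#' @export
hotspot_test <- function(profile, bootstrap = 1000L, seed = NULL) {
  stopifnot(inherits(profile, "crossover_profile"), nrow(profile) >= 3L)
  p <- profile[order(profile$offset), , drop = FALSE]
  jumps <- abs(diff(p$correction))
  jmax <- max(jumps)
  at <- which.max(jumps)
  fit <- lm(correction ~ offset, data = p)
  mu <- pmin(1, pmax(0, predict(fit)))
  depth <- ifelse(is.na(p$depth_integrated), 1e4, p$depth_integrated)
  null_max <- with_opt_seed(seed, {
    vapply(seq_len(bootstrap), function(i) {
      ## retention noise propagated through the correction estimate
      ret <- rbinom(nrow(p), depth, pmax(1e-9, (1 - mu) * p$vaf_wt)) / depth
      cc <- pmin(1, pmax(0, 1 - ret / p$vaf_wt))
      max(abs(diff(cc)))
    }, numeric(1))
  })
  list(max_jump = jmax,
       between_offsets = c(p$offset[at], p$offset[at + 1L]),
       p_value = mean(null_max >= jmax))
}
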