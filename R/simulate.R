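## Seeded simulators for every input class the analysis pipelines consume:
## short paired-end amplicon reads (3-primer junction assay and deep arm
## resequencing), dilution-series control panels, Nanopore-like long reads
## with optional ITR remnants, and ddPCR droplet tables.

#' Parameters for short paired-end read simulation
#'
#' @param n_pairs number of read pairs.
#' @param read_len read length per mate (default 75 nt).
#' @param integrated_fraction proportion of fragments drawn from the edited
#'   (integrated) amplicon.
#' @param per_base_error substitution probability per base, modelling the
#'   residual error after quality filtering.
#' @param quality constant Phred quality emitted for every base.
#' @param frag_len fragment length (default two read lengths, so mates tile
#'   the fragment without overlap).
#' @param junction_span_frac fraction of fragments placed so that one mate
#'   fully contains the genotype junction k-mer.
#' @param crossover_model `"uniform"` (crossover distance uniform over the
#'   arm), `"none"` (integrated arms carry the vector/reference sequence
#'   throughout), or a function `f(n, L)` returning `n` crossover distances
#'   in `[0, L]`.
#' @param haplotype_fractions optional named numeric of donor haplotype
#'   proportions (default: equal).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a `short_read_params` list.
#' @export
short_read_params <- function(n_pairs, read_len = 75L,
                              integrated_fraction = 0,
                              per_base_error = 0.001,
                              quality = 37L,
                              frag_len = 2L * read_len,
                              junction_span_frac = 0.5,
                              crossover_model = "uniform",
                              haplotype_fractions = NULL,
                              seed = NULL) {
  stopifnot(n_pairs >= 1, read_len >= 20,
            integrated_fraction >= 0, integrated_fraction <= 1,
            per_base_error >= 0, per_base_error <= 1,
            junction_span_frac >= 0, junction_span_frac <= 1,
            frag_len >= read_len)
  structure(list(n_pairs = as.integer(n_pairs), read_len = as.integer(read_len),
                 integrated_fraction = integrated_fraction,
                 per_base_error = per_base_error, quality = as.integer(quality),
                 frag_len = as.integer(frag_len),
                 junction_span_frac = junction_span_frac,
                 crossover_model = crossover_model,
                 haplotype_fractions = haplotype_fractions,
                 seed = seed),
            class = "short_read_params")
}

with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

## substitute donor (alt) bases into an amplicon at the arm SNP positions
## of one haplotype; `arm_start` is the arm's 0-based offset in the amplicon
apply_snp_alts <- function(seq, snps, arm_len, arm_start) {
  if (nrow(snps) == 0L) return(seq)
  idx <- snp_arm_index(snps$offset, snps$arm, arm_len) + arm_start
  for (i in seq_len(nrow(snps)))
    substr(seq, idx[i] + 1L, idx[i] + 1L) <- snps$alt[i]
  seq
}

side_snps <- function(model, side) {
  model$snps[model$snps$arm == side, , drop = FALSE]
}

crossover_sampler <- function(crossover_model) {
  if (is.function(crossover_model)) return(crossover_model)
  switch(crossover_model,
         uniform = function(n, L) runif(n, 0, L),
         none = function(n, L) rep(L + 1, n), # beyond every SNP: all corrected
         stop("unknown crossover model: ", crossover_model))
}

## Build the distinct template sequences for one side.
## WT templates: one per haplotype (donor alts applied to the WT amplicon).
## Edited templates: per haplotype, one per "number of payload-proximal SNPs
## corrected" (crossover distance falls between consecutive SNP offsets).
build_side_templates <- function(model, side, amp) {
  arm_len <- nchar(if (side == "left") model$left_arm else model$right_arm)
  snps <- side_snps(model, side)
  haps <- if (nrow(snps)) sort(unique(snps$haplotype)) else 1L
  wt_arm_start <- amp$regions$wt$arm["start"]
  ed_arm_start <- amp$regions$edited$arm["start"]
  wt_tpl <- lapply(haps, function(h)
    apply_snp_alts(amp$wt, snps[snps$haplotype == h, , drop = FALSE],
                   arm_len, wt_arm_start))
  names(wt_tpl) <- paste0("wt_h", haps)
  ed_tpl <- list()
  offsets <- lapply(haps, function(h)
    sort(snps$offset[snps$haplotype == h]))
  names(offsets) <- haps
  for (h in haps) {
    offs <- offsets[[as.character(h)]]
    hs <- snps[snps$haplotype == h, , drop = FALSE]
    hs <- hs[order(hs$offset), , drop = FALSE]
    for (corrected in 0:length(offs)) {
      retained <- if (corrected < nrow(hs))
        hs[seq.int(corrected + 1L, nrow(hs)), , drop = FALSE]
      else hs[0, , drop = FALSE]
      ed_tpl[[paste0("ed_h", h, "_c", corrected)]] <-
        apply_snp_alts(amp$edited, retained, arm_len, ed_arm_start)
    }
  }
  list(haps = haps, offsets = offsets, wt = wt_tpl, edited = ed_tpl,
       arm_len = arm_len)
}

## junction position (0-based boundary between arm and genotype-specific
## sequence) in the WT / edited amplicon of one side
junction_pos <- function(amp, which = c("wt", "edited")) {
  which <- match.arg(which)
  r <- amp$regions[[which]]
  if (amp$side == "left") unname(r$arm["end"]) else unname(r$arm["start"])
}

## Sample fragment starts; a `span` fragment places the full junction k-mer
## inside one mate.
sample_starts <- function(n, tpl_len, frag, read_len, j0, half_k, span) {
  max_start <- tpl_len - frag
  if (max_start < 0L) stop("fragment length exceeds amplicon length")
  out <- integer(n)
  plain <- !span
  out[plain] <- sample.int(max_start + 1L, sum(plain), replace = TRUE) - 1L
  if (any(span)) {
    ## mate 1 covers [s, s+read_len); mate 2 covers [s+frag-read_len, s+frag)
    iv1 <- c(j0 + half_k - read_len, j0 - half_k)
    iv2 <- c(j0 + half_k - frag, j0 - half_k - frag + read_len)
    cand <- unique(c(seq2(iv1[1], iv1[2]), seq2(iv2[1], iv2[2])))
    cand <- cand[cand >= 0L & cand <= max_start]
    if (length(cand) == 0L) cand <- 0:max_start
    out[span] <- cand[sample.int(length(cand), sum(span), replace = TRUE)]
  }
  out
}

seq2 <- function(a, b) if (b < a) integer(0) else seq.int(a, b)

## vectorized substitution-error injection
inject_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }
  seqs
}

#' Simulate short paired-end 3-primer amplicon reads
#'
#' Each fragment is drawn from the WT or edited amplicon with probability
#' `1 - integrated_fraction` / `integrated_fraction`. For edited fragments a
#' donor haplotype and a crossover distance are sampled; donor SNP bases
#' closer to the payload than the crossover are "corrected" to the vector
#' (reference) base, the rest retain the donor allele. Substitution errors
#' are injected at `per_base_error`. Deterministic given `params$seed`.
#'
#' @param model a [locus_model()].
#' @param side `"left"` or `"right"`.
#' @param params a [short_read_params()].
#' @return a [read_set()] with two rows per pair and a `truth` column
#'   (`"wt"`/`"edited"` per fragment).
#' @export
simulate_short_reads <- function(model, side = c("left", "right"), params) {
  side <- match.arg(side)
  stopifnot(inherits(model, "locus_model"),
            inherits(params, "short_read_params"))
  amp <- build_amplicons(model, side)
  if (params$read_len > min(nchar(amp$wt), nchar(amp$edited)))
    stop("read_len exceeds amplicon length")
  with_opt_seed(params$seed, {
    tset <- build_side_templates(model, side, amp)
    n <- params$n_pairs
    edited <- runif(n) < params$integrated_fraction
    hf <- params$haplotype_fractions %||%
      setNames(rep(1 / length(tset$haps), length(tset$haps)),
               tset$haps)
    hf <- hf / sum(hf)
    hap <- tset$haps[sample.int(length(tset$haps), n, replace = TRUE,
                                prob = hf[as.character(tset$haps)])]
    sampler <- crossover_sampler(params$crossover_model)
    keys <- character(n)
    keys[!edited] <- paste0("wt_h", hap[!edited])
    if (any(edited)) {
      L <- tset$arm_len
      X <- sampler(sum(edited), L)
      eh <- hap[edited]
      corrected <- integer(sum(edited))
      for (h in tset$haps) {
        sel <- eh == h
        offs <- tset$offsets[[as.character(h)]]
        corrected[sel] <- if (length(offs))
          findInterval(X[sel], offs) else 0L
      }
      keys[edited] <- paste0("ed_h", eh, "_c", corrected)
    }
    templates <- c(tset$wt, tset$edited)
    tpl <- unlist(templates[keys], use.names = FALSE)
    tpl_len <- nchar(tpl)

    half_k <- model$junction_k %/% 2L
    span <- runif(n) < params$junction_span_frac
    j0 <- ifelse(edited, junction_pos(amp, "edited"), junction_pos(amp, "wt"))
    starts <- integer(n)
    for (grp in split(seq_len(n), paste(edited, tpl_len))) {
      i1 <- grp[1]
      starts[grp] <- sample_starts(length(grp), tpl_len[i1], params$frag_len,
                                   params$read_len, j0[i1], half_k, span[grp])
    }
    r1 <- substring(tpl, starts + 1L, starts + params$read_len)
    r2 <- revcomp(substring(tpl, starts + params$frag_len - params$read_len + 1L,
                            starts + params$frag_len))
    r1 <- inject_substitutions(r1, params$per_base_error)
    r2 <- inject_substitutions(r2, params$per_base_error)
    q <- strrep(phred_char(params$quality), params$read_len)
    truth <- ifelse(edited, "edited", "wt")
    read_set(id = c(sprintf("p%07d/1", seq_len(n)), sprintf("p%07d/2", seq_len(n))),
             seq = c(r1, r2), qual = rep(q, 2L * n),
             pair_id = rep(seq_len(n), 2L), mate = rep(c(1L, 2L), each = n),
             truth = rep(truth, 2L))
  })
}

#' Simulate deep arm-resequencing reads for fidelity and crossover analysis
#'
#' Generates paired reads uniformly tiling one homology arm from either the
#' WT alleles (donor haplotypes at their het SNP positions) or the
#' integrated alleles (donor SNPs partially corrected under the crossover
#' model). Nominal interior coverage is `depth`.
#'
#' @param model a [locus_model()].
#' @param side `"left"` or `"right"`.
#' @param allele `"wt"` or `"integrated"`.
#' @param depth target interior coverage (x-fold).
#' @param params a [short_read_params()]; `n_pairs` and `integrated_fraction`
#'   are ignored (derived from `depth` and `allele`).
#' @param plant optional data.frame (`pos` 0-based arm index, `alt`, `vaf`)
#'   of extra mutations injected per read, for caller benchmarking.
#' @return a [read_set()].
#' @export
simulate_arm_reads <- function(model, side = c("left", "right"),
                               allele = c("wt", "integrated"),
                               depth = 10000, params = short_read_params(1),
                               plant = NULL) {
  side <- match.arg(side)
  allele <- match.arg(allele)
  arm <- if (side == "left") model$left_arm else model$right_arm
  L <- nchar(arm)
  n <- as.integer(round(depth * L / (2 * params$read_len)))
  with_opt_seed(params$seed, {
    snps <- side_snps(model, side)
    haps <- if (nrow(snps)) sort(unique(snps$haplotype)) else 1L
    hf <- params$haplotype_fractions %||%
      setNames(rep(1 / length(haps), length(haps)), haps)
    hf <- hf / sum(hf)
    hap <- haps[sample.int(length(haps), n, replace = TRUE,
                           prob = hf[as.character(haps)])]
    if (allele == "wt") {
      tpls <- lapply(haps, function(h)
        apply_snp_alts(arm, snps[snps$haplotype == h, , drop = FALSE], L, 0L))
      names(tpls) <- as.character(haps)
      keys <- as.character(hap)
    } else {
      sampler <- crossover_sampler(params$crossover_model)
      X <- sampler(n, L)
      keys <- character(n)
      tpls <- list()
      for (h in haps) {
        hs <- snps[snps$haplotype == h, , drop = FALSE]
        hs <- hs[order(hs$offset), , drop = FALSE]
        offs <- hs$offset
        sel <- hap == h
        corrected <- if (length(offs)) findInterval(X[sel], offs) else 0L
        keys[sel] <- paste0(h, "_c", corrected)
        for (cc in 0:length(offs)) {
          retained <- if (cc < nrow(hs))
            hs[seq.int(cc + 1L, nrow(hs)), , drop = FALSE]
          else hs[0, , drop = FALSE]
          tpls[[paste0(h, "_c", cc)]] <- apply_snp_alts(arm, retained, L, 0L)
        }
      }
    }
    tpl <- unlist(tpls[keys], use.names = FALSE)
    max_start <- L - params$frag_len
    starts <- sample.int(max_start + 1L, n, replace = TRUE) - 1L
    r1 <- substring(tpl, starts + 1L, starts + params$read_len)
    r2 <- revcomp(substring(tpl, starts + params$frag_len - params$read_len + 1L,
                            starts + params$frag_len))
    if (!is.null(plant) && nrow(plant)) {
      for (i in seq_len(nrow(plant))) {
        p <- plant$pos[i]
        ## mate 1 covers [s, s+read_len); mate 2 covers the fragment tail
        c1 <- p >= starts & p < starts + params$read_len
        c2 <- p >= starts + params$frag_len - params$read_len &
          p < starts + params$frag_len
        flip <- runif(n) < plant$vaf[i]
        w1 <- which(c1 & flip)
        for (j in w1) substr(r1[j], p - starts[j] + 1L, p - starts[j] + 1L) <-
            plant$alt[i]
        w2 <- which(c2 & flip)
        for (j in w2) {
          rp <- starts[j] + params$frag_len - p # 1-based in revcomp read
          substr(r2[j], rp, rp) <- revcomp(plant$alt[i])
        }
      }
    }
    r1 <- inject_substitutions(r1, params$per_base_error)
    r2 <- inject_substitutions(r2, params$per_base_error)
    q <- strrep(phred_char(params$quality), params$read_len)
    read_set(id = c(sprintf("a%07d/1", seq_len(n)), sprintf("a%07d/2", seq_len(n))),
             seq = c(r1, r2), qual = rep(q, 2L * n),
             pair_id = rep(seq_len(n), 2L), mate = rep(c(1L, 2L), each = n))
  })
}

#' Simulate a dilution-series control panel
#'
#' `type = "junction"` mixes WT and edited amplicons at the given levels (the
#' 5-step standard curve for junction counting: 0, 1, 2, 5, 10%), optionally
#' applying a per-cycle amplification-efficiency bias so the standard-curve
#' correction has something to correct: with relative efficiency `rho` over
#' `cycles` cycles, a mixing level `f` amplifies to an observed template
#' fraction `f * rho^cycles / (f * rho^cycles + 1 - f)`.
#'
#' `type = "snv"` builds the SNV limit-of-detection panel: reads tile one
#' homology arm with a single planted substitution at each level (the 8-step
#' design uses levels 0, 0.1, 0.5, 1, 2, 5, 10 and 100%).
#'
#' @param model a [locus_model()].
#' @param side `"left"` or `"right"`.
#' @param levels numeric vector of mixing proportions in `[0, 1]`.
#' @param n_pairs read pairs per panel member.
#' @param params a [short_read_params()] supplying read length, error rate
#'   and seed (panel member i uses `seed + i - 1`).
#' @param type `"junction"` or `"snv"`.
#' @param rho,cycles amplification bias (junction panels only).
#' @param snv_pos,snv_alt planted variant (snv panels; defaults to an A>G or
#'   T>G change at mid-arm).
#' @return list of [read_set()]s, one per level, each carrying attributes
#'   `expected_percent` and (snv panels) `snv_pos`, `snv_alt`.
#' @export
simulate_control_panel <- function(model, side = c("left", "right"),
                                   levels = c(0, 0.01, 0.02, 0.05, 0.10),
                                   n_pairs = 20000,
                                   params = short_read_params(1),
                                   type = c("junction", "snv"),
                                   rho = 1, cycles = 20L,
                                   snv_pos = NULL, snv_alt = NULL) {
  side <- match.arg(side)
  type <- match.arg(type)
  stopifnot(all(levels >= 0 & levels <= 1))
  base_seed <- params$seed %||% NA
  out <- vector("list", length(levels))
  arm <- if (side == "left") model$left_arm else model$right_arm
  L <- nchar(arm)
  if (type == "snv") {
    if (is.null(snv_pos)) snv_pos <- L %/% 2L
    ref <- substr(arm, snv_pos + 1L, snv_pos + 1L)
    if (is.null(snv_alt)) snv_alt <- setdiff(DNA_BASES, ref)[1]
  }
  for (i in seq_along(levels)) {
    f <- levels[i]
    p <- params
    p$n_pairs <- as.integer(n_pairs)
    if (!is.na(base_seed)) p$seed <- as.integer(base_seed) + i - 1L
    if (type == "junction") {
      g <- f * rho^cycles
      p$integrated_fraction <- if (f >= 1) 1 else g / (g + 1 - f)
      rs <- simulate_short_reads(model, side, p)
    } else {
      alt_arm <- arm
      substr(alt_arm, snv_pos + 1L, snv_pos + 1L) <- snv_alt
      if (p$frag_len > L)
        stop("fragment length exceeds the arm length")
      rs <- with_opt_seed(p$seed, {
        n <- p$n_pairs
        alt <- runif(n) < f
        tpl <- ifelse(alt, alt_arm, arm)
        starts <- sample.int(L - p$frag_len + 1L, n, replace = TRUE) - 1L
        r1 <- substring(tpl, starts + 1L, starts + p$read_len)
        r2 <- revcomp(substring(tpl, starts + p$frag_len - p$read_len + 1L,
                                starts + p$frag_len))
        r1 <- inject_substitutions(r1, p$per_base_error)
        r2 <- inject_substitutions(r2, p$per_base_error)
        q <- strrep(phred_char(p$quality), p$read_len)
        read_set(id = c(sprintf("s%07d/1", seq_len(n)),
                        sprintf("s%07d/2", seq_len(n))),
                 seq = c(r1, r2), qual = rep(q, 2L * n),
                 pair_id = rep(seq_len(n), 2L),
                 mate = rep(c(1L, 2L), each = n))
      })
      attr(rs, "snv_pos") <- snv_pos
      attr(rs, "snv_alt") <- snv_alt
    }
    attr(rs, "expected_percent") <- 100 * f
    out[[i]] <- rs
  }
  names(out) <- sprintf("level_%g", 100 * levels)
  out
}

#' Parameters for long-read simulation
#'
#' @param n_reads number of reads.
#' @param sub_rate,ins_rate,del_rate per-base substitution / insertion /
#'   deletion probabilities (defaults 2%/2%/1%, i.e. 5% total error).
#' @param itr_fraction proportion of reads from the ITR-containing template.
#' @param wt_fraction proportion from the WT amplicon.
#' @param mispriming_fraction proportion of payload-side mispriming products
#'   (no genomic flank beyond the junction).
#' @param trim_probs named numeric: probability of each retained
#'   (payload-facing) d-region suffix length, emulating documented ITR
#'   trimming positions; `NULL` keeps the full d-region.
#' @param truncation_prob probability a read is truncated to a random
#'   sub-span of its template.
#' @param seed integer seed or `NULL`.
#' @return a `long_read_params` list.
#' @export
long_read_params <- function(n_reads, sub_rate = 0.02, ins_rate = 0.02,
                             del_rate = 0.01, itr_fraction = 0,
                             wt_fraction = 0, mispriming_fraction = 0,
                             trim_probs = NULL, truncation_prob = 0,
                             seed = NULL) {
  stopifnot(n_reads >= 1,
            sub_rate >= 0, sub_rate <= 1, ins_rate >= 0, ins_rate <= 1,
            del_rate >= 0, del_rate <= 1,
            itr_fraction >= 0, itr_fraction <= 1,
            wt_fraction >= 0, wt_fraction <= 1,
            mispriming_fraction >= 0, mispriming_fraction <= 1,
            itr_fraction + wt_fraction + mispriming_fraction <= 1,
            truncation_prob >= 0, truncation_prob <= 1)
  structure(list(n_reads = as.integer(n_reads), sub_rate = sub_rate,
                 ins_rate = ins_rate, del_rate = del_rate,
                 itr_fraction = itr_fraction, wt_fraction = wt_fraction,
                 mispriming_fraction = mispriming_fraction,
                 trim_probs = trim_probs, truncation_prob = truncation_prob,
                 seed = seed),
            class = "long_read_params")
}

## apply substitution/insertion/deletion noise to one sequence
mutate_long <- function(seq, sub, ins, del) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  smask <- runif(n) < sub
  if (any(smask)) {
    repl <- sample(DNA_BASES, sum(smask), replace = TRUE)
    same <- repl == ch[smask]
    while (any(same)) {
      repl[same] <- sample(DNA_BASES, sum(same), replace = TRUE)
      same <- repl == ch[smask]
    }
    ch[smask] <- repl
  }
  dmask <- runif(n) < del
  imask <- runif(n) < ins
  emit <- ch
  emit[dmask] <- ""
  insch <- character(n)
  insch[imask] <- sample(DNA_BASES, sum(imask), replace = TRUE)
  paste(paste0(emit, insch), collapse = "")
}

#' Simulate Nanopore-like long amplicon reads
#'
#' Reads are drawn from the seamless (edited), ITR-containing, WT or
#' mispriming templates of one side per the mixing proportions in `params`,
#' with indel and substitution noise applied. The ITR template's d-region is
#' trimmed per `trim_probs` (payload-facing suffix retained). Each read
#' carries a constant quality string encoding its expected per-base accuracy,
#' and a `truth` column records the generating template.
#'
#' @param model a [locus_model()].
#' @param side `"left"` or `"right"`.
#' @param params a [long_read_params()].
#' @return a [read_set()] (single-end) with a `truth` column in
#'   `{"seamless", "itr", "wt", "mispriming"}`.
#' @export
simulate_long_reads <- function(model, side = c("left", "right"), params) {
  side <- match.arg(side)
  stopifnot(inherits(model, "locus_model"),
            inherits(params, "long_read_params"))
  amp <- build_amplicons(model, side)
  d <- model$itr_d_region
  dl <- nchar(d)
  trim <- params$trim_probs %||% setNames(1, dl)
  trim_lens <- as.integer(names(trim))
  if (any(trim_lens < 1L | trim_lens > dl))
    stop("trim_probs lengths must be in [1, d-region length]")
  with_opt_seed(params$seed, {
    n <- params$n_reads
    cls <- sample(c("itr", "wt", "mispriming", "seamless"), n, replace = TRUE,
                  prob = c(params$itr_fraction, params$wt_fraction,
                           params$mispriming_fraction,
                           1 - params$itr_fraction - params$wt_fraction -
                             params$mispriming_fraction))
    ## mispriming: payload-side product only, no genomic flank
    misprime_tpl <- if (side == "left") {
      r <- amp$regions$edited
      substring(amp$edited, r$arm["start"] + 1L, nchar(amp$edited))
    } else {
      r <- amp$regions$edited
      substring(amp$edited, 1L, r$arm["end"])
    }
    itr_tpl_for <- function(t) {
      kept <- substring(d, dl - t + 1L, dl) # payload-facing suffix
      r <- amp$regions$itr
      if (side == "left")
        paste0(substring(amp$itr, 1L, r$flank["end"]), kept,
               substring(amp$itr, r$arm["start"] + 1L, nchar(amp$itr)))
      else
        paste0(substring(amp$itr, 1L, r$arm["end"]), kept,
               substring(amp$itr, r$flank["start"] + 1L, nchar(amp$itr)))
    }
    itr_tpls <- lapply(trim_lens, itr_tpl_for)
    names(itr_tpls) <- as.character(trim_lens)
    tpl <- character(n)
    tpl[cls == "seamless"] <- amp$edited
    tpl[cls == "wt"] <- amp$wt
    tpl[cls == "mispriming"] <- misprime_tpl
    n_itr <- sum(cls == "itr")
    if (n_itr) {
      tl <- trim_lens[sample.int(length(trim_lens), n_itr, replace = TRUE,
                                 prob = trim)]
      tpl[cls == "itr"] <- unlist(itr_tpls[as.character(tl)],
                                  use.names = FALSE)
    }
    trunc <- runif(n) < params$truncation_prob
    for (i in which(trunc)) {
      len <- nchar(tpl[i])
      keep <- as.integer(round(runif(1, 0.3, 0.95) * len))
      from_start <- runif(1) < 0.5
      tpl[i] <- if (from_start) substring(tpl[i], 1L, keep)
      else substring(tpl[i], len - keep + 1L, len)
    }
    seqs <- vapply(tpl, mutate_long, character(1),
                   sub = params$sub_rate, ins = params$ins_rate,
                   del = params$del_rate, USE.NAMES = FALSE)
    ## half the reads come off the reverse strand
    rc <- runif(n) < 0.5
    seqs[rc] <- revcomp(seqs[rc])
    err <- params$sub_rate + params$ins_rate + params$del_rate
    qual <- vapply(nchar(seqs), function(l) const_qual(err, l), character(1))
    read_set(id = sprintf("L%06d", seq_len(n)), seq = seqs, qual = qual,
             pair_id = seq_len(n), mate = 0L, truth = cls)
  })
}

#' Parameters for droplet partitioning simulation
#'
#' @param n_droplets number of droplets.
#' @param lambda_payload_free,lambda_genomic_free,lambda_linked mean free
#'   payload / free genomic / linked (integrated) molecules per droplet.
#' @param shear_prob probability that a linked molecule is sheared before
#'   partitioning into one free payload plus one free genomic molecule.
#' @param seed integer seed or `NULL`.
#' @return a `droplet_sim_params` list.
#' @export
droplet_params <- function(n_droplets, lambda_payload_free = 0,
                           lambda_genomic_free = 0, lambda_linked = 0,
                           shear_prob = 0, seed = NULL) {
  stopifnot(n_droplets >= 1, lambda_payload_free >= 0,
            lambda_genomic_free >= 0, lambda_linked >= 0,
            shear_prob >= 0, shear_prob <= 1)
  structure(list(n_droplets = as.integer(n_droplets),
                 lambda_payload_free = lambda_payload_free,
                 lambda_genomic_free = lambda_genomic_free,
                 lambda_linked = lambda_linked,
                 shear_prob = shear_prob, seed = seed),
            class = "droplet_sim_params")
}

#' Simulate ddPCR droplet partitioning
#'
#' Free payload, free genomic and linked molecules partition as three
#' independent Poissons. Shearing acts before partitioning: a sheared linked
#' molecule becomes one free payload plus one free genomic molecule, which
#' then partition independently. A droplet is FAM-positive if it holds any
#' payload-bearing molecule and HEX-positive if it holds any genomic-bearing
#' molecule; linked molecules light both channels.
#'
#' @param params a [droplet_params()].
#' @return a [droplet_table()].
#' @export
simulate_droplets <- function(params) {
  stopifnot(inherits(params, "droplet_sim_params"))
  with_opt_seed(params$seed, {
    N <- params$n_droplets
    sh <- params$shear_prob
    lamL <- params$lambda_linked * (1 - sh)
    lamP <- params$lambda_payload_free + params$lambda_linked * sh
    lamG <- params$lambda_genomic_free + params$lambda_linked * sh
    nP <- rpois(N, lamP); nG <- rpois(N, lamG); nL <- rpois(N, lamL)
    fam <- nP > 0L | nL > 0L
    hex <- nG > 0L | nL > 0L
    droplet_table(n_pp = sum(fam & hex), n_pn = sum(fam & !hex),
                  n_np = sum(!fam & hex), n_nn = sum(!fam & !hex))
  })
}
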