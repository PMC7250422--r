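test_that("pileup counts equal a brute-force per-column tally", {
  m <- test_model()
  arm <- m$right_arm
  withr::with_seed(41, {
    n <- 150L
    starts <- sample.int(nchar(arm) - 75L, n, replace = TRUE) - 1L
    seqs <- substring(arm, starts + 1L, starts + 75L)
    seqs <- intequant:::inject_substitutions(seqs, 0.01)
    # mixed qualities: some bases below Q30 must be excluded
    quals <- vapply(1:n, function(i)
      paste(sample(c("I", "5"), 75, TRUE, prob = c(0.9, 0.1)), # Q40 / Q20
            collapse = ""), character(1))
    rs <- read_set(sprintf("r%d", 1:n), seqs, quals)
    pl <- align_short_reads(rs, arm, "R", require_proper_pair = FALSE)
    pu <- pileup_reads(pl, min_bq = 30)
    idx <- match(pl$id, rs$id)
    oracle <- brute_force_pileup(pl$seq, pl$qual, pl$pos, nchar(arm))
    expect_equal(unname(pu$counts), unname(oracle))
  })
})

test_that("variant filters implement the depth, quality and frequency gates", {
  ref <- withr::with_seed(8, paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                                   collapse = ""))
  altb <- setdiff(c("A", "C", "G", "T"), substr(ref, 200, 200))[1]
  mkpile <- function(depth, altn, pos = 200L, alt = altb, qual = "I") {
    n <- depth
    seqs <- rep(substr(ref, pos - 19L, pos + 20L), n)
    alt_read <- seqs[1]
    substr(alt_read, 20L, 20L) <- alt
    if (altn > 0) seqs[1:altn] <- alt_read
    rs <- read_set(sprintf("r%d", 1:n), seqs, rep(strrep(qual, 40), n))
    pl <- align_short_reads(rs, ref, "amp", require_proper_pair = FALSE)
    pileup_reads(pl)
  }
  # 50% variant at high depth is called
  v <- pileup_variants(mkpile(1000, 500), min_depth = 200)
  hit <- v[v$pos == 199L & v$alt == altb, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$frequency, 0.5, tolerance = 1e-9)
  # depth below 200 suppresses the call regardless of frequency
  v2 <- pileup_variants(mkpile(150, 75), min_depth = 200)
  expect_equal(nrow(v2[v2$pos == 199L, ]), 0L)
  # alt bases below Q30 are excluded entirely
  v3 <- pileup_variants(mkpile(1000, 500, qual = "5"), min_depth = 200)
  expect_equal(nrow(v3), 0L)
  # frequency below min_vf suppressed
  v4 <- pileup_variants(mkpile(5000, 2), min_vf = 0.0005, min_depth = 200)
  expect_equal(nrow(v4[v4$pos == 199L & v4$alt == altb, ]), 0L)
})

test_that("planted indels are called from the pileup", {
  ref <- withr::with_seed(9, paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                                   collapse = ""))
  n <- 400L
  base <- substr(ref, 101L, 180L)
  del_read <- paste0(substr(base, 1L, 40L), substr(base, 42L, 80L))
  ins_read <- paste0(substr(base, 1L, 40L), "A", substr(base, 41L, 79L))
  seqs <- c(rep(base, n / 2), rep(del_read, n / 4), rep(ins_read, n / 4))
  rs <- read_set(sprintf("r%d", seq_along(seqs)), seqs,
                 strrep("I", nchar(seqs)))
  pl <- align_short_reads(rs, ref, "amp", require_proper_pair = FALSE)
  v <- pileup_variants(pl, min_depth = 100)
  del_hit <- v$type == "del" & abs(v$pos - 140L) <= 2L
  expect_true(any(del_hit))
  expect_true(any(v$type == "ins" & abs(v$pos - 140L) <= 2L))
  expect_equal(max(v$frequency[del_hit]), 0.25, tolerance = 0.05)
})

test_that("de novo verdicts follow the three reproducibility criteria", {
  wt <- mk_variant_table(data.frame(pos = 50L, frequency = 0.5,
                                    depth = 10000L, alt = "T", ref = "A",
                                    alt_count = 5000L))
  mk <- function(...) mk_variant_table(data.frame(...))
  # 0.7% in both replicates, absent in WT -> de novo
  r1 <- mk(pos = c(50L, 80L), frequency = c(0.49, 0.007), alt = c("T", "C"),
           ref = c("A", "G"), depth = 10000L,
           alt_count = c(4900L, 70L))
  r2 <- mk(pos = c(50L, 80L), frequency = c(0.51, 0.008), alt = c("T", "C"),
           ref = c("A", "G"), depth = 10000L,
           alt_count = c(5100L, 80L))
  rep_both <- call_de_novo(r1, r2, wt)
  cand <- rep_both$candidates
  expect_equal(cand$verdict[cand$pos == 80L], "de_novo")
  expect_equal(cand$verdict[cand$pos == 50L], "present_in_wt")
  expect_equal(rep_both$n_de_novo, 1L)
  # single-replicate candidates are not reported
  r2b <- mk(pos = 50L, frequency = 0.5, alt = "T", ref = "A",
            depth = 10000L, alt_count = 5000L)
  rep_single <- call_de_novo(r1, r2b, wt)
  expect_equal(rep_single$candidates$verdict[
    rep_single$candidates$pos == 80L], "single_replicate")
  expect_equal(rep_single$n_de_novo, 0L)
  # sub-threshold candidates get the below_threshold code
  r1c <- mk(pos = 80L, frequency = 0.003, alt = "C", ref = "G",
            depth = 10000L, alt_count = 30L)
  r2c <- mk(pos = 80L, frequency = 0.004, alt = "C", ref = "G",
            depth = 10000L, alt_count = 40L)
  expect_equal(call_de_novo(r1c, r2c, wt)$candidates$verdict, "below_threshold")
  # mismatched amplicons error
  other <- mk_variant_table(data.frame(pos = 1L, frequency = 0.5, alt = "T",
                                       ref = "A", depth = 1000L,
                                       alt_count = 500L),
                            amplicon_id = "other")
  expect_error(call_de_novo(r1, other, wt), "different amplicons")
})

test_that("raising the reporting threshold never adds de novo calls", {
  withr::with_seed(19, {
    mk_rand <- function() {
      n <- 30L
      mk_variant_table(data.frame(
        pos = sample(900L, n), type = "snv", ref = "A",
        alt = sample(c("C", "G", "T"), n, TRUE),
        depth = 10000L, alt_count = rbinom(n, 10000L, 0.004)))
    }
    r1 <- mk_rand(); r2 <- mk_rand(); wt <- mk_rand()
    r1$frequency <- r1$alt_count / r1$depth
    r2$frequency <- r2$alt_count / r2$depth
    wt$frequency <- wt$alt_count / wt$depth
    counts <- vapply(c(0.001, 0.003, 0.005, 0.01),
                     function(th) call_de_novo(r1, r2, wt, th)$n_de_novo,
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("panel evaluation scores a perfect and an empty caller correctly", {
  lv <- c(0, 0.01, 0.05, 0.5)
  truth <- data.frame(expected_vaf = lv,
                      pos = c(NA, 100L, 100L, 100L),
                      alt = c(NA, "T", "T", "T"))
  perfect <- lapply(lv, function(f) {
    if (f == 0) return(mk_variant_table(data.frame(pos = integer(0),
                                                   frequency = numeric(0),
                                                   alt = character(0),
                                                   ref = character(0),
                                                   depth = integer(0),
                                                   alt_count = integer(0))))
    mk_variant_table(data.frame(pos = 100L, frequency = f, alt = "T",
                                ref = "A", depth = 10000L,
                                alt_count = round(10000 * f)))
  })
  ev <- evaluate_panel(perfect, truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$r_squared, 1)
  expect_equal(ev$slope, 1, tolerance = 1e-9)
  empty <- lapply(lv, function(f) perfect[[1]])
  ev0 <- evaluate_panel(empty, truth)
  expect_equal(ev0$sensitivity, 0)
})
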