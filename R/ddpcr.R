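## Poisson linkage analysis of four-class ddPCR droplet counts: separates
## linked (integrated) molecules from free payload and free genomic
## molecules, and reports the integration (linkage) percentage.

#' Poisson occupancy estimate from negative-droplet counts
#'
#' Inverts the Poisson zero class: with a fraction `n_negative / n_total` of
#' droplets empty for a species, its mean occupancy is
#' `-log(n_negative / n_total)` molecules per droplet.
#'
#' @param n_negative number of droplets negative for the species.
#' @param n_total total droplets.
#' @return estimated molecules per droplet.
#' @export
poisson_lambda <- function(n_negative, n_total) {
  if (n_total <= 0 || n_negative > n_total)
    stop("require 0 < n_negative <= n_total")
  if (n_negative == 0)
    stop("no negative droplets: assay saturated")
  -log(n_negative / n_total)
}

#' Estimate molecular linkage from a droplet table
#'
#' Under three independent Poisson species (free payload, free genomic,
#' linked), the double-negative fraction exceeds the product of the two
#' single-channel negative fractions by exactly the linked occupancy:
#' with `f_A` the HEX-negative fraction, `f_B` the FAM-negative fraction and
#' `f_nn` the double-negative fraction,
#' `lambda_linked = log(f_nn / (f_A * f_B))`,
#' `lambda_payload_free = -log(f_B) - lambda_linked`, and
#' `lambda_genomic_free = -log(f_A) - lambda_linked`. The linkage
#' (integration) percentage is `100 * lambda_linked /
#' (lambda_genomic_free + lambda_linked)`: the fraction of target alleles
#' physically linked to payload.
#'
#' @param table a [droplet_table()].
#' @param bootstrap number of droplet-resampling bootstrap replicates for
#'   confidence intervals (0 disables).
#' @param conf confidence level.
#' @param seed optional seed for the bootstrap.
#' @return object of class `linkage_result` with the three lambda estimates,
#'   `linkage_percent`, bootstrap `ci` (matrix or `NULL`) and a
#'   `no_excess_linkage` flag (raw linked estimate below zero, clipped).
#' @export
estimate_linkage <- function(table, bootstrap = 0L, conf = 0.95,
                             seed = NULL) {
  stopifnot(inherits(table, "droplet_table"))
  est <- linkage_point(table)
  ci <- NULL
  if (bootstrap > 0L) {
    N <- table$n_pp + table$n_pn + table$n_np + table$n_nn
    probs <- c(table$n_pp, table$n_pn, table$n_np, table$n_nn) / N
    boots <- with_opt_seed(seed, {
      draws <- rmultinom(bootstrap, N, probs)
      apply(draws, 2, function(d) {
        if (d[4] == 0) return(rep(NA_real_, 4))
        b <- try(linkage_point(droplet_table(d[1], d[2], d[3], d[4])),
                 silent = TRUE)
        if (inherits(b, "try-error")) rep(NA_real_, 4)
        else c(b$lambda_payload_free, b$lambda_genomic_free,
               b$lambda_linked, b$linkage_percent)
      })
    })
    a <- (1 - conf) / 2
    ci <- t(apply(boots, 1, quantile, probs = c(a, 1 - a), na.rm = TRUE))
    rownames(ci) <- c("lambda_payload_free", "lambda_genomic_free",
                      "lambda_linked", "linkage_percent")
  }
  structure(c(est, list(ci = ci, conf = conf)), class = "linkage_result")
}

linkage_point <- function(table) {
  N <- table$n_pp + table$n_pn + table$n_np + table$n_nn
  if (table$n_nn == 0)
    stop("no double-negative droplets: assay saturated")
  est <- linkage_from_fractions(
    c(f_pp = table$n_pp / N, f_pn = table$n_pn / N,
      f_np = table$n_np / N, f_nn = table$n_nn / N))
  c(est, list(n_droplets = N))
}

#' Invert the droplet model from class fractions
#'
#' The closed-form inverse of [expected_droplet_fractions()]; operating on
#' fractions directly makes the round-trip identity exact.
#'
#' @param fractions named numeric with `f_pp`, `f_pn`, `f_np`, `f_nn`
#'   (summing to 1).
#' @return list of lambda estimates and `linkage_percent` as in
#'   [estimate_linkage()].
#' @export
linkage_from_fractions <- function(fractions) {
  f_A <- fractions[["f_pn"]] + fractions[["f_nn"]] # HEX-negative fraction
  f_B <- fractions[["f_np"]] + fractions[["f_nn"]] # FAM-negative fraction
  f_nn <- fractions[["f_nn"]]
  if (f_nn <= 0) stop("no double-negative fraction: assay saturated")
  lam_linked_raw <- log(f_nn / (f_A * f_B))
  no_excess <- lam_linked_raw < 0
  lam_linked <- max(0, lam_linked_raw)
  lam_p <- max(0, -log(f_B) - lam_linked)
  lam_g <- max(0, -log(f_A) - lam_linked)
  denom <- lam_g + lam_linked
  linkage_percent <- if (denom > 0) 100 * lam_linked / denom else 0
  list(lambda_payload_free = lam_p, lambda_genomic_free = lam_g,
       lambda_linked = lam_linked, lambda_linked_raw = lam_linked_raw,
       linkage_percent = linkage_percent, no_excess_linkage = no_excess)
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("ddPCR linkage analysis (", x$n_droplets, " droplets)\n", sep = "")
  cat(sprintf("  lambda payload (free): %.5g\n", x$lambda_payload_free))
  cat(sprintf("  lambda genomic (free): %.5g\n", x$lambda_genomic_free))
  cat(sprintf("  lambda linked:         %.5g%s\n", x$lambda_linked,
              if (x$no_excess_linkage) "  [no excess linkage]" else ""))
  cat(sprintf("  linkage: %.4g%% of target alleles integrated\n",
              x$linkage_percent))
  if (!is.null(x$ci))
    cat(sprintf("  linkage %d%% CI: [%.4g, %.4g]\n", round(100 * x$conf),
                x$ci["linkage_percent", 1], x$ci["linkage_percent", 2]))
  invisible(x)
}

#' Expected droplet class fractions for given occupancies
#'
#' Closed-form expectations under the three-Poisson droplet model; the exact
#' inverse of [estimate_linkage()] on infinite data. Mainly used to verify
#' the round-trip identity.
#'
#' @param lambda_payload_free,lambda_genomic_free,lambda_linked mean
#'   molecules per droplet.
#' @return named numeric of expected fractions `f_pp`, `f_pn`, `f_np`,
#'   `f_nn`.
#' @export
expected_droplet_fractions <- function(lambda_payload_free,
                                       lambda_genomic_free,
                                       lambda_linked) {
  lambda_payload_free <- unname(lambda_payload_free)
  lambda_genomic_free <- unname(lambda_genomic_free)
  lambda_linked <- unname(lambda_linked)
  p_fam_neg <- exp(-lambda_payload_free - lambda_linked)
  p_hex_neg <- exp(-lambda_genomic_free - lambda_linked)
  f_nn <- exp(-lambda_payload_free - lambda_genomic_free - lambda_linked)
  f_pn <- p_hex_neg - f_nn
  f_np <- p_fam_neg - f_nn
  f_pp <- 1 - p_fam_neg - p_hex_neg + f_nn
  c(f_pp = f_pp, f_pn = f_pn, f_np = f_np, f_nn = f_nn)
}
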