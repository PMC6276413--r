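#' Hardy-Weinberg equilibrium tests for one SNP
#'
#' Computes both the 1-df chi-squared goodness-of-fit test against the
#' expected (p^2, 2pq, q^2) genotype proportions and the conditional
#' exact test (probability of the observed heterozygote count given the
#' allele counts; the p-value sums the probabilities of all heterozygote
#' counts no more probable than the observed one).
#'
#' @param counts integer vector `(n0, n1, n2)` of genotype counts
#'   (reference homozygote, heterozygote, alternate homozygote).
#' @param alpha significance level used for the `in_hwe` flag
#'   (default 0.05, applied to the exact p).
#' @param snp optional SNP label carried into the result.
#' @return object of class `"hwe_result"`: list with `snp`, `counts`,
#'   `chi2`, `chi2_p`, `exact_p`, `in_hwe`, `monomorphic`.
#' @export
#' @examples
#' hwe_test(c(25, 50, 25))   # perfect HWE proportions: chi2 = 0, p = 1
hwe_test <- function(counts, alpha = 0.05, snp = NA_character_) {
  counts <- as.integer(counts)
  if (length(counts) != 3L || any(counts < 0) || sum(counts) < 1)
    .fail("'counts' must be three nonnegative genotype counts with total >= 1")
  n <- sum(counts)
  n_alt <- counts[2] + 2L * counts[3]
  n_ref <- 2L * n - n_alt
  if (n_alt == 0L || n_ref == 0L) {
    out <- list(snp = snp, counts = counts, chi2 = 0, chi2_p = 1,
                exact_p = 1, in_hwe = TRUE, monomorphic = TRUE)
    class(out) <- "hwe_result"
    return(out)
  }
  q <- n_alt / (2 * n)
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  chi2_p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  exact_p <- .hwe_exact_p(counts[2], n_ref, n_alt)
  out <- list(snp = snp, counts = counts, chi2 = chi2, chi2_p = chi2_p,
              exact_p = exact_p, in_hwe = exact_p >= alpha,
              monomorphic = FALSE)
  class(out) <- "hwe_result"
  out
}

## conditional exact HWE p: closed-form probability of each heterozygote
## count h compatible with the allele counts,
##   P(h) = n! / (n_aa! h! n_bb!) * 2^h * n_ref! n_alt! / (2n)!,
## summed over counts whose probability does not exceed the observed one
.hwe_exact_p <- function(h_obs, n_ref, n_alt) {
  n <- (n_ref + n_alt) / 2
  rare <- min(n_ref, n_alt)
  hs <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hs, function(h) {
    n_bb <- (rare - h) / 2
    n_aa <- n - h - n_bb
    lgamma(n + 1) - lgamma(n_aa + 1) - lgamma(h + 1) - lgamma(n_bb + 1) +
      h * log(2) + lgamma(n_ref + 1) + lgamma(n_alt + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(h_obs, hs)]
  if (is.na(p_obs)) .fail("heterozygote count incompatible with allele counts")
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf(
    "HWE test%s: counts (%d, %d, %d)%s\n  chi2 = %.4g (p = %.4g), exact p = %.4g -> %s\n",
    if (is.na(x$snp)) "" else paste0(" [", x$snp, "]"),
    x$counts[1], x$counts[2], x$counts[3],
    if (x$monomorphic) " [monomorphic]" else "",
    x$chi2, x$chi2_p, x$exact_p,
    if (x$in_hwe) "in HWE" else "out of HWE"))
  invisible(x)
}

#' Per-SNP HWE screen over a genotype matrix
#'
#' @param geno genotype matrix (subjects x SNPs, 0/1/2/NA).
#' @param alpha significance level for the `in_hwe` flag.
#' @return data.frame with one row per SNP: counts, chi2, both p-values,
#'   `monomorphic` and `in_hwe`.
#' @export
hwe_screen <- function(geno, alpha = 0.05) {
  res <- lapply(colnames(geno), function(snp) {
    g <- geno[, snp]
    h <- hwe_test(tabulate(g + 1L, nbins = 3L), alpha = alpha, snp = snp)
    data.frame(snp = snp, n0 = h$counts[1], n1 = h$counts[2], n2 = h$counts[3],
               chi2 = h$chi2, chi2_p = h$chi2_p, exact_p = h$exact_p,
               monomorphic = h$monomorphic, in_hwe = h$in_hwe)
  })
  do.call(rbind, res)
}
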