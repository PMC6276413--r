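#' Analysis of molecular variance (AMOVA) over a genotype matrix
#'
#' Partitions the total genetic variance — measured as squared pairwise
#' differences of alternate-allele counts summed over SNPs — into among-
#' and within-group components, reports the Phi statistic
#' (among / total) and a permutation p-value obtained by shuffling group
#' labels. Used here as a sample-homogeneity check: for a homogeneous
#' cohort split into arbitrary groups, Phi should be indistinguishable
#' from its permutation null.
#'
#' @param geno genotype matrix (subjects x SNPs, 0/1/2; missing cells
#'   contribute nothing to the pairwise distances).
#' @param grouping vector of group labels, one per subject (>= 2 groups,
#'   each with >= 2 subjects).
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @return object of class `"amova_result"`: variance components
#'   (`sigma2_among`, `sigma2_within`), `phi`, `p` (add-one corrected),
#'   sums of squares and degrees of freedom.
#' @export
amova <- function(geno, grouping, n_perm = 1000, seed = 1L) {
  if (is.null(dim(geno))) .fail("'geno' must be a matrix")
  n <- nrow(geno)
  grouping <- as.character(grouping)
  if (length(grouping) != n) .fail("one group label per subject is required")
  tab <- table(grouping)
  if (length(tab) < 2L)
    .fail("AMOVA needs >= 2 groups; the among-group component is undefined for one group")
  if (any(tab < 2L)) .fail("every group needs >= 2 subjects")

  ## squared Euclidean distances over allele counts; NAs contribute 0
  g0 <- geno
  g0[is.na(g0)] <- 0
  gram <- tcrossprod(g0)
  sq <- diag(gram)
  d2 <- outer(sq, sq, "+") - 2 * gram

  ss_from <- function(labels) {
    groups <- split(seq_len(n), labels)
    ss_w <- sum(vapply(groups, function(idx) {
      sum(d2[idx, idx]) / (2 * length(idx))
    }, numeric(1)))
    ss_t <- sum(d2) / (2 * n)
    c(total = ss_t, within = ss_w, among = ss_t - ss_w)
  }
  phi_from <- function(labels) {
    ss <- ss_from(labels)
    tabl <- table(labels)
    g <- length(tabl)
    df_a <- g - 1
    df_w <- n - g
    s2_w <- ss[["within"]] / df_w
    n0 <- (n - sum(tabl^2) / n) / df_a
    s2_a <- (ss[["among"]] / df_a - s2_w) / n0
    tot <- s2_a + s2_w
    phi <- if (tot <= .Machine$double.eps) 0 else s2_a / tot
    list(ss = ss, s2_a = s2_a, s2_w = s2_w, phi = phi,
         df_a = df_a, df_w = df_w)
  }

  obs <- phi_from(grouping)
  if (sum(d2) <= .Machine$double.eps) {
    out <- list(sigma2_among = 0, sigma2_within = 0, phi = 0, p = 1,
                n_perm = n_perm, ss = obs$ss, df_among = obs$df_a,
                df_within = obs$df_w, seed = seed)
    class(out) <- "amova_result"
    return(out)
  }
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    phi_b <- phi_from(sample(grouping))$phi
    if (phi_b >= obs$phi - 1e-12) exceed <- exceed + 1L
  }
  out <- list(
    sigma2_among = obs$s2_a, sigma2_within = obs$s2_w, phi = obs$phi,
    p = (1 + exceed) / (n_perm + 1), n_perm = n_perm, ss = obs$ss,
    df_among = obs$df_a, df_within = obs$df_w, seed = seed
  )
  class(out) <- "amova_result"
  out
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA\n")
  cat(sprintf("  among groups : SS %.3f (df %d), sigma2 %.4f\n",
              x$ss[["among"]], x$df_among, x$sigma2_among))
  cat(sprintf("  within groups: SS %.3f (df %d), sigma2 %.4f\n",
              x$ss[["within"]], x$df_within, x$sigma2_within))
  cat(sprintf("  Phi = %.4f, permutation p = %.4g (%d permutations)\n",
              x$phi, x$p, x$n_perm))
  invisible(x)
}

#' Homogeneity check by repeated random splits
#'
#' The homogeneity use case of [amova()] when no natural grouping
#' exists: the cohort is split into random halves `n_splits` times and
#' the AMOVA permutation p recorded for each split.
#'
#' @param geno genotype matrix.
#' @param n_splits number of random half-splits (default 5).
#' @param n_perm permutations per split.
#' @param seed integer seed.
#' @return data.frame with one row per split: `phi` and `p`.
#' @export
amova_homogeneity <- function(geno, n_splits = 5, n_perm = 1000, seed = 1L) {
  n <- nrow(geno)
  set.seed(seed)
  out <- lapply(seq_len(n_splits), function(k) {
    labels <- sample(rep(c("A", "B"), length.out = n))
    a <- amova(geno, labels, n_perm = n_perm,
               seed = sample.int(.Machine$integer.max, 1))
    data.frame(split = k, phi = a$phi, p = a$p)
  })
  do.call(rbind, out)
}
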