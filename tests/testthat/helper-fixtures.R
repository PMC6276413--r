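# Shared fixture builders: small fully-specified simulation specs so
# each test controls its own effect sizes and noise.

# A compact spec with explicit lipid models. `snp_effects` is a named
# list per lipid; covariates default to none for clean arithmetic.
make_test_spec <- function(n = 200, n_snps = 5, maf = 0.3, f = 0,
                           tc_effects = list(), hdl_effects = list(),
                           tg_effects = list(),
                           tc_sd = 10, hdl_sd = 5, tg_sd = 15,
                           tc_beta = numeric(0), hdl_beta = numeric(0),
                           tg_beta = numeric(0),
                           seed = 1L) {
  snps <- snp_panel(n_snps, maf = maf, f = f)
  simulation_spec(
    n, snps,
    list(
      tc = list(intercept = 216, covar_beta = tc_beta,
                snp_effects = tc_effects, residual_sd = tc_sd),
      hdl = list(intercept = 55, covar_beta = hdl_beta,
                 snp_effects = hdl_effects, residual_sd = hdl_sd),
      tg = list(intercept = 104, covar_beta = tg_beta,
                snp_effects = tg_effects, residual_sd = tg_sd)
    ),
    seed = seed
  )
}

# Deterministic three-genotype lipid fixture: group sizes and exact
# values chosen per test.
make_groups <- function(values_by_genotype) {
  g <- rep(as.integer(names(values_by_genotype)),
           lengths(values_by_genotype))
  y <- unlist(values_by_genotype, use.names = FALSE)
  list(y = y, g = g)
}

# Independent dynamic-programming oracle for the conditional exact HWE
# distribution: pairs alleles sequentially without replacement and
# accumulates the heterozygote-count distribution. Shares no code with
# the closed-form implementation.
hwe_het_distribution_dp <- function(n_ref, n_alt) {
  n <- (n_ref + n_alt) / 2
  # state: probability by (remaining ref alleles); track het count dist
  # dist[[as.character(a)]] = named numeric: P(h hets so far, a refs left)
  dist <- list()
  dist[[as.character(n_ref)]] <- c(`0` = 1)
  for (pair in seq_len(n)) {
    nxt <- list()
    total_alleles <- 2 * (n - pair + 1)
    for (a_chr in names(dist)) {
      a <- as.numeric(a_chr)
      b <- total_alleles - a
      probs <- dist[[a_chr]]
      add <- function(a2, h_shift, p_step) {
        if (p_step <= 0) return()
        key <- as.character(a2)
        cur <- nxt[[key]]
        shifted <- probs * p_step
        names(shifted) <- as.character(as.numeric(names(probs)) + h_shift)
        if (is.null(cur)) nxt[[key]] <<- shifted
        else {
          for (h in names(shifted))
            cur[h] <- (if (h %in% names(cur)) cur[[h]] else 0) + shifted[[h]]
          nxt[[key]] <<- cur
        }
      }
      denom <- total_alleles * (total_alleles - 1)
      add(a - 2, 0, a * (a - 1) / denom)        # ref/ref pair
      add(a - 1, 1, 2 * a * b / denom)          # heterozygote
      add(a, 0, b * (b - 1) / denom)            # alt/alt pair
    }
    dist <- nxt
  }
  out <- dist[["0"]]
  out[order(as.numeric(names(out)))]
}
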