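#' Simulate a genotype matrix
#'
#' Draws independent genotypes per SNP with frequencies
#' P(0) = (1-q)^2 + Fq(1-q), P(1) = 2q(1-q)(1-F), P(2) = q^2 + Fq(1-q)
#' for minor-allele frequency q and inbreeding coefficient F (F = 0 is
#' Hardy-Weinberg equilibrium).
#'
#' @param spec a [simulation_spec()].
#' @return integer matrix, subjects x SNPs, values in 0/1/2; rownames are
#'   subject IDs, colnames rsIDs; SNP annotation attached as attribute
#'   `"annotation"`.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  .draw_genotypes(spec)
}

.draw_genotypes <- function(spec) {
  n <- spec$n_subjects
  m <- nrow(spec$snps)
  g <- matrix(0L, n, m,
              dimnames = list(sprintf("S%04d", seq_len(n)), spec$snps$rsid))
  for (j in seq_len(m)) {
    p <- genotype_freqs(spec$snps$maf[j], spec$snps$f[j])
    g[, j] <- sample(0:2, n, replace = TRUE, prob = p)
  }
  attr(g, "annotation") <- spec$snps[c("rsid", "gene", "ref", "alt")]
  g
}

## draw covariates; marginals per the spec, positive quantities as
## truncated normals (redrawn) or gamma (vfat, METs); macronutrient %E
## are compositional: protein and fat are drawn, carbohydrate takes the
## remainder of the target total plus a small independent component so
## its SD matches the spec and carb+prot+fat stays <= 100
.draw_covariates <- function(spec) {
  n <- spec$n_subjects
  cv <- spec$covariates
  rtnorm <- function(n, mean, sd, lower = 0) {
    x <- stats::rnorm(n, mean, sd)
    for (it in 1:100) {
      bad <- x <= lower
      if (!any(bad)) break
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    x
  }
  rgam <- function(n, mean, sd) {
    shape <- (mean / sd)^2
    stats::rgamma(n, shape = shape, scale = sd^2 / mean)
  }
  age <- rtnorm(n, cv$age[["mean"]], cv$age[["sd"]], cv$age_min %||% 18)
  sex <- ifelse(stats::runif(n) < cv$sex_prop_male, "M", "F")
  weight <- rtnorm(n, cv$weight[["mean"]], cv$weight[["sd"]])
  bmi <- rtnorm(n, cv$bmi[["mean"]], cv$bmi[["sd"]])
  tfat <- rtnorm(n, cv$tfat[["mean"]], cv$tfat[["sd"]])
  vfat <- rgam(n, cv$vfat[["mean"]], cv$vfat[["sd"]])
  if (spec$adiposity_cor > 0) {
    ## Gaussian-copula reordering of (bmi, tfat, vfat) toward a common
    ## latent factor; marginals are preserved exactly
    r <- sqrt(spec$adiposity_cor)
    z0 <- stats::rnorm(n)
    lat <- function() r * z0 + sqrt(1 - r^2) * stats::rnorm(n)
    bmi <- sort(bmi)[rank(lat(), ties.method = "first")]
    tfat <- sort(tfat)[rank(lat(), ties.method = "first")]
    vfat <- sort(vfat)[rank(lat(), ties.method = "first")]
  }
  glucose <- rtnorm(n, cv$glucose[["mean"]], cv$glucose[["sd"]])
  energy <- rtnorm(n, cv$energy[["mean"]], cv$energy[["sd"]],
                   cv$energy_min %||% 500)
  prot <- rtnorm(n, cv$prot_pct[["mean"]], cv$prot_pct[["sd"]])
  fat <- rtnorm(n, cv$fat_pct[["mean"]], cv$fat_pct[["sd"]])
  total <- cv$carb_pct[["mean"]] + cv$prot_pct[["mean"]] + cv$fat_pct[["mean"]]
  eps_var <- cv$carb_pct[["sd"]]^2 - cv$prot_pct[["sd"]]^2 - cv$fat_pct[["sd"]]^2
  eps_sd <- sqrt(max(eps_var, 0))
  eps <- stats::rnorm(n, 0, eps_sd)
  eps <- pmin(eps, 100 - total)            # keep the composition <= 100 %E
  carb <- pmax(total - prot - fat + eps, 1)
  chol <- rtnorm(n, cv$chol_intake[["mean"]], cv$chol_intake[["sd"]])
  mets <- rgam(n, cv$mets[["mean"]], cv$mets[["sd"]])
  smoker <- as.integer(stats::runif(n) < cv$smoker_prev)
  drinker <- as.integer(stats::runif(n) < cv$drinker_prev)
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = age, sex = sex, weight = weight, bmi = bmi, tfat = tfat,
    vfat = vfat, glucose = glucose, energy = energy, carb_pct = carb,
    prot_pct = prot, fat_pct = fat, chol_intake = chol, mets = mets,
    smoker = smoker, drinker = drinker,
    stringsAsFactors = FALSE
  )
}

#' Design-variable view of a cohort table
#'
#' Maps cohort columns onto the variables used in generating models and
#' regression design matrices: `sex` becomes 0/1 (configurable reference),
#' energy becomes `energy100` (kcal/100); everything else passes through.
#'
#' @param cohort cohort data.frame.
#' @param sex_code which sex is coded 1 (default `"M"`, i.e. female = 0).
#' @return data.frame of numeric design variables.
#' @export
covariate_design <- function(cohort, sex_code = "M") {
  out <- cohort[intersect(
    c("age", "weight", "bmi", "tfat", "vfat", "glucose", "carb_pct",
      "prot_pct", "fat_pct", "chol_intake", "mets", "smoker", "drinker"),
    names(cohort))]
  if ("sex" %in% names(cohort))
    out$sex <- as.integer(cohort$sex == sex_code)
  if ("energy" %in% names(cohort))
    out$energy100 <- cohort$energy / 100
  out
}

#' Simulate a full cohort (phenotypes + genotypes + ground truth)
#'
#' Each measured lipid (TC, HDL-c, TG) is generated as intercept +
#' per-genotype SNP effects + covariate effects + Gaussian noise; LDL-c
#' is then derived with the Friedewald equation, so the four lipids are
#' internally consistent by construction. Subjects whose draw would give
#' a non-positive lipid have their noise redrawn.
#'
#' @param spec a [simulation_spec()].
#' @return object of class `"sim_cohort"`: list with `cohort` (data.frame),
#'   `genotypes` (matrix as in [simulate_genotypes()]) and `truth` — per
#'   lipid (including derived LDL-c) the causal SNP IDs, the generating
#'   per-genotype effect triplets and the population R-squared.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  geno <- .draw_genotypes(spec)
  cov <- .draw_covariates(spec)
  design <- covariate_design(cov)
  n <- spec$n_subjects

  lp <- list()
  for (lip in c("tc", "hdl", "tg")) {
    m <- spec$lipid_models[[lip]]
    eta <- rep(m$intercept, n)
    for (snp in names(m$snp_effects))
      eta <- eta + m$snp_effects[[snp]][geno[, snp] + 1L]
    for (v in names(m$covar_beta))
      eta <- eta + m$covar_beta[[v]] * design[[v]]
    lp[[lip]] <- eta
  }
  noise <- list(
    tc = stats::rnorm(n, 0, spec$lipid_models$tc$residual_sd),
    hdl = stats::rnorm(n, 0, spec$lipid_models$hdl$residual_sd),
    tg = stats::rnorm(n, 0, spec$lipid_models$tg$residual_sd)
  )
  for (it in 1:200) {
    tc <- lp$tc + noise$tc; hdl <- lp$hdl + noise$hdl; tg <- lp$tg + noise$tg
    ldl <- tc - hdl - tg / 5
    bad <- tc <= 0 | hdl <= 0 | tg <= 0 | ldl <= 0
    if (!any(bad)) break
    for (lip in c("tc", "hdl", "tg"))
      noise[[lip]][bad] <- stats::rnorm(sum(bad), 0,
                                        spec$lipid_models[[lip]]$residual_sd)
  }
  if (any(bad))
    .fail("could not draw positive lipid panels; check the spec's moments")

  cohort <- cbind(
    cov[1:8],
    data.frame(tc = tc, hdl = hdl, ldl = ldl, tg = tg),
    cov[9:ncol(cov)]
  )

  truth <- list()
  for (lip in c("tc", "hdl", "tg")) {
    m <- spec$lipid_models[[lip]]
    truth[[lip]] <- list(
      causal = names(m$snp_effects), effects = m$snp_effects,
      covar_beta = m$covar_beta, intercept = m$intercept,
      residual_sd = m$residual_sd, r2 = population_r2(spec, lip)
    )
  }
  comb <- .ldl_combined_model(spec)
  truth$ldl <- list(
    causal = names(comb$snp_effects), effects = comb$snp_effects,
    covar_beta = comb$covar_beta, intercept = NA_real_,
    residual_sd = sqrt(comb$residual_var), r2 = population_r2(spec, "ldl")
  )

  structure(list(cohort = cohort, genotypes = geno, truth = truth,
                 spec = spec),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$cohort), "subjects,",
      ncol(x$genotypes), "SNPs (seed", x$spec$seed, ")\n")
  for (lip in LIPIDS) {
    t <- x$truth[[lip]]
    cat(sprintf("  %-3s mean %.1f sd %.1f | %d causal SNP(s), population R2 %.3f\n",
                toupper(lip), mean(x$cohort[[lip]]), stats::sd(x$cohort[[lip]]),
                length(t$causal), t$r2))
  }
  invisible(x)
}
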