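## Simulation specifications for synthetic genotype + phenotype cohorts.
##
## A spec fully determines a cohort given a seed: a SNP panel (MAF and
## inbreeding coefficient F per SNP), generating linear models for the
## three measured lipids (TC, HDL-c, TG; LDL-c is always derived by
## Friedewald, never simulated), and marginal distributions for the
## lifestyle/adiposity covariates.

#' Build a SNP panel table
#'
#' @param n number of SNPs.
#' @param maf minor-allele frequencies, recycled to length `n`; each in
#'   (0, 0.5].
#' @param f inbreeding coefficients, recycled; each in \[0, 1\]. F = 0 is
#'   Hardy-Weinberg equilibrium; F > 0 produces a heterozygote deficit.
#' @param rsid,gene optional labels; synthetic defaults are generated.
#' @return data.frame with columns `rsid`, `gene`, `ref`, `alt`, `maf`, `f`.
#' @export
snp_panel <- function(n, maf = 0.3, f = 0,
                      rsid = NULL, gene = NULL) {
  if (!is.numeric(n) || n < 1) .fail("'n' must be a positive count")
  maf <- rep_len(maf, n)
  f <- rep_len(f, n)
  if (any(maf <= 0 | maf > 0.5))
    .fail("MAF must lie in (0, 0.5]")
  if (any(f < 0 | f > 1))
    .fail("inbreeding coefficient F must lie in [0, 1]")
  if (is.null(rsid)) rsid <- sprintf("rs%06d", 100000L + seq_len(n))
  if (anyDuplicated(rsid)) .fail("rsIDs must be unique")
  if (is.null(gene)) gene <- sprintf("GENE%02d", ((seq_len(n) - 1L) %% 30L) + 1L)
  bases <- c("A", "C", "G", "T")
  ref <- bases[((seq_len(n) - 1L) %% 4L) + 1L]
  alt <- bases[(seq_len(n) %% 4L) + 1L]
  data.frame(rsid = rsid, gene = gene, ref = ref, alt = alt,
             maf = maf, f = f, stringsAsFactors = FALSE)
}

## default marginal covariate distributions (means/SDs on the scale of a
## middle-aged overweight/obese European cohort; mg/dl, kg, kcal/d)
default_covariates <- function() {
  list(
    age = c(mean = 45.8, sd = 10.5), age_min = 18,
    sex_prop_male = 92 / 304,
    weight = c(mean = 87.7, sd = 13.0),
    bmi = c(mean = 31.6, sd = 3.5),
    tfat = c(mean = 36.9, sd = 7.6),
    vfat = c(mean = 1.48, sd = 0.90),     # gamma-distributed (positive, skewed)
    glucose = c(mean = 96.6, sd = 14.1),
    energy = c(mean = 2970, sd = 934), energy_min = 500,
    carb_pct = c(mean = 40.7, sd = 6.8),
    prot_pct = c(mean = 17.0, sd = 2.9),
    fat_pct = c(mean = 40.4, sd = 5.8),
    chol_intake = c(mean = 350, sd = 120),
    mets = c(mean = 23.8, sd = 20.0),     # gamma-distributed
    smoker_prev = 0.219,
    drinker_prev = 0.135
  )
}

#' Construct a cohort simulation specification
#'
#' @param n_subjects number of subjects.
#' @param snps SNP panel from [snp_panel()].
#' @param lipid_models named list with elements `tc`, `hdl`, `tg`; each a
#'   list with `intercept` (mg/dl), `covar_beta` (named numeric over design
#'   variables; energy enters as `energy100`, kcal/100), `snp_effects`
#'   (named list, each a length-3 numeric: mg/dl shift for genotypes
#'   0/1/2 — arbitrary, so non-additive and heterozygote-advantage
#'   patterns are expressible) and `residual_sd` (mg/dl, > 0). LDL-c has
#'   no model of its own: it is derived by Friedewald from the other
#'   three.
#' @param covariates marginal distribution list; see
#'   `lipidgrs:::default_covariates()` for the expected fields.
#' @param adiposity_cor optional correlation in \[0, 1) imposed on the
#'   (bmi, tfat, vfat) block through a Gaussian copula; default 0
#'   (independent draws).
#' @param seed integer seed; every simulation from this spec is a pure
#'   function of it.
#' @return object of class `"sim_spec"`.
#' @export
simulation_spec <- function(n_subjects, snps, lipid_models,
                            covariates = default_covariates(),
                            adiposity_cor = 0, seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1)
    .fail("'n_subjects' must be a positive count")
  if (!is.data.frame(snps) ||
      !all(c("rsid", "maf", "f") %in% names(snps)))
    .fail("'snps' must be a snp_panel() data.frame")
  if (any(snps$maf <= 0 | snps$maf > 0.5)) .fail("MAF must lie in (0, 0.5]")
  if (any(snps$f < 0 | snps$f > 1)) .fail("F must lie in [0, 1]")
  if (!all(c("tc", "hdl", "tg") %in% names(lipid_models)))
    .fail("'lipid_models' needs elements tc, hdl, tg")
  if ("ldl" %in% names(lipid_models))
    .fail("LDL-c is derived by the Friedewald equation; do not give it a generating model")
  for (lip in c("tc", "hdl", "tg")) {
    m <- lipid_models[[lip]]
    .assert_scalar_number(m$intercept, paste0(lip, "$intercept"))
    .assert_scalar_number(m$residual_sd, paste0(lip, "$residual_sd"))
    if (m$residual_sd <= 0) .fail("residual SD must be > 0 (%s)", lip)
    if (length(m$snp_effects)) {
      missing_snps <- setdiff(names(m$snp_effects), snps$rsid)
      if (length(missing_snps))
        .fail("effect triplet given for SNP(s) absent from the panel: %s",
              paste(missing_snps, collapse = ", "))
      if (!all(vapply(m$snp_effects, length, 1L) == 3L))
        .fail("each snp_effects entry must be a length-3 genotype triplet")
    }
  }
  if (adiposity_cor < 0 || adiposity_cor >= 1)
    .fail("'adiposity_cor' must be in [0, 1)")
  sds <- unlist(lapply(covariates, function(x)
    if (is.numeric(x) && "sd" %in% names(x)) x[["sd"]] else NULL))
  if (any(sds < 0)) .fail("covariate SDs must be >= 0")
  structure(
    list(n_subjects = as.integer(n_subjects), snps = snps,
         lipid_models = lipid_models, covariates = covariates,
         adiposity_cor = adiposity_cor, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Cohort simulation spec:", x$n_subjects, "subjects,",
      nrow(x$snps), "SNPs, seed", x$seed, "\n")
  for (lip in c("tc", "hdl", "tg")) {
    m <- x$lipid_models[[lip]]
    cat(sprintf(
      "  %-3s intercept %.1f, %d causal SNP(s), %d covariate(s), residual SD %.1f (pop R2 %.3f)\n",
      toupper(lip), m$intercept, length(m$snp_effects),
      length(m$covar_beta), m$residual_sd, population_r2(x, lip)))
  }
  invisible(x)
}

## moments of a normal truncated below at 'lower'
.tnorm_moments <- function(mu, sigma, lower) {
  if (sigma == 0) return(c(mean = mu, var = 0))
  a <- (lower - mu) / sigma
  lam <- stats::dnorm(a) / (1 - stats::pnorm(a))
  c(mean = mu + sigma * lam,
    var = sigma^2 * (1 + a * lam - lam^2))
}

## mean and variance of each model design variable implied by the spec
## (accounting for truncation / the gamma marginals actually drawn)
design_moments <- function(spec) {
  cv <- spec$covariates
  tn <- function(key, lower = 0) {
    .tnorm_moments(cv[[key]][["mean"]], cv[[key]][["sd"]], lower)
  }
  gam <- function(key) c(mean = cv[[key]][["mean"]], var = cv[[key]][["sd"]]^2)
  bern <- function(p) c(mean = p, var = p * (1 - p))
  en <- tn("energy", cv$energy_min %||% 500)
  out <- rbind(
    age = tn("age", cv$age_min %||% 18),
    sex = bern(cv$sex_prop_male),
    weight = tn("weight"),
    bmi = tn("bmi"),
    tfat = tn("tfat"),
    vfat = gam("vfat"),
    glucose = tn("glucose"),
    energy100 = c(en[["mean"]] / 100, en[["var"]] / 1e4),
    carb_pct = c(cv$carb_pct[["mean"]], cv$carb_pct[["sd"]]^2),
    prot_pct = tn("prot_pct"),
    fat_pct = tn("fat_pct"),
    chol_intake = tn("chol_intake"),
    mets = gam("mets"),
    smoker = bern(cv$smoker_prev),
    drinker = bern(cv$drinker_prev)
  )
  colnames(out) <- c("mean", "var")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## per-SNP mean and variance of a genotype effect triplet under (maf, F)
.triplet_moments <- function(effects, maf, f) {
  p <- genotype_freqs(maf, f)
  mu <- sum(p * effects)
  c(mean = mu, var = sum(p * effects^2) - mu^2)
}

## explained variance (genotype + covariate, independence across terms)
## and the pieces needed for intercept/R2 arithmetic
.model_moments <- function(spec, lipid) {
  stopifnot(lipid %in% c("tc", "hdl", "tg"))
  m <- spec$lipid_models[[lipid]]
  dm <- design_moments(spec)
  g_mean <- 0; g_var <- 0
  for (snp in names(m$snp_effects)) {
    i <- match(snp, spec$snps$rsid)
    tm <- .triplet_moments(m$snp_effects[[snp]], spec$snps$maf[i], spec$snps$f[i])
    g_mean <- g_mean + tm[["mean"]]; g_var <- g_var + tm[["var"]]
  }
  c_mean <- 0; c_var <- 0
  if (length(m$covar_beta)) {
    vars <- names(m$covar_beta)
    bad <- setdiff(vars, rownames(dm))
    if (length(bad)) .fail("unknown design variable(s): %s", paste(bad, collapse = ", "))
    c_mean <- sum(m$covar_beta * dm[vars, "mean"])
    c_var <- sum(m$covar_beta^2 * dm[vars, "var"])
    if (spec$adiposity_cor > 0) {
      adip <- intersect(vars, c("bmi", "tfat", "vfat"))
      if (length(adip) > 1) {
        for (i in seq_along(adip)[-1]) for (j in seq_len(i - 1)) {
          vi <- adip[i]; vj <- adip[j]
          c_var <- c_var + 2 * m$covar_beta[[vi]] * m$covar_beta[[vj]] *
            spec$adiposity_cor * sqrt(dm[vi, "var"] * dm[vj, "var"])
        }
      }
    }
  }
  c(lp_mean = m$intercept + g_mean + c_mean,
    explained_var = g_var + c_var,
    residual_var = m$residual_sd^2)
}

#' Population R-squared of a generating lipid model
#'
#' The fraction of a lipid's variance attributable to its generating
#' predictors (genotype triplets plus covariates), computed analytically
#' from the spec. For LDL-c the generating model is the Friedewald
#' combination of the TC, HDL-c and TG models.
#'
#' @param spec a [simulation_spec()].
#' @param lipid one of `"tc"`, `"hdl"`, `"tg"`, `"ldl"`.
#' @return scalar in \[0, 1\].
#' @export
population_r2 <- function(spec, lipid = c("tc", "hdl", "tg", "ldl")) {
  lipid <- match.arg(lipid)
  if (lipid != "ldl") {
    mm <- .model_moments(spec, lipid)
    return(unname(mm["explained_var"] / (mm["explained_var"] + mm["residual_var"])))
  }
  comb <- .ldl_combined_model(spec)
  dm <- design_moments(spec)
  g_var <- 0
  for (snp in names(comb$snp_effects)) {
    i <- match(snp, spec$snps$rsid)
    g_var <- g_var + .triplet_moments(comb$snp_effects[[snp]],
                                      spec$snps$maf[i], spec$snps$f[i])[["var"]]
  }
  c_var <- if (length(comb$covar_beta))
    sum(comb$covar_beta^2 * dm[names(comb$covar_beta), "var"]) else 0
  (g_var + c_var) / (g_var + c_var + comb$residual_var)
}

## the generating model for derived LDL-c: ldl = tc - hdl - tg/5 applied
## to the three linear predictors and independent noises
.ldl_combined_model <- function(spec) {
  w <- c(tc = 1, hdl = -1, tg = -0.2)
  snp_eff <- list(); covar <- numeric(0)
  for (lip in names(w)) {
    m <- spec$lipid_models[[lip]]
    for (snp in names(m$snp_effects)) {
      cur <- snp_eff[[snp]] %||% c(0, 0, 0)
      snp_eff[[snp]] <- cur + w[[lip]] * m$snp_effects[[snp]]
    }
    for (v in names(m$covar_beta)) {
      covar[v] <- (if (v %in% names(covar)) covar[[v]] else 0) +
        w[[lip]] * m$covar_beta[[v]]
    }
  }
  snp_eff <- Filter(function(e) any(abs(e - e[1]) > 1e-12), snp_eff)
  covar <- covar[abs(covar) > 1e-12]
  list(
    snp_effects = snp_eff, covar_beta = covar,
    residual_var = spec$lipid_models$tc$residual_sd^2 +
      spec$lipid_models$hdl$residual_sd^2 +
      spec$lipid_models$tg$residual_sd^2 / 25
  )
}

#' Default study-conditions simulation spec
#'
#' A 304-subject, 95-SNP cohort whose lipid and covariate marginals match
#' a middle-aged overweight/obese European study population (TC 216±38,
#' HDL-c 55.3±12.9, TG 104±56 mg/dl), with 10 causal SNPs per measured
#' lipid (two shared by all lipids), mixed dominant / recessive /
#' heterozygote-advantage genotype effect patterns, and covariate effects
#' of the magnitude seen in that population (e.g. +0.80 mg/dl TC per
#' year of age, +6.55 mg/dl TC per risk genotype). Intercepts and
#' residual SDs are solved analytically so that the population lipid
#' means and SDs hit the targets.
#'
#' @param seed integer seed.
#' @param n_subjects cohort size (default 304).
#' @param n_snps panel size (default 95).
#' @param effect_scale multiplier applied to all genotype effect triplets
#'   (1 = the default per-risk-genotype magnitudes: 6.55 TC, 1.12 HDL-c,
#'   4.20 TG mg/dl). Larger values create stronger, easier-to-recover
#'   genetic signal; residual SDs are re-solved to keep the target SDs.
#' @return a [simulation_spec()].
#' @export
default_simulation_spec <- function(seed = 1L, n_subjects = 304L,
                                    n_snps = 95L, effect_scale = 1) {
  snps <- snp_panel(n_snps, maf = rep_len(seq(0.10, 0.50, by = 0.05), n_snps))
  targets <- list(tc = c(216, 38), hdl = c(55.3, 12.9), tg = c(104, 56))
  magnitude <- c(tc = 6.55, hdl = 1.12, tg = 4.20) * effect_scale
  direction <- c(tc = 1, hdl = -1, tg = 1)
  ## dominant / recessive / heterozygote-advantage base patterns
  patterns <- list(c(0, 1, 1), c(0, 0, 1), c(1, 0, 1))
  pattern_of <- c(1, 1, 1, 1, 1, 1, 2, 2, 3, 3)   # 6 dom, 2 rec, 2 het-adv
  causal <- list(
    tc = seq_len(min(10L, n_snps)),
    hdl = c(1L, 2L, seq(11L, 18L)),
    tg = c(1L, 2L, seq(19L, 26L))
  )
  causal <- lapply(causal, function(i) i[i <= n_snps])
  covar_beta <- list(
    tc = c(age = 0.80, energy100 = 0.38),
    hdl = c(age = 0.22, sex = 4.51, energy100 = 0.18, prot_pct = 0.93,
            chol_intake = -0.01, drinker = 5.83, vfat = -5.22),
    tg = c(drinker = -19.21, tfat = -1.14, vfat = 30.95)
  )
  lipid_models <- list()
  for (lip in c("tc", "hdl", "tg")) {
    idx <- causal[[lip]]
    eff <- lapply(seq_along(idx), function(k) {
      direction[[lip]] * magnitude[[lip]] *
        patterns[[pattern_of[(k - 1L) %% 10L + 1L]]]
    })
    names(eff) <- snps$rsid[idx]
    lipid_models[[lip]] <- list(intercept = 0, covar_beta = covar_beta[[lip]],
                                snp_effects = eff, residual_sd = 1)
  }
  spec <- simulation_spec(n_subjects, snps, lipid_models, seed = seed)
  ## solve intercepts and residual SDs against the target moments
  for (lip in c("tc", "hdl", "tg")) {
    mm <- .model_moments(spec, lip)
    tgt <- targets[[lip]]
    resid_var <- tgt[2]^2 - mm[["explained_var"]]
    if (resid_var <= 0)
      .fail("genotype/covariate effects for %s exceed the target variance", lip)
    spec$lipid_models[[lip]]$residual_sd <- sqrt(resid_var)
    spec$lipid_models[[lip]]$intercept <-
      tgt[1] - (mm[["lp_mean"]] - spec$lipid_models[[lip]]$intercept)
  }
  spec
}

#' Read a simulation spec from a YAML or JSON config file
#'
#' The file mirrors the [simulation_spec()] arguments: `n_subjects`,
#' `seed`, `snps` (either a full table or `{n, maf, f}`), `lipid_models`
#' and optional `covariates` overrides. Missing parts fall back to the
#' defaults of [default_simulation_spec()] / `default_covariates()`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a [simulation_spec()].
#' @export
read_simulation_spec <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$n_subjects) && is.null(cfg$lipid_models))
    return(default_simulation_spec(seed = cfg$seed %||% 1L))
  snps <- if (is.data.frame(cfg$snps)) cfg$snps
  else snp_panel(cfg$snps$n %||% 95L, maf = cfg$snps$maf %||% 0.3,
                 f = cfg$snps$f %||% 0)
  lm_cfg <- lapply(cfg$lipid_models, function(m) {
    list(intercept = m$intercept,
         covar_beta = unlist(m$covar_beta) %||% numeric(0),
         snp_effects = lapply(m$snp_effects, as.numeric),
         residual_sd = m$residual_sd)
  })
  cov <- default_covariates()
  for (k in names(cfg$covariates)) cov[[k]] <- unlist(cfg$covariates[[k]])
  simulation_spec(cfg$n_subjects, snps, lm_cfg, covariates = cov,
                  adiposity_cor = cfg$adiposity_cor %||% 0,
                  seed = cfg$seed %||% 1L)
}
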