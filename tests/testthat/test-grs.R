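test_that("ANOVA prescreen F matches the textbook formula and aov", {
  fx <- make_groups(list(`0` = c(210, 220, 215, 225),
                         `1` = c(230, 228, 241, 235, 233),
                         `2` = c(250, 260, 255)))
  res <- anova_prescreen(fx$y, fx$g)
  # independent oracle: stats::aov
  av <- summary(aov(fx$y ~ factor(fx$g)))[[1]]
  expect_equal(res$F, av[1, "F value"], tolerance = 1e-12)
  expect_equal(res$p, av[1, "Pr(>F)"], tolerance = 1e-12)
  expect_true(res$keep)
})

test_that("prescreen discards flat SNPs and degenerate group structures", {
  set.seed(2)
  fx <- make_groups(list(`0` = rnorm(20, 216, 5), `1` = rnorm(20, 216, 5),
                         `2` = rnorm(20, 216, 5)))
  # identical means by construction at population level: mostly p >> 0.25
  res <- anova_prescreen(rep(c(1, 2), 30) + 0 * fx$g, fx$g)
  expect_false(res$keep)  # group means exactly equal -> F ~ 0
  res2 <- anova_prescreen(rnorm(10), rep(0, 10))
  expect_false(res2$keep)
  expect_match(res2$reason, "fewer than 2")
})

test_that("risk coding separates the adverse genotype (upward lipids)", {
  set.seed(31)
  fx <- make_groups(list(`0` = rnorm(40, 200, 8), `1` = rnorm(40, 201, 8),
                         `2` = rnorm(40, 230, 8)))
  cd <- code_genotype_risk(fx$y, fx$g, direction = 1)
  expect_s3_class(cd, "risk_coding")
  expect_identical(sort(cd$risk_genotypes), "2")
  expect_identical(unname(cd$map[c("0", "1", "2")]), c(0L, 0L, 1L))
})

test_that("risk direction reverses for HDL", {
  set.seed(32)
  fx <- make_groups(list(`0` = rnorm(40, 60, 4), `1` = rnorm(40, 62, 4),
                         `2` = rnorm(40, 48, 4)))
  cd <- code_genotype_risk(fx$y, fx$g, direction = -1)
  expect_identical(cd$risk_genotypes, "2")
})

test_that("heterozygote advantage groups both homozygotes as risk", {
  # HDL pattern (50, 60, 50): heterozygotes carry the favorable mean
  set.seed(33)
  fx <- make_groups(list(`0` = rnorm(50, 50, 4), `1` = rnorm(50, 60, 4),
                         `2` = rnorm(50, 50, 4)))
  cd <- code_genotype_risk(fx$y, fx$g, direction = -1)
  expect_identical(sort(cd$risk_genotypes), c("0", "2"))
  expect_identical(unname(cd$map[c("0", "1", "2")]), c(1L, 0L, 1L))

  # independent check of the grouping rule by enumerating all pairwise
  # post hoc decisions: anchor = most adverse mean; a genotype joins the
  # risk category iff its comparison with the anchor is non-significant
  groups <- split(fx$y, fx$g)
  pt <- pairwise.t.test(fx$y, factor(fx$g), p.adjust.method = "bonferroni",
                        pool.sd = TRUE)$p.value
  pair_p <- function(a, b) {
    if (!is.na(pt[as.character(max(a, b)), as.character(min(a, b))]))
      pt[as.character(max(a, b)), as.character(min(a, b))]
    else pt[as.character(min(a, b)), as.character(max(a, b))]
  }
  means <- sapply(groups, mean)
  anchor <- as.integer(names(which.min(means)))  # adverse = lowest for HDL
  expected_risk <- sort(c(anchor, Filter(function(g2)
    pair_p(anchor, g2) >= 0.05, setdiff(c(0, 1, 2), anchor))))
  expect_identical(sort(as.integer(cd$risk_genotypes)),
                   as.integer(expected_risk))
})

test_that("coding returns NULL when no comparison separates the categories", {
  set.seed(34)
  fx <- make_groups(list(`0` = rnorm(30, 216, 10), `1` = rnorm(30, 216, 10),
                         `2` = rnorm(30, 216, 10)))
  expect_null(code_genotype_risk(fx$y, fx$g, direction = 1))
})

test_that("undersized genotype groups merge into the nearest mean", {
  fx <- make_groups(list(`0` = c(200, 205, 210, 202, 208),
                         `1` = c(228, 232, 230, 229, 231),
                         `2` = 233))  # single subject, nearest to group 1
  expect_warning(cd <- code_genotype_risk(fx$y, fx$g, direction = 1),
                 "merged")
  expect_identical(cd$map[["2"]], cd$map[["1"]])
})

test_that("Dunnett's T3 is chosen under variance heterogeneity", {
  set.seed(35)
  fx <- make_groups(list(`0` = rnorm(60, 200, 1), `1` = rnorm(60, 203, 1),
                         `2` = rnorm(60, 230, 25)))
  cd <- code_genotype_risk(fx$y, fx$g, direction = 1)
  expect_identical(cd$posthoc, "DunnettT3")
  set.seed(36)
  fx2 <- make_groups(list(`0` = rnorm(60, 200, 8), `1` = rnorm(60, 203, 8),
                          `2` = rnorm(60, 230, 8)))
  cd2 <- code_genotype_risk(fx2$y, fx2$g, direction = 1)
  expect_identical(cd2$posthoc, "Bonferroni")
})

test_that("binarized t statistic matches the pooled-variance formula", {
  a <- c(228, 231, 235, 229, 233, 238)   # risk category values
  b <- c(210, 214, 208, 212, 215, 209)   # nonrisk
  fx <- make_groups(list(`0` = b, `2` = a))
  cd <- list(map = c(`0` = 0L, `2` = 1L), direction = 1)
  class(cd) <- "risk_coding"
  res <- binarized_t_select(fx$y, fx$g, cd)
  # closed-form pooled t computed independently
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_true(res$keep)
  # wrong direction: same data, HDL-style coding must NOT keep
  cd$direction <- -1
  expect_false(binarized_t_select(fx$y, fx$g, cd)$keep)
})

test_that("degenerate zero-variance equal-mean groups are dropped", {
  fx <- make_groups(list(`0` = rep(216, 10), `2` = rep(216, 10)))
  cd <- structure(list(map = c(`0` = 0L, `2` = 1L), direction = 1),
                  class = "risk_coding")
  res <- binarized_t_select(fx$y, fx$g, cd)
  expect_equal(res$p, 1)
  expect_false(res$keep)
  # constant shift with tiny SD: p -> 0, kept
  fx2 <- make_groups(list(`0` = rep(216, 10) + rnorm(10, 0, 1e-6),
                          `2` = rep(230, 10) + rnorm(10, 0, 1e-6)))
  expect_true(binarized_t_select(fx2$y, fx2$g, cd)$keep)
})

test_that("prevalence filter excludes below 10% and keeps exactly 10%", {
  g <- c(rep(2L, 9), rep(0L, 91))
  cd <- structure(list(map = c(`0` = 0L, `2` = 1L), direction = 1),
                  class = "risk_coding")
  expect_false(prevalence_filter(g, cd)$keep)    # 9% risk -> excluded
  g2 <- c(rep(2L, 10), rep(0L, 90))
  expect_true(prevalence_filter(g2, cd)$keep)    # exactly 10% -> kept
})

test_that("GRS equals the hand-summed risk indicators on a written fixture", {
  geno <- matrix(c(
    0L, 1L, 2L, 0L, 1L,
    2L, 2L, 0L, 1L, 0L,
    1L, 0L, 1L, 2L, 2L,
    0L, 0L, 0L, 0L, 0L
  ), nrow = 4, byrow = TRUE,
  dimnames = list(paste0("S", 1:4), paste0("snp", 1:5)))
  cd <- function(snp, risk) {
    map <- c(`0` = 0L, `1` = 0L, `2` = 0L)
    map[as.character(risk)] <- 1L
    structure(list(snp = snp, map = map, direction = 1),
              class = "risk_coding")
  }
  codings <- list(tc = list(cd("snp1", 2), cd("snp2", c(1, 2)),
                            cd("snp3", 0), cd("snp4", 1), cd("snp5", 2)))
  grs <- build_grs(codings, geno)
  # hand enumeration:
  # S1: snp1=0 no; snp2=1 yes; snp3=2 no; snp4=0 no; snp5=1 no  -> 1
  # S2: snp1=2 yes; snp2=2 yes; snp3=0 yes; snp4=1 yes; snp5=0 no -> 4
  # S3: snp1=1 no; snp2=0 no; snp3=1 no; snp4=2 no; snp5=2 yes -> 1
  # S4: all zero -> snp3 risk(0) yes -> 1
  expect_identical(grs$grs_tc, c(1L, 4L, 1L, 1L))
  # upper bound: subject carrying the risk genotype everywhere
  geno2 <- rbind(geno, S5 = c(2L, 2L, 0L, 1L, 2L))
  expect_identical(build_grs(codings, geno2)$grs_tc[5], 5L)
  # zero retained codings -> all-zero scores
  expect_identical(build_grs(list(tc = list()), geno)$grs_tc, rep(0L, 4))
  # unknown SNP -> error
  expect_error(build_grs(list(tc = list(cd("nope", 2))), geno), "absent")
})

test_that("missing genotype policies behave as configured", {
  geno <- matrix(c(2L, NA, 2L, 2L), 2, 2,
                 dimnames = list(c("S1", "S2"), c("a", "b")))
  cd <- function(snp) structure(
    list(snp = snp, map = c(`0` = 0L, `1` = 0L, `2` = 1L), direction = 1),
    class = "risk_coding")
  codings <- list(tc = list(cd("a"), cd("b")))
  cc <- build_grs(codings, geno, missing = "complete_case")
  expect_true(is.na(cc$grs_tc[2]))
  expect_identical(cc$grs_tc[1], 2L)
  obs <- build_grs(codings, geno, missing = "observed")
  expect_identical(obs$grs_tc, c(2L, 1L))
})

test_that("pipeline recovers a pleiotropic SNP into the four-way intersection", {
  # one SNP with strong adverse effects on TC, HDL (down) and TG -> its
  # Friedewald combination also shifts LDL; it must reach every GRS
  eff_snp <- "rs100001"
  spec <- make_test_spec(
    n = 304, n_snps = 12, maf = 0.3, seed = 41L,
    tc_effects = stats::setNames(list(c(0, 18, 18)), eff_snp),
    hdl_effects = stats::setNames(list(c(0, -6, -6)), eff_snp),
    tg_effects = stats::setNames(list(c(0, 25, 25)), eff_snp),
    tc_sd = 12, hdl_sd = 5, tg_sd = 20)
  sim <- simulate_cohort(spec)
  res <- suppressWarnings(run_grs_pipeline(sim$cohort, sim$genotypes))
  expect_true(eff_snp %in% res$venn$common)
  expect_true(all(res$grs$grs_tc >= 0, na.rm = TRUE))
  # audit: every SNP x lipid appears exactly once
  expect_equal(nrow(res$audit), 12 * 4)
  expect_true(all(table(res$audit$snp) == 4))
})

test_that("GRS is invariant to SNP and subject ordering", {
  spec <- make_test_spec(
    n = 150, n_snps = 8, maf = 0.3, seed = 42L,
    tc_effects = list(rs100001 = c(0, 15, 15), rs100003 = c(0, 0, 20)),
    tc_sd = 10)
  sim <- simulate_cohort(spec)
  res1 <- suppressWarnings(run_grs_pipeline(sim$cohort, sim$genotypes))
  perm_snp <- sample(ncol(sim$genotypes))
  perm_sub <- sample(nrow(sim$cohort))
  geno2 <- sim$genotypes[perm_sub, perm_snp]
  cohort2 <- sim$cohort[perm_sub, ]
  res2 <- suppressWarnings(run_grs_pipeline(cohort2, geno2))
  m <- match(res1$grs$subject_id, res2$grs$subject_id)
  expect_identical(res1$grs$grs_tc, res2$grs$grs_tc[m])
  expect_setequal(names(res1$codings$tc), names(res2$codings$tc))
})

test_that("tightening thresholds never enlarges the retained SNP set", {
  spec <- make_test_spec(
    n = 200, n_snps = 10, maf = 0.3, seed = 43L,
    tc_effects = list(rs100001 = c(0, 8, 8), rs100002 = c(0, 0, 12),
                      rs100005 = c(0, 4, 6)),
    tc_sd = 14)
  sim <- simulate_cohort(spec)
  loose <- suppressWarnings(run_grs_pipeline(
    sim$cohort, sim$genotypes, grs_config(alpha_keep = 0.25, alpha_trend = 0.10)))
  tight <- suppressWarnings(run_grs_pipeline(
    sim$cohort, sim$genotypes, grs_config(alpha_keep = 0.10, alpha_trend = 0.02)))
  for (lip in c("tc", "ldl", "hdl", "tg")) {
    expect_true(all(names(tight$codings[[lip]]) %in%
                      names(loose$codings[[lip]])))
  }
})

test_that("additive effects place the adverse homozygote in the risk set", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    spec <- make_test_spec(
      n = 250, n_snps = 4, maf = 0.35, seed = 50L + s,
      tc_effects = list(rs100002 = c(0, 9, 18)), tc_sd = 12)
    sim <- simulate_cohort(spec)
    res <- suppressWarnings(run_grs_pipeline(sim$cohort, sim$genotypes))
    cd <- res$codings$tc[["rs100002"]]
    if (!is.null(cd)) {
      total <- total + 1
      if ("2" %in% cd$risk_genotypes) hits <- hits + 1
    }
  }
  expect_gt(total, 5)
  expect_equal(hits, total)  # adverse homozygote always inside when retained
})

test_that("venn summary set algebra is exact on a constructed case", {
  sets <- list(tc = c("a", "b", "c", "x"), ldl = c("a", "d", "x"),
               hdl = c("e", "f", "x"), tg = c("x", "g"))
  v <- venn_summary(sets)
  expect_identical(v$common, "x")
  expect_identical(sort(v$exclusive$tc), c("b", "c"))
  expect_equal(v$n_exclusive_total, 2 + 1 + 2 + 1)
  expect_identical(sort(v$pairwise[["tc:ldl"]]), c("a", "x"))
})
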