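## Phenotype-driven genotype risk coding and genetic risk scores.
##
## Per lipid trait and SNP the pipeline is:
##   1. ANOVA prescreen across genotype groups (discard P > 0.25);
##   2. post hoc risk coding: Levene's test picks Bonferroni (equal
##      variances) or Dunnett's T3 (unequal); the genotype with the most
##      adverse mean anchors the risk category and genotypes not
##      significantly different from it are grouped in;
##   3. two-sample t-test of the lipid by risk category, keeping SNPs
##      with at least a marginal trend (P < 0.10) in the adverse
##      direction;
##   4. prevalence filter: both categories must hold >= 10% of subjects;
##   5. the per-lipid GRS is the subject's count of risk genotypes over
##      the retained SNPs.

#' Default configuration for the GRS pipeline
#'
#' @param alpha_keep ANOVA prescreen retention threshold (keep p <=
#'   `alpha_keep`; default 0.25).
#' @param alpha_posthoc significance level declaring two genotype means
#'   "different" in the post hoc grouping (default 0.05).
#' @param alpha_trend binarized t-test threshold (keep p < `alpha_trend`;
#'   default 0.10).
#' @param min_prop minimum prevalence of each risk/nonrisk category
#'   (exclude if either proportion < `min_prop`; default 0.10).
#' @param levene_alpha Levene threshold below which variances are treated
#'   as unequal and Dunnett's T3 replaces Bonferroni (default 0.05).
#' @param anchor `"adverse"` groups genotypes by non-significance against
#'   the most adverse mean (default); `"favorable"` anchors the grouping
#'   at the most favorable mean instead.
#' @param missing `"complete_case"` (default) gives a subject `NA` on a
#'   lipid's GRS if any contributing genotype is missing;
#'   `"observed"` sums over the observed SNPs.
#' @return a named list of class `"grs_config"`.
#' @export
grs_config <- function(alpha_keep = 0.25, alpha_posthoc = 0.05,
                       alpha_trend = 0.10, min_prop = 0.10,
                       levene_alpha = 0.05,
                       anchor = c("adverse", "favorable"),
                       missing = c("complete_case", "observed")) {
  structure(list(
    alpha_keep = alpha_keep, alpha_posthoc = alpha_posthoc,
    alpha_trend = alpha_trend, min_prop = min_prop,
    levene_alpha = levene_alpha, anchor = match.arg(anchor),
    missing = match.arg(missing)
  ), class = "grs_config")
}

#' One-way ANOVA prescreen of a SNP against a lipid
#'
#' Fixed-effects one-way ANOVA of the lipid across genotype groups;
#' the SNP is kept when p <= `alpha_keep` (the discard rule is
#' "clearly not associated", p > 0.25).
#'
#' @param y numeric lipid values.
#' @param g genotype vector (0/1/2; NA allowed).
#' @param alpha_keep retention threshold (default 0.25).
#' @return list with `keep`, `F`, `p`, `df`, and `reason` when
#'   auto-discarded (fewer than 2 populated groups).
#' @export
anova_prescreen <- function(y, g, alpha_keep = 0.25) {
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  groups <- split(y, g)
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L)
    return(list(keep = FALSE, F = NA_real_, p = NA_real_,
                df = c(NA_real_, NA_real_), reason = "fewer than 2 genotype groups"))
  if (any(lengths(groups) < 2L) && sum(lengths(groups) >= 2L) < 2L)
    return(list(keep = FALSE, F = NA_real_, p = NA_real_,
                df = c(NA_real_, NA_real_), reason = "fewer than 2 groups with >= 2 subjects"))
  n <- length(y); k <- length(groups)
  grand <- mean(y)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  df1 <- k - 1; df2 <- n - k
  if (ssw <= 0) {
    f <- if (ssb <= 0) 0 else Inf
  } else f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(keep = p <= alpha_keep, F = f, p = p, df = c(df1, df2), reason = NULL)
}

## Dunnett's T3 pairwise p-values: Welch t statistics referred to the
## studentized maximum modulus distribution, approximated by the
## independence (Sidak-type) form 1 - (2*pt(|t|, df) - 1)^k
.dunnett_t3 <- function(groups) {
  ids <- names(groups)
  k <- length(ids) * (length(ids) - 1) / 2
  out <- list()
  for (i in seq_along(ids)[-1]) for (j in seq_len(i - 1)) {
    a <- groups[[ids[i]]]; b <- groups[[ids[j]]]
    va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
    se <- sqrt(va + vb)
    if (se == 0) {
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      t <- (mean(a) - mean(b)) / se
      df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
      p_unadj <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
      p <- 1 - (1 - p_unadj)^k
    }
    out[[paste(ids[i], ids[j], sep = "-")]] <- p
  }
  out
}

## Bonferroni pairwise p-values with a pooled error variance
.bonferroni_pairwise <- function(groups) {
  ids <- names(groups)
  k <- length(ids) * (length(ids) - 1) / 2
  n <- sum(lengths(groups))
  df <- n - length(groups)
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0)) / df
  out <- list()
  for (i in seq_along(ids)[-1]) for (j in seq_len(i - 1)) {
    a <- groups[[ids[i]]]; b <- groups[[ids[j]]]
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    if (se == 0) {
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      t <- (mean(a) - mean(b)) / se
      p <- min(1, k * 2 * stats::pt(abs(t), df, lower.tail = FALSE))
    }
    out[[paste(ids[i], ids[j], sep = "-")]] <- p
  }
  out
}

#' Code a SNP's genotypes as risk / nonrisk from observed lipid means
#'
#' The genotype with the most adverse observed mean (highest for
#' TC/LDL-c/TG, lowest for HDL-c) anchors the risk category; genotypes
#' whose post hoc comparison against the anchor is non-significant join
#' it ("similar effects grouped in a single category"); the rest form the
#' nonrisk category. Variance homogeneity (Levene) chooses between
#' Bonferroni-adjusted pooled-t comparisons and Dunnett's T3 Welch
#' comparisons. Returns `NULL` when no post hoc comparison separates the
#' resulting categories.
#'
#' @param y numeric lipid values.
#' @param g genotype vector (0/1/2; NA allowed).
#' @param direction `+1` when the adverse shift is upward (TC, LDL-c,
#'   TG), `-1` when downward (HDL-c).
#' @param config a [grs_config()].
#' @param snp,lipid optional labels carried into the result.
#' @return object of class `"risk_coding"` (list with the genotype ->
#'   0/1 map, stage statistics and the post hoc audit trail), or `NULL`.
#' @export
code_genotype_risk <- function(y, g, direction = 1, config = grs_config(),
                               snp = NA_character_, lipid = NA_character_) {
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- as.integer(g[ok])
  groups <- split(y, g)
  groups <- groups[lengths(groups) > 0L]
  ## merge undersized genotype groups into the nearest-mean group
  merged_into <- stats::setNames(names(groups), names(groups))
  repeat {
    sizes <- lengths(groups)
    if (length(groups) < 2L || all(sizes >= 2L)) break
    small <- names(groups)[which.min(sizes)]
    means <- vapply(groups, mean, 0)
    others <- setdiff(names(groups), small)
    target <- others[which.min(abs(means[others] - means[small]))]
    warning(sprintf("genotype %s has < 2 subjects; merged into genotype group %s",
                    small, target), call. = FALSE)
    groups[[target]] <- c(groups[[target]], groups[[small]])
    merged_into[merged_into == small] <- target
    groups[[small]] <- NULL
  }
  if (length(groups) < 2L) return(NULL)

  ## variance homogeneity -> post hoc family
  lev_p <- tryCatch({
    gi <- factor(rep(names(groups), lengths(groups)))
    yi <- unlist(groups, use.names = FALSE)
    car::leveneTest(yi, gi, center = mean)[1, "Pr(>F)"]
  }, error = function(e) NA_real_)
  method <- if (!is.na(lev_p) && lev_p < config$levene_alpha)
    "DunnettT3" else "Bonferroni"
  pairp <- if (method == "DunnettT3") .dunnett_t3(groups)
  else .bonferroni_pairwise(groups)

  means <- vapply(groups, mean, 0)
  anchor_side <- if (config$anchor == "adverse") direction else -direction
  anchor <- names(which.max(anchor_side * means))
  pair_p <- function(a, b) {
    pairp[[paste(a, b, sep = "-")]] %||% pairp[[paste(b, a, sep = "-")]]
  }
  anchor_cat <- anchor
  for (gname in setdiff(names(groups), anchor)) {
    if (pair_p(anchor, gname) >= config$alpha_posthoc)
      anchor_cat <- c(anchor_cat, gname)
  }
  other_cat <- setdiff(names(groups), anchor_cat)
  if (!length(other_cat)) return(NULL)
  ## the anchor category is the risk one when anchored at the adverse
  ## mean, the nonrisk one when anchored at the favorable mean
  if (config$anchor == "adverse") {
    risk_groups <- anchor_cat; nonrisk_groups <- other_cat
  } else {
    risk_groups <- other_cat; nonrisk_groups <- anchor_cat
  }
  ## at least one significant comparison must separate the categories
  separated <- any(vapply(risk_groups, function(a)
    any(vapply(nonrisk_groups, function(b)
      pair_p(a, b) < config$alpha_posthoc, TRUE)), TRUE))
  if (!separated) return(NULL)

  map <- stats::setNames(integer(length(merged_into)), names(merged_into))
  map[] <- as.integer(merged_into %in% risk_groups)
  structure(list(
    snp = snp, lipid = lipid, direction = direction,
    map = map, risk_genotypes = names(map)[map == 1L],
    group_means = means, group_n = lengths(groups),
    levene_p = lev_p, posthoc = method, pairwise_p = unlist(pairp),
    anchor = anchor
  ), class = "risk_coding")
}

#' @export
print.risk_coding <- function(x, ...) {
  cat(sprintf("Risk coding%s%s: risk genotype(s) {%s} [%s]\n",
              if (is.na(x$snp)) "" else paste0(" ", x$snp),
              if (is.na(x$lipid)) "" else paste0(" / ", toupper(x$lipid)),
              paste(x$risk_genotypes, collapse = ","), x$posthoc))
  print(round(rbind(mean = x$group_means, n = x$group_n), 2))
  invisible(x)
}

#' Binarized t-test selection of a coded SNP
#'
#' Pooled-variance two-sample t-test of the lipid between the risk and
#' nonrisk categories; the SNP is kept when p < `alpha_trend` (marginal
#' trend) and the observed mean difference lies in the adverse direction.
#'
#' @param y numeric lipid values.
#' @param g genotype vector.
#' @param coding a [code_genotype_risk()] result.
#' @param alpha_trend threshold (default 0.10).
#' @return list with `keep`, `t`, `p`, `mean_risk`, `mean_nonrisk`.
#' @export
binarized_t_select <- function(y, g, coding, alpha_trend = 0.10) {
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- as.character(g[ok])
  risk <- coding$map[g] == 1L
  a <- y[risk]; b <- y[!risk]
  if (!length(a) || !length(b))
    .fail("both risk and nonrisk categories must be nonempty")
  if (stats::var(a) + stats::var(b) == 0 && mean(a) == mean(b))
    return(list(keep = FALSE, t = 0, p = 1,
                mean_risk = mean(a), mean_nonrisk = mean(b)))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  right_sign <- coding$direction * (mean(a) - mean(b)) > 0
  list(keep = tt$p.value < alpha_trend && right_sign,
       t = unname(tt$statistic), p = tt$p.value,
       mean_risk = mean(a), mean_nonrisk = mean(b))
}

#' Prevalence filter on a risk coding
#'
#' Excludes SNPs for which either the risk or the nonrisk category holds
#' fewer than `min_prop` of the genotyped subjects (model-instability
#' guard).
#'
#' @param g genotype vector.
#' @param coding a [code_genotype_risk()] result.
#' @param min_prop minimum category proportion (default 0.10; the rule
#'   excludes strictly below it, so exactly 10% is kept).
#' @return list with `keep`, `prop_risk`, `prop_nonrisk`.
#' @export
prevalence_filter <- function(g, coding, min_prop = 0.10) {
  g <- as.character(g[!is.na(g)])
  prop_risk <- mean(coding$map[g] == 1L)
  list(keep = prop_risk >= min_prop && (1 - prop_risk) >= min_prop,
       prop_risk = prop_risk, prop_nonrisk = 1 - prop_risk)
}

#' Sum risk genotypes into genetic risk scores
#'
#' @param codings named list (by lipid) of lists of `risk_coding`
#'   objects.
#' @param geno genotype matrix.
#' @param missing missing-genotype policy, see [grs_config()].
#' @return data.frame: `subject_id` plus one integer GRS column per
#'   lipid (`grs_tc`, ...). `NA` under the complete-case policy when a
#'   contributing genotype is missing.
#' @export
build_grs <- function(codings, geno,
                      missing = c("complete_case", "observed")) {
  missing <- match.arg(missing)
  out <- data.frame(subject_id = rownames(geno), stringsAsFactors = FALSE)
  for (lipid in names(codings)) {
    score <- rep(0L, nrow(geno))
    na_mask <- rep(FALSE, nrow(geno))
    for (cd in codings[[lipid]]) {
      if (!cd$snp %in% colnames(geno))
        .fail("coding references SNP '%s' absent from the genotype matrix", cd$snp)
      g <- geno[, cd$snp]
      risk <- cd$map[as.character(g)] == 1L
      miss <- is.na(g) | is.na(risk)
      na_mask <- na_mask | miss
      risk[miss] <- FALSE
      score <- score + as.integer(risk)
    }
    if (missing == "complete_case") score[na_mask] <- NA_integer_
    out[[paste0("grs_", lipid)]] <- score
  }
  out
}

#' Run the full GRS construction pipeline
#'
#' Executes prescreen -> risk coding -> binarized t selection ->
#' prevalence filter -> summation for each of the four lipid traits, and
#' assembles the per-stage audit trail plus the Venn set algebra of the
#' per-lipid SNP association sets.
#'
#' @param cohort cohort data.frame with columns `subject_id`, `tc`,
#'   `ldl`, `hdl`, `tg`.
#' @param geno genotype matrix aligned to the cohort (matching subject
#'   IDs in the rownames).
#' @param config a [grs_config()].
#' @return object of class `"grs_result"`: `grs` (data.frame of the four
#'   scores), `codings` (retained codings per lipid), `audit`
#'   (per SNP x lipid stage log), `stage_counts`, `venn`.
#' @export
run_grs_pipeline <- function(cohort, geno, config = grs_config()) {
  if (!all(c("subject_id", LIPIDS) %in% names(cohort)))
    .fail("cohort must contain subject_id, tc, ldl, hdl, tg")
  mismatch <- c(setdiff(cohort$subject_id, rownames(geno)),
                setdiff(rownames(geno), cohort$subject_id))
  if (length(mismatch))
    .fail("subject IDs differ between cohort and genotypes: %s",
          paste(utils::head(mismatch, 5), collapse = ", "))
  geno <- geno[cohort$subject_id, , drop = FALSE]

  audit <- list()
  codings <- stats::setNames(vector("list", length(LIPIDS)), LIPIDS)
  for (lipid in LIPIDS) {
    y <- cohort[[lipid]]
    dir <- ADVERSE_DIRECTION[[lipid]]
    keep_codings <- list()
    for (snp in colnames(geno)) {
      g <- geno[, snp]
      rec <- data.frame(snp = snp, lipid = lipid, stage = NA_character_,
                        anova_p = NA_real_, t_p = NA_real_,
                        prop_risk = NA_real_, retained = FALSE,
                        reason = NA_character_)
      pre <- anova_prescreen(y, g, config$alpha_keep)
      rec$anova_p <- pre$p
      if (!pre$keep) {
        rec$stage <- "prescreen"
        rec$reason <- pre$reason %||% "ANOVA p > alpha_keep"
        audit[[length(audit) + 1L]] <- rec
        next
      }
      cd <- withCallingHandlers(
        code_genotype_risk(y, g, dir, config, snp = snp, lipid = lipid),
        warning = function(w) invokeRestart("muffleWarning"))
      if (is.null(cd)) {
        rec$stage <- "coding"; rec$reason <- "no genotype separation in post hoc tests"
        audit[[length(audit) + 1L]] <- rec
        next
      }
      ts <- binarized_t_select(y, g, cd, config$alpha_trend)
      rec$t_p <- ts$p
      if (!ts$keep) {
        rec$stage <- "t_select"; rec$reason <- "no marginal trend (p >= alpha_trend or wrong direction)"
        audit[[length(audit) + 1L]] <- rec
        next
      }
      pv <- prevalence_filter(g, cd, config$min_prop)
      rec$prop_risk <- pv$prop_risk
      if (!pv$keep) {
        rec$stage <- "prevalence"; rec$reason <- "category prevalence < min_prop"
        audit[[length(audit) + 1L]] <- rec
        next
      }
      rec$stage <- "final"; rec$retained <- TRUE
      audit[[length(audit) + 1L]] <- rec
      keep_codings[[snp]] <- cd
    }
    codings[[lipid]] <- keep_codings
  }
  audit <- do.call(rbind, audit)

  stage_counts <- do.call(rbind, lapply(LIPIDS, function(lipid) {
    a <- audit[audit$lipid == lipid, ]
    data.frame(
      lipid = lipid,
      screened = sum(a$stage != "prescreen" | a$retained),
      coded = sum(!a$stage %in% c("prescreen", "coding")),
      t_selected = sum(!a$stage %in% c("prescreen", "coding", "t_select")),
      prevalence_excluded = sum(a$stage == "prevalence"),
      final = sum(a$retained)
    )
  }))
  ## union counts across lipids per stage (how many distinct SNPs survive
  ## at least one lipid's filter at each stage)
  union_counts <- c(
    screened = length(unique(audit$snp[audit$stage != "prescreen"])),
    coded = length(unique(audit$snp[!audit$stage %in% c("prescreen", "coding")])),
    t_selected = length(unique(audit$snp[!audit$stage %in% c("prescreen", "coding", "t_select")])),
    final = length(unique(audit$snp[audit$retained]))
  )

  sets <- lapply(codings, names)
  venn <- venn_summary(sets)
  grs <- build_grs(codings, geno, missing = config$missing)
  structure(list(grs = grs, codings = codings, audit = audit,
                 stage_counts = stage_counts, union_counts = union_counts,
                 venn = venn, config = config),
            class = "grs_result")
}

#' Set algebra of per-lipid SNP association sets
#'
#' @param sets named list of character vectors (SNPs per lipid).
#' @return list with per-lipid sizes, exclusive SNPs per lipid, the
#'   total exclusive count, all pairwise intersections and the common
#'   (all-sets) intersection.
#' @export
venn_summary <- function(sets) {
  all_snps <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_snps %in% s,
                       logical(length(all_snps)))
  if (length(all_snps) == 1L) membership <- matrix(membership, nrow = 1)
  exclusive <- lapply(seq_along(sets), function(i) {
    all_snps[membership[, i] & rowSums(membership) == 1L]
  })
  names(exclusive) <- names(sets)
  pairwise <- list()
  nm <- names(sets)
  for (i in seq_along(sets)[-1]) for (j in seq_len(i - 1))
    pairwise[[paste(nm[j], nm[i], sep = ":")]] <-
      intersect(sets[[nm[j]]], sets[[nm[i]]])
  list(
    sizes = lengths(sets),
    exclusive = exclusive,
    n_exclusive = lengths(exclusive),
    n_exclusive_total = sum(lengths(exclusive)),
    pairwise = pairwise,
    common = Reduce(intersect, sets),
    union = all_snps
  )
}

#' @export
print.grs_result <- function(x, ...) {
  cat("GRS pipeline result\n")
  print(x$stage_counts, row.names = FALSE)
  cat(sprintf("Distinct SNPs: %d screened-in, %d t-selected, %d final; %d exclusive to one lipid\n",
              x$union_counts[["screened"]], x$union_counts[["t_selected"]],
              x$union_counts[["final"]], x$venn$n_exclusive_total))
  invisible(x)
}
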