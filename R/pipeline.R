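## End-to-end orchestration: candidate predictor sets, the per-lipid
## strategy comparison (LARS vs exhaustive best subsets under AIC/AICC/
## BIC vs bootstrapped stepwise, each optimism-corrected), and the
## report bundle written by run_analysis().

#' Candidate predictor set for one lipid
#'
#' Age, sex, BMI, adiposity (TFAT, VFAT), physical activity (METs),
#' energy (per 100 kcal), macronutrient %E, cholesterol intake, smoking
#' and drinking status, plus the lipid's own GRS.
#'
#' @param lipid one of `"tc"`, `"ldl"`, `"hdl"`, `"tg"`.
#' @param extra further column names to append.
#' @return character vector of design-variable names.
#' @export
candidate_set <- function(lipid = c("tc", "ldl", "hdl", "tg"),
                          extra = character(0)) {
  lipid <- match.arg(lipid)
  unique(c("age", "sex", "bmi", "tfat", "vfat", "mets", "energy100",
           "carb_pct", "prot_pct", "fat_pct", "chol_intake", "smoker",
           "drinker", paste0("grs_", lipid), extra))
}

#' Compare selection strategies for one lipid with optimism correction
#'
#' Runs least-angle regression, exhaustive best subsets under each
#' requested criterion, and bootstrapped stepwise; attaches a Harrell
#' bootstrap optimism report to each (the *entire* selection is rerun
#' on every resample) and picks the winner by optimism-corrected
#' adjusted R-squared.
#'
#' @param lipid response lipid name (column of `data`).
#' @param data data.frame holding the response and all candidates
#'   (typically `cbind(covariate_design(cohort), grs, cohort[lipids])`).
#' @param candidates candidate predictor names (default
#'   [candidate_set()]).
#' @param criteria best-subset criteria to compare (default all three).
#' @param B_optimism bootstrap resamples for the optimism correction.
#' @param B_stepwise resamples for the bootstrapped stepwise strategy.
#' @param max_size largest subset size for the exhaustive search.
#' @param seed integer seed.
#' @return object of class `"lipid_model_set"`: named list of
#'   `lipid_fit`s (each with `$optimism`), plus `winner`.
#' @export
fit_lipid_models <- function(lipid, data, candidates = candidate_set(lipid),
                             criteria = c("aic", "aicc", "bic"),
                             B_optimism = 200, B_stepwise = 200,
                             max_size = length(candidates), seed = 1L) {
  missing_cols <- setdiff(c(lipid, candidates), names(data))
  if (length(missing_cols))
    .fail("data lacks column(s): %s", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(data[c(lipid, candidates)])
  d <- data[keep, , drop = FALSE]
  if (nrow(d) < length(candidates) + 2)
    .fail("too few complete cases (%d) for %d candidates", nrow(d),
          length(candidates))

  procedures <- list(
    LARS = function(dd) lars_select(lipid, candidates, dd)
  )
  for (cr in criteria) {
    procedures[[paste0("BSRP_", toupper(cr))]] <- local({
      cr_local <- cr
      function(dd) best_subset(lipid, candidates, dd, criterion = cr_local,
                               max_size = max_size)
    })
  }
  procedures$BSM <- function(dd)
    bootstrap_stepwise(lipid, candidates, dd, B = B_stepwise, seed = seed)

  reports <- list()
  for (nm in names(procedures)) {
    proc <- procedures[[nm]]
    fit <- suppressWarnings(proc(d))
    fit$optimism <- suppressWarnings(
      optimism_correct(proc, d, B = B_optimism, seed = seed))
    reports[[nm]] <- fit
  }
  winner <- select_best_model(reports)
  structure(list(lipid = lipid, reports = reports, winner = winner,
                 n = nrow(d), seed = seed),
            class = "lipid_model_set")
}

#' @export
print.lipid_model_set <- function(x, ...) {
  cat(sprintf("Model comparison for %s (n = %d)\n", toupper(x$lipid), x$n))
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    cat(sprintf("  %-9s %d predictor(s), adj R2 %.4f, corrected %.4f%s\n",
                nm, length(r$predictors), r$adj_r2,
                r$optimism$corrected[["adj_r2"]],
                if (identical(r, x$winner)) "  <- winner" else ""))
  }
  invisible(x)
}

#' Assemble a per-lipid model report table
#'
#' One row per predictor (beta ± SE and PC2) plus the constant and the
#' fit/optimism metrics, in the layout of a published model table.
#'
#' @param model_sets named list (by lipid) of [fit_lipid_models()]
#'   results.
#' @return data.frame in long format: `lipid`, `row`, `beta`, `se`,
#'   `pc2`, `value`.
#' @export
model_report <- function(model_sets) {
  rows <- list()
  for (lipid in names(model_sets)) {
    w <- model_sets[[lipid]]$winner
    ct <- w$coef_table
    for (pred in w$predictors) {
      rows[[length(rows) + 1L]] <- data.frame(
        lipid = lipid, row = pred, beta = ct[pred, "Estimate"],
        se = ct[pred, "Std. Error"], pc2 = unname(w$pc2[pred]),
        value = NA_real_)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      lipid = lipid, row = "Constant",
      beta = ct["(Intercept)", "Estimate"],
      se = ct["(Intercept)", "Std. Error"], pc2 = NA_real_,
      value = NA_real_)
    o <- w$optimism
    strategy_label <- paste0("strategy:", w$strategy,
                             if (!is.null(w$criterion))
                               paste0("/", toupper(w$criterion)) else "")
    metrics <- stats::setNames(
      c(NA_real_, w$r2, w$adj_r2, o$optimism[["r2"]], o$optimism[["adj_r2"]],
        o$corrected[["r2"]], o$corrected[["adj_r2"]]),
      c(strategy_label, "R2", "adj_R2", "optimism_R2", "optimism_adj_R2",
        "corrected_R2", "corrected_adj_R2"))
    for (mn in names(metrics)) {
      rows[[length(rows) + 1L]] <- data.frame(
        lipid = lipid, row = mn, beta = NA_real_, se = NA_real_,
        pc2 = NA_real_, value = metrics[[mn]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis and write the report bundle
#'
#' Quality control (per-SNP HWE, AMOVA homogeneity on random halves),
#' the GRS pipeline with its audit log and Venn summary, the per-lipid
#' strategy comparison with optimism correction, and GRS-by-lifestyle
#' interaction scans. All outputs plus a run manifest (seed, config
#' hash, package version) are written under `out_dir`.
#'
#' @param cohort cohort data.frame (or `NULL` to simulate from `spec`).
#' @param geno genotype matrix (or `NULL` to simulate).
#' @param spec optional [simulation_spec()] used when cohort/genotypes
#'   are not supplied.
#' @param out_dir output directory.
#' @param config a [grs_config()].
#' @param candidates candidate predictors (default [candidate_set()]
#'   per lipid).
#' @param B_optimism,B_stepwise,max_size,criteria model-selection
#'   controls, see [fit_lipid_models()].
#' @param n_perm AMOVA permutations.
#' @param seed integer seed.
#' @return invisibly, a list with all in-memory results.
#' @export
run_analysis <- function(cohort = NULL, geno = NULL, spec = NULL,
                         out_dir, config = grs_config(),
                         candidates = NULL,
                         criteria = c("aic", "aicc", "bic"),
                         B_optimism = 200, B_stepwise = 200,
                         max_size = 8, n_perm = 200, seed = 1L) {
  if (is.null(cohort) != is.null(geno))
    .fail("supply both cohort and genotypes, or neither (with a spec)")
  if (is.null(cohort)) {
    if (is.null(spec)) .fail("either data or a simulation spec is required")
    sim <- simulate_cohort(spec)
    cohort <- sim$cohort; geno <- sim$genotypes
  }
  if (nrow(cohort) < 3) .fail("cohort must have at least 3 subjects")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  qc <- hwe_screen(geno)
  utils::write.table(qc, file.path(out_dir, "hwe.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  homog <- amova_homogeneity(geno, n_splits = 3, n_perm = n_perm, seed = seed)
  utils::write.table(homog, file.path(out_dir, "amova.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  grs_res <- suppressWarnings(run_grs_pipeline(cohort, geno, config))
  utils::write.table(grs_res$audit, file.path(out_dir, "grs_audit.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_cohort_csv(grs_res$grs, file.path(out_dir, "grs.csv"))
  jsonlite::write_json(
    list(sizes = as.list(grs_res$venn$sizes),
         exclusive = grs_res$venn$exclusive,
         n_exclusive = as.list(grs_res$venn$n_exclusive),
         n_exclusive_total = grs_res$venn$n_exclusive_total,
         common = grs_res$venn$common),
    file.path(out_dir, "venn.json"), auto_unbox = TRUE, pretty = TRUE)

  design <- cbind(covariate_design(cohort),
                  grs_res$grs[-1],
                  cohort[LIPIDS])
  model_sets <- list()
  interactions <- list()
  for (lipid in LIPIDS) {
    cand <- candidates %||% candidate_set(lipid)
    cand <- intersect(cand, names(design))
    model_sets[[lipid]] <- fit_lipid_models(
      lipid, design, candidates = cand, criteria = criteria,
      B_optimism = B_optimism, B_stepwise = B_stepwise,
      max_size = min(max_size, length(cand)), seed = seed)
    lifestyle <- design[intersect(c("energy100", "carb_pct", "prot_pct",
                                    "fat_pct", "chol_intake", "mets",
                                    "smoker", "drinker"), names(design))]
    interactions[[lipid]] <- suppressWarnings(
      interaction_scan(design[[paste0("grs_", lipid)]], lifestyle,
                       design[[lipid]]))
  }
  report <- model_report(model_sets)
  utils::write.table(report, file.path(out_dir, "models.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  inter_tab <- do.call(rbind, Map(cbind, lipid = names(interactions),
                                  interactions))
  utils::write.table(inter_tab, file.path(out_dir, "interactions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_cohort_summary(cohort_summary(cohort),
                       path_tsv = file.path(out_dir, "summary.tsv"),
                       path_md = file.path(out_dir, "summary.md"))

  cfg_for_hash <- list(config = unclass(config), criteria = criteria,
                       B_optimism = B_optimism, B_stepwise = B_stepwise,
                       max_size = max_size, n_perm = n_perm, seed = seed)
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg_for_hash, cfg_file)
  manifest <- list(
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("lipidgrs")),
    n_subjects = nrow(cohort), n_snps = ncol(geno)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(qc = qc, amova = homog, grs = grs_res,
                 models = model_sets, interactions = interactions,
                 report = report, manifest = manifest))
}
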