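## End-to-end orchestration: simulate or load a cohort, build the six
## model variants (nongenetic / genetic / multifactorial, each as a
## liability model and as a risk score), stratify, evaluate, and write
## score tables, evaluation reports and a reproducible run manifest.

#' Run the full risk-modelling pipeline
#'
#' For each configured SNP panel, constructs the six model variants of
#' the analysis this package reimplements — nGLT and nGRS (nongenetic
#' liability and score), GLT and PRS (genetic), MLT and MRS
#' (multifactorial) — on a simulated or supplied cohort, normalizes all
#' scores to the common 0-10 scale, and evaluates each variant by rank
#' AUC, per-point OR, quartile stratification (plus an optional
#' discrete cutoff), 10-fold cross-validation and per-cohort AUCs.
#' Liability variants are evaluated with and without the
#' family-history update. The multifactorial liability is the exact
#' sum of the genetic and nongenetic liabilities; the multifactorial
#' score is the mean of the two normalized component scores.
#'
#' @param config A named list or the path of a YAML file with entries:
#'   `n` (simulated cohort size), `seed`, `prevalence`, `heritability`,
#'   `panels` (named list of weight-table paths or data frames;
#'   defaults to the bundled 47-SNP panel), `use_default_covariates`
#'   (default TRUE), `cutoff` (optional discrete threshold on the 0-10
#'   scale), `k` (CV folds, default 10), `out_dir` (optional; when set,
#'   score tables, evaluation TSVs and `manifest.json` are written).
#' @return Invisibly, a list with `cohort`, per-variant `scores`
#'   (score sets), `evaluations` (data frame), `quartiles`, `cv`,
#'   `per_cohort` and `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    n = 2378L, seed = 1L, prevalence = 0.17, heritability = 0.5,
    use_default_covariates = TRUE, k = 10L, cutoff = NULL,
    out_dir = NULL), config)
  check_probability(cfg$prevalence, "prevalence")

  panels <- cfg$panels %||% list(panel47 = dcvd_snp_panel())
  panels <- lapply(panels, function(p)
    if (is.character(p)) read_snp_weights(p) else validate_snp_weights(p))

  schemes <- if (isTRUE(cfg$use_default_covariates))
    default_covariate_schemes() else cfg$schemes

  ## cohort: simulated under the union of all panels' loci
  all_w <- unique(do.call(rbind, lapply(panels, function(p)
    p[, c("rsid", "raf", "or")])))
  spec <- simulation_spec(cfg$n, weights = all_w, schemes = schemes,
                          prevalence = cfg$prevalence,
                          heritability = cfg$heritability, seed = cfg$seed)
  cohort <- simulate_cohort(spec)
  status <- cohort$samples$status
  cats <- cohort$samples[, cohort$scheme_names, drop = FALSE]

  ids <- cohort$samples$sample_id
  fh <- cohort$samples$fh
  ng_model <- liability_model(schemes = schemes,
                              prevalence = cfg$prevalence,
                              heritability = cfg$heritability)
  ## liability variants come in pairs: base (no family history, so the
  ## multifactorial liability is exactly genetic + nongenetic) and
  ## "_fh" with the conditional family-history update
  scores <- list()
  ## constant raw scores (e.g. an all-null panel) have no range to
  ## normalize; map them to the scale midpoint so null configurations
  ## still evaluate
  norm_safe <- function(values, type) {
    if (length(unique(values[!is.na(values)])) < 2L) {
      out <- data.frame(sample = ids, raw = as.numeric(values),
                        normalized = ifelse(is.na(values), NA_real_, 5))
      return(structure(out, class = c("score_set", "data.frame"),
                       x_min = NA_real_, x_range = NA_real_,
                       score_type = type, n_clipped = 0L))
    }
    minmax_normalize(values, score_type = type, sample_ids = ids)
  }
  add_lt <- function(scores, name, model, type, ...) {
    scores[[name]] <- norm_safe(measured_liability(model, ...), type)
    scores[[paste0(name, "_fh")]] <- norm_safe(
      measured_liability(model, ..., fh = fh), type)
    scores
  }
  scores <- add_lt(scores, "nGLT", ng_model, "liability",
                   categories = cats)
  scores$nGRS <- norm_safe(nongenetic_score(cats, schemes), "nongenetic")

  for (pn in names(panels)) {
    w <- panels[[pn]]
    g_model <- liability_model(weights = w, prevalence = cfg$prevalence,
                               heritability = cfg$heritability)
    m_model <- liability_model(weights = w, schemes = schemes,
                               prevalence = cfg$prevalence,
                               heritability = cfg$heritability)
    d <- cohort$dosages[, w$rsid, drop = FALSE]
    scores <- add_lt(scores, paste0("GLT_", pn), g_model, "liability",
                     dosages = d)
    scores <- add_lt(scores, paste0("MLT_", pn), m_model, "multifactorial",
                     dosages = d, categories = cats)
    scores[[paste0("PRS_", pn)]] <- norm_safe(compute_prs(d, w), "prs")
    mrs <- (scores[[paste0("PRS_", pn)]]$normalized +
            scores$nGRS$normalized) / 2
    scores[[paste0("MRS_", pn)]] <- norm_safe(mrs, "multifactorial")
  }

  evaluations <- do.call(rbind, lapply(names(scores), function(nm) {
    s <- scores[[nm]]
    a <- auc_rank(s, status)
    pp <- tryCatch(per_point_or(s, status),
                   error = function(e) list(or = NA, ci_lo = NA,
                                            ci_hi = NA, p = NA))
    data.frame(model = nm, n_cases = a$n_cases, n_controls = a$n_controls,
               auc = a$auc, auc_lo = a$ci_lo, auc_hi = a$ci_hi,
               per_point_or = pp$or, or_lo = pp$ci_lo, or_hi = pp$ci_hi,
               or_p = pp$p)
  }))

  quartiles <- lapply(scores, function(s)
    tryCatch(quartile_assign(s, status), error = function(e) NULL))
  discrete <- if (!is.null(cfg$cutoff))
    lapply(scores, dichotomize, status = status, cutoff = cfg$cutoff)
  cv <- lapply(scores, function(s)
    tryCatch(kfold_cv(s$raw, status, k = cfg$k,
                      seed = derive_seed(cfg$seed, 7L)),
             error = function(e) NULL))
  per_cohort <- lapply(scores, per_cohort_eval, status = status,
                       cohort = cohort$samples$cohort)

  manifest <- list(
    package = "dcvdrisk",
    version = as.character(utils::packageVersion("dcvdrisk")),
    seed = cfg$seed, n = cfg$n, prevalence = cfg$prevalence,
    heritability = cfg$heritability,
    panels = lapply(panels, function(p) list(n_snps = nrow(p))),
    cutoff = cfg$cutoff, k = cfg$k,
    mrs_rule = "mean of normalized PRS and normalized nongenetic score",
    quartile_reference = "pooled sample (cases + controls)")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(scores))
      write_score_set(scores[[nm]],
                      file.path(cfg$out_dir, paste0("scores_", nm, ".tsv")))
    utils::write.table(evaluations,
                       file.path(cfg$out_dir, "evaluations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_cohort(cohort, file.path(cfg$out_dir, "cohort"))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  invisible(list(cohort = cohort, scores = scores,
                 evaluations = evaluations, quartiles = quartiles,
                 discrete = discrete, cv = cv, per_cohort = per_cohort,
                 manifest = manifest))
}
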