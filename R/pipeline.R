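# Orchestration: cohort -> features -> signature -> models -> report.
# All randomness flows from one master seed via named substreams (cohort,
# folds, bootstrap), and the run manifest records everything needed to
# reproduce the numeric outputs byte for byte.

#' Assemble a pipeline run configuration
#'
#' @param output_dir Directory for all run artifacts.
#' @param cohort_dir Existing cohort directory (images/, masks/,
#'   clinical.csv); when `NULL`, a synthetic cohort is generated from
#'   `synthetic`.
#' @param synthetic A `cohort_config` for synthetic runs.
#' @param Ng Gray-level count for texture extraction.
#' @param n_repeats Cross-validation repetitions for the signature.
#' @param n_boot Bootstrap resamples for the C-index comparison.
#' @param seed Master seed; substreams for cohort generation, fold
#'   assignment and the bootstrap are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(output_dir, cohort_dir = NULL,
                       synthetic = cohort_config(), Ng = 32L,
                       n_repeats = 100L, n_boot = 1000L, seed = 1L) {
  if (!is.null(cohort_dir) && !dir.exists(cohort_dir)) {
    stop("cohort_dir does not exist: ", cohort_dir)
  }
  structure(
    list(output_dir = output_dir, cohort_dir = cohort_dir,
         synthetic = synthetic, Ng = as.integer(Ng),
         n_repeats = as.integer(n_repeats), n_boot = as.integer(n_boot),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

.clinical_vars <- c("age55", "male", "size_mm", "lnm", "ete",
                    "distant_mets", "rai_dose")

#' Validate a cohort before analysis
#'
#' Checks image/mask pairing and dimensions, ROI size (>= 16 cells),
#' completeness of the clinical table, time positivity and event coding.
#' Reports violations without failing; the pipeline fails fast on a
#' non-empty report.
#'
#' @param cohort A `rad_cohort`.
#' @return Data frame with columns `patient`, `field`, `message`; zero rows
#'   when the cohort is clean.
#' @export
validate_cohort <- function(cohort) {
  v <- list()
  flag <- function(patient, field, message) {
    v[[length(v) + 1L]] <<- data.frame(patient = patient, field = field,
                                       message = message)
  }
  clin <- cohort$clinical
  ids <- vapply(cohort$patients, `[[`, character(1), "id")
  for (id in setdiff(clin$id, ids)) flag(id, "image", "no image for patient")
  for (id in setdiff(ids, clin$id)) flag(id, "clinical", "no clinical row")
  for (p in cohort$patients) {
    if (!identical(dim(p$image), dim(p$mask))) {
      flag(p$id, "mask", "mask dimensions do not match image")
    } else if (sum(p$mask) < 16L) {
      flag(p$id, "mask", sprintf("degenerate ROI: %d cells", sum(p$mask)))
    }
  }
  need <- c("id", "time", "event", .clinical_vars)
  for (f in setdiff(need, names(clin))) flag("-", f, "missing clinical column")
  for (f in intersect(need, names(clin))) {
    bad <- which(is.na(clin[[f]]))
    for (b in bad) flag(clin$id[b], f, "missing value")
  }
  if ("time" %in% names(clin)) {
    for (b in which(!is.na(clin$time) & clin$time <= 0)) {
      flag(clin$id[b], "time", "non-positive survival time")
    }
  }
  if ("event" %in% names(clin)) {
    for (b in which(!is.na(clin$event) & !clin$event %in% c(0, 1))) {
      flag(clin$id[b], "event", "event indicator must be 0 or 1")
    }
  }
  if (length(v) == 0L) {
    return(data.frame(patient = character(), field = character(),
                      message = character()))
  }
  do.call(rbind, v)
}

write_md_table <- function(df, con) {
  writeLines(paste0("| ", paste(names(df), collapse = " | "), " |"), con)
  writeLines(paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"), con)
  for (k in seq_len(nrow(df))) {
    writeLines(paste0("| ", paste(unlist(df[k, ]), collapse = " | "), " |"),
               con)
  }
  writeLines("", con)
}

#' Run the full radiomics survival pipeline
#'
#' Generates (or reads) the cohort, validates it, extracts the 730-feature
#' table, builds the radiomics signature by repeated cross-validated
#' LASSO-Cox selection, scores every patient, fits the univariate models,
#' the multivariate clinicopathologic model and the radiomics-augmented
#' model, compares their C-indices by bootstrap, and writes every artifact
#' plus a run manifest to `config$output_dir`.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with `cohort`, `features`, `signature`,
#'   `scores`, `fits`, `comparison`, `tables`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 3L)  # cohort, folds, bootstrap

  cohort <- if (is.null(config$cohort_dir)) {
    syn <- config$synthetic
    syn$seed <- seeds[1]
    generate_cohort(syn)
  } else {
    read_cohort(config$cohort_dir)
  }

  violations <- validate_cohort(cohort)
  if (nrow(violations) > 0L) {
    stop("cohort validation failed:\n",
         paste(sprintf("  [%s] %s: %s", violations$patient, violations$field,
                       violations$message), collapse = "\n"))
  }
  clin <- cohort$clinical

  features <- extract_cohort(cohort$patients, texture_config(config$Ng))
  write.csv(features, file.path(out, "features.csv"), row.names = FALSE)

  fmat <- as.matrix(features[, -1, drop = FALSE])
  fm <- standardize(fmat)
  signature <- repeated_cv_select(fm, clin$time, clin$event,
                                  n_repeats = config$n_repeats,
                                  base_seed = seeds[2])
  write_signature(signature, file.path(out, "signature.json"))

  scores <- rad_score(signature, fmat)
  write.csv(data.frame(id = features$id, rad_score = scores),
            file.path(out, "rad_scores.csv"), row.names = FALSE)

  design_clin <- clin[, .clinical_vars]
  design_aug <- cbind(design_clin, rad_score = scores)
  univariate <- lapply(
    setNames(nm = c(.clinical_vars, "rad_score")),
    function(v) fit_cox(design_aug[, v, drop = FALSE], clin$time, clin$event)
  )
  clin_fit <- fit_cox(design_clin, clin$time, clin$event)
  aug_fit <- fit_cox(design_aug, clin$time, clin$event)
  comparison <- compare_models(clin_fit, aug_fit, clin$time, clin$event,
                               n_boot = config$n_boot, seed = seeds[3])
  tables <- build_model_tables(univariate, clin_fit, aug_fit, comparison)

  write.csv(tables$univariate, file.path(out, "univariate.csv"),
            row.names = FALSE)
  write.csv(tables$clinicopathologic,
            file.path(out, "model_clinicopathologic.csv"), row.names = FALSE)
  write.csv(tables$radiomics, file.path(out, "model_radiomics.csv"),
            row.names = FALSE)
  con <- file(file.path(out, "tables.md"), "w")
  for (nm in names(tables)) {
    writeLines(paste0("## ", nm, "\n"), con)
    write_md_table(tables[[nm]], con)
  }
  close(con)
  jsonlite::write_json(
    list(c_base = comparison$c_base, c_aug = comparison$c_aug,
         diff = comparison$diff, ci_low = comparison$ci_low,
         ci_high = comparison$ci_high, n_boot = comparison$n_boot,
         seed = comparison$seed),
    file.path(out, "cindex_comparison.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("radsig")),
         seed = config$seed,
         substreams = list(cohort = seeds[1], folds = seeds[2],
                           bootstrap = seeds[3]),
         Ng = config$Ng, n_repeats = config$n_repeats,
         n_boot = config$n_boot,
         cohort_dir = if (is.null(config$cohort_dir)) NA else
           config$cohort_dir,
         n_patients = nrow(clin), n_events = sum(clin$event),
         signature_size = signature$K),
    file.path(out, "run_manifest.json"), auto_unbox = TRUE, digits = NA
  )

  invisible(list(cohort = cohort, features = features, signature = signature,
                 scores = scores,
                 fits = list(univariate = univariate, clinical = clin_fit,
                             augmented = aug_fit),
                 comparison = comparison, tables = tables))
}
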