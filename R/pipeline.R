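# End-to-end orchestration: one config in, one run directory of
# artifacts out. Every stage artifact is individually re-runnable.

#' Pipeline run configuration
#'
#' One global `seed` deterministically derives the cohort and search
#' seeds, so a run is reproducible from its archived config alone.
#'
#' @param cohort a [cohort_spec()] (its own seed is overridden by the
#'   derived cohort seed), or a manifest CSV path, or a feature-table
#'   CSV path.
#' @param source `"images"` (render + extract) or `"table"` (direct
#'   feature sampling / CSV).
#' @param combos `"all"` or a subset of [combination_names()].
#' @param glcm [glcm_settings()].
#' @param automo [automo_config()] (its seed is overridden).
#' @param threshold redundancy cutoff.
#' @param out_dir output directory.
#' @param seed global seed.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), source = c("images", "table"),
                            combos = "all", glcm = glcm_settings(),
                            automo = automo_config(), threshold = 0.8,
                            out_dir = tempfile("rader_run_"), seed = 1L) {
  source <- match.arg(source)
  if (identical(combos, "all")) combos <- combination_names()
  if (!all(combos %in% combination_names()))
    rader_abort("unknown combination in `combos`", "config")
  structure(list(cohort = cohort, source = source, combos = combos,
                 glcm = glcm, automo = automo, threshold = threshold,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

config_json <- function(config) {
  cohort <- config$cohort
  jsonlite::toJSON(list(
    seed = config$seed, source = config$source, combos = config$combos,
    threshold = config$threshold,
    glcm = config$glcm,
    automo = unclass(config$automo),
    cohort = if (inherits(cohort, "cohort_spec")) unclass(cohort) else cohort
  ), auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the full pipeline
#'
#' extract -> delta -> assemble -> normalize/select -> train -> weights
#' -> fuse -> evaluate, for each requested combination; writes feature
#' tables, selection results, the model archive, weights, per-patient
#' predictions, and the comparison report under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return the run directory path (invisibly); the `evaluation_report`
#'   is attached as attribute `"report"`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 2)
  writeLines(config_json(config), file.path(config$out_dir, "config.json"))

  tables <- pipeline_tables(config, cohort_seed = seeds[1])
  combined <- fm_cbind(tables$pre, tables$post, tables$delta)
  write_feature_table(combined, file.path(config$out_dir, "features.csv"))

  automo <- config$automo
  automo$seed <- seeds[2]
  report <- compare_combinations(tables, automo, combos = config$combos,
                                 threshold = config$threshold)
  write_run_artifacts(report, config$out_dir)
  out <- config$out_dir
  attr(out, "report") <- report
  invisible(out)
}

pipeline_tables <- function(config, cohort_seed) {
  cohort <- config$cohort
  if (is.character(cohort)) {
    if (grepl("manifest", basename(cohort))) {
      patients <- read_cohort(cohort)
      ext <- extract_cohort_features(patients, config$glcm)
      return(ext[c("pre", "post", "delta")])
    }
    return(split_provenance(read_feature_table(cohort)))
  }
  stopifnot(inherits(cohort, "cohort_spec"))
  spec <- cohort
  spec$seed <- as.integer(cohort_seed)
  if (config$source == "table") {
    split_provenance(generate_feature_table(spec, settings = config$glcm))
  } else {
    ext <- extract_cohort_features(generate_cohort(spec), config$glcm)
    ext[c("pre", "post", "delta")]
  }
}

write_run_artifacts <- function(report, out_dir) {
  for (combo in names(report$details)) {
    d <- report$details[[combo]]
    tag <- gsub("\\+", "_", combo)
    jsonlite::write_json(
      list(combo = combo, retained = d$selection$retained,
           removed = d$selection$removed, threshold = d$selection$threshold),
      file.path(out_dir, paste0("selection_", tag, ".json")),
      auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(combo = combo,
           omega = d$weights$omega, raw = d$weights$raw,
           models = lapply(d$archive$models, function(cand) {
             list(cost = cand$cost, gamma = cand$gamma,
                  beta = which(cand$beta),
                  objectives = as.list(cand$objectives))
           })),
      file.path(out_dir, paste0("archive_", tag, ".json")),
      auto_unbox = TRUE, digits = NA)
    write.csv(d$predictions,
              file.path(out_dir, paste0("predictions_", tag, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(report$table, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
}

# -- model bundle (train once, predict later) -------------------------------

#' Serialize a trained combination to a JSON model bundle
#'
#' The bundle carries everything `predict` needs: normalization
#' parameters, the retained feature set, each archive member's dual
#' solution and calibration, and the fusion weights.
#'
#' @param prep list with `params` (z-score) and `retained`.
#' @param archive [train_automo()] result.
#' @param weights [compute_weights()] result.
#' @param combo combination id.
#' @param path output JSON path.
#' @export
save_model_bundle <- function(prep, archive, weights, combo, path) {
  bundle <- list(
    combo = combo,
    zscore = list(mean = as.list(prep$params$mean),
                  sd = as.list(prep$params$sd),
                  dropped = prep$params$dropped),
    retained = prep$retained,
    feature_names = archive$feature_names,
    fold_seed = archive$fold_seed,
    omega = weights$omega,
    models = lapply(archive$models, function(cand) {
      list(cost = cand$cost, gamma = cand$gamma, beta = which(cand$beta),
           objectives = as.list(cand$objectives),
           alpha = cand$fit$alpha, b = cand$fit$b, y = cand$fit$y,
           sv = apply(cand$fit$x, 1, as.list),
           platt = cand$fit$platt)
    })
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a JSON model bundle
#'
#' @param path bundle path from [save_model_bundle()].
#' @return list mirroring the saved structure, with `rader_svm` fits
#'   reconstructed.
#' @export
load_model_bundle <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = FALSE)
  feature_names <- unlist(b$feature_names)
  n_feat <- length(feature_names)
  models <- lapply(b$models, function(m) {
    beta <- rep(FALSE, n_feat)
    beta[unlist(m$beta)] <- TRUE
    sv <- do.call(rbind, lapply(m$sv, unlist))
    fit <- structure(list(x = sv, y = unlist(m$y), alpha = unlist(m$alpha),
                          b = m$b, cost = m$cost, gamma = m$gamma,
                          platt = list(A = m$platt$A, B = m$platt$B)),
                     class = "rader_svm")
    list(cost = m$cost, gamma = m$gamma, beta = beta,
         objectives = unlist(m$objectives), fit = fit)
  })
  archive <- structure(list(models = models, feature_names = feature_names,
                            fold_seed = b$fold_seed,
                            generation_log = data.frame()),
                       class = "pareto_archive")
  omega <- unlist(b$omega)
  list(combo = b$combo,
       params = list(mean = unlist(b$zscore$mean), sd = unlist(b$zscore$sd),
                     dropped = unlist(b$zscore$dropped) %||% character(0)),
       retained = unlist(b$retained), archive = archive,
       weights = structure(list(omega = omega, raw = omega,
                                zero_set = which(omega == 0)),
                           class = "fusion_weights"))
}
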