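#' Write a table as UTF-8 TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path File path.
#' @return Data frame (no name mangling, strings kept as character).
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

#' Load a pipeline configuration
#'
#' Accepts a YAML or JSON file, or an already-constructed list. Fields:
#' `seed` (integer), `outdir`, `design` (arguments to [design_config()]),
#' optional `behavior`, `patterns`, `ratings` parameter blocks, and
#' `analyses` (character vector choosing which stages to run; default all).
#'
#' @param config Path to a .yaml/.yml/.json file, or a list.
#' @return Normalized config list of class `pipeline_config`.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("load_config: need a list or file path",
                             call. = FALSE)
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (is.null(config$outdir)) stop("load_config: outdir is required",
                                   call. = FALSE)
  config$analyses <- if (is.null(config$analyses))
    c("behavior", "rsa", "ers") else config$analyses
  class(config) <- c("pipeline_config", class(config))
  config
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic analysis pipeline
#'
#' Generates (or, for supplied tables, loads) the design, responses, voxel
#' patterns and relatedness ratings, then runs the behavioral scoring and
#' specificity categorization, the ANOVA recipes on hits and false alarms,
#' the model-based RSA with run-bias correction and its group ANOVA, and the
#' ERS analysis with its mixed model. All outputs are written as TSV/JSON
#' under `config$outdir` together with a JSON log recording the seed, the
#' config hash and exclusion counts. Deterministic given the seed.
#'
#' @param config A [load_config()]-compatible config (list or file path).
#' @return Invisibly, a list with the main result tables.
#' @export
run_pipeline <- function(config) {
  config <- load_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed, config_hash = .config_hash(config),
              started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dcfg <- stage("design", do.call(design_config,
                                  c(config$design, list(seed = config$seed))))
  design <- stage("design", generate_design(dcfg))
  responses <- stage("behavior", simulate_responses(
    design, do.call(behavior_params, config$behavior %||% list()),
    seed = config$seed + 1L))
  ratings <- stage("ratings", simulate_relatedness(
    design, do.call(rating_params, config$ratings %||% list()),
    seed = config$seed + 2L))
  out <- list()
  write_tsv(design$test, file.path(config$outdir, "trials_test.tsv"))
  write_tsv(design$encoding, file.path(config$outdir, "trials_encoding.tsv"))
  write_tsv(responses, file.path(config$outdir, "responses.tsv"))
  write_tsv(ratings, file.path(config$outdir, "ratings.tsv"))

  if ("behavior" %in% config$analyses) {
    summ <- stage("behavior", score_recognition(responses))
    cats <- stage("behavior", categorize_all(responses))
    feat <- stage("behavior", build_trial_features(responses, ratings))
    write_tsv(summ$hits, file.path(config$outdir, "hits.tsv"))
    write_tsv(summ$false_alarms, file.path(config$outdir, "false_alarms.tsv"))
    write_tsv(cats$counts, file.path(config$outdir, "category_counts.tsv"))
    write_tsv(feat, file.path(config$outdir, "lure_features.tsv"))
    hit_aov <- stage("behavior", mixed_anova(
      summ$hits, dv = "hit_rate", subject = "subject", between = "delay",
      within = "emotion"))
    fa_aov <- stage("behavior", mixed_anova(
      summ$false_alarms, dv = "fa_rate", subject = "subject",
      between = "delay", within = c("emotion", "lure_type")))
    write_tsv(as.data.frame(hit_aov),
              file.path(config$outdir, "anova_hits.tsv"))
    write_tsv(as.data.frame(fa_aov),
              file.path(config$outdir, "anova_false_alarms.tsv"))
    out$behavior <- list(hits = summ$hits, false_alarms = summ$false_alarms,
                         categories = cats$counts, anova_hits = hit_aov,
                         anova_fas = fa_aov)
    log$behavior <- list(dropped_lure_trials = attr(feat, "dropped"))
  }

  needs_patterns <- any(c("rsa", "ers") %in% config$analyses)
  if (needs_patterns) {
    store <- stage("patterns", simulate_patterns(
      design, do.call(pattern_params, config$patterns %||% list()),
      seed = config$seed + 3L))
  }
  if ("rsa" %in% config$analyses) {
    fits <- stage("rsa", fit_models_all(store))
    write_tsv(fits, file.path(config$outdir, "rsa_model_fits.tsv"))
    cellf <- interaction(fits$delay, fits$emotion, fits$model)
    keep <- if (min(table(cellf)) >= 3)
      unsplit(lapply(split(fits$z, cellf), exclude_outliers), cellf)
    else rep(TRUE, nrow(fits))  # too few subjects for the +-3 SD rule
    log$rsa <- list(outliers_excluded = sum(!keep))
    kept_subj <- names(which(tapply(keep, fits$subject, all)))
    rsa_aov <- stage("rsa", mixed_anova(
      fits[fits$subject %in% kept_subj, ], dv = "z", subject = "subject",
      between = "delay", within = c("emotion", "model")))
    write_tsv(as.data.frame(rsa_aov),
              file.path(config$outdir, "anova_rsa.tsv"))
    out$rsa <- list(fits = fits, anova = rsa_aov)
  }
  if ("ers" %in% config$analyses) {
    ers <- stage("ers", compute_ers(store))
    write_tsv(ers, file.path(config$outdir, "ers.tsv"))
    ers_ok <- ers[ers$valid, ]
    ers_lmm <- stage("ers", fit_mixed_model(
      mixed_model_spec("z", "delay * emotion", c("subject", "set"),
                       family = "gaussian"),
      ers_ok))
    write_tsv(ers_lmm$coefficients, file.path(config$outdir, "ers_lmm.tsv"))
    log$ers <- list(invalid_records = sum(!ers$valid),
                    lmm_converged = ers_lmm$converged)
    out$ers <- list(records = ers, lmm = ers_lmm)
  }
  log$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  jsonlite::write_json(log, file.path(config$outdir, "pipeline_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
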