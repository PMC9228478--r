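#' Column schemas of the tab-delimited interchange tables
#'
#' Named list of readr column specifications for the pipeline's interchange
#' files: `cohort`, `metabolites`, `qc`, `processed`.
#'
#' @return Named list of `readr::cols()` objects.
#' @export
table_schemas <- function() {
  list(
    cohort = readr::cols(
      child_id = readr::col_character(),
      family_id = readr::col_character(),
      cohort = readr::col_character(),
      zygosity = readr::col_character(),
      birth_order = readr::col_integer(),
      sex = readr::col_character(),
      age = readr::col_double(),
      first_morning = readr::col_logical(),
      freeze_delay = readr::col_double(),
      urine_sufficient = readr::col_logical(),
      second_multiple = readr::col_logical(),
      duplicate_of_other_cohort = readr::col_logical(),
      creatinine = readr::col_double()
    ),
    metabolites = readr::cols(
      sample_id = readr::col_character(),
      metabolite_id = readr::col_character(),
      platform = readr::col_character(),
      value = readr::col_double(),
      below_lod = readr::col_logical(),
      missing = readr::col_logical(),
      lod = readr::col_double()
    ),
    qc = readr::cols(
      metabolite_id = readr::col_character(),
      injection = readr::col_integer(),
      value = readr::col_double()
    ),
    processed = readr::cols(
      sample_id = readr::col_character(),
      metabolite_id = readr::col_character(),
      platform = readr::col_character(),
      value = readr::col_double()
    )
  )
}

#' Read a tab-delimited interchange table against a schema
#'
#' Reads a UTF-8, tab-delimited file with header and `NA` missing token,
#' enforcing column types from [table_schemas()]. Unknown extra columns
#' are accepted with a warning; a missing mandatory column is an error
#' naming it.
#'
#' @param path File path.
#' @param schema Schema name (`"cohort"`, `"metabolites"`, `"qc"`,
#'   `"processed"`) or a `readr::cols()` object.
#' @return A tibble.
#' @export
read_table <- function(path, schema) {
  if (is.character(schema)) {
    schemas <- table_schemas()
    if (!schema %in% names(schemas)) {
      abort(paste("unknown schema:", schema))
    }
    schema <- schemas[[schema]]
  }
  header <- names(readr::read_tsv(path, n_max = 0, col_types = readr::cols(),
                                  progress = FALSE, show_col_types = FALSE))
  wanted <- names(schema$cols)
  missing_cols <- setdiff(wanted, header)
  if (length(missing_cols)) {
    abort(paste("mandatory column(s) absent:",
                paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(header, wanted)
  if (length(extra)) {
    warn(paste("unknown extra column(s) accepted:",
               paste(extra, collapse = ", ")))
  }
  schema$default <- readr::col_guess()
  readr::read_tsv(path, col_types = schema, na = "NA", progress = FALSE,
                  show_col_types = FALSE)
}

#' Write a tab-delimited interchange table
#'
#' UTF-8, header row, `NA` as the missing token — the exact format
#' [read_table()] consumes, so tables round-trip.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(x)
}

#' Assemble and validate a pipeline run configuration
#'
#' Thresholds default to the conventional analysis settings: 10% metabolite
#' missingness, 15% RSDqc, FDR `q <= 0.05`, covariate-selection LRT at
#' 0.05, 95% confidence level, Blom offset 3/8.
#'
#' @param missing_threshold,rsd_threshold Metabolite filter settings.
#' @param fdr_q FDR significance threshold.
#' @param lrt_alpha Covariate-selection rejection level.
#' @param ci_level Confidence level of profile intervals.
#' @param int_offset Inverse-normal-transform offset constant.
#' @param seed Integer seed for simulated inputs.
#' @param analyses Association layouts to run (names of
#'   `scan_analyses()`); `NULL` runs all eight.
#' @param sim_spec Optional [simulation_spec()] used when the run
#'   simulates its inputs.
#' @param ci Whether the twin stage computes profile intervals.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(missing_threshold = 0.10,
                       rsd_threshold = 15,
                       fdr_q = 0.05,
                       lrt_alpha = 0.05,
                       ci_level = 0.95,
                       int_offset = 3 / 8,
                       seed = 1L,
                       analyses = NULL,
                       sim_spec = NULL,
                       ci = FALSE) {
  stopifnot(
    missing_threshold >= 0, missing_threshold <= 1,
    rsd_threshold >= 0,
    fdr_q >= 0, fdr_q <= 1,
    lrt_alpha > 0, lrt_alpha < 1,
    ci_level > 0, ci_level < 1
  )
  analyses <- analyses %||% names(scan_analyses())
  bad <- setdiff(analyses, names(scan_analyses()))
  if (length(bad)) abort(paste("unknown analyses:", paste(bad, collapse = ", ")))
  structure(list(
    missing_threshold = missing_threshold,
    rsd_threshold = rsd_threshold,
    fdr_q = fdr_q,
    lrt_alpha = lrt_alpha,
    ci_level = ci_level,
    int_offset = int_offset,
    seed = as.integer(seed),
    analyses = analyses,
    sim_spec = sim_spec,
    ci = ci
  ), class = "run_config")
}

#' Run the complete pipeline into an artifact directory
#'
#' Simulates a cohort (when the config carries a simulation spec) or reads
#' the three input tables from `input_dir`, then runs preprocessing, the
#' configured association scans, the twin-model pipeline and the platform
#' report, writing every stage's tables plus a plain-text provenance log
#' (settings, seed, package version) into `out_dir`. Identical
#' configuration and seed give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @param input_dir Directory holding `cohort.tsv`, `metabolites.tsv`,
#'   `qc.tsv` when no simulation spec is configured.
#' @return Invisibly, a named list of the stage outputs.
#' @export
run_all <- function(config, out_dir, input_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  if (!is.null(config$sim_spec)) {
    sim <- stage("simulate", simulate_cohort(config$sim_spec))
    cohort <- sim$cohort
    metabolites <- sim$metabolites
    qc <- sim$qc
    write_table(cohort, file.path(out_dir, "cohort.tsv"))
    write_table(metabolites, file.path(out_dir, "metabolites.tsv"))
    write_table(qc, file.path(out_dir, "qc.tsv"))
  } else {
    if (is.null(input_dir)) {
      abort("no simulation spec configured: `input_dir` is required")
    }
    cohort <- stage("read", read_table(file.path(input_dir, "cohort.tsv"),
                                       "cohort"))
    metabolites <- stage("read", read_table(
      file.path(input_dir, "metabolites.tsv"), "metabolites"
    ))
    qc <- stage("read", read_table(file.path(input_dir, "qc.tsv"), "qc"))
  }

  prep <- stage("preprocess", preprocess_pipeline(
    metabolites, cohort, qc,
    missing_threshold = config$missing_threshold,
    rsd_threshold = config$rsd_threshold,
    int_offset = config$int_offset
  ))
  write_table(prep$processed, file.path(out_dir, "processed.tsv"))
  write_table(prep$sample_report, file.path(out_dir, "sample_exclusions.tsv"))
  write_table(prep$metabolite_report,
              file.path(out_dir, "metabolite_exclusions.tsv"))

  scans <- stage("associate", purrr::map_dfr(config$analyses, function(a) {
    run_association_scan(prep$processed, prep$cohort, analysis = a,
                         fdr_q = config$fdr_q)
  }))
  write_table(scans, file.path(out_dir, "associations.tsv"))

  twin <- stage("twinfit", run_twin_pipeline(
    prep$processed, prep$cohort,
    ci = config$ci, level = config$ci_level, alpha = config$lrt_alpha
  ))
  write_table(twin, file.path(out_dir, "twin_results.tsv"))

  report <- stage("report", platform_summary(twin))
  write_table(report$platform, file.path(out_dir, "platform_summary.tsv"))
  if (!is.null(report$bands)) {
    write_table(report$bands, file.path(out_dir, "reliability_bands.tsv"))
  }

  provenance <- c(
    sprintf("twinmetab_version: %s",
            as.character(utils::packageVersion("twinmetab"))),
    sprintf("seed: %d", config$seed),
    sprintf("missing_threshold: %g", config$missing_threshold),
    sprintf("rsd_threshold: %g", config$rsd_threshold),
    sprintf("fdr_q: %g", config$fdr_q),
    sprintf("lrt_alpha: %g", config$lrt_alpha),
    sprintf("ci_level: %g", config$ci_level),
    sprintf("int_offset: %g", config$int_offset),
    sprintf("analyses: %s", paste(config$analyses, collapse = ","))
  )
  writeLines(provenance, file.path(out_dir, "provenance.txt"))

  invisible(list(
    cohort = cohort, metabolites = metabolites, qc = qc,
    preprocess = prep, associations = scans, twin = twin, report = report
  ))
}
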