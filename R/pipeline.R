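#' Materialize a complete synthetic cohort fixture directory
#'
#' Writes every table the analysis stages read: per-compartment repertoire
#' TSVs under `repertoires/`, flow panels and time-course CSVs, the somatic
#' variant table, survival, ROI and ELISpot CSVs, plus sidecar ground-truth
#' tables (`*_truth.csv`) kept separate from the measurement files so the
#' pipeline stays blind to the planted labels.
#'
#' @param dir Output directory (created if needed).
#' @param cohort A [cohort_config()].
#' @param repertoire A [repertoire_config()].
#' @param n_variants,variant_pass_fraction Variant generator settings.
#' @param survival_hazard_ratio,survival_n_per_group Survival generator
#'   settings.
#' @return The directory path, invisibly; a `manifest.json` lists the files.
#' @export
write_cohort_fixtures <- function(dir,
                                  cohort = cohort_config(),
                                  repertoire = repertoire_config(),
                                  n_variants = 100,
                                  variant_pass_fraction = 0.3,
                                  survival_hazard_ratio = 0.3,
                                  survival_n_per_group = 50) {
  dir.create(file.path(dir, "repertoires"), recursive = TRUE, showWarnings = FALSE)
  seed <- cohort$seed

  reps <- gen_repertoires(repertoire)
  for (nm in names(reps)) {
    write_repertoire(reps[[nm]], file.path(dir, "repertoires", paste0(nm, ".tsv")))
  }

  flow <- gen_flow_cohort(cohort)
  readr::write_csv(flow$panels, file.path(dir, "flow_panels.csv"), progress = FALSE)
  readr::write_csv(flow$truth, file.path(dir, "flow_truth.csv"), progress = FALSE)
  readr::write_csv(gen_flow_timecourse(cohort),
                   file.path(dir, "flow_timecourse.csv"), progress = FALSE)

  vars <- gen_variants(n_variants, variant_pass_fraction, seed = seed + 2L)
  readr::write_csv(vars$variants, file.path(dir, "variants.csv"), progress = FALSE)
  readr::write_csv(vars$truth, file.path(dir, "variant_truth.csv"), progress = FALSE)

  surv <- gen_survival(survival_n_per_group, survival_hazard_ratio,
                       censor_rate = 0.01, seed = seed + 3L)
  readr::write_csv(surv, file.path(dir, "survival.csv"), progress = FALSE)

  readr::write_csv(gen_roi_cohort(flow$truth, seed = seed + 4L),
                   file.path(dir, "roi.csv"), progress = FALSE)
  readr::write_csv(gen_elispot_plate(seed = seed + 5L),
                   file.path(dir, "elispot.csv"), progress = FALSE)

  manifest <- sort(setdiff(list.files(dir, recursive = TRUE), "manifest.json"))
  jsonlite::write_json(list(seed = seed, files = manifest),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

default_run_options <- function() {
  list(
    activation = list(rule = "geom_gate", threshold = 1, floor = 0.01),
    repertoire = list(identity = "cdr3_nt", top_n = 30, reactive_cutoff = 0.02),
    neoepitope = list(min_callers = 2, fpkm_threshold = 100, binding_cutoff = 0.5),
    elispot = list(cutoff = 100)
  )
}

merge_options <- function(defaults, user) {
  for (nm in names(user)) {
    unknown <- setdiff(names(user[[nm]]), names(defaults[[nm]]))
    if (!nm %in% names(defaults) || length(unknown) > 0) {
      abort(paste0("unknown option key(s): ",
                   paste(c(if (!nm %in% names(defaults)) nm, unknown), collapse = ", ")),
            class = "tilmonitor_bad_config")
    }
    defaults[[nm]][names(user[[nm]])] <- user[[nm]]
  }
  defaults
}

#' Load and validate a run configuration
#'
#' The config is a YAML file (or an equivalent list) with keys `inputs`
#' (paths per table kind: `flow_panels`, `flow_timecourse`,
#' `repertoire_dir`, `variants`, `survival`, `roi`, `elispot`), `options`
#' (per-stage settings), `seed` and `out_dir`. Unknown keys are rejected;
#' the resolved config is serialized verbatim into the output directory.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return A validated config list.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  allowed <- c("inputs", "options", "seed", "out_dir")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", "),
                 "; allowed: ", paste(allowed, collapse = ", ")),
          class = "tilmonitor_bad_config")
  }
  if (is.null(config$inputs) || length(config$inputs) == 0) {
    abort(paste0("config must list at least one input; required keys: ",
                 "inputs (with one or more table paths), out_dir"),
          class = "tilmonitor_bad_config")
  }
  input_kinds <- c("flow_panels", "flow_timecourse", "repertoire_dir",
                   "variants", "survival", "roi", "elispot")
  unknown_in <- setdiff(names(config$inputs), input_kinds)
  if (length(unknown_in) > 0) {
    abort(paste0("unknown input kind(s): ", paste(unknown_in, collapse = ", ")),
          class = "tilmonitor_bad_config")
  }
  if (is.null(config$out_dir)) {
    abort("config must set `out_dir`", class = "tilmonitor_bad_config")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$options <- merge_options(default_run_options(), config$options %||% list())
  config
}

#' Point a run configuration at a fixture directory
#'
#' Convenience constructor wiring every file written by
#' [write_cohort_fixtures()] into a [load_run_config()]-ready list.
#'
#' @param fixture_dir Directory from [write_cohort_fixtures()].
#' @param out_dir Output directory for the run.
#' @param seed Integer seed recorded in the summary.
#' @param options Optional per-stage option overrides.
#' @return A validated config list.
#' @export
fixture_run_config <- function(fixture_dir, out_dir, seed = 1, options = list()) {
  load_run_config(list(
    inputs = list(
      flow_panels = file.path(fixture_dir, "flow_panels.csv"),
      flow_timecourse = file.path(fixture_dir, "flow_timecourse.csv"),
      repertoire_dir = file.path(fixture_dir, "repertoires"),
      variants = file.path(fixture_dir, "variants.csv"),
      survival = file.path(fixture_dir, "survival.csv"),
      roi = file.path(fixture_dir, "roi.csv"),
      elispot = file.path(fixture_dir, "elispot.csv")
    ),
    options = options,
    seed = seed,
    out_dir = out_dir
  ))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
          class = "tilmonitor_stage_error", parent = e)
  })
}

round_sig <- function(x, digits = 6) {
  if (is.numeric(x)) signif(x, digits) else x
}

#' Run every configured analysis stage and write a cohort report bundle
#'
#' Executes the activation, repertoire, neoepitope, tissue, ELISpot and
#' survival stages for which inputs are configured; writes per-stage CSVs, a
#' single `summary.json`, a `report.txt` and a `run_log.json` (resolved
#' config plus an MD5 checksum of every input) into `out_dir`. Output is
#' deterministic: the same config and inputs yield byte-identical files.
#'
#' @param config A config path or list accepted by [load_run_config()].
#' @return The summary list, invisibly.
#' @export
run_cohort_analysis <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- cfg$inputs
  for (p in unlist(inputs)) {
    if (!file.exists(p)) {
      abort(paste0("configured input does not exist: ", p),
            class = "tilmonitor_bad_config")
    }
  }
  summary <- list(seed = cfg$seed, stages = character(0))
  wcsv <- function(x, name) {
    readr::write_csv(dplyr::mutate(x, dplyr::across(dplyr::where(is.numeric), round_sig)),
                     file.path(cfg$out_dir, name), progress = FALSE)
  }

  if (!is.null(inputs$flow_panels)) {
    res <- run_stage("activation", {
      panels <- read_subset_panels(inputs$flow_panels)
      opt <- cfg$options$activation
      results <- activation_index_cohort(panels, rule = opt$rule,
                                         threshold = opt$threshold,
                                         floor = opt$floor)
      classify_cohort(results)
    })
    wcsv(res$labels, "activation.csv")
    summary$stages <- c(summary$stages, "activation")
    summary$activation <- list(
      n_responders = res$n_responders,
      n_non_responders = res$n_non_responders,
      responder_ids = res$labels$patient_id[res$labels$responder]
    )
  }

  if (!is.null(inputs$flow_timecourse)) {
    res <- run_stage("timecourse", {
      timecourse_summary(read_subset_panels(inputs$flow_timecourse))
    })
    wcsv(res$summary, "timecourse.csv")
    summary$stages <- c(summary$stages, "timecourse")
    summary$timecourse_peaks <- setNames(
      as.character(res$peak$peak_timepoint), res$peak$subset)
  }

  if (!is.null(inputs$repertoire_dir)) {
    res <- run_stage("repertoire", {
      reps <- read_repertoire_dir(inputs$repertoire_dir)
      opt <- cfg$options$repertoire
      nms <- names(reps)
      clon <- tibble::tibble(
        sample = nms,
        clonality = vapply(reps, clonality, numeric(1)),
        richness = vapply(reps, function(r) nrow(filter_productive(r)), numeric(1)),
        top_n_mass = vapply(reps, function(r)
          cumulative_frequency(top_n_clones(r, opt$top_n)), numeric(1))
      )
      overlap <- tidyr::expand_grid(a = nms, b = nms) |>
        dplyr::filter(a < b) |>
        dplyr::mutate(morisita_horn = purrr::map2_dbl(a, b, function(i, j)
          morisita_horn(reps[[i]], reps[[j]], by = opt$identity)))
      list(clonality = clon, overlap = overlap)
    })
    wcsv(res$clonality, "clonality.csv")
    wcsv(res$overlap, "overlap.csv")
    summary$stages <- c(summary$stages, "repertoire")
    summary$repertoire <- list(
      samples = res$clonality$sample,
      mean_clonality = mean(res$clonality$clonality)
    )
  }

  if (!is.null(inputs$variants)) {
    res <- run_stage("neoepitope", {
      variants <- readr::read_csv(inputs$variants, show_col_types = FALSE,
                                  progress = FALSE)
      opt <- cfg$options$neoepitope
      neoepitope_chain(variants, min_callers = opt$min_callers,
                       fpkm_threshold = opt$fpkm_threshold,
                       binding_cutoff = opt$binding_cutoff)
    })
    wcsv(dplyr::select(res$filtered, -peptides), "neoepitope_filtered.csv")
    wcsv(res$scores, "neoepitope_peptides.csv")
    summary$stages <- c(summary$stages, "neoepitope")
    summary$neoepitope <- list(
      n_input = nrow(res$filtered) + nrow(res$rejected),
      n_filtered = nrow(res$filtered),
      n_candidates = nrow(res$candidates),
      n_peptides = nrow(res$scores)
    )
  }

  if (!is.null(inputs$roi)) {
    res <- run_stage("tissue", {
      roi <- readr::read_csv(inputs$roi, show_col_types = FALSE, progress = FALSE)
      roi_aggregate(roi)
    })
    wcsv(res, "tissue_summary.csv")
    summary$stages <- c(summary$stages, "tissue")
    cd3 <- res |>
      dplyr::filter(phenotype == "CD3") |>
      dplyr::group_by(compartment) |>
      dplyr::summarise(mean_density = mean(mean_density), .groups = "drop")
    summary$tissue <- setNames(as.list(round_sig(cd3$mean_density)), cd3$compartment)
  }

  if (!is.null(inputs$elispot)) {
    res <- run_stage("elispot", {
      wells <- readr::read_csv(inputs$elispot, show_col_types = FALSE,
                               progress = FALSE)
      dplyr::mutate(wells, positive = elispot_call(sfc, cfg$options$elispot$cutoff))
    })
    wcsv(res, "elispot_calls.csv")
    summary$stages <- c(summary$stages, "elispot")
    summary$elispot <- list(n_positive = sum(res$positive), n_wells = nrow(res))
  }

  if (!is.null(inputs$survival)) {
    res <- run_stage("survival", {
      surv <- read_survival(inputs$survival)
      km <- km_estimate(surv)
      lr <- if ("group" %in% names(surv) &&
                length(unique(surv$group)) == 2 && sum(surv$event) > 0) {
        logrank_test(surv)
      } else NULL
      fu <- withCallingHandlers(
        reverse_km_followup(surv),
        tilmonitor_undefined_median = function(w) invokeRestart("muffleWarning")
      )
      list(km = km, lr = lr, fu = fu)
    })
    wcsv(res$km$table, "survival_km.csv")
    summary$stages <- c(summary$stages, "survival")
    summary$survival <- list(
      median_survival = round_sig(res$km$median),
      median_followup = round_sig(res$fu$median_followup),
      logrank_chisq = if (!is.null(res$lr)) round_sig(res$lr$chisq),
      logrank_p = if (!is.null(res$lr)) round_sig(res$lr$p_value)
    )
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  writeLines(make_report(summary), file.path(cfg$out_dir, "report.txt"))
  input_files <- unlist(lapply(unlist(inputs), function(p) {
    if (dir.exists(p)) list.files(p, full.names = TRUE, recursive = TRUE) else p
  }))
  log <- list(
    config = cfg[c("inputs", "options", "seed", "out_dir")],
    input_md5 = as.list(tools::md5sum(input_files))
  )
  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}

#' Render a human-readable cohort report
#'
#' One titled section per executed stage, numbers at 4 significant digits,
#' all traceable to the stage CSVs written alongside the summary.
#'
#' @param summary The summary list produced by [run_cohort_analysis()].
#' @return A character vector of report lines.
#' @export
make_report <- function(summary) {
  stopifnot(length(summary$stages) >= 1)
  fmt <- function(x) format(signif(x, 4), trim = TRUE)
  lines <- c("Cohort immune-monitoring report",
             paste0("seed: ", summary$seed),
             paste0("stages: ", paste(summary$stages, collapse = ", ")), "")
  if ("activation" %in% summary$stages) {
    a <- summary$activation
    lines <- c(lines, "## Activation index",
               paste0("responders: ", a$n_responders, " / ",
                      a$n_responders + a$n_non_responders),
               paste0("responder ids: ", paste(a$responder_ids, collapse = ", ")), "")
  }
  if ("timecourse" %in% summary$stages) {
    p <- summary$timecourse_peaks
    lines <- c(lines, "## Peripheral time course (peak timepoint per subset)",
               paste0(names(p), ": ", unlist(p)), "")
  }
  if ("repertoire" %in% summary$stages) {
    r <- summary$repertoire
    lines <- c(lines, "## TCRb repertoire",
               paste0("samples: ", paste(r$samples, collapse = ", ")),
               paste0("mean clonality: ", fmt(r$mean_clonality)), "")
  }
  if ("neoepitope" %in% summary$stages) {
    ne <- summary$neoepitope
    lines <- c(lines, "## Neoepitope candidates",
               paste0("variants in: ", ne$n_input, "; passing filters: ",
                      ne$n_filtered, "; with binding peptides: ", ne$n_candidates),
               paste0("scored peptides: ", ne$n_peptides), "")
  }
  if ("tissue" %in% summary$stages) {
    t <- summary$tissue
    lines <- c(lines, "## Tissue (CD3 mean density, cells/mm2)",
               paste0(names(t), ": ", fmt(unlist(t))), "")
  }
  if ("elispot" %in% summary$stages) {
    e <- summary$elispot
    lines <- c(lines, "## ELISpot",
               paste0("positive wells: ", e$n_positive, " / ", e$n_wells), "")
  }
  if ("survival" %in% summary$stages) {
    s <- summary$survival
    lines <- c(lines, "## Survival",
               paste0("median follow-up (reverse KM): ",
                      fmt(s$median_followup), " months"),
               if (!is.null(s$logrank_p))
                 paste0("log-rank chisq: ", fmt(s$logrank_chisq),
                        ", p = ", fmt(s$logrank_p)), "")
  }
  lines
}
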