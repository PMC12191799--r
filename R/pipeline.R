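#' Declarative configuration for a full screening run
#'
#' Collects every tunable of the simulate - preprocess - screen - calibrate
#' - classify - enrich - score pipeline in one list that round-trips
#' losslessly through JSON ([save_run_config()] / [load_run_config()]).
#' With `simulate = TRUE` all inputs are generated; otherwise `expr_path`,
#' `clinical_path`, `gmt_path` and `citations_path` must point at existing
#' TSV/GMT files.
#'
#' @param simulate generate synthetic inputs instead of reading files.
#' @param n_subjects,n_features,effect_feature_ids,true_log_hazard,n_gene_sets,planted_overlap
#'   forwarded to [simulation_config()] / [generate_gene_sets()] when
#'   simulating.
#' @param expr_path,clinical_path,gmt_path,citations_path input files when
#'   not simulating.
#' @param anchor anchor gene ID.
#' @param stage_filter,min_days,max_days cohort inclusion rule.
#' @param z_threshold anchor-outlier cut, see [remove_anchor_outliers()].
#' @param improvement_factor see [improvement_filter()].
#' @param iterations Monte Carlo iterations for [calibrate()].
#' @param thresholds `"fixed_2"` (the +/-2.0 group boundaries) or
#'   `"empirical"` (the calibration's q025/q975).
#' @param alpha,k_clusters,top_n enrichment / triage tunables.
#' @param seed master seed for the whole run.
#' @return a `run_config` list.
#' @export
run_config <- function(simulate = TRUE,
                       n_subjects = 189L, n_features = 500L,
                       effect_feature_ids = character(),
                       true_log_hazard = log(2),
                       n_gene_sets = 10L, planted_overlap = 1.0,
                       expr_path = NULL, clinical_path = NULL,
                       gmt_path = NULL, citations_path = NULL,
                       anchor = "OPCML",
                       stage_filter = "IIIC",
                       min_days = 0L, max_days = 3650L,
                       z_threshold = 6,
                       improvement_factor = 0.9,
                       iterations = 10L,
                       thresholds = c("fixed_2", "empirical"),
                       alpha = 0.05, k_clusters = 20L, top_n = 30L,
                       seed = 1L) {
  thresholds <- match.arg(thresholds)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
save_run_config <- function(config, path) {
  # digits = I(17): doubles survive the JSON round trip bit for bit
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, digits = I(17), null = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$effect_feature_ids <- as.character(raw$effect_feature_ids)
  int_fields <- c(
    "n_subjects", "n_features", "n_gene_sets", "min_days", "max_days",
    "iterations", "k_clusters", "top_n", "seed"
  )
  dbl_fields <- c(
    "true_log_hazard", "planted_overlap", "z_threshold",
    "improvement_factor", "alpha"
  )
  for (nm in intersect(int_fields, names(raw))) raw[[nm]] <- as.integer(raw[[nm]])
  for (nm in intersect(dbl_fields, names(raw))) raw[[nm]] <- as.double(raw[[nm]])
  cfg <- do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
  for (nm in names(raw)) if (is.null(raw[[nm]])) cfg[nm] <- list(NULL)
  cfg
}

.stage <- function(name, expr) {
  message(sprintf("[ratiosurv] stage %s", name))
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
      call. = FALSE
    )
  })
}

#' Run the full anchor-ratio screening pipeline
#'
#' Executes the stages in order — simulate (or load), preprocess, screen,
#' calibrate, classify, enrich, score — writing every stage output plus a
#' run manifest under `out_dir`. Outputs are byte-stable under a fixed
#' config and seed (the manifest records versions and a config hash, never
#' a timestamp).
#'
#' Files written: `expression.tsv`, `clinical.tsv`, `gene_sets.gmt`,
#' `citations.tsv` (when simulating), `screen.tsv`, `calibration.json`,
#' `null_hrz.tsv`, `enriched.tsv`, `triage.tsv`, `manifest.json`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results
#'   (`records`, `calibration`, `enriched`, `triage_table`, `manifest`).
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  if (isTRUE(config$simulate)) {
    sim <- .stage("simulate", {
      sc <- simulation_config(
        n_subjects = config$n_subjects, n_features = config$n_features,
        anchor_feature_id = config$anchor,
        effect_feature_ids = config$effect_feature_ids,
        true_log_hazard = config$true_log_hazard,
        censor_horizon = config$max_days,
        seed = config$seed
      )
      expr <- generate_expression(sc)
      cohort <- generate_survival(sc, expr)
      sets <- generate_gene_sets(sc,
        n_sets = config$n_gene_sets,
        planted_overlap = config$planted_overlap
      )
      citations <- synthetic_citation_counts(sets$universe, seed = config$seed)
      write_expression_tsv(expr, p("expression.tsv"))
      write_clinical_tsv(cohort, p("clinical.tsv"))
      write_gmt(sets, p("gene_sets.gmt"))
      utils::write.table(citations, p("citations.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      list(expr = expr, cohort = cohort, sets = sets, citations = citations)
    })
    expr <- sim$expr; cohort <- sim$cohort
    sets <- sim$sets; citations <- sim$citations
  } else {
    loaded <- .stage("load", {
      list(
        expr = read_expression_tsv(config$expr_path),
        cohort = read_clinical_tsv(config$clinical_path),
        sets = read_gmt(config$gmt_path),
        citations = utils::read.delim(config$citations_path,
          stringsAsFactors = FALSE
        )
      )
    })
    expr <- loaded$expr; cohort <- loaded$cohort
    sets <- loaded$sets; citations <- loaded$citations
  }

  pre <- .stage("preprocess", {
    cohort_f <- filter_cohort(cohort,
      stage_filter = config$stage_filter,
      min_days = config$min_days, max_days = config$max_days
    )
    expr_f <- remove_anchor_outliers(expr, config$anchor, config$z_threshold)
    al <- suppressWarnings(align_subjects(expr_f, cohort_f))
    message(sprintf(
      "[ratiosurv]   %d subjects, %d features after preprocessing",
      ncol(al$expr), nrow(al$expr)
    ))
    al
  })

  records <- .stage("screen", {
    lg <- log2p4_transform(pre$expr)
    ratios <- compute_ratios(lg, config$anchor)
    screen_all(ratios, lg, pre$cohort,
      improvement_factor = config$improvement_factor
    )
  })

  calibration <- .stage("calibrate", {
    calibrate(pre$expr, pre$cohort, config$anchor,
      n_iterations = config$iterations,
      rng_seed = .derive_seed(config$seed, 7L)
    )
  })
  write_calibration_report(calibration, p("calibration.json"), p("null_hrz.tsv"))

  records <- .stage("classify", {
    thr <- if (config$thresholds == "empirical") {
      empirical_thresholds(calibration)
    } else {
      group_thresholds()
    }
    classify_groups(records, thr)
  })
  write_screen_tsv(records, p("screen.tsv"))
  message(sprintf(
    "[ratiosurv]   %d OPCML_plus, %d GENEi_plus, %d skipped",
    sum(records$group == "OPCML_plus"), sum(records$group == "GENEi_plus"),
    sum(!is.na(records$skipped_reason))
  ))

  enriched <- .stage("enrich", {
    en <- suppressWarnings(
      enrich_functions(records, sets, alpha = config$alpha)
    )
    en <- dedup_functions(en)
    if (nrow(en) >= 2L) {
      en <- cluster_functions(en, k = min(config$k_clusters, nrow(en)))
    } else if (nrow(en) > 0L) {
      en$cluster_id <- 1L
    }
    en
  })
  write_enrichment_tsv(enriched, p("enriched.tsv"))

  triage_table <- .stage("score", {
    if (nrow(enriched) == 0L) {
      enriched
    } else {
      tab <- fetch_counts(
        unique(unlist(enriched$member_hits)),
        citation_client_fixture(citations)
      )
      triage(enriched, tab, top_n = config$top_n)
    }
  })
  write_enrichment_tsv(triage_table, p("triage.tsv"))

  manifest <- .stage("manifest", {
    cfg_file <- tempfile(fileext = ".json")
    on.exit(unlink(cfg_file), add = TRUE)
    save_run_config(config, cfg_file)
    m <- list(
      package = "ratiosurv",
      package_version = as.character(utils::packageVersion("ratiosurv")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      survival_version = as.character(utils::packageVersion("survival")),
      seed = config$seed,
      config_hash = unname(tools::md5sum(cfg_file)),
      config = unclass(config)
    )
    jsonlite::write_json(m, p("manifest.json"),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
    )
    m
  })

  invisible(list(
    records = records, calibration = calibration,
    enriched = enriched, triage_table = triage_table, manifest = manifest
  ))
}
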