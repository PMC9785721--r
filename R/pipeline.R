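#' Pipeline scenario configuration
#'
#' Three reproducible experiment presets:
#' * `raw_unmix_9` - 250 raw spectra (100 NS, 90 BCC, 60 MM) on the full
#'   detector range with fluorescence and ripple retained, no preprocessing,
#'   unmixed into 9 components;
#' * `preprocessed_sweep_4_30` - the full cohort, preprocessed, normal-skin
#'   spectra unmixed into every component count of `sweep_range`;
#' * `basis_constrained_8` - the full cohort, preprocessed, unmixed into
#'   8 components of which 4 are the fixed library basis; the classification
#'   battery runs on the resolved concentrations.
#'
#' @param scenario one of the preset names.
#' @param seed root seed; all stage seeds are derived from it.
#' @param n_scale scale factor on the cohort class sizes (use < 1 for quick
#'   runs; 1 reproduces the stated cohort).
#' @param sweep_range component counts for the sweep scenario.
#' @param max_iter ALS iteration cap.
#' @param acquisition an [acquisition_model]; defaults to fluorescence +
#'   ripple + SNR 3 for `raw_unmix_9` and ripple + SNR 3 (no fluorescence
#'   survives preprocessing anyway) for the preprocessed scenarios.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = c("raw_unmix_9",
                                         "preprocessed_sweep_4_30",
                                         "basis_constrained_8"),
                            seed = 1, n_scale = 1,
                            sweep_range = 4:30, max_iter = 150,
                            acquisition = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(acquisition)) acquisition <- acquisition_model(target_snr = 3)
  structure(list(scenario = scenario, seed = as.integer(seed),
                 n_scale = n_scale, sweep_range = sweep_range,
                 max_iter = as.integer(max_iter),
                 acquisition = acquisition),
            class = "pipeline_config")
}

scenario_profiles <- function(config) {
  if (config$scenario == "raw_unmix_9") {
    base <- default_class_profiles(n_scale = config$n_scale)
    n <- function(k) max(1L, as.integer(round(k * config$n_scale)))
    base$NS$n_samples <- n(100)
    base$BCC$n_samples <- n(90)
    base$MM$n_samples <- n(60)
    base[c("NS", "BCC", "MM")]
  } else {
    default_class_profiles(n_scale = config$n_scale)
  }
}

write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  path
}

#' Run a pipeline scenario
#'
#' Executes generate -> (preprocess) -> rank -> unmix (-> classify) and
#' writes all artifacts plus a manifest (config echo, seed, file checksums,
#' metric summary) to `out_dir`. A rerun with the same config and seed
#' reproduces the files bit for bit.
#'
#' @param config a [pipeline_config].
#' @param out_dir artifact directory (created if needed).
#' @return invisible list with the in-memory results (`dataset`, `spectra`,
#'   `rank`, `models`, `report`, `manifest_path`).
#' @export
run_scenario <- function(config, out_dir = tempfile("scenario_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "generate"
  res <- tryCatch({
    grid <- default_grid(raw = config$scenario == "raw_unmix_9")
    profiles <- scenario_profiles(config)
    dataset <- simulate_dataset(profiles,
                                library = build_component_library(grid),
                                acquisition = config$acquisition,
                                grid = grid, seed = config$seed)
    write_dataset(dataset, file.path(out_dir, "dataset"))
    spectra <- dataset$spectra

    if (config$scenario != "raw_unmix_9") {
      stage <- "preprocess"
      spectra <- preprocess_spectra(spectra, crop = c(1114, 1874))
      write_spectra_csv(spectra, file.path(out_dir, "preprocessed.csv"))
    }

    stage <- "rank"
    rk <- scan_rank(spectra, max_rank = min(30, nrow(spectra$values)))
    write_matrix_csv(data.frame(rank = seq_along(rk$singular_values),
                                singular_value = rk$singular_values),
                     file.path(out_dir, "scree.csv"))

    stage <- "unmix"
    models <- list(); report <- NULL
    if (config$scenario == "raw_unmix_9") {
      cfg <- mcr_config(9, max_iter = config$max_iter, seed = config$seed)
      models[["A9"]] <- fit_mcr(spectra, cfg)
    } else if (config$scenario == "preprocessed_sweep_4_30") {
      ns <- spectra
      keep <- ns$labels == "NS"
      ns$values <- ns$values[keep, , drop = FALSE]
      ns$labels <- ns$labels[keep]
      for (A in config$sweep_range) {
        cfg <- mcr_config(A, max_iter = config$max_iter, seed = config$seed)
        models[[paste0("A", A)]] <- fit_mcr(ns, cfg)
      }
    } else {
      basis <- dataset$s_true
      models[["A8"]] <- fit_with_basis(spectra, basis, n_free = 4,
                                       max_iter = config$max_iter,
                                       seed = config$seed)
      stage <- "classify"
      report <- run_contrasts(models[["A8"]], spectra$labels,
                              seed = config$seed)
      save_report(report, file.path(out_dir, "classification"))
    }
    for (nm in names(models)) {
      write_matrix_csv(models[[nm]]$concentrations,
                       file.path(out_dir, paste0("C_", nm, ".csv")))
      write_matrix_csv(models[[nm]]$spectra,
                       file.path(out_dir, paste0("S_", nm, ".csv")))
      write_matrix_csv(models[[nm]]$trace,
                       file.path(out_dir, paste0("trace_", nm, ".csv")))
    }
    list(dataset = dataset, spectra = spectra, rank = rk, models = models,
         report = report)
  }, error = function(e) {
    stop("scenario '", config$scenario, "' failed at stage '", stage,
         "': ", conditionMessage(e), call. = FALSE)
  })

  metrics <- lapply(res$models, function(m)
    c(m$metrics, list(n_iter = m$n_iter_run, converged = m$converged)))
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    scenario = config$scenario, seed = config$seed,
    n_scale = config$n_scale, max_iter = config$max_iter,
    suggested_rank = res$rank$suggested_rank,
    metrics = metrics,
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(res, list(manifest_path = manifest_path, out_dir = out_dir)))
}

save_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  auc_rows <- list()
  for (ct in names(report$per_component))
    for (comp in names(report$per_component[[ct]])) {
      r <- report$per_component[[ct]][[comp]]
      auc_rows[[length(auc_rows) + 1]] <-
        data.frame(contrast = ct, scorer = comp, auc = r$auc,
                   ci_low = r$ci_low, ci_high = r$ci_high,
                   n_pos = r$n_pos, n_neg = r$n_neg)
    }
  for (ct in names(report$logistic)) {
    r <- report$logistic[[ct]]$roc
    auc_rows[[length(auc_rows) + 1]] <-
      data.frame(contrast = ct, scorer = "logistic", auc = r$auc,
                 ci_low = r$ci_low, ci_high = r$ci_high,
                 n_pos = r$n_pos, n_neg = r$n_neg)
  }
  for (ct in names(report$plsda)) {
    r <- report$plsda[[ct]]$roc
    auc_rows[[length(auc_rows) + 1]] <-
      data.frame(contrast = ct, scorer = "plsda", auc = r$auc,
                 ci_low = r$ci_low, ci_high = r$ci_high,
                 n_pos = r$n_pos, n_neg = r$n_neg)
  }
  write_matrix_csv(do.call(rbind, auc_rows), file.path(dir, "auc.csv"))
  pv <- lapply(report$logistic, function(x) as.list(x$report$wald_p_values))
  jsonlite::write_json(pv, file.path(dir, "logistic_p_values.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bp <- do.call(rbind, lapply(names(report$boxplots), function(nm) {
    b <- report$boxplots[[nm]]
    b$component <- nm
    as.data.frame(b)
  }))
  write_matrix_csv(bp, file.path(dir, "boxplots.csv"))
  invisible(dir)
}

#' Command-line entry point
#'
#' Minimal subcommand dispatcher, e.g.
#' `Rscript -e 'ramanmcr::raman_cli()' run --scenario basis_constrained_8
#'  --seed 1 --out outdir --n-scale 0.1`.
#' Subcommands: `simulate`, `preprocess`, `rank`, `unmix`, `run`.
#'
#' @param args character vector of arguments (defaults to the command line).
#' @return invisibly, the result of the dispatched operation.
#' @export
raman_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: <simulate|preprocess|rank|unmix|run> [--key value ...]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    opts[[gsub("-", "_", key)]] <- rest[i + 1]
    i <- i + 2
  }
  get <- function(name, default) {
    if (!is.null(opts[[name]])) opts[[name]] else default
  }
  seed <- as.integer(get("seed", 1))
  out <- get("out", tempfile("ramanmcr_"))
  switch(cmd,
    simulate = {
      ds <- simulate_dataset(
        default_class_profiles(n_scale = as.numeric(get("n_scale", 1))),
        acquisition = acquisition_model(
          target_snr = as.numeric(get("snr", 3))),
        seed = seed)
      write_dataset(ds, out)
      cat("dataset written to", out, "\n")
      invisible(ds)
    },
    preprocess = {
      sp <- read_spectra_csv(get("input", stop("--input required")))
      sp <- preprocess_spectra(sp)
      write_spectra_csv(sp, out)
      cat("preprocessed spectra written to", out, "\n")
      invisible(sp)
    },
    rank = {
      sp <- read_spectra_csv(get("input", stop("--input required")))
      rk <- scan_rank(sp, max_rank = as.integer(get("max", 30)))
      print(rk)
      invisible(rk)
    },
    unmix = {
      sp <- read_spectra_csv(get("input", stop("--input required")))
      fixed <- NULL
      if (!is.null(opts$basis)) {
        basis <- read_basis_csv(opts$basis)
        if (ncol(basis) != length(sp$axis))
          stop("basis grid does not match the spectra grid")
        fixed <- basis
      }
      cfg <- mcr_config(as.integer(get("components",
                                       if (is.null(fixed)) 4 else
                                         nrow(fixed))),
                        max_iter = as.integer(get("max_iter", 150)),
                        conv_tol_pct = as.numeric(get("tol", 0.1)),
                        allowed_noise_pct = as.numeric(get("noise", 10)),
                        fixed_spectra = fixed, seed = seed)
      m <- fit_mcr(sp, cfg)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_matrix_csv(m$concentrations, file.path(out, "C.csv"))
      write_matrix_csv(m$spectra, file.path(out, "S.csv"))
      write_matrix_csv(m$trace, file.path(out, "trace.csv"))
      jsonlite::write_json(m$metrics, file.path(out, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      print(m)
      invisible(m)
    },
    run = {
      cfg <- pipeline_config(get("scenario", "basis_constrained_8"),
                             seed = seed,
                             n_scale = as.numeric(get("n_scale", 1)),
                             max_iter = as.integer(get("max_iter", 150)))
      res <- run_scenario(cfg, out)
      cat("artifacts written to", out, "\n")
      invisible(res)
    },
    stop("unknown subcommand: ", cmd)
  )
}
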