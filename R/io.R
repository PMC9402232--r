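.record_cols <- c("construct", "filament_id", "event_id", "assay",
                  "n_steps", "is_last_step", "force_pN", "lifetime_s")

#' Read and validate force-lifetime records
#'
#' Reads the CSV record schema (\code{construct, filament_id, event_id,
#' assay, n_steps, is_last_step, force_pN, lifetime_s}); the two numeric
#' columns are required, the rest are filled with defaults when absent, and
#' unknown columns are preserved untouched.
#'
#' @param path CSV file path.
#' @return Validated records \code{data.frame}.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("force_pN", "lifetime_s")) {
    if (!col %in% names(df)) stop("missing column ", col)
    df[[col]] <- as.numeric(df[[col]])
  }
  bad <- which(!is.finite(df$lifetime_s) | df$lifetime_s <= 0)
  if (length(bad)) {
    stop("non-positive or missing lifetime_s at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(!is.finite(df$force_pN))
  if (length(bad)) {
    stop("non-finite force_pN at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!"construct" %in% names(df)) df$construct <- "unknown"
  if (!"filament_id" %in% names(df)) df$filament_id <- "f001"
  if (!"event_id" %in% names(df)) df$event_id <- sprintf("e%06d", seq_len(nrow(df)))
  if (!"assay" %in% names(df)) df$assay <- "constant"
  if (!"n_steps" %in% names(df)) df$n_steps <- 1L
  if (!"is_last_step" %in% names(df)) df$is_last_step <- TRUE
  if (any(df$n_steps < 1)) stop("n_steps must be >= 1")
  df
}

#' @rdname read_records
#' @param records Records \code{data.frame}.
#' @param path Output CSV path.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write/read a raw trace as CSV plus JSON sidecar
#'
#' The trace goes to a two-column CSV (\code{time_s, force_pN}); sampling
#' rate, waveform, stiffness, seed and ground-truth annotations go to
#' \code{<path>.json}.
#'
#' @param trace A \code{\link{trap_trace}}.
#' @param path CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_trace <- function(trace, path) {
  tt <- seq_along(trace$force) / trace$fs
  utils::write.csv(data.frame(time_s = tt, force_pN = trace$force), path,
                   row.names = FALSE, quote = FALSE)
  side <- list(sampling_rate = trace$fs, waveform = trace$waveform,
               stiffness = trace$stiffness,
               metadata = trace$metadata[setdiff(names(trace$metadata), "clean")])
  if (!is.null(trace$truth)) {
    tr <- trace$truth
    tr$boundaries <- NULL
    side$truth <- tr
  }
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = I(17),
                              null = "null", dataframe = "columns"),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  truth <- if (!is.null(side$truth)) as.data.frame(side$truth) else NULL
  trap_trace(df$force_pN, side$sampling_rate, waveform = side$waveform,
             stiffness = side$stiffness, metadata = side$metadata,
             truth = truth)
}

#' Export detected events as ingestible records
#'
#' Writes the detector output in the record CSV schema so detected events can
#' be re-read (after optional manual editing) with \code{\link{read_records}}.
#'
#' @param events Detection \code{data.frame}
#'   (\code{\link{annotate_constant_force_events}} output).
#' @param path Output CSV path.
#' @param construct,filament_id,assay Metadata stamped on every row.
#' @param drop_excluded Drop rows with a non-missing exclusion reason?
#' @return Invisibly, the written records \code{data.frame}.
#' @export
write_detected_events <- function(events, path, construct = "unknown",
                                  filament_id = "f001", assay = "constant",
                                  drop_excluded = TRUE) {
  ev <- events
  if (drop_excluded && "excluded_reason" %in% names(ev)) {
    ev <- ev[is.na(ev$excluded_reason), , drop = FALSE]
  }
  rec <- data.frame(construct = construct, filament_id = filament_id,
                    event_id = sprintf("e%06d", seq_len(nrow(ev))),
                    assay = assay, n_steps = ev$n_steps,
                    is_last_step = TRUE,
                    force_pN = ev$last_step_force_pN,
                    lifetime_s = ev$last_step_lifetime_s)
  write_records(rec, path)
  invisible(rec)
}

#' Write a fit report (Table-style JSON)
#'
#' Serializes one or more fits to a JSON report: per-fit parameters laid out
#' per transition (columns 2->0, 2->1, 1->0, 1->2 for the catch bond, B->U
#' for the slip bond) with k0 and x rows, logL, AIC/BIC, and a delta-AIC /
#' delta-BIC comparison table when several fits are given.
#'
#' @param fits A \code{bond_fit} or named list of them.
#' @param path Output JSON path.
#' @return Invisibly, the report list.
#' @export
write_fit_report <- function(fits, path) {
  if (inherits(fits, "bond_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$model_kind, character(1))
  }
  tr_table <- function(fit) {
    m <- fit$model
    cols <- switch(fit$model_kind,
      slip = list("B->U" = m$bu),
      two_state_slip = list("B1->U" = m$b1u, "B2->U" = m$b2u),
      catch = list("2->0" = m$t20, "2->1" = m$t21, "1->0" = m$t10,
                   "1->2" = m$t12))
    lapply(cols, .tr_to_list)
  }
  rep_fit <- function(fit) {
    out <- list(model_kind = fit$model_kind,
                transitions = tr_table(fit),
                theta = as.list(fit$theta), free = fit$free,
                logL = fit$logL, n_obs = fit$n_obs, n_free = fit$n_free,
                aic = fit$aic, bic = fit$bic,
                converged = fit$converged, seed = fit$seed,
                method = fit$method)
    if (fit$model_kind == "two_state_slip") out$p1 <- fit$model$p1
    if (fit$model_kind == "catch") out$pi0 <- fit$model$pi0
    out
  }
  report <- list(fits = lapply(fits, rep_fit))
  if (length(fits) > 1) {
    report$comparison <- compare_fits(fits)
  }
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = I(17),
                              null = "null", dataframe = "columns"),
             path)
  invisible(report)
}

#' Rebuild fit results from a report file
#'
#' @param path JSON report path.
#' @return Named list of \code{bond_fit} objects.
#' @export
read_fit_report <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(rep$fits, function(f) {
    slots <- .param_slots(f$model_kind,
                          directional = any(grepl("x_minus", names(f$theta))))
    th <- unlist(f$theta)
    pi0 <- if (!is.null(f$pi0)) unlist(f$pi0) else c(1, 0)
    model <- .build_model(f$model_kind, th, slots,
                          directional = any(grepl("x_minus", names(th))),
                          pi0 = pi0)
    .make_fit_result(f$model_kind, model, th, unlist(f$free), f$logL,
                     f$n_obs, isTRUE(f$converged), f$seed, f$method)
  })
}

#' Run a simulate -> fit -> stats pipeline from a config
#'
#' Executes a reproducible end-to-end run: simulate a dataset from a
#' configured generating model (or load records from CSV), fit the requested
#' models, compare them, and write fit report, records and a manifest to the
#' output directory. Every stochastic stage takes its seed from the config,
#' so identical configs give identical outputs.
#'
#' @param config YAML file path or an R list with elements:
#'   \code{seed}; \code{kBT} (optional); either \code{records} (CSV path) or
#'   \code{simulate} (list: \code{model} (JSON string/path or model list),
#'   \code{n_events}, \code{assay}, optional \code{molecules_per_event},
#'   \code{n_filaments}); \code{fit} (list: \code{models} = character subset
#'   of slip/two_state_slip/catch, optional \code{epochs}, \code{population},
#'   \code{fixed}, \code{directional}); optional \code{bootstrap} (list:
#'   \code{model}, \code{n_boot}, \code{level}).
#' @param out_dir Output directory (created if needed).
#' @return List: records, fits, comparison, optional bootstrap, manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- physical_config(if (!is.null(config$kBT)) config$kBT else 4.11)
  seed <- as.integer(config$seed)
  stage <- "input"
  res <- tryCatch({
    records <- if (!is.null(config$records)) {
      read_records(config$records)
    } else {
      stage <- "simulate"
      sim <- config$simulate
      model <- if (is.character(sim$model)) model_from_json(sim$model) else
        model_from_json(jsonlite::toJSON(sim$model, auto_unbox = TRUE, digits = I(17)))
      simulate_dataset(model, n_events = sim$n_events,
                       molecules_per_event = sim$molecules_per_event,
                       assay = if (is.null(sim$assay)) "constant" else sim$assay,
                       n_filaments = if (is.null(sim$n_filaments)) 10L else
                         sim$n_filaments,
                       cfg = cfg, seed = seed)
    }
    write_records(records, file.path(out_dir, "records.csv"))
    stage <- "fit"
    fits <- list()
    for (mk in config$fit$models) {
      fits[[mk]] <- if (mk == "catch") {
        fit_catch_genetic(records,
                          epochs = if (is.null(config$fit$epochs)) 100 else
                            config$fit$epochs,
                          population = if (is.null(config$fit$population)) 200 else
                            config$fit$population,
                          directional = isTRUE(config$fit$directional),
                          fixed = unlist(config$fit$fixed),
                          cfg = cfg, seed = seed + 1L)
      } else {
        fit_mle_local(mk, records, fixed = unlist(config$fit$fixed),
                      cfg = cfg, seed = seed + 1L)
      }
    }
    write_fit_report(fits, file.path(out_dir, "fits.json"))
    boot <- NULL
    if (!is.null(config$bootstrap)) {
      stage <- "bootstrap"
      bc <- config$bootstrap
      boot <- bootstrap_mle(records, bc$model,
                            n_boot = bc$n_boot,
                            level = if (is.null(bc$level)) 95 else bc$level,
                            boot_epochs = if (is.null(bc$epochs)) 20 else bc$epochs,
                            point_fit = fits[[bc$model]],
                            cfg = cfg, seed = seed + 2L)
      utils::write.csv(as.data.frame(boot$replicates),
                       file.path(out_dir, "bootstrap_replicates.csv"),
                       row.names = FALSE)
    }
    stage <- "manifest"
    manifest <- list(
      seed = seed, kBT = cfg$kBT,
      n_records = nrow(records),
      stages = c("simulate/load", "fit",
                 if (!is.null(boot)) "bootstrap"),
      outputs = list.files(out_dir),
      checksums = vapply(list.files(out_dir, full.names = TRUE),
                         function(f) unname(unclass(tools::md5sum(f))),
                         character(1)),
      package_version = as.character(utils::packageVersion("catchbond")))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = I(17)),
               file.path(out_dir, "manifest.json"))
    list(records = records, fits = fits,
         comparison = if (length(fits) > 1) compare_fits(fits) else NULL,
         bootstrap = boot, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}
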