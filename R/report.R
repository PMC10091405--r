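# Orchestration: run every analysis stage over one or more labeled
# ensembles, aggregate replicates, and write the table/matrix/grid exports.

#' Assemble an analysis configuration
#'
#' @param inputs named list: label -> input (a structure file path or a
#'   `conformer_ensemble`).  Labels must be unique and paths must exist.
#' @param reference optional reference for the RMSD stage: a structure file
#'   path or coordinate matrix; default is each ensemble's first frame.
#' @param endpoints optional 2-vector of end-to-end endpoint atom indices
#'   (default: C1 of the first residue, C4 of the last).
#' @param hbond an [hbond_criterion()].
#' @param bin_width phi/psi histogram bin width in degrees.
#' @param temperature temperature in Kelvin for Boltzmann inversion.
#' @param windows pucker classification windows ([pucker_windows()]).
#' @param aliases residue-name alias table (e.g. [heparin_aliases()]).
#' @param volume_selection `"all"` (default) or `"heavy"` atoms for the
#'   MVEE volume stage.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(inputs, reference = NULL, endpoints = NULL,
                            hbond = hbond_criterion(), bin_width = 5,
                            temperature = 300, windows = pucker_windows(),
                            aliases = heparin_aliases(),
                            volume_selection = c("all", "heavy")) {
  if (!length(inputs) || is.null(names(inputs)) ||
      anyDuplicated(names(inputs)) || any(!nzchar(names(inputs))))
    stop("inputs must be a named list with unique labels", call. = FALSE)
  for (x in inputs)
    if (is.character(x) && !file.exists(x))
      stop("input path does not exist: ", x, call. = FALSE)
  structure(list(inputs = inputs, reference = reference,
                 endpoints = endpoints, hbond = hbond,
                 bin_width = bin_width, temperature = temperature,
                 windows = windows, aliases = aliases,
                 volume_selection = match.arg(volume_selection)),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Recognized keys: `inputs` (map label -> path), `reference`, `bin_width`,
#' `temperature`, `hbond: {max_da_distance, min_dha_angle}`,
#' `volume_selection`.
#'
#' @param path YAML file path.
#' @return an [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$inputs)) stop("config must list inputs", call. = FALSE)
  hb <- if (!is.null(y$hbond))
    hbond_criterion(y$hbond$max_da_distance %||% 3.0,
                    y$hbond$min_dha_angle %||% 135)
  else hbond_criterion()
  analysis_config(inputs = as.list(y$inputs),
                  reference = y$reference,
                  bin_width = y$bin_width %||% 5,
                  temperature = y$temperature %||% 300,
                  hbond = hb,
                  volume_selection = y$volume_selection %||% "all")
}

run_stage <- function(bundle_label, stage, expr) {
  tryCatch(list(status = "done", value = expr),
           error = function(e) {
             warning(bundle_label, "/", stage, " failed: ",
                     conditionMessage(e), call. = FALSE)
             list(status = "failed", reason = conditionMessage(e))
           })
}

#' Run the full descriptor analysis over labeled ensembles
#'
#' For every label: the five global descriptors (end-to-end distance,
#' atomic fluctuations, RMSD, radius of gyration, MVEE volume) as
#' mean +/- SD summaries, per-ring pucker occupancies, pooled phi/psi
#' free-energy grids per ordered linkage type, and the residue
#' hydrogen-bond contact map.  Stage failures are isolated per label and
#' stage -- each stage in the returned bundle is `"done"` or
#' `"failed"` with a reason, never silently dropped.
#'
#' @param config an [analysis_config()].
#' @return list of class `report_bundle`: per-label stage results plus a
#'   provenance block (config echo, package version, timestamp).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  labels <- names(config$inputs)
  per_label <- lapply(labels, function(lab) {
    ens <- tryCatch({
      x <- config$inputs[[lab]]
      if (inherits(x, "conformer_ensemble")) x else read_structure(x)
    }, error = function(e) e)
    if (inherits(ens, "error"))
      return(list(status = "failed", reason = conditionMessage(ens)))
    ref <- config$reference
    if (is.character(ref)) ref <- frame_coords(read_structure(ref), 1L)
    vol_sel <- if (config$volume_selection == "heavy")
      heavy_atoms(ens$topology) else NULL

    summaries <- run_stage(lab, "descriptors", {
      out <- list(
        dist = summarize_series(end_to_end_distance(ens, config$endpoints)),
        radgyr = summarize_series(radius_of_gyration(ens)),
        RMSD = summarize_series(rmsd_series(ens, ref %||% 1L)),
        volume = summarize_series(volume_series(ens, vol_sel)))
      if (n_frames(ens) >= 2L)
        out$fluct <- atomic_fluctuations(ens)$summary
      out
    })
    pucker <- run_stage(lab, "pucker", {
      pucker_occupancy(ens, windows = config$windows)
    })
    landscape <- run_stage(lab, "landscape", {
      lk <- identify_glycosidic_linkages(ens$topology, config$aliases)
      if (!nrow(lk)) stop("no glycosidic linkages identified")
      series <- lapply(seq_len(nrow(lk)), function(i)
        phi_psi_series(ens, lk[i, ]))
      types <- vapply(series, `[[`, "", "linkage_type")
      grids <- lapply(unique(types), function(tp)
        free_energy_map(pooled_histogram(series[types == tp], tp,
                                         config$bin_width),
                        config$temperature))
      names(grids) <- unique(types)
      grids
    })
    hbonds <- run_stage(lab, "hbond", {
      residue_contact_map(ens, config$hbond)
    })
    list(status = "done", summaries = summaries, pucker = pucker,
         landscape = landscape, hbond = hbonds)
  })
  names(per_label) <- labels
  structure(list(labels = per_label,
                 provenance = list(
                   package = "gagshape",
                   version = as.character(utils::packageVersion("gagshape")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   sd_convention = "population (divide by n)",
                   config = list(bin_width = config$bin_width,
                                 temperature = config$temperature,
                                 volume_selection = config$volume_selection,
                                 hbond = unclass(config$hbond)))),
            class = "report_bundle")
}

#' Write a report bundle to a directory
#'
#' Writes `summary.tsv` (label, descriptor, mean, sd, n, sd_convention),
#' `pucker_occupancy.tsv`, `fe_map_<type>.csv` grids, `hbond_map.csv`
#' matrices and `provenance.json`, and returns a manifest of every file
#' with its MD5 checksum.  Deterministic stages rewrite bit-identically on
#' identical input.
#'
#' @param bundle a `report_bundle` from [run_analysis()].
#' @param directory output directory (created if needed).
#' @return data.frame manifest (`file`, `md5`), invisibly written as
#'   `manifest.tsv` as well.
#' @export
write_report <- function(bundle, directory) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", directory, call. = FALSE)
  probe <- file.path(directory, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory not writable: ", directory,
                        call. = FALSE)
  unlink(probe)
  files <- character()
  emit <- function(fname) files <<- c(files, fname)

  sum_rows <- NULL
  pucker_rows <- NULL
  for (lab in names(bundle$labels)) {
    b <- bundle$labels[[lab]]
    if (!identical(b$status, "done")) next
    if (identical(b$summaries$status, "done")) {
      for (s in b$summaries$value)
        sum_rows <- rbind(sum_rows, data.frame(
          label = lab, descriptor = s$name, mean = s$mean, sd = s$sd,
          n = s$n, sd_convention = "population", stringsAsFactors = FALSE))
    }
    if (identical(b$pucker$status, "done"))
      pucker_rows <- rbind(pucker_rows,
                           cbind(label = lab, b$pucker$value))
    if (identical(b$landscape$status, "done")) {
      for (tp in names(b$landscape$value)) {
        safe <- gsub("[^A-Za-z0-9]+", "_", tp)
        f <- paste0("fe_map_", lab, "_", safe, ".csv")
        write_fe_grid(b$landscape$value[[tp]],
                      file.path(directory, paste0("fe_map_", lab, "_", safe,
                                                  ".tsv")),
                      file.path(directory, f))
        emit(paste0("fe_map_", lab, "_", safe, ".tsv")); emit(f)
      }
    }
    if (identical(b$hbond$status, "done")) {
      f <- paste0("hbond_map_", lab, ".csv")
      write_contact_map(b$hbond$value,
                        file.path(directory, paste0("hbond_map_", lab,
                                                    ".tsv")),
                        file.path(directory, f))
      emit(paste0("hbond_map_", lab, ".tsv")); emit(f)
    }
  }
  if (!is.null(sum_rows)) {
    utils::write.table(sum_rows, file.path(directory, "summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    emit("summary.tsv")
  }
  if (!is.null(pucker_rows)) {
    utils::write.table(pucker_rows,
                       file.path(directory, "pucker_occupancy.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    emit("pucker_occupancy.tsv")
  }
  status <- lapply(bundle$labels, function(b) {
    if (!identical(b$status, "done")) return(list(status = b$status,
                                                  reason = b$reason))
    lapply(b[c("summaries", "pucker", "landscape", "hbond")], function(st)
      if (identical(st$status, "done")) "done"
      else paste0("failed: ", st$reason))
  })
  jsonlite::write_json(list(provenance = bundle$provenance, stages = status),
                       file.path(directory, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  emit("provenance.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(directory,
                                                              files))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(directory, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest
}

#' Did every stage of a bundle succeed?
#'
#' @param bundle a `report_bundle`.
#' @return `TRUE` if every label and stage is `"done"`.
#' @export
bundle_ok <- function(bundle) {
  all(vapply(bundle$labels, function(b) {
    identical(b$status, "done") &&
      all(vapply(b[c("summaries", "pucker", "landscape", "hbond")],
                 function(st) identical(st$status, "done"), logical(1L)))
  }, logical(1L)))
}
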