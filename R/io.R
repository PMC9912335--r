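# Trace, event, and spectrum file I/O, configuration, and the pipeline
# driver. Traces are stored as CSV with a commented JSON metadata header, so
# samples round-trip bit-exactly and metadata losslessly through plain text.

trace_meta <- function(trace) {
  list(format = "neotrap-trace", version = 1L,
       sample_rate = trace$acquisition$sample_rate,
       cutoff = trace$acquisition$cutoff,
       filter_family = trace$acquisition$filter_family,
       filter_order = trace$acquisition$filter_order,
       duration = trace$duration,
       seed = trace$seed,
       preset = trace$preset %||% NA,
       protocol = list(duration_s = trace$protocol$duration_s,
                       voltage_mV = trace$protocol$voltage_mV),
       noise = unclass(trace$noise),
       scheme = unclass(trace$scheme))
}

#' Write a current trace to CSV
#'
#' Header lines starting with `#` carry the full generator/acquisition
#' metadata as one JSON object; the body has `time_s` and `current_pA`
#' columns. Samples are written with full double precision (17 significant
#' digits) so that write -> read is bit-exact.
#'
#' @param trace A `current_trace`.
#' @param path Output path (.csv).
#' @return Invisibly, the path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  if (!grepl("\\.csv$", path, ignore.case = TRUE))
    stop("write_trace: unknown extension (expected .csv): ", path)
  meta <- jsonlite::toJSON(trace_meta(trace), auto_unbox = TRUE, digits = NA,
                           null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", meta), "time_s,current_pA"), con)
  tt <- (seq_along(trace$current) - 0.5) * trace$time_step
  writeLines(paste(formatC(tt, digits = 17, format = "g"),
                   formatC(trace$current, digits = 17, format = "g"),
                   sep = ","), con)
  invisible(path)
}

#' Read a current trace written by [write_trace()]
#'
#' @param path CSV path.
#' @return A `current_trace` with the original metadata.
#' @export
read_trace <- function(path) {
  if (!grepl("\\.csv$", path, ignore.case = TRUE))
    stop("read_trace: unknown extension (expected .csv): ", path)
  head2 <- readLines(path, n = 2)
  if (length(head2) < 2 || !startsWith(head2[1], "# ") ||
      !identical(head2[2], "time_s,current_pA"))
    stop("read_trace: malformed header in ", path)
  meta <- jsonlite::fromJSON(sub("^# ", "", head2[1]))
  if (!identical(meta$format, "neotrap-trace"))
    stop("read_trace: not a neotrap trace file")
  d <- utils::read.csv(path, comment.char = "#")
  acq <- acquisition_spec(meta$sample_rate, meta$cutoff, meta$filter_family,
                          meta$filter_order)
  sc <- meta$scheme
  scheme <- kinetic_scheme(i0_pA = sc$i0_pA, docked_frac = sc$docked_frac,
                           attempt_frac = sc$attempt_frac,
                           trapped_frac = sc$trapped_frac,
                           dock_rate = sc$dock_rate,
                           undock_rate = sc$undock_rate,
                           undock_rate_neg = sc$undock_rate_neg,
                           lock_rate = sc$lock_rate,
                           capture_rate = sc$capture_rate,
                           escape_rate = sc$escape_rate,
                           v_ref_mV = sc$v_ref_mV)
  tr <- structure(list(
    current = d$current_pA, time_step = 1 / meta$sample_rate,
    duration = meta$duration, acquisition = acq,
    noise = noise_model(meta$noise$white_psd, meta$noise$pink_A,
                        meta$noise$alpha),
    protocol = voltage_protocol(meta$protocol$duration_s,
                                meta$protocol$voltage_mV),
    scheme = scheme, seed = as.numeric(meta$seed)), class = "current_trace")
  if (!is.null(meta$preset) && !is.na(meta$preset)) tr$preset <- meta$preset
  tr
}

#' Write / read an event table as CSV
#'
#' Columns `start`, `end`, `dwell_s`, `mean_pA`, `rel_blockade`,
#' `quality_ok`; detection settings in a `#` JSON header.
#'
#' @param events An `event_table`.
#' @param path CSV path.
#' @return Invisibly the path (write) or an `event_table` (read).
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  meta <- jsonlite::toJSON(
    list(format = "neotrap-events", baseline = attr(events, "baseline"),
         sigma = attr(events, "sigma"), k = attr(events, "k"),
         fs = attr(events, "fs"), min_dwell_s = attr(events, "min_dwell_s"),
         total_time = attr(events, "total_time"),
         unoccupied_time = attr(events, "unoccupied_time")),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  utils::write.csv(as.data.frame(events), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  l1 <- readLines(path, n = 1)
  if (!startsWith(l1, "# ")) stop("read_events: malformed header")
  meta <- jsonlite::fromJSON(sub("^# ", "", l1))
  d <- utils::read.csv(path, comment.char = "#")
  for (nm in c("baseline", "sigma", "k", "fs", "min_dwell_s", "total_time",
               "unoccupied_time"))
    attr(d, nm) <- meta[[nm]]
  class(d) <- c("event_table", "data.frame")
  d
}

#' Read a model configuration file
#'
#' YAML key-value configuration with optional `geometry`, `origami`,
#' `electrolyte`, `mesh`, and `solver` sections; missing fields take the
#' package defaults.
#'
#' @param path YAML file path.
#' @return List with `geometry` (`pore_geometry`), `origami`
#'   (`origami_model` or NULL), `electrolyte` (`electrolyte_spec`), `mesh`
#'   (argument list for [build_domain()]), `solver` (`solver_options`),
#'   `voltage` (V).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  geometry <- do.call(pore_geometry, cfg$geometry %||% list())
  origami <- if (isFALSE(cfg$origami)) NULL
             else do.call(origami_model, cfg$origami %||% list())
  electrolyte <- do.call(electrolyte_spec, cfg$electrolyte %||% list())
  solver <- do.call(solver_options, cfg$solver %||% list())
  list(geometry = geometry, origami = origami, electrolyte = electrolyte,
       mesh = cfg$mesh %||% list(), solver = solver,
       voltage = cfg$voltage %||% 0.1)
}

#' Run the full vertical-versus-horizontal demonstration pipeline
#'
#' Executes the standard stages in order: the field solver for both origami
#' orientations (EOF flow-rate ratio), synthetic trace generation for the
#' vertical and horizontal trapping kinetics, event detection and rate
#' fitting for each, and the cholesterol fold-change / barrier conversion.
#' Deterministic given the seed; all artifacts are written under `outdir`.
#'
#' @param config List (or path to a YAML file) with optional elements
#'   `seed`, `outdir`, `trace_duration` (s), `run_field` (logical),
#'   `mesh` (arguments to [build_domain()]), `solver` (arguments to
#'   [solver_options()]), `voltage` (V).
#' @return List (also written as `summary.json` in `outdir`): flow-rate
#'   ratio (if run), recovered capture/escape rates per orientation, escape
#'   contrast, fold change and barrier increase.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  outdir <- config$outdir %||% tempfile("neotrap_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(seed = seed)

  if (isTRUE(config$run_field %||% TRUE)) {
    geometry <- do.call(pore_geometry, config$geometry %||% list())
    electrolyte <- do.call(electrolyte_spec, config$electrolyte %||% list())
    mesh_args <- config$mesh %||% list()
    opts <- do.call(solver_options, config$solver %||% list())
    voltage <- config$voltage %||% 0.1
    qq <- lapply(c("vertical", "horizontal"), function(orient) {
      org <- do.call(origami_model,
                     c(list(orientation = orient), config$origami %||% list()))
      mesh <- do.call(build_domain, c(list(geometry = geometry, origami = org),
                                      mesh_args))
      sol <- solve_coupled(mesh, electrolyte, voltage, opts)
      write_field(sol, file.path(outdir, paste0("field_", orient, ".csv")))
      field_summary(sol)
    })
    names(qq) <- c("vertical", "horizontal")
    res$field <- qq
    res$flow_ratio <- qq$vertical$flow_rate_m3s / qq$horizontal$flow_rate_m3s
  }

  dur <- config$trace_duration %||% 60
  rates <- lapply(c(vertical = "vertical_avidin",
                    horizontal = "horizontal_avidin"), function(pr) {
    tr <- make_fixture(pr, seed = seed, duration = dur)
    write_trace(tr, file.path(outdir, paste0(pr, ".csv")))
    ev <- detect_events(tr)
    write_events(ev, file.path(outdir, paste0(pr, "_events.csv")))
    rt <- capture_rate(ev, bootstrap = 200, seed = seed)
    list(capture = rt$capture_rate, escape = rt$escape_rate,
         n_events = rt$n_events)
  })
  res$rates <- rates
  res$capture_ratio <- rates$vertical$capture / rates$horizontal$capture
  res$escape_contrast <- rates$horizontal$escape / rates$vertical$escape

  # cholesterol locking: uniform-sphere tau vs the bare-sphere tau
  set.seed(seed)
  tau_chol <- fit_dwell_exponential(stats::rexp(2000, 20))$tau
  tau_bare <- fit_dwell_exponential(stats::rexp(2000, 20 * 98))$tau
  res$fold_change <- fold_change(tau_chol, tau_bare)
  res$barrier_kBT <- barrier_increase(res$fold_change)

  jsonlite::write_json(res, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$outdir <- outdir
  res
}
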