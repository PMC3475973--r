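#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration describing a complete run and
#' validates it against every module-level constraint before anything is
#' executed. All defaults are materialized into the returned object, so
#' writing it back out ([write_outputs()] embeds it in the metadata JSON)
#' and reloading reproduces the identical run. A metadata JSON produced by
#' [write_outputs()] is itself accepted (its embedded `config` is used).
#'
#' Recognized fields:
#' * `mode` — `"simulate"` (default), `"equilibrium"`, `"preset"` or
#'   `"classic"`.
#' * `b`, `d` — demography; alternatively `mortality` (a curve spec with
#'   `form` plus its parameters, see [mortality_curve()]) together with `l`.
#' * `delta_c` (constant influx) or `schedule` (list of `{t, delta_c}`
#'   pairs), plus optional `horizon`.
#' * `solver` — any of `method`, `dt`, `stride`, `rtol`, `atol`, `eps`,
#'   `t_max` (defaults per [solver_options()]).
#' * `clamp` — clamp inadmissible absorption probabilities (default
#'   `FALSE`).
#' * `preset` — scenario name for `mode = "preset"`.
#' * `delta_c_grid` — vector, or `{from, to, by}`, for
#'   `mode = "equilibrium"`.
#' * `classic` — for `mode = "classic"`: `type` (`"one_compartment"` or
#'   `"phase_switch"`) with the corresponding constructor arguments and a
#'   `times` grid (`{from, to, by}`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `tkcd_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be a .yaml, .yml or .json file", call. = FALSE))
  if (!is.list(raw))
    stop("config did not parse to a mapping", call. = FALSE)
  if (!is.null(raw[["config"]]) && !is.null(raw[["version"]]))
    raw <- raw[["config"]]  # metadata file round-trip
  as_tkcd_config(raw)
}

#' @rdname read_run_config
#' @param raw A configuration given directly as a named list (same fields
#'   as the file format).
#' @export
as_tkcd_config <- function(raw) {
  known <- c("mode", "b", "d", "l", "mortality", "delta_c", "schedule",
             "horizon", "solver", "clamp", "preset", "delta_c_grid",
             "classic")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)

  mode <- raw[["mode"]] %||% if (!is.null(raw[["preset"]])) "preset" else
    if (!is.null(raw[["delta_c_grid"]])) "equilibrium" else
    if (!is.null(raw[["classic"]])) "classic" else "simulate"
  if (!mode %in% c("simulate", "equilibrium", "preset", "classic"))
    stop(sprintf("invalid `mode`: %s", mode), call. = FALSE)

  cfg <- list(mode = mode)

  if (mode %in% c("simulate", "equilibrium")) {
    if (is.null(raw[["b"]]))
      stop("config field `b` is required", call. = FALSE)
    if (!is.null(raw[["d"]])) {
      d <- as.numeric(raw[["d"]])
      if (!is.null(raw[["l"]]) && raw[["l"]] != length(d))
        stop(sprintf("config field `l` (%s) does not match length of `d` (%d)",
                     raw[["l"]], length(d)), call. = FALSE)
    } else if (!is.null(raw[["mortality"]])) {
      if (is.null(raw[["l"]]))
        stop("config field `l` is required with a `mortality` curve",
             call. = FALSE)
      m <- raw[["mortality"]]
      if (is.null(m[["form"]]))
        stop("config field `mortality$form` is required", call. = FALSE)
      crv <- mortality_curve(m[["form"]],
                             table = if (!is.null(m[["table"]]))
                               as.data.frame(m[["table"]]) else NULL,
                             d0 = m[["d0"]], steepness = m[["steepness"]])
      d <- discretize_mortality(crv, raw[["l"]])
    } else {
      stop("config must give either `d` or a `mortality` curve",
           call. = FALSE)
    }
    params <- tkcd_params(raw[["b"]], d)
    cfg$b <- params$b
    cfg$d <- params$d
    cfg$l <- params$l
  }

  if (mode == "simulate") {
    if (!is.null(raw[["delta_c"]]) && !is.null(raw[["schedule"]]))
      stop("give either `delta_c` or `schedule`, not both", call. = FALSE)
    if (!is.null(raw[["schedule"]])) {
      seg <- raw[["schedule"]]
      if (is.data.frame(seg)) seg <- split(seg, seq_len(nrow(seg)))
      tt <- vapply(seg, function(s) as.numeric(s$t), numeric(1))
      lv <- vapply(seg, function(s) as.numeric(s$delta_c), numeric(1))
      sched <- exposure_schedule(tt, lv, horizon = raw[["horizon"]])
      cfg$schedule <- lapply(seq_along(tt), function(i)
        list(t = tt[i], delta_c = lv[i]))
    } else if (!is.null(raw[["delta_c"]])) {
      sched <- constant_exposure(as.numeric(raw[["delta_c"]]),
                                 horizon = raw[["horizon"]])
      cfg$delta_c <- as.numeric(raw[["delta_c"]])
    } else {
      stop("config must give `delta_c` or `schedule` for mode \"simulate\"",
           call. = FALSE)
    }
    if (!is.null(raw[["horizon"]])) cfg$horizon <- as.numeric(raw[["horizon"]])
  }

  if (mode == "equilibrium") {
    g <- raw[["delta_c_grid"]]
    if (is.null(g))
      stop("config field `delta_c_grid` is required for mode \"equilibrium\"",
           call. = FALSE)
    grid <- if (is.list(g)) seq(g[["from"]], g[["to"]], by = g[["by"]] %||% 1)
            else as.numeric(g)
    if (any(!is.finite(grid)) || any(grid < 0))
      stop("`delta_c_grid` must be finite and >= 0", call. = FALSE)
    cfg$delta_c_grid <- grid
  }

  if (mode == "preset") {
    if (is.null(raw[["preset"]]) ||
        !raw[["preset"]] %in% c("low", "moderate", "high"))
      stop("config field `preset` must be \"low\", \"moderate\" or \"high\"",
           call. = FALSE)
    cfg$preset <- raw[["preset"]]
  }

  if (mode == "classic") {
    cl <- raw[["classic"]]
    if (is.null(cl) || is.null(cl[["type"]]))
      stop("config field `classic$type` is required for mode \"classic\"",
           call. = FALSE)
    times <- cl[["times"]] %||% list(from = 0, to = 50, by = 0.1)
    cl[["times"]] <- times
    # constructor validates the rest
    config_classic_model(cl)
    cfg$classic <- cl
  }

  if (mode %in% c("simulate", "preset")) {
    so <- raw[["solver"]] %||% list()
    opts <- solver_options(method = so[["method"]] %||% "rk4",
                           dt = so[["dt"]] %||% 0.01,
                           stride = so[["stride"]] %||% 1L,
                           rtol = so[["rtol"]] %||% 1e-10,
                           atol = so[["atol"]] %||% 1e-12,
                           eps = so[["eps"]] %||% 1e-9,
                           t_max = so[["t_max"]] %||%
                             if (mode == "preset") 250 else 200)
    cfg$solver <- unclass(opts)
    cfg$clamp <- isTRUE(raw[["clamp"]])
  }

  structure(cfg, class = "tkcd_config")
}

config_classic_model <- function(cl) {
  args <- cl[setdiff(names(cl), c("type", "times"))]
  switch(cl[["type"]],
    one_compartment = do.call(one_compartment, args),
    phase_switch = do.call(phase_switch, args),
    stop(sprintf("unknown classic model type: %s", cl[["type"]]), call. = FALSE))
}

#' Execute a validated configuration
#'
#' Dispatches on `config$mode`: a simulation or preset run returns a
#' `tkcd_trajectory`, an equilibrium scan a data frame
#' (see [equilibrium_scan()]), and a classic-model run a data frame with
#' columns `t` and `C_int`.
#'
#' @param config A `tkcd_config` from [read_run_config()] or
#'   [as_tkcd_config()] applied to a list.
#' @return The run result; identical configurations produce identical
#'   results (the pipeline involves no randomness).
#' @export
run_tkcd <- function(config) {
  if (!inherits(config, "tkcd_config"))
    stop("`config` must come from read_run_config()", call. = FALSE)
  switch(config$mode,
    simulate = {
      params <- tkcd_params(config$b, config$d)
      sched <- if (!is.null(config$schedule)) {
        tt <- vapply(config$schedule, `[[`, numeric(1), "t")
        lv <- vapply(config$schedule, `[[`, numeric(1), "delta_c")
        exposure_schedule(tt, lv, horizon = config$horizon)
      } else constant_exposure(config$delta_c, horizon = config$horizon)
      simulate_tkcd(params, sched, opts = do.call(solver_options,
                                                  config$solver),
                    clamp = config$clamp)
    },
    preset = run_preset(config$preset,
                        opts = do.call(solver_options, config$solver)),
    equilibrium = {
      params <- tkcd_params(config$b, config$d)
      equilibrium_scan(params, config$delta_c_grid)
    },
    classic = {
      cl <- config$classic
      model <- config_classic_model(cl)
      tt <- seq(cl[["times"]]$from, cl[["times"]]$to, by = cl[["times"]]$by)
      C <- if (inherits(model, "one_compartment"))
        one_compartment_solution(model, tt)
      else phase_switch_solution(model, tt)
      data.frame(t = tt, C_int = C)
    })
}

#' Write run outputs
#'
#' Writes the result as CSV (numbers rendered with 12 significant digits;
#' undefined elimination rates as empty fields, never 0) plus a metadata
#' JSON carrying the full materialized configuration, package version, and
#' the admissibility and equilibration flags. Rewriting the same run
#' produces byte-identical files.
#'
#' @param x A run result (`tkcd_trajectory`, `tkcd_equilibrium`, or a data
#'   frame from [run_tkcd()]).
#' @param stem Output path without extension; `<stem>.csv` and
#'   `<stem>.json` are written.
#' @param config Optional `tkcd_config` to embed in the metadata.
#' @return Invisibly, the two paths written.
#' @export
write_outputs <- function(x, stem, config = NULL) {
  dir <- dirname(stem)
  if (!dir.exists(dir))
    stop(sprintf("output directory does not exist: %s", dir), call. = FALSE)
  if (inherits(x, "tkcd_equilibrium"))
    x_df <- data.frame(delta_c = x$delta_c, N_total = x$N_total,
                       C_int = x$C_int, loss_pct = x$loss_pct, k = x$k,
                       iterations = x$iterations, residual = x$residual)
  else x_df <- as.data.frame(x)

  fmt <- function(col) {
    if (!is.numeric(col)) return(as.character(col))
    ifelse(is.na(col), "", sprintf("%.12g", col))
  }
  out <- vapply(x_df, fmt, character(nrow(x_df)))
  if (nrow(x_df) == 1L) out <- t(out)
  csv <- paste0(stem, ".csv")
  con <- file(csv, "wb")  # fixed newline convention keeps reruns identical
  writeLines(paste(colnames(x_df), collapse = ","), con)
  writeLines(apply(out, 1L, paste, collapse = ","), con)
  close(con)

  meta <- list(
    package = "tkcd",
    version = as.character(utils::packageVersion("tkcd")),
    result = class(x)[1L],
    rows = nrow(x_df),
    admissible = attr(x, "admissible"),
    equilibrated = attr(x, "equilibrated"),
    config = if (!is.null(config)) unclass(config))
  meta <- meta[!vapply(meta, is.null, logical(1))]
  json <- paste0(stem, ".json")
  jsonlite::write_json(meta, json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(csv = csv, json = json))
}
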