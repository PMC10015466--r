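# Required numeric columns per dataset kind
.dataset_columns <- list(
  nmrd = c("freq_MHz", "temperature_K", "r1_mM_s"),
  o17 = c("temperature_K", "R2r_s", "dOmega_r_rad_s"),
  titration = "pH",
  trace = c("time_s", "absorbance")
)

#' Read a delimited-text dataset
#'
#' Reads one of the package's dataset kinds from a delimited text file with
#' a one-line header. The delimiter (tab, comma or whitespace) is detected
#' from the header; columns are matched by name, so column order is
#' irrelevant. Malformed (non-numeric) cells are reported with their line
#' number.
#'
#' @param path file path
#' @param kind one of `"nmrd"`, `"o17"`, `"titration"`, `"trace"`
#' @return a data.frame of the requested kind (classed `nmrd_dataset` /
#'   `o17_dataset` where applicable)
#' @export
read_dataset <- function(path, kind = c("nmrd", "o17", "titration", "trace")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("file has no data rows: ", path)
  sep <- if (grepl("\t", lines[1])) "\t" else if (grepl(",", lines[1])) ","
    else "[[:space:]]+"
  split1 <- function(s) trimws(strsplit(s, sep)[[1]])
  header <- split1(lines[1])
  required <- .dataset_columns[[kind]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols))
    stop(sprintf("file %s is missing required %s column(s): %s",
                 path, kind, paste(missing_cols, collapse = ", ")))
  rows <- lapply(seq_along(lines)[-1], function(i) {
    cells <- split1(lines[i])
    if (length(cells) != length(header))
      stop(sprintf("line %d of %s: expected %d fields, found %d",
                   i, path, length(header), length(cells)))
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(vals) & !cells %in% c("NA", ""))
    if (length(bad))
      stop(sprintf("line %d of %s: non-numeric value '%s' in column '%s'",
                   i, path, cells[bad[1]], header[bad[1]]))
    vals
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- header
  if (kind == "titration" &&
      !any(grepl("^A", header) | header == "V_base_mL"))
    stop("titration file needs absorbance (A<wavelength>) or V_base_mL columns")
  if (kind == "nmrd") class(df) <- c("nmrd_dataset", "data.frame")
  if (kind == "o17") class(df) <- c("o17_dataset", "data.frame")
  df
}

#' Write a dataset as tab-separated text
#'
#' @param x data.frame (any of the package's dataset kinds)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dataset <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.known_config_keys <- c("task", "seed", "out", "input", "fixture", "params",
                        "free", "options")

#' Read and validate a run configuration
#'
#' YAML configuration with top-level keys `task` (mandatory), `seed`,
#' `out`, `input` (path or list of paths), `fixture`, `params`, `free`,
#' `options`. Unknown keys are rejected before any computation.
#'
#' @param path YAML file path
#' @return validated config (list), class `run_config`
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a config list built in code
#' @export
as_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .known_config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$task)) stop("config must name a task")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "run_config")
}

# tiny FNV-1a hash for provenance stamping (no external digest dependency)
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 19661366
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", h)
}

.provenance <- function(cfg, fixed = NULL) {
  list(package = "fetiron",
       version = as.character(utils::packageVersion("fetiron")),
       task = cfg$task,
       seed = cfg$seed,
       config_hash = .config_hash(unclass(cfg)),
       fixed_parameters = fixed)
}

#' Execute a named task from a run configuration
#'
#' Dispatches the tasks exposed by the command-line entry point
#' (`speciate`, `simulate-nmrd`, `simulate-o17`, `synth-traces`,
#' `fit-global`, `fit-o17`, `fit-kinetics`, `predict-r1`, `predict-kd`),
#' writes the result to `cfg$out` (tab-separated table or JSON, depending
#' on the task) together with a provenance block (package version, seed,
#' config hash, fixed parameters) in `<out>.prov.json`.
#'
#' @param cfg a `run_config` (from [read_run_config()] or
#'   [as_run_config()])
#' @return the computed result, invisibly
#' @export
run_task <- function(cfg) {
  cfg <- as_run_config(unclass(cfg))
  p <- cfg$params %||% list()
  fixture <- cfg$fixture %||% "FeL2"
  out <- cfg$out
  result <- switch(cfg$task,
    "speciate" = {
      d <- distribution_curve(tiron_constants(),
                              p$total_Fe %||% 2e-4, p$total_L %||% 9e-3,
                              seq(p$pH_from %||% 0, p$pH_to %||% 10,
                                  by = p$pH_by %||% 0.1))
      if (!is.null(out)) write_dataset(d, out)
      d
    },
    "simulate-nmrd" = {
      ns <- noise_spec(kind = p$noise_kind %||% "relative-gaussian",
                       sigma = p$sigma %||% 0, seed = cfg$seed)
      d <- make_nmrd(tiron_relax_params(fixture), noise = ns)
      if (!is.null(out)) write_dataset(d, out)
      d
    },
    "simulate-o17" = {
      ns <- noise_spec(kind = p$noise_kind %||% "relative-gaussian",
                       sigma = p$sigma %||% 0, seed = cfg$seed)
      d <- make_o17(tiron_o17_params(fixture), noise = ns)
      if (!is.null(out)) write_dataset(d, out)
      d
    },
    "synth-traces" = {
      kd <- p$kd %||% observed_kd(tiron_rate_constants(), tiron_constants(),
                                  pH = p$pH %||% 6.5,
                                  total_Fe = 1e-4, total_L = 5e-4,
                                  CDTA = p$CDTA %||% 8e-3)
      ns <- noise_spec("absolute-gaussian", p$sigma %||% 0.002,
                       seed = cfg$seed)
      tr <- make_traces(kd, noise = ns)[[1]]
      d <- data.frame(time_s = tr$times, absorbance = tr$absorbance)
      if (!is.null(out)) write_dataset(d, out)
      d
    },
    "predict-r1" = {
      d <- total_r1(tiron_relax_params(fixture),
                    p$freq %||% 60, p$temp %||% 298.15)
      if (!is.null(out)) write_dataset(d, out)
      d
    },
    "predict-kd" = {
      kd <- observed_kd(tiron_rate_constants(), tiron_constants(),
                        pH = p$pH %||% 7.4,
                        total_Fe = p$total_Fe %||% 1e-4,
                        total_L = p$total_L %||% 5e-4,
                        CDTA = p$CDTA %||% 0)
      res <- list(kd_s = kd, half_life_h = half_life(kd))
      if (!is.null(out))
        jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
      res
    },
    "fit-kinetics" = {
      paths <- as.character(cfg$input)
      fits <- lapply(paths, function(pp) {
        d <- read_dataset(pp, "trace")
        f <- fit_trace(kinetic_trace(d$time_s, d$absorbance))
        list(file = pp, kd = f$kd, sigma_kd = f$sigma_kd,
             flags = f$flags)
      })
      if (!is.null(out))
        jsonlite::write_json(fits, out, auto_unbox = TRUE, digits = NA)
      fits
    },
    "fit-o17" = ,
    "fit-global" = {
      paths <- as.character(cfg$input)
      datasets <- lapply(paths, function(pp) {
        hdr <- readLines(pp, n = 1)
        if (grepl("r1_mM_s", hdr)) read_dataset(pp, "nmrd")
        else read_dataset(pp, "o17")
      })
      th <- global_theta(tiron_relax_params(fixture),
                         tryCatch(tiron_o17_params(fixture),
                                  error = function(e) NULL))
      free <- as.character(cfg$free %||%
                             c("Delta2", "tauv", "tauR", "tauM", "A_O"))
      prob <- fit_problem(datasets, th, free)
      fit <- fit_global(prob, seed = cfg$seed)
      res <- list(estimates = as.list(fit$coefficients$estimate),
                  sigma = as.list(fit$coefficients$sigma),
                  free = free,
                  fixed = as.list(fit$fixed),
                  objective = fit$objective,
                  converged = fit$converged)
      names(res$estimates) <- free
      names(res$sigma) <- free
      if (!is.null(out))
        jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
      res
    },
    stop("unknown task: ", cfg$task)
  )
  if (!is.null(out)) {
    jsonlite::write_json(.provenance(cfg), paste0(out, ".prov.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
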