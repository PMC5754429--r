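# Configuration files, assemblage construction, and CSV output.

config_sections <- c("growth", "division", "mortality", "predation",
                     "chemostat", "assemblage", "run")

section_fields <- list(
  growth = c("a_inf", "b", "alpha", "beta", "xi", "r"),
  division = c("xth", "delta", "k_shape", "q_shape", "k_scale", "k_power",
               "idealised"),
  mortality = c("m0"),
  predation = c("nu", "epsilon", "ratio_mode", "log_width", "s0"),
  chemostat = c("rho0", "N0", "theta"),
  assemblage = c("n_species", "w_min", "w_max"),
  run = c("seed", "n_grid", "n_cells", "t_end", "out")
)

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with sections mirroring the parameter
#' objects (`growth`, `division`, `mortality`, `predation`, `chemostat`,
#' `assemblage`, `run`). Every invariant of the parameter constructors is
#' enforced; unknown sections or keys are rejected with the offending
#' field path, and every defaulted value is materialised in the returned
#' object so that output headers can echo the complete configuration.
#'
#' @param path path to a YAML file.
#' @return a `run_config` list with constructed parameter objects and the
#'   full echo of all values under `$echo`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop2("config_missing", paste("no such file:", path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop2("config_invalid", "configuration must be a mapping")
  unknown <- setdiff(names(raw), config_sections)
  if (length(unknown)) {
    stop2("config_unknown_section",
          paste("unknown section(s):", paste(unknown, collapse = ", ")))
  }
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), section_fields[[sec]])
    if (length(bad)) {
      stop2("config_unknown_key",
            sprintf("unknown key(s) in section '%s': %s", sec,
                    paste(paste0(sec, ".", bad), collapse = ", ")))
    }
  }
  if (is.null(raw$growth)) {
    stop2("config_missing_section", "missing required section: growth")
  }
  if (is.null(raw$division)) {
    stop2("config_missing_section", "missing required section: division")
  }
  get <- function(sec, key, default) raw[[sec]][[key]] %||% default
  cfg <- list()
  cfg$growth <- do.call(growth_params, raw$growth)
  div_args <- raw$division
  div_args$idealised <- isTRUE(div_args$idealised)
  cfg$division <- do.call(division_spec, div_args)
  cfg$mortality <- mortality_spec(get("mortality", "m0", 0.1))
  cfg$predation <- do.call(predation_spec, raw$predation %||% list())
  cfg$chemostat <- do.call(chemostat_params, raw$chemostat %||% list())
  if (!is.null(raw$assemblage)) {
    cfg$assemblage <- make_assemblage(get("assemblage", "n_species", 1),
                                      get("assemblage", "w_min", 1),
                                      get("assemblage", "w_max", 1))
  }
  cfg$run <- list(seed = get("run", "seed", 1L),
                  n_grid = get("run", "n_grid", 512L),
                  n_cells = get("run", "n_cells", 256L),
                  t_end = get("run", "t_end", 100),
                  out = get("run", "out", NULL))
  cfg$echo <- c(
    lapply(cfg$growth, identity),
    list(xth = cfg$division$xth, delta = cfg$division$delta,
         k_shape = cfg$division$k_shape, q_shape = cfg$division$q_shape,
         k_scale = cfg$division$k_scale, idealised = cfg$division$idealised,
         m0 = cfg$mortality$m0,
         nu = cfg$predation$nu, epsilon = cfg$predation$epsilon,
         ratio_mode = cfg$predation$ratio_mode,
         log_width = cfg$predation$log_width, s0 = cfg$predation$s0,
         rho0 = cfg$chemostat$rho0, N0 = cfg$chemostat$N0,
         theta = cfg$chemostat$theta),
    cfg$run[!vapply(cfg$run, is.null, logical(1))])
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config with sections:",
      paste(setdiff(names(x), "echo"), collapse = ", "), "\n")
  invisible(x)
}

#' Log-spaced species assemblage
#'
#' `n_species` characteristic sizes log-spaced on `[w_min, w_max]` with the
#' endpoints inset by half a log step, so that each species represents an
#' equal share of the log-trait axis (the weights used when a finite
#' assemblage approximates the species continuum).
#'
#' @param n_species number of species.
#' @param w_min,w_max community size bounds.
#' @return a [species_assemblage()].
#' @export
make_assemblage <- function(n_species, w_min, w_max) {
  if (n_species < 1) stop2("bad_input", "need at least one species")
  if (w_min > w_max) stop2("bad_bounds", "requires w_min <= w_max")
  if (n_species == 1 || w_min == w_max) {
    return(species_assemblage(sqrt(w_min * w_max), w_min, w_max))
  }
  step <- (log(w_max) - log(w_min)) / n_species
  ws <- exp(log(w_min) + step * (seq_len(n_species) - 0.5))
  species_assemblage(ws, w_min, w_max)
}

#' Write a profile table as headered CSV
#'
#' Full-precision CSV with `#`-prefixed metadata rows (parameter echo,
#' solver residuals, seed) ahead of the header, so that every output file
#' carries the complete configuration that produced it.
#'
#' @param data data frame of finite numeric columns.
#' @param path output path.
#' @param meta named list written as `# key: value` rows.
#' @return the path, invisibly.
#' @export
write_profile_csv <- function(data, path, meta = list()) {
  num <- vapply(data, is.numeric, logical(1))
  for (cn in names(data)[num]) {
    bad <- which(!is.finite(data[[cn]]))
    if (length(bad)) {
      stop2("nonfinite_output",
            sprintf("non-finite value in column '%s', row %d", cn, bad[1]))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, format(meta[[k]], digits = 17)), con)
  }
  utils::write.csv(format(data, digits = 17, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
write_timeseries_csv <- write_profile_csv

#' Read a headered CSV written by [write_profile_csv()]
#'
#' @param path file path.
#' @return data frame; the metadata rows are attached as attribute
#'   `"meta"` (named character).
#' @export
read_profile_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- NULL
  if (length(meta_lines)) {
    kv <- regmatches(meta_lines, regexec("^# ([^:]+): (.*)$", meta_lines))
    meta <- stats::setNames(vapply(kv, `[`, character(1), 3),
                            vapply(kv, `[`, character(1), 2))
  }
  out <- utils::read.csv(text = lines[!grepl("^#", lines)])
  attr(out, "meta") <- meta
  out
}
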