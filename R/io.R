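#' Write and read delimited result tables
#'
#' CSV dialect: comma separator, dot decimal, header row required,
#' locale-independent, full double precision (round-trips to 15 significant
#' digits). `tfm_read_table()` reports malformed rows with their line
#' numbers rather than silently dropping them.
#'
#' @param records A data frame.
#' @param path File path.
#' @return `tfm_write_table()` returns `path` invisibly;
#'   `tfm_read_table()` returns a tibble.
#' @export
tfm_write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname tfm_write_table
#' @export
tfm_read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 100L)
  header <- head_lines[!startsWith(head_lines, "#")][1]
  if (is.na(header) || !nzchar(header) ||
      !grepl("[A-Za-z]", strsplit(header, ",")[[1]][1])) {
    stop("missing header row in ", path, call. = FALSE)
  }
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop("malformed rows in ", path, ": ",
         paste(sprintf("line %d (%s)", probs$row + 1L, probs$expected),
               collapse = "; "), call. = FALSE)
  }
  ## a numeric column polluted by a stray token is silently read as
  ## character; flag the offending lines instead
  for (nm in names(out)) {
    x <- out[[nm]]
    if (is.character(x)) {
      num <- suppressWarnings(as.numeric(x))
      if (any(is.na(num) & !is.na(x)) && any(!is.na(num))) {
        bad <- which(is.na(num) & !is.na(x)) + 1L
        stop("malformed rows in ", path, ": column '", nm,
             "' is not numeric on line ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  out
}

#' Read and validate a run configuration
#'
#' JSON mapping consumed by the command-line interface. Unknown keys are
#' rejected; the `command` key selects the subcommand and the remaining
#' keys mirror the arguments of the corresponding package functions.
#'
#' @param path Path to a JSON config file.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the jsonlite package is required for config files.", call. = FALSE)
  }
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A named list to validate.
#' @export
validate_run_config <- function(config) {
  allowed <- c("command", "alpha", "beta", "P", "R", "V2", "gamma",
               "kon_p", "koff_p", "kon_tf", "koff_tf", "r",
               "model", "tuning", "saturating_tf", "topology",
               "k_dim", "k_mon", "horizon", "n_trajectories",
               "alpha_min", "alpha_max", "beta_min", "beta_max", "n_grid",
               "expression_scale", "kd_tf", "variant", "fc_floor",
               "n_boot", "input", "output", "seed", "verbosity")
  if (is.null(names(config)) || any(!nzchar(names(config)))) {
    stop("config must be a named mapping.", call. = FALSE)
  }
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$command)) {
    stop("config must name a command.", call. = FALSE)
  }
  structure(config, class = "run_config")
}

#' Provenance header lines for output files
#'
#' Every CLI artifact starts with commented lines recording the package
#' version, seed and full parameter set, so a run can be reproduced from
#' its outputs alone.
#'
#' @param params Named list of run parameters.
#' @param seed The seed used (or `NA`).
#' @return Character vector of `#`-prefixed lines.
#' @export
provenance_header <- function(params, seed = NA) {
  c(paste0("# tfmodes ", as.character(utils::packageVersion("tfmodes"))),
    paste0("# seed: ", seed),
    paste0("# params: ",
           paste(names(params), unlist(lapply(params, format)),
                 sep = "=", collapse = " ")))
}
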