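#' Write / read a map pair as TSV
#'
#' Long-format interchange: columns `delay_fs`, `be_eV`, `counts_on`,
#' `counts_off`, preceded by `#`-prefixed header lines carrying the edge,
#' seed and the full generator truth record as JSON, so that
#' write-then-read round-trips both the values and the metadata.
#'
#' @param pair A `trxps_map_pair`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(pair, path) {
  check_pair(pair)
  meta <- list(
    edge = attr(pair, "edge"),
    seed = attr(pair, "seed"),
    truth = attr(pair, "truth")
  )
  meta$truth$config$regions <- as.list(meta$truth$config$regions)
  header <- c(
    paste0("# trxps_map_pair v1"),
    paste0("# meta: ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                        digits = NA, null = "null"))
  )
  body <- sprintf("%.17g\t%.17g\t%.17g\t%.17g",
                  pair$delay, pair$energy, pair$on, pair$off)
  writeLines(c(header, "delay_fs\tbe_eV\tcounts_on\tcounts_off", body), path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  lines <- readLines(path, n = 3)
  if (!startsWith(lines[1], "# trxps_map_pair")) {
    abort("not a trxps map file (missing `# trxps_map_pair` header).",
          class = "trxps_data_error")
  }
  meta <- jsonlite::fromJSON(sub("^# meta: ", "", lines[2]),
                             simplifyVector = TRUE)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("delay_fs", "be_eV", "counts_on", "counts_off")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("map file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "trxps_data_error")
  }
  n_e <- length(unique(tab$be_eV))
  n_d <- length(unique(tab$delay_fs))
  if (n_e * n_d != nrow(tab)) {
    abort("map file grid lengths are inconsistent with the row count.",
          class = "trxps_data_error")
  }
  out <- tibble::tibble(delay = tab$delay_fs, energy = tab$be_eV,
                        on = tab$counts_on, off = tab$counts_off)
  structure(out, class = c("trxps_map_pair", class(out)),
            truth = meta$truth, edge = meta$edge, seed = meta$seed)
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config Configuration list.
#' @param path File path.
#' @return `path` / the validated configuration.
#' @export
write_config <- function(config, path) {
  cfg <- config
  cfg$regions <- as.list(as.data.frame(cfg$regions))
  attr(cfg, "validated") <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$regions)) {
    cfg$regions <- tibble::as_tibble(cfg$regions)
  }
  validate_config(cfg)
}

#' Export a traces table as TSV
#'
#' @param traces Tibble with `delay`, `value`, `sigma` (optionally
#'   `region`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  readr::write_tsv(traces, path)
  invisible(path)
}
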