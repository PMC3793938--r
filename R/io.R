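## Delimited-text interchange with declared schemas.  CSV with a "#"
## comment header carrying units; numerics serialised at 17 significant
## digits so write-then-read round-trips to full double precision.

#' Read a delimited table against a declared schema
#'
#' @param path File path.
#' @param schema Named character vector mapping required column names to
#'   types (`"numeric"`, `"integer"`, `"character"`).  Extra columns are
#'   rejected; missing columns raise an error naming the column.
#' @return A tibble with columns in schema order.
#' @export
read_table_checked <- function(path, schema) {
  if (!file.exists(path)) stop("schema_error: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop("schema_error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), names(schema))
  if (length(extra)) {
    stop("schema_error: unexpected column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  df <- df[names(schema)]
  for (nm in names(schema)) {
    raw <- df[[nm]]
    df[[nm]] <- switch(schema[[nm]],
      numeric = suppressWarnings(as.numeric(raw)),
      integer = suppressWarnings(as.integer(raw)),
      character = as.character(raw),
      stop("unknown schema type: ", schema[[nm]], call. = FALSE))
    if (schema[[nm]] != "character") {
      ## literal NA/NaN are legitimate missing values; anything else
      ## that fails to parse is a schema violation
      bad <- is.na(df[[nm]]) &
        !(trimws(as.character(raw)) %in% c("NA", "NaN", "nan", "") | is.na(raw))
      if (any(bad)) {
        stop("schema_error: non-numeric values in column ", nm, call. = FALSE)
      }
    }
  }
  tibble::as_tibble(df)
}

#' Write a delimited table with full numeric precision
#'
#' @param df Data frame.
#' @param path Output path.
#' @param header Optional comment lines (units, provenance) written
#'   before the column header, each prefixed with `#`.
#' @return `path`, invisibly.
#' @export
write_table_checked <- function(df, path, header = NULL) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      out[[nm]] <- sprintf("%.17g", out[[nm]])
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.landscape_schema <- c(
  species = "character", n_level = "numeric",
  sla = "numeric", h = "numeric", lls = "numeric", td0 = "numeric",
  i_sla = "integer", i_h = "integer", i_lls = "integer", i_td0 = "integer",
  perf = "numeric", mean_cn = "numeric", mean_f_int = "numeric",
  net_photo = "numeric", su = "numeric", nue = "numeric", rue = "numeric",
  mean_p = "numeric", mean_q = "numeric", sra = "numeric",
  status = "character")

#' Write / read a landscape table
#'
#' @param table Landscape tibble from [run_campaign()].
#' @param path File path.
#' @return The path (write) or the validated tibble (read).
#' @export
write_landscape <- function(table, path) {
  write_table_checked(table[names(.landscape_schema)], path,
                      header = c("trait-space landscape table",
                                 "units: sla cm2 g-1; h cm; lls degree-days; td0 tillers m-2; perf g plant-1 yr-1"))
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) read_table_checked(path, .landscape_schema)

.driver_schema <- c(day = "integer", par = "numeric", temp = "numeric")
.schedule_schema <- c(day = "integer", kind = "character", magnitude = "numeric")
.species_schema <- c(species = "character", sla = "numeric", h = "numeric",
                     lls = "numeric", td = "numeric")

#' Read daily climate drivers (`day`, `par`, `temp`)
#' @param path File path.
#' @return Validated tibble.
#' @export
read_drivers <- function(path) read_table_checked(path, .driver_schema)

#' Read a management schedule (`day`, `kind`, `magnitude`)
#' @param path CSV or YAML file. YAML must hold a list of events with
#'   fields `day`, `kind`, `magnitude`.
#' @return Validated tibble.
#' @export
read_schedule <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    ev <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(ev, function(e) {
      tibble::tibble(day = as.integer(e$day), kind = as.character(e$kind),
                     magnitude = as.numeric(e$magnitude))
    }))
    return(df)
  }
  read_table_checked(path, .schedule_schema)
}

#' Read a species trait table (`species`, `sla`, `h`, `lls`, `td`)
#' @param path File path.
#' @return Validated tibble.
#' @export
read_species_table <- function(path) read_table_checked(path, .species_schema)

.config_keys <- c("seed", "out_dir", "n_levels", "fraction", "steps", "years",
                  "spin_cycles", "species", "climate", "management", "log_level")

#' Read and validate a pipeline run configuration
#'
#' YAML configuration binding the pipeline stages.  Recognised keys:
#' `seed`, `out_dir`, `n_levels`, `fraction`, `steps`, `years`,
#' `spin_cycles`, `species` (either `n` archetypes or a `file`),
#' `climate` (generator settings), `management` (application days and
#' cut settings), `log_level`.  Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated list of class `run_config` with defaults filled.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown)) {
    stop("config_error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(seed = 1L, out_dir = ".", n_levels = c(120, 360),
                   fraction = 0.3, steps = 5, years = 2, spin_cycles = 3,
                   species = list(n = 2), climate = list(), management = list(),
                   log_level = "info")
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg$n_levels <- as.numeric(unlist(cfg$n_levels))
  if (any(cfg$n_levels <= 0)) stop("config_error: n_levels must be positive", call. = FALSE)
  if (cfg$years < 1) stop("config_error: years must be >= 1", call. = FALSE)
  structure(cfg, class = "run_config")
}

log_json <- function(level, event, ..., con = stderr()) {
  if (isTRUE(getOption("grasscape.quiet", FALSE))) return(invisible())
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                level = level, event = event), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

config_hash <- function(cfg) {
  ser <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)
  ## small stable polynomial hash; enough to identify a config in logs
  bytes <- utf8ToInt(as.character(ser))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
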