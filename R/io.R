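#' CSV schemas of the interchange tables
#'
#' Every table the package reads or writes uses a unit-bearing CSV header.
#' @format A named list mapping schema name to required column names:
#' \describe{
#'   \item{culture_series}{time_h, live_per_ml, dead_per_ml,
#'     metabolite_fmole_per_ml}
#'   \item{chromatogram}{rt_min, signal}
#'   \item{plate}{compound, conc_uM, od600, replicate}
#'   \item{trajectory}{generation, count_a, count_b}
#'   \item{fluorescence}{time_h, norm_intensity}
#'   \item{colony_screen}{size_class, colonies_counted, screened,
#'     auxotrophs_found}
#' }
#' @export
crossfeed_schemas <- list(
  culture_series = c("time_h", "live_per_ml", "dead_per_ml",
                     "metabolite_fmole_per_ml"),
  chromatogram = c("rt_min", "signal"),
  plate = c("compound", "conc_uM", "od600", "replicate"),
  trajectory = c("generation", "count_a", "count_b"),
  fluorescence = c("time_h", "norm_intensity"),
  colony_screen = c("size_class", "colonies_counted", "screened",
                    "auxotrophs_found")
)

#' Read an interchange CSV with schema validation
#'
#' Header matching is order-insensitive and case-insensitive; columns beyond
#' the schema are accepted with a warning and carried through. A missing
#' required column is an error naming the column.
#'
#' @param path Path to a CSV file.
#' @param schema One of `names(crossfeed_schemas)`.
#' @return A tibble whose required columns bear the canonical schema names.
#' @export
read_table <- function(path, schema) {
  schema <- match.arg(schema, names(crossfeed_schemas))
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  cols <- crossfeed_schemas[[schema]]
  df <- readr::read_csv(path, show_col_types = FALSE)
  # case-insensitive header match onto canonical names
  lower <- tolower(names(df))
  for (col in cols) {
    hit <- which(lower == tolower(col))
    if (length(hit) == 0) {
      abort(paste0("schema '", schema, "': missing column '", col,
                   "' in ", path))
    }
    names(df)[hit[1]] <- col
  }
  extra <- setdiff(names(df), cols)
  if (length(extra)) {
    warn(paste0("extra column(s) carried through: ",
                paste(extra, collapse = ", ")))
  }
  numeric_cols <- setdiff(cols, c("compound", "size_class"))
  for (col in numeric_cols) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) &
                     !is.na(df[[col]]))
      if (length(bad)) {
        abort(paste0("column '", col, "' has unparsable value(s) at data ",
                     "row(s): ", paste(head(bad, 5), collapse = ", ")))
      }
      df[[col]] <- as.numeric(df[[col]])
    }
  }
  as_tibble(df)
}

#' Write an interchange CSV
#'
#' @param df A data frame carrying at least the schema's columns.
#' @param path Output path.
#' @param schema One of `names(crossfeed_schemas)`.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema) {
  schema <- match.arg(schema, names(crossfeed_schemas))
  check_columns(df, crossfeed_schemas[[schema]], paste0("schema '", schema, "'"))
  readr::write_csv(df, path)
  invisible(path)
}

#' Run one pipeline stage from a configuration list
#'
#' Dispatches to the package's generators and estimators from a declarative
#' configuration, writes the stage's outputs, and drops a provenance sidecar
#' (`<output>.provenance.json`: stage, parameters, seed, package version,
#' output checksum) next to each output. Identical configuration and seed
#' produce byte-identical outputs.
#'
#' @param config A list with elements `stage` (one of `"synth"`,
#'   `"simulate"`, `"release_rate"`, `"quantify_hplc"`, `"bioassay"`,
#'   `"growth"`, `"fitness"`, `"screen"`), `params` (stage-specific named
#'   list), optional `input` path(s), `output` path, and optional `seed`.
#'   Unknown top-level keys are rejected.
#' @return A list with `output` (path) and `result` (the stage's in-memory
#'   result), invisibly.
#' @export
run_pipeline <- function(config) {
  allowed <- c("stage", "params", "input", "output", "seed", "log_level")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  stage <- match.arg(config$stage,
                     c("synth", "simulate", "release_rate", "quantify_hplc",
                       "bioassay", "growth", "fitness", "screen"))
  params <- config$params %||% list()
  seed <- config$seed
  out_path <- config$output
  if (is.null(out_path)) abort("config$output is required")

  result <- switch(stage,
    synth = pipeline_synth(params, seed, out_path),
    simulate = {
      p <- do.call(ecology_params, params$ecology %||% list())
      sim <- simulate_coculture(
        p,
        init = params$init %||% c(R = 3e6 / 1.1, C = 3e6 - 3e6 / 1.1, O = 0),
        duration = params$duration %||% 60,
        mode = params$mode %||% "serial",
        time_unit = params$time_unit %||% "generations"
      )
      readr::write_csv(as_tibble(sim), out_path)
      sim
    },
    release_rate = {
      series <- read_table(config$input, "culture_series")
      r <- estimate_release_rate(series, dil = params$dil %||% log(2) / 8,
                                 steady_window = params$steady_window)
      readr::write_csv(tibble(release_fmole_per_cell_per_h = r), out_path)
      r
    },
    quantify_hplc = {
      chrom <- read_table(config$input, "chromatogram")
      std <- readr::read_csv(params$standards, show_col_types = FALSE)
      curve <- fit_standard_curve(std)
      q <- quantify_chromatogram(chrom, curve,
                                 window = params$window %||% c(6.5, 8))
      readr::write_csv(q, out_path)
      q
    },
    bioassay = {
      plate <- read_table(config$input, "plate")
      curve <- fit_yield_curve(plate,
                               linear_range = params$linear_range %||% c(0, 2))
      unknowns <- params$unknown_od
      res <- if (is.null(unknowns)) glance(curve)
             else infer_gsh_equivalents(unknowns, curve)
      readr::write_csv(res, out_path)
      res
    },
    growth = {
      series <- read_table(config$input, "fluorescence")
      mu <- max_growth_rate(series)
      readr::write_csv(tibble(max_growth_rate_per_h = mu), out_path)
      mu
    },
    fitness = {
      traj <- read_table(config$input, "trajectory")
      fit <- competition_fitness(traj)
      readr::write_csv(as_tibble(fit), out_path)
      fit
    },
    screen = {
      scr <- read_table(config$input, "colony_screen")
      f <- auxotroph_frequency(scr)
      readr::write_csv(tibble(auxotroph_frequency = f), out_path)
      f
    }
  )

  sidecar <- paste0(out_path, ".provenance.json")
  jsonlite::write_json(
    list(stage = stage,
         params = params,
         seed = seed,
         package = "crossfeedr",
         version = as.character(utils::packageVersion("crossfeedr")),
         output = basename(out_path),
         md5 = unname(tools::md5sum(out_path))),
    sidecar, auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(list(output = out_path, result = result))
}

#' @noRd
pipeline_synth <- function(params, seed, out_path) {
  kind <- match.arg(params$kind %||% "culture",
                    c("culture", "chromatogram", "plate", "competition",
                      "fluorescence"))
  noise <- do.call(noise_spec, modifyList(params$noise %||% list(),
                                          list(seed = seed)))
  eco <- do.call(ecology_params, params$ecology %||% list())
  tbl <- switch(kind,
    culture = gen_chemostat_series(eco, noise = noise),
    chromatogram = gen_chromatogram(do.call(chromatogram_spec,
                                            params$spec %||% list()),
                                    noise = noise),
    plate = gen_bioassay_plate(noise = noise),
    competition = gen_competition(eco, init_ratio = params$init_ratio %||% 1,
                                  noise = noise),
    fluorescence = gen_fluorescence_series(noise = noise)
  )
  schema <- switch(kind, culture = "culture_series",
                   chromatogram = "chromatogram", plate = "plate",
                   competition = "trajectory", fluorescence = "fluorescence")
  write_table(tbl, out_path, schema)
  tbl
}
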