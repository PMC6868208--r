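read_checked <- function(path, required, kind) {
  if (!file.exists(path)) abort(sprintf("%s file not found: %s", kind, path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    abort(sprintf("%s file %s is missing columns: %s", kind, path,
                  paste(missing, collapse = ", ")))
  }
  x
}

#' Read and write the standard study CSVs
#'
#' Long-format CSV readers/writers for the four study inputs. All files are
#' UTF-8 with a mandatory header.
#'
#' * positions: `group_id, condition, frame_index, time_s, fish_id, x_cm,
#'   y_cm[, z_cm]`
#' * body lengths: `group_id, fish_id, standard_length_mm`
#' * behaviour: `group_id, condition, clip_index, behaviour, present`
#'   (long) — [read_behaviour_wide()] accepts one column per behaviour
#'   instead
#' * cortisol: `group_id, condition, fish_id, cortisol_ng_per_g`
#'
#' @param path CSV file path.
#' @param x Tibble to write.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name study_io
NULL

#' @rdname study_io
#' @export
read_positions <- function(path) {
  read_checked(path, c("group_id", "condition", "frame_index", "fish_id",
                       "x_cm", "y_cm"), "position")
}

#' @rdname study_io
#' @export
read_body_lengths <- function(path) {
  read_checked(path, c("group_id", "fish_id", "standard_length_mm"),
               "body-length")
}

#' @rdname study_io
#' @export
read_behaviour <- function(path) {
  x <- read_checked(path, c("group_id", "condition", "clip_index",
                            "behaviour", "present"), "behaviour")
  check_behaviour_table(x)
}

#' @rdname study_io
#' @export
read_behaviour_wide <- function(path) {
  x <- read_checked(path, c("group_id", "condition", "clip_index"), "behaviour")
  long <- tidyr::pivot_longer(x, -c("group_id", "condition", "clip_index"),
                              names_to = "behaviour", values_to = "present")
  check_behaviour_table(long)
}

#' @rdname study_io
#' @export
read_cortisol <- function(path) {
  read_checked(path, c("group_id", "condition", "fish_id",
                       "cortisol_ng_per_g"), "cortisol")
}

#' @rdname study_io
#' @export
write_positions <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname study_io
#' @export
write_body_lengths <- write_positions

#' @rdname study_io
#' @export
write_behaviour <- write_positions

#' @rdname study_io
#' @export
write_cortisol <- write_positions

#' Write a simulated study to disk
#'
#' Emits the four standard CSVs plus a provenance JSON capturing the
#' generating configuration and seed.
#'
#' @param study A `shoal_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "shoal_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    positions = file.path(dir, "positions.csv"),
    behaviour = file.path(dir, "behaviour.csv"),
    body_lengths = file.path(dir, "body_lengths.csv"),
    cortisol = file.path(dir, "cortisol.csv"),
    provenance = file.path(dir, "provenance.json")
  )
  readr::write_csv(study$positions, files[["positions"]])
  readr::write_csv(study$behaviour, files[["behaviour"]])
  readr::write_csv(study$body_lengths, files[["body_lengths"]])
  readr::write_csv(study$cortisol, files[["cortisol"]])
  cfg <- unclass(study$config)
  cfg$tank <- unclass(cfg$tank)
  jsonlite::write_json(
    list(seed = study$seed, config = cfg,
         package_version = as.character(utils::packageVersion("shoalmetrics"))),
    files[["provenance"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(files)
}

#' Write analysis artefacts
#'
#' Writes the per-frame metric table, the correlation matrix (with its
#' per-pair method labels), the selection audit log and the results table
#' of a fitted [run_full_analysis()] object.
#'
#' @param analysis A `shoal_analysis`.
#' @param dir Output directory.
#' @return Invisibly, the named vector of files written.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "shoal_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    metrics = file.path(dir, "frame_metrics.csv"),
    correlations = file.path(dir, "correlation_matrix.csv"),
    methods = file.path(dir, "correlation_methods.csv"),
    selection = file.path(dir, "selection_audit.json"),
    results = file.path(dir, "results.csv")
  )
  readr::write_csv(analysis$metrics, files[["metrics"]])
  r <- as.data.frame(analysis$correlations$r)
  readr::write_csv(cbind(metric = rownames(analysis$correlations$r), r),
                   files[["correlations"]])
  m <- as.data.frame(analysis$correlations$method)
  readr::write_csv(cbind(metric = rownames(analysis$correlations$method), m),
                   files[["methods"]])
  jsonlite::write_json(
    list(retained = analysis$selection$retained,
         threshold = analysis$selection$threshold,
         forced = analysis$selection$forced,
         audit = analysis$selection$audit,
         provenance = analysis$provenance),
    files[["selection"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  readr::write_csv(analysis$results, files[["results"]])
  invisible(files)
}
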