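# Delimited-text interchange for trials, labels and count tables.

#' Write a trial to CSV with a JSON metadata sidecar
#'
#' One row per sample with columns `subject_id, side, repetition, angle_deg,
#' velocity_deg_s, torque_nm`. The generating spec (when present) is written
#' alongside as `<path>.json`.
#'
#' @param trial An `imc_trial` or list of repetition data frames.
#' @param path Output CSV path.
#' @param subject_id,side Identifiers stored in the CSV.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path, subject_id = "S01", side = "R") {
  long <- do.call(rbind, lapply(trial, function(rep) {
    data.frame(subject_id = subject_id, side = side,
               repetition = rep$repetition[1L],
               angle_deg = rep$angle_deg,
               velocity_deg_s = rep$velocity_deg_s,
               torque_nm = rep$torque_nm)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  spec <- attr(trial, "spec")
  if (!is.null(spec)) {
    jsonlite::write_json(unclass(spec), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a trial CSV
#'
#' @param path CSV written by [write_trial_csv()] (or following its dialect).
#' @return List of per-repetition data frames, ordered by repetition index.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path)
  needed <- c("repetition", "angle_deg", "torque_nm")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("trial CSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  reps <- split(df, df$repetition)
  structure(unname(reps[order(as.integer(names(reps)))]), class = "imc_trial")
}

#' Write / read a cohort manifest
#'
#' Columns `trial_id, injury_class, injected_pattern` (plus any label columns
#' added by classification).
#'
#' @param manifest Manifest data frame.
#' @param path CSV path.
#' @return `path` (write) or the manifest data frame (read).
#' @export
write_manifest_csv <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest_csv
#' @export
read_manifest_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a pattern-by-class count table
#'
#' CSV with patterns as the first column and one column per injury class.
#'
#' @param table 4 x 5 count matrix.
#' @param path CSV path.
#' @return `path` (write) or the validated count matrix (read).
#' @export
write_counts_csv <- function(table, path) {
  table <- .validate_count_table(table)
  df <- data.frame(pattern = rownames(table), table, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  .validate_count_table(m[imc_patterns(), injury_classes(), drop = FALSE])
}
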