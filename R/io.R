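#' Write and read a subject recording container
#'
#' A recording is stored as one directory per subject holding plain-text
#' members: `signal.csv` (channels x samples, one row per channel, labelled),
#' `events.csv` (onset_sample, rating) and `meta.json` (sampling rate, site,
#' montage, subject index).  Ground-truth latent states, when present, go to
#' `ground_truth.json` so recovery tests can read them; pipeline stages never
#' do.  Writing is atomic: members are written to a temporary directory that
#' is renamed into place, so a crash never leaves a partial container.
#'
#' @param recording A `subject_recording`.
#' @param path Directory to create (must not exist).
#' @return `path`, invisibly.
#' @export
write_subject_recording <- function(recording, path) {
  stopifnot(inherits(recording, "subject_recording"))
  if (dir.exists(path)) stop("path already exists: ", path)
  tmp <- paste0(path, ".tmp-", Sys.getpid())
  dir.create(tmp, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE))
  sig <- as.data.frame(recording$signal)
  names(sig) <- paste0("s", seq_len(ncol(sig)))
  write.csv(cbind(channel = recording$montage, sig),
            file.path(tmp, "signal.csv"), row.names = FALSE)
  write.csv(data.frame(onset_sample = recording$event_samples,
                       rating = recording$ratings),
            file.path(tmp, "events.csv"), row.names = FALSE)
  jsonlite::write_json(list(sampling_rate = recording$sampling_rate,
                            site = recording$site,
                            montage = recording$montage,
                            subject_index = recording$subject_index),
                       file.path(tmp, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(recording$ground_truth))
    jsonlite::write_json(recording$ground_truth,
                         file.path(tmp, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!file.rename(tmp, path)) stop("could not move container into place")
  ok <- TRUE
  invisible(path)
}

#' @rdname write_subject_recording
#' @export
read_subject_recording <- function(path) {
  need <- file.path(path, c("signal.csv", "events.csv", "meta.json"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("malformed container, missing: ",
         paste(basename(missing), collapse = ", "))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  sig <- read.csv(file.path(path, "signal.csv"), check.names = FALSE)
  if (names(sig)[1] != "channel")
    stop("malformed signal.csv: first column must be 'channel'")
  montage <- sig$channel
  if (!identical(montage, meta$montage))
    stop("signal.csv channels disagree with meta.json montage")
  signal <- as.matrix(sig[, -1, drop = FALSE])
  dimnames(signal) <- list(montage, NULL)
  events <- read.csv(file.path(path, "events.csv"))
  if (!all(c("onset_sample", "rating") %in% names(events)))
    stop("malformed events.csv: need onset_sample and rating columns")
  gt_path <- file.path(path, "ground_truth.json")
  gt <- if (file.exists(gt_path))
    jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  structure(list(signal = signal,
                 sampling_rate = meta$sampling_rate,
                 event_samples = as.integer(events$onset_sample),
                 ratings = events$rating,
                 site = meta$site,
                 montage = montage,
                 subject_index = as.integer(meta$subject_index),
                 ground_truth = gt),
            class = "subject_recording")
}

#' Write a cohort to disk
#'
#' One container directory per subject (`sub-01`, `sub-02`, ...) plus a
#' `manifest.json` recording the configuration and subject paths.
#'
#' @param cohort An `eeg_cohort`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  if (dir.exists(path)) stop("path already exists: ", path)
  dir.create(path, recursive = TRUE)
  subdirs <- sprintf("sub-%02d", seq_along(cohort))
  for (i in seq_along(cohort))
    write_subject_recording(cohort[[i]], file.path(path, subdirs[i]))
  cfg <- attr(cohort, "config")
  jsonlite::write_json(list(subjects = subdirs, config = unclass(cfg)),
                       file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  subjects <- lapply(manifest$subjects,
                     function(s) read_subject_recording(file.path(path, s)))
  cfg <- manifest$config
  cfg$rating_params <- as.list(cfg$rating_params)
  structure(subjects, class = "eeg_cohort",
            config = structure(cfg, class = "cohort_config"))
}

#' Write group results to disk
#'
#' Serializes a [run_pipeline()] result: scalar statistics to
#' `group_result.json`, and tables (decoding summary, band attribution,
#' per-frequency correlation, autocorrelation, site-mean weight maps) to
#' CSV.  Files are written to a temporary directory renamed into place.
#'
#' @param result A `group_result`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "group_result"))
  if (dir.exists(path)) stop("path already exists: ", path)
  tmp <- paste0(path, ".tmp-", Sys.getpid())
  dir.create(tmp, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE))
  jsonlite::write_json(glance(result), file.path(tmp, "group_result.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  jsonlite::write_json(result$null_distribution,
                       file.path(tmp, "null_distribution.json"), digits = NA)
  write.csv(result$decoding_summary, file.path(tmp, "decoding_summary.csv"),
            row.names = FALSE)
  write.csv(result$band_attribution$per_subject,
            file.path(tmp, "band_attribution.csv"), row.names = FALSE)
  if (is.data.frame(result$per_frequency))
    write.csv(result$per_frequency, file.path(tmp, "per_frequency.csv"),
              row.names = FALSE)
  write.csv(result$autocorrelation, file.path(tmp, "autocorrelation.csv"),
            row.names = FALSE)
  for (s in names(result$site_mean_weight_maps))
    write.csv(result$site_mean_weight_maps[[s]],
              file.path(tmp, paste0("weights_", s, ".csv")))
  if (!file.rename(tmp, path)) stop("could not move results into place")
  ok <- TRUE
  invisible(path)
}
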