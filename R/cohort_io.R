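#' Write a cohort to a directory
#'
#' Serializes an [simulate_cohort()] result to the pipeline's on-disk
#' dialect: `cohort.json` (patients with severities, rater panels, aid
#' flags, and the simulation seed), one CSV per stride and side
#' (`patient<id>_stride<j>_<side>.csv`, columns `percent_cycle` plus one
#' column per angle), and `events.csv` with the gait events and
#' spatiotemporal stride measurements.
#'
#' @param cohort an `sms_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sms_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  meta <- list(
    seed = cohort$config$seed,
    patients = cohort$patients,
    raters = cohort$raters
  )
  jsonlite::write_json(meta, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)

  readr::write_csv(cohort$events, file.path(dir, "events.csv"),
                   progress = FALSE)

  keys <- dplyr::distinct(cohort$angles, .data$patient_id, .data$stride,
                          .data$side)
  for (r in seq_len(nrow(keys))) {
    sub <- dplyr::filter(
      cohort$angles,
      .data$patient_id == keys$patient_id[r],
      .data$stride == keys$stride[r],
      .data$side == keys$side[r]
    )
    out <- dplyr::select(sub, percent_cycle = "pct",
                         dplyr::all_of(sms_angles()))
    fn <- sprintf("patient%s_stride%d_%s.csv",
                  keys$patient_id[r], keys$stride[r], keys$side[r])
    readr::write_csv(out, file.path(dir, fn), progress = FALSE)
  }
  invisible(dir)
}

#' Read a cohort directory
#'
#' Inverse of [write_cohort()]; numeric values round-trip losslessly
#' (shortest round-trip decimal representation on write).
#'
#' @param dir directory written by [write_cohort()].
#' @return an `sms_cohort` (without the original `sim_config`; the seed is
#'   kept in `$seed`).
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  patients <- tibble::as_tibble(meta$patients)
  raters <- tibble::as_tibble(meta$raters)
  events <- readr::read_csv(
    file.path(dir, "events.csv"), show_col_types = FALSE, progress = FALSE)

  files <- list.files(dir, pattern = "^patient.*_stride\\d+_(ipsi|contra)\\.csv$")
  parse1 <- function(fn) {
    m <- regmatches(fn, regexec("^patient(.+)_stride(\\d+)_(ipsi|contra)\\.csv$", fn))[[1]]
    tab <- readr::read_csv(file.path(dir, fn), show_col_types = FALSE,
                           progress = FALSE)
    tibble::tibble(
      patient_id = m[2], side = m[4], stride = as.integer(m[3]),
      pct = tab$percent_cycle
    ) |>
      dplyr::bind_cols(dplyr::select(tab, -"percent_cycle"))
  }
  angles <- dplyr::bind_rows(lapply(files, parse1)) |>
    dplyr::arrange(.data$patient_id, .data$side, .data$stride, .data$pct)

  structure(
    list(patients = patients, events = events, angles = angles,
         raters = raters, seed = meta$seed),
    class = "sms_cohort"
  )
}
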