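#' @name cohort_io
#' @title Cohort file formats
#'
#' @description
#' The clinical table travels as CSV with a header (`patient_id`, the 15
#' feature columns, empty cells for missing values); outcomes as CSV
#' (`patient_id`, `event_kind`, `time_days`); polar maps as a wide CSV with
#' one row per patient x channel (`patient_id`, `channel`, `p0001` ..
#' `p1008`, pixels in column-major 28 x 36 order, 0-100 scale).
NULL

#' Write a cohort to disk
#'
#' @param cohort List with `clinical`, `outcomes` and optionally `maps`
#'   and `truth` (as from [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- cohort$outcomes$patient_id
  paths <- c(clinical = file.path(dir, "clinical.csv"),
             outcomes = file.path(dir, "outcomes.csv"))
  clin <- cbind(data.frame(patient_id = ids), cohort$clinical)
  data.table::fwrite(clin, paths["clinical"], na = "")
  data.table::fwrite(cohort$outcomes[, c("patient_id", "event_kind",
                                         "time_days")],
                     paths["outcomes"])
  if (!is.null(cohort$maps)) {
    paths["maps"] <- file.path(dir, "polar_maps.csv")
    n <- dim(cohort$maps)[1]
    channels <- c("perfusion", "motion", "thickening", "phase", "amplitude")
    flat <- matrix(aperm(cohort$maps, c(3, 4, 2, 1)), ncol = n)  # 5040 x n
    wide <- data.table::as.data.table(t(matrix(flat, nrow = 28 * 36)))
    data.table::setnames(wide, sprintf("p%04d", seq_len(28 * 36)))
    meta <- data.table::data.table(patient_id = rep(ids, each = 5),
                                   channel = rep(channels, n))
    data.table::fwrite(cbind(meta, wide), paths["maps"])
  }
  if (!is.null(cohort$truth)) {
    paths["truth"] <- file.path(dir, "truth_cif.csv")
    tr <- cohort$truth
    bins <- seq_len(tr$grid$n_bins) - 1L
    long <- do.call(rbind, lapply(names(tr$cif), function(ev)
      data.table::data.table(
        patient_id = rep(ids, times = length(bins)),
        event = ev,
        t_days = rep(bins * tr$grid$bin_width_days, each = length(ids)),
        true_cif = as.vector(tr$cif[[ev]]))))
    data.table::fwrite(long, paths["truth"])
  }
  invisible(paths)
}

#' Read a cohort from disk
#'
#' @param dir Directory holding `clinical.csv`, `outcomes.csv` and
#'   optionally `polar_maps.csv`.
#' @param grid A [time_grid()] for outcome discretization.
#' @return List with `clinical` (data.frame), `outcomes`
#'   ([outcome_table()]) and `maps` (array, or NULL).
#' @export
read_cohort <- function(dir, grid = time_grid()) {
  clin <- data.table::fread(file.path(dir, "clinical.csv"),
                            data.table = FALSE)
  ids <- clin$patient_id
  clin$patient_id <- NULL
  out <- data.table::fread(file.path(dir, "outcomes.csv"),
                           data.table = FALSE)
  if (!identical(out$patient_id, ids))
    stop("clinical and outcomes files disagree on patient ids")
  outcomes <- outcome_table(out$event_kind, out$time_days, grid,
                            patient_id = out$patient_id)
  maps <- NULL
  mp <- file.path(dir, "polar_maps.csv")
  if (file.exists(mp)) {
    mdt <- data.table::fread(mp, data.table = FALSE)
    channels <- c("perfusion", "motion", "thickening", "phase", "amplitude")
    n <- length(ids)
    if (nrow(mdt) != 5 * n) stop("polar map file has unexpected row count")
    ord <- order(match(mdt$patient_id, ids), match(mdt$channel, channels))
    mdt <- mdt[ord, ]
    px <- as.matrix(mdt[, -(1:2)])
    maps <- aperm(array(t(px), dim = c(28, 36, 5, n)), c(4, 3, 1, 2))
  }
  list(clinical = clin, outcomes = outcomes, maps = maps)
}
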