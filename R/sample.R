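#' Per-patient cell table container
#'
#' Bundles everything the readout computations need for one patient: the
#' tumour-cell records (centroid coordinates in micrometres and per-compartment
#' mean optical densities), the TIL coordinates, and the analysed region areas.
#'
#' @param patient_id Patient identifier (scalar, coerced to character).
#' @param cells `data.frame` with columns `cell_id`, `x_um`, `y_um`,
#'   `od_membrane`, `od_cytoplasm` and optionally `od_nucleus`. ODs are in
#'   scaled OD units (100 x base-10 DAB absorbance, see [deconvolve_dab()]).
#' @param tils `data.frame` with columns `x_um`, `y_um`, `compartment`
#'   (`"stromal"` or `"intraepithelial"`); may be empty.
#' @param epithelium_area_mm2 Analysed tumour-epithelium area in mm^2
#'   (denominator of the OD-positive cell density).
#' @param tumor_center_area_mm2 Tumour-centre area in mm^2 (denominator of the
#'   stromal TIL density).
#'
#' @return An object of class `qcs_sample`.
#' @export
qcs_sample <- function(patient_id, cells,
                       tils = data.frame(x_um = numeric(), y_um = numeric(),
                                         compartment = character()),
                       epithelium_area_mm2 = NA_real_,
                       tumor_center_area_mm2 = NA_real_) {
  stopifnot(length(patient_id) == 1L)
  cells <- as.data.frame(cells)
  required <- c("x_um", "y_um", "od_membrane")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0)
    stop("cell table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(cells) > 0) {
    if (any(!is.finite(cells$x_um)) || any(!is.finite(cells$y_um)))
      stop("cell coordinates must be finite")
    if (any(cells$od_membrane < 0, na.rm = TRUE))
      stop("membrane OD values must be >= 0")
  }
  if (!is.null(cells$cell_id) && anyDuplicated(cells$cell_id))
    stop("duplicated cell_id in cell table")
  structure(
    list(patient_id = as.character(patient_id),
         cells = cells,
         tils = as.data.frame(tils),
         epithelium_area_mm2 = epithelium_area_mm2,
         tumor_center_area_mm2 = tumor_center_area_mm2),
    class = "qcs_sample")
}

#' @export
print.qcs_sample <- function(x, ...) {
  cat(sprintf("<qcs_sample> patient %s: %d cells, %d TILs, epithelium %.3g mm^2\n",
              x$patient_id, nrow(x$cells), nrow(x$tils),
              x$epithelium_area_mm2))
  invisible(x)
}

#' Read and write the cell/TIL/area/clinical table interchange formats
#'
#' Long-format CSV tables keyed by `patient_id` (the schema of the synthetic
#' cohort generator). `read_cohort_tables()` reassembles them into a list of
#' [qcs_sample()] objects.
#'
#' @param samples List of `qcs_sample` objects.
#' @param dir Directory for `cells.csv`, `tils.csv`, `areas.csv`.
#' @return `write_cohort_tables()` returns the directory invisibly;
#'   `read_cohort_tables()` returns a named list of `qcs_sample`.
#' @export
write_cohort_tables <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- do.call(rbind, lapply(samples, function(s)
    cbind(patient_id = s$patient_id, s$cells)))
  tils <- do.call(rbind, lapply(samples, function(s) {
    if (nrow(s$tils) == 0) return(NULL)
    cbind(patient_id = s$patient_id, s$tils)
  }))
  if (is.null(tils))
    tils <- data.frame(patient_id = character(), x_um = numeric(),
                       y_um = numeric(), compartment = character())
  areas <- do.call(rbind, lapply(samples, function(s)
    data.frame(patient_id = s$patient_id,
               epithelium_area_mm2 = s$epithelium_area_mm2,
               tumor_center_area_mm2 = s$tumor_center_area_mm2)))
  write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write.csv(tils, file.path(dir, "tils.csv"), row.names = FALSE)
  write.csv(areas, file.path(dir, "areas.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort_tables
#' @export
read_cohort_tables <- function(dir) {
  cells <- read.csv(file.path(dir, "cells.csv"))
  tils <- read.csv(file.path(dir, "tils.csv"))
  areas <- read.csv(file.path(dir, "areas.csv"))
  out <- lapply(areas$patient_id, function(pid) {
    qcs_sample(
      patient_id = pid,
      cells = cells[cells$patient_id == pid,
                    setdiff(names(cells), "patient_id"), drop = FALSE],
      tils = tils[tils$patient_id == pid,
                  setdiff(names(tils), "patient_id"), drop = FALSE],
      epithelium_area_mm2 =
        areas$epithelium_area_mm2[areas$patient_id == pid],
      tumor_center_area_mm2 =
        areas$tumor_center_area_mm2[areas$patient_id == pid])
  })
  names(out) <- as.character(areas$patient_id)
  out
}
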