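#' Construct well annotations
#'
#' One row per acquired well: whether it is an EV-containing sample or a
#' matched buffer/medium control, the input particle dose estimated by
#' nanoparticle tracking analysis (NTA), the acquiring instrument and, for
#' sample wells, the id of the matched control well whose MFIs are subtracted
#' during background correction.
#'
#' @param well_id Well identifiers.
#' @param kind `"sample"` or `"control"` per well.
#' @param sample_id Biological sample identifier.
#' @param input_dose Input particle count per assay (NTA-based); 0 for
#'   controls.
#' @param instrument_id Acquiring instrument identifier.
#' @param matched_control_id For sample wells, the `well_id` of the matched
#'   control; must be non-empty for every sample well.
#' @return A tibble of class `ev_annotations`.
#' @export
well_annotations <- function(well_id, kind, sample_id = well_id,
                             input_dose = 0, instrument_id = "sim",
                             matched_control_id = "") {
  ann <- tibble::tibble(well_id = well_id, kind = kind, sample_id = sample_id,
                        input_dose = input_dose, instrument_id = instrument_id,
                        matched_control_id = matched_control_id)
  if (!all(ann$kind %in% c("sample", "control"))) {
    abort_validation("kind must be 'sample' or 'control'")
  }
  if (any(ann$input_dose < 0)) abort_validation("input_dose must be >= 0")
  bad <- ann$kind == "sample" & (is.na(ann$matched_control_id) |
                                   ann$matched_control_id == "")
  if (any(bad)) {
    abort_validation(paste0("sample well(s) without matched_control_id: ",
                            paste(ann$well_id[bad], collapse = ", ")))
  }
  class(ann) <- c("ev_annotations", class(ann))
  ann
}

#' Read well annotations from a YAML file
#' @param path Annotation YAML file as written by [write_annotations()].
#' @return An [well_annotations()] tibble.
#' @export
read_annotations <- function(path) {
  doc <- yaml::read_yaml(path)
  rows <- dplyr::bind_rows(lapply(doc$wells, tibble::as_tibble))
  well_annotations(rows$well_id, rows$kind, rows$sample_id,
                   as.numeric(rows$input_dose), rows$instrument_id,
                   rows$matched_control_id %||% "")
}

#' Write well annotations to a YAML file
#' @param ann An [well_annotations()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  yaml::write_yaml(list(wells = lapply(seq_len(nrow(ann)), function(i) {
    as.list(ann[i, , drop = FALSE])
  })), path, precision = 15)
  invisible(path)
}
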