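#' Log10 sample/control ratio signature
#'
#' Cross-instrument normalization: instead of background subtraction (whose
#' scale depends on instrument gain), each population is summarized as
#' `R = log10(mfi_sample / mfi_control)` using the raw (uncorrected) well
#' medians. A common multiplicative gain applied to both wells cancels in the
#' ratio, which is what makes signatures from differently scaled cytometers
#' comparable. Medians below the floor `epsilon` are raised to it, so R is
#' always finite; the floor used is recorded in the result's metadata.
#'
#' @param sample,control Per-population MFI tibbles from [population_mfi()]
#'   over the same panel.
#' @param epsilon Intensity floor (> 0). Default 1 reporter unit, the
#'   smallest intensity quantum worth resolving on this scale.
#' @param sample_id,instrument_id Identifiers carried into the result.
#' @param panel Optional [ev_panel()] to attach roles.
#' @return An `ev_logratio` tibble: `pop_id`, `marker_name`, (`role`),
#'   `mfi_sample`, `mfi_control`, `log10_ratio`, `qc_flag`; attributes
#'   `epsilon`, `sample_id`, `instrument_id`.
#' @export
log_ratio <- function(sample, control, epsilon = 1,
                      sample_id = "sample", instrument_id = "unknown",
                      panel = NULL) {
  if (epsilon <= 0) abort_validation("epsilon must be > 0")
  check_same_panel(sample, control)
  out <- tibble::tibble(
    pop_id = sample$pop_id,
    marker_name = sample$marker_name,
    mfi_sample = sample$mfi,
    mfi_control = control$mfi,
    log10_ratio = log10(pmax(sample$mfi, epsilon) / pmax(control$mfi, epsilon)),
    qc_flag = sample$qc_flag | control$qc_flag
  )
  if (!is.null(panel)) {
    out <- dplyr::left_join(out,
                            tibble::tibble(pop_id = panel$id, role = panel$role),
                            by = "pop_id")
    out <- dplyr::relocate(out, "role", .after = "marker_name")
  }
  structure(out, class = c("ev_logratio", class(out)),
            epsilon = epsilon, sample_id = sample_id,
            instrument_id = instrument_id)
}

#' Concordance of two runs of the same sample
#'
#' Compares two log-ratio signatures of the same panel — typically the same
#' sample acquired on two instruments. Rank (Spearman) correlation is the
#' right scale-free summary here: what should agree across instruments is
#' which markers stand out, not their absolute intensities. Isotype-control
#' rows are excluded when roles are available.
#'
#' @param a,b `ev_logratio` tables over the same panel.
#' @param positive_threshold Log10-ratio above which a marker is counted as
#'   "positive" for the both/either tally (default `log10(2)`, i.e. sample
#'   median at least twice its control).
#' @return List of class `ev_concordance`: `spearman`, `n_markers`,
#'   `per_marker` (marker, R in a, R in b, delta), `positive_both`,
#'   `positive_either`, `positive_threshold`.
#' @export
compare_runs <- function(a, b, positive_threshold = log10(2)) {
  stopifnot(inherits(a, "ev_logratio"), inherits(b, "ev_logratio"))
  if (!identical(a$pop_id, b$pop_id) ||
      !identical(a$marker_name, b$marker_name)) {
    abort_validation("log-ratio tables cover different panels")
  }
  keep <- !is.na(a$log10_ratio) & !is.na(b$log10_ratio)
  if ("role" %in% names(a)) keep <- keep & a$role != "isotype_control"
  if (sum(keep) < 3) {
    abort_insufficient("fewer than 3 shared non-missing marker rows")
  }
  ra <- a$log10_ratio[keep]
  rb <- b$log10_ratio[keep]
  per_marker <- tibble::tibble(marker_name = a$marker_name[keep],
                               r_a = ra, r_b = rb, delta = rb - ra)
  pos_a <- ra > positive_threshold
  pos_b <- rb > positive_threshold
  structure(list(
    spearman = stats::cor(ra, rb, method = "spearman"),
    n_markers = sum(keep),
    per_marker = per_marker,
    positive_both = sum(pos_a & pos_b),
    positive_either = sum(pos_a | pos_b),
    positive_threshold = positive_threshold
  ), class = "ev_concordance")
}

#' @export
print.ev_concordance <- function(x, ...) {
  cat(sprintf(paste0("<ev_concordance> %d markers, Spearman rho = %.3f; ",
                     "positive in both: %d, in either: %d (R > %.3f)\n"),
              x$n_markers, x$spearman, x$positive_both, x$positive_either,
              x$positive_threshold))
  invisible(x)
}

#' Export a populations x samples matrix for heatmap display
#'
#' Assembles signature or log-ratio tables into one matrix (rows in panel
#' order, columns in input order), writes it as CSV, and optionally renders a
#' heatmap figure via pheatmap.
#'
#' @param tables Non-empty list of `ev_signature` or `ev_logratio` tables on
#'   a common panel; column names come from the list names (or `sample_id`
#'   attributes, or S1..Sn).
#' @param path Output CSV path.
#' @param value Column to use: `"auto"` picks `log10_ratio` or `delta_mfi`.
#' @param plot_file Optional path for a rendered heatmap (PDF/PNG by
#'   extension); requires the pheatmap package.
#' @return The matrix, invisibly.
#' @export
heatmap_export <- function(tables, path, value = "auto", plot_file = NULL) {
  if (length(tables) < 1) abort_validation("need at least one table to export")
  pick <- function(t) {
    if (value != "auto") return(t[[value]])
    if ("log10_ratio" %in% names(t)) t$log10_ratio else t$delta_mfi
  }
  ref <- tables[[1]]
  for (t in tables[-1]) {
    if (!identical(t$pop_id, ref$pop_id)) {
      abort_validation("tables cover different panels")
    }
  }
  m <- vapply(tables, pick, numeric(nrow(ref)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(ref))
  rownames(m) <- ref$marker_name
  colnames(m) <- names(tables) %||%
    paste0("S", seq_along(tables))
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  if (!is.null(plot_file) && requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       filename = plot_file)
  }
  invisible(m)
}

#' Read back a heatmap matrix written by [heatmap_export()]
#' @param path CSV path.
#' @return Numeric matrix with marker rownames.
#' @export
read_heatmap_matrix <- function(path) {
  as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
}
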