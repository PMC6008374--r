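#' Construct a capture-bead panel definition
#'
#' A panel maps each hard-dyed capture-bead population to its antibody target
#' and to its expected location in transformed dye space (the two bead-ID
#' channels, e.g. FITC and PE). Downstream demultiplexing assigns events to the
#' nearest centroid under each population's own dispersion, so centroids and
#' dispersions are stored on the transformed (asinh) scale on which gating is
#' performed.
#'
#' @param populations A data frame with one row per bead population and columns
#'   `id` (integer), `marker_name` (unique), `role` (`"marker"` or
#'   `"isotype_control"`), `centroid_dye1`, `centroid_dye2` (transformed
#'   intensities), and `disp11`, `disp12`, `disp22` (entries of the symmetric
#'   2x2 dispersion of the transformed dye intensities).
#' @param version_tag Free-text tag identifying the panel version.
#' @param transformed_range Numeric length-2; the declared range of transformed
#'   dye intensities every centroid must lie within.
#'
#' @return A `ev_panel` object (a tibble with panel metadata attributes).
#' @export
ev_panel <- function(populations, version_tag = "unversioned",
                     transformed_range = c(0, 10)) {
  pop <- tibble::as_tibble(populations)
  required <- c("id", "marker_name", "role", "centroid_dye1", "centroid_dye2",
                "disp11", "disp12", "disp22")
  missing <- setdiff(required, names(pop))
  if (length(missing) > 0) {
    abort_validation(paste0("panel is missing columns: ",
                            paste(missing, collapse = ", ")))
  }
  pop$id <- as.integer(pop$id)
  pop <- pop[order(pop$id), , drop = FALSE]
  out <- structure(pop,
                   class = c("ev_panel", class(pop)),
                   version_tag = version_tag,
                   transformed_range = transformed_range)
  validate_panel(out)
  out
}

#' Validate a panel definition
#'
#' Checks the panel invariants: unique marker names and ids, at least one
#' isotype-control population, symmetric positive-definite dispersions, and all
#' centroids inside the declared transformed-intensity range.
#'
#' @param panel An [ev_panel()].
#' @return The panel, invisibly unchanged, or a validation error.
#' @export
validate_panel <- function(panel) {
  if (anyDuplicated(panel$marker_name) > 0) {
    abort_validation("duplicate marker names in panel")
  }
  if (anyDuplicated(panel$id) > 0) {
    abort_validation("duplicate population ids in panel")
  }
  if (!all(panel$role %in% c("marker", "isotype_control"))) {
    abort_validation("role must be 'marker' or 'isotype_control'")
  }
  if (sum(panel$role == "isotype_control") < 1) {
    abort_validation("panel must contain at least one isotype-control population")
  }
  rng <- attr(panel, "transformed_range")
  cents <- c(panel$centroid_dye1, panel$centroid_dye2)
  if (any(cents < rng[1] | cents > rng[2])) {
    abort_validation("panel centroid outside declared transformed-intensity range")
  }
  for (i in seq_len(nrow(panel))) {
    m <- matrix(c(panel$disp11[i], panel$disp12[i],
                  panel$disp12[i], panel$disp22[i]), 2, 2)
    if (!is_spd_2x2(m)) {
      abort_validation(sprintf("dispersion of population '%s' is not symmetric positive-definite",
                               panel$marker_name[i]))
    }
  }
  invisible(panel)
}

#' @export
print.ev_panel <- function(x, ...) {
  cat(sprintf("<ev_panel> %d populations (%d markers, %d isotype controls), version '%s'\n",
              nrow(x), sum(x$role == "marker"), sum(x$role == "isotype_control"),
              attr(x, "version_tag")))
  NextMethod()
}

# The 37 marker + 2 isotype-control targets of the common commercial 39-plex
# EV capture-bead panel.
panel_marker_names <- function() {
  c("CD1c", "CD2", "CD3", "CD4", "CD8", "CD9", "CD11c", "CD14", "CD19",
    "CD20", "CD24", "CD25", "CD29", "CD31", "CD40", "CD41b", "CD42a",
    "CD44", "CD45", "CD49e", "CD56", "CD62P", "CD63", "CD69", "CD81",
    "CD86", "CD105", "CD133/1", "CD142", "CD146", "CD209", "CD326",
    "HLA-ABC", "HLA-DRDPDQ", "MCSP", "ROR1", "SSEA-4",
    "mIgG1 isotype", "REA isotype")
}

#' The packaged default 39-population panel
#'
#' Returns the synthetic default panel: the standard 37-marker + 2
#' isotype-control target list, with dye-space centroids placed on a regular
#' 6x7 grid (minus three vacancies) in asinh-transformed FITC x PE space. The
#' true dye coordinates of the commercial bead kit are proprietary and
#' unpublished, so this layout is invented; grid spacing is >= 6x the
#' within-population SD, which preserves the structure of the demultiplexing
#' problem (well-separated, slightly overlapping-tail clusters) without the
#' vendor's map.
#'
#' @param dispersion_sd Within-population SD of the transformed dye
#'   intensities (same for both dye axes; dispersion is isotropic).
#' @return An [ev_panel()] with 39 populations.
#' @export
default_panel <- function(dispersion_sd = 0.12) {
  markers <- panel_marker_names()
  d1 <- seq(2.6, 6.6, by = 0.8)           # 6 columns
  d2 <- seq(2.2, 7.0, by = 0.8)           # 7 rows
  grid <- expand.grid(centroid_dye1 = d1, centroid_dye2 = d2)
  grid <- grid[seq_along(markers), , drop = FALSE]  # 39 of 42 cells occupied
  ev_panel(tibble::tibble(
    id = seq_along(markers),
    marker_name = markers,
    role = ifelse(grepl("isotype", markers), "isotype_control", "marker"),
    centroid_dye1 = grid$centroid_dye1,
    centroid_dye2 = grid$centroid_dye2,
    disp11 = dispersion_sd^2,
    disp12 = 0,
    disp22 = dispersion_sd^2
  ), version_tag = "synthetic-grid-1")
}

#' Read a panel definition from a YAML file
#'
#' @param path Path to a panel YAML file, as written by [write_panel()].
#' @return A validated [ev_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  doc <- yaml::read_yaml(path)
  pops <- dplyr::bind_rows(lapply(doc$populations, function(p) {
    tibble::tibble(
      id = as.integer(p$id),
      marker_name = p$marker_name,
      role = p$role,
      centroid_dye1 = as.numeric(p$centroid[[1]]),
      centroid_dye2 = as.numeric(p$centroid[[2]]),
      disp11 = as.numeric(p$dispersion[[1]]),
      disp12 = as.numeric(p$dispersion[[2]]),
      disp22 = as.numeric(p$dispersion[[3]])
    )
  }))
  ev_panel(pops,
           version_tag = doc$version_tag %||% "unversioned",
           transformed_range = as.numeric(doc$transformed_range %||% c(0, 10)))
}

#' Write a panel definition to a YAML file
#'
#' @param panel An [ev_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  doc <- list(
    version_tag = attr(panel, "version_tag"),
    transformed_range = as.numeric(attr(panel, "transformed_range")),
    populations = lapply(seq_len(nrow(panel)), function(i) {
      list(id = panel$id[i],
           marker_name = panel$marker_name[i],
           role = panel$role[i],
           centroid = c(panel$centroid_dye1[i], panel$centroid_dye2[i]),
           dispersion = c(panel$disp11[i], panel$disp12[i], panel$disp22[i]))
    })
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
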