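#' Read leaf reflectance spectra from a wide CSV
#'
#' Expects the EcoSIS-style wide layout: a `leaf_id` column, a `replicate`
#' column, then one column per wavelength in nanometres (numeric header,
#' strictly increasing left to right). Reflectance is a fraction; values
#' slightly above 1 (up to 1.2, occasional leaf-clip artifacts) are
#' tolerated and flagged, anything beyond is an error.
#'
#' @param path Path to the CSV file.
#' @return A long tibble with columns `leaf_id`, `replicate`, `wavelength`
#'   (nm), `reflectance`. Wavelengths are validated to lie in 350-2500 nm.
#' @export
read_spectra <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  spectra_long(wide)
}

# Validate and reshape a wide spectra table (leaf_id, replicate, <nm>...).
spectra_long <- function(wide) {
  nm <- names(wide)
  if (!all(c("leaf_id", "replicate") %in% nm)) {
    stop("wide spectra table needs 'leaf_id' and 'replicate' columns",
         call. = FALSE)
  }
  wl_cols <- setdiff(nm, c("leaf_id", "replicate"))
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (any(is.na(wl))) {
    stop("non-numeric wavelength column header(s): ",
         paste(utils::head(wl_cols[is.na(wl)], 3), collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(wl, strictly = TRUE)) {
    stop("wavelength headers must be strictly increasing", call. = FALSE)
  }
  if (any(wl < 350 | wl > 2500)) {
    stop("wavelengths outside the 350-2500 nm instrument range", call. = FALSE)
  }
  long <- tidyr::pivot_longer(wide, cols = dplyr::all_of(wl_cols),
                              names_to = "wavelength",
                              values_to = "reflectance")
  long$wavelength <- as.numeric(long$wavelength)
  if (any(!is.finite(long$reflectance))) {
    stop("non-numeric or missing reflectance values", call. = FALSE)
  }
  if (any(long$reflectance < 0 | long$reflectance > 1.2)) {
    stop("reflectance outside [0, 1.2]", call. = FALSE)
  }
  if (any(long$reflectance > 1)) {
    warning("reflectance values above 1 (<= 1.2) present; kept and flagged")
  }
  long$leaf_id <- as.character(long$leaf_id)
  long
}

#' Write spectra to the wide CSV layout
#'
#' Inverse of [read_spectra()]; round-trips values through text at full
#' precision.
#'
#' @param spectra Long spectra tibble (`leaf_id`, `replicate`, `wavelength`,
#'   `reflectance`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  wide <- tidyr::pivot_wider(spectra, id_cols = c("leaf_id", "replicate"),
                             names_from = "wavelength",
                             values_from = "reflectance")
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Average replicate scans into one spectrum per leaf
#'
#' Each leaf is scanned 3-4 times on different sections; the per-wavelength
#' arithmetic mean gives the single spectrum used downstream. All
#' replicates of a leaf must share the same wavelength grid.
#'
#' @param spectra Long spectra tibble with one or more replicates per leaf.
#' @return A long tibble `leaf_id`, `wavelength`, `reflectance` with one
#'   spectrum per leaf, plus `n_replicates`.
#' @export
average_replicates <- function(spectra) {
  grids <- dplyr::summarise(
    dplyr::group_by(spectra, .data$leaf_id, .data$replicate),
    grid = paste(.data$wavelength, collapse = ","), .groups = "drop"
  )
  bad <- dplyr::summarise(dplyr::group_by(grids, .data$leaf_id),
                          ok = dplyr::n_distinct(.data$grid) == 1L,
                          .groups = "drop")
  if (any(!bad$ok)) {
    stop("replicates on mismatched wavelength grids for leaf: ",
         paste(bad$leaf_id[!bad$ok], collapse = ", "), call. = FALSE)
  }
  dplyr::summarise(
    dplyr::group_by(spectra, .data$leaf_id, .data$wavelength),
    n_replicates = dplyr::n(),
    reflectance = mean(.data$reflectance),
    .groups = "drop"
  )
}

#' Regrid a spectrum onto a regular wavelength grid
#'
#' Linear interpolation onto an integer-nanometre grid, by default
#' 500-2400 nm at 1 nm — the window used for the spectra-trait models,
#' trimming detector-edge noise at both ends of the 350-2500 nm instrument
#' range. Interpolated values are clipped to [0, 1.2].
#'
#' @param spectra Long tibble `leaf_id`, `wavelength`, `reflectance`
#'   (replicates already averaged; a `replicate` column, if present, is
#'   regridded per replicate).
#' @param grid_start,grid_end,step Target grid in nm.
#' @return A long tibble on the common grid, same identifier columns.
#' @export
regrid_spectra <- function(spectra, grid_start = 500, grid_end = 2400,
                           step = 1) {
  grid <- seq(grid_start, grid_end, by = step)
  keys <- intersect(c("leaf_id", "replicate"), names(spectra))
  groups <- dplyr::group_split(
    dplyr::group_by(spectra, dplyr::across(dplyr::all_of(keys)))
  )
  purrr::map_dfr(groups, function(g) {
    if (min(g$wavelength) > grid_start || max(g$wavelength) < grid_end) {
      stop("requested grid [", grid_start, ", ", grid_end,
           "] nm outside the measured range [", min(g$wavelength), ", ",
           max(g$wavelength), "] nm", call. = FALSE)
    }
    out <- g[rep(1L, length(grid)), keys, drop = FALSE]
    out$wavelength <- grid
    out$reflectance <- pmin(pmax(
      stats::approx(g$wavelength, g$reflectance, xout = grid)$y, 0), 1.2)
    out
  })
}

#' Assemble the leaf-by-wavelength matrix consumed by PLSR
#'
#' Averages replicates (if present), regrids onto the common grid, and
#' returns a numeric matrix with one row per leaf and one column per
#' wavelength.
#'
#' @param spectra Long spectra tibble.
#' @param grid_start,grid_end,step Passed to [regrid_spectra()].
#' @return A numeric matrix; rownames are `leaf_id`, colnames the grid in
#'   nm (as character).
#' @export
spectra_matrix <- function(spectra, grid_start = 500, grid_end = 2400,
                           step = 1) {
  if ("replicate" %in% names(spectra)) {
    spectra <- average_replicates(spectra)
  }
  rg <- regrid_spectra(spectra, grid_start, grid_end, step)
  wide <- tidyr::pivot_wider(rg, id_cols = "leaf_id",
                             names_from = "wavelength",
                             values_from = "reflectance")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$leaf_id
  m
}
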