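#' Read occurrence records from CSV
#'
#' Accepts community-science exports (iNaturalist / GBIF style). Column names
#' are configurable; an iNaturalist `observed_on` date column is recognised
#' out of the box. Rows whose coordinates or dates cannot be parsed, or whose
#' coordinates are out of range, are dropped and the drop count is reported
#' with a message.
#'
#' @param path CSV file path.
#' @param source one of `"inat"`, `"gbif"`, `"synthetic"`.
#' @param cols named list mapping the fields `lon`, `lat`, `date`, and
#'   optionally `species`, `id`, to column names in the file.
#' @return data.frame with columns `record_id`, `lon`, `lat`, `date`
#'   (class `Date`), `species`, `source`. Attribute `n_dropped` counts
#'   discarded rows.
#' @export
read_occurrences <- function(path,
                             source = c("inat", "gbif", "synthetic"),
                             cols = list(lon = "longitude", lat = "latitude",
                                         date = NULL, species = "species",
                                         id = NULL)) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (is.null(cols$date)) {
    cols$date <- intersect(c("observed_on", "eventDate", "date"), names(raw))[1]
    if (is.na(cols$date)) cols$date <- "date"
  }
  for (field in c("lon", "lat", "date")) {
    if (!cols[[field]] %in% names(raw)) {
      stop("missing required column '", cols[[field]], "' (", field, ")",
           call. = FALSE)
    }
  }
  lon <- suppressWarnings(as.numeric(raw[[cols$lon]]))
  lat <- suppressWarnings(as.numeric(raw[[cols$lat]]))
  date <- as.Date(raw[[cols$date]], optional = TRUE)
  species <- if (!is.null(cols$species) && cols$species %in% names(raw)) {
    raw[[cols$species]]
  } else {
    rep(NA_character_, nrow(raw))
  }
  id <- if (!is.null(cols$id) && cols$id %in% names(raw)) {
    raw[[cols$id]]
  } else if (nrow(raw)) {
    sprintf("%s-%06d", source, seq_len(nrow(raw)))
  } else {
    character(0)
  }
  ok <- !is.na(lon) & !is.na(lat) & !is.na(date) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  ok[is.na(ok)] <- FALSE
  dropped <- sum(!ok)
  if (dropped > 0) {
    message(dropped, " row(s) dropped (unparseable or out-of-range)")
  }
  out <- data.frame(
    record_id = id[ok], lon = lon[ok], lat = lat[ok], date = date[ok],
    species = species[ok], source = rep(source, sum(ok)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$record_id)) {
    stop("record_id values are not unique", call. = FALSE)
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Write occurrences to CSV
#' @param occs occurrence data.frame (see [read_occurrences()]).
#' @param path output path.
#' @export
write_occurrences <- function(occs, path) {
  utils::write.csv(
    data.frame(record_id = occs$record_id, longitude = occs$lon,
               latitude = occs$lat, observed_on = as.character(occs$date),
               species = occs$species),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Deduplicate occurrences across sources
#'
#' Records identical on (lon, lat, date, species) are collapsed to the first.
#' Needed when the same observation is exported by both iNaturalist and GBIF.
#'
#' @param occs occurrence data.frame.
#' @return deduplicated data.frame.
#' @export
dedupe_occurrences <- function(occs) {
  key <- paste(occs$lon, occs$lat, occs$date, occs$species, sep = "\r")
  occs[!duplicated(key), , drop = FALSE]
}

#' Clip occurrences to an extent
#'
#' Membership is half-open: `min <= coordinate < max` on both axes, so a
#' point on a shared edge between two adjacent extents belongs to exactly one.
#'
#' @param occs occurrence data.frame.
#' @param ext an [extent()].
#' @return the retained rows.
#' @export
clip_to_extent <- function(occs, ext) {
  stopifnot(inherits(ext, "extent"))
  keep <- occs$lon >= ext$min_lon & occs$lon < ext$max_lon &
    occs$lat >= ext$min_lat & occs$lat < ext$max_lat
  occs[keep, , drop = FALSE]
}

#' Spatially thin occurrences to one record per grid cell
#'
#' Community-science sampling is spatially biased (clustered near people);
#' thinning to at most one record per predictor-grid cell (~4 km^2 at 2.5
#' arc-min) flattens that bias before model fitting. Within a cell one record
#' is kept uniformly at random under `seed`. Points off the grid are dropped
#' with a warning.
#'
#' @param occs occurrence data.frame.
#' @param grid a [grid_layer()] defining the thinning cells.
#' @param seed integer seed for the within-cell choice.
#' @return thinned data.frame, ordered by cell index (deterministic given
#'   seed).
#' @export
thin_occurrences <- function(occs, grid, seed = 1L) {
  idx <- cell_index(grid, occs$lon, occs$lat)
  off <- is.na(idx$cell)
  if (any(off)) {
    warning(sum(off), " occurrence(s) off the thinning grid dropped")
    occs <- occs[!off, , drop = FALSE]
    idx <- idx[!off, , drop = FALSE]
  }
  if (!nrow(occs)) return(occs)
  # The within-cell draw is keyed on (seed, cell id) so the choice in a cell
  # is unaffected by which other cells exist: thinning then commutes with
  # cell-aligned clipping and is idempotent.
  cells <- split(seq_len(nrow(occs)), idx$cell)
  keep <- mapply(function(rows, cell) {
    if (length(rows) == 1L) return(rows)
    pick <- local_seed((seed + as.numeric(cell)) %% .Machine$integer.max,
                       sample.int(length(rows), 1L))
    rows[pick]
  }, cells, as.numeric(names(cells)))
  keep <- keep[order(as.numeric(names(cells)))]
  occs[keep, , drop = FALSE]
}

#' Sample background points from a raster
#'
#' Draws `n` points uniformly over the non-nodata cells of `template` whose
#' centers lie inside `extent` (cells may repeat), returning cell-center
#' coordinates labelled `background`. Presence-background models contrast
#' these with occurrences.
#'
#' @param template a [grid_layer()] whose nodata mask defines valid land.
#' @param n number of points (default 50000, the study setting).
#' @param ext an [extent()]; defaults to the template's own extent.
#' @param seed integer seed.
#' @return data.frame `lon`, `lat`, `label = "background"`.
#' @export
sample_background <- function(template, n = 50000L, ext = layer_extent(template),
                              seed = 1L) {
  stopifnot(n >= 1)
  rows <- rep(seq_len(template$nrow), each = template$ncol)
  cols <- rep(seq_len(template$ncol), times = template$nrow)
  ctr <- cell_center(template, rows, cols)
  valid <- which(!is.na(t(template$values)) &
                   ctr$lon >= ext$min_lon & ctr$lon < ext$max_lon &
                   ctr$lat >= ext$min_lat & ctr$lat < ext$max_lat)
  if (!length(valid)) stop("no valid (non-nodata) cells in extent", call. = FALSE)
  picks <- valid[local_seed(seed, sample.int(length(valid), n, replace = TRUE))]
  data.frame(lon = ctr$lon[picks], lat = ctr$lat[picks],
             label = "background", stringsAsFactors = FALSE)
}

#' Extract predictor values at points
#'
#' Nearest-cell (containing-cell) lookup on each layer. Points that hit
#' nodata in any layer are dropped and counted.
#'
#' @param points data.frame with `lon`, `lat` and optionally `label`.
#' @param layers named list of co-registered [grid_layer()]s.
#' @return data.frame of the surviving points with one numeric column per
#'   layer; attribute `n_dropped` counts removals.
#' @export
extract_values <- function(points, layers) {
  stopifnot(length(layers) >= 1)
  nms <- names(layers)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- vapply(layers, `[[`, "", "name")
  }
  for (l in layers[-1]) {
    if (!same_geometry(layers[[1]], l)) {
      stop("layer geometries do not match", call. = FALSE)
    }
  }
  vals <- vapply(layers, function(l) layer_value_at(l, points$lon, points$lat),
                 numeric(nrow(points)))
  vals <- matrix(vals, nrow = nrow(points),
                 dimnames = list(NULL, nms))
  ok <- stats::complete.cases(vals)
  dropped <- sum(!ok)
  if (dropped > 0) message(dropped, " point(s) on nodata dropped")
  out <- cbind(points[ok, , drop = FALSE],
               as.data.frame(vals[ok, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}
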