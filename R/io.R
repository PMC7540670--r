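#' @include RangePolygon.R scoring.R
NULL

#' Read a range polygon from GeoJSON
#'
#' Accepts RFC 7946 Polygon, MultiPolygon, Feature or FeatureCollection
#' objects (all features are merged into one multipolygon; coordinates are
#' taken as lon/lat WGS84, the only CRS GeoJSON allows).
#'
#' @param path path to a .geojson / .json file.
#' @param label label for the polygon; defaults to the file name.
#' @return a [RangePolygon-class].
#' @export
readRangeGeoJSON <- function(path, label = NULL) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(label)) label <- sub("\\.(geo)?json$", "", basename(path))
  rings <- list(); hole <- logical(0)
  addPolygon <- function(coords) {
    # coords: list of rings; first exterior, rest holes
    for (k in seq_along(coords)) {
      m <- do.call(rbind, lapply(coords[[k]], function(pt)
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
      rings[[length(rings) + 1L]] <<- m
      hole[length(rings)] <<- k > 1
    }
  }
  addGeometry <- function(geom) {
    type <- geom$type
    if (is.null(type)) stop("invalid GeoJSON: geometry without type")
    switch(type,
      Polygon = addPolygon(geom$coordinates),
      MultiPolygon = for (pg in geom$coordinates) addPolygon(pg),
      Feature = addGeometry(geom$geometry),
      FeatureCollection = for (f in geom$features) addGeometry(f),
      GeometryCollection = for (g in geom$geometries) addGeometry(g),
      stop("unsupported GeoJSON type: ", type))
  }
  addGeometry(gj)
  RangePolygon(rings, label = label, hole = hole)
}

#' Write a range polygon to GeoJSON
#'
#' Writes a [RangePolygon-class] as an RFC 7946 MultiPolygon Feature, holes
#' grouped with the shell that contains them, shells counter-clockwise and
#' holes clockwise.
#'
#' @param poly a [RangePolygon-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRangeGeoJSON <- function(poly, path) {
  shells <- which(!poly@hole)
  if (!length(shells)) stop("empty polygon")
  polys <- lapply(shells, function(s) {
    ringList <- list(.gjRing(poly@rings[[s]], ccw = TRUE))
    for (h in which(poly@hole)) {
      probe <- poly@rings[[h]][1, ] * 0.999 + colMeans(poly@rings[[h]]) * 0.001
      if (.pipRing(probe[1], probe[2], poly@rings[[s]]))
        ringList[[length(ringList) + 1L]] <- .gjRing(poly@rings[[h]], ccw = FALSE)
    }
    ringList
  })
  obj <- list(type = "Feature",
    properties = list(label = poly@label),
    geometry = list(type = "MultiPolygon", coordinates = polys))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.gjRing <- function(ring, ccw = TRUE) {
  isCCW <- .ringAreaSigned(ring) > 0
  if (isCCW != ccw) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  ring <- rbind(ring, ring[1, , drop = FALSE])
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

#' Read occurrence records from CSV
#'
#' Expects a header row with columns \code{lon}, \code{lat} and optionally
#' \code{species}; extra columns are ignored.
#'
#' @param path CSV path.
#' @param species optional species id to filter on.
#' @return data.frame with lon, lat (and species when present).
#' @export
readOccurrences <- function(path, species = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lon", "lat") %in% names(d)))
    stop("occurrence CSV needs columns lon, lat")
  if (!is.null(species)) {
    if (!"species" %in% names(d)) stop("no species column to filter on")
    d <- d[d$species == species, , drop = FALSE]
  }
  d
}

#' Read/write a probability surface as long-format CSV
#'
#' The on-disk format is one row per masked cell with columns
#' \code{lon, lat, lambda_bar, p} (cell centres).  The grid is reconstructed
#' from the coordinates on read: the resolution is the smallest positive
#' coordinate step, and rows present in the file define the mask.
#'
#' @param surface a [ProbabilitySurface-class].
#' @param path CSV path.
#' @param clampEps clamp bound used when re-deriving p on read.
#' @return \code{writeSurfaceCSV} returns the path invisibly;
#'   \code{readSurfaceCSV} returns a [ProbabilitySurface-class].
#' @export
writeSurfaceCSV <- function(surface, path) {
  grid <- surface@grid
  m <- grid@mask
  ctr <- cellCenters(grid)
  utils::write.csv(data.frame(lon = ctr[m, 1], lat = ctr[m, 2],
    lambda_bar = surface@lambdaBar[m], p = surface@p[m]), path,
    row.names = FALSE)
  invisible(path)
}

#' @rdname writeSurfaceCSV
#' @export
readSurfaceCSV <- function(path, clampEps = 1e-10) {
  d <- utils::read.csv(path)
  if (!all(c("lon", "lat", "lambda_bar") %in% names(d)))
    stop("surface CSV needs columns lon, lat, lambda_bar")
  lons <- sort(unique(d$lon)); lats <- sort(unique(d$lat))
  step <- function(v) if (length(v) > 1) min(diff(v)) else NA_real_
  res <- min(step(lons), step(lats), na.rm = TRUE)
  if (!is.finite(res) || res <= 0) stop("cannot infer grid resolution")
  west <- min(lons) - res / 2
  south <- min(lats) - res / 2
  nCols <- as.integer(round((max(lons) + res / 2 - west) / res))
  nRows <- as.integer(round((max(lats) + res / 2 - south) / res))
  ci <- as.integer(round((d$lon - west - res / 2) / res)) + 1L
  ri <- as.integer(round((d$lat - south - res / 2) / res)) + 1L
  if (any(ci < 1 | ci > nCols | ri < 1 | ri > nRows))
    stop("surface CSV coordinates do not form a regular grid")
  idx <- (ri - 1L) * nCols + ci
  n <- nCols * nRows
  mask <- rep(FALSE, n); mask[idx] <- TRUE
  lambdaBar <- rep(NA_real_, n); lambdaBar[idx] <- d$lambda_bar
  cy <- south + (seq_len(nRows) - 0.5) * res
  areas <- rep(.cellAreaKm2(cy - res / 2, cy + res / 2, res), each = nCols)
  grid <- new("GridSpec", resolutionArcmin = res * 60, west = west,
    south = south, nCols = nCols, nRows = nRows, mask = mask,
    cellAreas = areas)
  occupancyProbability(lambdaBar, grid, clampEps)
}

#' Write a deviance result with provenance
#'
#' Emits the seven deviance/score fields as JSON (with the run
#' configuration echoed for provenance) or CSV.
#'
#' @param result a [DevianceResult-class].
#' @param path output path.
#' @param format "json" or "csv".
#' @param config optional configuration list echoed into JSON output.
#' @return the path, invisibly.
#' @export
writeDevianceResult <- function(result, path, format = c("json", "csv"),
                                config = NULL) {
  format <- match.arg(format)
  df <- as.data.frame(result)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    obj <- as.list(df)
    if (!is.null(config)) obj$config <- config
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Default run configuration
#'
#' The pipeline constants: grid resolution 10 arc minutes, alpha-hull disk
#' radius 8 degrees, probability clamp 1e-10 and importance threshold 0.8.
#' Values supplied in \code{...} or read from a JSON config file override
#' the defaults; the resulting list is echoed into outputs for provenance.
#'
#' @param ... named overrides.
#' @param configFile optional JSON file of overrides.
#' @return named list with resolutionArcmin, alphaDeg, clampEps,
#'   importanceThreshold, seed.
#' @export
runConfig <- function(..., configFile = NULL) {
  cfg <- list(resolutionArcmin = 10, alphaDeg = 8, clampEps = 1e-10,
    importanceThreshold = 0.8, seed = 1L)
  if (!is.null(configFile)) {
    over <- jsonlite::read_json(configFile, simplifyVector = TRUE)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}
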