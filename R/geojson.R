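# Minimal GeoJSON I/O for the formats the pipeline exchanges:
# FeatureCollections of Polygons (gaps, home ranges) and LineStrings (routes).
# Coordinates are written as-is (projected meters); consumers that need
# geographic GeoJSON should reproject outside the package.

# one feature: list(geometry_type, coords, properties)
.gj_feature <- function(type, coords, properties) {
  list(type = "Feature",
       properties = properties,
       geometry = list(type = type, coordinates = coords))
}

#' Write polygons to a GeoJSON FeatureCollection
#'
#' @param polys list of polygons; each element is either a ring matrix or a
#'   list of ring matrices (first exterior, rest holes).
#' @param properties data.frame with one row per polygon (optional).
#' @param path output file.
#' @export
write_polygons_geojson <- function(polys, path, properties = NULL) {
  feats <- lapply(seq_along(polys), function(i) {
    rings <- polys[[i]]
    if (!is.list(rings) || is.data.frame(rings)) rings <- list(rings)
    coords <- lapply(rings, function(r) {
      r <- as_xy(r)
      if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])  # close ring
      unname(lapply(seq_len(nrow(r)), function(j) c(r[j, 1], r[j, 2])))
    })
    props <- if (is.null(properties)) setNames(list(), character(0))
             else as.list(properties[i, , drop = FALSE])
    .gj_feature("Polygon", coords, props)
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Write polylines to a GeoJSON FeatureCollection
#'
#' @param lines list of two-column vertex matrices.
#' @param properties data.frame with one row per line (optional).
#' @param path output file.
#' @export
write_lines_geojson <- function(lines, path, properties = NULL) {
  feats <- lapply(seq_along(lines), function(i) {
    r <- as_xy(lines[[i]])
    coords <- unname(lapply(seq_len(nrow(r)), function(j) c(r[j, 1], r[j, 2])))
    props <- if (is.null(properties)) setNames(list(), character(0))
             else as.list(properties[i, , drop = FALSE])
    .gj_feature("LineString", coords, props)
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection of Polygons or LineStrings
#'
#' @param path GeoJSON file.
#' @return List with `geometries` (list of ring-lists for polygons, vertex
#'   matrices for linestrings), `types`, and `properties` (data.frame).
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  geoms <- list(); types <- character(0); props <- list()
  for (f in gj$features) {
    g <- f$geometry
    if (g$type == "Polygon") {
      rings <- lapply(g$coordinates, function(ring)
        do.call(rbind, lapply(ring, function(p) c(x = p[[1]], y = p[[2]]))))
      geoms[[length(geoms) + 1]] <- rings
    } else if (g$type == "LineString") {
      geoms[[length(geoms) + 1]] <-
        do.call(rbind, lapply(g$coordinates, function(p) c(x = p[[1]], y = p[[2]])))
    } else stop("unsupported geometry type: ", g$type)
    types <- c(types, g$type)
    props[[length(props) + 1]] <- f$properties
  }
  pdf <- if (all(lengths(props) == 0)) NULL else {
    keys <- unique(unlist(lapply(props, names)))
    as.data.frame(lapply(setNames(keys, keys), function(k)
      sapply(props, function(p) if (is.null(p[[k]])) NA else p[[k]])),
      stringsAsFactors = FALSE)
  }
  list(geometries = geoms, types = types, properties = pdf)
}
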