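# Plain-text interchange: trajectory / table CSV, polygon GeoJSON, scene JSON.

#' Write / read a trajectory as CSV
#'
#' Columns: `id`, `timestamp` (ISO-8601 UTC), `x`, `y` (planar metres).
#' Optional flag columns are passed through.
#' @param traj Trajectory data frame.
#' @param path Output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- data.frame(id = traj$id, timestamp = iso8601(traj$t), x = traj$x, y = traj$y)
  extra <- setdiff(names(traj), c("id", "t", "x", "y"))
  for (cn in extra) out[[cn]] <- traj[[cn]]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @return `read_trajectory_csv`: the trajectory data frame.
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(id = as.character(d$id), t = parse_iso8601(d$timestamp),
                    x = d$x, y = d$y, stringsAsFactors = FALSE)
  extra <- setdiff(names(d), c("id", "timestamp", "x", "y"))
  for (cn in extra) out[[cn]] <- d[[cn]]
  check_trajectory(out)
}

close_ring <- function(r) {
  cbind(c(r$x, r$x[1]), c(r$y, r$y[1]))
}

#' Write CFA polygons as GeoJSON
#'
#' Each `cfa` becomes one MultiPolygon feature with `species`, `individual`
#' and `level` properties; holes are nested under their enclosing outer
#' ring.
#' @param cfas List of `cfa` objects (a single `cfa` is accepted).
#' @param path Output file.
#' @export
write_cfa_geojson <- function(cfas, path) {
  if (inherits(cfas, "cfa")) cfas <- list(cfas)
  features <- lapply(cfas, function(cf) {
    polys <- rings_to_polygons(cf$rings)
    coords <- lapply(polys, function(p) lapply(p, close_ring))
    list(type = "Feature",
         properties = list(species = cf$species, individual = cf$individual,
                           level = cf$level),
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cfa_geojson
#' @return `read_cfa_geojson`: list of `cfa` objects.
#' @export
read_cfa_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(gj$features, function(ft) {
    rings <- list()
    for (poly in ft$geometry$coordinates) {
      for (ring in poly) {
        m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
        m <- m[-nrow(m), , drop = FALSE]  # drop closing vertex
        rings[[length(rings) + 1]] <- list(x = m[, 1], y = m[, 2])
      }
    }
    pr <- ft$properties
    structure(list(rings = rings, level = pr$level, species = pr$species,
                   individual = pr$individual, area = rings_area(rings)),
              class = "cfa")
  })
}

#' Write an observation or plot table as CSV
#' @param table Data frame.
#' @param path Output file.
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a scene as JSON (cube plus truth sidecar in one file)
#'
#' A plain-text serialisation of the reflectance cube with its wavelengths,
#' planted truth fields, fraction maps and generating seed; intended for
#' small scenes.
#' @param scene A `scene`.
#' @param path Output file.
#' @export
write_scene_json <- function(scene, path) {
  obj <- list(
    dim = dim(scene$reflectance),
    wavelengths = scene$wavelengths,
    origin = scene$origin, res = scene$res,
    seed = scene$config$seed,
    reflectance = as.numeric(scene$reflectance),
    fractions = as.numeric(scene$fractions),
    endmember_labels = rownames(scene$endmembers),
    biomass = as.numeric(scene$biomass),
    nitrogen = as.numeric(scene$nitrogen)
  )
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_scene_json
#' @return `read_scene_json`: a `scene` (without the pre-mixing grass cube).
#' @export
read_scene_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- o$dim
  lib <- endmember_library(o$wavelengths, labels = o$endmember_labels)
  structure(list(
    reflectance = array(o$reflectance, dim = d),
    grass_reflectance = NULL,
    fractions = array(o$fractions, dim = c(d[1], d[2], length(o$endmember_labels)),
                      dimnames = list(NULL, NULL, o$endmember_labels)),
    biomass = matrix(o$biomass, d[1], d[2]),
    nitrogen = matrix(o$nitrogen, d[1], d[2]),
    endmembers = lib, wavelengths = o$wavelengths,
    origin = o$origin, res = o$res,
    config = list(seed = o$seed)
  ), class = "scene")
}
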