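# Habitat map: numbered bush polygons fringing the interior of a fenced park.
# The map is the spatial universe of every analysis; capture locations are
# always coarsened to the centroid of the bush of capture.

#' Construct a habitat map
#'
#' @param bushes named list of open polygon rings (n x 2 matrices); names are
#'   the integer bush ids
#' @param fence closed polyline (m x 2 matrix, last vertex == first) tracing
#'   the park perimeter fence
#' @param crs_note free-text note on the coordinate frame
#' @param fence_buffer maximum distance (m) allowed between a bush centroid and
#'   the fence; bushes line the park perimeter
#' @return object of class `habitat_map` with elements `bushes` (list of
#'   rings), `bush_ids`, `centroids` (matrix), `fence`, `crs_note`
#' @export
habitat_map <- function(bushes, fence, crs_note = "local park metres",
                        fence_buffer = 10) {
  ids <- suppressWarnings(as.integer(names(bushes)))
  if (anyNA(ids) || anyDuplicated(ids))
    stop("bush ids must be unique integers")
  fence <- as.matrix(fence)
  if (!isTRUE(all.equal(fence[1, ], fence[nrow(fence), ], check.attributes = FALSE)))
    stop("fence polyline must be closed (first vertex repeated last)")
  cents <- matrix(NA_real_, length(bushes), 2)
  for (i in seq_along(bushes)) {
    poly <- as.matrix(bushes[[i]])
    if (polygon_area(poly) <= 0)
      stop(sprintf("bush %d has non-positive area", ids[i]))
    if (!is_simple_ring(poly))
      stop(sprintf("bush %d polygon is self-intersecting", ids[i]))
    cents[i, ] <- polygon_centroid(poly)
    bushes[[i]] <- poly
  }
  d2f <- vapply(seq_len(nrow(cents)), function(i) {
    pr <- project_on_polyline(cents[i, ], fence)
    sqrt(sum((cents[i, ] - pr$point)^2))
  }, numeric(1))
  if (any(d2f > fence_buffer))
    stop(sprintf("bush centroid(s) %s farther than %.1f m from the fence",
                 paste(ids[d2f > fence_buffer], collapse = ", "), fence_buffer))
  rownames(cents) <- as.character(ids)
  structure(list(bushes = bushes, bush_ids = ids, centroids = cents,
                 fence = fence, crs_note = crs_note),
            class = "habitat_map")
}

is_simple_ring <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  for (i in seq_len(n)) {
    p1 <- poly[i, ]; p2 <- poly[if (i == n) 1 else i + 1, ]
    for (j in seq_len(n)) {
      if (j == i) next
      # skip edges sharing a vertex with edge i
      jn <- if (j == n) 1 else j + 1
      if (jn == i || j == (if (i == n) 1 else i + 1)) next
      q1 <- poly[j, ]; q2 <- poly[jn, ]
      if (segments_intersect(p1, p2, q1, q2)) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.habitat_map <- function(x, ...) {
  cat(sprintf("habitat_map: %d bushes, fence length %.1f m (%s)\n",
              length(x$bushes), polyline_length(x$fence), x$crs_note))
  invisible(x)
}

polyline_length <- function(line) {
  sum(sqrt(rowSums((line[-1, , drop = FALSE] - line[-nrow(line), , drop = FALSE])^2)))
}

#' Read a habitat map from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features with an integer `bush_id`
#' property, plus one LineString feature with property `feature = "fence"`
#' tracing the park perimeter.
#'
#' @param path GeoJSON file
#' @param fence_buffer see [habitat_map()]
#' @return a `habitat_map`
#' @export
read_habitat_geojson <- function(path, fence_buffer = 10) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  bushes <- list(); fence <- NULL; crs_note <- "local park metres"
  if (!is.null(gj$crs_note)) crs_note <- gj$crs_note
  for (ft in gj$features) {
    geom <- ft$geometry
    if (identical(geom$type, "Polygon")) {
      id <- ft$properties$bush_id
      if (is.null(id)) stop("polygon feature without bush_id property")
      ring <- do.call(rbind, lapply(geom$coordinates[[1]], function(p)
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
      # GeoJSON rings are closed; store open
      if (isTRUE(all.equal(ring[1, ], ring[nrow(ring), ])))
        ring <- ring[-nrow(ring), , drop = FALSE]
      bushes[[as.character(id)]] <- ring
    } else if (identical(geom$type, "LineString")) {
      fence <- do.call(rbind, lapply(geom$coordinates, function(p)
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    }
  }
  if (is.null(fence)) stop("no fence LineString feature in habitat file")
  habitat_map(bushes, fence, crs_note = crs_note, fence_buffer = fence_buffer)
}

#' Write a habitat map to GeoJSON
#' @param habitat a `habitat_map`
#' @param path output file
#' @export
write_habitat_geojson <- function(habitat, path) {
  feats <- lapply(seq_along(habitat$bushes), function(i) {
    ring <- habitat$bushes[[i]]
    ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(bush_id = habitat$bush_ids[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) as.numeric(ring[j, ])))))
  })
  feats[[length(feats) + 1]] <- list(
    type = "Feature", properties = list(feature = "fence"),
    geometry = list(type = "LineString",
                    coordinates = lapply(seq_len(nrow(habitat$fence)),
                                         function(j) as.numeric(habitat$fence[j, ]))))
  jsonlite::write_json(list(type = "FeatureCollection",
                            crs_note = habitat$crs_note, features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bush centroids
#' @param habitat a `habitat_map`
#' @return matrix of centroids with bush ids as rownames
#' @export
bush_centroids <- function(habitat) habitat$centroids
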