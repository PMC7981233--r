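# Spatial statistics: bush distance matrices, home-range polygons from
# farthest capture points, and the average-distance statistic d' used to
# quantify male spatial distancing.

#' Bush-to-bush distance matrix
#'
#' Euclidean distances are straight lines between bush centroids. Perimeter
#' distances follow the park fence: each centroid is projected
#' perpendicularly onto the fence polyline and the shorter of the two
#' along-fence arcs between projections is taken. The perimeter metric
#' reflects that the open park centre is not a dispersal corridor; lizards
#' move along the fence-line bushes.
#'
#' @param habitat a `habitat_map` with at least two bushes
#' @param metric "euclidean" or "perimeter"
#' @return symmetric matrix (m) with bush ids as dimnames and attribute
#'   `metric`
#' @export
bush_distance_matrix <- function(habitat, metric = c("perimeter", "euclidean")) {
  metric <- match.arg(metric)
  cents <- habitat$centroids
  if (nrow(cents) < 2) stop("need at least two bushes")
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(cents))
  } else {
    pr <- lapply(seq_len(nrow(cents)), function(i)
      project_on_polyline(cents[i, ], habitat$fence))
    arcs <- vapply(pr, `[[`, numeric(1), "arc")
    total <- pr[[1]]$total
    ad <- abs(outer(arcs, arcs, "-"))
    d <- pmin(ad, total - ad)
    dimnames(d) <- list(rownames(cents), rownames(cents))
  }
  attr(d, "metric") <- metric
  d
}

#' Home range of one individual from its capture bushes
#'
#' With a single distinct capture bush the home range is that bush polygon;
#' with two or more the range is the convex hull of the union of all capture
#' bush polygons — the deterministic region containing the farthest capture
#' points and all area in between.
#'
#' @param captures validated capture table
#' @param id individual id
#' @param habitat a `habitat_map`
#' @return list of class `home_range`: `id`, `bush_ids`, `polygon` (open
#'   ring), `area` (m^2), `n_capture_cohorts`, `single_bush` flag
#' @export
home_range <- function(captures, id, habitat) {
  rec <- captures[captures$id == id, ]
  if (nrow(rec) == 0) stop("no capture records for individual ", id)
  bids <- sort(unique(rec$bush_id))
  polys <- habitat$bushes[as.character(bids)]
  if (length(bids) == 1) {
    poly <- polys[[1]]
  } else {
    poly <- convex_hull(do.call(rbind, polys))
  }
  structure(list(id = id, bush_ids = bids, polygon = poly,
                 area = polygon_area(poly),
                 n_capture_cohorts = nrow(rec),
                 single_bush = length(bids) == 1),
            class = "home_range")
}

#' Home ranges for every individual in a capture table
#'
#' @param captures validated capture table
#' @param habitat a `habitat_map`
#' @param exclude_single_capture drop individuals captured in only one cohort
#'   (their range collapses to one bush); default keeps them flagged
#' @return list of `home_range` objects named by id, plus a summary
#'   data.frame in attribute `"summary"` (id, sex, n_capture_cohorts,
#'   n_bushes, area, log_area, single_bush)
#' @export
home_ranges <- function(captures, habitat, exclude_single_capture = FALSE) {
  ids <- sort(unique(captures$id))
  hrs <- lapply(ids, function(i) home_range(captures, i, habitat))
  names(hrs) <- ids
  if (exclude_single_capture) {
    keep <- vapply(hrs, function(h) h$n_capture_cohorts > 1, logical(1))
    hrs <- hrs[keep]
  }
  sex <- vapply(names(hrs), function(i) captures$sex[captures$id == i][1], "")
  smry <- data.frame(
    id = names(hrs),
    sex = sex,
    n_capture_cohorts = vapply(hrs, `[[`, numeric(1), "n_capture_cohorts"),
    n_bushes = vapply(hrs, function(h) length(h$bush_ids), numeric(1)),
    area = vapply(hrs, `[[`, numeric(1), "area"),
    single_bush = vapply(hrs, `[[`, logical(1), "single_bush"),
    stringsAsFactors = FALSE, row.names = NULL)
  smry$log_area <- log(smry$area)
  attr(hrs, "summary") <- smry
  hrs
}

#' Average distance of a male from all other males of its cohort
#'
#' d' = (d1 + d2 + ... + d(n-1)) / (n - 1), the arithmetic mean of the
#' distances from the focal male to each of the other n-1 males in the
#' cohort. Males captured in the same bush contribute distance 0 (capture
#' locations are coarsened to bush centroids).
#'
#' @param focal_id focal male id
#' @param cohort_bush named integer vector: bush id per male of the cohort
#'   (names are male ids), including the focal
#' @param dmat bush distance matrix from [bush_distance_matrix()]
#' @return list of class `average_distance`: `id`, `d_prime`, `n` (cohort
#'   male count), `components` (named distances to the other males)
#' @export
average_distance <- function(focal_id, cohort_bush, dmat) {
  if (!focal_id %in% names(cohort_bush)) stop("focal male not in cohort")
  n <- length(cohort_bush)
  if (n < 2) {
    return(structure(list(id = focal_id, d_prime = NA_real_, n = n,
                          components = numeric(0), flagged = TRUE),
                     class = "average_distance"))
  }
  others <- setdiff(names(cohort_bush), focal_id)
  fb <- as.character(cohort_bush[[focal_id]])
  comp <- vapply(others, function(o) dmat[fb, as.character(cohort_bush[[o]])],
                 numeric(1))
  structure(list(id = focal_id, d_prime = sum(comp) / (n - 1), n = n,
                 components = comp, flagged = FALSE),
            class = "average_distance")
}
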