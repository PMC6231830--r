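# Spatial exposure statistics: Clark-Evans nearest-neighbour index and
# settlement typology, sector waste density, household hazard proximity,
# built-up concentration and road density.

#' Clark-Evans nearest-neighbour index
#'
#' Computes the ratio of the observed mean nearest-neighbour distance to its
#' expectation under complete spatial randomness, `0.5 / sqrt(n / area)`.
#' Values below 1 indicate clustering, 1 randomness, above 1 regularity
#' (a perfect square lattice reaches 2). No edge correction is applied,
#' matching the basic Clark-Evans form.
#'
#' @param points Two-column matrix (x, y) of point coordinates in metres.
#' @param area Study area in square metres; required when
#'   `area_method = "provided"`.
#' @param area_method How to obtain the area: `"provided"`, `"convex_hull"`
#'   of the points, or `"bounding_box"`. Defaults to the convex hull when
#'   `area` is missing.
#' @return An object of class `nni_result`: list with `n`, `area`, `d_obs`,
#'   `d_exp`, `nni` and `typology` (see [classify_settlement()]).
#' @examples
#' pts <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
#' nearest_neighbor_index(pts, area = 1)$nni   # 4
#' @export
nearest_neighbor_index <- function(points, area = NULL,
                                   area_method = c("provided", "convex_hull",
                                                   "bounding_box")) {
  points <- as.matrix(points)
  if (nrow(points) < 2)
    stop("nearest-neighbour index undefined for fewer than 2 points",
         call. = FALSE)
  if (is.null(area)) {
    area_method <- if (missing(area_method)) "convex_hull"
                   else match.arg(area_method)
  } else area_method <- match.arg(area_method)
  area <- switch(area_method,
    provided = {
      if (is.null(area)) stop("area must be supplied", call. = FALSE)
      area
    },
    convex_hull = polygon_area(convex_hull(points)),
    bounding_box = diff(range(points[, 1])) * diff(range(points[, 2])))
  if (!is.finite(area) || area <= 0)
    stop("study area must be positive", call. = FALSE)
  d_obs <- mean(nn_distances(points))
  d_exp <- 0.5 / sqrt(nrow(points) / area)
  nni <- d_obs / d_exp
  structure(list(n = nrow(points), area = area, d_obs = d_obs,
                 d_exp = d_exp, nni = nni,
                 typology = classify_settlement(nni)),
            class = "nni_result")
}

#' @export
print.nni_result <- function(x, ...) {
  cat(sprintf("NNI %.3f (n=%d, d_obs=%.2f m, d_exp=%.2f m): %s\n",
              x$nni, x$n, x$d_obs, x$d_exp, x$typology))
  invisible(x)
}

#' Classify settlement typology from the nearest-neighbour index
#'
#' The index is rounded half-up to one decimal before classing (the
#' granularity of the reporting table, which leaves gaps between 0.5-0.6 and
#' 0.9-1.0 otherwise): rounded values at or below 0.5 are highly clustered,
#' 0.6-0.9 clustered, exactly 1.0 random, above 1.0 regular.
#'
#' @param nni Non-negative numeric vector of index values.
#' @return Character vector in `{highly_clustered, clustered, random,
#'   regular}`.
#' @export
classify_settlement <- function(nni) {
  if (any(nni < 0)) stop("nni must be non-negative", call. = FALSE)
  r <- round_half_up(nni, 1L)
  out <- ifelse(r <= 0.5, "highly_clustered",
         ifelse(r <= 0.9, "clustered",
         ifelse(r == 1.0, "random", "regular")))
  out
}

#' Sector waste density per 100 residents
#'
#' Number of qualifying waste spots (solid mounds or liquid puddles with
#' diameter at or above the threshold) in a sector per 100 residents.
#'
#' @param spot_diameters Diameters (m) of the spots lying in the sector.
#' @param population Number of residents of the sector; must be positive.
#' @param threshold Qualifying diameter in metres (default 1.0, inclusive).
#' @return Spots per 100 residents.
#' @export
sector_waste_density <- function(spot_diameters, population,
                                 threshold = 1.0) {
  if (is.na(population) || population <= 0)
    stop("waste density undefined for sectors without residents",
         call. = FALSE)
  100 * sum(spot_diameters >= threshold) / population
}

#' Distance from each household to the nearest qualifying waste spot
#'
#' Planar Euclidean distance from each household location to the nearest
#' solid mound or liquid puddle with diameter at or above the threshold,
#' whichever is nearer, searched across the whole site (not restricted to
#' the household's own sector). Uses a uniform-grid spatial index whose
#' result is exactly the brute-force scan.
#'
#' @param households Data frame with `x`, `y` columns (household locations).
#' @param spots Data frame with `x`, `y`, `diameter` columns.
#' @param threshold Qualifying diameter in metres (default 1.0, inclusive).
#' @return Numeric vector of distances (m), one per household.
#' @export
nearest_waste_distance <- function(households, spots, threshold = 1.0) {
  q <- spots[spots$diameter >= threshold, , drop = FALSE]
  if (nrow(q) == 0)
    stop("no qualifying waste spots at threshold ", threshold, call. = FALSE)
  if (nrow(households) == 0) return(numeric(0))
  idx <- point_grid_index(cbind(q$x, q$y))
  query_nearest_point(idx, households$x, households$y)$distance
}

#' Built-up concentration of a site
#'
#' Delineates, per village, the core built-up region as a hull of the
#' constructed (residential, nonresidential, mixed) parcel centroids and
#' reports the summed core area, its share of the total site area, and the
#' share of constructed parcels whose centroid falls inside a core.
#'
#' @param site An `hdss_site` with `total_area_ha` set.
#' @param hull_method `"convex"` (default) or `"grid"`: the grid method
#'   unions occupied square cells of side `cell_m` holding at least
#'   `min_parcels` centroids, giving a concave core that can exclude
#'   outlying parcels.
#' @param cell_m,min_parcels Grid-method tuning parameters.
#' @return List via [concentration_report()]: `core_area_ha`,
#'   `core_area_share_pct`, `parcels_in_core`, `total_parcels`,
#'   `parcels_in_core_share_pct`.
#' @export
builtup_concentration <- function(site, hull_method = c("convex", "grid"),
                                  cell_m = 50, min_parcels = 1L) {
  hull_method <- match.arg(hull_method)
  p <- site$parcels
  built <- p[p$use_class %in% c("residential", "nonresidential", "mixed"), ]
  if (nrow(built) == 0) stop("no constructed parcels", call. = FALSE)
  core_area_m2 <- 0
  in_core <- 0L
  for (vc in unique(built$village_code)) {
    b <- built[built$village_code == vc, ]
    pts <- cbind(b$x, b$y)
    if (nrow(b) < 3) {
      core_area_m2 <- core_area_m2 + sum(b$area_m2)
      in_core <- in_core + nrow(b)
    } else if (hull_method == "convex") {
      hull <- convex_hull(pts)
      core_area_m2 <- core_area_m2 + polygon_area(hull)
      inside <- points_in_polygon(pts, hull)
      # hull vertices are on the boundary, which counts as in-core
      on_hull <- seq_len(nrow(pts)) %in% chull(pts)
      in_core <- in_core + sum(inside | on_hull)
    } else {
      cx <- floor(pts[, 1] / cell_m); cy <- floor(pts[, 2] / cell_m)
      key <- paste(cx, cy)
      occ <- table(key)
      core_cells <- names(occ)[occ >= min_parcels]
      core_area_m2 <- core_area_m2 + length(core_cells) * cell_m^2
      in_core <- in_core + sum(key %in% core_cells)
    }
  }
  concentration_report(core_area_m2 / 1e4, site$total_area_ha,
                       in_core, nrow(built))
}

#' Concentration shares from core/total areas and parcel counts
#'
#' The reporting arithmetic behind [builtup_concentration()], exposed so
#' that externally tabulated areas and counts can be summarised the same
#' way: shares are half-up percentages via [ratio_report()].
#'
#' @param core_area_ha,total_area_ha Core and total areas in hectares.
#' @param parcels_in_core,total_parcels Constructed-parcel counts.
#' @return List with the areas, counts and percentage shares
#'   (`core_area_share_pct` at 2 decimals, `parcels_in_core_share_pct` at 2).
#' @export
concentration_report <- function(core_area_ha, total_area_ha,
                                 parcels_in_core, total_parcels) {
  list(core_area_ha = core_area_ha, total_area_ha = total_area_ha,
       core_area_share_pct = ratio_report(core_area_ha, total_area_ha, 2L),
       parcels_in_core = parcels_in_core, total_parcels = total_parcels,
       parcels_in_core_share_pct = ratio_report(parcels_in_core,
                                                total_parcels, 2L))
}

#' Road density
#'
#' Total road length divided by surface area, optionally restricted to a
#' subset of road typologies.
#'
#' @param roads Road layer data frame with `length_m` and `typology`.
#' @param area_km2 Surface area in square kilometres.
#' @param typologies Optional character vector of typologies to include.
#' @return Kilometres of road per square kilometre.
#' @export
road_density <- function(roads, area_km2, typologies = NULL) {
  if (area_km2 <= 0) stop("area must be positive", call. = FALSE)
  if (!is.null(typologies))
    roads <- roads[roads$typology %in% typologies, , drop = FALSE]
  sum(roads$length_m) / 1000 / area_km2
}
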