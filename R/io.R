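# Round half-up at k decimals. base::round() rounds half to even, which does
# not match the reporting convention used for published percentages.
round_half_up <- function(x, k = 0L) {
  p <- 10^k
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Report a ratio as a half-up-rounded percentage
#'
#' The percentage convention used throughout the site reports: `100 *
#' numerator / denominator`, rounded half-up at the requested number of
#' decimals (so 61.85 prints as 61.9, not 61.8).
#'
#' @param numerator Count (or real) numerator.
#' @param denominator Positive count or real denominator.
#' @param decimals Number of decimals kept, between 0 and 4.
#' @return Numeric percentage.
#' @examples
#' ratio_report(418, 676, 1)   # 61.8
#' @export
ratio_report <- function(numerator, denominator, decimals = 1L) {
  if (any(denominator <= 0)) stop("denominator must be > 0", call. = FALSE)
  if (decimals < 0 || decimals > 4)
    stop("decimals must be in [0, 4]", call. = FALSE)
  round_half_up(100 * numerator / denominator, decimals)
}

# --- GeoJSON helpers (hand-rolled on jsonlite: coordinates are written at
# micro-metre precision so write -> read -> write is byte-identical) ---

fmt_coord <- function(x) as.numeric(formatC(x, format = "f", digits = 6))

geojson_feature <- function(geom_type, coords, props) {
  list(type = "Feature",
       geometry = list(type = geom_type, coordinates = coords),
       properties = props)
}

poly_coords <- function(mat) {
  mat <- rbind(mat, mat[1, , drop = FALSE])   # close the ring
  list(lapply(seq_len(nrow(mat)), function(i) fmt_coord(mat[i, ])))
}

line_coords <- function(mat)
  lapply(seq_len(nrow(mat)), function(i) fmt_coord(mat[i, ]))

write_geojson <- function(features, path, crs_note) {
  fc <- list(type = "FeatureCollection", crs_note = crs_note,
             features = features)
  json <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path, useBytes = TRUE)
}

read_geojson <- function(path) {
  if (!file.exists(path)) stop("missing layer file: ", path, call. = FALSE)
  fc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) stop("malformed GeoJSON in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a FeatureCollection: ", path, call. = FALSE)
  fc
}

ring_to_matrix <- function(ring) {
  m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  m[-nrow(m), , drop = FALSE]                 # drop closing vertex
}

#' Write a site to a directory of GeoJSON and CSV layers
#'
#' Writes `parcels.geojson`, `sectors.geojson`, `waste_spots.geojson`,
#' `roads.geojson`, `water_bodies.geojson`, `households.csv`,
#' `individuals.csv`, `villages.csv`, `site.json` and, for synthetic sites,
#' `manifest.json` with the true generator parameters. Output is
#' deterministic: writing the same site twice gives byte-identical files.
#'
#' @param site An `hdss_site`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_site <- function(site, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  crs <- site$crs_note

  p <- site$parcels
  feats <- lapply(seq_len(nrow(p)), function(i) geojson_feature(
    "Polygon", poly_coords(p$geometry[[i]]),
    list(uid = p$uid[i], village_code = p$village_code[i],
         sector_num = p$sector_num[i], sector_code = p$sector_code[i],
         parcel_seq = p$parcel_seq[i], use_class = p$use_class[i],
         landuse_level1 = p$landuse_level1[i],
         landuse_level2 = p$landuse_level2[i],
         landuse_level3 = p$landuse_level3[i],
         x = fmt_coord(p$x[i]), y = fmt_coord(p$y[i]),
         area_m2 = fmt_coord(p$area_m2[i]))))
  write_geojson(feats, file.path(dir, "parcels.geojson"), crs)

  s <- site$sectors
  feats <- lapply(seq_len(nrow(s)), function(i) geojson_feature(
    "Polygon", poly_coords(s$boundary[[i]]),
    list(village_code = s$village_code[i], sector_code = s$sector_code[i],
         sector_num = s$sector_num[i], area_ha = fmt_coord(s$area_ha[i]),
         population = s$population[i])))
  write_geojson(feats, file.path(dir, "sectors.geojson"), crs)

  w <- site$waste_spots
  feats <- lapply(seq_len(nrow(w)), function(i) geojson_feature(
    "Point", fmt_coord(c(w$x[i], w$y[i])),
    list(spot_id = w$spot_id[i], kind = w$kind[i],
         diameter = fmt_coord(w$diameter[i]),
         village_code = w$village_code[i], sector_num = w$sector_num[i],
         sector_code = w$sector_code[i])))
  write_geojson(feats, file.path(dir, "waste_spots.geojson"), crs)

  r <- site$roads
  feats <- lapply(seq_len(nrow(r)), function(i) geojson_feature(
    "LineString", line_coords(r$geometry[[i]]),
    list(road_id = r$road_id[i], village_code = r$village_code[i],
         typology = r$typology[i], surface = r$surface[i],
         quality = r$quality[i], length_m = fmt_coord(r$length_m[i]))))
  write_geojson(feats, file.path(dir, "roads.geojson"), crs)

  wb <- site$water_bodies
  feats <- lapply(seq_len(nrow(wb)), function(i) geojson_feature(
    "Polygon", poly_coords(wb$geometry[[i]]),
    list(body_id = wb$body_id[i], village_code = wb$village_code[i],
         kind = wb$kind[i], area_m2 = fmt_coord(wb$area_m2[i]))))
  write_geojson(feats, file.path(dir, "water_bodies.geojson"), crs)

  hh <- site$households
  hh$x <- fmt_coord(hh$x); hh$y <- fmt_coord(hh$y)
  write.csv(hh, file.path(dir, "households.csv"), row.names = FALSE)
  write.csv(site$individuals, file.path(dir, "individuals.csv"),
            row.names = FALSE)
  write.csv(site$villages, file.path(dir, "villages.csv"), row.names = FALSE)

  meta <- list(crs_note = crs, total_area_ha = site$total_area_ha)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "site.json"), useBytes = TRUE)
  if (!is.null(site$manifest))
    writeLines(jsonlite::toJSON(site$manifest, auto_unbox = TRUE, digits = NA),
               file.path(dir, "manifest.json"), useBytes = TRUE)
  invisible(dir)
}

#' Read a site from a directory written by [write_site()]
#'
#' @param dir Directory holding the layer files.
#' @return An `hdss_site`. Geometry survives the round trip to within
#'   1e-6 m; `write_site(read_site(d))` is byte-identical to the original.
#' @export
read_site <- function(dir) {
  prop <- function(f, nm, default = NA) {
    v <- f$properties[[nm]]
    if (is.null(v)) default else v
  }
  fc <- read_geojson(file.path(dir, "parcels.geojson"))
  parcels <- do.call(rbind, lapply(fc$features, function(f) data.frame(
    uid = prop(f, "uid"), village_code = as.integer(prop(f, "village_code")),
    sector_num = as.integer(prop(f, "sector_num")),
    sector_code = prop(f, "sector_code"),
    parcel_seq = as.integer(prop(f, "parcel_seq")),
    use_class = prop(f, "use_class"),
    landuse_level1 = prop(f, "landuse_level1"),
    landuse_level2 = prop(f, "landuse_level2"),
    landuse_level3 = prop(f, "landuse_level3"),
    x = as.numeric(prop(f, "x")), y = as.numeric(prop(f, "y")),
    area_m2 = as.numeric(prop(f, "area_m2")))))
  if (is.null(parcels)) parcels <- data.frame()
  else parcels$geometry <- lapply(fc$features, function(f)
    ring_to_matrix(f$geometry$coordinates[[1]]))

  fc <- read_geojson(file.path(dir, "sectors.geojson"))
  sectors <- do.call(rbind, lapply(fc$features, function(f) data.frame(
    village_code = as.integer(prop(f, "village_code")),
    sector_code = prop(f, "sector_code"),
    sector_num = as.integer(prop(f, "sector_num")),
    area_ha = as.numeric(prop(f, "area_ha")),
    population = as.integer(prop(f, "population")))))
  if (is.null(sectors)) sectors <- data.frame()
  else sectors$boundary <- lapply(fc$features, function(f)
    ring_to_matrix(f$geometry$coordinates[[1]]))

  fc <- read_geojson(file.path(dir, "waste_spots.geojson"))
  waste <- if (length(fc$features)) do.call(rbind, lapply(fc$features,
    function(f) data.frame(
      spot_id = prop(f, "spot_id"), kind = prop(f, "kind"),
      x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]],
      diameter = as.numeric(prop(f, "diameter")),
      village_code = as.integer(prop(f, "village_code")),
      sector_num = as.integer(prop(f, "sector_num")),
      sector_code = prop(f, "sector_code")))) else empty_waste_spots()

  fc <- read_geojson(file.path(dir, "roads.geojson"))
  roads <- if (length(fc$features)) {
    r <- do.call(rbind, lapply(fc$features, function(f) data.frame(
      road_id = prop(f, "road_id"),
      village_code = as.integer(prop(f, "village_code")),
      typology = prop(f, "typology"), surface = prop(f, "surface"),
      quality = prop(f, "quality"),
      length_m = as.numeric(prop(f, "length_m")))))
    r$geometry <- lapply(fc$features, function(f)
      do.call(rbind, lapply(f$geometry$coordinates,
                            function(p) c(p[[1]], p[[2]]))))
    r
  } else empty_roads()

  fc_wb <- read_geojson(file.path(dir, "water_bodies.geojson"))
  water <- if (length(fc_wb$features)) {
    wb <- do.call(rbind, lapply(fc_wb$features, function(f) data.frame(
      body_id = prop(f, "body_id"),
      village_code = as.integer(prop(f, "village_code")),
      kind = prop(f, "kind"), area_m2 = as.numeric(prop(f, "area_m2")))))
    wb$geometry <- lapply(fc_wb$features, function(f)
      ring_to_matrix(f$geometry$coordinates[[1]]))
    wb
  } else empty_water_bodies()

  hh_path <- file.path(dir, "households.csv")
  if (!file.exists(hh_path)) stop("missing layer file: ", hh_path,
                                  call. = FALSE)
  households <- read.csv(hh_path, colClasses = c(household_id = "character",
                                                 parcel_uid = "character"))
  if (nrow(households) == 0) households <- empty_households()
  individuals <- read.csv(file.path(dir, "individuals.csv"),
                          colClasses = c(uid = "character",
                                         household_id = "character"))
  if (nrow(individuals) == 0) individuals <- empty_individuals()
  villages <- read.csv(file.path(dir, "villages.csv"))
  meta <- jsonlite::fromJSON(file.path(dir, "site.json"))
  manifest <- if (file.exists(file.path(dir, "manifest.json")))
    jsonlite::fromJSON(file.path(dir, "manifest.json")) else NULL

  new_site(villages, sectors, parcels, households, individuals, waste,
           roads, water, crs_note = meta$crs_note,
           total_area_ha = meta$total_area_ha, manifest = manifest)
}

#' Summarise a site's constructs
#'
#' Tabulates parcel counts by use class (with totals), waste spots by kind,
#' road lengths by typology and water bodies by kind, each with the number
#' of villages possessing the feature — the standard site-description table.
#'
#' @param site An `hdss_site`.
#' @return A list of class `site_summary` with elements `parcels_by_class`,
#'   `total_parcels`, `features` (feature type, count, villages possessing)
#'   and `n_villages`.
#' @export
summarize_site <- function(site) {
  p <- site$parcels
  by_class <- as.list(table(factor(p$use_class, levels = USE_CLASSES)))
  feats <- list()
  add <- function(domain, type, n, villages) feats[[length(feats) + 1L]] <<-
    data.frame(domain = domain, feature = type, n = n,
               villages = villages)
  if (nrow(p)) for (uc in USE_CLASSES) {
    sub <- p[p$use_class == uc, ]
    if (nrow(sub)) add("physical", paste0("parcel_", uc), nrow(sub),
                       length(unique(sub$village_code)))
  }
  w <- site$waste_spots
  if (nrow(w)) for (k in unique(w$kind))
    add("physical", paste0("waste_", k), sum(w$kind == k),
        length(unique(w$village_code[w$kind == k])))
  r <- site$roads
  if (nrow(r)) for (ty in unique(r$typology))
    add("social", paste0("road_", ty),
        round(sum(r$length_m[r$typology == ty]) / 1000, 1),
        length(unique(r$village_code[r$typology == ty])))
  wb <- site$water_bodies
  if (nrow(wb)) for (k in unique(wb$kind))
    add("physical", paste0("water_", k), sum(wb$kind == k),
        length(unique(wb$village_code[wb$kind == k])))
  structure(list(parcels_by_class = by_class, total_parcels = nrow(p),
                 features = if (length(feats)) do.call(rbind, feats)
                            else data.frame(),
                 n_villages = nrow(site$villages)),
            class = "site_summary")
}

#' @export
print.site_summary <- function(x, ...) {
  cat("site summary:", x$n_villages, "villages,", x$total_parcels,
      "parcels\n")
  cc <- x$parcels_by_class
  for (nm in names(cc)) if (cc[[nm]] > 0)
    cat(sprintf("  %-15s %6d (%.2f%%)\n", nm, cc[[nm]],
                ratio_report(cc[[nm]], x$total_parcels, 2)))
  invisible(x)
}
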