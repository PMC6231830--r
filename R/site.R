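# Site container: a list of plain data frames, one per layer, mirroring the
# GeoJSON/CSV layers on disk. Geometry list-columns hold two-column coordinate
# matrices in planar metres.

USE_CLASSES <- c("residential", "nonresidential", "mixed", "vacant", "ruined")
CASTE_CLASSES <- c("General", "OBC", "SCST")
SES_CLASSES <- c("rich", "middle", "poor")
PATTERNS <- c("clustered", "linear", "circular", "regular")

#' Construct a surveillance-site object
#'
#' Bundles the layers of a georeferenced surveillance site: villages,
#' sectors, land parcels, households, individuals, waste spots and roads.
#' Every parcel belongs to exactly one sector of exactly one village; the
#' 19-digit parcel identifier encodes that hierarchy.
#'
#' @param villages Data frame with columns `village_code` (integer), `name`,
#'   `pattern` (settlement pattern), `size_class` (`"large"` > 1000 parcels,
#'   `"small"` otherwise) and `n_parcels`.
#' @param sectors Data frame with `village_code`, `sector_code` (alphabetic
#'   label), `sector_num` (numeric code used inside the parcel identifier),
#'   `area_ha`, `population` and a `boundary` list-column of coordinate
#'   matrices.
#' @param parcels Data frame with `uid`, `village_code`, `sector_num`,
#'   `sector_code`, `parcel_seq`, `use_class`, `landuse_level1..3`, centroid
#'   `x`, `y`, `area_m2` and a `geometry` list-column.
#' @param households,individuals,waste_spots,roads,water_bodies Layer data
#'   frames; empty prototypes are used when omitted.
#' @param crs_note Free-text declaration that coordinates are planar metres.
#' @param total_area_ha Total site area in hectares.
#' @param manifest Optional list of true generator parameters (synthetic
#'   sites record the structural model they were drawn from).
#' @return An object of class `hdss_site`.
#' @export
new_site <- function(villages, sectors, parcels,
                     households = empty_households(),
                     individuals = empty_individuals(),
                     waste_spots = empty_waste_spots(),
                     roads = empty_roads(),
                     water_bodies = empty_water_bodies(),
                     crs_note = "planar metres (local projected grid)",
                     total_area_ha = NA_real_, manifest = NULL) {
  structure(list(villages = villages, sectors = sectors, parcels = parcels,
                 households = households, individuals = individuals,
                 waste_spots = waste_spots, roads = roads,
                 water_bodies = water_bodies, crs_note = crs_note,
                 total_area_ha = total_area_ha, manifest = manifest),
            class = "hdss_site")
}

empty_households <- function() {
  data.frame(household_id = character(), parcel_uid = character(),
             village_code = integer(), sector_num = integer(),
             sector_code = character(), caste = character(),
             ses = character(), n_members = integer(),
             water_source = character(), toilet = logical(),
             liquid_disposal = character(), solid_disposal = character(),
             x = numeric(), y = numeric())
}

empty_individuals <- function() {
  data.frame(uid = character(), household_id = character(),
             age = numeric(), sex = character())
}

empty_waste_spots <- function() {
  data.frame(spot_id = character(), kind = character(), x = numeric(),
             y = numeric(), diameter = numeric(),
             village_code = integer(), sector_num = integer(),
             sector_code = character())
}

empty_roads <- function() {
  out <- data.frame(road_id = character(), village_code = integer(),
                    typology = character(), surface = character(),
                    quality = character(), length_m = numeric())
  out$geometry <- list()
  out
}

empty_water_bodies <- function() {
  out <- data.frame(body_id = character(), village_code = integer(),
                    kind = character(), area_m2 = numeric())
  out$geometry <- list()
  out
}

#' @export
print.hdss_site <- function(x, ...) {
  cat("<hdss_site>", nrow(x$villages), "villages,", nrow(x$sectors),
      "sectors,", nrow(x$parcels), "parcels,", nrow(x$households),
      "households,", nrow(x$waste_spots), "waste spots\n")
  invisible(x)
}

# Alphabetic sector labels: A..Z, AA, AB, ...
sector_alpha <- function(i) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]; s <- ""
    while (n > 0) {
      r <- (n - 1L) %% 26L
      s <- paste0(LETTERS[r + 1L], s)
      n <- (n - 1L) %/% 26L
    }
    out[k] <- s
  }
  out
}

#' Validate the structural integrity of a site
#'
#' Report-only audit of the container invariants: unique village codes,
#' unique parcel identifiers, identifier/hierarchy consistency, every parcel
#' in exactly one sector, households attached to residential or mixed
#' parcels, 9-digit individual identifiers, positive waste-spot diameters,
#' sector populations equal to the sum of member household sizes, and
#' conservation of parcel counts across use classes.
#'
#' @param site An `hdss_site` object.
#' @return An object of class `site_validation`: a data frame of violations
#'   (zero rows when the site is well formed) with the use-class count table
#'   attached as attribute `use_class_counts`.
#' @export
validate_site <- function(site) {
  v <- list()
  note <- function(check, msg) v[[length(v) + 1L]] <<- data.frame(
    check = check, message = msg)

  if (anyDuplicated(site$villages$village_code))
    note("village_codes_unique", "duplicated village codes")
  sec_key <- paste(site$sectors$village_code, site$sectors$sector_num)
  if (anyDuplicated(sec_key))
    note("sector_codes_unique", "duplicated sector within village")

  p <- site$parcels
  if (nrow(p)) {
    dup <- duplicated(p$uid)
    if (any(dup))
      note("parcel_uid_unique", paste("parcel uid assigned more than once:",
           paste(utils::head(unique(p$uid[dup]), 3), collapse = ", ")))
    parsed <- tryCatch(parse_parcel_uid(p$uid), error = function(e) NULL)
    if (is.null(parsed)) {
      note("uid_parses", "one or more parcel uids are malformed")
    } else {
      bad <- parsed$village != p$village_code | parsed$sector != p$sector_num |
        parsed$parcel != p$parcel_seq
      if (any(bad))
        note("uid_hierarchy", paste0(sum(bad),
             " parcel uid(s) disagree with their hierarchy columns"))
    }
    if (!all(p$use_class %in% USE_CLASSES))
      note("use_class_valid", "unknown parcel use class")
    orphan <- !(paste(p$village_code, p$sector_num) %in% sec_key)
    if (any(orphan))
      note("parcel_sector_exists", paste0(sum(orphan),
           " parcel(s) reference a sector that does not exist"))
    zero <- p$area_m2 <= 0 & p$use_class != "vacant"
    if (any(zero))
      note("parcel_area_positive", paste0(sum(zero),
           " non-vacant parcel(s) with non-positive area"))
  }

  hh <- site$households
  if (nrow(hh)) {
    miss <- !(hh$parcel_uid %in% p$uid)
    if (any(miss))
      note("household_parcel_exists", paste0(sum(miss),
           " household(s) on unknown parcels"))
    uc <- p$use_class[match(hh$parcel_uid, p$uid)]
    badc <- !is.na(uc) & !(uc %in% c("residential", "mixed"))
    if (any(badc))
      note("household_parcel_class", paste0(sum(badc),
           " household(s) on non-residential, non-mixed parcels"))
    pop <- tapply(hh$n_members, paste(hh$village_code, hh$sector_num), sum)
    declared <- site$sectors$population[match(names(pop), sec_key)]
    off <- !is.na(declared) & declared != as.integer(pop)
    if (any(off))
      note("sector_population", paste0(sum(off),
           " sector(s) with population != sum of household sizes"))
  }

  ind <- site$individuals
  if (nrow(ind)) {
    if (!all(grepl("^[0-9]{9}$", ind$uid)))
      note("individual_uid_format", "individual uid not 9 digits")
    if (anyDuplicated(ind$uid))
      note("individual_uid_unique", "duplicated individual uid")
  }

  if (nrow(site$waste_spots) && any(site$waste_spots$diameter <= 0))
    note("waste_diameter_positive", "waste spot with non-positive diameter")

  out <- if (length(v)) do.call(rbind, v) else
    data.frame(check = character(), message = character())
  counts <- table(factor(p$use_class, levels = USE_CLASSES))
  attr(out, "use_class_counts") <- c(as.list(counts), total = nrow(p))
  class(out) <- c("site_validation", class(out))
  out
}

#' @export
print.site_validation <- function(x, ...) {
  if (nrow(x) == 0) cat("site valid: no violations\n")
  else { cat(nrow(x), "violation(s):\n"); print.data.frame(x) }
  cc <- attr(x, "use_class_counts")
  cat("parcels by use class:",
      paste(names(cc), unlist(cc), sep = "=", collapse = " "), "\n")
  invisible(x)
}
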