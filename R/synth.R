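# Synthetic settlement generator. Produces sites with the morphological and
# social structure the exposure analysis assumes, under a known structural
# model (recorded in the site manifest) so downstream estimators can be
# validated by parameter recovery.

#' Configuration for the synthetic-site generator
#'
#' Defaults encode the study conditions of a large rural surveillance site:
#' 51 villages whose parcel counts follow a wide lognormal (median ~590,
#' mean ~900, clamped to 25-3279); a settlement-pattern mix dominated by
#' clustered morphology with linear and circular variants and a rare regular
#' village; use-class mix 56.08/38.54/5.38% residential/nonresidential/
#' mixed; sector-level caste segregation via a Dirichlet profile with low
#' concentration (strong segregation); an ordinal caste-to-SES link; and a
#' sector-level log-linear waste intensity
#' `exp(gamma0 + gamma1 * lowSES_share + gamma2 * SCST_share)` spots per
#' hectare.
#'
#' @param n_villages Number of villages.
#' @param village_size Lognormal parcel-count parameters
#'   (`meanlog`, `sdlog`, `min`, `max`).
#' @param pattern_mix Named probabilities over
#'   `clustered`/`linear`/`circular`/`regular`.
#' @param cluster_process Thomas-process parameters for clustered villages:
#'   `parents_per_150` parents per 150 parcels and offspring spread
#'   `sigma` (m).
#' @param parcel_side Side (m) of the square parcel cells.
#' @param sector_tiling Target and maximum core-sector parcel counts and
#'   maximum outer-sector count.
#' @param use_mix Probabilities over parcel use classes.
#' @param caste_site_shares Site-level caste composition (General, OBC,
#'   SC/ST).
#' @param caste_segregation Dirichlet concentration of sector caste
#'   profiles: small values give segregated (dominance-prone) sectors,
#'   `Inf` makes every sector equal to the site shares.
#' @param ses_given_caste Ordinal-logit shift per caste toward poorer SES
#'   (General is reference) plus the two cutpoints.
#' @param covariate_model Logistic coefficients linking SES rank (1 rich -
#'   3 poor) to water source, toilet, liquid and solid disposal.
#' @param households_extra Poisson mean of extra households per residential
#'   or mixed parcel (each gets `1 + Poisson(households_extra)`).
#' @param household_size_extra Poisson mean of household members beyond the
#'   first.
#' @param waste_model Log-linear intensity coefficients `gamma0` (log
#'   baseline spots/ha), `gamma1` (low-SES-share effect), `gamma2`
#'   (SC/ST-share effect), lognormal diameter parameters and the solid-spot
#'   fraction.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(
    n_villages = 51L,
    village_size = list(meanlog = log(587), sdlog = 0.95,
                        min = 25L, max = 3279L),
    pattern_mix = c(clustered = 0.58, linear = 0.20, circular = 0.20,
                    regular = 0.02),
    cluster_process = list(parents_per_150 = 1, sigma = 10),
    parcel_side = 15,
    sector_tiling = list(core_target = 70L, core_max = 500L,
                         outer_max = 50L),
    use_mix = c(residential = 0.5608, nonresidential = 0.3854,
                mixed = 0.0538, vacant = 0, ruined = 0),
    caste_site_shares = c(General = 0.35, OBC = 0.45, SCST = 0.20),
    caste_segregation = 5,
    ses_given_caste = list(shift = c(General = 0, OBC = 0.7, SCST = 1.3),
                           cutpoints = c(-0.3, 1.2)),
    ses_sector_sd = 0.8,
    covariate_model = list(water_inside = c(1.2, -0.8),
                           toilet = c(1.5, -0.9),
                           liquid_drain = c(0.8, -0.7),
                           solid_collected = c(0.2, -0.5)),
    households_extra = 0.2,
    household_size_extra = 5.1,
    waste_model = list(gamma0 = log(15), gamma1 = 0.6, gamma2 = 0.9,
                       diameter_meanlog = 0.3146, diameter_sdlog = 0.6,
                       p_solid = 0.14)) {
  pattern_mix <- pattern_mix / sum(pattern_mix)
  use_mix <- use_mix / sum(use_mix)
  stopifnot(all(names(pattern_mix) %in% PATTERNS),
            abs(sum(caste_site_shares) - 1) < 1e-8 ||
              sum(caste_site_shares) > 0,
            cluster_process$sigma > 0,
            all(is.finite(unlist(waste_model[c("gamma1", "gamma2")]))))
  caste_site_shares <- caste_site_shares / sum(caste_site_shares)
  structure(as.list(environment()), class = "synth_config")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(length(alpha), 1)] <- 1
  g / sum(g)
}

#' Generate parcel centroids under a settlement pattern
#'
#' Realises each settlement-typology class as a planar point process inside
#' a rectangular frame: `clustered` is a Thomas-style parent/offspring
#' process (Gaussian offspring around uniform parents), `regular` a
#' (optionally jittered) square lattice, `linear` an elongated band,
#' `circular` an annular band. Exactly `n` points inside the frame are
#' returned.
#'
#' @param pattern One of `"clustered"`, `"linear"`, `"circular"`,
#'   `"regular"`.
#' @param n Number of points (>= 2).
#' @param frame Numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @param params Pattern parameters: `n_parents` and `sigma` (clustered),
#'   `spacing` and `jitter` (regular), `band_width` (linear),
#'   `ring_width` (circular).
#' @return An `n` x 2 coordinate matrix.
#' @export
generate_parcel_centroids <- function(pattern, n, frame, params = list()) {
  pattern <- match.arg(pattern, PATTERNS)
  n <- as.integer(n)
  if (n < 2) stop("need at least 2 points (index undefined below that)",
                  call. = FALSE)
  xr <- frame[1:2]; yr <- frame[3:4]
  if (diff(xr) <= 0 || diff(yr) <= 0) stop("frame has no area", call. = FALSE)
  inside <- function(p) p[, 1] >= xr[1] & p[, 1] <= xr[2] &
    p[, 2] >= yr[1] & p[, 2] <= yr[2]
  collect <- function(draw) {
    pts <- matrix(numeric(0), 0, 2)
    while (nrow(pts) < n) {
      cand <- draw(max(2L * (n - nrow(pts)), 32L))
      pts <- rbind(pts, cand[inside(cand), , drop = FALSE])
    }
    pts[seq_len(n), , drop = FALSE]
  }
  switch(pattern,
    clustered = {
      k <- params$n_parents %||% max(3L, round(n / 150))
      sigma <- params$sigma %||% 10
      px <- runif(k, xr[1] + 0.15 * diff(xr), xr[2] - 0.15 * diff(xr))
      py <- runif(k, yr[1] + 0.15 * diff(yr), yr[2] - 0.15 * diff(yr))
      collect(function(m) {
        j <- sample.int(k, m, replace = TRUE)
        cbind(px[j] + rnorm(m, 0, sigma), py[j] + rnorm(m, 0, sigma))
      })
    },
    linear = {
      bw <- params$band_width %||% 40
      ymid <- mean(yr)
      collect(function(m) cbind(runif(m, xr[1], xr[2]),
                                ymid + rnorm(m, 0, bw / 2)))
    },
    circular = {
      r0 <- params$radius %||% (0.35 * min(diff(xr), diff(yr)))
      rw <- params$ring_width %||% 30
      cx <- mean(xr); cy <- mean(yr)
      collect(function(m) {
        th <- runif(m, 0, 2 * pi)
        r <- r0 + rnorm(m, 0, rw / 2)
        cbind(cx + r * cos(th), cy + r * sin(th))
      })
    },
    regular = {
      s <- params$spacing %||% sqrt(diff(xr) * diff(yr) / n)
      jit <- params$jitter %||% (0.15 * s)
      nx <- max(1L, floor(diff(xr) / s))
      gx <- xr[1] + s / 2 + s * (0:(nx - 1))
      ny <- ceiling(n / nx)
      gy <- yr[1] + s / 2 + s * (0:(ny - 1))
      g <- expand.grid(x = gx, y = gy)[seq_len(n), ]
      pts <- cbind(g$x + if (jit > 0) runif(n, -jit, jit) else 0,
                   g$y + if (jit > 0) runif(n, -jit, jit) else 0)
      pts[, 1] <- pmin(pmax(pts[, 1], xr[1]), xr[2])
      pts[, 2] <- pmin(pmax(pts[, 2], yr[1]), yr[2])
      pts
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Spatial partition of parcel centroids into sectors honouring the core
# size cap; returns an integer sector assignment.
tile_sectors <- function(xy, tiling) {
  n <- nrow(xy)
  if (n <= tiling$core_max && n <= tiling$core_target * 1.5)
    return(rep(1L, n))
  k <- max(2L, round(n / tiling$core_target))
  k <- min(k, n)
  jit <- cbind(xy[, 1] + runif(n) * 1e-3, xy[, 2] + runif(n) * 1e-3)
  cl <- kmeans(jit, centers = k, nstart = 2L, iter.max = 50L)$cluster
  for (pass in 1:10) {
    sizes <- table(cl)
    big <- as.integer(names(sizes)[sizes > tiling$core_max])
    if (length(big) == 0) break
    for (b in big) {
      idx <- which(cl == b)
      kk <- ceiling(length(idx) / tiling$core_target)
      sub <- kmeans(jit[idx, , drop = FALSE], centers = kk, nstart = 2L,
                    iter.max = 50L)$cluster
      cl[idx] <- max(cl) + sub
    }
  }
  # renumber 1..K by mean x then y for determinism
  ord <- order(tapply(xy[, 1], cl, mean), tapply(xy[, 2], cl, mean))
  match(cl, as.integer(names(table(cl))[ord]))
}

#' Generate one synthetic village
#'
#' Draws a parcel count, settlement pattern and frame; generates centroids
#' via [generate_parcel_centroids()]; lays square parcel cells on them;
#' partitions them into sectors (spatial clustering honouring the core-size
#' bounds, mimicking road-bounded demarcation); assigns use classes; builds
#' hierarchical parcel identifiers; and traces sector-boundary roads.
#'
#' @param config A [synth_config()].
#' @param village_index 1-based village number (becomes the village code).
#' @param n_parcels Optional fixed parcel count (otherwise drawn).
#' @return List with elements `village` (one-row data frame), `sectors`,
#'   `parcels` and `roads`.
#' @export
generate_village <- function(config, village_index, n_parcels = NULL) {
  vs <- config$village_size
  n <- n_parcels %||% max(vs$min, min(vs$max,
    round(rlnorm(1, vs$meanlog, vs$sdlog))))
  n <- as.integer(n)
  pattern <- sample(names(config$pattern_mix), 1, prob = config$pattern_mix)
  side <- min(2500, max(300, sqrt(n) * 30))
  ox <- ((village_index - 1) %% 8) * 5000
  oy <- ((village_index - 1) %/% 8) * 5000
  frame <- c(ox, ox + side, oy, oy + side)
  params <- list(n_parents = max(3L, round(n *
                   config$cluster_process$parents_per_150 / 150)),
                 sigma = config$cluster_process$sigma)
  xy <- generate_parcel_centroids(pattern, n, frame, params)

  sec <- tile_sectors(xy, config$sector_tiling)
  n_sec <- max(sec)
  if (n_sec > 99)
    stop("configuration error: sector code capacity (99) exceeded",
         call. = FALSE)
  if (max(table(sec)) > 9999)
    stop("configuration error: parcel sequence capacity exceeded",
         call. = FALSE)

  use <- sample(names(config$use_mix), n, replace = TRUE,
                prob = config$use_mix)
  l1 <- ifelse(use %in% c("residential", "nonresidential", "mixed"),
               "Built-Up", ifelse(use == "vacant", "Vacant Land",
                                  "Waste Land"))
  l2 <- c(residential = "Residential", nonresidential = "Commercial",
          mixed = "Mixed", vacant = "Open", ruined = "Derelict")[use]
  l3 <- paste0(l2, "-General")

  parcel_seq <- stats::ave(seq_len(n), sec, FUN = seq_along)
  uid <- build_parcel_uid(356, 8, 88, 2, village_index, sec, parcel_seq)
  h <- config$parcel_side / 2
  geometry <- lapply(seq_len(n), function(i) cbind(
    xy[i, 1] + c(-h, h, h, -h), xy[i, 2] + c(-h, -h, h, h)))
  parcels <- data.frame(uid = uid, village_code = village_index,
                        sector_num = sec, sector_code = sector_alpha(sec),
                        parcel_seq = parcel_seq, use_class = use,
                        landuse_level1 = l1, landuse_level2 = unname(l2),
                        landuse_level3 = unname(l3),
                        x = xy[, 1], y = xy[, 2],
                        area_m2 = config$parcel_side^2)
  parcels$geometry <- geometry

  sectors <- do.call(rbind, lapply(seq_len(n_sec), function(s) {
    idx <- which(sec == s)
    corners <- do.call(rbind, geometry[idx])
    hull <- convex_hull(corners)
    out <- data.frame(village_code = village_index,
                      sector_code = sector_alpha(s), sector_num = s,
                      area_ha = polygon_area(hull) / 1e4,
                      population = 0L)
    out$boundary <- list(hull)
    out
  }))

  roads <- do.call(rbind, lapply(seq_len(n_sec), function(s) {
    hull <- sectors$boundary[[s]]
    ring <- rbind(hull, hull[1, , drop = FALSE])
    len <- sum(sqrt(diff(ring[, 1])^2 + diff(ring[, 2])^2))
    ty <- sample(c("village_road", "public_lane", "private_lane"), 1,
                 prob = c(0.5, 0.35, 0.15))
    out <- data.frame(road_id = sprintf("R%03d-%02d", village_index, s),
                      village_code = village_index, typology = ty,
                      surface = sample(c("metalled", "semimetalled",
                                         "unmetalled"), 1,
                                       prob = c(0.5, 0.3, 0.2)),
                      quality = sample(c("good", "average", "poor"), 1,
                                       prob = c(0.4, 0.4, 0.2)),
                      length_m = len)
    out$geometry <- list(ring)
    out
  }))

  village <- data.frame(village_code = village_index,
                        name = sprintf("V%03d", village_index),
                        pattern = pattern,
                        size_class = if (n > 1000) "large" else "small",
                        n_parcels = n,
                        frame_xmin = frame[1], frame_xmax = frame[2],
                        frame_ymin = frame[3], frame_ymax = frame[4])
  list(village = village, sectors = sectors, parcels = parcels,
       roads = roads)
}

#' Assign households with socially structured composition
#'
#' Every residential or mixed parcel receives `1 + Poisson` households.
#' Each sector draws a caste profile from a Dirichlet distribution centred
#' on the site shares with concentration `caste_segregation` (low values
#' produce segregated, dominance-prone sectors; infinite concentration
#' reproduces the site shares in every sector). Household SES is drawn from
#' an ordinal logit shifted by caste, and behavioural covariates (water
#' source, toilet, liquid/solid disposal) from logistic models on SES rank.
#'
#' @param vil Village list from [generate_village()].
#' @param config A [synth_config()].
#' @return The village list with a `households` data frame added and sector
#'   populations filled in.
#' @export
assign_households <- function(vil, config) {
  p <- vil$parcels
  res <- which(p$use_class %in% c("residential", "mixed"))
  shares <- config$caste_site_shares
  conc <- config$caste_segregation
  n_sec <- nrow(vil$sectors)
  profiles <- t(vapply(seq_len(n_sec), function(s) {
    if (is.infinite(conc)) shares else rdirichlet1(conc * shares)
  }, numeric(length(shares))))
  colnames(profiles) <- names(shares)

  n_hh_parcel <- 1L + rpois(length(res), config$households_extra)
  pid <- rep(res, n_hh_parcel)
  m <- length(pid)
  if (m == 0) { vil$households <- empty_households(); return(vil) }
  sec <- p$sector_num[pid]
  caste <- vapply(sec, function(s)
    sample(names(shares), 1, prob = profiles[s, ]), character(1))
  wealth <- rnorm(n_sec, 0, config$ses_sector_sd %||% 0)
  shift <- config$ses_given_caste$shift[caste]
  latent <- shift + wealth[sec] + rlogis(m)
  cp <- config$ses_given_caste$cutpoints
  ses <- ifelse(latent < cp[1], "rich", ifelse(latent < cp[2],
                "middle", "poor"))
  r <- match(ses, SES_CLASSES)   # 1 rich .. 3 poor
  cm <- config$covariate_model
  pr <- function(co) stats::plogis(co[1] + co[2] * (r - 1))
  hh <- data.frame(
    household_id = paste0(p$uid[pid], "-",
                          stats::ave(pid, pid, FUN = seq_along)),
    parcel_uid = p$uid[pid], village_code = p$village_code[pid],
    sector_num = sec, sector_code = p$sector_code[pid],
    caste = caste, ses = ses,
    n_members = 1L + rpois(m, config$household_size_extra),
    water_source = ifelse(runif(m) < pr(cm$water_inside), "inside",
                          "outside"),
    toilet = runif(m) < pr(cm$toilet),
    liquid_disposal = ifelse(runif(m) < pr(cm$liquid_drain), "drain",
                             "open"),
    solid_disposal = ifelse(runif(m) < pr(cm$solid_collected), "collected",
                            "open_dump"),
    x = p$x[pid], y = p$y[pid])
  pop <- tapply(hh$n_members, hh$sector_num, sum)
  vil$sectors$population <- as.integer(
    ifelse(is.na(pop[as.character(vil$sectors$sector_num)]), 0L,
           pop[as.character(vil$sectors$sector_num)]))
  vil$households <- hh
  vil$caste_profiles <- profiles
  vil
}

#' Place waste spots by a sector-driven inhomogeneous Poisson process
#'
#' Spot counts per sector are Poisson with intensity
#' `exp(gamma0 + gamma1 * lowSES_share + gamma2 * SCST_share)` per hectare
#' of sector area; locations are uniform within the sector boundary;
#' diameters are lognormal (the default parameters make ~70% of spots
#' qualify at the 1 m threshold); kind is solid mound or liquid puddle.
#'
#' @param vil Village list with households assigned.
#' @param config A [synth_config()].
#' @return The village list with a `waste_spots` data frame added.
#' @export
place_waste_spots <- function(vil, config) {
  wm <- config$waste_model
  hh <- vil$households
  spots <- list()
  for (s in seq_len(nrow(vil$sectors))) {
    sub <- hh[hh$sector_num == vil$sectors$sector_num[s], , drop = FALSE]
    low <- if (nrow(sub)) mean(sub$ses == "poor") else 0
    scst <- if (nrow(sub)) mean(sub$caste == "SCST") else 0
    lam <- exp(wm$gamma0 + wm$gamma1 * low + wm$gamma2 * scst)
    n_s <- if (is.finite(lam)) rpois(1, lam * vil$sectors$area_ha[s]) else 0L
    if (n_s == 0) next
    hull <- vil$sectors$boundary[[s]]
    bb <- c(range(hull[, 1]), range(hull[, 2]))
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(pts) < n_s && tries < 200L) {
      cand <- cbind(runif(2 * n_s, bb[1], bb[2]),
                    runif(2 * n_s, bb[3], bb[4]))
      pts <- rbind(pts, cand[points_in_polygon(cand, hull), , drop = FALSE])
      tries <- tries + 1L
    }
    if (nrow(pts) < n_s)
      pts <- rbind(pts, cbind(runif(n_s - nrow(pts), bb[1], bb[2]),
                              runif(n_s - nrow(pts), bb[3], bb[4])))
    pts <- pts[seq_len(n_s), , drop = FALSE]
    spots[[length(spots) + 1L]] <- data.frame(
      spot_id = sprintf("W%03d-%02d-%04d", vil$village$village_code,
                        vil$sectors$sector_num[s], seq_len(n_s)),
      kind = sample(c("solid_mound", "liquid_puddle"), n_s, replace = TRUE,
                    prob = c(wm$p_solid, 1 - wm$p_solid)),
      x = pts[, 1], y = pts[, 2],
      diameter = rlnorm(n_s, wm$diameter_meanlog, wm$diameter_sdlog),
      village_code = vil$village$village_code,
      sector_num = vil$sectors$sector_num[s],
      sector_code = vil$sectors$sector_code[s])
  }
  vil$waste_spots <- if (length(spots)) do.call(rbind, spots)
                     else empty_waste_spots()
  vil
}

#' Generate a complete synthetic surveillance site
#'
#' Runs [generate_village()], [assign_households()] and
#' [place_waste_spots()] for every village, generates individuals with
#' random 9-digit identifiers, and assembles an `hdss_site` whose manifest
#' records the exact structural parameters used (for parameter-recovery
#' testing). Deterministic under `seed`.
#'
#' @param config A [synth_config()].
#' @param seed Integer RNG seed.
#' @param individuals Generate the individual layer (default TRUE).
#' @return An `hdss_site`.
#' @export
generate_site <- function(config = synth_config(), seed = 1L,
                          individuals = TRUE) {
  set.seed(seed)
  vils <- lapply(seq_len(config$n_villages), function(i) {
    v <- generate_village(config, i)
    v <- assign_households(v, config)
    place_waste_spots(v, config)
  })
  villages <- do.call(rbind, lapply(vils, `[[`, "village"))
  sectors <- do.call(rbind, lapply(vils, `[[`, "sectors"))
  parcels <- do.call(rbind, lapply(vils, `[[`, "parcels"))
  roads <- do.call(rbind, lapply(vils, `[[`, "roads"))
  households <- do.call(rbind, lapply(vils, `[[`, "households"))
  waste <- do.call(rbind, lapply(vils, `[[`, "waste_spots"))
  rownames(sectors) <- rownames(parcels) <- rownames(households) <-
    rownames(waste) <- rownames(roads) <- NULL

  ind <- if (individuals && nrow(households)) {
    tot <- sum(households$n_members)
    data.frame(uid = allocate_individual_uid(tot),
               household_id = rep(households$household_id,
                                  households$n_members),
               age = pmin(95, round(rgamma(tot, shape = 2, scale = 14))),
               sex = sample(c("female", "male"), tot, replace = TRUE))
  } else empty_individuals()

  frame_area_ha <- sum((villages$frame_xmax - villages$frame_xmin) *
                       (villages$frame_ymax - villages$frame_ymin)) / 1e4
  manifest <- list(seed = seed,
                   n_villages = config$n_villages,
                   caste_site_shares = as.list(config$caste_site_shares),
                   caste_segregation = config$caste_segregation,
                   ses_given_caste = config$ses_given_caste,
                   waste_model = config$waste_model,
                   use_mix = as.list(config$use_mix),
                   households_extra = config$households_extra,
                   pattern_mix = as.list(config$pattern_mix))
  new_site(villages, sectors, parcels, households, ind, waste, roads,
           total_area_ha = frame_area_ha, manifest = manifest)
}
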