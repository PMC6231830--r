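# Association of dominance classes with exposure indicators, and the
# household-level analysis dataset joining sector-level indicators to
# households.

#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with the standard tie correction
#' `1 - sum(t^3 - t) / (N^3 - N)` and a chi-square reference distribution
#' on `k - 1` degrees of freedom. Implemented directly from the rank
#' formula so the tie-correction factor is exposed.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`; at least two
#'   non-empty groups.
#' @return List of class `kw_result`: `H`, `df`, `p`, `tie_correction`.
#' @examples
#' kruskal_wallis(c(1:3, 4:6, 7:9), rep(letters[1:3], each = 3))
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2) stop("at least two groups are required", call. = FALSE)
  n <- length(values)
  r <- rank(values)
  rs <- tapply(r, groups, sum)
  ns <- tabulate(groups)
  H <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (C == 0) {               # all values identical
    H <- 0; p <- 1
  } else {
    H <- H / C
    H <- max(H, 0)
    p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  structure(list(H = H, df = k - 1L, p = p, tie_correction = C),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4f, df = %d, p = %.4g\n",
              x$H, x$df, x$p))
  invisible(x)
}

#' Household-level analysis dataset
#'
#' Joins the sector-level exposure indicators (waste density per 100
#' residents, dominance labels) onto every household together with its
#' nearest-qualifying-waste distance, producing the dataset used by the
#' association and mediation analyses.
#'
#' @param site An `hdss_site` with households and waste spots.
#' @param threshold Qualifying waste-spot diameter (m).
#' @param dominance_threshold Dominance ratio threshold.
#' @return Household data frame with added columns `nearest_waste_m`,
#'   `log_nearest_waste`, `waste_density`, `dominant_caste`,
#'   `dominant_ses`, `dom_caste_scst` and `dom_ses_poor` (binary
#'   indicators), plus a `sector_id` cluster key.
#' @export
exposure_dataset <- function(site, threshold = 1.0,
                             dominance_threshold = 1.5) {
  hh <- site$households
  if (nrow(hh) == 0) stop("site has no households", call. = FALSE)
  hh$nearest_waste_m <- nearest_waste_distance(hh, site$waste_spots,
                                               threshold)
  hh$log_nearest_waste <- log(pmax(hh$nearest_waste_m, 0.5))
  sec <- site$sectors
  sec_key <- paste(sec$village_code, sec$sector_num)
  w <- site$waste_spots
  wq <- w[w$diameter >= threshold, , drop = FALSE]
  counts <- table(factor(paste(wq$village_code, wq$sector_num),
                         levels = sec_key))
  dens <- ifelse(sec$population > 0,
                 100 * as.numeric(counts) / sec$population, NA_real_)
  lab <- dominance_labels(site, dominance_threshold)
  lab_key <- paste(lab$village_code, lab$sector_num)
  hh_key <- paste(hh$village_code, hh$sector_num)
  m <- match(hh_key, sec_key)
  hh$waste_density <- dens[m]
  ml <- match(hh_key, lab_key)
  hh$dominant_caste <- lab$dominant_caste[ml]
  hh$dominant_ses <- lab$dominant_ses[ml]
  hh$dom_caste_scst <- as.integer(hh$dominant_caste == "SCST")
  hh$dom_ses_poor <- as.integer(hh$dominant_ses == "poor")
  hh$sector_id <- hh_key
  hh
}

#' Compare exposure indicators across dominant-class groups
#'
#' Groups sectors (for waste density) or households (for nearest-waste
#' distance) by the dominant class of the chosen attribute, reports group
#' medians and a Kruskal-Wallis test across the dominant-class groups.
#' Sectors or households in sectors with no dominant class (`"none"`) are
#' excluded, as are empty groups (with a warning).
#'
#' @param site An `hdss_site`.
#' @param indicator `"waste_density"` (sector level) or
#'   `"nearest_distance"` (household level).
#' @param attribute `"caste"` or `"ses"`.
#' @param threshold,dominance_threshold Qualifying diameter and dominance
#'   ratio.
#' @return List of class `dominance_comparison`: `medians` (named by
#'   class), `n` per group, and `test` (a `kw_result`).
#' @export
compare_by_dominance <- function(site,
                                 indicator = c("waste_density",
                                               "nearest_distance"),
                                 attribute = c("caste", "ses"),
                                 threshold = 1.0,
                                 dominance_threshold = 1.5) {
  indicator <- match.arg(indicator)
  attribute <- match.arg(attribute)
  classes <- if (attribute == "caste") CASTE_CLASSES else SES_CLASSES
  lab <- dominance_labels(site, dominance_threshold)
  dom_col <- paste0("dominant_", attribute)
  if (indicator == "waste_density") {
    sec <- site$sectors
    sec_key <- paste(sec$village_code, sec$sector_num)
    w <- site$waste_spots
    wq <- w[w$diameter >= threshold, , drop = FALSE]
    counts <- table(factor(paste(wq$village_code, wq$sector_num),
                           levels = sec_key))
    vals <- ifelse(sec$population > 0,
                   100 * as.numeric(counts) / sec$population, NA_real_)
    grp <- lab[[dom_col]][match(sec_key, paste(lab$village_code,
                                               lab$sector_num))]
  } else {
    ds <- exposure_dataset(site, threshold, dominance_threshold)
    vals <- ds$nearest_waste_m
    grp <- ds[[dom_col]]
  }
  keep <- !is.na(vals) & !is.na(grp) & grp %in% classes
  vals <- vals[keep]; grp <- factor(grp[keep], levels = classes)
  present <- levels(grp)[tabulate(grp) > 0]
  if (length(present) < length(classes))
    warning("empty dominant-class group(s) excluded: ",
            paste(setdiff(classes, present), collapse = ", "))
  if (length(present) < 2)
    stop("fewer than two dominant-class groups present", call. = FALSE)
  grp <- factor(as.character(grp), levels = present)
  structure(list(
    indicator = indicator, attribute = attribute,
    medians = tapply(vals, grp, median),
    n = tapply(vals, grp, length),
    test = kruskal_wallis(vals, grp)), class = "dominance_comparison")
}

#' @export
print.dominance_comparison <- function(x, ...) {
  cat(x$indicator, "by dominant", x$attribute, "class:\n")
  print(round(x$medians, 2))
  print(x$test)
  invisible(x)
}
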