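# Sector dominance: a sector is dominant for a class when its prevalence of
# that class reaches 1.5 times the site-wide average prevalence.

#' Site-wide prevalence of a household attribute
#'
#' Household-weighted proportions of each class of `attribute` (caste or
#' socioeconomic status) across the whole site.
#'
#' @param households Household data frame with a `caste` and/or `ses` column.
#' @param attribute `"caste"` or `"ses"`.
#' @return Named numeric vector of proportions summing to 1.
#' @export
site_prevalence <- function(households, attribute = c("caste", "ses")) {
  attribute <- match.arg(attribute)
  if (nrow(households) == 0)
    stop("no households: prevalence undefined", call. = FALSE)
  lev <- if (attribute == "caste") CASTE_CLASSES else SES_CLASSES
  x <- factor(households[[attribute]], levels = lev)
  tab <- table(x)
  prop <- as.numeric(tab) / sum(tab)
  names(prop) <- lev
  prop
}

#' Classify one sector's dominance for an attribute
#'
#' A class qualifies when the sector's prevalence of it is at least
#' `threshold` times the site prevalence (inclusive boundary). The dominant
#' class is the qualifying class with the largest ratio, ties broken
#' lexicographically; `none` when no class qualifies. Sectors without
#' households are excluded from dominance analysis, signalled by an `NA`
#' label rather than an error.
#'
#' @param sector_households Household rows of one sector.
#' @param prevalence Site prevalence from [site_prevalence()].
#' @param attribute `"caste"` or `"ses"`.
#' @param threshold Dominance ratio threshold (default 1.5).
#' @return List of class `dominance_label`: `attribute`, `dominant_class`
#'   (`"none"`, a class name, or `NA` for an empty sector), `ratio` (named
#'   vector of prevalence ratios) and `qualifying_classes`.
#' @export
classify_sector_dominance <- function(sector_households, prevalence,
                                      attribute = c("caste", "ses"),
                                      threshold = 1.5) {
  attribute <- match.arg(attribute)
  if (nrow(sector_households) == 0)
    return(structure(list(attribute = attribute, dominant_class = NA_character_,
                          ratio = setNames(numeric(length(prevalence)),
                                           names(prevalence)),
                          qualifying_classes = character(),
                          excluded = TRUE), class = "dominance_label"))
  sec <- site_prevalence(sector_households, attribute)
  ratio <- ifelse(prevalence > 0, sec / prevalence, 0)
  names(ratio) <- names(prevalence)
  qual <- names(ratio)[ratio >= threshold - 1e-9]
  dom <- if (length(qual) == 0) "none" else {
    best <- qual[order(-ratio[qual], qual)]
    best[1]
  }
  structure(list(attribute = attribute, dominant_class = dom, ratio = ratio,
                 qualifying_classes = qual, excluded = FALSE),
            class = "dominance_label")
}

#' Dominance labels for every sector of a site
#'
#' Applies [classify_sector_dominance()] to each sector for both caste and
#' socioeconomic status. Only sectors with households receive labels;
#' uninhabited sectors are marked excluded.
#'
#' @param site An `hdss_site` with households assigned.
#' @param threshold Dominance ratio threshold (default 1.5).
#' @return Data frame with one row per sector: `village_code`, `sector_num`,
#'   `sector_code`, `inhabited`, `dominant_caste`, `caste_ratio` (ratio of
#'   the dominant caste), `dominant_ses`, `ses_ratio`.
#' @export
dominance_labels <- function(site, threshold = 1.5) {
  hh <- site$households
  prev_caste <- site_prevalence(hh, "caste")
  prev_ses <- site_prevalence(hh, "ses")
  key <- paste(hh$village_code, hh$sector_num)
  sec <- site$sectors
  sec_key <- paste(sec$village_code, sec$sector_num)
  rows <- lapply(seq_len(nrow(sec)), function(i) {
    sub <- hh[key == sec_key[i], , drop = FALSE]
    lc <- classify_sector_dominance(sub, prev_caste, "caste", threshold)
    ls <- classify_sector_dominance(sub, prev_ses, "ses", threshold)
    data.frame(village_code = sec$village_code[i],
               sector_num = sec$sector_num[i],
               sector_code = sec$sector_code[i],
               inhabited = nrow(sub) > 0,
               dominant_caste = lc$dominant_class,
               caste_ratio = if (lc$dominant_class %in% names(lc$ratio))
                 unname(lc$ratio[lc$dominant_class]) else NA_real_,
               dominant_ses = ls$dominant_class,
               ses_ratio = if (ls$dominant_class %in% names(ls$ratio))
                 unname(ls$ratio[ls$dominant_class]) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Summarise dominant-sector counts and percentages
#'
#' Counts, over inhabited sectors only, how many sectors have a dominant
#' caste and a dominant socioeconomic class, with per-class breakdowns;
#' percentages are half-up at one decimal via [ratio_report()].
#'
#' @param labels Per-sector label data frame from [dominance_labels()] (or
#'   constructed equivalently).
#' @return List of class `dominance_summary`: `n_inhabited`,
#'   `caste_dominant_n`, `caste_dominant_pct`, `ses_dominant_n`,
#'   `ses_dominant_pct`, `by_caste_class`, `by_ses_class`.
#' @export
dominance_summary <- function(labels) {
  inh <- labels[labels$inhabited, , drop = FALSE]
  n <- nrow(inh)
  if (n == 0) stop("no inhabited sectors", call. = FALSE)
  caste_n <- sum(inh$dominant_caste != "none")
  ses_n <- sum(inh$dominant_ses != "none")
  pct <- function(k) if (n > 0) ratio_report(k, n, 1L) else 0
  structure(list(
    n_inhabited = n,
    caste_dominant_n = caste_n, caste_dominant_pct = pct(caste_n),
    ses_dominant_n = ses_n, ses_dominant_pct = pct(ses_n),
    by_caste_class = table(factor(inh$dominant_caste,
                                  levels = c(CASTE_CLASSES, "none"))),
    by_ses_class = table(factor(inh$dominant_ses,
                                levels = c(SES_CLASSES, "none")))),
    class = "dominance_summary")
}

#' @export
print.dominance_summary <- function(x, ...) {
  cat(sprintf("dominant caste: %d/%d sectors (%.1f%%)\n",
              x$caste_dominant_n, x$n_inhabited, x$caste_dominant_pct))
  cat(sprintf("dominant SES:   %d/%d sectors (%.1f%%)\n",
              x$ses_dominant_n, x$n_inhabited, x$ses_dominant_pct))
  invisible(x)
}
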