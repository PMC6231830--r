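# Ground-truthing audit design: pilot village stratification, parcel
# sampling with a minimum per village, 10% field checks, LQAS accept/reject
# and error-rate reporting.

#' Select pilot villages by size and settlement-pattern strata
#'
#' Stratified random draw of six villages: two each from the large-linear
#' and large-circular strata and one each from the small-linear and
#' small-circular strata (large means more than 1000 parcels).
#'
#' @param villages Village data frame with `size_class` and `pattern`
#'   columns.
#' @return The six selected village rows.
#' @export
select_pilot_villages <- function(villages) {
  want <- list(c("large", "linear", 2L), c("large", "circular", 2L),
               c("small", "linear", 1L), c("small", "circular", 1L))
  picks <- lapply(want, function(w) {
    idx <- which(villages$size_class == w[1] & villages$pattern == w[2])
    need <- as.integer(w[3])
    if (length(idx) < need)
      stop("stratum ", w[1], "-", w[2], " has only ", length(idx),
           " village(s), need ", need, call. = FALSE)
    idx[sample.int(length(idx), need)]
  })
  villages[unlist(picks), , drop = FALSE]
}

#' Audit sampling plan
#'
#' @param rate Sampling fraction of parcels (default 0.051).
#' @param min_per_village Minimum parcels sampled per village (default 30).
#' @return List of class `sampling_plan`.
#' @export
sampling_plan <- function(rate = 0.051, min_per_village = 30L) {
  if (rate <= 0 || rate > 1) stop("rate must be in (0, 1]", call. = FALSE)
  if (min_per_village < 1) stop("min_per_village must be >= 1",
                                call. = FALSE)
  structure(list(rate = rate, min_per_village = as.integer(min_per_village)),
            class = "sampling_plan")
}

#' Audit sample size implied by the plan
#'
#' `max(min_per_village, ceiling(rate * n))`, capped at `n`.
#'
#' @param n_parcels Number of parcels in the village.
#' @param plan A [sampling_plan()].
#' @return Integer sample size.
#' @export
audit_sample_size <- function(n_parcels, plan = sampling_plan()) {
  as.integer(pmin(n_parcels,
                  pmax(plan$min_per_village,
                       ceiling(plan$rate * n_parcels))))
}

#' Sample parcels of one village for audit
#'
#' Simple random sampling without replacement at the plan's size,
#' allocated across use-class strata proportionally to their sizes
#' (largest-remainder apportionment).
#'
#' @param parcels Parcel rows of one village.
#' @param plan A [sampling_plan()].
#' @return The sampled parcel rows.
#' @export
sample_parcels_for_audit <- function(parcels, plan = sampling_plan()) {
  n <- nrow(parcels)
  if (n == 0) stop("village has no parcels", call. = FALSE)
  size <- audit_sample_size(n, plan)
  strata <- split(seq_len(n), parcels$use_class)
  exact <- vapply(strata, length, integer(1)) * size / n
  alloc <- floor(exact)
  rem <- size - sum(alloc)
  if (rem > 0) {
    ord <- order(exact - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
  }
  alloc <- pmin(alloc, vapply(strata, length, integer(1)))
  idx <- unlist(lapply(names(strata), function(s) {
    k <- alloc[[s]]
    if (k == 0) integer(0) else strata[[s]][sample.int(length(strata[[s]]), k)]
  }), use.names = FALSE)
  if (length(idx) < size) {
    rest <- setdiff(seq_len(n), idx)
    idx <- c(idx, rest[sample.int(length(rest), size - length(idx))])
  }
  parcels[sort(idx), , drop = FALSE]
}

#' Per-stratum field-check sample
#'
#' Draws `ceiling(fraction * stratum size)` parcels per stratum by simple
#' random sampling without replacement, mirroring the 10% random
#' field-based cross-checks stratified by field-worker task.
#'
#' @param parcels Parcel data frame.
#' @param fraction Sampling fraction (default 0.10).
#' @param strata Vector of stratum labels, one per parcel (defaults to the
#'   use class).
#' @return The sampled parcel rows.
#' @export
field_check_sample <- function(parcels, fraction = 0.10,
                               strata = parcels$use_class) {
  if (nrow(parcels) == 0) stop("no parcels to check", call. = FALSE)
  groups <- split(seq_len(nrow(parcels)), strata)
  idx <- unlist(lapply(groups, function(g) {
    k <- min(length(g), ceiling(fraction * length(g)))
    g[sample.int(length(g), k)]
  }), use.names = FALSE)
  parcels[sort(idx), , drop = FALSE]
}

#' Construct or derive an LQAS plan
#'
#' Lot quality assurance sampling accepts a data lot when the number of
#' defects in a sample of `sample_n` is at most `decision_d`. When `(n, d)`
#' are not supplied they are derived as the smallest `n` admitting a `d`
#' that satisfies both binomial risk bounds: producer risk
#' `P(reject | p = aql) <= alpha` and consumer risk
#' `P(accept | p = rql) <= beta`.
#'
#' @param sample_n,decision_d Explicit plan, or `NULL` to derive.
#' @param aql Acceptable quality level (defect probability).
#' @param rql Rejectable quality level; must exceed `aql`.
#' @param alpha,beta Producer and consumer risks.
#' @param max_n Search cap for the derived plan.
#' @return List of class `lqas_plan` with `sample_n`, `decision_d`, and
#'   the achieved risks.
#' @export
lqas_plan <- function(sample_n = NULL, decision_d = NULL, aql = 0.05,
                      rql = 0.20, alpha = 0.10, beta = 0.10,
                      max_n = 2000L) {
  if (!is.null(sample_n) && !is.null(decision_d)) {
    if (decision_d >= sample_n)
      stop("decision_d must be smaller than sample_n", call. = FALSE)
    return(structure(list(sample_n = as.integer(sample_n),
                          decision_d = as.integer(decision_d),
                          aql = aql, rql = rql),
                     class = "lqas_plan"))
  }
  if (aql >= rql) stop("infeasible risks: aql must be below rql",
                       call. = FALSE)
  for (n in 1:max_n) {
    for (d in 0:(n - 1)) {
      ok_prod <- pbinom(d, n, aql) >= 1 - alpha
      ok_cons <- pbinom(d, n, rql) <= beta
      if (!ok_cons) break   # acceptance prob at rql only grows with d
      if (ok_prod)
        return(structure(list(sample_n = n, decision_d = d, aql = aql,
                              rql = rql,
                              producer_risk = 1 - pbinom(d, n, aql),
                              consumer_risk = pbinom(d, n, rql)),
                         class = "lqas_plan"))
    }
  }
  stop("infeasible LQAS plan within n <= ", max_n, call. = FALSE)
}

#' LQAS accept/reject decision
#'
#' @param defects_in_sample Number of defective parcels found.
#' @param plan An [lqas_plan()].
#' @return `"accept"` if defects are at most the decision threshold,
#'   otherwise `"reject"`.
#' @export
lqas_decision <- function(defects_in_sample, plan) {
  if (defects_in_sample > plan$sample_n)
    stop("defects exceed sample size", call. = FALSE)
  if (defects_in_sample <= plan$decision_d) "accept" else "reject"
}

#' LQAS operating characteristic
#'
#' Probability of accepting a lot with true defect probability `p`:
#' `pbinom(decision_d, sample_n, p)`.
#'
#' @param plan An [lqas_plan()].
#' @param p Vector of true defect probabilities.
#' @return Acceptance probabilities.
#' @export
lqas_oc <- function(plan, p) pbinom(plan$decision_d, plan$sample_n, p)

#' Error-rate report over audit records
#'
#' Per-category percentages (half-up, 2 decimals) of size, shape, location
#' and attribute errors plus vacant-missing counts and the temporal-change
#' breakdown.
#'
#' @param audits Data frame with logical columns `size_error`,
#'   `shape_error`, `location_error`, `attribute_error`, `vacant_missing`
#'   and a `temporal_change` column in
#'   `{none, new_construction, other}`.
#' @param denominator Denominator for the percentages (typically the total
#'   parcel count, which may exceed the number audited).
#' @return List of class `error_report` with counts and `pct` (named
#'   percentages).
#' @export
error_rate_report <- function(audits, denominator) {
  flags <- c("size_error", "shape_error", "location_error",
             "attribute_error")
  counts <- vapply(flags, function(f)
    if (f %in% names(audits)) sum(audits[[f]], na.rm = TRUE) else 0L,
    numeric(1))
  if (denominator < max(counts))
    stop("denominator smaller than a flag count", call. = FALSE)
  any_positional <- if (all(c("size_error", "shape_error",
                              "location_error") %in% names(audits)))
    sum(audits$size_error | audits$shape_error | audits$location_error,
        na.rm = TRUE) else NA_integer_
  tc <- if ("temporal_change" %in% names(audits))
    table(factor(audits$temporal_change,
                 levels = c("none", "new_construction", "other")))
    else NULL
  changed <- if (!is.null(tc)) sum(tc[c("new_construction", "other")]) else 0
  structure(list(
    counts = counts,
    pct = vapply(counts, function(k) ratio_report(k, denominator, 2L),
                 numeric(1)),
    any_positional = any_positional,
    any_positional_pct = if (!is.na(any_positional))
      ratio_report(any_positional, denominator, 2L) else NA_real_,
    vacant_missing = if ("vacant_missing" %in% names(audits))
      sum(audits$vacant_missing, na.rm = TRUE) else 0L,
    temporal_change = tc,
    new_construction_pct = if (changed > 0)
      ratio_report(tc[["new_construction"]], changed, 1L) else NA_real_,
    denominator = denominator), class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  for (f in names(x$counts))
    cat(sprintf("  %-16s %6d (%.2f%%)\n", f, x$counts[[f]], x$pct[[f]]))
  if (!is.na(x$any_positional))
    cat(sprintf("  any positional   %6d (%.2f%%)\n", x$any_positional,
                x$any_positional_pct))
  invisible(x)
}
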