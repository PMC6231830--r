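# Regression-based mediation (path) analysis with sector-cluster bootstrap.
# The product-of-coefficients decomposition is used: for each mediator M,
# indirect = a (exposure -> M) * b (M -> outcome | exposure), direct = the
# exposure coefficient in the outcome model. For all-linear paths the
# identity total = direct + sum(indirect) holds exactly.

#' Specify a mediation path model
#'
#' Describes the structure: a household-level outcome (typically
#' log nearest-waste distance), a household exposure (caste, coded as
#' indicator contrasts against the first level), one or more sector-level
#' mediators joined to households by sector membership (waste density,
#' SES-dominance or caste-dominance indicators), household covariates, and
#' the sector cluster key used by the bootstrap.
#'
#' @param outcome,exposure Column names.
#' @param mediators Character vector of mediator column names. Columns with
#'   only the values 0/1 (or logical) are modelled with a logistic link;
#'   numeric columns with a linear model.
#' @param covariates Character vector of adjustment columns.
#' @param cluster Column naming the sector cluster (default `"sector_id"`).
#' @return List of class `path_model_spec`.
#' @export
path_model_spec <- function(outcome, exposure, mediators,
                            covariates = character(),
                            cluster = "sector_id") {
  stopifnot(is.character(outcome), is.character(exposure),
            length(mediators) >= 1)
  structure(list(outcome = outcome, exposure = exposure,
                 mediators = mediators, covariates = covariates,
                 cluster = cluster), class = "path_model_spec")
}

# Internal: design matrices shared by the full fit and the bootstrap.
path_matrices <- function(data, spec) {
  vars <- c(spec$outcome, spec$exposure, spec$mediators, spec$covariates,
            spec$cluster)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  data <- data[complete.cases(data[vars]), vars]
  for (v in c(spec$exposure, spec$covariates))
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
  fx <- reformulate(c(spec$exposure, spec$covariates))
  mm <- model.matrix(fx, data)
  assign <- attr(mm, "assign")
  terms_x <- attr(stats::terms(fx), "term.labels")
  expo_cols <- which(assign == match(spec$exposure, terms_x))
  med_mat <- sapply(spec$mediators, function(m) as.numeric(data[[m]]))
  med_mat <- matrix(med_mat, ncol = length(spec$mediators),
                    dimnames = list(NULL, spec$mediators))
  med_binary <- vapply(spec$mediators, function(m) {
    u <- unique(med_mat[, m])
    all(u %in% c(0, 1))
  }, logical(1))
  list(data = data, X = mm, expo_cols = expo_cols, med = med_mat,
       med_binary = med_binary, y = as.numeric(data[[spec$outcome]]),
       cluster = as.character(data[[spec$cluster]]))
}

ols_coef <- function(X, y) {
  fit <- lm.fit(X, y)
  fit$coefficients
}

ols_full <- function(X, y) {
  fit <- lm.fit(X, y)
  cf <- fit$coefficients
  if (anyNA(cf))
    stop("singular fit; collinear columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  res <- fit$residuals
  sigma2 <- sum(res^2) / fit$df.residual
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- names(cf)
  list(coef = cf, se = se)
}

logit_coef <- function(X, m, se = FALSE) {
  fit <- suppressWarnings(stats::glm.fit(X, m,
    family = binomial(), control = list(maxit = 50)))
  cf <- fit$coefficients
  if (!se) return(cf)
  w <- fit$weights
  XtWXinv <- tryCatch(chol2inv(chol(crossprod(X * sqrt(w)))),
                      error = function(e) NULL)
  list(coef = cf,
       se = if (is.null(XtWXinv)) rep(NA_real_, length(cf))
            else sqrt(diag(XtWXinv)))
}

# One pass of the full path decomposition on given rows; returns NULL when
# a fit is degenerate (used to drop bootstrap replicates).
path_pass <- function(pm, rows = NULL, strict = FALSE) {
  X <- pm$X; med <- pm$med; y <- pm$y
  if (!is.null(rows)) { X <- X[rows, , drop = FALSE]
                        med <- med[rows, , drop = FALSE]; y <- y[rows] }
  k_med <- ncol(med)
  a <- matrix(NA_real_, k_med, length(pm$expo_cols),
              dimnames = list(colnames(med), colnames(X)[pm$expo_cols]))
  for (j in seq_len(k_med)) {
    cf <- if (pm$med_binary[j]) tryCatch(logit_coef(X, med[, j]),
                                         error = function(e) NULL)
          else ols_coef(X, med[, j])
    if (is.null(cf) || anyNA(cf[pm$expo_cols])) {
      if (strict) stop("singular mediator fit for '", colnames(med)[j],
                       "'", call. = FALSE)
      return(NULL)
    }
    a[j, ] <- cf[pm$expo_cols]
  }
  Xy <- cbind(X, med)
  cf_out <- ols_coef(Xy, y)
  cf_tot <- ols_coef(X, y)
  if (anyNA(cf_out[c(pm$expo_cols, ncol(X) + seq_len(k_med))]) ||
      anyNA(cf_tot[pm$expo_cols])) {
    if (strict) {
      bad <- names(cf_out)[is.na(cf_out)]
      stop("singular fit; collinear columns: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    return(NULL)
  }
  b <- cf_out[ncol(X) + seq_len(k_med)]
  names(b) <- colnames(med)
  direct <- cf_out[pm$expo_cols]
  total <- cf_tot[pm$expo_cols]
  indirect <- a * matrix(b, nrow = k_med, ncol = length(direct))
  list(a = a, b = b, direct = direct, total = total, indirect = indirect)
}

#' Fit a mediation path model
#'
#' Fits, at household level on complete cases: one model per mediator
#' (linear for continuous mediators, logistic for binary dominance
#' indicators) regressing the mediator on exposure and covariates; the
#' outcome model on exposure, mediators and covariates; and the total
#' model on exposure and covariates. Indirect effects are the products of
#' the exposure-to-mediator and mediator-to-outcome coefficients. With
#' all-linear paths `total = direct + sum(indirect)` exactly; with
#' logistic mediator links the products are on mixed scales and the
#' identity does not hold (reported as is).
#'
#' @param data Household-level data frame (see [exposure_dataset()]).
#' @param spec A [path_model_spec()].
#' @return Object of class `path_fit`: matrices/vectors `a`, `b`,
#'   `direct`, `total`, `indirect` (with standard errors `a_se`, `b_se`,
#'   `direct_se` for the main fit), the number of complete cases `n`, and
#'   the spec.
#' @export
fit_path_model <- function(data, spec) {
  pm <- path_matrices(data, spec)
  if (nrow(pm$X) == 0) stop("no complete cases", call. = FALSE)
  zerovar <- vapply(seq_len(ncol(pm$med)),
                    function(j) stats::var(pm$med[, j]) == 0, logical(1))
  if (any(zerovar))
    stop("singular fit; collinear columns: zero-variance mediator ",
         paste(colnames(pm$med)[zerovar], collapse = ", "), call. = FALSE)
  est <- path_pass(pm, strict = TRUE)

  # standard errors for the reported paths
  a_se <- est$a; a_se[] <- NA_real_
  for (j in seq_len(ncol(pm$med))) {
    f <- if (pm$med_binary[j]) logit_coef(pm$X, pm$med[, j], se = TRUE)
         else ols_full(pm$X, pm$med[, j])
    a_se[j, ] <- f$se[pm$expo_cols]
  }
  fo <- ols_full(cbind(pm$X, pm$med), pm$y)
  ft <- ols_full(pm$X, pm$y)
  structure(list(a = est$a, b = est$b, direct = est$direct,
                 total = est$total, indirect = est$indirect,
                 a_se = a_se,
                 b_se = fo$se[ncol(pm$X) + seq_len(ncol(pm$med))],
                 direct_se = fo$se[pm$expo_cols],
                 total_se = ft$se[pm$expo_cols],
                 n = nrow(pm$X), spec = spec),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat("path model on", x$n, "households\n")
  cat("a (exposure -> mediator):\n"); print(round(x$a, 4))
  cat("b (mediator -> outcome):\n"); print(round(x$b, 4))
  cat("indirect (a*b):\n"); print(round(x$indirect, 4))
  cat("direct:", round(x$direct, 4), " total:", round(x$total, 4), "\n")
  invisible(x)
}

#' Cluster-bootstrap confidence intervals for indirect effects
#'
#' Nonparametric bootstrap that resamples sectors (clusters) with
#' replacement — mediators are sector-level quantities, so household
#' resampling would understate their sampling variability. Percentile
#' intervals are reported for every indirect, direct and total effect.
#' Replicates with degenerate fits (e.g. a resample in which a dominance
#' indicator is constant) are dropped and counted.
#'
#' @param data Household-level data frame.
#' @param spec A [path_model_spec()].
#' @param B Number of bootstrap replicates (warning below 100).
#' @param seed Integer seed; fixed seed gives identical intervals.
#' @param level Confidence level (default 0.95).
#' @return Object of class `mediation_result`: the point `estimates`
#'   (a `path_fit`), `ci_indirect` (array mediator x exposure-term x
#'   bounds), `ci_direct`, `ci_total`, `B`, `B_used`, `dropped`, `seed`.
#' @export
indirect_effect_bootstrap <- function(data, spec, B = 1000L, seed = NULL,
                                      level = 0.95) {
  if (B < 100) warning("B < 100 gives unstable percentile intervals")
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_path_model(data, spec)
  pm <- path_matrices(data, spec)
  cl <- pm$cluster
  clusters <- unique(cl)
  rows_by_cl <- split(seq_along(cl), cl)[clusters]
  k_med <- ncol(pm$med)
  k_exp <- length(pm$expo_cols)
  ind_b <- array(NA_real_, c(B, k_med, k_exp))
  dir_b <- matrix(NA_real_, B, k_exp)
  tot_b <- matrix(NA_real_, B, k_exp)
  dropped <- 0L
  for (b in seq_len(B)) {
    pick <- sample.int(length(clusters), replace = TRUE)
    rows <- unlist(rows_by_cl[pick], use.names = FALSE)
    est <- path_pass(pm, rows)
    if (is.null(est)) { dropped <- dropped + 1L; next }
    ind_b[b, , ] <- est$indirect
    dir_b[b, ] <- est$direct
    tot_b[b, ] <- est$total
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qn <- function(v) quantile(v, probs, na.rm = TRUE, names = FALSE)
  ci_ind <- array(NA_real_, c(k_med, k_exp, 2),
                  dimnames = list(rownames(fit$indirect),
                                  colnames(fit$indirect),
                                  c("lower", "upper")))
  for (j in seq_len(k_med)) for (e in seq_len(k_exp))
    ci_ind[j, e, ] <- qn(ind_b[, j, e])
  ci_dir <- t(apply(dir_b, 2, qn))
  ci_tot <- t(apply(tot_b, 2, qn))
  dimnames(ci_dir) <- dimnames(ci_tot) <-
    list(colnames(fit$indirect), c("lower", "upper"))
  structure(list(estimates = fit, ci_indirect = ci_ind,
                 ci_direct = ci_dir, ci_total = ci_tot,
                 B = B, B_used = B - dropped, dropped = dropped,
                 seed = seed, level = level),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation (cluster bootstrap, B = %d, %d used)\n",
              x$B, x$B_used))
  for (j in rownames(x$ci_indirect)) for (e in colnames(x$ci_indirect))
    cat(sprintf("  indirect via %s [%s]: %.4f (%.4f, %.4f)\n", j, e,
                x$estimates$indirect[j, e], x$ci_indirect[j, e, "lower"],
                x$ci_indirect[j, e, "upper"]))
  invisible(x)
}

#' Simulate household data from a linear structural mediation model
#'
#' The validation generator for the path estimator: sectors are
#' caste-homogeneous (the exposure is constant within a sector, the
#' sharpest form of the segregation the settlement generator produces),
#' the sector-level mediator is `a * exposure + noise`, and the
#' household-level outcome is
#' `c_direct * exposure + b * mediator + covariate effect + noise`, so the
#' true indirect effect is exactly `a * b`.
#'
#' @param n_sectors Number of sectors (clusters).
#' @param hh_per_sector Mean households per sector (Poisson + 1).
#' @param p_exposed Probability a sector is of the exposed caste.
#' @param a,b,c_direct Structural coefficients.
#' @param sigma_m,sigma_y Mediator and outcome noise SDs.
#' @param covariate_effect Effect of the binary household covariate.
#' @return Data frame with `sector_id`, `scst` (exposure), `waste_density`
#'   (mediator), `log_nearest_waste` (outcome) and `toilet` (covariate);
#'   the true effects are in `attr(, "truth")`.
#' @export
simulate_path_data <- function(n_sectors = 250L, hh_per_sector = 20,
                               p_exposed = 0.35, a = 0.5, b = -0.4,
                               c_direct = -0.1, sigma_m = 0.5,
                               sigma_y = 1.0, covariate_effect = 0.3) {
  xs <- rbinom(n_sectors, 1, p_exposed)
  ms <- a * xs + rnorm(n_sectors, 0, sigma_m)
  nh <- 1L + rpois(n_sectors, hh_per_sector - 1)
  sec <- rep(seq_len(n_sectors), nh)
  n <- length(sec)
  z <- rbinom(n, 1, 0.5)
  y <- c_direct * xs[sec] + b * ms[sec] + covariate_effect * z +
    rnorm(n, 0, sigma_y)
  out <- data.frame(sector_id = sprintf("S%04d", sec), scst = xs[sec],
                    waste_density = ms[sec], log_nearest_waste = y,
                    toilet = z)
  attr(out, "truth") <- list(a = a, b = b, indirect = a * b,
                             direct = c_direct,
                             total = c_direct + a * b)
  out
}
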