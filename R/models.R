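# GLMM fitting, AICc multimodel inference, conditional R2 and marginal
# means for the daily metrics.
#
# Estimation is by maximum likelihood with crossed random intercepts for
# animal and date (Laplace approximation, via glmmTMB). Coefficients are
# reported on each response's reporting scale: identity for Gaussian
# responses, the natural-log scale for the log-transformed activity
# total, rates/rate ratios for Poisson counts, and additive effects on
# the proportion scale for the binomial share (see `cell_means()` for
# how each scale combines).

#' Specification of one candidate mixed model
#'
#' @param response column name of the response in the daily metrics table.
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @param fixed fixed-effect structure: `"global"`
#'   (season + species + interaction), `"season"`, `"species"` or
#'   `"null"`. Reference levels are fixed to drought and gemsbok.
#' @param scale reporting-scale tag (see [study_coefficients()]).
#' @param heteroscedastic Gaussian only: model a separate residual
#'   variance per species-by-season cell.
#' @param log_transform fit on the natural log of the response.
#' @param weights column holding binomial weights (daily activity
#'   totals), required for the binomial family.
#' @param complete_flag optional logical column; rows where it is `FALSE`
#'   are excluded before fitting.
#' @return a `model_spec` object.
#' @export
model_spec <- function(response, family = c("gaussian", "binomial", "poisson"),
                       fixed = c("global", "season", "species", "null"),
                       scale = "identity", heteroscedastic = FALSE,
                       log_transform = FALSE, weights = NULL,
                       complete_flag = NULL) {
  family <- match.arg(family)
  fixed <- match.arg(fixed)
  if (!scale %in% DL_SCALES) stop("unknown scale tag: ", scale)
  if (family != "gaussian" && heteroscedastic) {
    stop("the per-cell variance structure applies to Gaussian fits only")
  }
  if (family == "binomial" && is.null(weights)) {
    stop("binomial fits need a weights column (daily totals)")
  }
  structure(list(response = response, family = family, fixed = fixed,
                 scale = scale, heteroscedastic = heteroscedastic,
                 log_transform = log_transform, weights = weights,
                 complete_flag = complete_flag),
            class = "model_spec")
}

# Built-in model specifications for the eight pipeline responses.
response_spec <- function(response, fixed = "global") {
  args <- switch(response,
    t_min = ,
    t_max = ,
    t_amplitude = list(family = "gaussian", scale = "identity",
                       heteroscedastic = TRUE, complete_flag = "complete_temp"),
    cumulative_cool_use = list(family = "gaussian", scale = "identity",
                               complete_flag = "complete_micro"),
    cool_hours = list(family = "poisson", scale = "response-rate",
                      complete_flag = "complete_micro"),
    travel_hours = list(family = "poisson", scale = "response-rate",
                        complete_flag = "complete_travel"),
    total_activity_24h = list(family = "gaussian", scale = "log",
                              log_transform = TRUE,
                              complete_flag = "complete_activity"),
    heat_activity_proportion = list(family = "binomial",
                                    scale = "response-proportion",
                                    weights = "activity_weight",
                                    complete_flag = "complete_activity"),
    stop("unknown response: ", response)
  )
  do.call(model_spec, c(list(response = response, fixed = fixed), args))
}

fixed_rhs <- function(fixed) {
  switch(fixed,
    global = "season * species",
    season = "season",
    species = "species",
    null = "1"
  )
}

canonical_term <- function(raw) {
  out <- rep(NA_character_, length(raw))
  out[raw == "(Intercept)"] <- "intercept"
  out[grepl("^season[^:]*$", raw)] <- "season"
  out[grepl("^species[^:]*$", raw)] <- "species"
  out[grepl(":", raw)] <- "interaction"
  out
}

#' Fit one generalized linear mixed model to the daily metrics
#'
#' Maximum-likelihood fit with crossed random intercepts for animal and
#' date. Gaussian fits may carry a per species-by-season residual
#' variance (dispersion) structure; binomial responses are daily
#' proportions weighted by daily activity totals; Poisson responses are
#' daily counts with a log link. Coefficients are returned on the spec's
#' reporting scale with Wald 95% confidence intervals (delta method for
#' the proportion-scale binomial effects).
#'
#' @param spec a [model_spec()].
#' @param data daily metrics table (see [assemble_daily()]).
#' @return a `mixed_fit` object: the underlying model plus the
#'   reporting-scale coefficient table, log-likelihood, parameter count
#'   `k` (fixed effects + variance/dispersion parameters), `n_obs`,
#'   `n_animals`, variance components and a convergence flag.
#' @export
fit_mixed <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  data <- droplevels_keep(data, spec)
  if (length(unique(data$season)) < 2) {
    stop("single-season data: both seasons are required to estimate ",
         "seasonal effects")
  }
  per_species <- table(unique(data[c("animal_id", "species")])$species)
  if (spec$fixed %in% c("global", "species") && any(per_species < 2)) {
    stop("need at least 2 animals per species, got: ",
         paste(names(per_species), per_species, collapse = ", "))
  }
  y <- data[[spec$response]]
  if (spec$family == "poisson" &&
      (any(y < 0) || any(abs(y - round(y)) > 1e-8))) {
    stop("Poisson response must be non-negative integer counts")
  }
  if (spec$family == "binomial" && (any(y < 0) || any(y > 1))) {
    stop("binomial response must be proportions in [0, 1]")
  }
  if (spec$log_transform) {
    if (any(y <= 0)) {
      data <- data[y > 0, , drop = FALSE]
      y <- data[[spec$response]]
    }
    data$.y <- log(y)
  } else {
    data$.y <- y
  }
  data$animal_id <- factor(data$animal_id)
  data$.date_f <- factor(data$date)
  form <- stats::as.formula(paste(
    ".y ~", fixed_rhs(spec$fixed), "+ (1 | animal_id) + (1 | .date_f)"))
  dispformula <- if (spec$heteroscedastic) ~ species * season else ~ 1
  fam <- switch(spec$family,
                gaussian = stats::gaussian(),
                poisson = stats::poisson(),
                binomial = stats::binomial())
  w <- if (!is.null(spec$weights)) round(data[[spec$weights]])
  if (spec$family == "gaussian") {
    # deterministic data (zero residual + random-effect variance) leaves
    # the mixed likelihood unbounded; the fixed effects then ARE the data
    ols <- stats::lm(stats::as.formula(paste(".y ~", fixed_rhs(spec$fixed))),
                     data = data)
    if (stats::sigma(ols) < 1e-8) {
      beta <- coef(ols)
      tab <- data.frame(term = canonical_term(names(beta)),
                        estimate = unname(beta), conf_low = unname(beta),
                        conf_high = unname(beta), scale = spec$scale)
      return(structure(list(
        model = ols, spec = spec, coefficients = tab,
        loglik = NA_real_, k = length(beta) + 3L, n_obs = nrow(data),
        n_animals = length(unique(data$animal_id)),
        variance_components = c(animal = 0, date = 0, residual = 0),
        family = spec$family, scale = spec$scale, converged = TRUE,
        pd_hessian = TRUE, degenerate = TRUE
      ), class = "mixed_fit"))
    }
  }
  fit <- withCallingHandlers(
    glmmTMB::glmmTMB(form, data = data, family = fam,
                     dispformula = dispformula, weights = w, REML = FALSE),
    warning = function(cond) invokeRestart("muffleWarning")
  )
  converged <- isTRUE(fit$fit$convergence == 0) && is.finite(as.numeric(logLik(fit)))
  # a non-PD Hessian usually marks a variance component on the zero
  # boundary; estimates remain usable but the flag is kept for inspection
  pd_hessian <- isTRUE(fit$sdr$pdHess)
  ll <- logLik(fit)
  vc <- glmmTMB::VarCorr(fit)$cond
  var_animal <- as.numeric(vc$animal_id %||% NA)
  var_date <- as.numeric(vc$.date_f %||% NA)
  var_resid <- residual_variance(fit, spec)
  out <- structure(list(
    model = fit, spec = spec,
    coefficients = report_coefficients(fit, spec),
    loglik = as.numeric(ll), k = attr(ll, "df"), n_obs = nrow(fit$frame),
    n_animals = length(unique(data$animal_id)),
    variance_components = c(animal = var_animal, date = var_date,
                            residual = var_resid),
    family = spec$family, scale = spec$scale, converged = converged,
    pd_hessian = pd_hessian
  ), class = "mixed_fit")
  if (!converged) {
    warning("model for ", spec$response, " (", spec$fixed,
            ") did not converge cleanly; inspect $model")
  }
  out
}

droplevels_keep <- function(data, spec) {
  keep <- !is.na(data[[spec$response]])
  if (!is.null(spec$complete_flag) && spec$complete_flag %in% names(data)) {
    keep <- keep & data[[spec$complete_flag]] %in% TRUE
  }
  if (!is.null(spec$weights)) {
    keep <- keep & !is.na(data[[spec$weights]]) & data[[spec$weights]] > 0
  }
  data <- data[keep, , drop = FALSE]
  data$season <- factor(data$season, levels = DL_SEASONS)
  data$species <- factor(data$species, levels = DL_SPECIES)
  droplevels(data, except = match(c("season", "species"), names(data)))
}

# family-appropriate residual variance for the R2 decomposition
residual_variance <- function(fit, spec) {
  switch(spec$family,
    gaussian = {
      if (spec$heteroscedastic) {
        mean(stats::predict(fit, type = "disp")^2)
      } else {
        stats::sigma(fit)^2
      }
    },
    poisson = {
      lambda_bar <- mean(stats::fitted(fit))
      log1p(1 / lambda_bar)
    },
    binomial = pi^2 / 3
  )
}

# Coefficients on the reporting scale with Wald 95% CIs.
report_coefficients <- function(fit, spec) {
  beta <- glmmTMB::fixef(fit)$cond
  V <- as.matrix(vcov(fit)$cond)
  terms <- canonical_term(names(beta))
  z <- qnorm(0.975)
  if (spec$scale %in% c("identity", "log")) {
    se <- sqrt(diag(V))
    tab <- data.frame(term = terms, estimate = unname(beta),
                      conf_low = unname(beta - z * se),
                      conf_high = unname(beta + z * se))
  } else if (spec$scale == "response-rate") {
    se <- sqrt(diag(V))
    tab <- data.frame(term = terms, estimate = exp(unname(beta)),
                      conf_low = exp(unname(beta - z * se)),
                      conf_high = exp(unname(beta + z * se)))
  } else if (spec$scale == "response-proportion") {
    # cell proportions from the logit-scale betas, then additive effects
    # on the proportion scale; delta-method CIs
    L <- cell_design(names(beta), terms)
    eta <- as.numeric(L %*% beta)
    p <- plogis(eta)
    Jp <- diag(p * (1 - p)) %*% L          # d cells / d beta
    C <- effect_contrasts(rownames(L))
    est <- as.numeric(C %*% p)
    G <- C %*% Jp
    se <- sqrt(pmax(diag(G %*% V %*% t(G)), 0))
    tab <- data.frame(term = rownames(C), estimate = est,
                      conf_low = est - z * se, conf_high = est + z * se)
  }
  tab$scale <- spec$scale
  rownames(tab) <- NULL
  tab
}

# link-scale design rows for the species-by-season cells present in a
# fixed-effect structure
cell_design <- function(raw_names, terms) {
  has_season <- "season" %in% terms
  has_species <- "species" %in% terms
  cells <- c("gemsbok.drought",
             if (has_season) "gemsbok.non-drought",
             if (has_species) "wildebeest.drought",
             if (has_season && has_species) "wildebeest.non-drought")
  L <- matrix(0, length(cells), length(raw_names),
              dimnames = list(cells, raw_names))
  L[, which(terms == "intercept")] <- 1
  for (cell in cells) {
    nd <- grepl("non-drought", cell)
    wb <- grepl("wildebeest", cell)
    if (nd) L[cell, which(terms == "season")] <- 1
    if (wb) L[cell, which(terms == "species")] <- 1
    if (nd && wb && "interaction" %in% terms) {
      L[cell, which(terms == "interaction")] <- 1
    }
  }
  L
}

# response-scale effect definitions (reference cell, simple differences,
# difference-in-differences) as contrasts over cell values
effect_contrasts <- function(cells) {
  rows <- list(intercept = setNames(as.numeric(cells == "gemsbok.drought"), cells))
  if ("gemsbok.non-drought" %in% cells) {
    v <- setNames(numeric(length(cells)), cells)
    v["gemsbok.non-drought"] <- 1; v["gemsbok.drought"] <- -1
    rows$season <- v
  }
  if ("wildebeest.drought" %in% cells) {
    v <- setNames(numeric(length(cells)), cells)
    v["wildebeest.drought"] <- 1; v["gemsbok.drought"] <- -1
    rows$species <- v
  }
  if ("wildebeest.non-drought" %in% cells) {
    v <- setNames(numeric(length(cells)), cells)
    v["wildebeest.non-drought"] <- 1; v["wildebeest.drought"] <- -1
    v["gemsbok.non-drought"] <- -1; v["gemsbok.drought"] <- 1
    rows$interaction <- v
  }
  do.call(rbind, rows)
}

#' Akaike's information criterion corrected for small samples
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`, undefined (an error)
#' when `n <= k + 1`. For a `mixed_fit`, `k` counts fixed effects plus
#' variance/dispersion parameters and `n` is the number of observation
#' rows.
#'
#' @param object a `mixed_fit`, or the log-likelihood as a number.
#' @param k,n parameter count and sample size (default method).
#' @param ... unused.
#' @return the AICc value.
#' @export
aicc <- function(object, ...) UseMethod("aicc")

#' @rdname aicc
#' @export
aicc.default <- function(object, k, n, ...) {
  loglik <- as.numeric(object)
  if (n <= k + 1) {
    stop("AICc undefined: n (", n, ") must exceed k + 1 (", k + 1, ")")
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc
#' @export
aicc.mixed_fit <- function(object, ...) {
  aicc(object$loglik, k = object$k, n = object$n_obs)
}

#' Akaike weights and the plausible set
#'
#' Normalized relative likelihoods `w_i = exp(-delta_i/2) / sum_j
#' exp(-delta_j/2)` with `delta_i = AICc_i - min AICc`; candidates with
#' `delta < 2` are flagged plausible.
#'
#' @param aiccs numeric vector of AICc values (at least one).
#' @return data frame: `aicc`, `delta_aicc`, `weight`, `plausible`.
#' @export
akaike_weights <- function(aiccs) {
  if (!length(aiccs)) stop("need at least one candidate model")
  delta <- aiccs - min(aiccs)
  w <- exp(-delta / 2)
  data.frame(aicc = aiccs, delta_aicc = delta, weight = w / sum(w),
             plausible = delta < 2)
}

#' Conditional R-squared for mixed models
#'
#' Proportion of variance explained jointly by the fixed and random
#' effects: `(var_fixed + var_random) / (var_fixed + var_random +
#' var_residual)`, with the family-appropriate residual variance on the
#' link scale for non-Gaussian fits (lognormal approximation
#' `log(1 + 1/mean fitted)` for Poisson, `pi^2/3` for logit binomial).
#'
#' @param x a `mixed_fit`, or the fixed-effect variance as a number.
#' @param var_random,var_residual summed random-effect variance and
#'   residual variance (numeric method).
#' @param ... unused.
#' @return R2 in [0, 1].
#' @export
conditional_r2 <- function(x, ...) UseMethod("conditional_r2")

#' @rdname conditional_r2
#' @export
conditional_r2.default <- function(x, var_random, var_residual, ...) {
  var_fixed <- as.numeric(x)
  total <- var_fixed + var_random + var_residual
  if (!is.finite(total) || total <= 0) {
    stop("conditional R2 undefined: total variance is zero")
  }
  (var_fixed + var_random) / total
}

#' @rdname conditional_r2
#' @export
conditional_r2.mixed_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) return(1)
  eta <- as.numeric(stats::model.matrix(
    stats::as.formula(paste("~", fixed_rhs(x$spec$fixed))),
    data = x$model$frame) %*% glmmTMB::fixef(x$model)$cond)
  var_f <- var(eta)
  vcs <- x$variance_components
  conditional_r2(var_f,
                 var_random = sum(vcs[c("animal", "date")], na.rm = TRUE),
                 var_residual = vcs[["residual"]])
}

#' Fit the candidate set and build the selection table
#'
#' Fits the global (season + species + interaction), season-only and
#' species-only candidates (optionally also the intercept-only null
#' model) and ranks them by AICc with Akaike weights, the plausible-set
#' flag (delta AICc < 2) and conditional R2.
#'
#' @param data daily metrics table.
#' @param response response name (one of the eight pipeline responses,
#'   or supply a full [model_spec()] via `spec_fn`).
#' @param include_null include the intercept-only candidate.
#' @param spec_fn function(response, fixed) returning a [model_spec()];
#'   defaults to the built-in pipeline specifications.
#' @return list: `fits` (named by structure), `selection` (data frame
#'   sorted by AICc).
#' @export
fit_candidates <- function(data, response, include_null = FALSE,
                           spec_fn = response_spec) {
  structures <- c("global", "season", "species", if (include_null) "null")
  fits <- lapply(structures, function(fx) fit_mixed(spec_fn(response, fx), data))
  names(fits) <- structures
  av <- vapply(fits, function(f) {
    tryCatch(aicc(f), error = function(e) NA_real_)
  }, numeric(1))
  ok <- is.finite(av)
  if (!any(ok)) stop("no candidate model for ", response, " yielded a finite AICc")
  sel <- data.frame(aicc = av, delta_aicc = NA_real_, weight = NA_real_,
                    plausible = NA)
  # candidates without a finite AICc (failed fits) are excluded from the
  # weight normalization but kept visible in the table
  sel[ok, ] <- akaike_weights(av[ok])
  sel <- cbind(model = structures, sel,
               conditional_r2 = vapply(fits, conditional_r2, numeric(1)),
               converged = vapply(fits, function(f) f$converged, logical(1)))
  sel <- sel[order(sel$aicc), ]
  rownames(sel) <- NULL
  list(fits = fits, selection = sel)
}

#' Estimated marginal means on the response scale
#'
#' Model-based predicted means per species-by-season cell (or per level
#' of a single factor for reduced models), averaged over the random
#' effects, with 95% confidence intervals. Uses delta-method
#' back-transformation to the response scale for log-link and logit-link
#' fits. For the log-transformed activity total the means remain on the
#' log scale (the model's response scale).
#'
#' @param fit a `mixed_fit`.
#' @param grid character vector of factors to cross (default both
#'   `species` and `season`); requesting a factor absent from the fit's
#'   fixed effects is an error.
#' @return data frame with the grid columns, `mean`, `conf_low`,
#'   `conf_high`.
#' @export
marginal_means <- function(fit, grid = c("species", "season")) {
  stopifnot(inherits(fit, "mixed_fit"))
  present <- c(if (fit$spec$fixed %in% c("global", "season")) "season",
               if (fit$spec$fixed %in% c("global", "species")) "species")
  missing <- setdiff(grid, present)
  if (length(missing)) {
    stop("factor(s) not in the fitted model: ", paste(missing, collapse = ", "))
  }
  emm <- emmeans::emmeans(fit$model,
                          stats::as.formula(paste("~", paste(grid, collapse = "*"))),
                          type = "response")
  out <- as.data.frame(emm)
  est_col <- intersect(c("response", "rate", "prob", "emmean"), names(out))[1]
  lo <- intersect(c("lower.CL", "asymp.LCL"), names(out))[1]
  hi <- intersect(c("upper.CL", "asymp.UCL"), names(out))[1]
  res <- out[, grid, drop = FALSE]
  res$mean <- out[[est_col]]
  res$conf_low <- out[[lo]]
  res$conf_high <- out[[hi]]
  res
}
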