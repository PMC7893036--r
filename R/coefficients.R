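# Published coefficient tables, cell-mean arithmetic and seasonal contrasts.
#
# A "coefficient table" throughout this package is a data frame with columns
#   response, term, estimate, conf_low, conf_high, scale
# where term is one of intercept / season / species / interaction, the
# reference levels are drought (season) and gemsbok (species), and `scale`
# says how the estimates combine into species-by-season cell means:
#   identity            additive, response units (e.g. degrees C)
#   log                 additive on the natural-log scale of the response
#   response-proportion additive on the proportion scale (0..1)
#   response-rate       multiplicative: intercept is a rate, the other
#                       terms are ratios (rate ratios)

DL_SCALES <- c("identity", "log", "response-proportion", "response-rate")
DL_TERMS <- c("intercept", "season", "species", "interaction")

#' Reference mixed-model coefficient estimates for the Kalahari drought study
#'
#' Published fixed-effect estimates (with 95% confidence intervals) from
#' generalized linear mixed models comparing daily bio-logger metrics of
#' gemsbok and wildebeest between a drought and a non-drought hot-dry
#' season. Reference levels are drought and gemsbok; `season` is the
#' non-drought effect, `species` the wildebeest effect, and `interaction`
#' the wildebeest-by-non-drought term. Estimates are on the scale given in
#' the `scale` column (see [cell_means()]). Responses whose most
#' parsimonious model dropped a term (the cool-hours model retains season
#' only) simply omit those rows.
#'
#' This table doubles as the default set of planted effects for the
#' synthetic-data generator, so that simulated studies reproduce the
#' published effect structure.
#'
#' @param response optional character vector; restrict to these responses.
#' @return a data frame with columns `response`, `term`, `estimate`,
#'   `conf_low`, `conf_high`, `scale`, `family`, `n_obs`, `n_animals`.
#' @export
study_coefficients <- function(response = NULL) {
  path <- system.file("extdata", "study_coefficients.csv",
                      package = "droughtlogger", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(response)) {
    missing <- setdiff(response, tab$response)
    if (length(missing)) {
      stop("unknown response(s): ", paste(missing, collapse = ", "))
    }
    tab <- tab[tab$response %in% response, , drop = FALSE]
  }
  tab
}

# Extract named term estimates from a one-response coefficient table,
# filling terms absent from the table with the scale's neutral element
# (0 additive, 1 multiplicative).
coef_terms <- function(coefs, scale = NULL) {
  stopifnot(is.data.frame(coefs), all(c("term", "estimate") %in% names(coefs)))
  if (length(unique(coefs$response %||% "x")) > 1L) {
    stop("coefficient table contains more than one response; subset first")
  }
  scale <- scale %||% unique(coefs$scale)
  if (length(scale) != 1L || !scale %in% DL_SCALES) {
    stop("coefficient table must carry a single valid scale tag (one of ",
         paste(DL_SCALES, collapse = ", "), ")")
  }
  bad <- setdiff(coefs$term, DL_TERMS)
  if (length(bad)) stop("unknown coefficient term(s): ", paste(bad, collapse = ", "))
  neutral <- if (scale == "response-rate") 1 else 0
  est <- setNames(rep(neutral, 4L), DL_TERMS)
  est[coefs$term] <- coefs$estimate
  attr(est, "scale") <- scale
  est
}

#' Species-by-season cell means from a tagged coefficient table
#'
#' Combines intercept, season, species and interaction estimates into the
#' four species-by-season cell means on the response scale, honouring the
#' table's scale tag: additive for `identity` and `response-proportion`,
#' additive-then-exponentiated for `log`, multiplicative for
#' `response-rate`. The reference cell (gemsbok, drought) is the intercept
#' (back-transformed for `log`).
#'
#' @param coefs a coefficient table for a single response (see
#'   [study_coefficients()]); terms absent from the table are treated as
#'   null effects.
#' @param scale override the table's scale tag.
#' @return a data frame with columns `species`, `season`, `mean`
#'   (response scale).
#' @export
cell_means <- function(coefs, scale = NULL) {
  est <- coef_terms(coefs, scale)
  scale <- attr(est, "scale")
  grid <- expand.grid(species = DL_SPECIES, season = DL_SEASONS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  w <- as.numeric(grid$species == "wildebeest")
  nd <- as.numeric(grid$season == "non-drought")
  grid$mean <- if (scale == "response-rate") {
    est["intercept"] * est["season"]^nd * est["species"]^w *
      est["interaction"]^(w * nd)
  } else {
    lp <- est["intercept"] + est["season"] * nd + est["species"] * w +
      est["interaction"] * w * nd
    if (scale == "log") exp(lp) else lp
  }
  grid
}

#' Seasonal change for one species on the response scale
#'
#' Computes the drought-minus-non-drought change implied by a coefficient
#' table, for one species at a time. On the identity and proportion scales
#' the change is additive (`-beta_season` for gemsbok,
#' `-(beta_season + beta_interaction)` for wildebeest, since the published
#' season effects are expressed for the non-drought season relative to the
#' drought reference). On the log and rate scales the change is the
#' multiplicative fractional change `exp(-(...)) - 1`.
#'
#' @param coefs single-response coefficient table with a scale tag.
#' @param species `"gemsbok"` or `"wildebeest"`.
#' @param direction `"drought_minus_nondrought"` (default) or
#'   `"nondrought_minus_drought"`; the contrast is antisymmetric on the
#'   additive scales and reciprocal-complement on the multiplicative ones.
#' @return a single number: additive change in response units, or
#'   fractional change for multiplicative scales (e.g. -0.362 for a 36.2%
#'   decline).
#' @export
seasonal_contrast <- function(coefs, species = c("gemsbok", "wildebeest"),
                              direction = c("drought_minus_nondrought",
                                            "nondrought_minus_drought")) {
  species <- match.arg(species)
  direction <- match.arg(direction)
  est <- coef_terms(coefs)
  scale <- attr(est, "scale")
  sgn <- if (direction == "drought_minus_nondrought") -1 else 1
  if (scale == "response-rate") {
    ratio <- est["season"] * if (species == "wildebeest") est["interaction"] else 1
    unname(ratio^sgn - 1)
  } else {
    delta <- est["season"] + if (species == "wildebeest") est["interaction"] else 0
    if (scale == "log") unname(exp(sgn * delta) - 1) else unname(sgn * delta)
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x
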