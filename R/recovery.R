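# Parameter-recovery report: planted truth vs fitted coefficients.

#' Compare fitted coefficients against planted truth
#'
#' For each fit, matches its reporting-scale coefficient table against
#' the planted coefficient values of the same response and reports the
#' bias (estimate minus planted value) and whether the planted value
#' falls inside the fit's 95% confidence interval. Responses fitted on
#' the rate scale are compared as rates/rate ratios, i.e. on the same
#' scale the planted table uses.
#'
#' @param truth a `planted_truth` object (from the generator).
#' @param fits a list of `mixed_fit` objects (possibly empty).
#' @return data frame: `response`, `term`, `planted`, `estimate`,
#'   `bias`, `conf_low`, `conf_high`, `covered`. Empty fits list gives an
#'   empty report.
#' @export
planted_recovery_table <- function(truth, fits) {
  stopifnot(inherits(truth, "planted_truth"))
  empty <- data.frame(response = character(), term = character(),
                      planted = numeric(), estimate = numeric(),
                      bias = numeric(), conf_low = numeric(),
                      conf_high = numeric(), covered = logical())
  if (!length(fits)) return(empty)
  planted <- truth$coefficients
  rows <- lapply(fits, function(fit) {
    stopifnot(inherits(fit, "mixed_fit"))
    resp <- fit$spec$response
    p <- planted[planted$response == resp, , drop = FALSE]
    if (!nrow(p)) {
      stop("no planted coefficients for response '", resp, "'")
    }
    if (!identical(unique(p$scale), fit$spec$scale)) {
      stop("scale mismatch for '", resp, "': planted ", unique(p$scale),
           ", fitted ", fit$spec$scale)
    }
    est <- fit$coefficients
    m <- merge(p[c("term", "estimate")], est, by = "term",
               suffixes = c("_planted", ""))
    data.frame(response = resp, term = m$term, planted = m$estimate_planted,
               estimate = m$estimate, bias = m$estimate - m$estimate_planted,
               conf_low = m$conf_low, conf_high = m$conf_high,
               covered = {
                 # numerical slack so degenerate (zero-width) intervals
                 # still cover a planted value they equal to rounding
                 eps <- 1e-8 * pmax(1, abs(m$estimate_planted))
                 m$estimate_planted >= m$conf_low - eps &
                   m$estimate_planted <= m$conf_high + eps
               })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
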