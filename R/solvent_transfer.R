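#' Cross-solvent pKa transfer regression
#'
#' Ordinary least squares of target-solvent pKa values on source-solvent
#' values, the basis for estimating pKa in 1,2-difluorobenzene from
#' acetonitrile or 1,2-dichloroethane data.  The residual standard deviation
#' uses n - 2 degrees of freedom and r^2 is the squared Pearson correlation.
#'
#' @param x source-solvent pKa values.
#' @param y target-solvent pKa values (same length; pairs with a missing
#'   member are dropped).
#' @param source,target solvent labels.
#' @param subset_tag optional compound-class tag describing the fitted subset
#'   (e.g. \code{"arylmalononitrile"}).
#' @return object of class \code{"transfer_fit"} wrapping the underlying
#'   \code{lm} fit, with \code{n}, \code{slope}, \code{intercept}, their
#'   standard errors, \code{sigma_resid}, \code{r2} and the fitted x-range.
#'   Methods: \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{residuals}, \code{plot}.
#' @examples
#' t3 <- load_fixture("table3")
#' fit <- fit_transfer(t3$pka_mecn, t3$pka_dfb, source = "MeCN", target = "1,2-DFB")
#' coef(fit)
#' @export
fit_transfer <- function(x, y, source = "source", target = "target",
                         subset_tag = "all") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("at least 3 complete pairs are required")
  if (stats::var(x) == 0) stop("degenerate predictor: zero variance in x")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # silence the perfect-fit warning
  structure(list(lm = fit, n = n,
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 slope_se = sm$coefficients[2, 2],
                 intercept_se = sm$coefficients[1, 2],
                 sigma_resid = sm$sigma, r2 = sm$r.squared,
                 source = source, target = target, subset_tag = subset_tag,
                 x_range = range(x)),
            class = "transfer_fit")
}

#' @export
print.transfer_fit <- function(x, ...) {
  cat(sprintf("pKa(%s) = %.2f(%.2f) pKa(%s) %+.2f(%.2f)   n = %d, sigma = %.2f, r2 = %.4f [%s]\n",
              x$target, x$slope, x$slope_se, x$source,
              x$intercept, x$intercept_se, x$n, x$sigma_resid, x$r2, x$subset_tag))
  invisible(x)
}

#' @export
summary.transfer_fit <- function(object, ...) {
  print(object)
  summary(object$lm, ...)
}

#' @export
coef.transfer_fit <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
residuals.transfer_fit <- function(object, ...) residuals(object$lm)

#' @export
plot.transfer_fit <- function(x, ...) {
  d <- x$lm$model
  plot(d$x, d$y, xlab = paste("pKa", x$source), ylab = paste("pKa", x$target), ...)
  abline(x$lm)
  invisible(x)
}

#' Predict target-solvent pKa values
#'
#' Applies the fitted transfer line; estimates are reported to one decimal
#' (half-away-from-zero) and flagged when the predictor lies outside the
#' fitted range (extrapolation).
#'
#' @param object a \code{\link{fit_transfer}} object.
#' @param newdata numeric vector of source-solvent pKa values (or a data
#'   frame with column \code{x}).
#' @param digits reporting precision (decimals); \code{NULL} for full
#'   precision.
#' @param ... unused.
#' @return data frame with \code{x}, \code{estimate}, \code{extrapolated}.
#' @export
predict.transfer_fit <- function(object, newdata, digits = 1, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else as.numeric(newdata)
  est <- object$slope * x + object$intercept
  if (!is.null(digits)) est <- round_half_up(est, digits)
  data.frame(x = x, estimate = est,
             extrapolated = x < object$x_range[1] | x > object$x_range[2])
}

#' Baseline uncertainty from dual-source estimates
#'
#' For compounds with estimates from both source solvents the individual
#' uncertainty is half the absolute difference between the two estimates plus
#' 0.1 pK units (for systematic effects).  The root mean square of these
#' individual uncertainties is the baseline uncertainty floor.
#'
#' @param est_a,est_b paired estimate vectors (rows with either member
#'   missing are ignored).
#' @param digits reporting precision for the returned baseline (default 1
#'   decimal); \code{NULL} for full precision.
#' @return RMS baseline uncertainty (pK units).
#' @export
compute_baseline <- function(est_a, est_b, digits = 1) {
  dual <- is.finite(est_a) & is.finite(est_b)
  if (!any(dual)) stop("no dual-source rows")
  u <- abs(est_a[dual] - est_b[dual]) / 2 + 0.1
  out <- sqrt(mean(u^2))
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Recommended pKa values with rule-based uncertainties
#'
#' For compounds estimated from both source solvents, the recommended value
#' is the average of the two estimates and the assigned uncertainty is the
#' larger of the baseline and the individual uncertainty (half the absolute
#' difference plus 0.1).  For single-source compounds the lone estimate is
#' taken with a conservative uncertainty of \code{u_single} (1.0 pK units).
#' Values and uncertainties are reported to one decimal,
#' half-away-from-zero.
#'
#' @param est_mecn,est_dce estimate vectors (NA where unavailable); names
#'   taken from \code{compound}.
#' @param compound optional compound identifiers.
#' @param baseline baseline uncertainty (pK units); default 0.5, the RMS over
#'   the dual-source rows of the packaged estimate table.  Pass the output of
#'   \code{\link{compute_baseline}} to recompute it from your own table.
#' @param u_single uncertainty assigned to single-source estimates.
#' @return data frame of class \code{"recommended_pka"}: \code{compound},
#'   \code{est_mecn}, \code{est_dce}, \code{recommended}, \code{u_assigned},
#'   \code{rule} (\code{"dual"} or \code{"single"}).
#' @examples
#' recommend_pka(34.3, 36.3)          # HBr row: 35.3 +- 1.1
#' recommend_pka(33.2, NA)            # single source: 33.2 +- 1.0
#' @export
recommend_pka <- function(est_mecn, est_dce, compound = NULL,
                          baseline = 0.5, u_single = 1.0) {
  if (!is.numeric(baseline) || baseline <= 0) stop("baseline must be positive")
  n <- max(length(est_mecn), length(est_dce))
  est_mecn <- rep_len(as.numeric(est_mecn), n)
  est_dce <- rep_len(as.numeric(est_dce), n)
  if (is.null(compound)) compound <- paste0("compound", seq_len(n))
  has_m <- is.finite(est_mecn); has_d <- is.finite(est_dce)
  if (any(!has_m & !has_d))
    stop("rows with no estimate at all: ",
         paste(compound[!has_m & !has_d], collapse = ", "))
  dual <- has_m & has_d
  rec <- ifelse(dual, (est_mecn + est_dce) / 2, ifelse(has_m, est_mecn, est_dce))
  u_ind <- abs(est_mecn - est_dce) / 2 + 0.1
  u <- ifelse(dual, pmax(baseline, round_half_up(u_ind, 1)), u_single)
  structure(data.frame(compound = compound,
                       est_mecn = est_mecn, est_dce = est_dce,
                       recommended = round_half_up(rec, 1),
                       u_assigned = round_half_up(u, 1),
                       rule = ifelse(dual, "dual", "single"),
                       stringsAsFactors = FALSE),
            class = c("recommended_pka", "data.frame"))
}

#' Offset-correct literature pKa values onto this scale
#'
#' Aligns a set of literature values with the present scale through one
#' reference compound measured in both: the offset is the difference of the
#' reference values (rounded to one decimal before application, matching the
#' published treatment), and each literature value is shifted by it.
#' Pairwise differences are preserved before the final per-value rounding.
#'
#' @param values numeric vector of literature pKa values.
#' @param reference_this reference compound's value on this scale.
#' @param reference_lit the same compound's literature value.
#' @return list: \code{offset} (1 decimal) and \code{corrected} (values plus
#'   offset, 1 decimal).
#' @examples
#' offset_correct(21.93, 41.0, 9.34)   # offset +31.7 -> 53.6
#' @export
offset_correct <- function(values, reference_this, reference_lit) {
  if (!is.finite(reference_this) || !is.finite(reference_lit))
    stop("both reference values are required")
  offset <- round_half_up(reference_this - reference_lit, 1)
  list(offset = offset, corrected = round_half_up(values + offset, 1))
}
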