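#' SAMI CoP P90 point estimate
#'
#' The South African Mining Industry Code of Practice classifies a HEG by a
#' point estimate of the 90th percentile of its current measurements.  The
#' code does not pin down the estimator, so three are offered:
#' \describe{
#'   \item{`empirical`}{the 90th sample percentile, linear interpolation
#'     (`quantile()` type 7, the R default);}
#'   \item{`normal`}{`AM + 1.2816 * SD`, assuming normally distributed
#'     concentrations;}
#'   \item{`lognormal`}{`GM * GSD^1.2816`, assuming lognormal
#'     concentrations.}
#' }
#' The default is `empirical`, the only estimator that uses no
#' distributional assumption.
#'
#' @param x Either a numeric vector of concentrations (mg/m3), a data frame
#'   of measurements, or (for the parametric methods only) a
#'   [heg_stats()] object.
#' @param method One of `"empirical"`, `"normal"`, `"lognormal"`.
#' @return The P90 point estimate, mg/m3.
#' @export
sami_p90 <- function(x, method = c("empirical", "normal", "lognormal")) {
  method <- match.arg(method)
  if (is.data.frame(x)) {
    x <- validate_measurements(x)$concentration
  }
  if (inherits(x, "heg_stats")) {
    st <- x
    if (method == "empirical") {
      stop("empirical P90 needs raw measurements, not summary statistics",
           call. = FALSE)
    }
  } else {
    if (!is.numeric(x) || length(x) < 2L) {
      stop("need at least 2 measurements", call. = FALSE)
    }
    if (any(x <= 0)) stop("concentrations must be > 0", call. = FALSE)
    st <- NULL
  }
  switch(method,
    empirical = unname(stats::quantile(x, 0.9, type = 7)),
    normal = {
      if (is.null(st)) st <- list(am = mean(x), sd = stats::sd(x))
      if (is.na(st$am) || is.na(st$sd)) {
        stop("normal method needs am and sd", call. = FALSE)
      }
      st$am + Z90 * st$sd
    },
    lognormal = {
      if (is.null(st)) {
        y <- log(x)
        st <- list(gm = exp(mean(y)), gsd = exp(stats::sd(y)))
      }
      st$gm * st$gsd^Z90
    })
}

#' Map a P90 estimate to a SAMI CoP exposure category
#'
#' Categories relative to the occupational exposure limit:
#' 1 ("very highly controlled") when `p90 < 0.1 * oel`;
#' 2 ("highly controlled") when `0.1 * oel <= p90 < 0.5 * oel`;
#' 3 ("adequately controlled") when `0.5 * oel <= p90 < oel`;
#' 4 ("poorly controlled") when `p90 >= oel`.
#' Lower bounds are inclusive, mirroring the code's ">=" conventions.
#'
#' @param p90 P90 estimate(s), mg/m3, `>= 0`.  Vectorised.
#' @param oel Occupational exposure limit, mg/m3 (default 2, respirable
#'   coal dust).
#' @return Integer category 1-4.
#' @export
sami_category <- function(p90, oel = DEFAULT_OEL) {
  if (any(!is.finite(p90)) || any(p90 < 0)) {
    stop("p90 must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(oel) || oel <= 0) stop("oel must be > 0", call. = FALSE)
  findInterval(p90, c(0.1, 0.5, 1) * oel) + 1L
}

#' SAMI CoP comparator for one HEG
#'
#' Convenience wrapper combining [sami_p90()] and [sami_category()].
#'
#' @inheritParams sami_p90
#' @inheritParams sami_category
#' @return A list with `p90`, `category` and `method`.
#' @export
sami_assess <- function(x, oel = DEFAULT_OEL,
                        method = c("empirical", "normal", "lognormal")) {
  method <- match.arg(method)
  p90 <- sami_p90(x, method)
  list(p90 = p90, category = sami_category(p90, oel), method = method)
}
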