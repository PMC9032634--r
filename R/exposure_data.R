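#' Validate a table of exposure measurements
#'
#' Checks that a data frame of worker-shift exposure measurements has the
#' required columns (`heg_id`, `year`, `concentration`, `campaign`), that
#' every concentration is strictly positive (the lognormal model has support
#' on the positive reals), that `heg_id` labels are non-empty and that
#' `campaign` is one of `"current"` or `"past"`.
#'
#' @param df A data frame of measurements.
#' @return The validated data frame with columns coerced to their canonical
#'   types (character, integer, double, character).
#' @export
validate_measurements <- function(df) {
  required <- c("heg_id", "year", "concentration", "campaign")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("measurement table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  conc <- as.numeric(df$concentration)
  bad <- which(!is.finite(conc) | conc <= 0)
  if (length(bad) > 0L) {
    stop("non-positive or non-finite concentration at row(s): ",
         paste(head(bad, 10L), collapse = ", "),
         " (lognormal support requires concentration > 0)", call. = FALSE)
  }
  heg <- as.character(df$heg_id)
  if (any(is.na(heg) | !nzchar(heg))) {
    stop("empty heg_id label(s) in measurement table", call. = FALSE)
  }
  campaign <- as.character(df$campaign)
  if (!all(campaign %in% c("current", "past"))) {
    stop("campaign must be 'current' or 'past'", call. = FALSE)
  }
  data.frame(heg_id = heg,
             year = as.integer(df$year),
             concentration = conc,
             campaign = campaign,
             stringsAsFactors = FALSE)
}

#' Read exposure measurements from CSV
#'
#' Reads a comma-separated file of personal exposure measurements, one
#' worker-shift measurement per row, with a header row naming the columns
#' `heg_id`, `year`, `concentration` (mg/m3, eight-hour time-weighted
#' average) and `campaign` (`"current"` or `"past"`).
#'
#' @param path Path to a CSV file.
#' @return A validated data frame of measurements.
#' @seealso [write_measurements()], [validate_measurements()]
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_measurements(df)
}

#' Write exposure measurements to CSV
#'
#' @param records A data frame of measurements (see [validate_measurements()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  records <- validate_measurements(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a set of HEG sufficient statistics
#'
#' The lognormal model depends on the data only through the sample size `n`,
#' the mean of the log-concentrations `ybar` and their sample standard
#' deviation `s_y` (denominator `n - 1`).  The geometric mean and geometric
#' standard deviation are the exponentials `gm = exp(ybar)`,
#' `gsd = exp(s_y)`.  Arithmetic summaries may be attached when known.
#'
#' @param n Integer sample size, at least 1 (at least 2 for `s_y` to carry
#'   information; a single observation must have `s_y = 0`).
#' @param ybar Mean of natural-log concentrations (log mg/m3).
#' @param s_y Sample standard deviation of log concentrations, `>= 0`.
#' @param am,sd Optional arithmetic mean and standard deviation (mg/m3).
#' @param heg_id,campaign Optional labels carried along for reporting.
#' @return An object of class `"heg_stats"`.
#' @export
heg_stats <- function(n, ybar, s_y, am = NA_real_, sd = NA_real_,
                      heg_id = NA_character_, campaign = NA_character_) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be an integer >= 1", call. = FALSE)
  if (!is.finite(ybar)) stop("ybar must be finite", call. = FALSE)
  if (!is.finite(s_y) || s_y < 0) stop("s_y must be >= 0", call. = FALSE)
  if (n == 1L && s_y != 0) stop("s_y is undefined for n = 1", call. = FALSE)
  structure(list(n = n, ybar = ybar, s_y = s_y,
                 gm = exp(ybar), gsd = exp(s_y),
                 am = am, sd = sd,
                 heg_id = heg_id, campaign = campaign),
            class = "heg_stats")
}

#' @export
print.heg_stats <- function(x, ...) {
  label <- if (!is.na(x$heg_id)) paste0(" [", x$heg_id,
    if (!is.na(x$campaign)) paste0(", ", x$campaign) else "", "]") else ""
  cat(sprintf("HEG sufficient statistics%s\n", label))
  cat(sprintf("  n = %d, GM = %.4g mg/m3, GSD = %.4g\n", x$n, x$gm, x$gsd))
  cat(sprintf("  ybar = %.5f, s_y = %.5f (natural logs)\n", x$ybar, x$s_y))
  if (!is.na(x$am)) cat(sprintf("  AM = %.4g, SD = %.4g mg/m3\n", x$am, x$sd))
  invisible(x)
}

#' Summarise one HEG's measurements
#'
#' Computes the sufficient statistics of a single homogeneous exposure
#' group's measurements for one campaign: sample size, arithmetic mean and
#' standard deviation, mean and sample standard deviation of the natural-log
#' concentrations, and the derived geometric mean and geometric standard
#' deviation.
#'
#' @param records A data frame of measurements for a single HEG and campaign.
#' @return An object of class `"heg_stats"`.
#' @examples
#' recs <- data.frame(heg_id = "X", year = 2020L,
#'                    concentration = c(1, 2, 4), campaign = "current")
#' summarize_heg(recs)  # GM = 2, GSD = exp(log(2)) = 2
#' @export
summarize_heg <- function(records) {
  records <- validate_measurements(records)
  if (length(unique(records$heg_id)) != 1L) {
    stop("records span more than one heg_id; summarise one HEG at a time",
         call. = FALSE)
  }
  if (length(unique(records$campaign)) != 1L) {
    stop("records span more than one campaign", call. = FALSE)
  }
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 measurements to estimate a spread",
                   call. = FALSE)
  y <- log(records$concentration)
  heg_stats(n = n,
            ybar = mean(y),
            s_y = stats::sd(y),
            am = mean(records$concentration),
            sd = stats::sd(records$concentration),
            heg_id = records$heg_id[1L],
            campaign = records$campaign[1L])
}

#' Reconstruct sufficient statistics from published GM/GSD summaries
#'
#' Monitoring reports typically print only `n`, the geometric mean and the
#' geometric standard deviation per group.  Because the lognormal posterior
#' depends on the data only through `(n, ybar, s_y)` these printed values
#' are enough to refit the model: `ybar = ln(gm)`, `s_y = ln(gsd)`.
#'
#' @param n Sample size, at least 2.
#' @param gm Geometric mean, mg/m3, `> 0`.
#' @param gsd Geometric standard deviation, `>= 1` (unitless).
#' @param heg_id,campaign Optional labels.
#' @return An object of class `"heg_stats"` with `am`/`sd` unset.
#' @export
stats_from_table <- function(n, gm, gsd,
                             heg_id = NA_character_,
                             campaign = NA_character_) {
  if (!is.finite(gm) || gm <= 0) stop("gm must be > 0", call. = FALSE)
  if (!is.finite(gsd) || gsd < 1) stop("gsd must be >= 1", call. = FALSE)
  heg_stats(n = n, ybar = log(gm), s_y = log(gsd),
            heg_id = heg_id, campaign = campaign)
}
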