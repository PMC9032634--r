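#' Default study configuration
#'
#' Configuration for [run_study()], overridable by a named list or a
#' YAML/JSON file.  Keys: `oel` (mg/m3), `k` (P95 cap multiplier, `Inf`
#' disables), `n0` and `prior_mode` (informative-prior elicitation),
#' `sami_method`, MCMC settings (`n_iter`, `n_warmup`, `n_chains`, `thin`,
#' `seed`), uniform-prior bounds (`mu_lower`, `mu_upper`, `sigma_lower`,
#' `sigma_upper`, on the log scale) and `fixture_seed` for the built-in
#' synthetic dataset.
#'
#' @return A named list of defaults.
#' @export
study_config <- function() {
  list(oel = DEFAULT_OEL,
       k = Inf,
       n0 = 5L,
       prior_mode = "moments",
       sami_method = "empirical",
       n_iter = 20000L,
       n_warmup = 2000L,
       n_chains = 4L,
       thin = 1L,
       seed = 12345L,
       mu_lower = log(0.001),
       mu_upper = log(100),
       sigma_lower = log(1.05),
       sigma_upper = log(10),
       fixture_seed = 20220407L)
}

merge_config <- function(config) {
  cfg <- study_config()
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path",
                             call. = FALSE)
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(config)] <- config
  if (is.null(cfg$k) || identical(cfg$k, "Inf")) cfg$k <- Inf
  cfg
}

#' Run the full compliance study
#'
#' For every HEG with current-campaign data: computes the SAMI CoP P90
#' comparator, fits the lognormal model by Gibbs sampling under the
#' non-informative uniform prior and (when historical data are available)
#' under the informative prior elicited from the HEG's past campaign, and
#' collects posterior summaries, exposure-category probabilities and
#' convergence diagnostics.  A HEG without past data gets only the
#' non-informative fit, with a warning.  Deterministic given the config
#' seeds.
#'
#' @param input `"fixtures"` for the built-in synthetic reproduction of the
#'   coal-dust study, a path to a measurement CSV, or a data frame of
#'   measurements.
#' @param config A named list overriding [study_config()] entries, or a
#'   path to a YAML/JSON file of them.
#' @return An object of class `"compliance_report"`: a list of data frames
#'   `sami`, `posterior`, `categories`, `diagnostics`, plus `meta`
#'   (config, per-fit seeds, bound-hit rates) and, in `draws`, the raw
#'   posterior draws per HEG and regime.
#' @examples
#' \donttest{
#' rep <- run_study("fixtures", config = list(n_iter = 2000, n_warmup = 500))
#' rep$sami
#' }
#' @export
run_study <- function(input = "fixtures", config = list()) {
  cfg <- merge_config(config)
  records <- if (is.data.frame(input)) {
    validate_measurements(input)
  } else if (identical(input, "fixtures")) {
    coal_fixtures(seed = cfg$fixture_seed)
  } else {
    read_measurements(input)
  }
  current <- records[records$campaign == "current", , drop = FALSE]
  past <- records[records$campaign == "past", , drop = FALSE]
  hegs <- sort(unique(current$heg_id))
  if (length(hegs) == 0L) stop("no current-campaign data", call. = FALSE)

  constraint <- p95_constraint(k = cfg$k, oel = cfg$oel)
  uprior <- uniform_prior(cfg$mu_lower, cfg$mu_upper,
                          cfg$sigma_lower, cfg$sigma_upper)

  sami_rows <- list(); post_rows <- list(); cat_rows <- list()
  diag_rows <- list(); draws_all <- list(); seeds <- list(); hits <- list()
  log_lines <- c(sprintf("study: %d HEG(s), OEL = %g mg/m3, k = %g, n0 = %d, prior_mode = %s",
                         length(hegs), cfg$oel, cfg$k, cfg$n0, cfg$prior_mode),
                 sprintf("mcmc: %d chains x %d draws (+%d warmup), seed %d",
                         cfg$n_chains, cfg$n_iter, cfg$n_warmup, cfg$seed))

  for (i in seq_along(hegs)) {
    h <- hegs[i]
    cur_h <- current[current$heg_id == h, , drop = FALSE]
    past_h <- past[past$heg_id == h, , drop = FALSE]
    st <- summarize_heg(cur_h)
    log_lines <- c(log_lines, sprintf(
      "%s current: n = %d, GM = %.3f, GSD = %.3f (ybar = %.4f, s_y = %.4f)",
      h, st$n, st$gm, st$gsd, st$ybar, st$s_y))

    sa <- sami_assess(cur_h, oel = cfg$oel, method = cfg$sami_method)
    sami_rows[[h]] <- data.frame(heg_id = h, p90 = sa$p90,
                                 category = sa$category, method = sa$method)

    regimes <- list(noninformative = uprior)
    if (nrow(past_h) >= 2L) {
      past_input <- if (cfg$prior_mode == "moments") summarize_heg(past_h) else past_h
      regimes$informative <- elicit_informative_prior(
        past_input, n0 = cfg$n0, mode = cfg$prior_mode,
        seed = cfg$seed + 7L * i, oel = cfg$oel, k = cfg$k,
        mu_lower = cfg$mu_lower,
        sigma2_lower = cfg$sigma_lower^2, sigma2_upper = cfg$sigma_upper^2)
      pr <- regimes$informative
      log_lines <- c(log_lines, sprintf(
        "%s informative prior: m0 = %.4f, v0 = %.4f, a0 = %.2f, b0 = %.4f",
        h, pr$m0, pr$v0, pr$a0, pr$b0))
    } else {
      warning(sprintf("%s: no historical data, informative fit skipped", h),
              call. = FALSE)
      log_lines <- c(log_lines, sprintf(
        "%s: no historical data, informative fit skipped", h))
    }

    for (regime in names(regimes)) {
      fit_seed <- cfg$seed + 100L * i + ifelse(regime == "informative", 1L, 0L)
      fit <- gibbs_lognormal(st, regimes[[regime]], constraint,
                             mcmc_config(n_iter = cfg$n_iter,
                                         n_warmup = cfg$n_warmup,
                                         n_chains = cfg$n_chains,
                                         seed = fit_seed, thin = cfg$thin))
      key <- paste(h, regime, sep = "|")
      draws_all[[key]] <- fit
      seeds[[key]] <- fit_seed
      hits[[key]] <- fit$bound_hits
      ps <- summarize_posterior(fit)
      ps <- cbind(heg_id = h, regime = regime, ps)
      post_rows[[key]] <- ps
      cp <- category_probabilities(fit, oel = cfg$oel)
      cat_rows[[key]] <- data.frame(heg_id = h, regime = regime,
                                    p1 = cp["p1"], p2 = cp["p2"],
                                    p3 = cp["p3"], p4 = cp["p4"],
                                    row.names = NULL)
      dg <- diagnose(fit)
      diag_rows[[key]] <- cbind(heg_id = h, regime = regime, dg)
      log_lines <- c(log_lines, sprintf(
        "%s %s: median GM = %.3f, P95 = %.3f, p4 = %.4f, max bound-hit = %.3f",
        h, regime, ps$median[ps$quantity == "gm"],
        ps$median[ps$quantity == "p95"], cp["p4"], max(fit$bound_hits)))
    }
  }

  structure(list(
    sami = do.call(rbind, c(sami_rows, list(make.row.names = FALSE))),
    posterior = do.call(rbind, c(post_rows, list(make.row.names = FALSE))),
    categories = do.call(rbind, c(cat_rows, list(make.row.names = FALSE))),
    diagnostics = do.call(rbind, c(diag_rows, list(make.row.names = FALSE))),
    draws = draws_all,
    meta = list(config = cfg, seeds = unlist(seeds),
                bound_hits = hits, log = log_lines)),
    class = "compliance_report")
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("Compliance report: %d HEG(s)\n", nrow(x$sami)))
  cat("\nSAMI CoP comparator:\n")
  print(x$sami, row.names = FALSE)
  p95 <- x$posterior[x$posterior$quantity == "p95", ]
  cat("\nPosterior P95 (median, 95% CrI):\n")
  print(p95[, c("heg_id", "regime", "median", "cri_lower", "cri_upper")],
        row.names = FALSE)
  cat("\nCategory-4 probabilities:\n")
  print(x$categories[, c("heg_id", "regime", "p4")], row.names = FALSE)
  bad <- x$diagnostics[!x$diagnostics$converged | !x$diagnostics$ess_ok, ]
  if (nrow(bad) > 0L) {
    cat("\nWARNING: diagnostics flagged:\n")
    print(bad, row.names = FALSE)
  } else {
    cat("\nAll fits pass R-hat <= 1.05 and ESS > 100 per chain.\n")
  }
  invisible(x)
}

#' Write report tables to disk
#'
#' Writes `sami.csv` (P90 comparator), `posterior_summary.csv` (medians and
#' 95% CrIs of GM/GSD/P95 per HEG and prior regime),
#' `category_probabilities.csv`, `diagnostics.csv` and a `run.log` with
#' per-HEG sufficient statistics, prior parameters and bound-hit rates.
#'
#' @param report A `"compliance_report"` from [run_study()].
#' @param outdir Output directory, created if absent.
#' @param draws Also persist the pooled posterior draws per fit as
#'   `draws_<heg>_<regime>.csv` (off by default; the files are large).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, outdir, draws = FALSE) {
  stopifnot(inherits(report, "compliance_report"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  wr <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
  }
  files <- c(wr(report$sami, "sami.csv"),
             wr(report$posterior, "posterior_summary.csv"),
             wr(report$categories, "category_probabilities.csv"),
             wr(report$diagnostics, "diagnostics.csv"))
  logp <- file.path(outdir, "run.log")
  writeLines(report$meta$log, logp)
  files <- c(files, logp)
  if (draws) {
    for (key in names(report$draws)) {
      nm <- paste0("draws_", gsub("[^A-Za-z0-9]+", "_", key), ".csv")
      files <- c(files, wr(as.data.frame(report$draws[[key]]), nm))
    }
  }
  invisible(files)
}

#' Plot posterior P95 medians and credible intervals per HEG
#'
#' Median and 95% CrI of the posterior P95 for each HEG, one point range
#' per prior regime, with a horizontal reference line at the exposure
#' limit.
#'
#' @param x A `"compliance_report"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.compliance_report <- function(x, ...) {
  p95 <- x$posterior[x$posterior$quantity == "p95", ]
  hegs <- unique(p95$heg_id)
  regimes <- unique(p95$regime)
  oel <- x$meta$config$oel
  offs <- seq(-0.15, 0.15, length.out = max(length(regimes), 2L))[seq_along(regimes)]
  xlim <- c(0.5, length(hegs) + 0.5)
  ylim <- c(0, max(p95$cri_upper) * 1.05)
  plot(NA, xlim = xlim, ylim = ylim, xaxt = "n",
       xlab = "", ylab = "P95 (mg/m3)",
       main = "Posterior P95: median and 95% CrI", ...)
  graphics::axis(1, at = seq_along(hegs), labels = hegs, las = 2)
  graphics::abline(h = oel, col = "red", lwd = 2)
  cols <- c("black", "blue", "darkgreen")
  for (j in seq_along(regimes)) {
    sub <- p95[p95$regime == regimes[j], ]
    at <- match(sub$heg_id, hegs) + offs[j]
    graphics::segments(at, sub$cri_lower, at, sub$cri_upper, col = cols[j])
    graphics::points(at, sub$median, pch = 19, col = cols[j])
  }
  graphics::legend("topright", legend = c(regimes, "OEL"),
                   col = c(cols[seq_along(regimes)], "red"),
                   pch = c(rep(19, length(regimes)), NA),
                   lty = c(rep(1, length(regimes)), 1), bty = "n")
  invisible(x)
}
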