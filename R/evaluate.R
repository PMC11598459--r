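#' Per-segment estimation error
#'
#' The fraction of incorrect gland-count candidates returned for one segment,
#' in percent: \code{Es = 100 * n_incorrect / n_total} over the deduplicated
#' candidate list. A failure segment (empty list) scores 100 (no estimation
#' was correct). A unique correct estimate scores 0; a two-candidate list
#' containing the truth scores 50.
#'
#' @param result A \code{"segment_result"} (or a plain integer vector of
#'   candidates).
#' @param true_nsg The true number of active glands.
#' @return Error percentage in \code{[0, 100]}.
#' @examples
#' segment_error(c(1L, 2L), 1) # 50
#' @export
segment_error <- function(result, true_nsg) {
  cands <- if (inherits(result, "segment_result")) result$nsg_candidates
           else as.integer(result)
  if (length(cands) == 0L) return(100)
  100 * sum(cands != true_nsg) / length(cands)
}

#' BCa bootstrap confidence interval for a mean
#'
#' Two-sided bias-corrected and accelerated (BCa) bootstrap interval for the
#' mean of a sample: the bias correction \code{z0} is the normal quantile of
#' the fraction of bootstrap means below the observed mean, and the
#' acceleration \code{a} comes from the jackknife skewness. Degenerate
#' samples (all values equal, or a bootstrap distribution without spread)
#' yield the point value as both endpoints.
#'
#' @param x Numeric sample.
#' @param n_boot Number of bootstrap replicates.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector \code{c(lower, upper)}.
#' @examples
#' set.seed(1)
#' bca_ci(rexp(40), n_boot = 2000)
#' @export
bca_ci <- function(x, n_boot = 1e4, conf = 0.95) {
  n <- length(x)
  theta <- mean(x)
  if (n < 2L || stats::sd(x) == 0) return(c(theta, theta))
  bm <- vapply(seq_len(n_boot),
               function(i) mean(x[sample.int(n, n, replace = TRUE)]), 0)
  prop <- mean(bm < theta) + 0.5 * mean(bm == theta)
  if (prop <= 0 || prop >= 1) return(c(theta, theta))
  z0 <- stats::qnorm(prop)
  jk <- vapply(seq_len(n), function(i) mean(x[-i]), 0)
  d <- mean(jk) - jk
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
  alpha <- (1 - conf) / 2
  z <- stats::qnorm(c(alpha, 1 - alpha))
  adj <- stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  stats::quantile(bm, probs = adj, names = FALSE, type = 6)
}

#' Scenario error rate with bootstrap confidence interval
#'
#' The error rate is the mean of the per-segment errors; its two-sided
#' confidence interval is computed with the BCa bootstrap ([bca_ci()]).
#'
#' @param errors Numeric vector of per-segment errors (percent).
#' @param n_boot Bootstrap replicates (default 1e4; raise to 1e5 for
#'   full-scale runs).
#' @param conf Confidence level.
#' @return A list with \code{rate}, \code{ci} (length-2 vector) and \code{n}.
#' @examples
#' error_rate(c(0, 0, 50, 100), n_boot = 500)
#' @export
error_rate <- function(errors, n_boot = 1e4, conf = 0.95) {
  if (length(errors) == 0L) stop("no per-segment errors supplied")
  list(rate = mean(errors), ci = bca_ci(errors, n_boot = n_boot, conf = conf),
       n = length(errors))
}

#' Run a full simulation/estimation scenario
#'
#' Simulates \code{n_signals} sensed signals for one combination of device
#' layout, cycle time and per-gland sweat rate, runs the estimator on every
#' segment, and aggregates per-gland-count and overall error rates, ambiguity
#' frequencies and failure frequencies. Fully reproducible from \code{seed}:
#' the global seed is split into per-signal substreams.
#'
#' @param layout A [device_layout()] (its \code{tcycle} and \code{Vmin} are
#'   the device parameters of the scenario).
#' @param gland A [gland_params()]; \code{gland$SRg} sets the sweat rate.
#' @param n_signals Number of simulated signals (study default 2000; reduced
#'   sizes reproduce the headline bounds).
#' @param duration_min Signal duration in minutes (default 15, five
#'   activity cycles).
#' @param nsg_range Gland counts sampled (default 1:11).
#' @param nsg_scheme \code{"stratified"} (equal signals per gland count, the
#'   default reporting mode for per-NSG curves) or \code{"uniform"}
#'   (uniform random draw).
#' @param seed Integer seed.
#' @param n_boot Bootstrap replicates for the confidence intervals.
#' @param include_failures Include failure segments (Es = 100) in the error
#'   aggregation (default TRUE); failure frequencies are always reported
#'   separately.
#' @return An object of class \code{"sg_scenario"}: list with \code{config},
#'   \code{segments} (per-segment table: \code{signal}, \code{segment},
#'   \code{true_nsg}, \code{status}, \code{es}, \code{type1..3}),
#'   \code{by_nsg} (per-gland-count table with error rates, CIs, ambiguity
#'   and failure frequencies) and \code{overall}.
#' @examples
#' sc <- run_scenario(device_layout("D"), gland_params(0.4), n_signals = 4,
#'                    nsg_range = 1:2, seed = 1, n_boot = 200)
#' sc$overall$rate
#' @export
run_scenario <- function(layout, gland = gland_params(), n_signals = 100L,
                         duration_min = 15, nsg_range = 1:11,
                         nsg_scheme = c("stratified", "uniform"), seed = 1L,
                         n_boot = 1e4, include_failures = TRUE) {
  stopifnot(inherits(layout, "device_layout"), inherits(gland, "gland_params"))
  nsg_scheme <- match.arg(nsg_scheme)
  n_signals <- as.integer(n_signals)
  set.seed(seed)
  nsg_draw <- if (nsg_scheme == "stratified")
    rep_len(rep(nsg_range, ceiling(n_signals / length(nsg_range))), n_signals)
  else sample(nsg_range, n_signals, replace = TRUE)
  sig_seeds <- sample.int(.Machine$integer.max - 1L, n_signals)

  rows <- vector("list", n_signals)
  for (i in seq_len(n_signals)) {
    sig <- simulate_signal(layout, nsg_draw[i], gland = gland,
                           duration_min = duration_min, seed = sig_seeds[i])
    fit <- estimate_nsg(sig, layout, gland = gland)
    rs <- fit$results
    rows[[i]] <- data.frame(
      signal = i, segment = seq_along(rs), true_nsg = nsg_draw[i],
      status = vapply(rs, `[[`, "", "status"),
      failure_step = vapply(rs, `[[`, "", "failure_step"),
      es = vapply(rs, segment_error, 0, true_nsg = nsg_draw[i]),
      type1 = vapply(rs, function(r) 1L %in% r$ambiguity_types, NA),
      type2 = vapply(rs, function(r) 2L %in% r$ambiguity_types, NA),
      type3 = vapply(rs, function(r) 3L %in% r$ambiguity_types, NA))
  }
  segdf <- do.call(rbind, rows)

  agg <- function(d) {
    use <- if (include_failures) d else d[d$status != "failure", , drop = FALSE]
    if (nrow(use) == 0L)
      return(data.frame(n_segments = nrow(d), error_rate_pct = 100,
                        ci_lo = 100, ci_hi = 100,
                        freq_type1 = 0, freq_type2 = 0, freq_type3 = 0,
                        freq_failure = mean(d$status == "failure")))
    er <- error_rate(use$es, n_boot = n_boot)
    data.frame(n_segments = nrow(d), error_rate_pct = er$rate,
               ci_lo = er$ci[1], ci_hi = er$ci[2],
               freq_type1 = mean(d$type1), freq_type2 = mean(d$type2),
               freq_type3 = mean(d$type3),
               freq_failure = mean(d$status == "failure"))
  }
  by_nsg <- do.call(rbind, lapply(sort(unique(segdf$true_nsg)), function(k) {
    cbind(nsg = k, agg(segdf[segdf$true_nsg == k, , drop = FALSE]))
  }))
  overall <- error_rate(if (include_failures) segdf$es
                        else segdf$es[segdf$status != "failure"],
                        n_boot = n_boot)

  structure(list(config = list(layout = layout$name, tcycle = layout$tcycle,
                               Vmin = layout$Vmin, SRg = gland$SRg,
                               nd_nominal = gland$SRg / layout$Vmin,
                               n_signals = n_signals,
                               duration_min = duration_min,
                               nsg_scheme = nsg_scheme, seed = seed,
                               n_boot = n_boot,
                               include_failures = include_failures),
                 segments = segdf, by_nsg = by_nsg, overall = overall),
            class = "sg_scenario")
}

#' @export
print.sg_scenario <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Scenario: layout %s, tcycle %g s, SRg %g nL/tAP (Nd ~ %g), %d signals\n",
              cfg$layout, cfg$tcycle, cfg$SRg, cfg$nd_nominal, cfg$n_signals))
  cat(sprintf("Overall error rate: %.2f%% (95%% CI %.2f-%.2f, %d segments)\n",
              x$overall$rate, x$overall$ci[1], x$overall$ci[2], x$overall$n))
  print(x$by_nsg, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.sg_scenario <- function(object, ...) {
  print(object, ...)
  invisible(object$by_nsg)
}

#' @export
plot.sg_scenario <- function(x, ...) {
  b <- x$by_nsg
  graphics::plot(b$nsg, b$error_rate_pct, type = "b", pch = 16,
                 ylim = range(0, b$ci_hi, b$error_rate_pct),
                 xlab = "number of active sweat glands",
                 ylab = "error rate (%)",
                 main = sprintf("Layout %s, tcycle %g s, Nd ~ %g",
                                x$config$layout, x$config$tcycle,
                                x$config$nd_nominal), ...)
  graphics::arrows(b$nsg, b$ci_lo, b$nsg, b$ci_hi, angle = 90, code = 3,
                   length = 0.04)
  invisible(x)
}

#' Results table of one or more scenarios
#'
#' Flattens scenario reports into the tabular text schema used by the file
#' interface: one row per (layout, tcycle, Nd, NSG).
#'
#' @param ... \code{"sg_scenario"} objects (or a single list of them).
#' @return A data frame with columns \code{layout}, \code{tcycle},
#'   \code{nd}, \code{nsg}, \code{n_segments}, \code{error_rate_pct},
#'   \code{ci_lo}, \code{ci_hi}, \code{freq_type1..3}, \code{freq_failure}.
#' @export
scenario_table <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "sg_scenario")) xs <- xs[[1L]]
  do.call(rbind, lapply(xs, function(s) {
    cbind(data.frame(layout = s$config$layout, tcycle = s$config$tcycle,
                     nd = s$config$nd_nominal), s$by_nsg)
  }))
}

#' Write / read a results table as tab-separated text
#'
#' @param table A data frame from [scenario_table()].
#' @param file Path.
#' @return \code{write_results}: \code{file} invisibly;
#'   \code{read_results}: the data frame.
#' @export
write_results <- function(table, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# sweatsense results v1", con)
  utils::write.table(table, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_results
#' @export
read_results <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t", skip = 1L)
}
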