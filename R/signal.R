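#' Synthesize the sensed pulse train from per-gland release streams
#'
#' Each release event arrives at the volumetric sensor after a pure
#' deterministic delay of \code{dtravel * tcycle}; droplets from different
#' glands arriving at the identical activation-grid timestamp merge into one
#' sensed droplet whose volume is the sum. Timing is exact: events carry an
#' integer activation-grid index (\code{tick}), and the transport shift adds
#' the integer \code{dtravel}.
#'
#' @param layout A [device_layout()].
#' @param placement A [assign_glands()] placement covering every gland.
#' @param streams A list of release-event data frames (one per gland, as
#'   returned by [simulate_gland()]), named or ordered by \code{gland_id}.
#' @return An object of class \code{"sweat_signal"}: a data frame with
#'   columns \code{tick}, \code{time_s}, \code{volume_nL}, plus attributes
#'   \code{tcycle}, \code{layout} and \code{sources} (a list giving, for each
#'   sensed droplet, the contributing gland ids; ground truth for evaluation
#'   only, never consulted by the estimator).
#' @examples
#' lay <- device_layout("D", tcycle = 0.5)
#' pl <- assign_glands(lay, 2, seed = 1)
#' ev <- simulate_gland(gland_params(0.4), n_cycles = 2, tcycle = 0.5)
#' sig <- synthesize_signal(lay, pl, list(ev, ev))
#' @export
synthesize_signal <- function(layout, placement, streams) {
  stopifnot(inherits(layout, "device_layout"))
  if (nrow(placement) != length(streams))
    stop("each gland in the placement needs exactly one event stream")
  arr_tick <- integer(0); arr_vol <- numeric(0); arr_gland <- integer(0)
  for (g in seq_len(nrow(placement))) {
    ev <- streams[[g]]
    if (is.null(ev) || !is.data.frame(ev))
      stop("gland ", placement$gland_id[g], " has no event stream")
    if (nrow(ev) == 0L) next
    arr_tick <- c(arr_tick, ev$tick + placement$dtravel[g])
    arr_vol <- c(arr_vol, ev$volume_nL)
    arr_gland <- c(arr_gland, rep.int(placement$gland_id[g], nrow(ev)))
  }
  ticks <- sort(unique(arr_tick))
  idx <- match(arr_tick, ticks)
  vol <- vapply(seq_along(ticks), function(i) sum(arr_vol[idx == i]), 0)
  sources <- lapply(seq_along(ticks), function(i) sort(arr_gland[idx == i]))
  out <- data.frame(tick = ticks, time_s = ticks * layout$tcycle,
                    volume_nL = vol)
  structure(out, tcycle = layout$tcycle, layout = layout, sources = sources,
            class = c("sweat_signal", "data.frame"))
}

#' Simulate a complete sensed signal
#'
#' End-to-end generator: places \code{n_glands} synchronized glands on random
#' collection sites of \code{layout}, simulates their pulsatile droplet
#' release over \code{duration_min} minutes, transports and merges the
#' droplets, and returns the sensed pulse train with its ground truth
#' attached.
#'
#' @param layout A [device_layout()].
#' @param n_glands Number of active glands.
#' @param gland A [gland_params()] object.
#' @param duration_min Signal duration in minutes (default 15, i.e. five
#'   3-minute activity cycles with the default timing).
#' @param seed Optional integer seed (placement is the only random element).
#' @param Vres0 Initial residual volume per gland (nL).
#' @return A \code{"sweat_signal"} with additional attributes \code{truth}
#'   (list: \code{n_glands}, \code{placement}, \code{release}, \code{gland},
#'   \code{n_cycles}) for evaluation.
#' @examples
#' sig <- simulate_signal(device_layout("D"), 3, gland_params(0.4), seed = 7)
#' @export
simulate_signal <- function(layout, n_glands, gland = gland_params(),
                            duration_min = 15, seed = NULL, Vres0 = 0) {
  stopifnot(inherits(layout, "device_layout"), inherits(gland, "gland_params"))
  n_cycles <- max(1L, as.integer(floor(duration_min * 60 / (gland$tAP + gland$tRP))))
  placement <- assign_glands(layout, n_glands, seed = seed)
  # synchronized identical glands share one release stream
  ev <- simulate_gland(gland, n_cycles = n_cycles, tcycle = layout$tcycle,
                       Vmin = layout$Vmin, Vres0 = Vres0)
  streams <- lapply(seq_len(n_glands), function(g) {
    e <- ev; e$gland_id <- as.integer(g); e
  })
  sig <- synthesize_signal(layout, placement, streams)
  attr(sig, "truth") <- list(n_glands = as.integer(n_glands),
                             placement = placement, release = ev,
                             gland = gland, n_cycles = n_cycles)
  sig
}

#' @export
print.sweat_signal <- function(x, ...) {
  cat(sprintf("Sensed sweat signal: %d droplet arrivals over %.1f s (tcycle %g s)\n",
              nrow(x), if (nrow(x)) max(x$time_s) else 0, attr(x, "tcycle")))
  tr <- attr(x, "truth")
  if (!is.null(tr))
    cat(sprintf("  ground truth: %d gland(s), %d activity cycle(s)\n",
                tr$n_glands, tr$n_cycles))
  print.data.frame(utils::head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat("  ...", nrow(x) - 8L, "more arrivals\n")
  invisible(x)
}

#' @export
plot.sweat_signal <- function(x, ...) {
  graphics::plot(x$time_s, x$volume_nL, type = "h", lwd = 2,
                 xlab = "time (s)", ylab = "sensed droplet volume (nL)",
                 main = "Discrete sweat-sensing pulse train", ...)
  invisible(x)
}

#' Simulate sensed signals from a device layout
#'
#' \code{simulate()} method for \code{"device_layout"}: draws \code{nsim}
#' signals with the stated number of glands (or one draw per element of
#' \code{n_glands}).
#'
#' @param object A [device_layout()].
#' @param nsim Number of signals.
#' @param seed Optional integer seed.
#' @param n_glands Gland count, recycled to length \code{nsim}.
#' @param gland A [gland_params()].
#' @param duration_min Signal duration in minutes.
#' @param ... Unused.
#' @return A list of \code{"sweat_signal"} objects.
#' @export
simulate.device_layout <- function(object, nsim = 1, seed = NULL,
                                   n_glands = 1L, gland = gland_params(),
                                   duration_min = 15, ...) {
  if (!is.null(seed)) set.seed(seed)
  n_glands <- rep_len(n_glands, nsim)
  seeds <- sample.int(.Machine$integer.max - 1L, nsim)
  lapply(seq_len(nsim), function(i)
    simulate_signal(object, n_glands[i], gland = gland,
                    duration_min = duration_min, seed = seeds[i]))
}

#' Write / read a sensed signal as tab-separated text
#'
#' The signal file holds the columns \code{tick}, \code{time_s},
#' \code{volume_nL} behind a versioned header line. The optional ground-truth
#' sidecar (\code{truth_file}) stores the gland placement and release times;
#' it is written separately so that the estimation path never touches it.
#'
#' @param signal A \code{"sweat_signal"}.
#' @param file Path of the signal file.
#' @param truth_file Optional path for the ground-truth sidecar.
#' @return \code{write_signal}: \code{file}, invisibly. \code{read_signal}:
#'   a \code{"sweat_signal"}.
#' @export
write_signal <- function(signal, file, truth_file = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# sweatsense signal v1 tcycle=%.17g", attr(signal, "tcycle")), con)
  utils::write.table(as.data.frame(signal)[, c("tick", "time_s", "volume_nL")],
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  tr <- attr(signal, "truth")
  if (!is.null(truth_file)) {
    if (is.null(tr)) stop("signal carries no ground truth to write")
    tcon <- file(truth_file, "w")
    writeLines(c(sprintf("# sweatsense truth v1 n_glands=%d n_cycles=%d SRg=%.17g tAP=%.17g tRP=%.17g",
                         tr$n_glands, tr$n_cycles, tr$gland$SRg, tr$gland$tAP,
                         tr$gland$tRP)), tcon)
    utils::write.table(tr$placement, tcon, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    close(tcon)
  }
  invisible(file)
}

#' @rdname write_signal
#' @param layout A [device_layout()] to attach on read (its \code{tcycle}
#'   must match the file header).
#' @export
read_signal <- function(file, layout) {
  stopifnot(inherits(layout, "device_layout"))
  header <- readLines(file, n = 1L)
  if (!grepl("^# sweatsense signal v1", header))
    stop("'", file, "' is not a sweatsense signal file (line 1: ", header, ")")
  tc <- as.numeric(sub(".*tcycle=", "", header))
  if (abs(tc - layout$tcycle) > 1e-12)
    stop("signal tcycle (", tc, ") does not match layout tcycle (",
         layout$tcycle, ")")
  df <- utils::read.table(file, header = TRUE, sep = "\t", skip = 1L)
  need <- c("tick", "time_s", "volume_nL")
  if (!all(need %in% names(df)))
    stop("'", file, "': expected columns ", paste(need, collapse = ", "))
  structure(df[need], tcycle = tc, layout = layout,
            class = c("sweat_signal", "data.frame"))
}

#' Write / read a device layout as YAML
#'
#' @param layout A [device_layout()].
#' @param file Path of the YAML file.
#' @return \code{write_layout}: \code{file}, invisibly; \code{read_layout}:
#'   a \code{"device_layout"}.
#' @export
write_layout <- function(layout, file) {
  stopifnot(inherits(layout, "device_layout"))
  yaml::write_yaml(list(name = layout$name,
                        n_distinct = length(layout$distinct_dtravel),
                        occurrences = layout$occurrences,
                        tcycle = layout$tcycle, Vmin = layout$Vmin,
                        Nleads = layout$Nleads), file)
  invisible(file)
}

#' @rdname write_layout
#' @export
read_layout <- function(file) {
  y <- yaml::read_yaml(file)
  device_layout(name = y$name, tcycle = y$tcycle, Vmin = y$Vmin,
                n_distinct = y$n_distinct, occurrences = y$occurrences,
                Nleads = y$Nleads)
}
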