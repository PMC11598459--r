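#' Maximum segmentation window duration for a layout
#'
#' The window cap equals the active-period duration plus the spread of travel
#' times of the layout (maximum minus minimum travel time): all droplets
#' produced during one active period reach the sensor within this span.
#'
#' @param layout A [device_layout()].
#' @param gland A [gland_params()] supplying \code{tAP}.
#' @return Window cap in seconds.
#' @export
segment_window_cap <- function(layout, gland = gland_params()) {
  d <- layout$distinct_dtravel
  gland$tAP + (max(d) - min(d)) * layout$tcycle
}

#' Segment a sensed signal into activity-cycle windows
#'
#' Splits the pulse train into windows, each expected to contain the droplets
#' of one active period. A window opens at the first arrival after a quiet
#' gap and collects every arrival within the window cap
#' ([segment_window_cap()]) of its opening time.
#'
#' Segmentation is infeasible when the window cap reaches the activity-cycle
#' period (\code{tAP + tRP}): windows from successive active periods then
#' necessarily overlap and droplets of one period can be attributed to the
#' next. In that case the whole signal is flagged as a segmentation failure
#' (the signal's expected segments are all reported as failures downstream).
#' With the tabulated travel-distance ranges this occurs for layout A at
#' every cycle time in 0.25--0.75 s.
#'
#' @param signal A \code{"sweat_signal"}.
#' @param layout A [device_layout()]; defaults to the layout attached to the
#'   signal.
#' @param gland A [gland_params()] supplying the active/rest timing.
#' @return A list of segments, each a data frame (\code{tick}, \code{time_s},
#'   \code{volume_nL}) with attributes \code{start_s} and \code{end_s}; the
#'   list carries attribute \code{failure = "segmentation"} (and length 0)
#'   when segmentation is infeasible for the layout.
#' @examples
#' sig <- simulate_signal(device_layout("D"), 2, gland_params(0.4), seed = 1)
#' length(segment_signal(sig)) # 5 windows in a 15-min signal
#' @export
segment_signal <- function(signal, layout = attr(signal, "layout"),
                           gland = gland_params()) {
  stopifnot(inherits(layout, "device_layout"))
  cap <- segment_window_cap(layout, gland)
  if (cap >= gland$tAP + gland$tRP) {
    warning("segmentation infeasible for layout ", layout$name,
            ": window cap (", cap, " s) reaches the activity-cycle period (",
            gland$tAP + gland$tRP, " s)")
    return(structure(list(), failure = "segmentation"))
  }
  if (nrow(signal) == 0L) return(list())
  df <- as.data.frame(signal)[order(signal$tick), , drop = FALSE]
  cap_ticks <- floor(cap / layout$tcycle + 1e-9)
  starts <- integer(0)
  cur_start <- df$tick[1L]
  starts <- cur_start
  grp <- integer(nrow(df))
  grp[1L] <- 1L
  for (i in seq_len(nrow(df))[-1L]) {
    if (df$tick[i] - cur_start > cap_ticks) {
      cur_start <- df$tick[i]
      starts <- c(starts, cur_start)
    }
    grp[i] <- length(starts)
  }
  lapply(seq_along(starts), function(w) {
    seg <- df[grp == w, , drop = FALSE]
    rownames(seg) <- NULL
    attr(seg, "start_s") <- starts[w] * layout$tcycle
    attr(seg, "end_s") <- starts[w] * layout$tcycle + cap
    seg
  })
}

#' Recover admissible non-merged droplet volumes for a segment
#'
#' Every sensed droplet is assumed to be an integer multiple of the (common)
#' non-merged droplet volume. A candidate volume is admissible when it lies
#' in the physical range \code{[Vmin, Vmin + SRg_max/tAP * tcycle)} and every
#' event volume divided by it is an integer within relative tolerance
#' \code{tol}. Candidates are enumerated exactly as the divisors
#' \code{v_min_event / m} of the smallest event volume, so no admissible
#' value can be missed. More than one admissible volume marks a type-1
#' (ambiguous quantization) segment; none marks a quantization failure.
#'
#' @param segment One segment from [segment_signal()] (or any data frame with
#'   \code{tick} and \code{volume_nL}).
#' @param Vmin Minimum transportable droplet volume (nL).
#' @param tcycle Tile activation interval (s).
#' @param srg_max Upper bound of the per-gland sweat rate used for the
#'   volume range, in nL/tAP (default 1, the top of the tabulated range).
#' @param tAP Active-period duration (s).
#' @param tol Relative tolerance for integer multiplicity.
#' @return A list of quantizations, each a list with \code{vsg_hat} (nL) and
#'   \code{mult} (integer multiplicities per event); empty list on failure.
#' @examples
#' seg <- data.frame(tick = c(0L, 30L), time_s = c(0, 15), volume_nL = c(0.2, 0.2))
#' quantize_segment(seg, Vmin = 0.2, tcycle = 0.5)
#' @export
quantize_segment <- function(segment, Vmin = 0.2, tcycle = 0.5, srg_max = 1,
                             tAP = 30, tol = 1e-6) {
  vols <- segment$volume_nL
  if (length(vols) == 0L) return(list())
  if (any(vols < Vmin - 1e-9))
    stop("event volume below Vmin: the transport system cannot move it")
  v_upper <- Vmin + srg_max / tAP * tcycle
  v0 <- min(vols)
  m_max <- floor(v0 / Vmin + tol)
  out <- list()
  for (m in seq_len(max(m_max, 0L))) {
    cand <- v0 / m
    if (cand < Vmin - 1e-12 || cand >= v_upper - 1e-12) next
    r <- vols / cand
    k <- round(r)
    if (all(k >= 1) && all(abs(r - k) <= tol * pmax(1, r)))
      out[[length(out) + 1L]] <- list(vsg_hat = cand, mult = as.integer(k))
  }
  out
}

#' Candidate inter-droplet intervals for a segment
#'
#' The spacings searched by the decomposition are restricted to the time
#' differences between the segment's first droplet and each later droplet,
#' filtered to \code{[tcycle, tAP/2]}: at least two droplets per active
#' period (so a per-gland pattern exists) and at most one droplet per tile
#' activation.
#'
#' @param segment A segment data frame with columns \code{tick},
#'   \code{time_s}.
#' @param tAP Active-period duration (s).
#' @param tcycle Tile activation interval (s).
#' @return Numeric vector of candidate spacings in seconds (possibly empty).
#' @examples
#' seg <- data.frame(tick = c(0, 12, 24, 36, 48), time_s = c(0, 6, 12, 18, 24))
#' candidate_intervals(seg, tAP = 30, tcycle = 0.5) # 6 and 12 s
#' @export
candidate_intervals <- function(segment, tAP = 30, tcycle = 0.5) {
  t <- sort(segment$time_s)
  if (length(t) < 2L) return(numeric(0))
  d <- unique(t[-1L] - t[1L])
  sort(d[d >= tcycle - 1e-9 & d <= tAP / 2 + 1e-9])
}
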