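#' Sweat-gland parameters
#'
#' Bundle the physiological parameters of an eccrine sweat gland used by the
#' pulsatile generation model: the volume secreted during one active period
#' (\code{SRg}), the active-period duration (\code{tAP}) and the resting-period
#' duration (\code{tRP}). One activity cycle lasts \code{tAP + tRP} seconds.
#'
#' @param SRg Sweat volume secreted per active period, in nL/tAP.
#'   Physiological range considered here is 0.4--1 nL/tAP, i.e. nominally
#'   2--5 transportable droplets per active period at \code{Vmin} = 0.2 nL.
#' @param tAP Active-period duration in seconds (default 30).
#' @param tRP Resting-period duration in seconds (default 150).
#' @return An object of class \code{"gland_params"}.
#' @examples
#' gland_params(0.7)
#' @export
gland_params <- function(SRg = 0.4, tAP = 30, tRP = 150) {
  if (!is.numeric(SRg) || length(SRg) != 1L || !is.finite(SRg) || SRg <= 0)
    stop("'SRg' must be a single positive number (nL per active period)")
  if (!is.numeric(tAP) || length(tAP) != 1L || tAP <= 0)
    stop("'tAP' must be a single positive number of seconds")
  if (!is.numeric(tRP) || length(tRP) != 1L || tRP < 0)
    stop("'tRP' must be a single non-negative number of seconds")
  structure(list(SRg = SRg, tAP = tAP, tRP = tRP), class = "gland_params")
}

#' @export
print.gland_params <- function(x, ...) {
  cat("Sweat-gland parameters\n")
  cat(sprintf("  SRg: %g nL/tAP  (nominal Nd at Vmin=0.2: %g droplets/tAP)\n",
              x$SRg, x$SRg / 0.2))
  cat(sprintf("  tAP: %g s, tRP: %g s (activity cycle %g s)\n",
              x$tAP, x$tRP, x$tAP + x$tRP))
  invisible(x)
}

#' Droplet count for one active period
#'
#' Number of transportable droplets produced during one active period,
#' \code{floor((SRg + Vres) / Vmin)}: the secreted volume plus any residual
#' carried over from the previous activity cycle, divided by the minimum
#' droplet volume the transport system can move.
#'
#' @param SRg Volume secreted during the active period (nL/tAP).
#' @param Vres Residual volume carried over from the previous cycle (nL),
#'   \code{0 <= Vres < Vmin}.
#' @param Vmin Minimum transportable droplet volume (nL), positive.
#' @return Integer droplet count.
#' @examples
#' droplet_count(0.4, 0, 0.2)   # 2
#' droplet_count(1.0, 0, 0.2)   # 5
#' droplet_count(0.7, 0.1, 0.2) # 4
#' @seealso [nd_sequence()] for the cycle-to-cycle recurrence.
#' @export
droplet_count <- function(SRg, Vres = 0, Vmin = 0.2) {
  if (!is.numeric(Vmin) || length(Vmin) != 1L || Vmin <= 0)
    stop("'Vmin' must be a single positive number")
  if (!is.numeric(SRg) || any(SRg <= 0)) stop("'SRg' must be positive")
  if (!is.numeric(Vres) || any(Vres < 0)) stop("'Vres' must be non-negative")
  if (any(Vres >= Vmin)) stop("'Vres' must be smaller than 'Vmin'")
  # tolerance so that e.g. 0.6/0.2 does not floor to 2
  as.integer(floor((SRg + Vres) / Vmin + 1e-9))
}

#' Idealized droplet-count sequence over consecutive activity cycles
#'
#' Iterates the droplet-count arithmetic over activity cycles with
#' residual-volume carry-over, under the idealization that every droplet
#' removes exactly \code{Vmin}: \code{Nd[k] = floor((SRg + Vres[k]) / Vmin)},
#' \code{Vres[k+1] = SRg + Vres[k] - Nd[k] * Vmin}. At SRg = 0.7 nL/tAP and
#' Vmin = 0.2 nL this alternates 3, 4, 3, 4, ... droplets (mean 3.5), which is
#' why that sweat rate is labelled Nd = 3.5 droplets/tAP.
#'
#' The event-level simulator ([simulate_gland()]) releases the entire
#' accumulated volume at a transport activation, so its realized droplets are
#' slightly larger than \code{Vmin} and its realized per-cycle counts can
#' differ from this idealized sequence (see the methods vignette).
#'
#' @param SRg Volume secreted per active period (nL/tAP).
#' @param Vmin Minimum transportable droplet volume (nL).
#' @param n_cycles Number of activity cycles to iterate.
#' @param Vres0 Initial residual volume (nL), default 0.
#' @return Integer vector of per-cycle droplet counts, with the final residual
#'   volume as attribute \code{"Vres"}.
#' @examples
#' nd_sequence(0.7, 0.2, 4)        # 3 4 3 4
#' mean(nd_sequence(0.7, 0.2, 50)) # 3.5
#' @export
nd_sequence <- function(SRg, Vmin = 0.2, n_cycles = 1L, Vres0 = 0) {
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 1)
    stop("'n_cycles' must be a positive integer")
  n_cycles <- as.integer(n_cycles)
  nd <- integer(n_cycles)
  vres <- Vres0
  for (k in seq_len(n_cycles)) {
    nd[k] <- droplet_count(SRg, vres, Vmin)
    vres <- SRg + vres - nd[k] * Vmin
    # guard against accumulation of floating error in the recurrence
    if (vres < 0) vres <- 0
    if (vres >= Vmin) vres <- vres - Vmin * floor(vres / Vmin + 1e-9)
  }
  structure(nd, Vres = vres)
}

#' Simulate droplet release by one sweat gland
#'
#' Event-level simulation of a single gland at one collection site. Volume
#' accumulates linearly at rate \code{SRg/tAP} during each active period and
#' is frozen during rest. Transport tiles activate at the absolute times
#' \code{k * tcycle} (a grid shared by all collection sites); at every
#' activation the entire accumulated volume is released as one droplet if it
#' has reached \code{Vmin}. Volume still below \code{Vmin} at the end of an
#' active period is carried to the next cycle as the residual \code{Vres}.
#'
#' Under this release rule every droplet volume \code{v} satisfies
#' \code{Vmin <= v < Vmin + (SRg/tAP) * tcycle}: the droplet crosses
#' \code{Vmin} strictly within one activation interval and keeps growing until
#' the next activation.
#'
#' @param params A [gland_params()] object.
#' @param n_cycles Number of activity cycles to simulate (>= 1).
#' @param tcycle Tile activation interval in seconds (> 0).
#' @param Vmin Minimum transportable droplet volume (nL).
#' @param phase Common start time of the synchronized active periods, in
#'   seconds (default 0; must lie on the activation grid).
#' @param Vres0 Initial residual volume (nL), \code{0 <= Vres0 < Vmin}.
#' @param gland_id Integer label attached to the events.
#' @return A data frame of release events with columns \code{gland_id},
#'   \code{cycle_index}, \code{tick} (activation-grid index; time is
#'   \code{tick * tcycle}), \code{time_s} and \code{volume_nL}, with the final
#'   residual volume as attribute \code{"Vres"} and the per-cycle droplet
#'   counts as attribute \code{"nd_per_cycle"}.
#' @examples
#' ev <- simulate_gland(gland_params(0.7), n_cycles = 3, tcycle = 0.5)
#' attr(ev, "nd_per_cycle")
#' @export
simulate_gland <- function(params, n_cycles = 1L, tcycle = 0.5, Vmin = 0.2,
                           phase = 0, Vres0 = 0, gland_id = 1L) {
  stopifnot(inherits(params, "gland_params"))
  if (!is.numeric(tcycle) || length(tcycle) != 1L || tcycle <= 0)
    stop("'tcycle' must be a single positive number of seconds")
  if (n_cycles < 1) stop("'n_cycles' must be >= 1")
  if (Vres0 < 0 || Vres0 >= Vmin) stop("'Vres0' must lie in [0, Vmin)")
  n_cycles <- as.integer(n_cycles)
  rate <- params$SRg / params$tAP      # nL/s during the active period
  period <- params$tAP + params$tRP
  eps <- 1e-9

  ticks <- integer(0)
  vols <- numeric(0)
  cyc <- integer(0)
  nd_per_cycle <- integer(n_cycles)
  vres <- Vres0

  for (m in seq_len(n_cycles)) {
    ap_start <- phase + (m - 1) * period
    ap_end <- ap_start + params$tAP
    v <- vres            # volume already in the droplet at AP start
    t_acc <- ap_start    # time accumulation of the current droplet started
    n_rel <- 0L
    repeat {
      t_cross <- t_acc + (Vmin - v) / rate
      if (t_cross > ap_end + eps) {       # never reaches Vmin this cycle
        vres <- v + rate * (ap_end - t_acc)
        break
      }
      k <- as.integer(ceiling(t_cross / tcycle - eps))  # next activation
      t_rel <- k * tcycle
      vol <- v + rate * (min(t_rel, ap_end) - t_acc)
      ticks <- c(ticks, k)
      vols <- c(vols, vol)
      cyc <- c(cyc, m)
      n_rel <- n_rel + 1L
      v <- 0
      t_acc <- t_rel
      if (t_acc >= ap_end - eps) { vres <- 0; break }
      if (n_rel > 1000L) stop("runaway droplet release loop")
    }
    nd_per_cycle[m] <- n_rel
  }

  out <- data.frame(gland_id = rep.int(as.integer(gland_id), length(ticks)),
                    cycle_index = cyc, tick = ticks,
                    time_s = ticks * tcycle, volume_nL = vols)
  attr(out, "Vres") <- vres
  attr(out, "nd_per_cycle") <- nd_per_cycle
  out
}
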