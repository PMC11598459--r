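#' Device layout presets and construction
#'
#' A discretized sweat-sensing device is characterized by the uniform
#' distribution of droplet travel distances (in transport tiles) over its
#' collection sites, together with the tile activation interval
#' \code{tcycle}, the minimum transportable droplet volume \code{Vmin} and
#' the number of electrical leads \code{Nleads}. The distinct travel
#' distances are the consecutive integers \code{1..k}; each occurs
#' \code{Ncollection / k} times.
#'
#' Presets (number of distinct distances x occurrences): A = 1260 x 4,
#' B = 144 x 35, C = 105 x 48, D = 70 x 72, E = 48 x 105, F = 28 x 180,
#' G = 1 x 5040 (all with 5040 collection sites); H = 140 x 72 and
#' I = 72 x 140 (10080 collection sites).
#'
#' @param name Preset label \code{"A"}--\code{"I"}, or any label when
#'   \code{n_distinct} is supplied explicitly.
#' @param tcycle Tile activation interval in seconds (0.25--0.75 typical).
#' @param Vmin Minimum transportable droplet volume in nL.
#' @param n_distinct Number of distinct travel distances (overrides preset).
#' @param occurrences Collection sites per distinct distance (overrides preset).
#' @param Nleads Number of sequentially activated leads (metadata only; the
#'   transport model is a pure delay of \code{dtravel * tcycle}).
#' @return An object of class \code{"device_layout"} with fields
#'   \code{name}, \code{distinct_dtravel}, \code{occurrences},
#'   \code{Ncollection}, \code{tcycle}, \code{Vmin}, \code{Nleads}.
#' @examples
#' device_layout("D", tcycle = 0.5)
#' device_layout("G", tcycle = 0.5)$distinct_dtravel # single distance
#' @export
device_layout <- function(name = "D", tcycle = 0.5, Vmin = 0.2,
                          n_distinct = NULL, occurrences = NULL, Nleads = 5L) {
  presets <- list(A = c(1260L, 4L), B = c(144L, 35L), C = c(105L, 48L),
                  D = c(70L, 72L), E = c(48L, 105L), F = c(28L, 180L),
                  G = c(1L, 5040L), H = c(140L, 72L), I = c(72L, 140L))
  if (is.null(n_distinct)) {
    if (!name %in% names(presets))
      stop("unknown layout '", name, "'; presets are ",
           paste(names(presets), collapse = ", "),
           " (or supply 'n_distinct' and 'occurrences')")
    n_distinct <- presets[[name]][1L]
    if (is.null(occurrences)) occurrences <- presets[[name]][2L]
  }
  if (is.null(occurrences)) stop("'occurrences' must be supplied with 'n_distinct'")
  n_distinct <- as.integer(n_distinct); occurrences <- as.integer(occurrences)
  if (n_distinct < 1L || occurrences < 1L)
    stop("'n_distinct' and 'occurrences' must be positive integers")
  if (!is.numeric(tcycle) || length(tcycle) != 1L || tcycle <= 0)
    stop("'tcycle' must be a single positive number of seconds")
  if (!is.numeric(Vmin) || length(Vmin) != 1L || Vmin <= 0)
    stop("'Vmin' must be a single positive number of nL")
  structure(list(name = name,
                 distinct_dtravel = seq_len(n_distinct),
                 occurrences = occurrences,
                 Ncollection = n_distinct * occurrences,
                 tcycle = tcycle, Vmin = Vmin, Nleads = as.integer(Nleads)),
            class = "device_layout")
}

#' @export
print.device_layout <- function(x, ...) {
  k <- length(x$distinct_dtravel)
  cat(sprintf("Device layout %s: %d collection sites (%d distinct travel distances x %d)\n",
              x$name, x$Ncollection, k, x$occurrences))
  cat(sprintf("  tcycle %g s, Vmin %g nL, Nleads %d; travel times %g-%g s\n",
              x$tcycle, x$Vmin, x$Nleads,
              travel_time(min(x$distinct_dtravel), x$tcycle),
              travel_time(max(x$distinct_dtravel), x$tcycle)))
  invisible(x)
}

#' Travel time of a droplet
#'
#' The delay from a collection site to the volumetric sensor: the product of
#' the travel distance (in tiles) and the tile activation interval.
#'
#' @param dtravel Travel distance in tiles (positive integer, vectorized).
#' @param tcycle Tile activation interval in seconds.
#' @return Travel time in seconds.
#' @examples
#' travel_time(1260, 0.75) # 945
#' @export
travel_time <- function(dtravel, tcycle) {
  if (any(dtravel < 1)) stop("'dtravel' must be >= 1 tile")
  dtravel * tcycle
}

#' Randomly assign sweat glands to collection sites
#'
#' Draws \code{n_glands} distinct collection sites uniformly without
#' replacement and returns the travel distance of each gland's site.
#' Enforces at most one gland per collection site.
#'
#' @param layout A [device_layout()].
#' @param n_glands Number of active sweat glands (1--11 in the study design).
#' @param seed Optional integer seed for reproducible placement.
#' @return Object of class \code{"gland_placement"}: a data frame with columns
#'   \code{gland_id}, \code{site} (site index) and \code{dtravel}.
#' @examples
#' assign_glands(device_layout("D"), 3, seed = 1)
#' @export
assign_glands <- function(layout, n_glands, seed = NULL) {
  stopifnot(inherits(layout, "device_layout"))
  n_glands <- as.integer(n_glands)
  if (n_glands < 1L) stop("'n_glands' must be >= 1")
  if (n_glands > layout$Ncollection)
    stop("more glands (", n_glands, ") than collection sites (",
         layout$Ncollection, ")")
  if (!is.null(seed)) set.seed(seed)
  sites <- sample.int(layout$Ncollection, n_glands)
  # site i has travel distance distinct_dtravel[ceiling(i / occurrences)]
  d <- layout$distinct_dtravel[(sites - 1L) %/% layout$occurrences + 1L]
  structure(data.frame(gland_id = seq_len(n_glands), site = sites, dtravel = d),
            class = c("gland_placement", "data.frame"))
}

#' Poisson occupancy check for device sizing
#'
#' Evaluates the Poisson model used to size the collection area: with active
#' glands distributed spatially at a given density, the number of glands in an
#' area A is Poisson with mean \code{lambda = density * A}. Returns the
#' probability that the device samples at least one gland overall, the
#' per-site probability of at most one gland, and the probability of more
#' than \code{nsg_max} glands over the whole collection area.
#'
#' @param density Active-gland density in glands/cm^2 (e.g. 10 on the forearm).
#' @param site_diameter_um Collection-site diameter in micrometers.
#' @param n_sites Number of collection sites.
#' @param nsg_max Gland-count cap of interest (default 11).
#' @return A list with \code{lambda_site}, \code{lambda_total},
#'   \code{p_at_least_one_overall}, \code{p_at_most_one_per_site} and
#'   \code{p_exceeds_nsg_max}.
#' @examples
#' occupancy_check(10, 100, 5040)
#' @export
occupancy_check <- function(density, site_diameter_um, n_sites, nsg_max = 11L) {
  if (density <= 0) stop("'density' must be positive")
  area_site_cm2 <- pi * (site_diameter_um * 1e-4 / 2)^2
  lambda_site <- density * area_site_cm2
  lambda_total <- lambda_site * n_sites
  list(lambda_site = lambda_site,
       lambda_total = lambda_total,
       p_at_least_one_overall = 1 - exp(-lambda_total),
       p_at_most_one_per_site = stats::ppois(1, lambda_site),
       p_exceeds_nsg_max = 1 - stats::ppois(nsg_max, lambda_total))
}
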