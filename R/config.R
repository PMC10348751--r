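#' Simulation configuration
#'
#' Collects every scalar controlling the spatial and temporal discretization,
#' the growth/dilution protocol, and the physical coefficients of the
#' community model. Defaults are the standard parameter set used throughout
#' the package: a 0.5 cm habitat at 0.005 cm resolution (100 grid points),
#' slow cell dispersal relative to fast mediator diffusion, and a serial
#' enrichment protocol diluting from 10^7 back to 10^4 cells/ml.
#'
#' Two derived time-steps are computed and stored: the mediator diffusion
#' step \code{dt = dt_factor * dz^2 / D_med} and the cell dispersal step
#' \code{dc = dc_factor * dz^2 / D_cell}. The prefactors (default 0.1) must
#' not exceed 0.5, the stability bound of the explicit diffusion scheme.
#'
#' @param Z total spatial extent of the community, cm.
#' @param dz grid spacing, cm; the number of grid points is \code{round(Z/dz)}.
#' @param D_cell cell dispersal (random-walk) coefficient, cm^2/hr.
#' @param D_med mediator diffusion coefficient, cm^2/hr.
#' @param k_Y local carrying capacity for total cell density, cells/ml;
#'   may be \code{Inf} to disable crowding.
#' @param k_sat interaction strength saturation concentration, fmol/ml
#'   (numerically interchangeable with cells/ml in the growth-rate formula).
#' @param TID total initial cell density summed over species, cells/ml.
#' @param ExtTh extinction threshold on the spatially averaged density of a
#'   species, cells/ml.
#' @param DilTh community density triggering a dilution, cells/ml.
#' @param n_gen target number of generations of enrichment.
#' @param dtau growth/uptake update time-step, hr.
#' @param dt_factor,dc_factor prefactors of the diffusion time-steps
#'   (\code{<= 0.5} for stability of the explicit scheme).
#' @param infinite_dispersal logical; if \code{TRUE}, species fields are
#'   re-uniformized across space after every growth step (the rapid-dispersal
#'   limit, which recovers well-mixed dynamics).
#' @param mediator_dilution what happens to mediator concentrations at a
#'   dilution step: diluted by the same factor as cells (default), retained,
#'   or reset to zero.
#' @param consumption_saturating logical; if \code{TRUE} consumption of a
#'   mediator is multiplied by \code{C/(C + k_sat)} so uptake vanishes as the
#'   mediator is depleted. Default \code{FALSE}: consumption is proportional
#'   to consumer density only, with concentrations clamped at zero.
#' @param max_round_hours wall cap on simulated time within one growth round,
#'   hr; a round that never reaches \code{DilTh} ends here.
#' @param max_rounds hard cap on the number of growth-dilution rounds.
#' @return An object of class \code{sim_config} (a list with the above fields
#'   plus derived \code{n_z}, \code{dt}, \code{dc}).
#' @examples
#' cfg <- sim_config()
#' cfg$n_z   # 100 grid points
#' cfg$dt    # mediator diffusion step, hr
#' @export
sim_config <- function(Z = 0.5, dz = 0.005,
                       D_cell = 5e-9, D_med = 1.8e-2,
                       k_Y = 1e9, k_sat = 1e4,
                       TID = 1e4, ExtTh = 0.1, DilTh = 1e7,
                       n_gen = 100, dtau = 0.01,
                       dt_factor = 0.1, dc_factor = 0.1,
                       infinite_dispersal = FALSE,
                       mediator_dilution = c("dilute", "retain", "reset"),
                       consumption_saturating = FALSE,
                       max_round_hours = 2000, max_rounds = 100) {
  mediator_dilution <- match.arg(mediator_dilution)
  num1 <- function(x, nm, positive = TRUE, allow_inf = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (!allow_inf && !is.finite(x)))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    if (positive && x <= 0)
      stop("'", nm, "' must be positive", call. = FALSE)
    as.numeric(x)
  }
  Z <- num1(Z, "Z"); dz <- num1(dz, "dz")
  D_cell <- num1(D_cell, "D_cell"); D_med <- num1(D_med, "D_med")
  k_Y <- num1(k_Y, "k_Y", allow_inf = TRUE)
  k_sat <- num1(k_sat, "k_sat")
  TID <- num1(TID, "TID"); ExtTh <- num1(ExtTh, "ExtTh")
  DilTh <- num1(DilTh, "DilTh")
  n_gen <- num1(n_gen, "n_gen"); dtau <- num1(dtau, "dtau")
  dt_factor <- num1(dt_factor, "dt_factor")
  dc_factor <- num1(dc_factor, "dc_factor")
  max_round_hours <- num1(max_round_hours, "max_round_hours")
  max_rounds <- num1(max_rounds, "max_rounds")
  if (!is.logical(infinite_dispersal) || length(infinite_dispersal) != 1L)
    stop("'infinite_dispersal' must be TRUE or FALSE")
  if (!is.logical(consumption_saturating) || length(consumption_saturating) != 1L)
    stop("'consumption_saturating' must be TRUE or FALSE")
  if (dt_factor > 0.5 || dc_factor > 0.5)
    stop("diffusion step prefactors must be <= 0.5 (explicit-scheme stability)")
  if (DilTh <= TID)
    stop("'DilTh' must exceed 'TID' (dilution factor DilTh/TID must be > 1)")
  n_z <- as.integer(round(Z / dz))
  if (n_z < 3) stop("grid must have at least 3 points (round(Z/dz) >= 3)")
  cfg <- list(Z = Z, dz = dz, n_z = n_z,
              D_cell = D_cell, D_med = D_med,
              k_Y = k_Y, k_sat = k_sat,
              TID = TID, ExtTh = ExtTh, DilTh = DilTh,
              n_gen = n_gen, dtau = dtau,
              dt_factor = dt_factor, dc_factor = dc_factor,
              dt = dt_factor * dz^2 / D_med,
              dc = dc_factor * dz^2 / D_cell,
              infinite_dispersal = infinite_dispersal,
              mediator_dilution = mediator_dilution,
              consumption_saturating = consumption_saturating,
              max_round_hours = max_round_hours,
              max_rounds = as.integer(max_rounds))
  class(cfg) <- "sim_config"
  cfg
}

#' Update a simulation configuration
#'
#' Returns a new \code{sim_config} with the named fields replaced and all
#' derived quantities (grid size, diffusion time-steps) recomputed.
#'
#' @param config a \code{sim_config}.
#' @param ... named fields to override, as accepted by [sim_config()].
#' @return A new \code{sim_config}.
#' @export
update_config <- function(config, ...) {
  stopifnot(inherits(config, "sim_config"))
  over <- list(...)
  if (length(over) == 0L) return(config)
  settable <- setdiff(names(config), c("n_z", "dt", "dc"))
  bad <- setdiff(names(over), settable)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  args <- unclass(config)[settable]
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  grid: Z = %g cm, dz = %g cm (%d points)\n", x$Z, x$dz, x$n_z))
  cat(sprintf("  D_cell = %g, D_med = %g cm^2/hr%s\n", x$D_cell, x$D_med,
              if (x$infinite_dispersal) " [infinite dispersal]" else ""))
  cat(sprintf("  time-steps: dtau = %g hr, dt = %.3g hr, dc = %.3g hr\n",
              x$dtau, x$dt, x$dc))
  cat(sprintf("  k_Y = %g, k_sat = %g, TID = %g, DilTh = %g, ExtTh = %g\n",
              x$k_Y, x$k_sat, x$TID, x$DilTh, x$ExtTh))
  cat(sprintf("  enrichment: %g generations target, dilution factor %g\n",
              x$n_gen, x$DilTh / x$TID))
  invisible(x)
}
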