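#' Spatial community state
#'
#' Bundles the species density fields and mediator concentration fields on
#' the 1D grid at one time point.
#'
#' @param S species density matrix, n_species x n_z, cells/ml.
#' @param C mediator concentration matrix, n_mediators x n_z, fmol/ml.
#' @param t elapsed time, hr.
#' @return An object of class \code{spatial_state}.
#' @export
spatial_state <- function(S, C, t = 0) {
  S <- as.matrix(S); C <- as.matrix(C)
  if (ncol(S) != ncol(C)) stop("S and C must share the same grid")
  if (any(!is.finite(S)) || any(!is.finite(C)))
    stop("state fields must be finite")
  if (any(S < 0) || any(C < 0)) stop("state fields must be nonnegative")
  structure(list(S = S, C = C, t = as.numeric(t)), class = "spatial_state")
}

#' Well-mixed community state
#'
#' @param S per-species density vector, cells/ml.
#' @param C per-mediator concentration vector, fmol/ml.
#' @param t elapsed time, hr.
#' @return An object of class \code{well_mixed_state}.
#' @export
well_mixed_state <- function(S, C, t = 0) {
  S <- as.numeric(S); C <- as.numeric(C)
  if (any(!is.finite(S)) || any(!is.finite(C)) || any(S < 0) || any(C < 0))
    stop("state fields must be finite and nonnegative")
  structure(list(S = S, C = C, t = as.numeric(t)), class = "well_mixed_state")
}

#' Local per-species net growth rate
#'
#' Evaluates, at a single location, the net growth rate of every species:
#' \deqn{(1 - \sum_k S_k / k_Y)\,[r_{0,i} + \sum_j \rho_{ij} g_{ij}(C_j)]}
#' where the mediator response is saturating, \eqn{C_j/(C_j + k_{sat})}, for
#' facilitative influences (\eqn{\rho_{ij} > 0}) and linear, \eqn{C_j/k_{sat}},
#' for inhibitory ones (\eqn{\rho_{ij} < 0}). Mediator influences add on top
#' of the basal rate; the logistic crowding factor multiplies the whole
#' bracket. The result may be negative.
#'
#' @param S_col species densities at one grid point (length n_species).
#' @param C_col mediator concentrations at that point (length n_mediators).
#' @param network an \code{interaction_network}.
#' @param config a \code{sim_config} (supplies \code{k_Y} and \code{k_sat}).
#' @return Numeric vector of net growth rates, 1/hr.
#' @examples
#' net <- generate_network(n_species = 2, n_mediators = 1, qc = 1,
#'                         fac_ratio = 1, seed = 4)
#' local_growth_rate(c(10, 10), net$params$rint0, net, sim_config())
#' @export
local_growth_rate <- function(S_col, C_col, network, config) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(config, "sim_config"))
  if (any(S_col < 0) || any(C_col < 0))
    stop("densities and concentrations must be nonnegative")
  if (length(S_col) != network$n_species ||
      length(C_col) != network$n_mediators)
    stop("column lengths must match the network dimensions")
  crowd <- 1 - sum(S_col) / config$k_Y
  fac <- C_col / (C_col + config$k_sat)
  inh <- C_col / config$k_sat
  bracket <- network$r0 +
    as.vector(pmax(network$rho, 0) %*% fac) +
    as.vector(pmin(network$rho, 0) %*% inh)
  crowd * bracket
}

#' One growth/uptake step (reference implementation)
#'
#' Advances a state by one \code{dtau}: every species density is updated
#' multiplicatively, \code{S <- S * exp(rate * dtau)}, with the local net
#' growth rate of [local_growth_rate()]; every mediator concentration is
#' updated by net production \code{(beta - alpha) \%*\% S * dtau} evaluated
#' at the pre-update densities and clamped at zero. No spatial coupling
#' happens in this step. This is a plain-R implementation used as a
#' cross-check of the compiled integrator; [advance()] is the fast path.
#'
#' @param state a \code{spatial_state} or \code{well_mixed_state}.
#' @param network an \code{interaction_network}.
#' @param config a \code{sim_config}.
#' @return A state of the same class, advanced by \code{dtau}.
#' @export
step_growth <- function(state, network, config) {
  wm <- inherits(state, "well_mixed_state")
  S <- if (wm) matrix(state$S) else state$S
  C <- if (wm) matrix(state$C) else state$C
  crowd <- 1 - colSums(S) / config$k_Y
  fac <- C / (C + config$k_sat)
  inh <- C / config$k_sat
  G <- matrix(network$r0, nrow(S), ncol(S)) +
    pmax(network$rho, 0) %*% fac + pmin(network$rho, 0) %*% inh
  rate <- sweep(G, 2, crowd, `*`)
  upt <- if (config$consumption_saturating) fac else 1
  C_new <- pmax(C + (network$beta %*% S - (network$alpha %*% S) * upt) *
                  config$dtau, 0)
  S_new <- S * exp(rate * config$dtau)
  t_new <- state$t + config$dtau
  if (wm) well_mixed_state(as.numeric(S_new), as.numeric(C_new), t_new)
  else spatial_state(S_new, C_new, t_new)
}

#' Explicit diffusion step(s) with no-flux boundaries
#'
#' Applies \code{n_steps} explicit second-difference diffusion updates to
#' each row of \code{field}, with reflecting boundaries at both ends. The
#' scheme conserves total mass exactly and preserves nonnegativity provided
#' \code{D * dt / dz^2 <= 0.5}; the step is refused beyond that bound.
#'
#' @param field numeric matrix (rows = variables, columns = grid points) or
#'   a numeric vector (one variable).
#' @param D diffusion coefficient, cm^2/hr.
#' @param dt time-step, hr.
#' @param dz grid spacing, cm.
#' @param n_steps number of steps to take.
#' @return The diffused field, same shape as the input.
#' @export
step_diffusion <- function(field, D, dt, dz, n_steps = 1) {
  vec <- is.null(dim(field))
  M <- if (vec) matrix(field, nrow = 1) else as.matrix(field)
  if (any(M < 0)) stop("field must be nonnegative")
  lambda <- D * dt / dz^2
  if (lambda > 0.5 + 1e-12)
    stop(sprintf(
      "explicit diffusion step unstable: D*dt/dz^2 = %.3g > 0.5", lambda))
  out <- cpp_diffuse(M, lambda, as.integer(n_steps))
  if (vec) as.numeric(out) else out
}

# Shared driver over the compiled kernel. dilth/ext_total default to
# "disabled"; run_enrichment() passes real thresholds.
.advance_kernel <- function(state, network, config, t_target,
                            dilth = Inf, ext_total = -Inf,
                            record_every = 0L, spatial = TRUE) {
  S <- if (spatial) state$S else matrix(state$S)
  C <- if (spatial) state$C else matrix(state$C)
  dt_med <- if (spatial) config$dt else Inf
  dc_cell <- if (spatial) config$dc else Inf
  if (spatial && config$dt_factor > 0.5 + 1e-12)
    stop("mediator diffusion step violates the stability bound")
  cpp_advance(S, C, network$rho, network$beta, network$alpha, network$r0,
              config$k_Y, config$k_sat, config$dtau,
              dt_med, config$dt_factor, dc_cell, config$dc_factor,
              state$t, t_target, dilth, ext_total,
              spatial && config$infinite_dispersal,
              config$consumption_saturating,
              as.integer(record_every))
}

.as_trajectory <- function(res, state_fun, record_every, config) {
  snaps <- res$snapshots
  states <- Map(function(S, C, t) state_fun(S, C, t),
                snaps$S, snaps$C, snaps$times)
  final <- state_fun(res$S, res$C, res$t)
  structure(list(final = final, times = unlist(snaps$times),
                 states = states, n_steps = res$n_steps),
            class = "spatcoex_trajectory")
}

#' Advance a spatial community state in time
#'
#' Integrates the coupled reaction-diffusion dynamics from \code{state$t} to
#' \code{t_target} using the asynchronous multi-timescale scheme: growth and
#' mediator production/consumption fire every \code{dtau}; mediator diffusion
#' steps fire every \code{dt = dt_factor dz^2 / D_med}; cell dispersal steps
#' every \code{dc = dc_factor dz^2 / D_cell}. When events coincide the order
#' is growth, then mediator diffusion, then cell dispersal. In
#' infinite-dispersal mode the species fields are re-uniformized across the
#' grid after every growth step and the dispersal events are skipped.
#'
#' @param state a \code{spatial_state}.
#' @param network an \code{interaction_network}.
#' @param config a \code{sim_config}.
#' @param t_target time to integrate to, hr (must exceed \code{state$t}).
#' @param record_every optional snapshot cadence in hours; if supplied, the
#'   returned trajectory carries full state snapshots at that cadence.
#' @return A \code{spatcoex_trajectory}: list with \code{final} (the state at
#'   \code{t_target}), and, when recording, \code{times} and \code{states}.
#' @examples
#' net <- generate_network(seed = 1)
#' cfg <- sim_config(Z = 0.05)  # small grid for a quick example
#' st <- initial_condition(net, cfg)
#' advance(st, net, cfg, t_target = 1)$final$t
#' @export
advance <- function(state, network, config, t_target, record_every = NULL) {
  stopifnot(inherits(state, "spatial_state"))
  if (t_target <= state$t) stop("'t_target' must exceed state$t")
  if (nrow(state$S) != network$n_species || ncol(state$S) != config$n_z)
    stop("state dimensions do not match network/config")
  rec <- if (is.null(record_every)) 0L
         else max(1L, as.integer(round(record_every / config$dtau)))
  res <- .advance_kernel(state, network, config, t_target,
                         record_every = rec)
  .as_trajectory(res, spatial_state, rec, config)
}

#' Integrate the well-mixed counterpart
#'
#' Same growth and mediator kinetics as [advance()] with all spatial terms
#' removed: one homogeneous compartment, the same \code{dtau} stepping, the
#' same multiplicative growth update and zero-clamped mediator bookkeeping.
#' Used as the non-spatial baseline against which spatial outcomes are
#' compared, always with the identical interaction network.
#'
#' @param state a \code{well_mixed_state}.
#' @inheritParams advance
#' @return A \code{spatcoex_trajectory} whose states are
#'   \code{well_mixed_state}s.
#' @export
simulate_well_mixed <- function(state, network, config, t_target,
                                record_every = NULL) {
  stopifnot(inherits(state, "well_mixed_state"))
  if (t_target <= state$t) stop("'t_target' must exceed state$t")
  rec <- if (is.null(record_every)) 0L
         else max(1L, as.integer(round(record_every / config$dtau)))
  res <- .advance_kernel(state, network, config, t_target,
                         record_every = rec, spatial = FALSE)
  .as_trajectory(res, function(S, C, t)
    well_mixed_state(as.numeric(S), as.numeric(C), t), rec, config)
}

#' Write a trajectory summary to CSV
#'
#' Writes one row per recorded snapshot: time (hr) and the spatially
#' averaged density of every species.
#'
#' @param trajectory a \code{spatcoex_trajectory} recorded with
#'   \code{record_every} (see [advance()]).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "spatcoex_trajectory"))
  if (!length(trajectory$states))
    stop("trajectory has no recorded snapshots; re-run with 'record_every'")
  ab <- t(vapply(trajectory$states, species_abundance,
                 numeric(length(species_abundance(trajectory$final)))))
  df <- data.frame(t_hours = trajectory$times, ab)
  names(df) <- c("t_hours", paste0("s", seq_len(ncol(ab))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Spatially averaged species abundances
#'
#' @param state a \code{spatial_state} or \code{well_mixed_state}.
#' @return Per-species density averaged over the grid, cells/ml.
#' @export
species_abundance <- function(state) {
  if (inherits(state, "well_mixed_state")) state$S else rowMeans(state$S)
}
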