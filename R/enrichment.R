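#' Structured initial condition: adjacent non-overlapping species blocks
#'
#' Places each species in its own contiguous block of grid points, blocks
#' adjacent and non-overlapping, covering the whole habitat. When the grid
#' does not divide evenly, the first \code{n_z mod n_species} blocks get one
#' extra point. The local density inside each block is set so that every
#' species has the same spatial average, \code{TID / n_species} (so the
#' community-wide spatial average is exactly \code{TID}). Mediators start
#' at zero everywhere.
#'
#' @param network an \code{interaction_network}.
#' @param config a \code{sim_config}.
#' @param permutation optional permutation of \code{1:n_species} giving the
#'   left-to-right order of the blocks; defaults to identity.
#' @return A \code{spatial_state} at \code{t = 0}.
#' @examples
#' st <- initial_condition(generate_network(seed = 1), sim_config())
#' rowMeans(st$S)  # each species averages TID / n_species = 1000 cells/ml
#' @export
initial_condition <- function(network, config, permutation = NULL) {
  nc <- network$n_species; nz <- config$n_z
  if (nc > nz)
    stop("more species than grid points: cannot build block initial condition")
  if (is.null(permutation)) permutation <- seq_len(nc)
  if (!identical(sort(as.integer(permutation)), seq_len(nc)))
    stop("'permutation' must be a permutation of 1:n_species")
  base <- nz %/% nc; rem <- nz %% nc
  sizes <- base + as.integer(seq_len(nc) <= rem)
  S <- matrix(0, nc, nz)
  stop_at <- cumsum(sizes)
  start_at <- c(1L, stop_at[-nc] + 1L)
  per_species <- config$TID / nc
  for (b in seq_len(nc)) {
    i <- permutation[b]
    S[i, start_at[b]:stop_at[b]] <- per_species * nz / sizes[b]
  }
  spatial_state(S, matrix(0, network$n_mediators, nz), t = 0)
}

#' Dilute a community, preserving its spatial distribution
#'
#' Divides every species density at every location by \code{factor}, then
#' zeroes out (declares extinct) any species whose spatially averaged
#' density has fallen below \code{ExtTh}. Mediators are, by default, diluted
#' by the same factor; they can instead be retained or reset to zero via
#' \code{mediators}.
#'
#' @param state a \code{spatial_state} or \code{well_mixed_state}.
#' @param factor dilution factor (> 1).
#' @param ExtTh extinction threshold on spatially averaged density, cells/ml.
#' @param mediators one of \code{"dilute"}, \code{"retain"}, \code{"reset"}.
#' @return A state of the same class.
#' @export
dilute <- function(state, factor, ExtTh,
                   mediators = c("dilute", "retain", "reset")) {
  mediators <- match.arg(mediators)
  if (factor <= 1) stop("'factor' must exceed 1")
  wm <- inherits(state, "well_mixed_state")
  S <- state$S / factor
  avg <- if (wm) S else rowMeans(S)
  extinct <- avg < ExtTh
  if (any(extinct)) {
    if (wm) S[extinct] <- 0 else S[extinct, ] <- 0
  }
  C <- switch(mediators,
              dilute = state$C / factor,
              retain = state$C,
              reset  = state$C * 0)
  if (wm) well_mixed_state(S, C, state$t) else spatial_state(S, C, state$t)
}

#' Serial growth-dilution enrichment of one community
#'
#' Runs the full enrichment protocol on one interaction network: start from
#' the structured block initial condition (or its well-mixed / uniform
#' counterpart), grow until the spatially averaged total community density
#' reaches \code{DilTh} (or the per-round wall cap \code{max_round_hours}
#' expires), record the per-species abundances, then dilute everything by
#' \code{DilTh / TID} and repeat. Generations are accrued per round as
#' \code{log2} of the realized fold-growth of total density; the protocol
#' stops once accumulated generations reach \code{n_gen} (or all species go
#' extinct, or \code{max_rounds} is hit). Stable coexistence is then scored
#' with [assess_coexistence()].
#'
#' @param network an \code{interaction_network}.
#' @param config a \code{sim_config}.
#' @param permutation optional spatial block order (see
#'   [initial_condition()]); ignored in well-mixed mode.
#' @param mode \code{"spatial"} (1D grid, block initial condition),
#'   \code{"well_mixed"} (single compartment), or \code{"infinite_dispersal"}
#'   (1D grid with uniform initial condition and species fields
#'   re-uniformized after every growth step).
#' @return An object of class \code{enrichment_result}: the per-round
#'   abundance table \code{rounds} (columns \code{round}, \code{t_hours},
#'   \code{generations}, \code{cum_generations}, then one \code{s<i>} column
#'   of spatially averaged density per species, recorded at round end before
#'   dilution), the \code{final_state}, the survivor sets, \code{richness}
#'   (count of stable survivors), and the Shannon diversity of the final
#'   community.
#' @examples
#' \donttest{
#' net <- generate_network(fac_ratio = 0.9, seed = 7)
#' res <- run_enrichment(net, sim_config(n_gen = 30), mode = "well_mixed")
#' res
#' }
#' @export
run_enrichment <- function(network, config, permutation = NULL,
                           mode = c("spatial", "well_mixed",
                                    "infinite_dispersal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "interaction_network"),
            inherits(config, "sim_config"))
  nc <- network$n_species
  spatial <- mode != "well_mixed"
  if (mode == "infinite_dispersal") {
    config <- update_config(config, infinite_dispersal = TRUE)
    state <- spatial_state(
      matrix(config$TID / nc, nc, config$n_z),
      matrix(0, network$n_mediators, config$n_z))
  } else if (mode == "spatial") {
    state <- initial_condition(network, config, permutation)
  } else {
    state <- well_mixed_state(rep(config$TID / nc, nc),
                              rep(0, network$n_mediators))
  }
  factor <- config$DilTh / config$TID
  cum_gen <- 0
  meta <- vector("list", config$max_rounds)
  abund <- matrix(NA_real_, config$max_rounds, nc)
  r <- 0L
  all_dead <- FALSE
  while (r < config$max_rounds) {
    r <- r + 1L
    start_total <- sum(species_abundance(state))
    res <- .advance_kernel(state, network, config,
                           t_target = state$t + config$max_round_hours,
                           dilth = config$DilTh, ext_total = config$ExtTh,
                           spatial = spatial)
    state <- if (spatial) spatial_state(res$S, res$C, res$t)
             else well_mixed_state(as.numeric(res$S), as.numeric(res$C), res$t)
    ab <- species_abundance(state)
    end_total <- sum(ab)
    gen <- if (end_total > 0 && start_total > 0)
      log2(end_total / start_total) else 0
    cum_gen <- cum_gen + gen
    meta[[r]] <- data.frame(round = r, t_hours = state$t,
                            generations = gen, cum_generations = cum_gen)
    abund[r, ] <- ab
    if (isTRUE(res$all_dead) || all(ab < config$ExtTh)) {
      all_dead <- TRUE
      break
    }
    if (cum_gen >= config$n_gen) break
    state <- dilute(state, factor, config$ExtTh, config$mediator_dilution)
  }
  rounds <- do.call(rbind, meta[seq_len(r)])
  ab_df <- as.data.frame(abund[seq_len(r), , drop = FALSE])
  names(ab_df) <- paste0("s", seq_len(nc))
  rounds <- cbind(rounds, ab_df)
  cx <- assess_coexistence(rounds, config$ExtTh)
  final_ab <- abund[r, ]
  sh <- if (any(final_ab > 0)) shannon_index(final_ab) else 0
  structure(list(rounds = rounds, final_state = state,
                 survivors_present = cx$survivors_present,
                 survivors_stable = cx$survivors_stable,
                 richness = cx$richness,
                 richness_present = length(cx$survivors_present),
                 shannon = sh, mode = mode, n_rounds = r,
                 total_generations = cum_gen,
                 all_extinct = all_dead,
                 network_seed = network$seed,
                 permutation = permutation),
            class = "enrichment_result")
}

#' Score stable coexistence from a per-round abundance trajectory
#'
#' A species is \emph{present} if its spatially averaged density at the end
#' of the last round exceeds \code{ExtTh}. A present species is \emph{stably
#' present} if its relative frequency at the end has not declined by more
#' than \code{decline_tolerance} (10 percent by default) of its value over
#' the final \code{window_generations} generations: the reference point is
#' the latest recorded round boundary at least \code{window_generations}
#' generations before the end. Richness is the number of stably present
#' species, or of all present species when \code{presence_only = TRUE}.
#'
#' @param rounds a per-round table as produced by [run_enrichment()]:
#'   must contain \code{cum_generations} and species abundance columns
#'   \code{s1, s2, ...} (spatially averaged density at round end).
#' @param ExtTh extinction threshold, cells/ml.
#' @param window_generations length of the stability window, generations.
#' @param decline_tolerance maximum tolerated fractional decline of relative
#'   frequency across the window.
#' @param presence_only if \code{TRUE}, richness counts all present species.
#' @return List with integer vectors \code{survivors_stable} and
#'   \code{survivors_present}, and \code{richness}.
#' @examples
#' tr <- data.frame(round = 1:11, cum_generations = seq(9.97, 109.7, 9.97),
#'                  s1 = rep(3e6, 11), s2 = rep(7e6, 11))
#' assess_coexistence(tr, ExtTh = 0.1)$richness  # both species stable
#' @export
assess_coexistence <- function(rounds, ExtTh, window_generations = 20,
                               decline_tolerance = 0.10,
                               presence_only = FALSE) {
  if (is.null(rounds) || nrow(rounds) == 0) stop("'rounds' must be non-empty")
  scol <- grep("^s[0-9]+$", names(rounds))
  if (!length(scol)) stop("'rounds' has no species abundance columns")
  A <- as.matrix(rounds[, scol, drop = FALSE])
  gen <- rounds$cum_generations
  n <- nrow(A)
  final <- A[n, ]
  present <- which(final > ExtTh)
  target <- gen[n] - window_generations
  ref_candidates <- which(gen <= target)
  if (length(ref_candidates)) {
    ref <- max(ref_candidates)
  } else {
    warning("recorded trajectory shorter than the stability window; ",
            "using the full trajectory")
    ref <- 1L
  }
  f_ref <- A[ref, ] / sum(A[ref, ])
  f_end <- final / sum(final)
  stable <- intersect(
    present,
    which(f_end >= (1 - decline_tolerance) * f_ref))
  richness <- if (presence_only) length(present) else length(stable)
  list(survivors_stable = as.integer(stable),
       survivors_present = as.integer(present),
       richness = richness)
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over species with positive abundance,
#' where \eqn{p_i} is the relative abundance.
#'
#' @param abundances nonnegative abundances, at least one positive.
#' @return The Shannon index (natural log), in \code{[0, log(n)]}.
#' @examples
#' shannon_index(c(1, 1, 1, 1))  # log(4)
#' @export
shannon_index <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be nonnegative")
  tot <- sum(abundances)
  if (tot <= 0) stop("at least one abundance must be positive")
  p <- abundances[abundances > 0] / tot
  -sum(p * log(p))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment result (%s mode, network seed %d)\n",
              x$mode, x$network_seed))
  cat(sprintf("  %d rounds, %.1f generations, %.1f hr simulated\n",
              x$n_rounds, x$total_generations,
              x$rounds$t_hours[x$n_rounds]))
  cat(sprintf("  richness (stable): %d   present: %d   Shannon: %.3f\n",
              x$richness, x$richness_present, x$shannon))
  if (x$all_extinct) cat("  community went fully extinct\n")
  invisible(x)
}

#' @export
summary.enrichment_result <- function(object, ...) {
  print(object)
  n <- object$n_rounds
  ab <- as.numeric(object$rounds[n, grep("^s[0-9]+$", names(object$rounds))])
  f <- ab / sum(ab)
  cat("  final relative frequencies:\n")
  for (i in order(f, decreasing = TRUE)) {
    if (ab[i] <= 0) next
    tag <- if (i %in% object$survivors_stable) "stable"
           else if (i %in% object$survivors_present) "present"
           else "extinct"
    cat(sprintf("    species %-2d  %6.3f  (%s)\n", i, f[i], tag))
  }
  invisible(object)
}

#' Plot per-round abundance trajectories
#'
#' @param x an \code{enrichment_result}.
#' @param log logical; log-scale the abundance axis.
#' @param ... passed to [graphics::matplot()].
#' @return \code{x}, invisibly.
#' @export
plot.enrichment_result <- function(x, log = TRUE, ...) {
  scol <- grep("^s[0-9]+$", names(x$rounds))
  A <- as.matrix(x$rounds[, scol, drop = FALSE])
  A[A <= 0] <- NA
  graphics::matplot(x$rounds$cum_generations, A, type = "b", pch = 16,
                    lty = 1, log = if (log) "y" else "",
                    xlab = "generations",
                    ylab = "spatial mean density (cells/ml)", ...)
  invisible(x)
}
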