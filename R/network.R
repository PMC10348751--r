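#' Generate a random mediator-explicit interaction network
#'
#' Draws the community blueprint: which species produce which mediators,
#' which mediators influence (and are therefore consumed by) which species,
#' and at what rates. Production links are present independently with
#' probability \code{qp} per (mediator, species) pair, influence links with
#' probability \code{qc}. Present production rates are drawn uniformly on
#' \code{[0.5, 1.5] * beta0}, consumption rates on \code{[0.5, 1.5] * alpha0}.
#' A present influence gets a magnitude uniform on \code{(0, rint0)} and a
#' sign that is positive (facilitative) with probability \code{fac_ratio} and
#' negative (inhibitory) otherwise. Consumption accompanies every influence
#' link regardless of its sign: a species consumes every mediator that
#' affects its growth rate.
#'
#' All random draws happen in a fixed order with a fixed count, so two
#' networks generated from the same seed but different \code{fac_ratio}
#' share topology, rates and influence magnitudes and differ only in the
#' signs of the influences (common random numbers across sweep conditions).
#' The caller's RNG state is left untouched.
#'
#' @param n_species number of species (cell types) in the initial pool.
#' @param n_mediators number of interaction mediators.
#' @param qp probability of a production link per (mediator, species) pair.
#' @param qc probability of an influence/consumption link per pair.
#' @param fac_ratio probability that a present influence is facilitative;
#'   e.g. a 90:10 fac:inh community pool has \code{fac_ratio = 0.9}.
#' @param beta0 mean production rate, fmol per cell per hour.
#' @param alpha0 mean consumption rate, fmol per cell per hour.
#' @param rint0 maximum influence magnitude, 1/hr at mediator saturation.
#' @param r0_range range of basal growth rates, 1/hr (length-2 numeric).
#' @param seed integer RNG seed; identical seeds give identical networks.
#' @return An object of class \code{interaction_network}: a list with
#'   \code{n_species}, \code{n_mediators}, matrices \code{rho}
#'   (species x mediators, signed influence), \code{beta} and \code{alpha}
#'   (mediators x species, production and consumption rates), the basal
#'   growth rates \code{r0}, the \code{seed} and the generation parameters.
#' @examples
#' net <- generate_network(seed = 1)
#' net
#' all((net$alpha > 0) == t(net$rho != 0))  # consumption tracks influence
#' @export
generate_network <- function(n_species = 10, n_mediators = 5,
                             qp = 0.5, qc = 0.5, fac_ratio = 0.5,
                             beta0 = 0.1, alpha0 = 0.15, rint0 = 0.2,
                             r0_range = c(0.1, 0.2), seed) {
  for (p in c(qp = qp, qc = qc, fac_ratio = fac_ratio)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("'qp', 'qc' and 'fac_ratio' must be probabilities in [0, 1]")
  }
  for (v in list(beta0 = beta0, alpha0 = alpha0, rint0 = rint0)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'beta0', 'alpha0' and 'rint0' must be positive numbers")
  }
  if (!is.numeric(r0_range) || length(r0_range) != 2L ||
      any(!is.finite(r0_range)) || r0_range[1] > r0_range[2] || r0_range[1] < 0)
    stop("'r0_range' must be a nondecreasing nonnegative pair")
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer 'seed' is required")
  n_species <- as.integer(n_species); n_mediators <- as.integer(n_mediators)
  if (n_species < 1L || n_mediators < 1L)
    stop("'n_species' and 'n_mediators' must be >= 1")

  nc <- n_species; nm <- n_mediators
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  # fixed draw order and count (common random numbers across conditions)
  u_prod    <- matrix(stats::runif(nm * nc), nm, nc)
  rate_prod <- matrix(stats::runif(nm * nc, 0.5 * beta0, 1.5 * beta0), nm, nc)
  u_infl    <- matrix(stats::runif(nm * nc), nm, nc)
  mag       <- matrix(stats::runif(nc * nm, 0, rint0), nc, nm)
  rate_cons <- matrix(stats::runif(nm * nc, 0.5 * alpha0, 1.5 * alpha0), nm, nc)
  r0        <- stats::runif(nc, r0_range[1], r0_range[2])
  u_sign    <- matrix(stats::runif(nc * nm), nc, nm)

  beta  <- rate_prod * (u_prod < qp)
  infl  <- u_infl < qc                    # (mediator j, species i)
  alpha <- rate_cons * infl
  sgn   <- ifelse(u_sign < fac_ratio, 1, -1)
  rho   <- sgn * mag * t(infl)            # (species i, mediator j)

  net <- list(n_species = nc, n_mediators = nm,
              rho = rho, beta = beta, alpha = alpha, r0 = r0,
              seed = as.integer(seed),
              params = list(qp = qp, qc = qc, fac_ratio = fac_ratio,
                            beta0 = beta0, alpha0 = alpha0, rint0 = rint0,
                            r0_range = as.numeric(r0_range)))
  class(net) <- "interaction_network"
  net
}

#' Weaken or remove self-facilitation links
#'
#' A self-facilitation link is a (species, mediator) pair in which the
#' species produces a mediator that positively influences its own growth.
#' This multiplies the influence magnitude of every such pair by
#' \code{factor}, leaving all other influences untouched. Used to probe how
#' much community outcomes depend on species feeding back on themselves.
#'
#' @param network an \code{interaction_network}.
#' @param factor scale in \code{[0, 1]}; \code{0} removes self-facilitation
#'   entirely, \code{1} is the identity.
#' @return A new \code{interaction_network}.
#' @export
scale_self_facilitation <- function(network, factor) {
  stopifnot(inherits(network, "interaction_network"))
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) ||
      factor < 0 || factor > 1)
    stop("'factor' must be a single number in [0, 1]")
  mask <- t(network$beta > 0) & (network$rho > 0)
  network$rho[mask] <- network$rho[mask] * factor
  network
}

#' Count self-facilitation links
#'
#' @param network an \code{interaction_network}.
#' @return Number of (species, mediator) pairs where the species produces a
#'   mediator that facilitates its own growth.
#' @export
count_self_facilitation <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  sum(t(network$beta > 0) & (network$rho > 0))
}

#' @export
print.interaction_network <- function(x, ...) {
  n_inf <- sum(x$rho != 0)
  cat(sprintf("Interaction network: %d species, %d mediators (seed %d)\n",
              x$n_species, x$n_mediators, x$seed))
  cat(sprintf("  production links: %d, influence/consumption links: %d\n",
              sum(x$beta > 0), n_inf))
  cat(sprintf("  facilitative: %d, inhibitory: %d, self-facilitation: %d\n",
              sum(x$rho > 0), sum(x$rho < 0), count_self_facilitation(x)))
  cat(sprintf("  basal growth rates: %.3f-%.3f /hr\n",
              min(x$r0), max(x$r0)))
  invisible(x)
}

#' Write an interaction network to disk
#'
#' Serializes the network to a self-describing JSON file (matrices, growth
#' rates, seed and generation parameters) at full double precision, so that
#' [read_network()] reproduces the object exactly.
#'
#' @param network an \code{interaction_network}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "interaction_network"))
  # doubles go out as %.17g strings: strtod round-trips them bit-exactly,
  # which plain JSON numbers (15 significant digits) do not
  enc <- function(x) sprintf("%.17g", as.numeric(x))
  payload <- list(format = "spatcoex_network", version = 1L,
                  n_species = network$n_species,
                  n_mediators = network$n_mediators,
                  seed = network$seed,
                  params = lapply(network$params, enc),
                  r0 = enc(network$r0),
                  rho = enc(network$rho),
                  beta = enc(network$beta),
                  alpha = enc(network$alpha))
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read an interaction network from disk
#'
#' @param path a file written by [write_network()].
#' @return The \code{interaction_network}.
#' @export
read_network <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$format, "spatcoex_network"))
    stop("not a spatcoex network file: ", path)
  nc <- as.integer(raw$n_species); nm <- as.integer(raw$n_mediators)
  dec <- function(x) as.numeric(x)
  net <- list(n_species = nc, n_mediators = nm,
              rho = matrix(dec(raw$rho), nc, nm),
              beta = matrix(dec(raw$beta), nm, nc),
              alpha = matrix(dec(raw$alpha), nm, nc),
              r0 = dec(raw$r0), seed = as.integer(raw$seed),
              params = list(qp = dec(raw$params$qp), qc = dec(raw$params$qc),
                            fac_ratio = dec(raw$params$fac_ratio),
                            beta0 = dec(raw$params$beta0),
                            alpha0 = dec(raw$params$alpha0),
                            rint0 = dec(raw$params$rint0),
                            r0_range = dec(raw$params$r0_range)))
  class(net) <- "interaction_network"
  net
}
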