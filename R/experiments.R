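#' Derive a per-instance RNG seed from a master seed
#'
#' Deterministic, collision-free over practical ensemble sizes, and kept
#' below 2^31 so it is always a valid R seed. Instance k of a sweep uses
#' the same seed in every condition and mode (common random numbers), so
#' paired conditions share networks wherever the network parameters agree.
#'
#' @param master_seed integer master seed.
#' @param k instance index (1-based).
#' @return A single integer seed.
#' @export
instance_seed <- function(master_seed, k) {
  s <- (as.numeric(master_seed) %% 1048573) * 2039 + as.numeric(k) * 7919
  as.integer(s %% 2147483629 + 1)
}

.default_network_params <- function() {
  list(n_species = 10, n_mediators = 5, qp = 0.5, qc = 0.5, fac_ratio = 0.5,
       beta0 = 0.1, alpha0 = 0.15, rint0 = 0.2, r0_range = c(0.1, 0.2))
}

# Which sweepable parameter names belong to the network generator vs the
# simulation config.
.network_param_names <- function() names(.default_network_params())

.run_instance <- function(k, master_seed, mode, config, network_params,
                          self_fac_factor = NULL) {
  seed <- instance_seed(master_seed, k)
  net <- do.call(generate_network, c(network_params, list(seed = seed)))
  if (!is.null(self_fac_factor))
    net <- scale_self_facilitation(net, self_fac_factor)
  out <- tryCatch(run_enrichment(net, config, mode = mode),
                  error = function(e) e)
  if (inherits(out, "error")) {
    data.frame(instance = k, seed = seed, mode = mode,
               richness = NA_real_, richness_present = NA_real_,
               shannon = NA_real_, n_rounds = NA_real_,
               generations = NA_real_,
               survivors = NA_character_,
               error = conditionMessage(out),
               stringsAsFactors = FALSE)
  } else {
    data.frame(instance = k, seed = seed, mode = mode,
               richness = out$richness,
               richness_present = out$richness_present,
               shannon = out$shannon, n_rounds = out$n_rounds,
               generations = out$total_generations,
               survivors = paste(out$survivors_stable, collapse = ","),
               error = NA_character_, stringsAsFactors = FALSE)
  }
}

#' Run an ensemble of enrichment simulations
#'
#' Simulates \code{n_instances} independent random communities under one
#' condition. Instance \code{k} draws its network from
#' \code{instance_seed(master_seed, k)}, so ensembles run under different
#' conditions or modes with the same master seed are paired: they share
#' identical networks wherever the network parameters coincide (and differ
#' only through the parameter under study otherwise). Instance-level
#' integration failures are recorded in the \code{error} column, never
#' fatal.
#'
#' @param n_instances number of random communities (>= 1).
#' @param master_seed integer master seed.
#' @param mode \code{"spatial"}, \code{"well_mixed"} or
#'   \code{"infinite_dispersal"} (see [run_enrichment()]).
#' @param config a \code{sim_config}.
#' @param network_params named list of overrides for [generate_network()]
#'   (e.g. \code{list(fac_ratio = 0.9)}).
#' @param self_fac_factor optional factor passed to
#'   [scale_self_facilitation()] on every generated network.
#' @return A data frame with one row per instance: seed, richness (stable),
#'   richness_present, Shannon index, rounds, generations, survivor set.
#' @examples
#' \donttest{
#' run_ensemble(3, master_seed = 1, mode = "well_mixed",
#'              config = sim_config(n_gen = 30))
#' }
#' @export
run_ensemble <- function(n_instances, master_seed,
                         mode = c("spatial", "well_mixed",
                                  "infinite_dispersal"),
                         config = sim_config(), network_params = list(),
                         self_fac_factor = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(n_instances) || n_instances < 1)
    stop("'n_instances' must be >= 1")
  params <- utils::modifyList(.default_network_params(), network_params)
  bad <- setdiff(names(network_params), .network_param_names())
  if (length(bad))
    stop("unknown network parameter(s): ", paste(bad, collapse = ", "))
  do.call(rbind, lapply(seq_len(n_instances), .run_instance,
                        master_seed = master_seed, mode = mode,
                        config = config, network_params = params,
                        self_fac_factor = self_fac_factor))
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples \code{values} with replacement \code{n_boot} times, takes the
#' mean of each resample, and returns the sample mean with the percentile
#' interval of the bootstrap distribution (order statistics, no
#' interpolation). Deterministic given \code{seed}.
#'
#' @param values numeric vector, length >= 2.
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed optional integer seed.
#' @return Named numeric vector \code{(mean, lower, upper)}.
#' @examples
#' bootstrap_ci(c(3, 3, 3, 3), seed = 1)  # degenerate: (3, 3, 3)
#' @export
bootstrap_ci <- function(values, n_boot = 100, level = 0.95, seed = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values for a bootstrap CI")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  boots <- vapply(seq_len(n_boot), function(b)
    mean(sample(values, replace = TRUE)), numeric(1))
  qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        type = 1, names = FALSE)
  c(mean = mean(values), lower = qs[1], upper = qs[2])
}

.split_condition <- function(cond) {
  cond <- as.list(cond)
  net_names <- intersect(names(cond), .network_param_names())
  cfg_names <- setdiff(names(cond), net_names)
  list(network = cond[net_names], config = cond[cfg_names])
}

#' Factorial parameter sweep with bootstrap statistics
#'
#' Runs a full factorial sweep over a named parameter grid, for each
#' requested mode, with \code{n_instances} paired random communities per
#' condition (instance \code{k} uses the same seed in every condition).
#' Grid names may refer to network-generation parameters (\code{qp},
#' \code{qc}, \code{fac_ratio}, \code{beta0}, \code{alpha0}, \code{rint0},
#' \code{n_species}, \code{n_mediators}) or to any settable
#' \code{sim_config} field (\code{D_cell}, \code{D_med}, \code{k_Y}, ...);
#' unknown names raise an error before any simulation starts. Per-condition
#' mean richness is reported with a percentile bootstrap confidence
#' interval over instances.
#'
#' @param grid named list of parameter value vectors (full factorial).
#' @param n_instances instances per condition.
#' @param master_seed integer master seed.
#' @param modes character vector of modes to run each condition in.
#' @param config base \code{sim_config} that grid entries override.
#' @param network_params base network parameter overrides.
#' @param n_boot,level bootstrap settings (see [bootstrap_ci()]).
#' @param reuse optional data frame of previously computed instance rows
#'   (as found in \code{sweep_instances.csv}); matching
#'   (condition, mode, instance) rows are taken from it instead of being
#'   recomputed. Because every instance is a pure function of its condition
#'   and seed, the aggregates are identical to a fresh run.
#' @return An object of class \code{sweep_table}: list with
#'   \code{instances} (one row per condition x mode x instance) and
#'   \code{aggregates} (per condition x mode: mean richness, bootstrap CI,
#'   mean Shannon, instance counts).
#' @examples
#' \donttest{
#' sw <- sweep_richness(list(fac_ratio = c(0.1, 0.9)), n_instances = 3,
#'                      master_seed = 1, modes = "well_mixed",
#'                      config = sim_config(n_gen = 30))
#' sw$aggregates
#' }
#' @export
sweep_richness <- function(grid, n_instances, master_seed,
                           modes = "spatial", config = sim_config(),
                           network_params = list(), n_boot = 100,
                           level = 0.95, reuse = NULL) {
  if (!is.list(grid) || is.null(names(grid)) || any(names(grid) == ""))
    stop("'grid' must be a fully named list of parameter vectors")
  known <- c(.network_param_names(),
             setdiff(names(sim_config()), c("n_z", "dt", "dc")))
  bad <- setdiff(names(grid), known)
  if (length(bad))
    stop("unknown sweep parameter(s): ", paste(bad, collapse = ", "))
  conditions <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
  inst_rows <- list(); agg_rows <- list(); idx <- 0L
  for (ci in seq_len(nrow(conditions))) {
    parts <- .split_condition(conditions[ci, , drop = FALSE])
    cfg <- do.call(update_config, c(list(config), parts$config))
    for (mode in modes) {
      idx <- idx + 1L
      full_params <- utils::modifyList(
        .default_network_params(),
        utils::modifyList(network_params, parts$network))
      ens_cols <- c("instance", "seed", "mode", "richness",
                    "richness_present", "shannon", "n_rounds",
                    "generations", "survivors", "error")
      ens <- do.call(rbind, lapply(seq_len(n_instances), function(k) {
        if (!is.null(reuse)) {
          hit <- reuse[reuse$condition == ci & reuse$mode == mode &
                         reuse$instance == k, , drop = FALSE]
          if (nrow(hit) == 1L) {
            row <- hit[, ens_cols, drop = FALSE]
            rownames(row) <- NULL
            return(row)
          }
        }
        .run_instance(k, master_seed, mode, cfg, full_params)
      }))
      inst <- cbind(conditions[rep(ci, nrow(ens)), , drop = FALSE],
                    condition = ci, ens, row.names = NULL)
      inst_rows[[idx]] <- inst
      ok <- ens$richness[!is.na(ens$richness)]
      ci_seed <- instance_seed(master_seed, 10000L + idx)
      stats <- if (length(ok) >= 2) bootstrap_ci(ok, n_boot, level, ci_seed)
               else c(mean = mean(ok), lower = NA_real_, upper = NA_real_)
      agg_rows[[idx]] <- cbind(
        conditions[ci, , drop = FALSE],
        data.frame(condition = ci, mode = mode,
                   mean_richness = unname(stats["mean"]),
                   ci_lower = unname(stats["lower"]),
                   ci_upper = unname(stats["upper"]),
                   mean_shannon = mean(ens$shannon, na.rm = TRUE),
                   n_instances = length(ok),
                   n_failed = sum(is.na(ens$richness))),
        row.names = NULL)
    }
  }
  structure(list(instances = do.call(rbind, inst_rows),
                 aggregates = do.call(rbind, agg_rows),
                 grid = grid, modes = modes,
                 n_instances = n_instances, master_seed = master_seed),
            class = "sweep_table")
}

#' @export
print.sweep_table <- function(x, ...) {
  cat(sprintf("Parameter sweep: %d condition(s) x %s, %d instances each\n",
              nrow(x$aggregates) / length(x$modes),
              paste(x$modes, collapse = "/"), x$n_instances))
  print(x$aggregates, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot sweep results (mean richness with bootstrap CI)
#'
#' @param x a \code{sweep_table}.
#' @param parameter which grid parameter to put on the x axis (default the
#'   first one).
#' @param ... passed to [graphics::plot()].
#' @return \code{x}, invisibly.
#' @export
plot.sweep_table <- function(x, parameter = names(x$grid)[1], ...) {
  agg <- x$aggregates
  xs <- agg[[parameter]]
  graphics::plot(range(xs), range(c(agg$ci_lower, agg$ci_upper, agg$mean_richness),
                                  na.rm = TRUE),
                 type = "n", xlab = parameter, ylab = "mean richness", ...)
  for (m in seq_along(x$modes)) {
    sub <- agg[agg$mode == x$modes[m], ]
    o <- order(sub[[parameter]])
    graphics::lines(sub[[parameter]][o], sub$mean_richness[o], col = m,
                    type = "b", pch = c(15, 16, 17)[m])
    graphics::arrows(sub[[parameter]][o], sub$ci_lower[o],
                     sub[[parameter]][o], sub$ci_upper[o],
                     angle = 90, code = 3, length = 0.03, col = m)
  }
  graphics::legend("topleft", legend = x$modes, col = seq_along(x$modes),
                   pch = c(15, 16, 17)[seq_along(x$modes)], bty = "n")
  invisible(x)
}

#' Spatial-arrangement shuffling experiment
#'
#' Re-runs the enrichment of one fixed network under \code{n_shuffles}
#' random permutations of the initial species block order, keeping species
#' properties and interactions intact, and compares each outcome to the
#' identity arrangement. Quantifies how much coexistence depends on which
#' species start next to which.
#'
#' @param network an \code{interaction_network}.
#' @param n_shuffles number of random arrangements (>= 1).
#' @param seed integer seed for the permutation draws.
#' @param config a \code{sim_config}.
#' @param mode passed to [run_enrichment()] (shuffling is only meaningful
#'   for spatial modes; in infinite-dispersal mode all arrangements are
#'   equivalent by construction).
#' @return List with \code{baseline_richness} (identity arrangement),
#'   \code{richness} per shuffle, the permutations used (one per row),
#'   \code{min}, \code{max}, and \code{fraction_differing} from baseline.
#' @export
shuffle_experiment <- function(network, n_shuffles, seed,
                               config = sim_config(), mode = "spatial") {
  if (n_shuffles < 1) stop("'n_shuffles' must be >= 1")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  nc <- network$n_species
  perms <- t(vapply(seq_len(n_shuffles), function(i) sample.int(nc),
                    integer(nc)))
  baseline <- run_enrichment(network, config, mode = mode)$richness
  rich <- vapply(seq_len(n_shuffles), function(i)
    run_enrichment(network, config, permutation = perms[i, ],
                   mode = mode)$richness, numeric(1))
  list(baseline_richness = baseline, richness = rich, permutations = perms,
       min = min(rich), max = max(rich),
       fraction_differing = mean(rich != baseline))
}
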