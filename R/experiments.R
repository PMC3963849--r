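# Experiment designs: the single-site scalar analysis, the two parameter
# sensitivity sweeps over triangular domains, the multi-site ensemble that
# mimics spatial sampling of tree cover, and the three-size-class run.

#' Reference scalar model
#'
#' The package's canonical one-class configuration: cover retention 0.9
#' without fire and 0.4 with fire, recruitment 0.1, fire certain below
#' cover 0.2 and absent above 0.8. Its undisturbed and disturbed steady
#' covers are 10/19 (about 0.526) and 0.15625.
#'
#' Note that for these thresholds the disturbed steady cover lies below
#' `theta1`, so once cover drops under 0.2 fire recurs every year and the
#' long-run distribution is unimodal at low cover; see
#' [bimodal_reference_model()] for a variant where both dynamics are
#' sticky but escapable and the distribution is bimodal.
#'
#' @param seed integer seed stored with the model.
#' @return a [tree_model()].
#' @export
reference_model <- function(seed = 1L) {
  tree_model(A_nf = 0.9, A_f = 0.4, a = 0.1,
             fire = fire_model(theta1 = 0.2, theta2 = 0.8), seed = seed)
}

#' Fast-recovery (resprouter) scalar model
#'
#' A one-class configuration representing fire-adapted savanna trees that
#' re-establish cover rapidly after a burn (thick bark, root reserves,
#' vigorous resprouting): retention 0.93 without fire, 0.3 with fire, and
#' a high recruitment rate 0.5 so that open space refills within a couple
#' of years. Rapid post-fire recovery is what lets the system climb back
#' through the fire-prone cover range before burning again, and is
#' therefore the demographic regime in which switching can hold the system
#' near both steady states — the natural base for the fire-parameter
#' sensitivity sweep.
#'
#' @param seed integer seed stored with the model.
#' @return a [tree_model()].
#' @export
resprouter_model <- function(seed = 1L) {
  tree_model(A_nf = 0.93, A_f = 0.3, a = 0.5,
             fire = fire_model(theta1 = 0.2, theta2 = 0.8), seed = seed)
}

#' Bimodal reference scalar model
#'
#' The [resprouter_model()] demography with the fire thresholds re-solved
#' via [invert_fire_thresholds()] so that the fire probability is
#' `p_at_nf` at the undisturbed steady state and `p_at_f` at the disturbed
#' one. With the defaults (0.05 and 0.9) both dynamics have a low risk of
#' being left while neither traps the system, the regime where switching
#' produces a clearly bimodal stationary cover distribution with clustered
#' fire years.
#'
#' @param p_at_nf,p_at_f target fire probabilities at the two steady
#'   states.
#' @param seed integer seed stored with the model.
#' @return a [tree_model()].
#' @export
bimodal_reference_model <- function(p_at_nf = 0.05, p_at_f = 0.9,
                                    seed = 1L) {
  base <- resprouter_model(seed)
  th <- invert_fire_thresholds(p_at_nf, p_at_f, base)
  tree_model(A_nf = base$A_nf, A_f = base$A_f, a = base$a,
             fire = fire_model(th[["theta1"]], th[["theta2"]]), seed = seed)
}

#' Three-size-class demonstration model
#'
#' A synthetic three-class Lefkovitch configuration (class 1 small trees,
#' class 2 medium, class 3 large) built for demonstration: without fire,
#' cover advances up the size ladder with high large-tree survival; with
#' fire, small trees are mostly killed, medium trees suffer topkill back
#' into the small class, and large trees largely resist. The fire feedback
#' reads the effective cover over classes 2 and 3 only, the small class
#' contributing no canopy. The demographic rates are the package's own
#' illustrative values, not estimates for a particular species.
#'
#' With the defaults the model switches between a forest-like state
#' (effective tall cover about 0.87, fire probability 0.08) and an open
#' savanna state (tall cover near zero, fire probability 0.93), with
#' strongly clustered fire years. Fire probability is capped at
#' `p_max = 0.95` — even on bare ground not every year carries an
#' ignition — which is what lets the system escape the low-cover state.
#'
#' @param theta1,theta2 fire thresholds on the effective (classes 2 + 3)
#'   cover.
#' @param p_max fire probability at or below `theta1`.
#' @param seed integer seed stored with the model.
#' @return a [tree_model()] with `n = 3` and `cover_classes = c(2, 3)`.
#' @export
three_class_model <- function(theta1 = 0, theta2 = 0.95, p_max = 0.95,
                              seed = 1L) {
  A_nf <- matrix(c(0.50, 0.00, 0.00,
                   0.40, 0.65, 0.00,
                   0.00, 0.30, 0.96),
                 nrow = 3L, byrow = TRUE)
  A_f <- matrix(c(0.05, 0.30, 0.00,
                  0.02, 0.45, 0.03,
                  0.00, 0.05, 0.80),
                nrow = 3L, byrow = TRUE)
  tree_model(A_nf = A_nf, A_f = A_f, a = 0.5,
             fire = fire_model(theta1, theta2, p_max = p_max,
                               cover_classes = c(2L, 3L)),
             seed = seed)
}

#' Derive a child seed from a master seed
#'
#' Counter-based derivation used by grid sweeps and ensembles so that every
#' point/site gets an independent, reproducible stream; results stay below
#' `2^31`.
#'
#' @param master integer master seed.
#' @param counter nonnegative integer counter (grid point or site number).
#' @return an integer seed.
#' @export
child_seed <- function(master, counter) {
  as.integer((as.double(master) %% 2147483647 * 48271 +
                as.double(counter) * 16807 + 1) %% 2147483647)
}

#' Single-site analysis bundle
#'
#' Runs one simulation and assembles the standard single-site artifacts:
#' permanence ratios, the three cover histograms (total / fire years /
#' no-fire years), the discretized chain with its stationary cover
#' distribution, and the bimodality reports from both routes.
#'
#' @param config a [tree_model()] (any dimension; the classical analysis
#'   uses one class).
#' @param horizon simulation length in years.
#' @param delta chain grid width.
#' @param bin_width histogram bin width.
#' @param burn_in years discarded by the statistics.
#' @param x0 initial state (default bare ground).
#' @param seed simulation seed (default the model's).
#' @return class `single_site_run`: list with `trajectory`, `permanence`,
#'   `histograms`, `chain`, `stationary_cover`, `bimodality_trajectory`,
#'   `bimodality_chain`.
#' @export
run_single_site <- function(config, horizon = 5000, delta = 0.01,
                            bin_width = 0.1, burn_in = 100, x0 = NULL,
                            seed = config$seed) {
  sim <- simulate_tree_cover(config, x0 = x0, horizon = horizon, seed = seed)
  chain <- build_chain(config, delta = delta)
  structure(list(trajectory = sim,
                 permanence = permanence_ratios(sim$fire, burn_in = burn_in),
                 histograms = histogram_by_dynamic(sim, bin_width, burn_in),
                 chain = chain,
                 stationary_cover = cover_distribution(chain, bin_width),
                 bimodality_trajectory = bimodality_index(sim,
                                                          bin_width = bin_width,
                                                          burn_in = burn_in),
                 bimodality_chain = bimodality_index(chain,
                                                     bin_width = bin_width)),
            class = "single_site_run")
}

#' @export
print.single_site_run <- function(x, ...) {
  print(x$trajectory)
  print(x$permanence)
  cat("Trajectory-mode "); print(x$bimodality_trajectory)
  cat("Chain-mode      "); print(x$bimodality_chain)
  invisible(x)
}

point_bimodality <- function(config, horizon, burn_in, bin_width, seed) {
  sim <- simulate_tree_cover(config, horizon = horizon, seed = seed)
  bimodality_index(sim, bin_width = bin_width, burn_in = burn_in)
}

new_sensitivity_grid <- function(df, axes) {
  structure(list(points = df, axes = axes), class = "sensitivity_grid")
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat("Sensitivity grid over (", x$axes[1L], ", ", x$axes[2L], "): ",
      nrow(x$points), " feasible points, ",
      sum(x$points$verdict == "bimodal"), " bimodal\n", sep = "")
  invisible(x)
}

#' Sensitivity sweep over demographic parameters
#'
#' Sweeps the scalar cover retentions without fire (`alpha_nf`) and with
#' fire (`alpha_f`) over the triangular feasible domain
#' `0 < alpha_f <= alpha_nf <= 1` (fire cannot improve survival), keeping
#' recruitment and the fire curve fixed. At each feasible, stable point a
#' fresh seeded simulation yields the bimodality index and the mean cover,
#' so the grid maps where switching produces bimodality: fast growth with
#' high fire resistance or slow growth with low resistance collapse the two
#' dynamics into one (unimodal, high or low mean), while fast growth with
#' high fire vulnerability keeps both steady states attractive and yields
#' bimodality.
#'
#' @param config scalar base [tree_model()] supplying `a` and the fire
#'   curve.
#' @param grid_step spacing of the retention values (`seq(grid_step, 1,
#'   by = grid_step)`).
#' @param horizon,burn_in,bin_width per-point simulation settings.
#' @param seed master seed; each grid point uses a derived child seed.
#' @return class `sensitivity_grid`: data frame `points` with columns
#'   `alpha_nf`, `alpha_f`, `B`, `mean_cover` (binned mean), `verdict`.
#'   Infeasible or unstable points are absent, not zero.
#' @export
sensitivity_demographic <- function(config, grid_step = 0.05, horizon = 5000,
                                    burn_in = 100, bin_width = 0.1,
                                    seed = 1L) {
  stopifnot(inherits(config, "tree_model"))
  if (config$n != 1L)
    stop("the demographic sweep is defined for the scalar (one-class) model")
  vals <- seq(grid_step, 1, by = grid_step)
  pts <- expand.grid(alpha_nf = vals, alpha_f = vals)
  pts <- pts[pts$alpha_f <= pts$alpha_nf + 1e-12, ]
  out <- vector("list", nrow(pts))
  cnt <- 0L
  for (r in seq_len(nrow(pts))) {
    m <- tree_model(A_nf = pts$alpha_nf[r], A_f = pts$alpha_f[r],
                    a = config$a, fire = config$fire,
                    recruitment = config$recruitment)
    st <- stability_check(m)
    if (!st$stable_nf || !st$stable_f) next
    cnt <- cnt + 1L
    rep <- point_bimodality(m, horizon, burn_in, bin_width,
                            seed = child_seed(seed, r))
    out[[r]] <- data.frame(alpha_nf = pts$alpha_nf[r],
                           alpha_f = pts$alpha_f[r],
                           B = rep$B, mean_cover = rep$mu,
                           verdict = rep$verdict)
  }
  if (!cnt) stop("no feasible grid points")
  new_sensitivity_grid(do.call(rbind, out[!vapply(out, is.null, TRUE)]),
                       c("alpha_nf", "alpha_f"))
}

#' Sensitivity sweep over fire-probability parameters
#'
#' Sweeps the target fire probabilities at the two steady states over the
#' triangular domain `0 < p_at_nf < p_at_f < 1`, solving for the thresholds
#' `(theta1, theta2)` at each point via [invert_fire_thresholds()] and
#' skipping infeasible points (where the thresholds escape `[0, 1]`). Low
#' fire risk at both steady states makes the no-fire dynamic dominant with
#' high mean cover; high risk at both makes fire dominant with low mean;
#' low risk at the undisturbed and high risk at the disturbed steady state
#' makes both dynamics sticky and the distribution bimodal.
#'
#' @param config scalar base [tree_model()] with `p_max = 1`, `p_min = 0`
#'   and distinct steady covers.
#' @param grid_step spacing of the probability values
#'   (`seq(grid_step, 1 - grid_step, by = grid_step)`).
#' @param horizon,burn_in,bin_width per-point simulation settings.
#' @param seed master seed for the per-point child seeds.
#' @return class `sensitivity_grid` with columns `p_at_nf`, `p_at_f`, `B`,
#'   `mean_cover`, `verdict`.
#' @export
sensitivity_fire <- function(config, grid_step = 0.05, horizon = 5000,
                             burn_in = 100, bin_width = 0.1, seed = 1L) {
  stopifnot(inherits(config, "tree_model"))
  if (config$n != 1L)
    stop("the fire sweep is defined for the scalar (one-class) model")
  st <- stability_check(config)
  if (!st$stable_nf || !st$stable_f)
    stop("both dynamics must be stable for the fire sweep")
  vals <- seq(grid_step, 1 - grid_step, by = grid_step)
  pts <- expand.grid(p_at_nf = vals, p_at_f = vals)
  pts <- pts[pts$p_at_f > pts$p_at_nf + 1e-12, ]
  out <- vector("list", nrow(pts))
  for (r in seq_len(nrow(pts))) {
    th <- try(invert_fire_thresholds(pts$p_at_nf[r], pts$p_at_f[r], config),
              silent = TRUE)
    if (inherits(th, "try-error")) next
    m <- tree_model(A_nf = config$A_nf, A_f = config$A_f, a = config$a,
                    fire = fire_model(th[["theta1"]], th[["theta2"]],
                                      p_max = 1, p_min = 0),
                    recruitment = config$recruitment)
    rep <- point_bimodality(m, horizon, burn_in, bin_width,
                            seed = child_seed(seed, r))
    out[[r]] <- data.frame(p_at_nf = pts$p_at_nf[r], p_at_f = pts$p_at_f[r],
                           B = rep$B, mean_cover = rep$mu,
                           verdict = rep$verdict)
  }
  keep <- !vapply(out, is.null, TRUE)
  if (!any(keep)) stop("no feasible grid points")
  new_sensitivity_grid(do.call(rbind, out[keep]), c("p_at_nf", "p_at_f"))
}

interval_spec_ok <- function(iv) {
  ok_pair <- function(p) is.numeric(p) && length(p) == 2L && p[1L] <= p[2L]
  if (is.list(iv)) all(vapply(iv, ok_pair, TRUE)) else ok_pair(iv)
}

draw_from_intervals <- function(iv, u_pick, u_val) {
  # iv: c(lo, hi) or a list of such (union of disjoint intervals, chosen
  # with probability proportional to length)
  if (is.list(iv)) {
    lens <- vapply(iv, function(p) p[2L] - p[1L], 0)
    if (all(lens == 0)) {
      pick <- iv[[1L + (u_pick >= 0.5) * (length(iv) > 1L)]]
    } else {
      cum <- cumsum(lens) / sum(lens)
      pick <- iv[[findInterval(u_pick, cum, left.open = TRUE) + 1L]]
    }
    iv <- pick
  }
  iv[1L] + u_val * (iv[2L] - iv[1L])
}

default_regime <- function(alpha_nf, alpha_f, a, theta1, theta2) {
  list(alpha_nf = alpha_nf, alpha_f = alpha_f, a = a,
       theta1 = theta1, theta2 = theta2)
}

#' Default parameter regimes for ensembles
#'
#' `ensemble_ranges_bimodal()` is a single regime whose every draw falls in
#' the bimodal band of the sensitivity maps: narrow no-fire demography,
#' wide fire vulnerability, thresholds placing low fire risk at the
#' undisturbed and high risk at the disturbed steady state.
#' `ensemble_regimes_high_low()` is a two-regime design mixing sites from a
#' high-cover unimodal regime (fire effectively switched off once the
#' canopy closes) and a low-cover unimodal regime (permanent fire); pooling
#' such sites at one instant yields a bimodal spatial sample even though
#' every site alone is unimodal.
#'
#' @return a regime list (or list of two regime lists) of per-parameter
#'   intervals for `alpha_nf`, `alpha_f`, `a`, `theta1`, `theta2`; an
#'   interval may be a union (list) of two disjoint `c(lo, hi)` pairs.
#' @export
ensemble_ranges_bimodal <- function() {
  default_regime(alpha_nf = c(0.90, 0.95), alpha_f = c(0.25, 0.35),
                 a = c(0.45, 0.55), theta1 = c(0.50, 0.60),
                 theta2 = c(0.90, 0.98))
}

#' @rdname ensemble_ranges_bimodal
#' @export
ensemble_regimes_high_low <- function() {
  list(high = default_regime(alpha_nf = c(0.90, 0.95), alpha_f = c(0.75, 0.85),
                             a = c(0.08, 0.12), theta1 = c(0.15, 0.25),
                             theta2 = c(0.55, 0.65)),
       low = default_regime(alpha_nf = c(0.25, 0.35), alpha_f = c(0.05, 0.15),
                            a = c(0.08, 0.12), theta1 = c(0.15, 0.25),
                            theta2 = c(0.75, 0.85)))
}

#' Multi-site ensemble design
#'
#' Describes a spatial-sampling experiment: `n_sites` independent sites,
#' each simulated for `horizon` years with parameters drawn uniformly from
#' the given ranges, and pooled at `sample_time`. `ranges` is either one
#' regime (a named list of intervals for `alpha_nf`, `alpha_f`, `a`,
#' `theta1`, `theta2`, where an interval may be a union of two disjoint
#' pairs) or a list of several regimes among which sites are split evenly.
#'
#' @param n_sites number of sites.
#' @param horizon per-site simulation length (years), `>= sample_time`.
#' @param sample_time year at which the spatial sample is taken; must
#'   exceed `burn_in`.
#' @param ranges regime specification (see above); default
#'   [ensemble_ranges_bimodal()].
#' @param seed master seed; sites use derived child seeds.
#' @param burn_in years regarded as initial transient.
#' @return class `ensemble_design`.
#' @export
ensemble_design <- function(n_sites = 1000, horizon = 5000, sample_time = 300,
                            ranges = ensemble_ranges_bimodal(), seed = 1L,
                            burn_in = 100) {
  if (sample_time <= burn_in)
    stop("sample_time (", sample_time, ") must exceed burn_in (", burn_in, ")")
  if (horizon < sample_time)
    stop("horizon (", horizon, ") must reach sample_time (", sample_time, ")")
  regimes <- if (!is.null(names(ranges)) &&
                 all(c("alpha_nf", "alpha_f", "a", "theta1", "theta2") %in%
                       names(ranges))) list(ranges) else ranges
  for (rg in regimes) {
    miss <- setdiff(c("alpha_nf", "alpha_f", "a", "theta1", "theta2"),
                    names(rg))
    if (length(miss))
      stop("regime is missing intervals for: ", paste(miss, collapse = ", "))
    bad <- names(rg)[!vapply(rg, interval_spec_ok, TRUE)]
    if (length(bad))
      stop("malformed interval specification for: ",
           paste(bad, collapse = ", "))
  }
  structure(list(n_sites = as.integer(n_sites), horizon = as.integer(horizon),
                 sample_time = as.integer(sample_time), regimes = regimes,
                 seed = as.integer(seed), burn_in = as.integer(burn_in)),
            class = "ensemble_design")
}

draw_site_model <- function(regime, recruitment, seed) {
  set.seed(seed)
  u <- stats::runif(10L)
  alpha_nf <- draw_from_intervals(regime$alpha_nf, u[1L], u[2L])
  alpha_f <- draw_from_intervals(regime$alpha_f, u[3L], u[4L])
  a <- draw_from_intervals(regime$a, u[5L], u[6L])
  theta1 <- draw_from_intervals(regime$theta1, u[7L], u[8L])
  theta2 <- draw_from_intervals(regime$theta2, u[9L], u[10L])
  if (theta2 < theta1) theta2 <- theta1
  tree_model(A_nf = alpha_nf, A_f = min(alpha_f, alpha_nf), a = a,
             fire = fire_model(theta1, theta2), recruitment = recruitment)
}

#' Run a multi-site ensemble (spatial sampling of tree cover)
#'
#' Simulates every site of an [ensemble_design()] independently (site `i`
#' uses child seed `child_seed(seed, i)` for both its parameter draw and
#' its fire sequence), then pools `(cover, fire status)` across sites at
#' `sample_time` — the spatial analogue of sampling one trajectory over
#' time. Also reports the pooled bimodality index at every `stride` years
#' from `burn_in + stride` to `horizon`, computed from the same per-site
#' trajectories.
#'
#' @param design an [ensemble_design()].
#' @param base_config optional [tree_model()] supplying the recruitment
#'   mode (default [reference_model()]).
#' @param bin_width histogram bin width for the pooled sample.
#' @param stride spacing of the bimodality time series (`NULL` to skip).
#' @return class `ensemble_run`: list with `sites` (data frame of drawn
#'   parameters, regime, cover and fire status at `sample_time`),
#'   `histogram` (pooled `cover_histogram`), `bimodality` (pooled report at
#'   `sample_time`), `b_series` (data frame `time`, `B`, `verdict`), and
#'   the `design`.
#' @export
run_ensemble <- function(design, base_config = reference_model(),
                         bin_width = 0.1, stride = 100L) {
  stopifnot(inherits(design, "ensemble_design"))
  n_sites <- design$n_sites
  regime_id <- rep(seq_along(design$regimes), length.out = n_sites)
  times <- if (is.null(stride)) integer(0) else
    seq(design$burn_in + stride, design$horizon, by = stride)
  times <- sort(unique(c(times, design$sample_time)))
  cover_mat <- matrix(NA_real_, n_sites, length(times))
  fire_mat <- matrix(NA_integer_, n_sites, length(times))
  params <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    sd_i <- child_seed(design$seed, i)
    m <- draw_site_model(design$regimes[[regime_id[i]]],
                         base_config$recruitment, seed = sd_i)
    sim <- simulate_tree_cover(m, horizon = design$horizon, seed = NULL)
    tc <- total_cover(sim)
    cover_mat[i, ] <- tc[times + 1L]
    fire_mat[i, ] <- sim$fire[times]
    params[[i]] <- data.frame(site = i, regime = regime_id[i],
                              alpha_nf = m$A_nf[1L, 1L], alpha_f = m$A_f[1L, 1L],
                              a = m$a, theta1 = m$fire$theta1,
                              theta2 = m$fire$theta2)
  }
  sites <- do.call(rbind, params)
  at <- which(times == design$sample_time)
  sites$cover <- cover_mat[, at]
  sites$fire <- fire_mat[, at]
  pooled <- pooled_bimodality(sites$cover, sites$fire, bin_width = bin_width)
  b_series <- do.call(rbind, lapply(seq_along(times), function(j) {
    repj <- pooled_bimodality(cover_mat[, j], fire_mat[, j],
                              bin_width = bin_width)
    data.frame(time = times[j], B = repj$B, verdict = repj$verdict)
  }))
  structure(list(sites = sites, histogram = attr(pooled, "histogram"),
                 bimodality = pooled, b_series = b_series, design = design),
            class = "ensemble_run")
}

#' @export
print.ensemble_run <- function(x, ...) {
  cat("Ensemble of", x$design$n_sites, "sites sampled at year",
      x$design$sample_time, "\n")
  print(x$bimodality)
  invisible(x)
}

#' Three-size-class analysis bundle
#'
#' Runs the multi-class model (by default one where fire reads only the
#' medium and large classes) and collects the per-class trajectory, the
#' fire-event sequence with its empirical two-state chain, the total-cover
#' distribution from the trajectory (and from the discretized chain when
#' `delta` is given), permanence ratios and the bimodality report.
#'
#' @param config3 a [tree_model()] with several classes; default
#'   [three_class_model()].
#' @param horizon simulation length in years.
#' @param bin_width histogram bin width.
#' @param burn_in years discarded by the statistics.
#' @param delta optional chain grid width (e.g. 0.1); `NULL` skips the
#'   chain.
#' @param x0 initial state.
#' @param seed simulation seed.
#' @return class `three_class_run`: list with `trajectory`, `fire_chain`,
#'   `permanence`, `cover_histogram`, `bimodality`, and (when `delta` is
#'   given) `chain` and `stationary_cover`.
#' @export
run_three_class <- function(config3 = three_class_model(), horizon = 5000,
                            bin_width = 0.1, burn_in = 100, delta = NULL,
                            x0 = NULL, seed = config3$seed) {
  stopifnot(inherits(config3, "tree_model"))
  sim <- simulate_tree_cover(config3, x0 = x0, horizon = horizon, seed = seed)
  d <- sim_year_data(sim, burn_in)
  out <- list(trajectory = sim,
              fire_chain = estimate_fire_chain(sim$fire[-seq_len(burn_in)]),
              permanence = permanence_ratios(sim$fire, burn_in = burn_in),
              cover_histogram = cover_histogram(d$cover, bin_width),
              bimodality = bimodality_index(sim, bin_width = bin_width,
                                            burn_in = burn_in))
  if (!is.null(delta)) {
    out$chain <- build_chain(config3, delta = delta)
    out$stationary_cover <- cover_distribution(out$chain, bin_width)
  }
  structure(out, class = "three_class_run")
}

#' @export
print.three_class_run <- function(x, ...) {
  print(x$trajectory)
  print(x$permanence)
  print(x$bimodality)
  invisible(x)
}
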