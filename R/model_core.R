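# Switched Lefkovitch model of tree cover under a fire-vegetation feedback.
#
# State: x(t), an n-vector of per-size-class cover fractions with x >= 0 and
# sum(x) <= 1. Each year a Bernoulli fire indicator F(t), with probability
# p(C) decreasing in the effective cover C, selects one of two stage
# matrices; survivors/transitions are applied first, then recruitment into
# the smallest class.

.SIMPLEX_TOL <- 1e-9

#' Fire-probability feedback model
#'
#' Fire probability as a piecewise-linear, non-increasing function of the
#' effective tree cover `C`: `p_max` for `C <= theta1`, `p_min` for
#' `C >= theta2`, and linear in between. More tree cover means less grass
#' fuel, hence less fire; the positive feedback (fire begets fire) enters
#' through this curve.
#'
#' @param theta1 lower cover threshold; at or below it fire probability is
#'   `p_max`.
#' @param theta2 upper cover threshold; at or above it fire probability is
#'   `p_min`. Must satisfy `0 <= theta1 <= theta2 <= 1`. When
#'   `theta1 == theta2` the curve degenerates to a step function
#'   (`p_max` for `C <= theta1`, `p_min` otherwise).
#' @param p_max,p_min fire probabilities on the two flat branches,
#'   `0 <= p_min <= p_max <= 1`. Defaults 1 and 0 anchor the curve at
#'   certain fire under heavy grass fuel and no fire once fuel is sparse.
#' @param cover_classes integer vector of size-class indices whose covers
#'   sum to the effective cover driving the feedback, or `NULL` (default)
#'   for all classes. Lets tall-class cover drive fire while seedlings are
#'   ignored.
#' @return an object of class `fire_model`.
#' @seealso [fire_probability()], [effective_cover()]
#' @export
fire_model <- function(theta1, theta2, p_max = 1, p_min = 0,
                       cover_classes = NULL) {
  check_scalar_unit(theta1, "theta1")
  check_scalar_unit(theta2, "theta2")
  check_scalar_unit(p_max, "p_max")
  check_scalar_unit(p_min, "p_min")
  if (theta1 > theta2)
    stop("invalid fire model: theta1 (", theta1, ") > theta2 (", theta2, ")")
  if (p_min > p_max)
    stop("invalid fire model: p_min (", p_min, ") > p_max (", p_max, ")")
  if (!is.null(cover_classes)) {
    cover_classes <- as.integer(cover_classes)
    if (length(cover_classes) == 0L || anyNA(cover_classes) ||
        any(cover_classes < 1L))
      stop("invalid fire model: cover_classes must be a nonempty set of ",
           "positive class indices")
    cover_classes <- sort(unique(cover_classes))
  }
  structure(list(theta1 = theta1, theta2 = theta2,
                 p_max = p_max, p_min = p_min,
                 cover_classes = cover_classes),
            class = "fire_model")
}

check_scalar_unit <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("invalid fire model: ", name, " must be a single number in [0, 1], ",
         "got ", deparse(x))
  invisible(x)
}

#' Fire probability at a given effective cover
#'
#' Evaluates the piecewise-linear feedback curve of a [fire_model()].
#' Vectorized over `C`.
#'
#' @param C effective tree cover, in `[0, 1]` (small numerical overshoot is
#'   tolerated and clipped).
#' @param fire a `fire_model`.
#' @return fire probabilities in `[p_min, p_max]`, non-increasing in `C`.
#' @export
fire_probability <- function(C, fire) {
  stopifnot(inherits(fire, "fire_model"))
  if (any(!is.finite(C)) || any(C < -.SIMPLEX_TOL) || any(C > 1 + .SIMPLEX_TOL))
    stop("effective cover must lie in [0, 1]; got ",
         paste(utils::head(C[!is.finite(C) | C < -.SIMPLEX_TOL |
                              C > 1 + .SIMPLEX_TOL], 3L), collapse = ", "))
  C <- pmin(pmax(C, 0), 1)
  t1 <- fire$theta1; t2 <- fire$theta2
  if (t2 > t1) {
    p <- fire$p_max + (fire$p_min - fire$p_max) * (C - t1) / (t2 - t1)
    p[C <= t1] <- fire$p_max
    p[C >= t2] <- fire$p_min
  } else {
    p <- ifelse(C <= t1, fire$p_max, fire$p_min)
  }
  p
}

#' Switched tree-cover model configuration
#'
#' Bundles the two Lefkovitch stage matrices (fire / no fire), the
#' recruitment rate and the fire-probability feedback into a validated
#' model object. Entry `A[i, j]` is the proportion of class-`j` cover
#' moving into class `i` in one year; column-sum deficits are mortality.
#'
#' @param A_nf,A_f nonnegative `n x n` stage matrices for fire-free and
#'   fire years. Every column sum must be `<= 1`.
#' @param a recruitment rate into class 1, in `[0, 1]`.
#' @param fire a [fire_model()]. A `NULL` `cover_classes` is resolved to
#'   all `n` classes.
#' @param seed optional integer seed stored with the model and used as the
#'   default by [simulate_tree_cover()].
#' @param recruitment `"space_limited"` (default): after the stage update
#'   `x' = A x`, recruitment adds `a * (1 - sum(x'))` to class 1, i.e. is
#'   proportional to free space, which keeps the state on the unit simplex
#'   for any valid matrices. `"constant"`: adds `a` to class 1 regardless
#'   of space; the step errors if the simplex is left.
#' @return an object of class `tree_model` with elements `A_nf`, `A_f`,
#'   `a`, `fire`, `n`, `seed`, `recruitment`.
#' @examples
#' m <- tree_model(A_nf = 0.9, A_f = 0.4, a = 0.1,
#'                 fire = fire_model(0.2, 0.8))
#' steady_state(m, "no_fire")
#' @export
tree_model <- function(A_nf, A_f, a, fire, seed = NULL,
                       recruitment = c("space_limited", "constant")) {
  recruitment <- match.arg(recruitment)
  A_nf <- as_stage_matrix(A_nf, "A_nf")
  A_f <- as_stage_matrix(A_f, "A_f")
  n <- nrow(A_nf)
  if (nrow(A_f) != n)
    stop("invalid model: A_nf is ", n, "x", n, " but A_f is ",
         nrow(A_f), "x", nrow(A_f))
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0 || a > 1)
    stop("invalid model: recruitment rate a must be a single number in [0, 1]")
  stopifnot(inherits(fire, "fire_model"))
  if (is.null(fire$cover_classes)) {
    fire$cover_classes <- seq_len(n)
  } else if (any(fire$cover_classes > n)) {
    stop("invalid model: cover_classes refer to class ",
         max(fire$cover_classes), " but the model has ", n, " classes")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(A_nf = A_nf, A_f = A_f, a = a, fire = fire, n = n,
                 seed = seed, recruitment = recruitment),
            class = "tree_model")
}

as_stage_matrix <- function(A, name) {
  A <- as.matrix(A)
  if (!is.numeric(A) || nrow(A) != ncol(A) || anyNA(A))
    stop("invalid model: ", name, " must be a square numeric matrix")
  if (any(A < 0))
    stop("invalid model: ", name, " has negative entries")
  cs <- colSums(A)
  bad <- which(cs > 1 + .SIMPLEX_TOL)
  if (length(bad))
    stop("invalid model: column ", bad[1L], " of ", name, " sums to ",
         format(cs[bad[1L]]), " > 1 (survival cannot exceed 1)")
  unname(A)
}

#' @export
print.tree_model <- function(x, ...) {
  cat("Switched tree-cover model (", x$n, " size class",
      if (x$n > 1L) "es", ")\n", sep = "")
  cat("  recruitment: a =", x$a, paste0("(", x$recruitment, ")"), "\n")
  cat("  fire feedback: p =", x$fire$p_max, "below cover", x$fire$theta1,
      "->", x$fire$p_min, "above", x$fire$theta2, "\n")
  cat("  effective cover over classes:",
      paste(x$fire$cover_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Effective cover driving the fire feedback
#'
#' Sum of the cover fractions over the classes named in the fire model's
#' `cover_classes` (e.g. only the tall classes when seedlings carry no
#' canopy).
#'
#' @param x state vector of per-class cover fractions.
#' @param fire a `fire_model` or a `tree_model` (whose fire component is
#'   used).
#' @return a single cover value in `[0, 1]`.
#' @export
effective_cover <- function(x, fire) {
  if (inherits(fire, "tree_model")) fire <- fire$fire
  stopifnot(inherits(fire, "fire_model"))
  classes <- fire$cover_classes
  if (is.null(classes)) classes <- seq_along(x)
  if (any(classes > length(x)))
    stop("cover_classes refer to class ", max(classes),
         " but the state has ", length(x), " classes")
  sum(x[classes])
}

check_state <- function(x, n, what = "state") {
  if (!is.numeric(x) || length(x) != n || anyNA(x))
    stop("invalid ", what, ": need a numeric vector of length ", n)
  if (any(x < -.SIMPLEX_TOL) || sum(x) > 1 + .SIMPLEX_TOL)
    stop("invalid ", what, ": components must be >= 0 and sum to <= 1 ",
         "(sum = ", format(sum(x)), ")")
  pmax(x, 0)
}

#' One-year update of the tree-cover state
#'
#' Applies the stage matrix selected by the fire indicator, then recruits
#' new seedlings into class 1: `x' = A x`, followed by
#' `x' + a * (1 - sum(x')) * e1` under space-limited recruitment (the
#' default) or `x' + a * e1` under constant recruitment.
#'
#' @param x current state (validated against the model dimension).
#' @param fired logical; `TRUE` selects the fire matrix `A_f`.
#' @param config a [tree_model()].
#' @return the next state vector.
#' @export
cover_step <- function(x, fired, config) {
  stopifnot(inherits(config, "tree_model"), is.logical(fired) || fired %in% c(0, 1))
  x <- check_state(x, config$n)
  A <- if (isTRUE(as.logical(fired))) config$A_f else config$A_nf
  xp <- drop(A %*% x)
  if (config$recruitment == "space_limited") {
    xp[1L] <- xp[1L] + config$a * (1 - sum(xp))
  } else {
    xp[1L] <- xp[1L] + config$a
  }
  s <- sum(xp)
  if (s > 1 + .SIMPLEX_TOL || any(xp < -.SIMPLEX_TOL))
    stop("step left the unit simplex (total cover ", format(s),
         "); check stage matrices and recruitment mode")
  pmin(pmax(xp, 0), 1)
}

#' Simulate a tree-cover trajectory
#'
#' Iterates the switched dynamics for `horizon` years. Each year the fire
#' indicator is drawn as `F(t) ~ Bernoulli(p(C(t)))` with `p` the fire
#' feedback evaluated at the pre-update state (fuel that carries a fire
#' exists before that year's mortality), unless `forced_fire` pins the
#' dynamic. Trajectories are reproducible: the same seed, model, initial
#' state and horizon give bit-identical output.
#'
#' @param config a [tree_model()].
#' @param x0 initial state; default all-zero cover (bare ground).
#' @param horizon number of years (`>= 1`).
#' @param forced_fire `NULL` (stochastic switching) or a single logical
#'   forcing the fire (`TRUE`) / no-fire (`FALSE`) dynamic every year.
#' @param seed integer seed for the fire draws; defaults to the model's
#'   stored seed. `NULL` leaves the RNG state untouched.
#' @return an object of class `tree_simulation`: a list with `states`
#'   (`(horizon + 1) x n` matrix, row `t + 1` is the state at year `t`),
#'   `fire` (integer 0/1 vector of length `horizon`, element `t + 1` being
#'   the indicator drawn at year `t`), `config`, `seed` and `horizon`.
#' @examples
#' m <- tree_model(0.9, 0.4, a = 0.1, fire = fire_model(0.2, 0.8), seed = 1)
#' sim <- simulate_tree_cover(m, horizon = 200)
#' permanence_ratios(sim$fire, burn_in = 100)
#' @export
simulate_tree_cover <- function(config, x0 = NULL, horizon,
                                forced_fire = NULL, seed = config$seed) {
  stopifnot(inherits(config, "tree_model"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 1)
    stop("horizon must be a single integer >= 1")
  horizon <- as.integer(horizon)
  n <- config$n
  if (is.null(x0)) x0 <- numeric(n)
  x0 <- check_state(x0, n, "initial state x0")
  if (!is.null(forced_fire)) {
    stopifnot(length(forced_fire) == 1L)
    forced_fire <- as.logical(forced_fire)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  u <- if (is.null(forced_fire)) stats::runif(horizon) else NULL

  fire <- config$fire
  t1 <- fire$theta1; t2 <- fire$theta2
  pmx <- fire$p_max; pmn <- fire$p_min
  slope <- if (t2 > t1) (pmn - pmx) / (t2 - t1) else 0
  fires <- integer(horizon)

  if (n == 1L) {
    # scalar fast path: both dynamics are affine maps x -> s*x + c
    a <- config$a
    if (config$recruitment == "space_limited") {
      s_nf <- (1 - a) * config$A_nf[1L, 1L]; c_nf <- a
      s_f <- (1 - a) * config$A_f[1L, 1L]; c_f <- a
    } else {
      s_nf <- config$A_nf[1L, 1L]; c_nf <- a
      s_f <- config$A_f[1L, 1L]; c_f <- a
    }
    xs <- numeric(horizon + 1L)
    xt <- x0[1L]
    xs[1L] <- xt
    if (is.null(forced_fire)) {
      for (t in seq_len(horizon)) {
        p <- if (xt <= t1) pmx else if (xt >= t2) pmn else pmx + slope * (xt - t1)
        if (u[t] < p) {
          xt <- s_f * xt + c_f
          fires[t] <- 1L
        } else {
          xt <- s_nf * xt + c_nf
        }
        xs[t + 1L] <- xt
      }
    } else {
      s <- if (forced_fire) s_f else s_nf
      cc <- if (forced_fire) c_f else c_nf
      for (t in seq_len(horizon)) {
        xt <- s * xt + cc
        xs[t + 1L] <- xt
      }
      fires[] <- as.integer(forced_fire)
    }
    if (max(xs) > 1 + .SIMPLEX_TOL || min(xs) < -.SIMPLEX_TOL)
      stop("trajectory left the unit simplex; invalid model")
    states <- matrix(pmin(pmax(xs, 0), 1), ncol = 1L)
  } else {
    classes <- fire$cover_classes
    a <- config$a
    space_limited <- config$recruitment == "space_limited"
    A_nf <- config$A_nf; A_f <- config$A_f
    states <- matrix(0, nrow = horizon + 1L, ncol = n)
    xt <- x0
    states[1L, ] <- xt
    for (t in seq_len(horizon)) {
      if (is.null(forced_fire)) {
        C <- sum(xt[classes])
        p <- if (C <= t1) pmx else if (C >= t2) pmn else pmx + slope * (C - t1)
        f <- u[t] < p
      } else {
        f <- forced_fire
      }
      xt <- drop((if (f) A_f else A_nf) %*% xt)
      xt[1L] <- xt[1L] + if (space_limited) a * (1 - sum(xt)) else a
      states[t + 1L, ] <- xt
      fires[t] <- as.integer(f)
    }
    if (max(rowSums(states)) > 1 + .SIMPLEX_TOL || min(states) < -.SIMPLEX_TOL)
      stop("trajectory left the unit simplex; invalid model")
    states[states < 0] <- 0
  }

  structure(list(states = states, fire = fires, config = config,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 horizon = horizon),
            class = "tree_simulation")
}

#' Total cover along a simulated trajectory
#'
#' @param result a `tree_simulation`.
#' @return numeric vector of length `horizon + 1` with the summed cover of
#'   all size classes at years `0..horizon`.
#' @export
total_cover <- function(result) {
  stopifnot(inherits(result, "tree_simulation"))
  rowSums(result$states)
}

#' @export
print.tree_simulation <- function(x, ...) {
  tc <- total_cover(x)
  cat("Tree-cover simulation:", x$horizon, "years,", x$config$n,
      "size class(es)\n")
  cat("  fire years:", sum(x$fire), "of", x$horizon, "\n")
  cat("  final total cover:", format(tc[length(tc)], digits = 4), "\n")
  invisible(x)
}

effective_update_matrix <- function(config, which = c("no_fire", "fire")) {
  which <- match.arg(which)
  A <- if (which == "fire") config$A_f else config$A_nf
  if (config$recruitment == "space_limited") {
    # x(t+1) = (I - a e1 1') A x + a e1
    e1 <- c(1, numeric(config$n - 1L))
    A - config$a * outer(e1, colSums(A))
  } else {
    A
  }
}

#' Closed-form steady state of one dynamic
#'
#' The fixed point of the affine yearly map when a single dynamic is
#' applied every year: `x* = (I - Atil)^(-1) b`, where `Atil` is the
#' effective update matrix (stage matrix composed with recruitment) and
#' `b = a e1`. Forcing the no-fire dynamic gives the undisturbed steady
#' state; forcing fire gives the disturbed one.
#'
#' @param config a [tree_model()].
#' @param which `"no_fire"` or `"fire"`.
#' @return the steady-state cover vector.
#' @export
steady_state <- function(config, which = c("no_fire", "fire")) {
  stopifnot(inherits(config, "tree_model"))
  which <- match.arg(which)
  n <- config$n
  Atil <- effective_update_matrix(config, which)
  rho <- max(Mod(eigen(Atil, only.values = TRUE)$values))
  if (rho >= 1 - 1e-12)
    stop("no steady state: the ", which, " dynamic has spectral radius ",
         format(rho), " >= 1")
  b <- c(config$a, numeric(n - 1L))
  xs <- solve(diag(n) - Atil, b)
  check_state(xs, n, paste0(which, " steady state"))
}

#' Both steady states with their fire probabilities
#'
#' @param config a [tree_model()].
#' @return class `steady_states`: list with `x_nf`, `x_f` (undisturbed and
#'   disturbed steady covers), `C_nf`, `C_f` (their effective covers) and
#'   `p_nf`, `p_f` (fire probabilities there). When the fire matrix is
#'   entrywise below the no-fire matrix, `C_f <= C_nf`.
#' @export
steady_states <- function(config) {
  x_nf <- steady_state(config, "no_fire")
  x_f <- steady_state(config, "fire")
  C_nf <- effective_cover(x_nf, config$fire)
  C_f <- effective_cover(x_f, config$fire)
  structure(list(x_nf = x_nf, x_f = x_f, C_nf = C_nf, C_f = C_f,
                 p_nf = fire_probability(C_nf, config$fire),
                 p_f = fire_probability(C_f, config$fire)),
            class = "steady_states")
}

#' @export
print.steady_states <- function(x, ...) {
  cat("Steady states of the two dynamics\n")
  cat("  undisturbed (no fire): cover",
      paste(format(x$x_nf, digits = 5), collapse = " "),
      "| effective", format(x$C_nf, digits = 5),
      "| p =", format(x$p_nf, digits = 4), "\n")
  cat("  disturbed   (fire):    cover",
      paste(format(x$x_f, digits = 5), collapse = " "),
      "| effective", format(x$C_f, digits = 5),
      "| p =", format(x$p_f, digits = 4), "\n")
  invisible(x)
}

#' Sufficient stability check for the switched system
#'
#' The switched system cannot diverge if every yearly update contracts in
#' some submultiplicative norm. For each dynamic the effective update
#' matrix `Atil` is formed and two norms are reported: the induced 1-norm
#' (maximum absolute column sum), used as the operative criterion, and the
#' maximum-element norm scaled by `n` (`n * max|a_ij|`, an upper bound on
#' the induced 1-norm and itself submultiplicative). A `TRUE` flag
#' guarantees every product of the two update maps contracts in 1-norm.
#'
#' @param config a [tree_model()].
#' @return class `stability_report`: list with logicals `stable_nf`,
#'   `stable_f` and a data frame `norms` (one row per dynamic, columns
#'   `norm1` and `n_max_element`).
#' @export
stability_check <- function(config) {
  stopifnot(inherits(config, "tree_model"))
  res <- lapply(c("no_fire", "fire"), function(w) {
    Atil <- effective_update_matrix(config, w)
    c(norm1 = max(colSums(abs(Atil))),
      n_max_element = config$n * max(abs(Atil)))
  })
  norms <- as.data.frame(do.call(rbind, res))
  rownames(norms) <- c("no_fire", "fire")
  structure(list(stable_nf = norms$norm1[1L] < 1,
                 stable_f = norms$norm1[2L] < 1,
                 norms = norms),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability (sufficient condition: induced 1-norm < 1)\n")
  print(cbind(x$norms, stable = c(x$stable_nf, x$stable_f)))
  invisible(x)
}

#' Fire thresholds realizing target probabilities at the steady states
#'
#' In the `p_max = 1`, `p_min = 0` regime the feedback line is fixed by
#' its value at the two steady-state covers. Given targets
#' `p(C_nf*) = p_at_nf` and `p(C_f*) = p_at_f`, the unique thresholds are
#' `theta2 - theta1 = (C_nf* - C_f*) / (p_at_f - p_at_nf)` and
#' `theta2 = C_nf* + p_at_nf * (theta2 - theta1)`. Used by the
#' fire-parameter sensitivity sweep, where the axes are the two target
#' probabilities.
#'
#' @param p_at_nf,p_at_f target fire probabilities at the undisturbed and
#'   disturbed steady states; both strictly inside `(0, 1)` with
#'   `p_at_f > p_at_nf`.
#' @param config a [tree_model()] whose fire model has `p_max = 1`,
#'   `p_min = 0` and whose steady effective covers satisfy `C_nf* > C_f*`.
#' @return named numeric vector `c(theta1, theta2)`. Errors if the
#'   solution escapes `0 <= theta1 <= theta2 <= 1` (infeasible targets).
#' @export
invert_fire_thresholds <- function(p_at_nf, p_at_f, config) {
  stopifnot(inherits(config, "tree_model"))
  if (abs(config$fire$p_max - 1) > 1e-12 || abs(config$fire$p_min) > 1e-12)
    stop("threshold inversion requires p_max = 1 and p_min = 0")
  for (p in c(p_at_nf, p_at_f))
    if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
      stop("target probabilities must lie strictly inside (0, 1)")
  if (p_at_f <= p_at_nf)
    stop("need p_at_f > p_at_nf (fire must be likelier at the disturbed ",
         "steady state); got ", p_at_nf, " and ", p_at_f)
  ss <- steady_states(config)
  if (ss$C_nf <= ss$C_f)
    stop("steady effective covers must satisfy C_nf* > C_f*")
  dtheta <- (ss$C_nf - ss$C_f) / (p_at_f - p_at_nf)
  theta2 <- ss$C_nf + p_at_nf * dtheta
  theta1 <- theta2 - dtheta
  if (theta1 < -1e-12 || theta2 > 1 + 1e-12)
    stop("infeasible targets: thresholds (", format(theta1), ", ",
         format(theta2), ") escape [0, 1]")
  c(theta1 = max(theta1, 0), theta2 = min(theta2, 1))
}
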