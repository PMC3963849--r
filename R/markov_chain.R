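# Ulam-type discretization of the switched dynamics into a finite Markov
# chain: the unit cube is cut into hypercube cells of side delta, cells
# whose center has total cover <= 1 become chain states, each dynamic
# yields a conditional transition matrix (exact interval overlaps at n = 1,
# a mapped sub-grid of points for n > 1), and the two are mixed by the
# per-cell fire probability evaluated at the cell center.

#' Hypercube state grid over the cover simplex
#'
#' Partitions each cover axis into `k = 1/delta` half-open cells
#' `[l, l + delta)` (last cell closed) and keeps the hypercubes whose
#' center satisfies total cover `<= 1`; each kept cell is one chain state.
#' States are ordered lexicographically by multi-index.
#'
#' @param n number of size classes (state dimension).
#' @param delta cell width; `1/delta` must be an integer.
#' @return class `state_grid`: list with `n`, `delta`, `k`, `index`
#'   (`N x n` matrix of 1-based per-axis cell indices), `centers`
#'   (`N x n` matrix of cell centers), `N`, and an internal lookup from
#'   linear cell index to state id.
#' @export
build_grid <- function(n, delta) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a single integer >= 1")
  n <- as.integer(n)
  k <- 1 / delta
  if (abs(k - round(k)) > 1e-9)
    stop("delta = ", delta, " does not divide [0, 1] evenly (1/delta = ",
         format(k), " is not an integer)")
  k <- as.integer(round(k))
  idx1 <- seq_len(k)
  idx <- as.matrix(expand.grid(rep(list(idx1), n), KEEP.OUT.ATTRS = FALSE))
  colnames(idx) <- NULL
  # lexicographic by multi-index (first axis most significant)
  ord <- do.call(order, as.data.frame(idx))
  idx <- idx[ord, , drop = FALSE]
  centers <- (idx - 0.5) * delta
  keep <- rowSums(centers) <= 1 + 1e-12
  idx <- idx[keep, , drop = FALSE]
  centers <- centers[keep, , drop = FALSE]
  N <- nrow(idx)
  lookup <- rep(NA_integer_, k^n)
  lookup[linear_cell_index(idx, k)] <- seq_len(N)
  structure(list(n = n, delta = delta, k = k, index = idx,
                 centers = centers, N = N, lookup = lookup),
            class = "state_grid")
}

linear_cell_index <- function(idx, k) {
  # idx: matrix of 1-based per-axis indices
  drop((idx - 1L) %*% k^(seq_len(ncol(idx)) - 1L)) + 1L
}

#' @export
print.state_grid <- function(x, ...) {
  cat("State grid: ", x$N, " accepted cells of width ", x$delta,
      " in dimension ", x$n, " (", x$k, " per axis)\n", sep = "")
  invisible(x)
}

#' Conditional transition matrices of the two dynamics
#'
#' Builds the row-stochastic matrices `T_nf` and `T_f` whose entry `(i, j)`
#' is the proportion of cell `i` mapping into cell `j` under the no-fire
#' (resp. fire) yearly update. For `n = 1` the affine maps are monotone, so
#' the image of each cell is an interval and the row is computed exactly
#' from normalized overlap lengths. For `n > 1` a regular sub-grid of
#' `samples_per_axis^n` points per cell (restricted to points with total
#' cover `<= 1`) is propagated and destination cells are counted.
#'
#' @param grid a [build_grid()] result.
#' @param config a [tree_model()] of matching dimension.
#' @param samples_per_axis points per axis per cell for the sampled route
#'   (ignored at `n = 1`).
#' @return list with matrices `T_nf` and `T_f` (`N x N`, rows sum to 1).
#' @export
build_conditional_transitions <- function(grid, config, samples_per_axis = 5L) {
  stopifnot(inherits(grid, "state_grid"), inherits(config, "tree_model"))
  if (grid$n != config$n)
    stop("grid dimension ", grid$n, " does not match model dimension ", config$n)
  if (grid$n == 1L) {
    list(T_nf = transitions_exact_1d(grid, config, fired = FALSE),
         T_f = transitions_exact_1d(grid, config, fired = TRUE))
  } else {
    list(T_nf = transitions_sampled(grid, config, fired = FALSE, samples_per_axis),
         T_f = transitions_sampled(grid, config, fired = TRUE, samples_per_axis))
  }
}

transitions_exact_1d <- function(grid, config, fired) {
  k <- grid$k; delta <- grid$delta; N <- grid$N
  Tm <- matrix(0, N, N)
  for (i in seq_len(N)) {
    lo <- (grid$index[i, 1L] - 1L) * delta
    hi <- grid$index[i, 1L] * delta
    glo <- cover_step(lo, fired, config)[1L]
    ghi <- cover_step(hi, fired, config)[1L]
    if (ghi < glo) { tmp <- glo; glo <- ghi; ghi <- tmp }
    if (ghi - glo < 1e-14) {
      j <- cell_of(0.5 * (glo + ghi), delta, k)
      Tm[i, j] <- 1
    } else {
      j_lo <- cell_of(glo, delta, k)
      j_hi <- cell_of(ghi - 1e-15, delta, k)
      for (j in j_lo:j_hi) {
        ov <- min(ghi, j * delta) - max(glo, (j - 1L) * delta)
        if (ov > 0) Tm[i, j] <- ov / (ghi - glo)
      }
    }
  }
  Tm / rowSums(Tm)
}

cell_of <- function(x, delta, k) {
  # half-open cells [l, l + delta), last cell closed
  min(max(floor(x / delta + 1e-12) + 1L, 1L), k)
}

transitions_sampled <- function(grid, config, fired, samples_per_axis) {
  s <- as.integer(samples_per_axis)
  stopifnot(s >= 1L)
  n <- grid$n; delta <- grid$delta; k <- grid$k; N <- grid$N
  offs <- (seq_len(s) - 0.5) / s * delta
  offsets <- as.matrix(expand.grid(rep(list(offs), n), KEEP.OUT.ATTRS = FALSE))
  colnames(offsets) <- NULL
  A <- if (fired) config$A_f else config$A_nf
  a <- config$a
  space_limited <- config$recruitment == "space_limited"
  Tm <- matrix(0, N, N)
  for (i in seq_len(N)) {
    lower <- (grid$index[i, ] - 1L) * delta
    pts <- sweep(offsets, 2L, lower, "+")
    ok <- rowSums(pts) <= 1 + 1e-12
    if (!any(ok)) pts <- grid$centers[i, , drop = FALSE] else pts <- pts[ok, , drop = FALSE]
    img <- pts %*% t(A)
    img[, 1L] <- img[, 1L] + if (space_limited) a * (1 - rowSums(img)) else a
    if (any(img < -1e-9) || any(rowSums(img) > 1 + 1e-9))
      stop("dynamic maps cell ", i, " materially outside the simplex; ",
           "invalid model")
    dest_idx <- pmin(pmax(floor(img / delta + 1e-12) + 1L, 1L), k)
    ids <- grid$lookup[linear_cell_index(dest_idx, k)]
    if (anyNA(ids)) {
      # float noise can push an image just over the simplex boundary;
      # reassign to the nearest accepted cell center
      for (m in which(is.na(ids))) {
        d2 <- rowSums(sweep(grid$centers, 2L, img[m, ], "-")^2)
        ids[m] <- which.min(d2)
      }
    }
    tab <- tabulate(ids, nbins = N)
    Tm[i, ] <- tab / sum(tab)
  }
  Tm
}

#' Mix the conditional transition matrices by fire probability
#'
#' Total-probability mixture: row `i` of the result is
#' `(1 - p[i]) * T_nf[i, ] + p[i] * T_f[i, ]`.
#'
#' @param T_nf,T_f conformable row-stochastic matrices.
#' @param p_state per-state fire probabilities in `[0, 1]`.
#' @return the mixed row-stochastic transition matrix.
#' @export
mix_transitions <- function(T_nf, T_f, p_state) {
  if (!all(dim(T_nf) == dim(T_f)) || length(p_state) != nrow(T_nf))
    stop("shape mismatch: T_nf ", paste(dim(T_nf), collapse = "x"),
         ", T_f ", paste(dim(T_f), collapse = "x"),
         ", p_state length ", length(p_state))
  if (any(p_state < 0) || any(p_state > 1))
    stop("p_state must lie in [0, 1]")
  (1 - p_state) * T_nf + p_state * T_f
}

#' Stationary distribution of a finite chain
#'
#' Solves `w T = w`, `sum(w) = 1`, `w >= 0` by power iteration from the
#' uniform vector, with a direct linear solve (one equation replaced by the
#' normalization) as fallback and cross-check. When the chain is reducible
#' with a unique closed communicating class, the solve is restricted to
#' that class and zeros are reported elsewhere. With several closed classes
#' the stationary vector is not unique; a convergent iterate (e.g. uniform
#' for the identity chain) is returned with `unique = FALSE` and a warning,
#' otherwise an error is raised.
#'
#' @param T row-stochastic transition matrix.
#' @param tol convergence tolerance on the L1 step change.
#' @param max_iter iteration cap for the power method.
#' @return stationary vector `w` with attributes `residual`
#'   (`sum(abs(w %*% T - w))`) and `unique`.
#' @export
stationary_distribution <- function(T, tol = 1e-13, max_iter = 1e6) {
  T <- as.matrix(T)
  N <- nrow(T)
  if (ncol(T) != N) stop("T must be square")
  rs <- rowSums(T)
  if (any(abs(rs - 1) > 1e-8) || any(T < -1e-12))
    stop("T must be row-stochastic (row sums in 1 +/- 1e-8, entries >= 0)")
  erg <- ergodicity_check(T)

  if (!erg$irreducible && erg$closed_classes == 1L) {
    cls <- erg$closed_members[[1L]]
    w <- numeric(N)
    w[cls] <- stationary_core(T[cls, cls, drop = FALSE], tol, max_iter)
    attributes(w) <- NULL
  } else {
    w <- stationary_core(T, tol, max_iter)
  }
  res <- sum(abs(drop(w %*% T) - w))
  if (res > 1e-10)
    stop("stationary solver did not converge: residual ", format(res),
         " after power iteration and direct solve")
  uniq <- erg$closed_classes <= 1L
  if (!uniq)
    warning("chain has ", erg$closed_classes, " closed classes; the ",
            "stationary distribution is not unique (returning one solution)")
  structure(w, residual = res, unique = uniq)
}

stationary_core <- function(T, tol, max_iter) {
  N <- nrow(T)
  w <- rep(1 / N, N)
  it <- 0L
  repeat {
    w2 <- drop(w %*% T)
    d <- sum(abs(w2 - w))
    w <- w2
    it <- it + 1L
    if (d < tol || it >= max_iter) break
  }
  if (sum(abs(drop(w %*% T) - w)) > 1e-11) {
    # direct solve: (t(T) - I) w = 0 with the last equation replaced by sum = 1
    Acoef <- t(T) - diag(N)
    Acoef[N, ] <- 1
    b <- c(numeric(N - 1L), 1)
    w_dir <- try(solve(Acoef, b), silent = TRUE)
    if (!inherits(w_dir, "try-error") &&
        sum(abs(drop(w_dir %*% T) - w_dir)) < sum(abs(drop(w %*% T) - w)))
      w <- w_dir
  }
  w <- pmax(w, 0)
  w / sum(w)
}

#' Irreducibility and aperiodicity of a transition matrix
#'
#' Strongly connected components of the positive-entry digraph give the
#' communicating classes; a class with no outgoing edges is closed. The
#' period of a closed class is the gcd of `d(u) + 1 - d(v)` over its edges,
#' with `d` BFS distances from an arbitrary class member.
#'
#' @param T row-stochastic matrix.
#' @param tol entries above this count as edges.
#' @return class `ergodicity_report`: list with `irreducible`, `aperiodic`
#'   (`NA` when several closed classes exist), `period`, `closed_classes`
#'   (count) and `closed_members` (list of index vectors).
#' @export
ergodicity_check <- function(T, tol = 0) {
  T <- as.matrix(T)
  N <- nrow(T)
  g <- igraph::graph_from_adjacency_matrix(T > tol, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  membership <- comp$membership
  # a class is closed iff no edge leaves it
  edges <- which(T > tol, arr.ind = TRUE)
  leaving <- unique(membership[edges[, 1L]][membership[edges[, 1L]] !=
                                            membership[edges[, 2L]]])
  closed_ids <- setdiff(seq_len(comp$no), leaving)
  closed_members <- lapply(closed_ids, function(cid) which(membership == cid))
  period_of <- function(members) {
    sub <- T[members, members, drop = FALSE] > tol
    d <- igraph::distances(igraph::graph_from_adjacency_matrix(sub,
                                                               mode = "directed"),
                           v = 1, mode = "out")
    e <- which(sub, arr.ind = TRUE)
    diffs <- d[e[, 1L]] + 1 - d[e[, 2L]]
    diffs <- diffs[is.finite(diffs) & diffs != 0]
    if (!length(diffs)) return(1L)
    Reduce(gcd_int, c(abs(diffs), if (any(d[e[, 1L]] + 1 == d[e[, 2L]])) 0L))
  }
  # gcd over all closed-class cycle lengths; also count self-loops
  periods <- vapply(closed_members, function(m) {
    if (any(diag(T)[m] > tol)) return(1L)
    as.integer(period_of(m))
  }, integer(1L))
  aperiodic <- if (length(periods) == 1L) periods[1L] == 1L else NA
  structure(list(irreducible = comp$no == 1L,
                 aperiodic = aperiodic,
                 period = if (length(periods) == 1L) periods[1L] else periods,
                 closed_classes = length(closed_ids),
                 closed_members = closed_members),
            class = "ergodicity_report")
}

gcd_int <- function(a, b) {
  a <- abs(as.integer(a)); b <- abs(as.integer(b))
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' @export
print.ergodicity_report <- function(x, ...) {
  cat("Chain structure: ",
      if (x$irreducible) "irreducible" else
        paste0("reducible (", x$closed_classes, " closed class",
               if (x$closed_classes != 1L) "es", ")"),
      if (isTRUE(x$aperiodic)) ", aperiodic" else
        if (isFALSE(x$aperiodic)) paste0(", periodic (period ", x$period, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Discretized chain of a switched tree-cover model
#'
#' Convenience pipeline: builds the grid, evaluates the fire probability at
#' every accepted cell center, forms the conditional matrices, mixes them
#' and solves for the stationary distribution. The chain depends only on
#' the model, never on a simulation seed.
#'
#' @param config a [tree_model()].
#' @param delta grid cell width (the standard scalar analysis uses 0.01).
#' @param samples_per_axis sampling density per axis for `n > 1` cells.
#' @return class `tree_chain`: list with `grid`, `p_state`, `T_nf`, `T_f`,
#'   `T`, `w` and the `ergodicity` report of `T`.
#' @examples
#' m <- tree_model(0.9, 0.4, a = 0.1, fire = fire_model(0.2, 0.8))
#' ch <- build_chain(m, delta = 0.05)
#' cover_distribution(ch, bin_width = 0.1)
#' @export
build_chain <- function(config, delta, samples_per_axis = 5L) {
  stopifnot(inherits(config, "tree_model"))
  grid <- build_grid(config$n, delta)
  classes <- config$fire$cover_classes
  Ceff <- rowSums(grid$centers[, classes, drop = FALSE])
  p_state <- fire_probability(pmin(Ceff, 1), config$fire)
  tr <- build_conditional_transitions(grid, config, samples_per_axis)
  T <- mix_transitions(tr$T_nf, tr$T_f, p_state)
  w <- stationary_distribution(T)
  structure(list(grid = grid, p_state = p_state,
                 T_nf = tr$T_nf, T_f = tr$T_f, T = T, w = w,
                 ergodicity = ergodicity_check(T)),
            class = "tree_chain")
}

#' @export
print.tree_chain <- function(x, ...) {
  cat("Discretized chain:", x$grid$N, "states (delta =", x$grid$delta, ")\n")
  cat("  mean fire probability under w:",
      format(sum(as.numeric(x$w) * x$p_state), digits = 4), "\n")
  invisible(x)
}

#' Stationary distribution of total cover
#'
#' Aggregates the stationary state mass by the total cover of each cell
#' center into bins of `bin_width`; mass is conserved exactly. If
#' `bin_width` is not an integer multiple of the grid width a warning is
#' issued (cells then straddle bin edges and are attributed by their
#' center).
#'
#' @param chain a [build_chain()] result.
#' @param bin_width histogram bin width over total cover.
#' @return a `cover_histogram` (see [cover_histogram()]).
#' @export
cover_distribution <- function(chain, bin_width = 0.1) {
  stopifnot(inherits(chain, "tree_chain"))
  ratio <- bin_width / chain$grid$delta
  if (abs(ratio - round(ratio)) > 1e-9)
    warning("bin_width ", bin_width, " is not a multiple of the grid width ",
            chain$grid$delta, "; rebinning by cell centers (mass conserved)")
  covers <- rowSums(chain$grid$centers)
  cover_histogram(covers, bin_width, weights = as.numeric(chain$w))
}
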