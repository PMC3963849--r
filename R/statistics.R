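# Summary statistics of switched trajectories and chains: permanence
# ratios, the empirical two-state fire chain, cover histograms and the
# histogram-based bimodality index B.

#' Cover histogram with fixed half-open bins
#'
#' Bins values over `[0, 1]` into cells `[l, l + bin_width)` (last bin
#' closed), the same convention the state grid uses. Bin centers sit at
#' `l + bin_width / 2`, which is what the histogram mean estimator
#' `sum(c_k * f_k) / sum(f_k)` uses.
#'
#' @param values numeric cover values in `[0, 1]` (may be empty).
#' @param bin_width bin width; `1/bin_width` must be an integer.
#' @param weights optional nonnegative weights (defaults to counts of 1).
#' @return class `cover_histogram`: list with `bin_width`, `breaks`,
#'   `centers`, `freq` (absolute frequencies / total weights per bin),
#'   `mass` (normalized, all zero when empty), `n_total` and `empty`.
#' @export
cover_histogram <- function(values, bin_width, weights = NULL) {
  k <- 1 / bin_width
  if (abs(k - round(k)) > 1e-9)
    stop("bin_width = ", bin_width, " does not divide [0, 1] evenly")
  k <- as.integer(round(k))
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(weights) == length(values))
  if (length(values) && (any(values < -1e-9) || any(values > 1 + 1e-9)))
    stop("cover values must lie in [0, 1]")
  idx <- pmin(pmax(floor(values / bin_width + 1e-9) + 1L, 1L), k)
  freq <- numeric(k)
  if (length(values)) {
    agg <- rowsum(weights, idx)
    freq[as.integer(rownames(agg))] <- as.numeric(agg)
  }
  tot <- sum(freq)
  structure(list(bin_width = bin_width,
                 breaks = seq(0, 1, by = bin_width),
                 centers = (seq_len(k) - 0.5) * bin_width,
                 freq = freq,
                 mass = if (tot > 0) freq / tot else freq,
                 n_total = tot,
                 empty = tot == 0),
            class = "cover_histogram")
}

#' Histogram (binned) mean of a cover histogram
#'
#' @param h a `cover_histogram`.
#' @return `sum(c_k * f_k) / sum(f_k)`, or `NA` for an empty histogram.
#' @export
histogram_mean <- function(h) {
  stopifnot(inherits(h, "cover_histogram"))
  if (h$empty) return(NA_real_)
  sum(h$centers * h$freq) / sum(h$freq)
}

#' @export
print.cover_histogram <- function(x, ...) {
  cat("Cover histogram (bins of width ", x$bin_width, ", total weight ",
      format(x$n_total), if (x$empty) ", EMPTY", ")\n", sep = "")
  nz <- which(x$mass > 0)
  if (length(nz))
    print(data.frame(center = x$centers[nz], mass = round(x$mass[nz], 4)),
          row.names = FALSE)
  invisible(x)
}

#' Permanence ratios of the fire / no-fire dynamics
#'
#' Fraction of years (after a burn-in) spent under each dynamic.
#'
#' @param fire_seq 0/1 vector of yearly fire indicators.
#' @param burn_in number of leading years to discard.
#' @return class `permanence_summary`: `V_f` and `V_nf` (year counts),
#'   `ratio_f`, `ratio_nf`, `window` (first and last year used, 1-based).
#' @export
permanence_ratios <- function(fire_seq, burn_in = 0) {
  fire_seq <- as.integer(fire_seq)
  if (any(is.na(fire_seq)) || any(!fire_seq %in% c(0L, 1L)))
    stop("fire_seq must contain only 0 and 1")
  if (burn_in >= length(fire_seq))
    stop("burn_in (", burn_in, ") leaves no years out of ", length(fire_seq))
  used <- fire_seq[(burn_in + 1L):length(fire_seq)]
  V_f <- sum(used)
  V_nf <- length(used) - V_f
  structure(list(V_f = V_f, V_nf = V_nf,
                 ratio_f = V_f / length(used),
                 ratio_nf = V_nf / length(used),
                 window = c(burn_in + 1L, length(fire_seq))),
            class = "permanence_summary")
}

#' @export
print.permanence_summary <- function(x, ...) {
  cat("Permanence over years ", x$window[1L], "-", x$window[2L], ": ",
      round(100 * x$ratio_nf, 1), "% no-fire, ",
      round(100 * x$ratio_f, 1), "% fire\n", sep = "")
  invisible(x)
}

#' Empirical two-state fire chain
#'
#' Estimates the 2x2 transition matrix of the fire indicator sequence:
#' entry `(s, s')` is the number of observed transitions `s -> s'` divided
#' by the visits to `s` (the last year, having no successor, is excluded).
#' A state never visited yields an undefined (`NA`) row, flagged rather
#' than imputed.
#'
#' @param fire_seq 0/1 vector, length `>= 2`.
#' @return 2x2 matrix with dimnames `no_fire`/`fire` and attribute
#'   `undefined_rows` (character vector of unvisited states).
#' @export
estimate_fire_chain <- function(fire_seq) {
  fire_seq <- as.integer(fire_seq)
  if (length(fire_seq) < 2L)
    stop("need at least two years to estimate transitions")
  from <- factor(fire_seq[-length(fire_seq)], levels = c(0L, 1L))
  to <- factor(fire_seq[-1L], levels = c(0L, 1L))
  counts <- table(from, to)
  visits <- rowSums(counts)
  P <- counts / ifelse(visits > 0, visits, NA)
  P <- matrix(as.numeric(P), 2L, 2L,
              dimnames = list(c("no_fire", "fire"), c("no_fire", "fire")))
  undef <- rownames(P)[visits == 0]
  attr(P, "undefined_rows") <- undef
  P
}

sim_year_data <- function(result, burn_in) {
  # year t (t = burn_in .. horizon - 1) pairs cover x(t) with the fire
  # indicator F(t) drawn at t
  stopifnot(inherits(result, "tree_simulation"))
  horizon <- result$horizon
  if (burn_in >= horizon)
    stop("burn_in (", burn_in, ") leaves no years out of ", horizon)
  yrs <- (burn_in + 1L):horizon
  list(cover = rowSums(result$states[yrs, , drop = FALSE]),
       fire = result$fire[yrs])
}

#' Cover histograms split by dynamic
#'
#' Attributes the cover of year `t` to the dynamic indicated by `F(t)` and
#' builds three identically binned histograms: all years, fire years and
#' no-fire years. The two subset histograms partition the total exactly.
#'
#' @param result a `tree_simulation`.
#' @param bin_width histogram bin width (0.1 in the standard analysis).
#' @param burn_in years discarded at the start.
#' @return list of `cover_histogram`s: `total`, `fire`, `no_fire`.
#' @export
histogram_by_dynamic <- function(result, bin_width = 0.1, burn_in = 100) {
  d <- sim_year_data(result, burn_in)
  list(total = cover_histogram(d$cover, bin_width),
       fire = cover_histogram(d$cover[d$fire == 1L], bin_width),
       no_fire = cover_histogram(d$cover[d$fire == 0L], bin_width))
}

bimodality_report <- function(mu, mu_star, dominant, threshold, tie,
                              mu_raw = NA_real_, phi = NA_real_) {
  B <- abs(mu_star - mu)
  structure(list(mu = mu, mu_star = mu_star, B = B,
                 threshold = threshold,
                 verdict = if (B >= threshold) "bimodal" else "unimodal",
                 dominant_dynamic = dominant, tie = tie,
                 mu_raw = mu_raw, fire_weight = phi),
            class = "bimodality_report")
}

#' @export
print.bimodality_report <- function(x, ...) {
  cat("Bimodality index B = ", format(x$B, digits = 4), " -> ", x$verdict,
      " (threshold ", x$threshold, ")\n", sep = "")
  cat("  mean cover mu = ", format(x$mu, digits = 4),
      "; mean of dominant (", x$dominant_dynamic, ") dynamic mu* = ",
      format(x$mu_star, digits = 4),
      if (x$tie) " [dominance tie, broken toward no-fire]", "\n", sep = "")
  invisible(x)
}

#' Bimodality index of a tree-cover distribution
#'
#' `B = |mu* - mu|`, where `mu` is the histogram mean of the full cover
#' distribution and `mu*` the histogram mean (same bins) of the years
#' belonging to the more frequent dynamic. A distribution with `B` at or
#' above the threshold (default 0.1) is classified as bimodal: when both
#' dynamics are sticky the dominant dynamic's mode sits far from the
#' overall mean, which lies between the two modes.
#'
#' For a trajectory (`tree_simulation`) the dominant dynamic is the fire
#' status with more post-burn-in years. For a discretized chain
#' (`tree_chain`) the stationary mass takes the role of year counts: the
#' expected fire weight is `phi = sum(w * p)`, the dominant dynamic is fire
#' when `phi > 0.5`, and `mu*` is the cover mean under the stationary mass
#' conditioned on the dominant dynamic (`w * p` or `w * (1 - p)`,
#' renormalized), rebinned to `bin_width` so that chain and trajectory
#' estimates use matching bins. Exact dominance ties are broken toward
#' no-fire and flagged.
#'
#' @param x a `tree_simulation` or a `tree_chain`.
#' @param bin_width histogram bin width shared by `mu` and `mu*`.
#' @param burn_in trajectory mode only: years discarded at the start.
#' @param threshold classification cutoff on `B`.
#' @param ... passed between methods.
#' @return a `bimodality_report`: list with `mu`, `mu_star`, `B`,
#'   `threshold`, `verdict`, `dominant_dynamic`, `tie`, plus `mu_raw` (the
#'   unbinned trajectory mean, trajectory mode) or `fire_weight` (`phi`,
#'   chain mode).
#' @export
bimodality_index <- function(x, ...) UseMethod("bimodality_index")

#' @rdname bimodality_index
#' @export
bimodality_index.tree_simulation <- function(x, bin_width = 0.1,
                                             burn_in = 100, threshold = 0.1,
                                             ...) {
  d <- sim_year_data(x, burn_in)
  pooled_bimodality(d$cover, d$fire, bin_width = bin_width,
                    threshold = threshold)
}

#' @rdname bimodality_index
#' @export
bimodality_index.tree_chain <- function(x, bin_width = 0.1, threshold = 0.1,
                                        ...) {
  w <- as.numeric(x$w)
  p <- x$p_state
  covers <- rowSums(x$grid$centers)
  phi <- sum(w * p)
  tie <- abs(phi - 0.5) < 1e-12
  dominant <- if (!tie && phi > 0.5) "fire" else "no_fire"
  wd <- if (dominant == "fire") w * p else w * (1 - p)
  if (sum(wd) <= 0)
    stop("dominant dynamic carries no stationary mass; cannot compute mu*")
  total_h <- cover_histogram(covers, bin_width, weights = w)
  dom_h <- cover_histogram(covers, bin_width, weights = wd)
  bimodality_report(mu = histogram_mean(total_h),
                    mu_star = histogram_mean(dom_h),
                    dominant = dominant, threshold = threshold, tie = tie,
                    phi = phi)
}

#' Bimodality of a pooled (e.g. multi-site) cover sample
#'
#' Same arithmetic as the trajectory-mode [bimodality_index()], with
#' site-years replaced by an arbitrary pool of `(cover, fire status)`
#' observations — e.g. many sites sampled at one time instant.
#'
#' @param covers numeric cover values.
#' @param fire_status 0/1 fire indicators, one per cover value.
#' @param bin_width histogram bin width.
#' @param threshold classification cutoff on `B`.
#' @return a `bimodality_report` (see [bimodality_index()]) with the pooled
#'   `total` histogram attached as attribute `histogram`.
#' @export
pooled_bimodality <- function(covers, fire_status, bin_width = 0.1,
                              threshold = 0.1) {
  fire_status <- as.integer(fire_status)
  stopifnot(length(covers) == length(fire_status))
  if (!length(covers)) stop("empty pool")
  if (any(!fire_status %in% c(0L, 1L))) stop("fire_status must be 0/1")
  n_f <- sum(fire_status)
  n_nf <- length(fire_status) - n_f
  tie <- n_f == n_nf
  dominant <- if (n_f > n_nf) "fire" else "no_fire"
  dom_covers <- covers[fire_status == (dominant == "fire")]
  total_h <- cover_histogram(covers, bin_width)
  dom_h <- cover_histogram(dom_covers, bin_width)
  report <- bimodality_report(mu = histogram_mean(total_h),
                              mu_star = histogram_mean(dom_h),
                              dominant = dominant, threshold = threshold,
                              tie = tie, mu_raw = mean(covers))
  attr(report, "histogram") <- total_h
  report
}
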