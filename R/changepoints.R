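# Continuous piecewise-linear fit: basis {1, x, (x - b)+}, breaks at observed
# abscissae. Returns the residual sum of squares.
.pwl_rss <- function(x, y, breaks) {
  X <- cbind(1, x)
  for (b in breaks) X <- cbind(X, pmax(x - b, 0))
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

.pwl_bic <- function(x, y, breaks) {
  n <- length(x)
  rss <- .pwl_rss(x, y, breaks)
  # each break is charged three parameters (slope change, break position,
  # and a unit for the position being optimised over the grid) on top of
  # intercept, slope and sigma -- a changepoint-adapted BIC count that keeps
  # the false-positive rate of the break search below nominal
  k <- 2 + 3 * length(breaks) + 1
  # floor the variance near machine precision so noiseless series do not
  # reward spurious extra breaks
  floor_rss <- n * (1e-8 * max(stats::sd(y), 1e-30))^2
  n * log(max(rss, floor_rss) / n) + k * log(n)
}

# Indices eligible as single breakpoints so that each segment keeps
# >= min_seg points (the break point is shared by both segments).
.break_index_range <- function(n, min_seg) {
  if (n < 2 * min_seg - 1) return(integer())
  seq(min_seg, n - min_seg + 1)
}

# Exhaustive search over break-index sets of size m.
.exhaustive_breaks <- function(x, y, m, min_seg) {
  n <- length(x)
  idx <- .break_index_range(n, min_seg)
  if (m == 0) return(list(breaks = numeric(), bic = .pwl_bic(x, y, numeric())))
  if (length(idx) == 0) return(NULL)
  sets <- utils::combn(idx, m, simplify = FALSE)
  # every adjacent pair of breaks must also enclose >= min_seg points
  sets <- Filter(function(s) m == 1 || all(diff(s) >= min_seg - 1), sets)
  if (length(sets) == 0) return(NULL)
  bics <- vapply(sets, function(s) .pwl_bic(x, y, x[s]), numeric(1))
  best <- which.min(bics)
  list(breaks = x[sets[[best]]], bic = bics[best])
}

# Cross-entropy stochastic search used when the series is too long for
# exhaustive placement: population of candidate break vectors drawn from
# normals whose mean/sd adapt to the elite fraction each iteration.
.ce_breaks <- function(x, y, m, min_seg, pop = 200L, elite_frac = 0.1,
                       iters = 50L, seed = 1L) {
  if (m == 0) return(list(breaks = numeric(), bic = .pwl_bic(x, y, numeric())))
  set.seed(seed + m)
  n <- length(x)
  idx_ok <- .break_index_range(n, min_seg)
  if (length(idx_ok) == 0) return(NULL)
  lo <- x[min(idx_ok)]; hi <- x[max(idx_ok)]
  mu <- lo + (hi - lo) * seq_len(m) / (m + 1)
  sd <- rep((hi - lo) / 2, m)
  n_elite <- max(2L, ceiling(pop * elite_frac))
  best <- NULL
  for (it in seq_len(iters)) {
    cand <- matrix(stats::rnorm(pop * m, mean = rep(mu, each = pop),
                                sd = rep(sd, each = pop)), nrow = pop)
    cand <- t(apply(cand, 1, function(v) sort(pmin(pmax(v, lo), hi))))
    if (m == 1) cand <- matrix(cand, ncol = 1)
    # snap to nearest eligible observed abscissa
    snap <- apply(cand, c(1, 2), function(v) x[idx_ok][which.min(abs(x[idx_ok] - v))])
    if (m == 1) snap <- matrix(snap, ncol = 1)
    keep <- apply(snap, 1, function(s)
      m == 1 || all(diff(match(s, x)) >= min_seg - 1))
    snap <- snap[keep, , drop = FALSE]
    if (nrow(snap) == 0) next
    bics <- apply(snap, 1, function(s) .pwl_bic(x, y, s))
    ord <- order(bics)
    elite <- snap[ord[seq_len(min(n_elite, nrow(snap)))], , drop = FALSE]
    mu <- colMeans(elite)
    sd <- pmax(apply(elite, 2, stats::sd), (hi - lo) * 1e-3)
    if (is.null(best) || bics[ord[1]] < best$bic)
      best <- list(breaks = snap[ord[1], ], bic = bics[ord[1]])
    if (max(sd) < (hi - lo) * 2e-3) break
  }
  best
}

#' Detect trend shift points on a curve
#'
#' Fits continuous piecewise-linear models with 0 to `max_breaks` breakpoints
#' and selects the break count by the Bayesian information criterion under
#' Gaussian residuals. Breakpoints are placed on observed ages, exhaustively
#' for series up to `exhaustive_n` points and by seeded cross-entropy
#' stochastic optimisation above that. Every segment must contain at least
#' `min_seg` points.
#'
#' @param age ages in Ma (any order; strictly distinct).
#' @param value curve values.
#' @param max_breaks maximum number of breakpoints considered.
#' @param min_seg minimum points per segment.
#' @param exhaustive_n series length up to which placement is exhaustive.
#' @param seed seed for the stochastic search.
#' @param curve_id label carried into the result.
#' @return data frame of shift points (possibly 0 rows): `curve_id`, `age`
#'   (Ma), `bic_with`, `bic_without`; attribute `n_breaks`.
#' @export
detect_shifts <- function(age, value, max_breaks = 2L, min_seg = 3L,
                          exhaustive_n = 80L, seed = 1L,
                          curve_id = NA_character_) {
  stopifnot(length(age) == length(value))
  empty <- data.frame(curve_id = character(), age = numeric(),
                      bic_with = numeric(), bic_without = numeric())
  if (length(age) < 6) {
    warning("series too short for shift detection (", length(age), " points)")
    attr(empty, "n_breaks") <- 0L
    return(empty)
  }
  if (anyDuplicated(age)) stop("ages must be strictly ordered (no duplicates)")
  ord <- order(age, decreasing = TRUE)       # oldest first
  a <- age[ord]; y <- value[ord]
  x <- a[1] - a                              # forward time since series start
  n <- length(x)
  search <- if (n <= exhaustive_n) {
    function(m) .exhaustive_breaks(x, y, m, min_seg)
  } else {
    function(m) .ce_breaks(x, y, m, min_seg, seed = seed)
  }
  fits <- lapply(0:max_breaks, search)
  ok <- !vapply(fits, is.null, logical(1))
  bics <- ifelse(ok, vapply(fits, function(f) if (is.null(f)) Inf else f$bic,
                            numeric(1)), Inf)
  k_best <- which.min(bics) - 1L             # break count
  if (k_best == 0) {
    attr(empty, "n_breaks") <- 0L
    return(empty)
  }
  breaks_x <- fits[[k_best + 1]]$breaks
  res <- data.frame(
    curve_id = curve_id, age = a[1] - breaks_x,
    bic_with = bics[k_best + 1], bic_without = bics[k_best])
  attr(res, "n_breaks") <- k_best
  res
}

# Mean of the three pairwise absolute age distances of a triple.
.mean_pairwise_dist <- function(a, b, c) (abs(a - b) + abs(a - c) + abs(b - c)) / 3

#' Match shift points across three curves into coincident triples
#'
#' Forms `min(n_shifts)` disjoint triples (one shift per curve each) that
#' minimise the total mean pairwise age distance. For realistic shift counts
#' the assignment is solved exactly by enumeration over subsets and pairings;
#' greedy nearest-age matching is used as a fallback for unusually many
#' shifts. Curves with fewer shifts contribute each shift at most once;
#' unmatched shifts are left out.
#'
#' @param shifts_by_curve named list of three numeric vectors of shift ages
#'   (Ma), e.g. `list(net_div = ..., cum_total = ..., sympatry = ...)`.
#' @return data frame of triples: one age column per curve, `mean_age`,
#'   `mean_pairwise_distance`; 0 rows (with a warning) when any curve has no
#'   shifts.
#' @export
match_triples <- function(shifts_by_curve) {
  stopifnot(length(shifts_by_curve) == 3)
  nms <- names(shifts_by_curve)
  if (is.null(nms)) nms <- c("curve1", "curve2", "curve3")
  lens <- lengths(shifts_by_curve)
  empty <- stats::setNames(
    data.frame(numeric(), numeric(), numeric(), numeric(), numeric()),
    c(paste0("age_", nms), "mean_age", "mean_pairwise_distance"))
  if (any(lens == 0)) {
    warning("curve(s) without shifts: ", paste(nms[lens == 0], collapse = ", "))
    return(empty)
  }
  m <- min(lens)
  combos <- lapply(lens, function(l) utils::combn(l, m, simplify = FALSE))
  perms <- .permutations(m)
  n_cases <- length(combos[[1]]) * length(combos[[2]]) *
    length(combos[[3]]) * length(perms)^2
  sets <- if (n_cases <= 2e5)
    .match_exact(shifts_by_curve, combos, perms)
  else .match_greedy(shifts_by_curve, lens)
  a <- sets[, 1]; b <- sets[, 2]; c_ <- sets[, 3]
  out <- data.frame(a = a, b = b, c = c_, mean_age = (a + b + c_) / 3,
                    mean_pairwise_distance = .mean_pairwise_dist(a, b, c_))
  names(out)[1:3] <- paste0("age_", nms)
  out <- out[order(-out$mean_age), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.permutations <- function(m) {
  if (m == 1) return(list(1L))
  sub <- .permutations(m - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(m))
    out[[length(out) + 1]] <- append(p, m, after = pos - 1L)
  out
}

# Exact minimum-total-distance matching by enumeration.
.match_exact <- function(sh, combos, perms) {
  best <- NULL; best_d <- Inf
  for (ia in combos[[1]]) for (ib in combos[[2]]) for (ic in combos[[3]]) {
    a <- sh[[1]][ia]
    for (pb in perms) {
      b <- sh[[2]][ib][pb]
      for (pc in perms) {
        c_ <- sh[[3]][ic][pc]
        d <- sum(.mean_pairwise_dist(a, b, c_))
        if (d < best_d) { best_d <- d; best <- cbind(a, b, c_) }
      }
    }
  }
  best
}

# Greedy fallback: accept disjoint triples in order of pairwise distance.
.match_greedy <- function(sh, lens) {
  grid <- expand.grid(i = seq_len(lens[1]), j = seq_len(lens[2]),
                      k = seq_len(lens[3]))
  a <- sh[[1]][grid$i]; b <- sh[[2]][grid$j]; c_ <- sh[[3]][grid$k]
  ord <- order(.mean_pairwise_dist(a, b, c_))
  used <- lapply(lens, function(n) logical(n))
  rows <- list()
  for (r in ord) {
    i <- grid$i[r]; j <- grid$j[r]; k <- grid$k[r]
    if (used[[1]][i] || used[[2]][j] || used[[3]][k]) next
    used[[1]][i] <- used[[2]][j] <- used[[3]][k] <- TRUE
    rows[[length(rows) + 1]] <- c(a[r], b[r], c_[r])
  }
  do.call(rbind, rows)
}

#' Randomisation test for the temporal coincidence of a shift triple
#'
#' Compares the observed mean pairwise age distance of a shift triple with
#' the distribution obtained by repeatedly sampling two ages from the
#' time-bin midpoints (the bin-resolved range and sympatry curves) and one
#' age from the 1-Myr net-diversification grid, all with replacement. The
#' p-value carries the add-one correction
#' `p = (1 + #{random distance <= observed}) / (n_rand + 1)`.
#'
#' @param observed_distance observed mean pairwise distance (Myr), or a
#'   1-row triple data frame from [match_triples()].
#' @param bin_midpoints bin midpoint ages (Ma).
#' @param rate_ages ages of the net-rate grid (Ma, 1-Myr spacing).
#' @param n_rand number of random triples (9,999 by default).
#' @param seed RNG seed.
#' @return the randomisation p-value.
#' @export
coincidence_test <- function(observed_distance, bin_midpoints, rate_ages,
                             n_rand = 9999L, seed = 1L) {
  if (is.data.frame(observed_distance))
    observed_distance <- observed_distance$mean_pairwise_distance[1]
  stopifnot(length(bin_midpoints) >= 3, length(rate_ages) >= 3)
  set.seed(seed)
  a <- sample(bin_midpoints, n_rand, replace = TRUE)
  b <- sample(bin_midpoints, n_rand, replace = TRUE)
  c_ <- sample(rate_ages, n_rand, replace = TRUE)
  d <- .mean_pairwise_dist(a, b, c_)
  (1 + sum(d <= observed_distance)) / (n_rand + 1)
}
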