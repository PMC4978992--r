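# Trapezoidal integral of y(x) over [a, b] with linear interpolation at the
# end points; x may be in decreasing order.
.trapz_between <- function(x, y, a, b) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  lo <- min(a, b); hi <- max(a, b)
  xs <- c(lo, x[x > lo & x < hi], hi)
  ys <- stats::approx(x, y, xout = xs, rule = 2)$y
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Area test: change in the gap between cumulative range curves
#'
#' Computes the area between the cumulative total and cumulative clade range
#' curves before and after a shift age, each divided by the length of its
#' interval, and returns the post/pre ratio as a percentage:
#' `100 * (A_post / T_post) / (A_pre / T_pre)`. Both curves are linearly
#' interpolated at the shift age. A value above 100 means the gap between the
#' curves (and so the accumulated degree of sympatry) grows faster after the
#' shift. A zero pre-shift area makes the ratio undefined (`NA`, flagged).
#'
#' @param age bin midpoint ages (Ma).
#' @param cum_total,cum_clade cumulative curves on the same age axis (km^2).
#' @param shift_age shift age (Ma), strictly inside the age span.
#' @return list: `ratio_pct` (or `NA`), `undefined`, `pre_rate`, `post_rate`
#'   (km^2, gap area per Myr).
#' @export
area_test <- function(age, cum_total, cum_clade, shift_age) {
  stopifnot(length(age) == length(cum_total),
            length(age) == length(cum_clade))
  if (shift_age <= min(age) || shift_age >= max(age))
    stop("shift_age must lie strictly inside the curves' age span")
  gap <- cum_total - cum_clade
  oldest <- max(age); youngest <- min(age)
  a_pre <- .trapz_between(age, gap, shift_age, oldest)
  a_post <- .trapz_between(age, gap, youngest, shift_age)
  t_pre <- oldest - shift_age
  t_post <- shift_age - youngest
  if (a_pre <= 0)
    return(list(ratio_pct = NA_real_, undefined = TRUE,
                pre_rate = 0, post_rate = a_post / t_post))
  list(ratio_pct = 100 * (a_post / t_post) / (a_pre / t_pre),
       undefined = FALSE, pre_rate = a_pre / t_pre,
       post_rate = a_post / t_post)
}

#' Slope test: average range size trend after a shift
#'
#' Ordinary least-squares regression of the per-bin average species range on
#' forward time (Myr since clade origin), restricted to bins younger than the
#' shift age, with a two-sided t-test on the slope. A significant negative
#' slope indicates shrinking average ranges toward the present.
#'
#' @param age bin midpoint ages (Ma).
#' @param avg per-bin average range (km^2).
#' @param shift_age shift age (Ma).
#' @param origin_age clade origin age used as the forward-time zero; defaults
#'   to the oldest bin midpoint.
#' @return list: `slope` (km^2 per Myr of forward time), `p`, `n`,
#'   `applicable` (`FALSE`, with `NA`s, when fewer than 3 post-shift bins).
#' @export
slope_test <- function(age, avg, shift_age, origin_age = max(age)) {
  keep <- age < shift_age
  if (sum(keep) < 3)
    return(list(slope = NA_real_, p = NA_real_, n = sum(keep),
                applicable = FALSE))
  tt <- origin_age - age[keep]
  y <- avg[keep]
  if (stats::var(y) == 0)
    return(list(slope = 0, p = 1, n = sum(keep), applicable = TRUE))
  fit <- stats::lm(y ~ tt)
  cf <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
  list(slope = unname(cf["tt", "Estimate"]),
       p = unname(cf["tt", "Pr(>|t|)"]), n = sum(keep), applicable = TRUE)
}

#' One-sided Wilcoxon test for a net-rate decrease
#'
#' Mann-Whitney test of the hypothesis that per-Myr net diversification rates
#' after the shift are smaller than before (alternative: after < before).
#' The exact distribution is used for `m + n <= 20` without ties; otherwise
#' the normal approximation with tie correction.
#'
#' @param net_before,net_after per-Myr net-rate values on each side of the
#'   shift.
#' @return the one-sided p-value.
#' @export
net_rate_wilcoxon <- function(net_before, net_after) {
  stopifnot(length(net_before) >= 2, length(net_after) >= 2)
  if (length(unique(c(net_before, net_after))) == 1) {
    warning("all net-rate values tied; p = 1")
    return(1)
  }
  ties <- any(duplicated(c(net_before, net_after)))
  exact <- (length(net_before) + length(net_after) <= 20) && !ties
  suppressWarnings(
    stats::wilcox.test(net_after, net_before, alternative = "less",
                       exact = exact, correct = TRUE)$p.value)
}

#' Exact one-sided binomial summary
#'
#' Tail probability `P(X >= n_success | n_trials, 1/2)` for the count of
#' shift points (or clades) complying with a directional prediction, under a
#' fair-coin null.
#'
#' @param n_success,n_trials compliance count and number of cases.
#' @return list: `n_success`, `n_trials`, `pct`, `binomial_p`.
#' @export
binomial_summary <- function(n_success, n_trials) {
  stopifnot(n_success >= 0, n_success <= n_trials)
  p <- stats::pbinom(n_success - 1, n_trials, 0.5, lower.tail = FALSE)
  list(n_success = as.integer(n_success), n_trials = as.integer(n_trials),
       pct = 100 * n_success / n_trials, binomial_p = p)
}

#' Assemble per-shift report rows and the cross-clade summary
#'
#' Takes a table of per-shift statistics (one row per matched shift triple)
#' and produces the cross-clade summary: counts, at shift and clade level, of
#' coincident shifts (`p_dist < alpha`), post-shift sympatry increases (by
#' default the printed-table rule `area_test < 100`; see `area_rule`),
#' net-rate decreases (`net_p < alpha`), and significant post-shift slopes
#' split by sign, each with its exact binomial p-value. A clade counts as a
#' success when at least one of its shift points complies.
#'
#' @param rows data frame with columns `clade_id`, `shift_age`,
#'   `shift_pct_of_duration`, `p_dist`, `area_test`, `net_p`, `slope`,
#'   `slope_p` (`NA` allowed where a test was not applicable).
#' @param alpha significance threshold.
#' @param area_rule `"lt100"` counts `area_test < 100` as a sympatry
#'   increase, matching the compliance marks of the source tables;
#'   `"gt100"` applies the ratio-definition reading.
#' @return list with `rows` (echoed) and `summary`, a data frame with one
#'   row per test at each of shift and clade level.
#' @export
summarize_report <- function(rows, alpha = 0.05,
                             area_rule = c("lt100", "gt100")) {
  area_rule <- match.arg(area_rule)
  need <- c("clade_id", "p_dist", "area_test", "net_p", "slope", "slope_p")
  stopifnot(all(need %in% names(rows)))
  comply <- data.frame(
    clade_id = rows$clade_id,
    p_dist = rows$p_dist < alpha,
    area = if (area_rule == "lt100") rows$area_test < 100
           else rows$area_test > 100,
    net = rows$net_p < alpha,
    slope_sig = !is.na(rows$slope_p) & rows$slope_p < alpha,
    slope_neg = !is.na(rows$slope_p) & rows$slope_p < alpha & rows$slope < 0)
  lvl <- function(x, trials) {
    s <- binomial_summary(sum(x, na.rm = TRUE), trials)
    data.frame(n_success = s$n_success, n_trials = s$n_trials, pct = s$pct,
               binomial_p = s$binomial_p)
  }
  tests <- c("p_dist", "area", "net", "slope_sig", "slope_neg")
  shift_level <- do.call(rbind, lapply(tests, function(tn)
    cbind(test = tn, level = "shift",
          lvl(comply[[tn]], sum(!is.na(comply[[tn]]))))))
  by_clade <- stats::aggregate(comply[tests], list(clade_id = comply$clade_id),
                               function(v) any(v, na.rm = TRUE))
  clade_level <- do.call(rbind, lapply(tests, function(tn)
    cbind(test = tn, level = "clade",
          lvl(by_clade[[tn]], nrow(by_clade)))))
  list(rows = rows, summary = rbind(shift_level, clade_level))
}

#' Summarise covariate birth-death correlations across clades
#'
#' Counts clades with a significantly negative sympatry-speciation
#' correlation, a significantly positive sympatry-extinction correlation, and
#' clades showing either (the prediction that sympatry depresses
#' diversification). Significance means the 95% credible interval excludes 0.
#'
#' @param tbl data frame with one row per clade and columns
#'   `gamma_lambda_mean`, `gamma_lambda_low`, `gamma_lambda_high`,
#'   `gamma_mu_mean`, `gamma_mu_low`, `gamma_mu_high`.
#' @return list of counts: `n_clades`, `lambda_negative`, `mu_positive`,
#'   `either`.
#' @export
summarize_covariate <- function(tbl) {
  lam_neg <- tbl$gamma_lambda_high < 0
  mu_pos <- tbl$gamma_mu_low > 0
  list(n_clades = nrow(tbl),
       lambda_negative = sum(lam_neg),
       mu_positive = sum(mu_pos),
       either = sum(lam_neg | mu_pos))
}
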