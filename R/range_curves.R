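#' Assemble range curves and the degree-of-sympatry series
#'
#' Builds, per time bin: species richness (species with a valid, non-degenerate
#' range estimate), the total range (sum of species MCP areas), the clade range
#' (union area), the average species range, both cumulative curves (oldest to
#' youngest), and the degree of sympatry (total / clade range; 1 means fully
#' disjoint ranges, the species count means identical ranges).
#'
#' @param species_bins per species-bin area table from [range_table()].
#' @param bin_unions per-bin union areas from [range_table()].
#' @param bin_midpoints bin midpoint ages (Ma), oldest first, one per bin.
#' @param cumulative_average if `TRUE`, the average-range series divides the
#'   cumulative total curve (rather than the per-bin total) by richness; the
#'   per-bin variant is the default.
#' @return a `range_curve_set`: data frame with columns `bin`, `bin_mid_ma`,
#'   `richness`, `total_km2`, `clade_km2`, `avg_km2`, `cum_total_km2`,
#'   `cum_clade_km2`, `sympatry_ratio`.
#' @export
build_curves <- function(species_bins, bin_unions, bin_midpoints,
                         cumulative_average = FALSE) {
  n_bins <- length(bin_midpoints)
  if (!all(bin_unions$bin %in% seq_len(n_bins)))
    stop("bin axes misaligned: union table has bins outside 1..", n_bins)
  if (!all(species_bins$bin %in% seq_len(n_bins)))
    stop("bin axes misaligned: species table has bins outside 1..", n_bins)
  valid <- species_bins[!species_bins$degenerate &
                          !is.na(species_bins$area_km2), , drop = FALSE]
  richness <- integer(n_bins)
  total <- numeric(n_bins)
  if (nrow(valid) > 0) {
    r <- table(factor(valid$bin, levels = seq_len(n_bins)))
    richness <- as.integer(r)
    t_sum <- tapply(valid$area_km2, factor(valid$bin, levels = seq_len(n_bins)),
                    sum)
    total <- as.numeric(ifelse(is.na(t_sum), 0, t_sum))
  }
  clade <- numeric(n_bins)
  clade[bin_unions$bin] <- bin_unions$union_km2
  bad <- clade < 1e-9 & total > 1e-9
  if (any(bad))
    stop("impossible state: zero clade union with nonzero total range in bin ",
         paste(which(bad), collapse = ", "))
  cum_total <- cumsum(total)
  cum_clade <- cumsum(clade)
  avg <- ifelse(richness > 0,
                (if (cumulative_average) cum_total else total) / richness, 0)
  sympatry <- ifelse(clade > 0, total / clade, NA_real_)
  out <- data.frame(
    bin = seq_len(n_bins), bin_mid_ma = bin_midpoints, richness = richness,
    total_km2 = total, clade_km2 = clade, avg_km2 = avg,
    cum_total_km2 = cum_total, cum_clade_km2 = cum_clade,
    sympatry_ratio = sympatry)
  class(out) <- c("range_curve_set", "data.frame")
  out
}

#' Degree-of-sympatry series
#'
#' The per-bin ratio of total to clade (union) range, with bin midpoint ages.
#' Bins without a defined ratio (zero union) are dropped.
#'
#' @param curves a `range_curve_set` from [build_curves()].
#' @return data frame with `bin_mid_ma` and `sympatry_ratio`.
#' @export
sympatry_series <- function(curves) {
  stopifnot(inherits(curves, "range_curve_set"))
  ok <- !is.na(curves$sympatry_ratio)
  data.frame(bin_mid_ma = curves$bin_mid_ma[ok],
             sympatry_ratio = curves$sympatry_ratio[ok])
}

#' Average species range series
#'
#' Per-bin mean species range (total range divided by richness); bins with no
#' valid species range are dropped. Degenerate (flagged) species-bin estimates
#' were already excluded from both numerator and denominator upstream.
#'
#' @param curves a `range_curve_set` from [build_curves()].
#' @return data frame with `bin_mid_ma` and `avg_km2`.
#' @export
average_range_series <- function(curves) {
  stopifnot(inherits(curves, "range_curve_set"))
  ok <- curves$richness > 0
  data.frame(bin_mid_ma = curves$bin_mid_ma[ok], avg_km2 = curves$avg_km2[ok])
}

#' Write a range curve set as a tidy CSV
#'
#' @param curves a `range_curve_set`.
#' @param path output CSV path.
#' @export
write_curves <- function(curves, path) {
  utils::write.csv(as.data.frame(curves), path, row.names = FALSE)
  invisible(path)
}
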