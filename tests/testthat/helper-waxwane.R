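# Shared fixture builders and independent oracles.

# Occurrence-table builder in the canonical dialect.
make_occ <- function(species, lng, lat, min_ma, max_ma, genus = "Genus",
                     clade = "cladeA") {
  data.frame(species = species, genus = genus, clade = clade,
             paleo_lng = lng, paleo_lat = lat, min_ma = min_ma,
             max_ma = max_ma, stringsAsFactors = FALSE)
}

# Axis-aligned square polygon (planar km) as a range_polygon.
square_poly <- function(x0, y0, side = 1) {
  mcp_area(cbind(c(x0, x0 + side, x0 + side, x0),
                 c(y0, y0, y0 + side, y0 + side)))
}

# Independent convex-hull area oracle: Andrew's monotone chain, implemented
# separately from the package's chull/shoelace path.
hull_area_oracle <- function(pts) {
  pts <- unique(pts[order(pts[, 1], pts[, 2]), , drop = FALSE])
  n <- nrow(pts)
  if (n < 3) return(0)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(pts[h[length(h) - 1], ], pts[h[length(h)], ],
                   pts[i, ]) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  ring <- pts[c(lower[-length(lower)], upper[-length(upper)]), , drop = FALSE]
  m <- nrow(ring)
  if (m < 3) return(0)
  j <- c(m, seq_len(m - 1))
  abs(sum(ring[j, 1] * ring[, 2] - ring[, 1] * ring[j, 2]) / 2)
}

# Monte-Carlo union-area oracle over the polygons' joint bounding box.
mc_union_oracle <- function(polys, n = 1e6, seed = 1) {
  set.seed(seed)
  rings <- lapply(polys, function(p) p$vertices)
  allv <- do.call(rbind, rings)
  xr <- range(allv[, 1]); yr <- range(allv[, 2])
  px <- runif(n, xr[1], xr[2]); py <- runif(n, yr[1], yr[2])
  inside <- rep(FALSE, n)
  for (r in rings) {
    m <- nrow(r)
    j <- c(m, seq_len(m - 1))
    inpoly <- rep(TRUE, n)
    for (e in seq_len(m)) {       # convex, counterclockwise: all left turns
      ex <- r[e, 1] - r[j[e], 1]; ey <- r[e, 2] - r[j[e], 2]
      inpoly <- inpoly & (ex * (py - r[j[e], 2]) - ey * (px - r[j[e], 1]) >= 0)
    }
    inside <- inside | inpoly
  }
  mean(inside) * diff(xr) * diff(yr)
}

# Two-segment continuous piecewise-linear series on an age axis.
two_segment_series <- function(ages, break_age, slope1, slope2, y0 = 0,
                               noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- max(ages) - ages                    # forward time
  bx <- max(ages) - break_age
  y <- y0 + slope1 * pmin(x, bx) + slope2 * pmax(x - bx, 0)
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  data.frame(age = ages, value = y)
}

# A smooth synthetic sympatry covariate rising toward the present.
rising_covariate <- function(origin_age = 60, bin = 2) {
  age <- seq(origin_age - bin / 2, bin / 2, by = -bin)
  data.frame(age = age, value = 1 + 3 / (1 + exp((age - origin_age / 2) / 5)))
}
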