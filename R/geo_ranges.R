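# Authalic Earth radius (km): sphere with the same surface area as the
# reference ellipsoid, so equal-area projections preserve true areas.
.R_EARTH <- 6371.0072

#' Choose an equal-area projection for a point set
#'
#' The projection is picked from the longitudinal and latitudinal extent of
#' the points: Lambert azimuthal equal-area for extents under 180 degrees of
#' longitude; Mollweide for wider extents confined within 60 degrees of
#' latitude from the equator; Albers equal-area conic for wide extents that
#' reach beyond 60 degrees north or south. Planar inputs (synthetic data in
#' km) bypass projection entirely.
#'
#' @param lon_extent longitudinal span of the point set, degrees.
#' @param lat_bounds numeric length-2, min and max latitude, degrees.
#' @param planar if `TRUE`, return `"planar_passthrough"`.
#' @return one of `"lambert_azimuthal"`, `"mollweide"`, `"albers"`,
#'   `"planar_passthrough"`.
#' @export
select_projection <- function(lon_extent, lat_bounds, planar = FALSE) {
  if (planar) return("planar_passthrough")
  stopifnot(lon_extent >= 0, length(lat_bounds) == 2)
  if (lon_extent < 180) return("lambert_azimuthal")
  if (max(abs(lat_bounds)) <= 60) return("mollweide")
  "albers"
}

# Lambert azimuthal equal-area, centered on (lon0, lat0); x, y in km.
.proj_lambert <- function(lon, lat, lon0, lat0) {
  lam <- (lon - lon0) * pi / 180
  phi <- lat * pi / 180
  phi0 <- lat0 * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam)
  if (any(denom < 1e-10))
    stop("point antipodal to the projection center; use the Albers projection")
  k <- sqrt(2 / denom)
  list(x = .R_EARTH * k * cos(phi) * sin(lam),
       y = .R_EARTH * k * (cos(phi0) * sin(phi) -
                             sin(phi0) * cos(phi) * cos(lam)))
}

# Mollweide, central meridian lon0; auxiliary angle solved by Newton.
.proj_mollweide <- function(lon, lat, lon0) {
  lam <- (lon - lon0) * pi / 180
  lam <- ((lam + pi) %% (2 * pi)) - pi
  phi <- lat * pi / 180
  theta <- phi
  for (i in 1:50) {
    f <- 2 * theta + sin(2 * theta) - pi * sin(phi)
    fp <- 2 + 2 * cos(2 * theta)
    step <- ifelse(abs(fp) < 1e-12, 0, f / fp)
    theta <- theta - step
    if (max(abs(step)) < 1e-13) break
  }
  theta[abs(phi) >= pi / 2 - 1e-12] <- sign(phi[abs(phi) >= pi / 2 - 1e-12]) * pi / 2
  list(x = .R_EARTH * (2 * sqrt(2) / pi) * lam * cos(theta),
       y = .R_EARTH * sqrt(2) * sin(theta))
}

# Albers equal-area conic; standard parallels from the latitude range.
.proj_albers <- function(lon, lat, lon0, lat0, lat1 = NULL, lat2 = NULL) {
  if (is.null(lat1)) lat1 <- lat0 - (max(lat) - min(lat)) / 3
  if (is.null(lat2)) lat2 <- lat0 + (max(lat) - min(lat)) / 3
  if (abs(lat2 - lat1) < 1) { lat1 <- lat0 - 5; lat2 <- lat0 + 5 }
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  p0 <- lat0 * pi / 180
  lam <- (lon - lon0) * pi / 180
  phi <- lat * pi / 180
  n <- (sin(p1) + sin(p2)) / 2
  if (abs(n) < 1e-8) {
    # equator-symmetric parallels: the conic degenerates to the Lambert
    # cylindrical equal-area limit
    return(list(x = .R_EARTH * lam * cos(p1),
                y = .R_EARTH * sin(phi) / cos(p1)))
  }
  C <- cos(p1)^2 + 2 * n * sin(p1)
  rho <- .R_EARTH * sqrt(pmax(C - 2 * n * sin(phi), 0)) / n
  rho0 <- .R_EARTH * sqrt(max(C - 2 * n * sin(p0), 0)) / n
  th <- n * lam
  list(x = rho * sin(th), y = rho0 - rho * cos(th))
}

#' Project geographic points onto an equal-area plane
#'
#' Projects lon/lat coordinates (degrees) to km on an equal-area plane,
#' centered on the point set's centroid. `"planar_passthrough"` returns the
#' input coordinates unchanged (already km).
#'
#' @param lon,lat coordinates in degrees (or km for planar input).
#' @param projection_id one of the values returned by [select_projection()],
#'   or `NULL` to select automatically.
#' @param center optional `c(lon0, lat0)` projection center; defaults to the
#'   point-set centroid.
#' @return a `projected_points` list with `x`, `y` (km) and `projection_id`.
#' @export
project_points <- function(lon, lat, projection_id = NULL, center = NULL) {
  stopifnot(length(lon) == length(lat), all(is.finite(lon)),
            all(is.finite(lat)))
  if (is.null(projection_id))
    projection_id <- select_projection(diff(range(lon)), range(lat))
  if (is.null(center)) center <- c(mean(lon), mean(lat))
  xy <- switch(projection_id,
    planar_passthrough = list(x = lon, y = lat),
    lambert_azimuthal = .proj_lambert(lon, lat, center[1], center[2]),
    mollweide = .proj_mollweide(lon, lat, center[1]),
    albers = .proj_albers(lon, lat, center[1], center[2]),
    stop("unknown projection_id: ", projection_id))
  structure(list(x = xy$x, y = xy$y, projection_id = projection_id,
                 center = center),
            class = "projected_points")
}

# Signed shoelace area of a ring given as x, y vectors (not closed).
.shoelace <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Minimum convex polygon (MCP) of a projected point set
#'
#' Computes the convex hull of the distinct points and its area by the
#' shoelace formula. Collinear point sets yield a zero-area polygon flagged
#' as degenerate. At least 3 distinct points are required.
#'
#' @param pts a `projected_points` object from [project_points()], or a
#'   two-column matrix of planar km coordinates.
#' @param species_name,bin_index optional labels carried through.
#' @return a `range_polygon` list: `vertices` (counterclockwise ring, km),
#'   `area_km2`, `degenerate`, labels.
#' @export
mcp_area <- function(pts, species_name = NA_character_,
                     bin_index = NA_integer_) {
  if (inherits(pts, "projected_points")) {
    xy <- cbind(pts$x, pts$y)
    proj <- pts$projection_id
  } else {
    xy <- as.matrix(pts)
    proj <- "planar_passthrough"
  }
  xy <- unique(xy[stats::complete.cases(xy), , drop = FALSE])
  if (nrow(xy) < 3)
    stop("insufficient points for a convex polygon: ", nrow(xy),
         " distinct point(s), need 3")
  h <- grDevices::chull(xy[, 1], xy[, 2])     # clockwise order
  ring <- xy[rev(h), , drop = FALSE]          # counterclockwise
  area <- .shoelace(ring[, 1], ring[, 2])
  degenerate <- nrow(ring) < 3 || area <= 1e-12 * max(1, max(abs(xy))^2)
  if (degenerate) area <- 0
  structure(list(species_name = species_name, bin_index = bin_index,
                 vertices = ring, area_km2 = area, degenerate = degenerate,
                 projection_id = proj),
            class = "range_polygon")
}

# --- exact union area of convex polygons (vertical slab decomposition) -----
#
# Within a vertical slab whose boundaries include every vertex x and every
# pairwise edge-intersection x, each convex polygon covers a single y-interval
# whose endpoints are linear in x and whose overlap structure cannot change;
# the union length is then linear in x, so slab area = width * length(mid).

# y-interval of a convex ring at vertical line x = x0 (NULL if no overlap).
.ring_interval_at <- function(ring, x0) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  x1 <- x; x2 <- x[j]; y1 <- y; y2 <- y[j]
  lo <- pmin(x1, x2); hi <- pmax(x1, x2)
  cross <- lo <= x0 & x0 <= hi & hi > lo
  if (!any(cross)) return(NULL)
  t <- (x0 - x1[cross]) / (x2[cross] - x1[cross])
  ys <- y1[cross] + t * (y2[cross] - y1[cross])
  c(min(ys), max(ys))
}

# Total length of the union of closed intervals given as 2-col matrix.
.interval_union_length <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(0)
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  total <- 0; cur_lo <- iv[1, 1]; cur_hi <- iv[1, 2]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    if (iv[i, 1] > cur_hi) {
      total <- total + (cur_hi - cur_lo)
      cur_lo <- iv[i, 1]; cur_hi <- iv[i, 2]
    } else cur_hi <- max(cur_hi, iv[i, 2])
  }
  total + (cur_hi - cur_lo)
}

# x-coordinates where segments from two edge sets intersect.
.edge_intersection_x <- function(e1, e2) {
  if (nrow(e1) == 0 || nrow(e2) == 0) return(numeric())
  i <- rep(seq_len(nrow(e1)), times = nrow(e2))
  k <- rep(seq_len(nrow(e2)), each = nrow(e1))
  p1x <- e1[i, 1]; p1y <- e1[i, 2]; p2x <- e1[i, 3]; p2y <- e1[i, 4]
  q1x <- e2[k, 1]; q1y <- e2[k, 2]; q2x <- e2[k, 3]; q2y <- e2[k, 4]
  rx <- p2x - p1x; ry <- p2y - p1y
  sx <- q2x - q1x; sy <- q2y - q1y
  denom <- rx * sy - ry * sx
  ok <- abs(denom) > 1e-12
  t <- ((q1x - p1x) * sy - (q1y - p1y) * sx) / denom
  u <- ((q1x - p1x) * ry - (q1y - p1y) * rx) / denom
  hit <- ok & t >= -1e-12 & t <= 1 + 1e-12 & u >= -1e-12 & u <= 1 + 1e-12
  (p1x + t * rx)[hit]
}

.ring_edges <- function(ring) {
  n <- nrow(ring)
  j <- c(2:n, 1)
  cbind(ring[, 1], ring[, 2], ring[j, 1], ring[j, 2])
}

#' Area of the union of convex range polygons
#'
#' Exact union area by vertical slab decomposition: slab boundaries are taken
#' at every polygon vertex and every pairwise edge crossing, inside which each
#' convex polygon covers one y-interval with linear endpoints, making the
#' union area piecewise linear and exactly integrable.
#'
#' @param polys list of `range_polygon` objects (see [mcp_area()]) on a common
#'   projected plane; degenerate polygons contribute nothing.
#' @return union area in km^2.
#' @export
union_area <- function(polys) {
  if (inherits(polys, "range_polygon")) polys <- list(polys)
  polys <- Filter(function(p) !p$degenerate && p$area_km2 > 0, polys)
  if (length(polys) == 0) return(0)
  projs <- unique(vapply(polys, function(p) p$projection_id, character(1)))
  if (length(projs) > 1)
    stop("polygons use mixed projections (", paste(projs, collapse = ", "),
         "); re-project on a common plane first")
  rings <- lapply(polys, function(p) p$vertices)
  edges <- lapply(rings, .ring_edges)
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  if (length(rings) > 1) {
    for (a in seq_len(length(rings) - 1))
      for (b in (a + 1):length(rings))
        xs <- c(xs, .edge_intersection_x(edges[[a]], edges[[b]]))
  }
  xs <- sort(unique(xs))
  if (length(xs) < 2) return(0)
  total <- 0
  for (s in seq_len(length(xs) - 1)) {
    w <- xs[s + 1] - xs[s]
    if (w <= 1e-12) next
    xm <- (xs[s] + xs[s + 1]) / 2
    iv <- do.call(rbind, lapply(rings, .ring_interval_at, x0 = xm))
    total <- total + w * .interval_union_length(iv)
  }
  total
}

#' Per-species, per-bin range table for a binned clade dataset
#'
#' For every species-bin combination with at least `min_points` distinct
#' occurrence points, computes the MCP area (per-species projection chosen by
#' [select_projection()]); species-bin sets with fewer points, or collinear
#' sets, are flagged. Also computes, per bin, the clade union area on a single
#' clade-wide projection so that species polygons are co-registered.
#'
#' @param ds a binned [clade_dataset()].
#' @param min_points minimum distinct occurrence points for an MCP (3).
#' @return list with `species_bins` (data frame: species, bin, n_points,
#'   projection, area_km2, degenerate) and `bin_unions` (data frame: bin,
#'   union_km2, n_species).
#' @export
range_table <- function(ds, min_points = 3L) {
  stopifnot(inherits(ds, "clade_dataset"))
  if (is.null(ds$records$bin))
    stop("dataset has no bin assignment; run assign_to_bins() first")
  rec <- ds$records
  planar <- identical(ds$coords, "planar")
  n_bins <- length(ds$binning$bin_midpoints)
  sp_rows <- list()
  union_rows <- list()
  for (b in sort(unique(rec$bin))) {
    sub <- rec[rec$bin == b, , drop = FALSE]
    clade_center <- c(mean(sub$paleo_lng), mean(sub$paleo_lat))
    clade_proj <- if (planar) "planar_passthrough" else
      select_projection(diff(range(sub$paleo_lng)), range(sub$paleo_lat))
    bin_polys <- list()
    for (sp in unique(sub$species)) {
      pp <- sub[sub$species == sp, , drop = FALSE]
      uniq <- unique(pp[, c("paleo_lng", "paleo_lat")])
      n_pts <- nrow(uniq)
      if (n_pts < min_points) {
        sp_rows[[length(sp_rows) + 1]] <- data.frame(
          species = sp, bin = b, n_points = n_pts, projection = NA_character_,
          area_km2 = NA_real_, degenerate = TRUE, stringsAsFactors = FALSE)
        next
      }
      proj_id <- if (planar) "planar_passthrough" else
        select_projection(diff(range(uniq$paleo_lng)), range(uniq$paleo_lat))
      prj <- project_points(uniq$paleo_lng, uniq$paleo_lat, proj_id)
      poly <- mcp_area(prj, species_name = sp, bin_index = b)
      sp_rows[[length(sp_rows) + 1]] <- data.frame(
        species = sp, bin = b, n_points = n_pts, projection = proj_id,
        area_km2 = poly$area_km2, degenerate = poly$degenerate,
        stringsAsFactors = FALSE)
      if (!poly$degenerate) {
        prj_c <- project_points(uniq$paleo_lng, uniq$paleo_lat, clade_proj,
                                center = clade_center)
        bin_polys[[length(bin_polys) + 1]] <-
          mcp_area(prj_c, species_name = sp, bin_index = b)
      }
    }
    union_rows[[length(union_rows) + 1]] <- data.frame(
      bin = b, union_km2 = union_area(bin_polys),
      n_species = length(bin_polys))
  }
  species_bins <- do.call(rbind, sp_rows)
  bin_unions <- do.call(rbind, union_rows)
  all_bins <- data.frame(bin = seq_len(n_bins))
  bin_unions <- merge(all_bins, bin_unions, by = "bin", all.x = TRUE)
  bin_unions$union_km2[is.na(bin_unions$union_km2)] <- 0
  bin_unions$n_species[is.na(bin_unions$n_species)] <- 0
  list(species_bins = species_bins, bin_unions = bin_unions)
}

#' Well-known-text representation of a range polygon
#'
#' @param poly a `range_polygon` from [mcp_area()].
#' @param digits coordinate digits.
#' @return a `POLYGON ((...))` WKT string (closed counterclockwise ring).
#' @export
as_wkt <- function(poly, digits = 3) {
  stopifnot(inherits(poly, "range_polygon"))
  ring <- rbind(poly$vertices, poly$vertices[1, , drop = FALSE])
  coords <- apply(round(ring, digits), 1, paste, collapse = " ")
  sprintf("POLYGON ((%s))", paste(coords, collapse = ", "))
}
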