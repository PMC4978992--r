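#' @keywords internal
"_PACKAGE"

# Canonical occurrence columns used throughout the package.
.canonical_cols <- c("species", "genus", "clade", "paleo_lng", "paleo_lat",
                     "min_ma", "max_ma")

#' Construct a clade dataset
#'
#' A `clade_dataset` bundles the occurrence records of a single clade with an
#' optional time-binning scheme and an append-only provenance log recording
#' every filter applied.
#'
#' @param records data frame with columns `species`, `genus`, `clade`,
#'   `paleo_lng`, `paleo_lat`, `min_ma`, `max_ma` (ages in Ma, coordinates in
#'   degrees unless `coords = "planar"`, in which case they are km on a plane).
#' @param clade_id clade identifier; defaults to the single value of
#'   `records$clade`.
#' @param coords `"geo"` for lon/lat degrees, `"planar"` for km coordinates
#'   produced by the synthetic generator.
#' @param provenance character vector of log lines.
#' @return object of class `clade_dataset`.
#' @export
clade_dataset <- function(records, clade_id = NULL, coords = c("geo", "planar"),
                          provenance = character()) {
  coords <- match.arg(coords)
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.canonical_cols, names(records))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(clade_id)) {
    ids <- unique(records$clade)
    if (length(ids) > 1)
      stop("records contain ", length(ids),
           " clades; pass clade_id to select one")
    clade_id <- if (length(ids) == 1) ids else "unknown"
  } else {
    records <- records[records$clade == clade_id, , drop = FALSE]
  }
  structure(
    list(clade_id = clade_id, records = records, binning = NULL,
         coords = coords, provenance = provenance),
    class = "clade_dataset")
}

#' @export
print.clade_dataset <- function(x, ...) {
  cat("<clade_dataset> clade:", x$clade_id, "\n",
      nrow(x$records), "occurrences,",
      length(unique(x$records$species)), "species\n")
  if (!is.null(x$binning))
    cat("  binned:", length(x$binning$bin_midpoints), "bins of",
        x$binning$bin_length, "Myr\n")
  if (length(x$provenance))
    cat(paste0("  - ", x$provenance, collapse = "\n"), "\n")
  invisible(x)
}

.log_step <- function(ds, msg) {
  ds$provenance <- c(ds$provenance, msg)
  ds
}

#' Read fossil occurrences from a CSV file
#'
#' Reads an occurrence table in Paleobiology-Database download style. Rows with
#' unparseable or invalid coordinates/ages (out-of-range coordinates,
#' `max_ma < min_ma`, missing species name) are dropped, counted, and reported
#' in the provenance log rather than silently discarded.
#'
#' @param path CSV file (UTF-8, header row).
#' @param dialect named character vector mapping canonical column names
#'   (`species`, `genus`, `clade`, `paleo_lng`, `paleo_lat`, `min_ma`,
#'   `max_ma`) to the file's column names. Canonical names absent from the map
#'   are looked up verbatim.
#' @param clade_id restrict to one clade when the file holds several.
#' @param coords coordinate convention, see [clade_dataset()].
#' @return a [clade_dataset()].
#' @export
read_occurrences <- function(path, dialect = NULL, clade_id = NULL,
                             coords = c("geo", "planar")) {
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("empty occurrence file: ", path)
  file_cols <- .canonical_cols
  names(file_cols) <- .canonical_cols
  if (!is.null(dialect)) file_cols[names(dialect)] <- dialect
  absent <- file_cols[!file_cols %in% names(raw)]
  if (length(absent) > 0)
    stop("missing required column(s) in ", path, ": ",
         paste(sprintf("%s (mapped from %s)", absent, names(absent)),
               collapse = ", "))
  rec <- data.frame(
    species   = as.character(raw[[file_cols["species"]]]),
    genus     = as.character(raw[[file_cols["genus"]]]),
    clade     = as.character(raw[[file_cols["clade"]]]),
    paleo_lng = suppressWarnings(as.numeric(raw[[file_cols["paleo_lng"]]])),
    paleo_lat = suppressWarnings(as.numeric(raw[[file_cols["paleo_lat"]]])),
    min_ma    = suppressWarnings(as.numeric(raw[[file_cols["min_ma"]]])),
    max_ma    = suppressWarnings(as.numeric(raw[[file_cols["max_ma"]]])),
    stringsAsFactors = FALSE)
  bad_coord <- is.na(rec$paleo_lng) | is.na(rec$paleo_lat)
  if (coords == "geo")
    bad_coord <- bad_coord |
      rec$paleo_lng < -180 | rec$paleo_lng > 180 |
      rec$paleo_lat < -90 | rec$paleo_lat > 90
  bad_age <- is.na(rec$min_ma) | is.na(rec$max_ma) |
    rec$min_ma < 0 | rec$max_ma < rec$min_ma
  bad_name <- is.na(rec$species) | rec$species == ""
  bad <- bad_coord | bad_age | bad_name
  keep <- rec[!bad, , drop = FALSE]
  if (nrow(keep) == 0) stop("no valid occurrence rows in ", path)
  prov <- sprintf(
    "read %d rows from %s; rejected %d (coords %d, ages %d, names %d)",
    nrow(rec), basename(path), sum(bad), sum(bad_coord), sum(bad_age),
    sum(bad_name))
  clade_dataset(keep, clade_id = clade_id, coords = coords, provenance = prov)
}

# Default open-nomenclature markers (species epithets flagging uncertain IDs).
.open_nomenclature_markers <- c("sp.", "spp.", "cf.", "aff.", "?", "indet.")

#' Remove species in open nomenclature
#'
#' Drops every species whose name contains an open-nomenclature marker (an
#' epithet such as `sp.` or a qualifier such as `cf.`), i.e. records with
#' uncertain taxonomic classification.
#'
#' @param ds a [clade_dataset()].
#' @param markers character vector of marker tokens.
#' @return filtered dataset, removals logged per species in provenance.
#' @export
filter_open_nomenclature <- function(ds,
                                     markers = .open_nomenclature_markers) {
  stopifnot(inherits(ds, "clade_dataset"))
  sp <- unique(ds$records$species)
  flagged <- vapply(sp, function(nm) {
    toks <- strsplit(nm, "\\s+")[[1]]
    any(tolower(toks) %in% tolower(markers)) || grepl("?", nm, fixed = TRUE)
  }, logical(1))
  drop <- sp[flagged]
  ds$records <- ds$records[!ds$records$species %in% drop, , drop = FALSE]
  .log_step(ds, sprintf(
    "open-nomenclature filter: removed %d species (%s)",
    length(drop),
    if (length(drop)) paste(utils::head(drop, 10), collapse = "; ") else "none"))
}

#' Remove species with a minimum number of total occurrences
#'
#' @param ds a [clade_dataset()].
#' @param k minimum occurrence count; species with fewer than `k` occurrences
#'   over the whole record are removed. `k = 1` leaves the dataset unchanged;
#'   `k = 10` reproduces the robustness filter.
#' @export
filter_min_total_occurrences <- function(ds, k = 1L) {
  stopifnot(inherits(ds, "clade_dataset"), k >= 1)
  counts <- table(ds$records$species)
  drop <- names(counts)[counts < k]
  ds$records <- ds$records[!ds$records$species %in% drop, , drop = FALSE]
  .log_step(ds, sprintf("min-occurrence filter (k = %d): removed %d species",
                        k, length(drop)))
}

# Largest run of consecutive empty bins strictly inside a species' occupied
# bin range; 0 for a contiguous record.
.max_bin_gap <- function(bins) {
  b <- sort(unique(bins))
  if (length(b) < 2) return(0L)
  max(diff(b)) - 1L
}

#' Remove taxa lacking a continuous stratigraphic range
#'
#' A species (and, when genus names are present, a genus) is removed when its
#' sequence of occupied time bins contains a gap of more than `max_gap_bins`
#' consecutive empty bins. The default (`0`) requires strict continuity.
#'
#' @param ds a binned [clade_dataset()] (see [assign_to_bins()]).
#' @param max_gap_bins tolerated gap, in bins.
#' @export
filter_stratigraphic_continuity <- function(ds, max_gap_bins = 0L) {
  stopifnot(inherits(ds, "clade_dataset"))
  if (is.null(ds$binning) || is.null(ds$records$bin))
    stop("dataset has no bin assignment; run assign_to_bins() first")
  gaps_sp <- tapply(ds$records$bin, ds$records$species, .max_bin_gap)
  drop_sp <- names(gaps_sp)[gaps_sp > max_gap_bins]
  n_sp <- length(drop_sp)
  ds$records <- ds$records[!ds$records$species %in% drop_sp, , drop = FALSE]
  n_gen <- 0L
  has_genus <- any(!is.na(ds$records$genus) & ds$records$genus != "")
  if (has_genus && nrow(ds$records) > 0) {
    gaps_gen <- tapply(ds$records$bin, ds$records$genus, .max_bin_gap)
    drop_gen <- names(gaps_gen)[gaps_gen > max_gap_bins]
    n_gen <- length(drop_gen)
    ds$records <- ds$records[!ds$records$genus %in% drop_gen, , drop = FALSE]
  }
  .log_step(ds, sprintf(
    "stratigraphic-continuity filter (max gap %d bins): removed %d species, %d genera",
    max_gap_bins, n_sp, n_gen))
}

#' Build an equal-length binning scheme over a clade's record
#'
#' Edges run from the oldest occurrence midpoint age down to the youngest, in
#' steps of `bin_length`; the oldest edge is extended so that every occurrence
#' midpoint is covered. Each bin contains its older edge; the youngest bin is
#' also closed at its younger edge.
#'
#' @param ds a [clade_dataset()].
#' @param bin_length bin width in Myr.
#' @return object of class `binning_scheme` with `bin_edges` (oldest first)
#'   and `bin_midpoints`.
#' @export
binning_scheme <- function(ds, bin_length) {
  stopifnot(inherits(ds, "clade_dataset"), bin_length > 0)
  mids <- (ds$records$min_ma + ds$records$max_ma) / 2
  young <- min(mids)
  old <- max(mids)
  n_bins <- max(1L, ceiling((old - young) / bin_length - 1e-9))
  edges <- young + bin_length * (n_bins:0)
  structure(
    list(clade_id = ds$clade_id, bin_length = bin_length, bin_edges = edges,
         bin_midpoints = (edges[-length(edges)] + edges[-1]) / 2,
         flagged = FALSE, n_violating = NA_integer_),
    class = "binning_scheme")
}

#' Choose the clade-specific bin length
#'
#' Picks, among candidate bin lengths, the smallest one (hence the most bins)
#' for which every bin spanned by the clade's record contains at least
#' `min_species` species each represented by at least `min_occurrences`
#' occurrences in that bin — the minimum requirement for a convex-polygon
#' range estimate. When no candidate satisfies the rule, the scheme minimising
#' the number of violating bins is returned with `flagged = TRUE`.
#'
#' @param ds a [clade_dataset()].
#' @param candidate_lengths candidate widths in Myr.
#' @param min_species,min_occurrences the per-bin adequacy rule.
#' @export
choose_bin_length <- function(ds, candidate_lengths = c(1, 2, 2.5, 5, 10),
                              min_species = 3L, min_occurrences = 3L) {
  stopifnot(inherits(ds, "clade_dataset"))
  if (length(candidate_lengths) == 0) stop("empty candidate length list")
  if (nrow(ds$records) == 0) stop("empty dataset")
  stopifnot(all(candidate_lengths > 0))
  cands <- sort(candidate_lengths)
  schemes <- lapply(cands, function(len) binning_scheme(ds, len))
  n_viol <- vapply(schemes, function(sc) {
    binned <- assign_to_bins(ds, sc)
    tab <- table(binned$records$bin, binned$records$species)
    per_bin <- rowSums(tab >= min_occurrences)
    all_bins <- seq_along(sc$bin_midpoints)
    counts <- integer(length(all_bins))
    counts[as.integer(rownames(tab))] <- per_bin
    sum(counts < min_species)
  }, integer(1))
  ok <- which(n_viol == 0)
  if (length(ok) > 0) {
    sc <- schemes[[ok[1]]]
    sc$n_violating <- 0L
    return(sc)
  }
  best <- which.min(n_viol)
  sc <- schemes[[best]]
  sc$flagged <- TRUE
  sc$n_violating <- n_viol[best]
  warning(sprintf(
    "no candidate bin length satisfies the %d-species/%d-occurrence rule; using %g Myr (%d violating bins)",
    min_species, min_occurrences, sc$bin_length, sc$n_violating))
  sc
}

#' Assign occurrences to time bins
#'
#' Bin indices count from 1 at the oldest bin. In `midpoint` mode each
#' occurrence is placed at `(min_ma + max_ma) / 2`; in `random` mode an age is
#' drawn uniformly in `[min_ma, max_ma]` under `seed`. An age falling exactly
#' on an interior edge belongs to the younger bin.
#'
#' @param ds a [clade_dataset()].
#' @param scheme a [binning_scheme()].
#' @param mode `"midpoint"` (deterministic, default) or `"random"`.
#' @param seed integer seed for `"random"` mode.
#' @return the dataset with a `bin` column and `binning` attached.
#' @export
assign_to_bins <- function(ds, scheme, mode = c("midpoint", "random"),
                           seed = 1L) {
  stopifnot(inherits(ds, "clade_dataset"), inherits(scheme, "binning_scheme"))
  mode <- match.arg(mode)
  if (mode == "midpoint") {
    age <- (ds$records$min_ma + ds$records$max_ma) / 2
  } else {
    set.seed(seed)
    age <- stats::runif(nrow(ds$records), ds$records$min_ma,
                        ds$records$max_ma)
    # age intervals may poke past the midpoint-anchored scheme: clamp
    age <- pmin(pmax(age, min(scheme$bin_edges)), max(scheme$bin_edges))
  }
  edges <- scheme$bin_edges              # decreasing in age
  n_bins <- length(edges) - 1L
  out <- (age > edges[1] + 1e-9) | (age < edges[length(edges)] - 1e-9)
  if (any(out))
    stop("occurrence outside binning scheme span: row(s) ",
         paste(utils::head(which(out), 5), collapse = ", "),
         " (species ", ds$records$species[which(out)[1]], ")")
  # bin i covers (edges[i+1], edges[i]]; ages at the youngest edge -> last bin
  bin <- n_bins + 1L - findInterval(age, rev(edges), left.open = TRUE,
                                    rightmost.closed = FALSE)
  bin[age <= edges[length(edges)]] <- n_bins
  bin[bin < 1L] <- 1L
  ds$records$bin <- as.integer(bin)
  ds$records$bin_age <- age
  ds$binning <- scheme
  .log_step(ds, sprintf("binned with %g-Myr bins (%d bins, %s mode)",
                        scheme$bin_length, n_bins, mode))
}

#' Write a filtered dataset and its provenance log
#'
#' @param ds a [clade_dataset()].
#' @param csv_path output CSV path.
#' @param log_path optional provenance log path; default `<csv>.log`.
#' @export
write_occurrences <- function(ds, csv_path,
                              log_path = paste0(csv_path, ".log")) {
  stopifnot(inherits(ds, "clade_dataset"))
  utils::write.csv(ds$records, csv_path, row.names = FALSE)
  writeLines(ds$provenance, log_path)
  invisible(csv_path)
}
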