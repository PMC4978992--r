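#' Pipeline run configuration
#'
#' Collects every knob of the analysis pipeline with explicit seeds (no
#' wall-clock seeding), so that a rerun with the same configuration and
#' inputs reproduces the same outputs.
#'
#' @param input occurrence CSV path, or a data frame in the canonical
#'   dialect, or a [clade_dataset()].
#' @param out_dir output directory for stage CSVs and the manifest.
#' @param coords `"geo"` or `"planar"` (see [clade_dataset()]).
#' @param dialect column-name map for [read_occurrences()].
#' @param markers open-nomenclature marker set.
#' @param k_min_occurrences species-level minimum total occurrences (1 = no
#'   filter; 10 = robustness mode).
#' @param max_gap_bins stratigraphic-continuity gap tolerance (bins).
#' @param candidate_bin_lengths candidate bin widths (Myr).
#' @param max_breaks,n_rand changepoint and coincidence-test settings.
#' @param mcmc list of MCMC settings: `iterations`, `burnin`, `thin` for the
#'   lineage-time sampler and `cov_iterations`, `cov_thin`,
#'   `cov_burnin_samples` for the covariate model.
#' @param seed master seed for every stochastic stage.
#' @param alpha significance threshold used in the report.
#' @return a `run_config` list.
#' @export
run_config <- function(input, out_dir, coords = "geo", dialect = NULL,
                       markers = .open_nomenclature_markers,
                       k_min_occurrences = 1L, max_gap_bins = 0L,
                       candidate_bin_lengths = c(1, 2, 2.5, 5, 10),
                       max_breaks = 2L, n_rand = 9999L,
                       mcmc = list(iterations = 20000L, burnin = 5000L,
                                   thin = 50L, cov_iterations = 20000L,
                                   cov_thin = 20L, cov_burnin_samples = 200L),
                       seed = 1L, alpha = 0.05) {
  if (is.character(input) && !file.exists(input))
    stop("input path does not exist: ", input)
  structure(as.list(environment()), class = "run_config")
}

.pipeline_stage_order <- c("filter", "bin", "ranges", "curves", "trends",
                           "rates", "shifts", "covariate", "tests", "report")

.stage_deps <- list(
  filter = character(), bin = "filter", ranges = "bin", curves = "ranges",
  trends = "curves", rates = "bin", shifts = c("curves", "rates"),
  covariate = c("curves", "rates"), tests = c("shifts", "curves", "rates"),
  report = c("tests", "covariate"))

#' Run the clade geographic-evolution pipeline
#'
#' Executes the requested stages in dependency order, writing each stage's
#' CSV outputs under the configured output directory together with a JSON
#' run manifest (input checksums, configuration echo, seeds, package
#' version, per-file checksums). Reruns with identical configuration and
#' inputs reproduce identical outputs.
#'
#' Stages: `filter` (read + open-nomenclature + minimum-occurrence filters),
#' `bin` (bin-length choice, bin assignment, stratigraphic continuity),
#' `ranges` (per species-bin MCP areas and clade unions), `curves` (range
#' curves and sympatry), `trends` (linear/sigmoid/generalized-logistic
#' comparison), `rates` (lineage-time MCMC and 1-Myr rate timeline),
#' `shifts` (changepoints, triple matching, coincidence test), `covariate`
#' (sympatry-dependent birth-death MCMC), `tests` (area/slope/net-rate
#' tests per shift), `report` (per-shift rows and cross-clade summary).
#'
#' @param config a [run_config()].
#' @param stages subset of stage names; defaults to all.
#' @return invisibly, a list with every stage's in-memory result, `status`
#'   (0 on success) and `manifest` path.
#' @export
run_pipeline <- function(config, stages = .pipeline_stage_order) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, .pipeline_stage_order, several.ok = TRUE)
  stages <- .pipeline_stage_order[.pipeline_stage_order %in% stages]
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  st <- list(files = character())
  out <- function(name) file.path(config$out_dir, name)
  emit <- function(df, name) {
    p <- out(name)
    utils::write.csv(df, p, row.names = FALSE)
    st$files <<- c(st$files, p)
    p
  }
  for (stage in stages) {
    missing <- setdiff(.stage_deps[[stage]], names(st))
    if (length(missing) > 0)
      stop("stage '", stage, "' requires earlier stage(s): ",
           paste(missing, collapse = ", "))
    st <- switch(stage,
      filter = .stage_filter(st, config, emit),
      bin = .stage_bin(st, config, emit),
      ranges = .stage_ranges(st, config, emit),
      curves = .stage_curves(st, config, emit),
      trends = .stage_trends(st, config, emit),
      rates = .stage_rates(st, config, emit),
      shifts = .stage_shifts(st, config, emit),
      covariate = .stage_covariate(st, config, emit),
      tests = .stage_tests(st, config, emit),
      report = .stage_report(st, config, emit))
  }
  manifest <- list(
    package = "waxwane",
    version = as.character(utils::packageVersion("waxwane")),
    seed = config$seed,
    config = config[setdiff(names(config), "input")],
    input = if (is.character(config$input))
      list(path = config$input,
           md5 = unname(tools::md5sum(config$input))) else "in-memory",
    stages = stages,
    outputs = lapply(stats::setNames(st$files, basename(st$files)),
                     function(p) unname(tools::md5sum(p))))
  mpath <- out("manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  st$manifest <- mpath
  st$status <- 0L
  invisible(st)
}

.stage_filter <- function(st, config, emit) {
  ds <- if (inherits(config$input, "clade_dataset")) config$input
  else if (is.data.frame(config$input))
    clade_dataset(config$input, coords = config$coords)
  else read_occurrences(config$input, dialect = config$dialect,
                        coords = config$coords)
  ds <- filter_open_nomenclature(ds, markers = config$markers)
  ds <- filter_min_total_occurrences(ds, k = config$k_min_occurrences)
  if (nrow(ds$records) == 0) stop("no occurrences left after filtering")
  st$filter <- ds
  st
}

.stage_bin <- function(st, config, emit) {
  ds <- st$filter
  scheme <- suppressWarnings(
    choose_bin_length(ds, config$candidate_bin_lengths))
  ds <- assign_to_bins(ds, scheme)
  ds <- filter_stratigraphic_continuity(ds, config$max_gap_bins)
  if (nrow(ds$records) == 0) stop("no occurrences left after continuity filter")
  emit(ds$records, "occurrences_filtered.csv")
  writeLines(ds$provenance, file.path(config$out_dir, "provenance.log"))
  st$bin <- ds
  st
}

.stage_ranges <- function(st, config, emit) {
  rt <- range_table(st$bin)
  emit(rt$species_bins, "species_bin_ranges.csv")
  emit(rt$bin_unions, "bin_unions.csv")
  st$ranges <- rt
  st
}

.stage_curves <- function(st, config, emit) {
  curves <- build_curves(st$ranges$species_bins, st$ranges$bin_unions,
                         st$bin$binning$bin_midpoints)
  emit(as.data.frame(curves), "range_curves.csv")
  st$curves <- curves
  st
}

.stage_trends <- function(st, config, emit) {
  cv <- st$curves
  ok <- which(cv$cum_total_km2 > 0)
  if (length(ok) < 5) {
    warning("fewer than 5 usable bins; skipping trend-model comparison")
    st$trends <- list(fits = NULL, best_model = NA_character_)
    return(st)
  }
  tt <- max(cv$bin_mid_ma) - cv$bin_mid_ma[ok]
  cmp <- compare_trends(tt, cv$cum_total_km2[ok], seed = config$seed)
  row <- data.frame(
    clade = st$bin$clade_id,
    loglik_linear = cmp$fits$linear$loglik,
    loglik_sigmoid = cmp$fits$sigmoid$loglik,
    loglik_genlogistic = cmp$fits$generalized_logistic$loglik,
    best_model = cmp$best_model)
  emit(row, "trend_fit.csv")
  st$trends <- cmp
  st
}

.stage_rates <- function(st, config, emit) {
  lt <- sample_lineage_times(
    st$bin, iterations = config$mcmc$iterations,
    burnin = config$mcmc$burnin, thin = config$mcmc$thin,
    seed = config$seed)
  tl <- rates_timeline(lt)
  emit(tl, "rates_timeline.csv")
  emit(lt$times, "lineage_times.csv")
  st$rates <- list(lineage_times = lt, timeline = tl)
  st
}

.stage_shifts <- function(st, config, emit) {
  cv <- st$curves
  tl <- st$rates$timeline
  net_ok <- is.finite(tl$net)
  shifts <- list(
    net_div = detect_shifts(tl$age[net_ok], tl$net[net_ok],
                            max_breaks = config$max_breaks,
                            seed = config$seed, curve_id = "net_div"),
    cum_total = detect_shifts(cv$bin_mid_ma, cv$cum_total_km2,
                              max_breaks = config$max_breaks,
                              seed = config$seed, curve_id = "cum_total"),
    sympatry = local({
      ss <- sympatry_series(cv)
      detect_shifts(ss$bin_mid_ma, ss$sympatry_ratio,
                    max_breaks = config$max_breaks,
                    seed = config$seed, curve_id = "sympatry")
    }))
  triples <- suppressWarnings(
    match_triples(lapply(shifts, function(s) s$age)))
  if (nrow(triples) > 0) {
    triples$p_dist <- vapply(seq_len(nrow(triples)), function(i)
      coincidence_test(triples$mean_pairwise_distance[i],
                       cv$bin_mid_ma, tl$age[net_ok],
                       n_rand = config$n_rand,
                       seed = config$seed + i), numeric(1))
    emit(triples, "shift_triples.csv")
  }
  st$shifts <- list(by_curve = shifts, triples = triples)
  st
}

.stage_covariate <- function(st, config, emit) {
  ss <- sympatry_series(st$curves)
  cov <- data.frame(age = ss$bin_mid_ma, value = ss$sympatry_ratio)
  post <- covariate_bd_mcmc(
    st$rates$lineage_times, cov,
    iterations = config$mcmc$cov_iterations,
    thin = config$mcmc$cov_thin,
    burnin_samples = config$mcmc$cov_burnin_samples,
    seed = config$seed)
  emit(post$summary, "covariate_bd_summary.csv")
  st$covariate <- post
  st
}

.stage_tests <- function(st, config, emit) {
  cv <- st$curves
  tl <- st$rates$timeline
  triples <- st$shifts$triples
  rows <- list()
  span <- range(cv$bin_mid_ma)
  duration <- span[2] - min(tl$age)
  for (i in seq_len(nrow(triples))) {
    shift <- triples$mean_age[i]
    if (shift <= span[1] || shift >= span[2]) next
    at <- area_test(cv$bin_mid_ma, cv$cum_total_km2, cv$cum_clade_km2, shift)
    av <- average_range_series(cv)
    sl <- slope_test(av$bin_mid_ma, av$avg_km2, shift,
                     origin_age = span[2])
    net_ok <- is.finite(tl$net)
    before <- tl$net[net_ok & tl$age > shift]
    after <- tl$net[net_ok & tl$age <= shift]
    net_p <- if (length(before) >= 2 && length(after) >= 2)
      net_rate_wilcoxon(before, after) else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      clade_id = st$bin$clade_id, shift_age = shift,
      shift_pct_of_duration = 100 * (span[2] - shift) / duration,
      p_dist = triples$p_dist[i],
      area_test = at$ratio_pct, net_p = net_p,
      slope = sl$slope, slope_p = sl$p)
  }
  st$tests <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (nrow(st$tests) > 0) emit(st$tests, "shift_tests.csv")
  st
}

.stage_report <- function(st, config, emit) {
  if (nrow(st$tests) == 0) {
    st$report <- list(rows = st$tests, summary = data.frame())
    return(st)
  }
  rep <- summarize_report(st$tests, alpha = config$alpha)
  emit(rep$rows, "report_rows.csv")
  emit(rep$summary, "report_summary.csv")
  st$report <- rep
  st
}
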