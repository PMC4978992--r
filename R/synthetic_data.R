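#' Configuration for the synthetic fossil-clade generator
#'
#' Bundles the generative parameters of [simulate_clade()] and
#' [simulate_preservation()]: birth-death rates with optional sympatry
#' feedback, Poisson preservation, lognormal species range radii with
#' dispersal and heritable specialisation (multiplicative shrinking of
#' descendant ranges), and occurrence age uncertainty.
#'
#' @param seed RNG seed.
#' @param lambda0,mu0 baseline speciation/extinction rates (events per
#'   lineage per Myr).
#' @param gamma_lambda,gamma_mu effects of the realised log degree of
#'   sympatry of the standing species on the log rates (0 = no feedback).
#' @param q preservation rate (occurrences per lineage per Myr).
#' @param t_max maximum clade lifespan (Myr); also the clade origin age (Ma).
#' @param range_radius_log_mean,range_radius_log_sd lognormal parameters of
#'   the founder species' range radius (km).
#' @param radius_noise_sd lognormal sd of the child/parent radius ratio.
#' @param dispersal_sd isotropic Gaussian step (km) of a child's range
#'   centroid from its parent's, for a parent of median founder range size;
#'   the realised step scales with the parent's radius, so specialised
#'   small-ranged lineages also disperse less.
#' @param specialisation_rate per-Myr multiplicative shrink applied to
#'   descendant radii (>= 0; 0 disables specialisation).
#' @param age_uncertainty half-width (Myr) of the min/max age interval
#'   attached to each occurrence.
#' @param sympatry_ref reference degree of sympatry at which the feedback is
#'   neutral: rates are multiplied by `exp(gamma * log(s / sympatry_ref))`,
#'   so overlap above the reference raises (or lowers) the rates.
#' @param clade_id label used in generated occurrence tables.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, lambda0 = 0.3, mu0 = 0.25,
                              gamma_lambda = 0, gamma_mu = 0, q = 3,
                              t_max = 80, range_radius_log_mean = log(300),
                              range_radius_log_sd = 0.6,
                              radius_noise_sd = 0.2, dispersal_sd = 200,
                              specialisation_rate = 0, age_uncertainty = 1,
                              sympatry_ref = 1.25, clade_id = "synthetic") {
  stopifnot(lambda0 > 0, mu0 >= 0, q > 0, t_max > 0,
            specialisation_rate >= 0, age_uncertainty >= 0,
            sympatry_ref >= 1)
  structure(as.list(environment()), class = "simulation_config")
}

# Unbiased Monte-Carlo union area of discs: sample points from the discs in
# proportion to their areas and average the inverse coverage count.
.disc_union_area <- function(cx, cy, r, n_mc = 1000L) {
  n <- length(cx)
  if (n == 0) return(0)
  areas <- pi * r^2
  if (n == 1) return(areas)
  pick <- sample.int(n, n_mc, replace = TRUE, prob = areas)
  u <- sqrt(stats::runif(n_mc))
  ang <- stats::runif(n_mc, 0, 2 * pi)
  px <- cx[pick] + r[pick] * u * cos(ang)
  py <- cy[pick] + r[pick] * u * sin(ang)
  d2 <- outer(px, cx, "-")^2 + outer(py, cy, "-")^2
  m <- rowSums(d2 <= matrix(r^2, n_mc, n, byrow = TRUE) * (1 + 1e-12))
  sum(areas) * mean(1 / pmax(m, 1))
}

#' Simulate a fossil clade with spatially explicit species ranges
#'
#' Continuous-time birth-death simulation from one ancestor. Species carry a
#' circular range (centroid, radius); a child's centroid takes an isotropic
#' Gaussian dispersal step from its parent's, and its radius is the parent's
#' shrunk by `exp(-specialisation_rate * dt)` (with `dt` the parent's age at
#' branching) times lognormal noise. When `gamma_lambda`/`gamma_mu` are
#' nonzero, rates are modulated each 1-Myr lattice step by the realised log
#' degree of sympatry of the standing species (sum of disc areas over their
#' union), giving the hypothesised specialisation feedback. The
#' simulation is conditioned, by rejection, on total extinction before
#' `t_max` and on at least `min_species` species ever existing.
#'
#' @param config a [simulation_config()].
#' @param min_species minimum total species count for an accepted history.
#' @param max_attempts rejection-sampling cap.
#' @param require_extinct condition on extinction before `t_max`.
#' @return a `true_history` list: `species` data frame (id, parent, ts, te in
#'   Ma, cx, cy, radius in km), `series` data frame of the per-1-Myr true
#'   richness and sympatry ratio, `origin_age`, `config`.
#' @export
simulate_clade <- function(config, min_species = 10L, max_attempts = 1000L,
                           require_extinct = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  for (attempt in seq_len(max_attempts)) {
    h <- .simulate_clade_once(config)
    ok_size <- !h$overflow && nrow(h$species) >= min_species
    ok_ext <- !require_extinct || all(!is.na(h$species$t_death))
    if (ok_size && ok_ext) {
      # convert forward times to ages with the origin at t_max Ma
      a0 <- config$t_max
      sp <- h$species
      out <- data.frame(
        id = sp$id, parent = sp$parent,
        ts = a0 - sp$t_birth,
        te = ifelse(is.na(sp$t_death), 0, a0 - sp$t_death),
        cx = sp$cx, cy = sp$cy, radius = sp$radius)
      ser <- .true_series(h$species)
      ser$age <- a0 - ser$t
      return(structure(list(species = out, series = ser, origin_age = a0,
                            config = config, attempt = attempt),
                       class = "true_history"))
    }
  }
  stop("no accepted clade history in ", max_attempts,
       " attempts; relax min_species/require_extinct or adjust rates")
}

# Realised degree of sympatry of a set of range discs (>= 1, by convention 1
# for fewer than two species).
.disc_sympatry <- function(cx, cy, r, n_mc = 600L) {
  if (length(cx) < 2) return(1)
  tot <- sum(pi * r^2)
  uni <- .disc_union_area(cx, cy, r, n_mc = n_mc)
  max(tot / max(uni, 1e-9), 1)
}

.simulate_clade_once <- function(cfg) {
  cap <- 4096L
  parent <- integer(cap); t_birth <- t_death <- numeric(cap)
  cx <- cy <- radius <- numeric(cap)
  parent[1] <- NA_integer_; t_birth[1] <- 0; t_death[1] <- NA_real_
  cx[1] <- 0; cy[1] <- 0
  radius[1] <- stats::rlnorm(1, cfg$range_radius_log_mean,
                             cfg$range_radius_log_sd)
  t_death[1] <- NA_real_
  n <- 1L
  alive <- 1L
  feedback <- cfg$gamma_lambda != 0 || cfg$gamma_mu != 0
  t <- 0
  step <- 1                                  # rate-update lattice, Myr
  repeat {
    if (length(alive) == 0 || t >= cfg$t_max) break
    z <- 0
    if (feedback) {
      # rates respond to the log degree of sympatry of the standing
      # species, centered at the neutral reference overlap
      s_now <- .disc_sympatry(cx[alive], cy[alive], radius[alive])
      z <- log(s_now / cfg$sympatry_ref)
    }
    lam <- cfg$lambda0 * exp(cfg$gamma_lambda * z)
    mu <- cfg$mu0 * exp(cfg$gamma_mu * z)
    seg_end <- min(t + step, cfg$t_max)
    while (t < seg_end && length(alive) > 0) {
      total <- length(alive) * (lam + mu)
      dt <- stats::rexp(1, total)
      if (t + dt > seg_end) { t <- seg_end; break }
      t <- t + dt
      who <- alive[sample.int(length(alive), 1)]
      if (stats::runif(1) < lam / (lam + mu)) {
        n <- n + 1L
        if (n > cap) break                    # runaway radiation: give up
        parent[n] <- who
        t_birth[n] <- t
        t_death[n] <- NA_real_
        # dispersal declines superlinearly with range size relative to the
        # clade founder: small-ranged specialists both disperse less and
        # stay inside the ancestral core, so range overlap builds as
        # specialisation proceeds. dispersal_sd is the founder-range step.
        step_sd <- cfg$dispersal_sd * (radius[who] / radius[1])^2
        cx[n] <- cx[who] + stats::rnorm(1, 0, step_sd)
        cy[n] <- cy[who] + stats::rnorm(1, 0, step_sd)
        dt_par <- t - t_birth[who]
        radius[n] <- radius[who] * exp(-cfg$specialisation_rate * dt_par) *
          stats::rlnorm(1, 0, cfg$radius_noise_sd)
        alive <- c(alive, n)
      } else {
        t_death[who] <- t
        alive <- setdiff(alive, who)
      }
    }
    if (n > cap) break
    if (length(alive) == 0) break
  }
  idx <- seq_len(min(n, cap))
  sp <- data.frame(id = idx, parent = parent[idx], t_birth = t_birth[idx],
                   t_death = t_death[idx], cx = cx[idx], cy = cy[idx],
                   radius = radius[idx])
  list(species = sp, overflow = n > cap)
}

# Per-lattice-step true richness and sympatry, reconstructed from the static
# species geometry (centroids and radii do not change within a lifespan).
.true_series <- function(sp, step = 1) {
  t_end <- suppressWarnings(max(sp$t_death, na.rm = TRUE))
  if (!is.finite(t_end)) t_end <- max(sp$t_birth)
  lattice <- seq(0, max(ceiling(t_end), 1), by = step)
  do.call(rbind, lapply(lattice, function(tt) {
    al <- which(sp$t_birth <= tt & (is.na(sp$t_death) | sp$t_death > tt))
    data.frame(t = tt, richness = length(al),
               sympatry = .disc_sympatry(sp$cx[al], sp$cy[al], sp$radius[al]))
  }))
}

#' Simulate Poisson fossil preservation of a clade history
#'
#' Each species leaves occurrences as a Poisson process with rate `q` over
#' its lifespan; each occurrence is placed uniformly within the species'
#' range disc, and its age interval is the true age plus/minus
#' `age_uncertainty`. Species with zero occurrences are dropped (incomplete
#' sampling) and logged in the `dropped_species` attribute.
#'
#' @param history a `true_history` from [simulate_clade()].
#' @param config a [simulation_config()]; defaults to the history's own.
#' @return data frame in the canonical occurrence dialect (`species`,
#'   `genus`, `clade`, `paleo_lng`, `paleo_lat` in planar km, `min_ma`,
#'   `max_ma`), with attribute `dropped_species`.
#' @export
simulate_preservation <- function(history, config = history$config) {
  stopifnot(inherits(history, "true_history"))
  sp <- history$species
  rows <- list()
  dropped <- character()
  for (i in seq_len(nrow(sp))) {
    d <- sp$ts[i] - sp$te[i]
    k <- stats::rpois(1, config$q * d)
    nm <- sprintf("Synthetica sp%04d", sp$id[i])
    if (k == 0) { dropped <- c(dropped, nm); next }
    ages <- stats::runif(k, sp$te[i], sp$ts[i])
    u <- sqrt(stats::runif(k))
    ang <- stats::runif(k, 0, 2 * pi)
    rows[[length(rows) + 1]] <- data.frame(
      species = nm, genus = "Synthetica", clade = config$clade_id,
      paleo_lng = sp$cx[i] + sp$radius[i] * u * cos(ang),
      paleo_lat = sp$cy[i] + sp$radius[i] * u * sin(ang),
      min_ma = pmax(ages - config$age_uncertainty, 0),
      max_ma = ages + config$age_uncertainty,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), genus = character(),
               clade = character(), paleo_lng = numeric(),
               paleo_lat = numeric(), min_ma = numeric(), max_ma = numeric())
  attr(out, "dropped_species") <- dropped
  out
}

#' Simulate lineage times under a stepwise covariate birth-death model
#'
#' Direct (non-spatial) birth-death simulation in age coordinates with rates
#' `lambda0 exp(gamma_lambda s_t)` and `mu0 exp(gamma_mu s_t)`, where `s_t`
#' is the supplied covariate standardised to zero mean and unit variance and
#' held stepwise constant over its bins. Used for parameter-recovery studies
#' of [covariate_bd_mcmc()] with a known covariate.
#'
#' @param lambda0,mu0 baseline rates (per lineage per Myr).
#' @param gamma_lambda,gamma_mu covariate effects.
#' @param covariate data frame with `age` (Ma) and `value`.
#' @param t_origin clade origin age (Ma).
#' @param seed RNG seed.
#' @param min_species,max_species accepted range of total species counts
#'   (rejection sampling; the cap bounds runtime).
#' @param max_attempts rejection cap.
#' @return data frame with `species`, `ts`, `te` (Ma; `te = 0` for lineages
#'   surviving to the present).
#' @export
simulate_bd_times <- function(lambda0, mu0, gamma_lambda, gamma_mu,
                              covariate, t_origin, seed = 1L,
                              min_species = 20L, max_species = 2000L,
                              max_attempts = 1000L) {
  set.seed(seed)
  s_sd <- stats::sd(covariate$value)
  z <- if (s_sd > 0) (covariate$value - mean(covariate$value)) / s_sd
       else rep(0, length(covariate$value))
  cov_age <- covariate$age
  s_at <- function(a) z[which.min(abs(cov_age - a))]
  for (attempt in seq_len(max_attempts)) {
    ts <- t_origin; te <- NA_real_
    alive <- 1L
    n <- 1L
    a <- t_origin                        # current age, decreasing
    overflow <- FALSE
    repeat {
      if (length(alive) == 0 || a <= 0) break
      seg_end <- max(a - 1, 0)           # 1-Myr lattice
      s <- s_at((a + seg_end) / 2)
      lam <- lambda0 * exp(gamma_lambda * s)
      mu <- mu0 * exp(gamma_mu * s)
      while (a > seg_end && length(alive) > 0) {
        total <- length(alive) * (lam + mu)
        dt <- stats::rexp(1, total)
        if (a - dt < seg_end) { a <- seg_end; break }
        a <- a - dt
        who <- sample.int(length(alive), 1)
        if (stats::runif(1) < lam / (lam + mu)) {
          n <- n + 1L
          if (n > max_species) { overflow <- TRUE; break }
          ts <- c(ts, a); te <- c(te, NA_real_)
          alive <- c(alive, n)
        } else {
          te[alive[who]] <- a
          alive <- alive[-who]
        }
      }
      if (overflow) break
    }
    if (overflow) next
    te[is.na(te)] <- 0
    if (n >= min_species)
      return(data.frame(species = sprintf("sp%04d", seq_len(n)),
                        ts = ts, te = te))
  }
  stop("no accepted birth-death history in ", max_attempts, " attempts")
}

#' Canned end-to-end simulation scenarios
#'
#' Three ready-made configurations: `"null"` (constant rates, no
#' specialisation: the pipeline should find no coincident shifts beyond the
#' false-positive rate), `"late-phase-specialisation"` (heritable range
#' shrinking plus sympatry feedback on both rates: post-shift sympatry
#' increase and net-rate decline expected), and `"covariate-extinction"`
#' (strong positive sympatry effect on extinction: the covariate model
#' should flag `gamma_mu > 0`).
#'
#' @param scenario scenario name.
#' @param seed RNG seed.
#' @param dir optional directory; when given, the occurrence CSV, the truth
#'   sidecar CSV and a JSON config echo are written there.
#' @return list: `occurrences` (data frame), `history` (`true_history`),
#'   `config`, and the file `paths` when `dir` was given.
#' @export
end_to_end_case <- function(scenario = c("null", "late-phase-specialisation",
                                         "covariate-extinction"),
                            seed = 1L, dir = NULL) {
  scenario <- match.arg(scenario)
  cfg <- switch(scenario,
    "null" = simulation_config(seed = seed),
    "late-phase-specialisation" = simulation_config(
      seed = seed, specialisation_rate = 0.04, gamma_lambda = -1,
      gamma_mu = 1.5),
    "covariate-extinction" = simulation_config(
      seed = seed, specialisation_rate = 0.02, gamma_mu = 2))
  hist <- simulate_clade(cfg, min_species = 60L, max_attempts = 3000L)
  occ <- simulate_preservation(hist)
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      occurrences = file.path(dir, sprintf("%s_occurrences.csv", scenario)),
      truth = file.path(dir, sprintf("%s_truth.csv", scenario)),
      config = file.path(dir, sprintf("%s_config.json", scenario)))
    paths$truth_series <- file.path(dir,
                                    sprintf("%s_truth_series.csv", scenario))
    utils::write.csv(occ, paths$occurrences, row.names = FALSE)
    utils::write.csv(hist$species, paths$truth, row.names = FALSE)
    utils::write.csv(hist$series, paths$truth_series, row.names = FALSE)
    jsonlite::write_json(
      c(list(scenario = scenario), unclass(cfg)), paths$config,
      auto_unbox = TRUE, digits = NA)
  }
  list(occurrences = occ, history = hist, config = cfg, paths = paths)
}
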