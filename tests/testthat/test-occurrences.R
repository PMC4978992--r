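test_that("reading occurrences parses valid rows and reports rejects", {
  df <- make_occ(c("Acme alpha", "Acme beta", "Acme gamma"),
                 lng = c(10, 11, 12), lat = c(0, 1, 2),
                 min_ma = c(10, 11, 12), max_ma = c(12, 13, 14))
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE)
  ds <- read_occurrences(p)
  expect_s3_class(ds, "clade_dataset")
  expect_equal(nrow(ds$records), 3)
  expect_equal(ds$clade_id, "cladeA")

  # a row with max_age < min_age is rejected and counted, not kept silently
  bad <- df
  bad$min_ma[2] <- 20
  write.csv(bad, p, row.names = FALSE)
  ds2 <- read_occurrences(p)
  expect_equal(nrow(ds2$records), 2)
  expect_match(ds2$provenance[1], "rejected 1")
})

test_that("a dialect map makes a column-permuted file parse identically", {
  df <- make_occ(c("Acme alpha", "Acme beta", "Acme gamma"),
                 lng = c(10, 11, 12), lat = c(0, 1, 2),
                 min_ma = c(10, 11, 12), max_ma = c(12, 13, 14))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, p1, row.names = FALSE)
  odd <- df[, c("max_ma", "paleo_lat", "species", "clade", "min_ma",
                "paleo_lng", "genus")]
  names(odd) <- c("late_age", "plat", "accepted_name", "group", "early_age",
                  "plng", "genus_name")
  write.csv(odd, p2, row.names = FALSE)
  dia <- c(species = "accepted_name", genus = "genus_name", clade = "group",
           paleo_lng = "plng", paleo_lat = "plat", min_ma = "early_age",
           max_ma = "late_age")
  ds1 <- read_occurrences(p1)
  ds2 <- read_occurrences(p2, dialect = dia)
  expect_equal(ds2$records, ds1$records)
})

test_that("missing columns and empty files raise informative errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  df <- make_occ("Acme alpha", 0, 0, 1, 2)
  write.csv(df[, -4], p, row.names = FALSE)
  expect_error(read_occurrences(p), "paleo_lng")
  writeLines("species,genus,clade,paleo_lng,paleo_lat,min_ma,max_ma", p)
  expect_error(read_occurrences(p), "empty")
})

test_that("open-nomenclature species are removed, counted per species", {
  nm <- c("Acme alpha", "Acme sp.", "Acme cf. beta", "Bcme aff. x",
          "Bcme indet.", "Ccme? dubia", "Dcme delta")
  ds <- clade_dataset(make_occ(rep(nm, each = 2), lng = 0, lat = 0,
                               min_ma = 1, max_ma = 2))
  out <- filter_open_nomenclature(ds)
  expect_setequal(unique(out$records$species), c("Acme alpha", "Dcme delta"))
  # count of removed species equals an independent text scan
  scan <- sum(vapply(nm, function(s)
    grepl("(^| )(sp\\.|spp\\.|cf\\.|aff\\.|indet\\.)( |$)", s) ||
      grepl("?", s, fixed = TRUE), logical(1)))
  expect_match(out$provenance[length(out$provenance)],
               sprintf("removed %d species", scan))
  # no-marker dataset passes through unchanged
  clean <- clade_dataset(make_occ(c("Aa bb", "Cc dd"), 0, 0, 1, 2))
  expect_equal(filter_open_nomenclature(clean)$records, clean$records)
})

test_that("minimum-occurrence filter applies the boundary exactly", {
  df <- make_occ(c(rep("Acme nine", 9), rep("Acme ten", 10)),
                 lng = 0, lat = 0, min_ma = 1, max_ma = 2)
  ds <- clade_dataset(df)
  out <- filter_min_total_occurrences(ds, k = 10)
  expect_setequal(unique(out$records$species), "Acme ten")
  expect_equal(nrow(filter_min_total_occurrences(ds, k = 1)$records),
               nrow(df))
})

test_that("bin assignment follows the midpoint and edge conventions", {
  # occurrence (min 10, max 12): midpoint 11 -> bin (10, 15]
  ds <- clade_dataset(make_occ(c("Aa bb", "Aa bb", "Aa bb"), 0, 0,
                               min_ma = c(10, 5, 0.5), max_ma = c(12, 5, 0.5)))
  sc <- binning_scheme(ds, 5)
  expect_equal(sc$bin_edges, c(15.5, 10.5, 5.5, 0.5))
  out <- assign_to_bins(ds, sc)
  expect_equal(out$records$bin[1], 1)        # midpoint 11 in oldest bin
  # an age exactly on an interior edge joins the younger bin
  ds2 <- clade_dataset(make_occ(rep("Aa bb", 3), 0, 0,
                                min_ma = c(15, 10, 5), max_ma = c(15, 10, 5)))
  sc2 <- binning_scheme(ds2, 5)
  expect_equal(sc2$bin_edges, c(15, 10, 5))
  out2 <- assign_to_bins(ds2, sc2)
  expect_equal(out2$records$bin, c(1L, 2L, 2L))  # 15 oldest bin; 10 younger;
                                                 # 5 (youngest edge) last bin
  # random-draw mode is reproducible under a fixed seed
  ds3 <- clade_dataset(make_occ(rep("Aa bb", 20), 0, 0,
                                min_ma = runif(20, 0.5, 7),
                                max_ma = runif(20, 8, 15)))
  sc3 <- binning_scheme(ds3, 5)
  r1 <- assign_to_bins(ds3, sc3, mode = "random", seed = 99)
  r2 <- assign_to_bins(ds3, sc3, mode = "random", seed = 99)
  expect_identical(r1$records$bin, r2$records$bin)
})

test_that("per-bin counts conserve the total and filters ignore row order", {
  set.seed(11)
  n <- 200
  df <- make_occ(sprintf("Sp %02d", sample(1:20, n, replace = TRUE)),
                 lng = runif(n, -20, 20), lat = runif(n, -10, 10),
                 min_ma = runif(n, 0, 50), max_ma = NA)
  df$max_ma <- df$min_ma + runif(n, 0, 3)
  ds <- clade_dataset(df)
  sc <- binning_scheme(ds, 10)
  binned <- assign_to_bins(ds, sc)
  expect_equal(sum(table(binned$records$bin)), nrow(df))
  # shuffling input rows leaves the retained species set unchanged
  shuf <- clade_dataset(df[sample.int(n), ])
  f1 <- filter_min_total_occurrences(filter_open_nomenclature(ds), k = 8)
  f2 <- filter_min_total_occurrences(filter_open_nomenclature(shuf), k = 8)
  expect_setequal(unique(f1$records$species), unique(f2$records$species))
})

test_that("stratigraphic continuity removes gapped species (brute force)", {
  # species occupying bins {5,4,3} is continuous; {5,3} has a gap
  # ages sit mid-bin for 10-Myr bins anchored by a young edge record at 0.5
  mk <- function(bins, name, n = 6) {
    age <- 5 + 10 * (n - bins)
    make_occ(rep(name, 3 * length(bins)), 0, 0,
             min_ma = rep(age, each = 3), max_ma = rep(age, each = 3),
             genus = "")
  }
  anchor <- function(name) make_occ(name, 0, 0, 0.5, 0.5, genus = "")
  df <- rbind(mk(c(5, 4, 3), "Aa continuous"), mk(c(5, 3), "Aa gapped"),
              mk(1:6, "Aa full"), anchor("Aa full"))
  ds <- clade_dataset(df)
  sc <- binning_scheme(ds, 10)
  binned <- assign_to_bins(ds, sc)
  out <- filter_stratigraphic_continuity(binned, max_gap_bins = 0)
  expect_setequal(unique(out$records$species), c("Aa continuous", "Aa full"))
  out1 <- filter_stratigraphic_continuity(binned, max_gap_bins = 1)
  expect_setequal(unique(out1$records$species),
                  c("Aa continuous", "Aa gapped", "Aa full"))

  # random occupancy patterns match an exhaustive run-gap oracle
  set.seed(7)
  for (rep in 1:20) {
    occ_bins <- sort(sample(1:8, sample(2:6, 1)))
    nm <- "Zz random"
    dfr <- rbind(mk(1:8, "Aa anchor", n = 8), anchor("Aa anchor"),
                 mk(occ_bins, nm, n = 8))
    dsr <- assign_to_bins(clade_dataset(dfr), binning_scheme(clade_dataset(dfr), 10))
    kept <- nm %in% filter_stratigraphic_continuity(dsr)$records$species
    oracle <- max(diff(occ_bins)) - 1 <= 0
    expect_equal(kept, oracle, info = paste(occ_bins, collapse = ","))
  }
  expect_error(filter_stratigraphic_continuity(ds), "bin")
})

test_that("bin-length choice keeps the most bins satisfying the 3x3 rule", {
  # construct: 3 species with 3 occurrences in each 5-Myr window, but the
  # 2-Myr windows split those occurrences apart
  set.seed(3)
  rows <- list(make_occ("Sp 1", runif(1), runif(1), 0.5, 0.5))  # edge anchor
  for (w in 0:3) {                            # four 5-Myr windows
    for (s in 1:3) {
      age <- 5 * w + c(1, 2.5, 4)             # spread inside the window
      rows[[length(rows) + 1]] <- make_occ(
        rep(sprintf("Sp %d", s), 3), lng = runif(3), lat = runif(3),
        min_ma = age, max_ma = age)
    }
  }
  ds <- clade_dataset(do.call(rbind, rows))
  sc <- choose_bin_length(ds, candidate_lengths = c(2, 5))
  expect_equal(sc$bin_length, 5)
  expect_false(sc$flagged)
  # exhaustive verification of the chosen scheme
  binned <- assign_to_bins(ds, sc)
  tab <- table(binned$records$bin, binned$records$species)
  expect_true(all(rowSums(tab >= 3) >= 3))
  # single valid candidate is returned as-is
  expect_equal(choose_bin_length(ds, 5)$bin_length, 5)
  # impossible rule -> flagged best-effort scheme
  expect_warning(sc_bad <- choose_bin_length(ds, 0.5), "no candidate")
  expect_true(sc_bad$flagged)
  expect_gt(sc_bad$n_violating, 0)
  expect_error(choose_bin_length(ds, numeric()), "empty")
})
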