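test_that("the icosahedral grid has the expected cell count and even areas", {
  g <- hex_grid(3)
  expect_equal(nrow(g), 10 * 9 + 2)
  # Monte-Carlo area audit: cell shares of 2e5 uniform sphere points
  set.seed(61)
  z <- rnorm(2e5); y <- rnorm(2e5); x <- rnorm(2e5)
  r <- sqrt(x^2 + y^2 + z^2)
  lat <- asin(z / r) * 180 / pi
  lon <- atan2(y / r, x / r) * 180 / pi
  cell <- paleodiv:::assign_cells(lat, lon, g)
  share <- tabulate(cell, nrow(g)) / 2e5
  expect_lt(sd(share) / mean(share), 0.12)
  expect_gt(min(share), 0.5 * mean(share))
})

test_that("occurrences map to single or disjoint cell sets as placed", {
  recs <- make_records(n = 5, paleolat = 10, paleolng = 20)
  gtm <- hex_bin(recs, 3)
  expect_equal(nrow(gtm$cells), 1L)
  expect_equal(gtm$cells$n_occ, 5L)
  anti <- rbind(make_records(n = 3, genus = "Genusa", paleolat = 10,
                             paleolng = 20),
                make_records(n = 3, genus = "Genusb", paleolat = -10,
                             paleolng = -160))
  gtm2 <- hex_bin(anti, 3)
  expect_equal(nrow(gtm2$cells), 2L)
  expect_equal(length(intersect(gtm2$cell_of[1:3], gtm2$cell_of[4:6])), 0L)
  expect_error(hex_bin(make_records(paleolat = 95), 3), "coordinates")
})

test_that("the modified Forbes index follows its closed form", {
  pa <- rbind(c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0),
              c(1, 1, 1, 1, 1, 0, 0, 1, 1, 1))
  # a = 5, b = 2, c = 3, n = 10
  f <- 5 * (10 + sqrt(10)) / (5 * (10 + sqrt(10)) + 1.5 * 2 * 3)
  d <- forbes_dissimilarity(pa)
  expect_equal(d[1, 2], 1 - f, tolerance = 1e-12)
  # identical assemblages and disjoint assemblages hit the bounds
  same <- rbind(c(1, 1, 0), c(1, 1, 0))
  expect_equal(forbes_dissimilarity(same)[1, 2], 0)
  disj <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(forbes_dissimilarity(disj)[1, 2], 1)
})

test_that("Forbes dissimilarity is symmetric, bounded, zero on diagonal", {
  set.seed(62)
  pa <- matrix(runif(80) < 0.4, 8, 10)
  pa[1, ] <- FALSE
  expect_warning(d <- forbes_dissimilarity(pa), "empty")
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("planted faunas with zero overlap are recovered exactly", {
  set.seed(63)
  recs <- rbind(
    make_records(n = 60, genus = sample(paste0("GenusA", 1:12), 60,
                                        replace = TRUE),
                 paleolat = rnorm(60, 20, 4), paleolng = rnorm(60, 30, 4)),
    make_records(n = 60, genus = sample(paste0("GenusB", 1:12), 60,
                                        replace = TRUE),
                 paleolat = rnorm(60, -25, 4), paleolng = rnorm(60, -120, 4))
  )
  gtm <- hex_bin(recs, 4)
  truth <- as.integer(grepl("^GenusA",
                            apply(gtm$pa, 1, function(r) {
                              colnames(gtm$pa)[which(r)[1]]
                            })))
  reg <- regionalize(gtm, k_range = 2:4)
  expect_equal(igraph::compare(reg$assignments$region_pam - 1L, truth,
                               method = "adjusted.rand"), 1)
  expect_equal(igraph::compare(reg$assignments$region_network - 1L, truth,
                               method = "adjusted.rand"), 1)
  expect_equal(reg$agreement, 1)
})

test_that("the two methods agree on noisy planted partitions", {
  aris <- vapply(1:3, function(s) {
    set.seed(70 + s)
    g1 <- paste0("GenusA", 1:15)
    g2 <- paste0("GenusB", 1:15)
    gc_ <- paste0("GenusC", 1:5)  # cosmopolitan taxa shared by both faunas
    pick <- function(pool, n) {
      # 10% of draws come from the cosmopolitan pool
      ifelse(runif(n) < 0.1, sample(gc_, n, TRUE), sample(pool, n, TRUE))
    }
    recs <- rbind(
      make_records(n = 250, genus = pick(g1, 250),
                   paleolat = rnorm(250, 20, 4), paleolng = rnorm(250, 30, 4)),
      make_records(n = 250, genus = pick(g2, 250),
                   paleolat = rnorm(250, -25, 4),
                   paleolng = rnorm(250, -120, 4))
    )
    regionalize(hex_bin(recs, 3), k_range = 2:4)$agreement
  }, numeric(1))
  expect_gte(mean(aris >= 0.8), 2 / 3)
})

test_that("degenerate matrices regionalize without crashing", {
  one <- hex_bin(make_records(n = 3), 3)
  reg <- regionalize(one)
  expect_equal(unique(reg$assignments$region_pam), 1L)
  # fully shared fauna: both methods see a single block; no crash
  set.seed(73)
  shared <- rbind(make_records(n = 20, genus = "Genusa",
                               paleolat = runif(20, -40, 40),
                               paleolng = runif(20, -90, 90)))
  expect_no_error(regionalize(hex_bin(shared, 3), k_range = 2:3))
})

test_that("spatial windows subset per bin and report stable areas", {
  bins <- data.frame(bin = c("b1", "b2"), max_ma = c(260, 255),
                     min_ma = c(255, 250))
  recs <- rbind(
    make_records(n = 10, max_ma = 258, min_ma = 257, paleolat = 10,
                 paleolng = 20),
    make_records(n = 10, max_ma = 252, min_ma = 251, paleolat = 12,
                 paleolng = 24)
  )
  grid <- hex_grid(3)
  cells <- unique(paleodiv:::assign_cells(recs$paleolat, recs$paleolng, grid))
  # whole-globe window: identity subsets
  all_cells <- grid$cell_id
  sw <- spatial_window(recs, bins, list(b1 = all_cells, b2 = all_cells),
                       grid = grid)
  expect_equal(nrow(sw$subsets$b1), 10)
  expect_equal(nrow(sw$subsets$b2), 10)
  # a window missing the points in one bin leaves it empty but logged
  sw2 <- spatial_window(recs, bins, list(b1 = cells, b2 = setdiff(all_cells,
                                                                  cells)),
                        grid = grid)
  expect_equal(nrow(sw2$subsets$b2), 0)
  expect_equal(sw2$audit$n_in_bin, c(10, 10))
  expect_error(spatial_window(recs, bins, list(b1 = cells), grid = grid),
               "b2")
})

test_that("a drifting cluster is tracked by a moving window", {
  set.seed(64)
  cfg <- sim_config(n_regions = 1, region_drift_deg_per_myr = 1.5,
                    rng_seed = 65)
  h <- simulate_bd(cfg)
  occ <- simulate_preservation(h, cfg)
  emit <- emit_occurrence_table(h, occ, cfg)
  recs <- emit$records
  st <- load_stage_table()
  st <- st[st$max_ma <= 276 & st$min_ma >= 244.2, ]
  bins <- data.frame(bin = st$stage, max_ma = st$max_ma, min_ma = st$min_ma)
  grid <- hex_grid(3)
  cell <- paleodiv:::assign_cells(recs$paleolat, recs$paleolng, grid)
  mid <- (recs$max_ma + recs$min_ma) / 2
  # build the window from each bin's own occupied cells (a tracked plate)
  wins <- lapply(seq_len(nrow(bins)), function(i) {
    unique(cell[mid <= bins$max_ma[i] & mid > bins$min_ma[i]])
  })
  names(wins) <- bins$bin
  sw <- spatial_window(recs, bins, wins, grid = grid)
  kept <- sw$audit$n_in_window / pmax(sw$audit$n_in_bin, 1)
  expect_true(all(kept[sw$audit$n_in_bin > 0] >= 0.95))
})

test_that("collinear-cell standardization follows the removal rule", {
  d_km <- geosphere::distm(cbind(c(0, 10), c(0, 0)))[1, 2] / 1000
  recs <- rbind(
    make_records(n = 10, genus = "Genusa", paleolat = 0, paleolng = 0),
    make_records(n = 1, genus = "Genusb", paleolat = 0, paleolng = 10),
    make_records(n = 10, genus = "Genusc", paleolat = 0, paleolng = 20)
  )
  bins <- data.frame(bin = "b1", max_ma = 250, min_ma = 248)
  # threshold between d and 2d: the 1-count middle cell goes first, the
  # remaining span is still 2d, so removal continues to a single cell
  res <- mst_standardize(recs, bins, resolution = 8,
                         threshold = 1.5 * d_km)
  expect_equal(res$audit$n_removed, 2L)
  expect_equal(res$audit$final_mst_km, 0)
  expect_equal(res$audit$n_cells_final, 1L)
  # generous threshold: nothing happens
  res2 <- mst_standardize(recs, bins, resolution = 8, threshold = 3 * d_km)
  expect_equal(res2$audit$n_removed, 0L)
  expect_equal(nrow(res2$records), nrow(recs))
})

test_that("median-threshold standardization equalizes the spatial footprint", {
  cfg <- sim_config(rng_seed = 66)
  h <- simulate_bd(cfg)
  occ <- simulate_preservation(h, cfg)
  emit <- emit_occurrence_table(h, occ, cfg)
  st <- load_stage_table()
  st <- st[st$max_ma <= 276 & st$min_ma >= 244.2, ]
  bins <- data.frame(bin = st$stage, max_ma = st$max_ma, min_ma = st$min_ma)
  res <- mst_standardize(emit$records, bins, resolution = 3)
  expect_true(all(res$audit$final_mst_km <= res$threshold + 1e-9))
  expect_true(all(res$audit$final_mst_km <= res$audit$raw_mst_km + 1e-9))
  expect_lte(stats::var(res$audit$final_mst_km),
             stats::var(res$audit$raw_mst_km))
  expect_lte(nrow(res$records), nrow(emit$records))
})
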