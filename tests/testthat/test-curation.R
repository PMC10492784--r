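test_that("the >10 Myr rule drops non-stage rows but keeps long stages", {
  recs <- rbind(
    make_records(genus = "Genusa", max_ma = 273.0, min_ma = 259.5,
                 stage = "Guadalupian", is_international_stage = FALSE),
    make_records(genus = "Genusb", max_ma = 227.0, min_ma = 208.5,
                 stage = "Norian", is_international_stage = TRUE)
  )
  cl <- clean_occurrences(recs, max_span = 10)
  expect_equal(cl$kept$genus, "Genusb")
  expect_equal(cl$log$rule, "age_span")
  # a span of exactly 10 Myr is kept (strict comparison)
  r10 <- make_records(max_ma = 260, min_ma = 250,
                      is_international_stage = FALSE)
  expect_equal(nrow(clean_occurrences(r10)$kept), 1L)
})

test_that("qualifier rows drop only when primary equals accepted genus", {
  recs <- rbind(
    make_records(genus = "Genusa", primary_reso = "cf.",
                 accepted_genus = "Genusa"),
    make_records(genus = "Genusa", primary_reso = "cf.",
                 accepted_genus = "Genusb"),
    make_records(genus = "Genusc", primary_reso = "aff.",
                 accepted_genus = "Genusc"),
    make_records(genus = "Genusd", primary_reso = "")
  )
  cl <- clean_occurrences(recs)
  expect_equal(sort(cl$kept$genus), c("Genusa", "Genusd"))
  expect_true(all(cl$log$rule == "qualifier"))
})

test_that("terrestrial and unparseable rows are partitioned with no loss", {
  recs <- rbind(
    make_records(environment = "terrestrial"),
    make_records(genus = ""),
    make_records(max_ma = NA),
    make_records()
  )
  cl <- clean_occurrences(recs)
  expect_equal(nrow(cl$kept) + nrow(cl$log), nrow(recs))
  expect_setequal(cl$log$rule, c("terrestrial", "ambiguous_genus", "bad_age"))
})

test_that("empty input cleans to empty output and empty log", {
  cl <- clean_occurrences(make_records()[0, ])
  expect_equal(nrow(cl$kept), 0L)
  expect_equal(nrow(cl$log), 0L)
})

test_that("subgenus stripping deletes or promotes bracketed names", {
  expect_equal(strip_subgenus("Neomegalodon (Rossiodus)", "delete_bracket"),
               "Neomegalodon")
  expect_equal(strip_subgenus("Neomegalodon (Rossiodus)", "promote",
                              "Rossiodus"), "Rossiodus")
  expect_equal(strip_subgenus("Neomegalodon (Rossiodus)", "promote",
                              "Other"), "Neomegalodon")
  expect_equal(strip_subgenus("Bositra", "delete_bracket"), "Bositra")
  expect_equal(strip_subgenus("Bositra", "promote"), "Bositra")
  expect_error(strip_subgenus("Broken (Name", "delete_bracket"),
               "unbalanced")
})

test_that("stratigraphic density flags pick out the far outlier", {
  set.seed(1)
  mid <- c(runif(50, 240, 250), 330)
  recs <- make_records(n = 51, genus = "Genusa", max_ma = mid + 1,
                       min_ma = mid - 1)
  flags <- flag_range_outliers(recs, density = 0.90)
  expect_true(flags[51])
  expect_lt(mean(flags[1:50]), 0.15)
})

test_that("uniform ages flag about the excluded density mass", {
  set.seed(2)
  mid <- runif(400, 200, 300)
  recs <- make_records(n = 400, genus = "Genusa", max_ma = mid + 0.5,
                       min_ma = mid - 0.5)
  frac <- mean(flag_range_outliers(recs, density = 0.90))
  expect_lt(abs(frac - 0.10), 0.04)
  expect_false(any(flag_range_outliers(recs, density = 1.0)))
})

test_that("single-occurrence genera are never flagged", {
  recs <- make_records(n = 1)
  expect_false(flag_range_outliers(recs))
})

test_that("age randomization is coeval per collection and deterministic", {
  recs <- rbind(
    make_records(genus = "Genusa", collection_no = 1, max_ma = 250, min_ma = 245),
    make_records(genus = "Genusb", collection_no = 1, max_ma = 250, min_ma = 245),
    make_records(genus = "Genusc", collection_no = 2, max_ma = 248, min_ma = 248)
  )
  reps <- randomize_ages(recs, n_replicates = 10, rng_seed = 42)
  expect_length(reps, 10)
  for (r in reps) {
    expect_equal(r$age[1], r$age[2])       # same collection, coeval
    expect_equal(r$age[3], 248)            # degenerate interval
    expect_true(all(r$age <= r$max_ma & r$age >= r$min_ma))
    expect_equal(nrow(r), nrow(recs))
    expect_setequal(r$genus, recs$genus)
  }
  reps2 <- randomize_ages(recs, n_replicates = 10, rng_seed = 42)
  expect_identical(reps, reps2)
  # draws differ across replicates
  expect_false(identical(reps[[1]]$age, reps[[2]]$age))
})

test_that("ecology assignment is pure lookup with epifaunal rollups", {
  recs <- rbind(
    make_records(genus = "Bositra", order = "Ostreida", class = "Bivalvia"),
    make_records(genus = "Genusx", order = "Lingulida", class = "Brachiopoda"),
    make_records(genus = "Genusy", order = "Spiriferida", class = "Brachiopoda"),
    make_records(genus = "Genusz", order = "Nonesuchida", class = "Bivalvia")
  )
  out <- assign_ecology(recs)
  expect_equal(out$eco_class,
               c("reclining", "infaunal", "pedicle_attached", "unknown"))
  expect_equal(out$tier,
               c("epifaunal", "infaunal", "epifaunal", "unknown"))
})

test_that("brachiopod orders map onto the end-Permian split", {
  recs <- rbind(
    make_records(order = "Spiriferida", class = "Brachiopoda"),
    make_records(order = "Thecideida", class = "Brachiopoda"),
    make_records(order = "Lingulida", class = "Brachiopoda")
  )
  out <- assign_pt_group(recs)
  expect_equal(out$pt_group, c("PT_e", "PT_s", "PT_s"))
  bad <- make_records(order = "Nonesuchida", class = "Brachiopoda")
  expect_warning(assign_pt_group(bad), "Nonesuchida")
  ps <- load_pt_split()
  expect_equal(anyDuplicated(ps$order), 0L)
})

test_that("injected artefacts are removed exactly, rule by rule", {
  for (noise in c("terrestrial", "qualifier")) {
    args <- list(qualifier_noise_p = 0, terrestrial_p = 0, subgenus_p = 0,
                 outlier_p = 0, rng_seed = 21)
    args[[if (noise == "terrestrial") "terrestrial_p"
          else "qualifier_noise_p"]] <- 0.15
    cfg <- do.call(sim_config, args)
    h <- simulate_bd(cfg)
    occ <- simulate_preservation(h, cfg)
    emit <- emit_occurrence_table(h, occ, cfg)
    truth_col <- if (noise == "terrestrial") "injected_terrestrial"
                 else "injected_qualifier"
    cl <- clean_occurrences(emit$records)
    expect_setequal(cl$log$row, which(emit$truth[[truth_col]]))
    rule <- if (noise == "terrestrial") "terrestrial" else "qualifier"
    expect_true(all(cl$log$rule == rule))
  }
})
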