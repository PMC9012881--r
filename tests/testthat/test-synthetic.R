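test_that("cohort skeleton honours the design: never-NF fraction, schedule window, determinism", {
  cfg <- cohort_config(n_patients = 36, frac_never_nf = 3 / 36, seed = 4)
  sk <- simulate_schedule(cfg)
  expect_equal(sum(is.na(sk$patients$nf_day)), 3)
  expect_true(all(sk$samples$day >= 0 & sk$samples$day <= 28))
  expect_true(all(sk$samples$patient_id %in% sk$patients$patient_id))
  nf <- sk$patients$nf_day[!is.na(sk$patients$nf_day)]
  expect_true(all(nf >= -3 & nf <= 20))

  # every patient febrile when the never-NF fraction is zero
  sk0 <- simulate_schedule(cohort_config(n_patients = 10, frac_never_nf = 0,
                                         seed = 1))
  expect_false(anyNA(sk0$patients$nf_day))

  # bitwise reproducibility
  sk2 <- simulate_schedule(cfg)
  expect_identical(sk, sk2)
  co1 <- simulate_cohort(cohort_config(n_patients = 6, seed = 9),
                         metabolome_truth(n_metabolites = 30,
                                          signature_ids = 1:3),
                         microbiome_truth(n_genera = 8))
  co2 <- simulate_cohort(cohort_config(n_patients = 6, seed = 9),
                         metabolome_truth(n_metabolites = 30,
                                          signature_ids = 1:3),
                         microbiome_truth(n_genera = 8))
  expect_identical(co1$metabolome, co2$metabolome)
  expect_identical(co1$counts, co2$counts)
})

test_that("configuration validation rejects impossible designs", {
  expect_error(cohort_config(n_patients = 1), "n_patients")
  expect_error(cohort_config(nf_day_range = c(5, -5)), "nf_day_range")
  expect_error(cohort_config(frac_never_nf = 1.2), "frac_never_nf")
  expect_error(microbiome_truth(n_genera = 5,
                                association = matrix(c(1, 1, 0, 0, 0), 5)),
               "zero")
  expect_error(microbiome_truth(n_genera = 3,
                                association = matrix(c(1e-7, 0, 0), 3)),
               "zero")
})

test_that("planted metabolite shift is recovered at its stated effect size", {
  # ~400 serum samples; log2 fold change 2 planted on metabolite 1
  cfg <- cohort_config(n_patients = 45, frac_never_nf = 0, seed = 21)
  tr <- metabolome_truth(n_metabolites = 20, signature_ids = 1L,
                         shift_log2fc = 2, detection_floor_quantile = 0)
  sk <- simulate_schedule(cfg)
  conc <- simulate_metabolome(sk, tr, seed = 22)
  serum <- sk$samples[sk$samples$type == "serum", ]
  grp <- assign_nf_groups(serum, sk$patients)
  expect_gte(nrow(conc), 350)
  lfc <- (mean(log(conc[grp == "post", 1])) -
          mean(log(conc[grp == "pre", 1]))) / log(2)
  expect_lt(abs(lfc - 2), 0.3)
  # unshifted metabolites stay centered
  lfc_null <- (colMeans(log(conc[grp == "post", -1])) -
               colMeans(log(conc[grp == "pre", -1]))) / log(2)
  expect_lt(max(abs(lfc_null)), 0.3)
})

test_that("detection floor produces the configured missingness", {
  cfg <- cohort_config(n_patients = 30, seed = 2)
  sk <- simulate_schedule(cfg)
  full <- simulate_metabolome(sk, metabolome_truth(
    n_metabolites = 40, signature_ids = integer(0),
    detection_floor_quantile = 0), seed = 3)
  expect_false(anyNA(full))
  q <- 0.2
  cens <- simulate_metabolome(sk, metabolome_truth(
    n_metabolites = 40, signature_ids = integer(0),
    detection_floor_quantile = q), seed = 3)
  frac <- colMeans(is.na(cens))
  n <- nrow(cens)
  tol <- 3 * sqrt(q * (1 - q) / n) + 1 / n
  expect_true(all(abs(frac - q) <= tol))
})

test_that("microbiome counts are exact multinomials at the drawn depth", {
  cfg <- cohort_config(n_patients = 8, seed = 6)
  sk <- simulate_schedule(cfg)
  mic <- simulate_microbiome(sk, microbiome_truth(
    n_genera = 12, depth_range = c(5000, 5000)), seed = 7)
  expect_true(all(rowSums(mic$counts) == 5000))
  expect_true(all(mic$counts >= 0))
  expect_identical(storage.mode(mic$counts), "integer")
  mic2 <- simulate_microbiome(sk, microbiome_truth(
    n_genera = 12, depth_range = c(2000, 20000)), seed = 8)
  expect_identical(unname(rowSums(mic2$counts)), unname(as.numeric(mic2$depths)))
})

test_that("forward log-contrast model has its closed form at zero noise", {
  # B column (+1, -1, 0, ...) and no noise: log metabolite value of a paired
  # serum sample equals log(rel_1 / rel_2) of its paired stool exactly
  cfg <- cohort_config(n_patients = 6, seed = 31)
  B <- matrix(0, 5, 1, dimnames = list(NULL, "1"))
  B[1:2, 1] <- c(1, -1)
  mt <- metabolome_truth(n_metabolites = 2, signature_ids = integer(0),
                         base_log_mean = 0, base_log_sd = 0,
                         detection_floor_quantile = 0)
  mic <- microbiome_truth(n_genera = 5, association = B, noise_sd = 0)
  co <- simulate_cohort(cfg, mt, mic)
  serum <- co$samples[co$samples$type == "serum", ]
  stool <- co$samples[co$samples$type == "stool", ]
  pairs <- pair_samples(serum, stool, max_lag_days = 3)
  expect_gt(nrow(pairs), 10)
  rel <- co$truth$rel_abundance
  expected <- log(rel[pairs$stool_id, 1] / rel[pairs$stool_id, 2])
  expect_equal(unname(log(co$metabolome[pairs$serum_id, 1])),
               unname(expected), tolerance = 1e-12)
  # metabolite 2 is untouched by the association
  expect_equal(unname(log(co$metabolome[pairs$serum_id, 2])),
               rep(0, nrow(pairs)), tolerance = 1e-12)
})

test_that("cohort written to disk round-trips through the TSV dialect", {
  co <- simulate_cohort(cohort_config(n_patients = 4, seed = 12),
                        metabolome_truth(n_metabolites = 15,
                                         signature_ids = 1:2),
                        microbiome_truth(n_genera = 6))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  met <- read_matrix_tsv(file.path(dir, "metabolome.tsv"))
  expect_equal(met, co$metabolome)
  cnt <- read_count_table(file.path(dir, "counts.tsv"))
  expect_equal(unname(cnt), unname(co$counts))
  smp <- read_sample_metadata(file.path(dir, "samples.tsv"))
  expect_equal(smp$sample_id, co$samples$sample_id)
  gm <- read_genus_map(file.path(dir, "genus_map.tsv"))
  expect_identical(gm, co$genus_map)
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(truth$config$n_patients, 4)
})
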