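# Synthetic claims generator: determinism, degenerate cases, round-trip,
# and agreement of the emitted fills with the generating dose model.

test_that("an empty population yields empty tables and labels", {
  ds <- generate_population(sim_config(0))
  expect_s3_class(ds, "claims_dataset")
  expect_equal(nrow(ds$patients), 0L)
  expect_equal(nrow(ds$enrollment), 0L)
  expect_equal(nrow(ds$prescriptions), 0L)
  expect_equal(nrow(ds$diagnoses), 0L)
  expect_equal(nrow(ds$ground_truth$labels), 0L)
})

test_that("a degenerate flat generator emits the constant target dose", {
  co <- 2
  cfg <- sim_config(40, seed = 3,
                    mixture_proportions = 1,
                    poly_coeffs = matrix(c(co, 0, 0), 1),
                    covariate_effect = 0, sigma = 1e-8,
                    stimulant_rate = 0, follow_up_range = c(12L, 12L),
                    drug_catalog = flat_catalog(),
                    nonoral_opioid_rate = 0)
  ds <- generate_population(cfg)
  cres <- build_cohort(ds)
  expect_equal(nrow(cres$cohort), 40L)
  doses <- dose_series_table(cres$cohort, ds$prescriptions, flat_catalog())
  # quantization: one 5 mg unit (factor 1) over 30 days = 1/6 mg/day steps
  expect_true(all(abs(doses$mme - expm1(co)) <= 0.5 * 5 / 30 + 1e-9))
})

test_that("generation is deterministic and patient streams are stable", {
  cfg <- sim_config(30, seed = 7)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$prescriptions, b$prescriptions)
  expect_identical(a$diagnoses, b$diagnoses)
  # first 30 patients unchanged when more are generated under the same seed
  big <- generate_population(sim_config(45, seed = 7))
  expect_identical(a$patients,
                   big$patients[seq_len(30), , drop = FALSE])
  expect_identical(a$prescriptions,
                   big$prescriptions[big$prescriptions$patient_id %in%
                                       a$patients$patient_id, , drop = FALSE])
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(10, sigma = 0), class = "rxtraj_config_error")
  expect_error(sim_config(10, mixture_proportions = c(0.5, 0)),
               regexp = "mixture_proportions")
  expect_error(sim_config(10, max_months = 120), regexp = "max_months")
  expect_error(sim_config(10, exclusion_fractions = c(bogus = 0.1)),
               regexp = "exclusion_fractions")
  no_oral <- data.frame(drug_id = "x", drug_class = "opioid",
                        route = "patch", strength_mg = 1, mme_factor = 1)
  expect_error(sim_config(10, drug_catalog = no_oral),
               regexp = "oral opioid")
})

test_that("write/read round-trips the dataset and manifest counts rows", {
  cfg <- sim_config(10, seed = 5,
                    exclusion_fractions = c(minor = 0.2, cancer = 0.2))
  ds <- generate_population(cfg)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  expect_equal(nrow(manifest), 5L)
  expect_equal(manifest$rows,
               c(nrow(ds$patients), nrow(ds$enrollment),
                 nrow(ds$prescriptions), nrow(ds$diagnoses),
                 nrow(ds$ground_truth$labels)))
  back <- read_dataset(dir)
  expect_equal(back$patients, ds$patients)
  expect_equal(back$enrollment, ds$enrollment)
  expect_equal(back$prescriptions[names(back$prescriptions) != "mme_factor"],
               ds$prescriptions)
  expect_equal(back$diagnoses, ds$diagnoses)
  expect_equal(back$ground_truth$labels, ds$ground_truth$labels)
  expect_equal(unname(back$ground_truth$poly_coeffs),
               unname(ds$ground_truth$poly_coeffs))
  expect_equal(back$exclusion_injections, ds$exclusion_injections)

  # empty dataset: header-only files
  dir2 <- withr::local_tempdir()
  write_dataset(generate_population(sim_config(0)), dir2)
  for (f in c("patients.csv", "prescriptions.csv"))
    expect_length(readLines(file.path(dir2, f)), 1L)
})

test_that("prescriptions respect the enrollment-span invariant", {
  cfg <- sim_config(150, seed = 11,
                    exclusion_fractions = c(short_pre_enrollment = 0.1,
                                            short_post_enrollment = 0.1))
  ds <- generate_population(cfg)
  en <- ds$enrollment
  rx <- ds$prescriptions
  span <- en[match(rx$patient_id, en$patient_id), ]
  expect_true(all(rx$day >= span$start_day & rx$day <= span$end_day))
  dg <- ds$diagnoses
  span2 <- en[match(dg$patient_id, en$patient_id), ]
  expect_true(all(dg$day >= span2$start_day & dg$day <= span2$end_day))
})

test_that("empirical group frequencies match the mixture proportions", {
  pr <- c(0.6, 0.3, 0.1)
  cfg <- sim_config(10000, seed = 99, mixture_proportions = pr,
                    poly_coeffs = rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
                    covariate_effect = rep(0, 3), stimulant_rate = rep(0, 3),
                    follow_up_range = c(3L, 6L))
  ds <- generate_population(cfg)
  freq <- tabulate(ds$ground_truth$labels$group, 3L) / 10000
  se <- sqrt(pr * (1 - pr) / 10000)
  expect_true(all(abs(freq - pr) <= 3 * se))
})

test_that("reconstructed window doses track the generating curve", {
  # lognormal mean on the raw scale: E[expm1(z)] = exp(mu + s^2/2) - 1
  mu0 <- c(2, 3); sig <- 0.1
  cfg <- sim_config(2000, seed = 13,
                    mixture_proportions = c(0.5, 0.5),
                    poly_coeffs = rbind(c(mu0[1], 0, 0), c(mu0[2], 0, 0)),
                    covariate_effect = c(0, 0), sigma = sig,
                    stimulant_rate = c(0, 0), follow_up_range = c(12L, 12L),
                    drug_catalog = flat_catalog(), nonoral_opioid_rate = 0)
  ds <- generate_population(cfg)
  cres <- build_cohort(ds)
  doses <- dose_series_table(cres$cohort, ds$prescriptions, flat_catalog())
  lab <- ds$ground_truth$labels
  doses$group <- lab$group[match(doses$patient_id, lab$patient_id)]
  for (g in 1:2) {
    x <- doses$mme[doses$group == g]
    target <- exp(mu0[g] + sig^2 / 2) - 1
    tol <- 3 * stats::sd(x) / sqrt(length(x)) + 0.5 * 5 / 30
    expect_lt(abs(mean(x) - target), tol)
  }
})
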