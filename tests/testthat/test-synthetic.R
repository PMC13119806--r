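# Synthetic-data generators: seeded determinism, zero-noise identities,
# and calibration of the noise model.

test_that("trait table is deterministic and matches the design size", {
  cfg <- default_experiment_config()
  t1 <- generate_trait_table(cfg, 7)
  t2 <- generate_trait_table(cfg, 7)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 4 * 4 * 3 * length(unique(cfg$cell_means$trait)))
  t3 <- generate_trait_table(cfg, 8)
  expect_false(identical(t1$value, t3$value))
})

test_that("zero-noise trait table reproduces every cell mean exactly", {
  cfg <- default_experiment_config()
  cfg$cell_means$se <- 0
  tab <- generate_trait_table(cfg, 3)
  cm <- cfg$cell_means
  key <- paste(tab$trait, tab$treatment, tab$period)
  expect_equal(tab$value,
               cm$mean[match(key, paste(cm$trait, cm$treatment, cm$period))])
})

test_that("replicate noise sd equals SE * sqrt(n)", {
  # 10,000 replicates of one cell: mean 14.5, SE 0.3, n = 3 noise model
  cfg <- mini_config(14.5, 0.3, replicates = 10000L)
  tab <- generate_trait_table(cfg, 11)
  expect_equal(sd(tab$value), 0.3 * sqrt(3), tolerance = 0.02)
  expect_equal(mean(tab$value), 14.5, tolerance = 0.02)
})

test_that("calibrated anatomy cell means agree with the published table", {
  tab <- generate_trait_table(default_experiment_config(), 1)
  an <- anatomy_reference()
  z <- mapply(function(tr, trt, pe, m, se) {
    v <- tab$value[tab$trait == tr & tab$treatment == trt & tab$period == pe]
    if (se == 0) { expect_equal(mean(v), m); 0 } else abs(mean(v) - m) / se
  }, an$trait, an$treatment, an$period, an$mean, an$se)
  # sample means of 3 replicates have sd = SE; across 128 cells all lie
  # within 4 SE and the mean |z| matches a standard half-normal scale
  expect_lt(max(z), 4)
  expect_lt(mean(z), 1.1)
})

test_that("monotone drought-effect configs give matching sample orderings", {
  # Chl decreases CK -> T3 at S3; with many replicates the sample means
  # preserve that ordering
  cfg <- default_experiment_config(replicates = 200L)
  tab <- generate_trait_table(cfg, 5)
  m <- sapply(c("CK", "T1", "T2", "T3"), function(trt)
    mean(tab$value[tab$trait == "Chl" & tab$treatment == trt &
                     tab$period == "S3"]))
  expect_true(all(diff(m) < 0))
})

test_that("color readings: zero noise is the identity, shape is correct", {
  r <- generate_color_readings(c(50, 10, 20), n_leaves = 3, reads_per_leaf = 4,
                               noise_sd = 0, seed = 1)
  expect_equal(nrow(r), 12)
  expect_true(all(r$L == 50 & r$a == 10 & r$b == 20))
  expect_error(generate_color_readings(c(50, 10, 20), noise_sd = -1),
               "non-negative")
})

test_that("calibrated color readings aggregate close to the target a*", {
  for (target in c(29.6, 3.7)) {
    r <- generate_color_readings(c(40, target, 20), n_leaves = 10,
                                 reads_per_leaf = 10, noise_sd = 1.5, seed = 1)
    expect_lt(abs(aggregate_color(r)$mean[2] - target), 1.0)
  }
})

test_that("absorbance round trip is exact at zero noise", {
  targets <- c(chl = 1.2, car = 0.4, ant = 0.1)
  ab <- generate_absorbance_sets(targets["chl"], targets["car"], targets["ant"])
  prof <- pigment_profile(ab)
  expect_equal(prof$Chl, unname(targets["chl"]), tolerance = 1e-9)
  expect_equal(prof$Car, unname(targets["car"]), tolerance = 1e-9)
  expect_equal(prof$Ant, unname(targets["ant"]), tolerance = 1e-9)
  # zero targets -> zero absorbances
  z <- generate_absorbance_sets(0, 0, 0)
  expect_equal(unlist(z[c("A445", "A645", "A663", "A530", "A657")]),
               c(A445 = 0, A645 = 0, A663 = 0, A530 = 0, A657 = 0))
})

test_that("absorbance round trip with 1% noise recovers contents within 3%", {
  rel_err <- sapply(1:50, function(s) {
    ab <- generate_absorbance_sets(1.2, 0.4, 0.1, noise_sd = 0.01, seed = s)
    prof <- pigment_profile(ab)
    max(abs(c(prof$Chl / 1.2, prof$Car / 0.4, prof$Ant / 0.1) - 1))
  })
  expect_lt(median(rel_err), 0.03)
})

test_that("vessel generator: counted subset and area consistency", {
  an <- generate_vessel_anatomy(n_vessels = 30, counted_fraction = 1, seed = 2)
  expect_equal(an$n_counted, 30L)
  expect_equal(an$n_total, 30L)
  # areas are pi r^2 for the drawn radii: radii back out positive
  expect_true(all(equivalent_radius(an$vessel_areas) > 0))
  expect_warning(generate_vessel_anatomy(n_vessels = 30, counted_fraction = 0.5,
                                         seed = 1),
                 "sampling rule")
  expect_error(generate_vessel_anatomy(n_vessels = 0), ">= 1")
})

test_that("mass-loss generator: flat tail at ge = 0 and exact tail slope", {
  s0 <- generate_mass_loss_series(0, noise_sd = 0)
  tail_w <- s0$fresh_weights[s0$times > 3600]
  expect_equal(diff(tail_w), rep(0, length(tail_w) - 1))
  # ge = 231, A = 0.01, de = 20 -> tail slope 2e-5 g/s
  s1 <- generate_mass_loss_series(231, leaf_area = 0.01, delta_e = 20,
                                  noise_sd = 0)
  i <- which(s1$times >= 3600)
  slope <- diff(s1$fresh_weights[i]) / diff(s1$times[i])
  expect_equal(slope, rep(-2e-5, length(slope)), tolerance = 1e-10)
  expect_error(generate_mass_loss_series(231, interval = -5), "positive")
})

test_that("pv generator follows the closed-form model", {
  p <- pv_gen_params(psi_sat = -1.2, apoplastic_fraction = 0.15,
                     rwc_tlp = 0.90)
  # full turgor: osmotic and turgor components cancel
  expect_equal(pv_water_potential(1, p), 0)
  # closed form at the turgor loss point
  expect_equal(pv_water_potential(0.90, p), -1.2 * 0.85 / 0.75)
  cv <- generate_pv_curve(p, seed = 4)
  rwc <- relative_water_content(cv$fresh_weight, cv$saturated_weight,
                                cv$dry_weight)
  expect_true(all(rwc > p$apoplastic_fraction))  # truncation rule
  expect_true(all(diff(cv$fresh_weight) <= 0))
  expect_error(pv_gen_params(psi_sat = 0.5), "negative")
  expect_error(pv_gen_params(apoplastic_fraction = 0.95), "rwc_tlp")
})

test_that("substreams make stages independently regenerable", {
  expect_identical(substream_seed(1, "pv"), substream_seed(1, "pv"))
  expect_false(substream_seed(1, "pv") == substream_seed(1, "color"))
  expect_lt(substream_seed(.Machine$integer.max, "x"), 2^31)
})
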