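# Seeded generators emulating every raw input of the drought experiment.
# Noise models: replicate values are Gaussian around the configured cell
# mean with sd = SE * sqrt(n), so that sample SEs over n replicates
# reproduce the configured SEs in expectation. All generators accept a
# seed and are bit-reproducible for a fixed seed.

#' Generate a replicate-level trait table for the factorial experiment
#'
#' Draws one value per (trait, treatment, period, replicate) from a
#' Gaussian centred on the configured cell mean with sd = SE * sqrt(n),
#' where n is the replicate count over which the configured SEs were
#' computed (`config$se_n`, 3 for the published tables) - so the noise
#' model stays fixed even when more replicates are generated. Each trait
#' uses its own named substream of the master seed, so adding or removing
#' traits does not perturb the draws of the others.
#'
#' @param config An `experiment_config`, e.g. [default_experiment_config()].
#' @param seed Integer master seed.
#' @return A long data frame (`treatment`, `period`, `replicate`, `trait`,
#'   `value`, `units`), one row per replicate observation.
#' @examples
#' tab <- generate_trait_table(default_experiment_config(), seed = 1)
#' nrow(tab)  # 4 treatments x 4 periods x 3 replicates x 26 traits
#' @export
generate_trait_table <- function(config, seed) {
  validate_experiment_config(config)
  cm <- config$cell_means
  nrep <- config$replicates
  se_n <- if (is.null(config$se_n)) nrep else config$se_n
  out <- vector("list", length(unique(cm$trait)))
  traits <- unique(cm$trait)
  for (i in seq_along(traits)) {
    tr <- traits[i]
    cells <- cm[cm$trait == tr, , drop = FALSE]
    vals <- with_seed(substream_seed(seed, paste0("trait:", tr)), {
      noise <- stats::rnorm(nrow(cells) * nrep,
                            sd = rep(cells$se * sqrt(se_n), each = nrep))
      rep(cells$mean, each = nrep) + noise
    })
    out[[i]] <- data.frame(
      treatment = rep(cells$treatment, each = nrep),
      period = rep(cells$period, each = nrep),
      replicate = rep.int(seq_len(nrep), nrow(cells)),
      trait = tr,
      value = vals,
      units = rep(cells$units, each = nrep),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

#' Generate per-leaf CIELAB color readings
#'
#' Emulates the colorimeter protocol: several leaves per replicate, each
#' read several times. Readings are the target CIELAB triplet plus an
#' optional per-leaf offset and per-reading Gaussian noise.
#'
#' @param mean_lab Numeric length-3 target (L*, a*, b*).
#' @param n_leaves Leaves per sample (protocol default 10).
#' @param reads_per_leaf Readings per leaf (protocol default 10).
#' @param noise_sd Per-reading Gaussian sd (same for all three channels).
#' @param seed Integer seed.
#' @param leaf_sd Optional per-leaf random-offset sd (default 0).
#' @return Data frame `leaf_id`, `reading_index`, `L`, `a`, `b`.
#' @export
generate_color_readings <- function(mean_lab, n_leaves = 10L, reads_per_leaf = 10L,
                                    noise_sd = 1.5, seed = 1L, leaf_sd = 0) {
  stopifnot(length(mean_lab) == 3L, n_leaves >= 1L, reads_per_leaf >= 1L)
  if (noise_sd < 0 || leaf_sd < 0) stop("noise sd must be non-negative")
  with_seed(seed, {
    nr <- n_leaves * reads_per_leaf
    leaf_off <- matrix(stats::rnorm(3L * n_leaves, sd = leaf_sd), ncol = 3L)
    read_noise <- matrix(stats::rnorm(3L * nr, sd = noise_sd), ncol = 3L)
    idx <- rep(seq_len(n_leaves), each = reads_per_leaf)
    vals <- matrix(rep(as.numeric(mean_lab), each = nr), ncol = 3L) +
      leaf_off[idx, , drop = FALSE] + read_noise
    data.frame(leaf_id = idx,
               reading_index = rep.int(seq_len(reads_per_leaf), n_leaves),
               L = vals[, 1L], a = vals[, 2L], b = vals[, 3L])
  })
}

#' Generate absorbance sets that invert to target pigment contents
#'
#' Solves the configured pigment equations backwards: given target
#' chlorophyll, carotenoid and anthocyanin contents (per g fresh weight),
#' produces the absorbances at 445/645/663 nm (chlorophyll/carotenoid
#' extract) and 530/657 nm (anthocyanin extract) that the forward
#' computation maps back onto the targets. The chlorophyll equation alone
#' does not pin down both red-band absorbances, so a fixed spectral shape
#' `a663_a645_ratio` is imposed; likewise `a657_frac` fixes A657/A530.
#' Optional multiplicative noise emulates photometric error.
#'
#' @param chl,car,ant Target contents (mg g-1 FW; ant in the configured
#'   relative units).
#' @param coeffs A [default_pigment_coefficients()]-style list.
#' @param mass,volume,dilution Chlorophyll/carotenoid extraction: fresh
#'   mass (g), extract volume (L), dilution factor.
#' @param ant_mass,ant_volume,ant_dilution Anthocyanin extraction.
#' @param noise_sd Multiplicative noise sd on each absorbance (0 = exact).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param a663_a645_ratio,a657_frac Spectral shape assumptions.
#' @return An [absorbance_set()].
#' @export
generate_absorbance_sets <- function(chl = 0, car = 0, ant = 0,
                                     coeffs = default_pigment_coefficients(),
                                     mass = 0.2, volume = 0.005, dilution = 1,
                                     ant_mass = 1, ant_volume = 0.01,
                                     ant_dilution = 5,
                                     noise_sd = 0, seed = 1L,
                                     a663_a645_ratio = 2.5, a657_frac = 0.1) {
  if (mass <= 0 || volume <= 0 || ant_mass <= 0 || ant_volume <= 0)
    stop("extraction mass and volume must be positive")
  chl <- as.numeric(chl); car <- as.numeric(car); ant <- as.numeric(ant)
  if (chl < 0 || car < 0 || ant < 0) stop("pigment targets must be >= 0")
  ct <- coeffs$chl_total
  denom <- ct[["A645"]] + ct[["A663"]] * a663_a645_ratio
  if (abs(denom) < 1e-12) stop("chlorophyll coefficient set is not invertible")
  conc_chl <- chl * mass / (volume * dilution)      # mg L-1 in the cuvette
  A645 <- conc_chl / denom
  A663 <- a663_a645_ratio * A645
  ca <- coeffs$chl_a; cb <- coeffs$chl_b
  chla <- ca[["A663"]] * A663 + ca[["A645"]] * A645
  chlb <- cb[["A645"]] * A645 + cb[["A663"]] * A663
  cr <- coeffs$car
  if (abs(cr$scale) < 1e-12) stop("carotenoid coefficient set is not invertible")
  conc_car <- car * mass / (volume * dilution)
  A445 <- (cr$denom * conc_car + cr$k_chla * chla + cr$k_chlb * chlb) / cr$scale
  ant_shape <- 1 - coeffs$ant_subtraction * a657_frac
  if (abs(ant_shape) < 1e-12) stop("anthocyanin shape assumption is not invertible")
  dA <- ant * ant_mass / (coeffs$ant_scale * ant_volume * ant_dilution)
  A530 <- dA / ant_shape
  A657 <- a657_frac * A530
  a <- c(A445 = A445, A645 = A645, A663 = A663, A530 = A530, A657 = A657)
  if (noise_sd > 0)
    a <- with_seed(seed, a * (1 + stats::rnorm(5L, sd = noise_sd)))
  absorbance_set(A445 = a[["A445"]], A645 = a[["A645"]], A663 = a[["A663"]],
                 A530 = a[["A530"]], A657 = a[["A657"]],
                 mass = mass, volume = volume, dilution = dilution,
                 ant_mass = ant_mass, ant_volume = ant_volume,
                 ant_dilution = ant_dilution)
}

#' Generate petiole vessel anatomy records
#'
#' Draws vessel radii from a Gaussian (truncated at a small positive
#' radius), converts to cross-section areas, and samples the counted
#' subset without replacement. The measurement protocol requires sizing
#' at least two-thirds of all vessels; smaller `counted_fraction`s are
#' allowed but warned about.
#'
#' @param n_vessels Total vessel count N (> 0).
#' @param radius_mean,radius_sd Radius distribution, micrometres.
#' @param counted_fraction Fraction of vessels sized (default 0.75).
#' @param leaf_area Supported leaf area, m^2.
#' @param petiole_length Petiole (conduit) length, m.
#' @param water_temperature Water temperature, deg C (sets viscosity).
#' @param seed Integer seed.
#' @return A [vessel_anatomy()] record.
#' @export
generate_vessel_anatomy <- function(n_vessels = 40L, radius_mean = 5.5,
                                    radius_sd = 0.8, counted_fraction = 0.75,
                                    leaf_area = 0.003, petiole_length = 0.02,
                                    water_temperature = 25, seed = 1L) {
  if (n_vessels < 1L) stop("n_vessels must be >= 1")
  if (radius_mean <= 0) stop("radii must be positive")
  if (counted_fraction <= 0 || counted_fraction > 1)
    stop("counted_fraction must be in (0, 1]")
  if (counted_fraction < 2 / 3)
    warning("counted_fraction below the 2/3 sampling rule of the protocol")
  with_seed(seed, {
    r <- stats::rnorm(n_vessels, radius_mean, radius_sd)
    r <- pmax(abs(r), 0.2 * radius_mean)   # keep radii physically positive
    areas <- pi * r^2
    n_counted <- max(1L, round(counted_fraction * n_vessels))
    counted <- sort(sample.int(n_vessels, n_counted))
    vessel_anatomy(vessel_areas = areas[counted], n_total = n_vessels,
                   leaf_area = leaf_area, petiole_length = petiole_length,
                   water_temperature = water_temperature)
  })
}

#' Generate a two-phase fresh-weight drydown series
#'
#' Emulates the dark drydown protocol behind the epidermal-conductance
#' estimate: an initial steeper phase while stomata close, followed by
#' the linear epidermal phase whose slope is exactly the value implied by
#' inverting the conductance equation for `ge_true`
#' (slope = ge * A * delta_e / 2.31e6, in g s-1).
#'
#' @param ge_true True epidermal conductance (the equation's units).
#' @param leaf_area Leaf area, m^2.
#' @param delta_e Leaf-air absolute humidity difference (equation units).
#' @param stomatal_multiplier Initial-phase slope as a multiple of the
#'   epidermal-phase slope (> 1).
#' @param stomatal_duration Duration of the initial phase, s.
#' @param total_duration Total weighing duration, s (protocol ~8 h).
#' @param interval Weighing interval, s (protocol 50 min = 3000 s).
#' @param noise_sd Balance noise sd, g.
#' @param saturated_weight,dry_weight Leaf weights, g.
#' @param seed Integer seed.
#' @return A [mass_loss_series()].
#' @export
generate_mass_loss_series <- function(ge_true, leaf_area = 0.01, delta_e = 20,
                                      stomatal_multiplier = 5,
                                      stomatal_duration = 3600,
                                      total_duration = 28800, interval = 3000,
                                      noise_sd = 0.002,
                                      saturated_weight = 2.0, dry_weight = 1.0,
                                      seed = 1L) {
  if (total_duration <= 0 || interval <= 0 || stomatal_duration <= 0)
    stop("durations and interval must be positive")
  if (stomatal_multiplier <= 1)
    stop("stomatal-phase slope must be steeper than the epidermal phase")
  if (ge_true < 0) stop("ge_true must be >= 0")
  times <- seq(0, total_duration, by = interval)
  tail_slope <- ge_true * leaf_area * delta_e / 2.31e6        # g s-1 lost
  stom_slope <- stomatal_multiplier * tail_slope
  loss <- ifelse(times <= stomatal_duration, stom_slope * times,
                 stom_slope * stomatal_duration +
                   tail_slope * (times - stomatal_duration))
  w <- saturated_weight - loss
  if (noise_sd > 0)
    w <- with_seed(seed, w + stats::rnorm(length(w), sd = noise_sd))
  if (any(w <= dry_weight))
    stop("drydown exhausted the leaf water pool; shorten total_duration")
  mass_loss_series(times = times, fresh_weights = pmin(w, saturated_weight),
                   leaf_area = leaf_area, delta_e = delta_e,
                   saturated_weight = saturated_weight, dry_weight = dry_weight)
}

#' Parameters for the synthetic pressure-volume curve generator
#'
#' @param psi_sat Osmotic potential at full saturation, MPa (< 0).
#' @param apoplastic_fraction Apoplastic water fraction (0 <= af < rwc_tlp).
#' @param rwc_tlp Relative water content at the turgor loss point.
#' @param n_points Number of observations along the drydown.
#' @param noise_sd Balance-pressure noise sd, MPa.
#' @return A validated `pv_gen_params` list.
#' @export
pv_gen_params <- function(psi_sat = -1.2, apoplastic_fraction = 0.15,
                          rwc_tlp = 0.90, n_points = 30L, noise_sd = 0.02) {
  if (psi_sat >= 0) stop("psi_sat must be negative")
  if (!(apoplastic_fraction >= 0 && apoplastic_fraction < rwc_tlp &&
        rwc_tlp < 1))
    stop("need 0 <= apoplastic_fraction < rwc_tlp < 1")
  if (n_points < 6L) stop("n_points must be >= 6")
  structure(list(psi_sat = psi_sat, apoplastic_fraction = apoplastic_fraction,
                 rwc_tlp = rwc_tlp, n_points = as.integer(n_points),
                 noise_sd = noise_sd),
            class = "pv_gen_params")
}

#' Closed-form water potential of the synthetic pressure-volume model
#'
#' Total water potential as the sum of an osmotic component
#' psi_sat * (1 - af) / (R - af) and a turgor component declining
#' linearly from -psi_sat at full hydration (R = 1) to zero at the turgor
#' loss point, zero below it.
#'
#' @param rwc Relative water content (fraction), may be a vector.
#' @param params A [pv_gen_params()] list.
#' @return Water potential in MPa (negative).
#' @export
pv_water_potential <- function(rwc, params) {
  af <- params$apoplastic_fraction
  if (any(rwc <= af)) stop("rwc must exceed the apoplastic fraction")
  osmotic <- params$psi_sat * (1 - af) / (rwc - af)
  turgor <- ifelse(rwc >= params$rwc_tlp,
                   -params$psi_sat * (rwc - params$rwc_tlp) /
                     (1 - params$rwc_tlp),
                   0)
  osmotic + turgor
}

#' Generate a synthetic pressure-volume observation sequence
#'
#' Relative water content declines on an even grid from full hydration
#' towards (but never reaching) the apoplastic fraction; balance pressure
#' is the negated model water potential plus Gaussian noise, floored at a
#' tiny positive value to respect the pressure-chamber convention.
#'
#' @param params A [pv_gen_params()] list.
#' @param saturated_mass,dry_mass Leaf masses, g.
#' @param seed Integer seed.
#' @param rwc_min Driest relative water content sampled (default 0.55,
#'   clamped above the apoplastic fraction).
#' @return A [pv_curve()].
#' @export
generate_pv_curve <- function(params, saturated_mass = 2.0, dry_mass = 1.0,
                              seed = 1L, rwc_min = 0.55) {
  if (saturated_mass <= dry_mass) stop("saturated_mass must exceed dry_mass")
  lo <- max(rwc_min, params$apoplastic_fraction + 0.05)
  rwc <- seq(1, lo, length.out = params$n_points)
  psi <- pv_water_potential(rwc, params)
  p <- -psi
  if (params$noise_sd > 0)
    p <- with_seed(seed, p + stats::rnorm(length(p), sd = params$noise_sd))
  p <- pmax(p, 1e-4)
  w <- dry_mass + rwc * (saturated_mass - dry_mass)
  pv_curve(balance_pressure = p, fresh_weight = w,
           saturated_weight = saturated_mass, dry_weight = dry_mass)
}
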