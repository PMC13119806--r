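# Default calibration of the synthetic experiment.
#
# Anatomical traits use the published replicate means and standard errors
# (n = 3) of the drought experiment directly. All other traits (color,
# pigments, enzymes, gas exchange, hydraulics) were only published as
# figures; their cell means here are a plausible reconstruction that
# honours every printed anchor value and percent change (e.g. a* of 29.6
# under T3 and 3.7 under CK at period S3, SOD +75.7% over CK at S2, Kmax
# spanning 9.7-22.5 mmol m-2 s-1 MPa-1) together with the qualitative
# temporal patterns described in the text. They are calibrations, not
# printed numbers.

#' Published anatomical trait summary (mean, SE, n = 3)
#'
#' Replicate-level summary of the eight leaf anatomical indices measured
#' in the drought experiment: upper/lower epidermis thickness (Uep, Lep),
#' palisade and spongy tissue thickness (Pt, St), xylem thickness (Xt),
#' main vein thickness (Mvt), leaf thickness (LT), all in micrometres, and
#' the dimensionless palisade-to-spongy ratio (PSR).
#'
#' @return Long data frame with columns `treatment`, `period`, `trait`,
#'   `mean`, `se`, `n`.
#' @export
anatomy_reference <- function() {
  tr <- rep(c("CK", "T1", "T2", "T3"), each = 4L)
  pe <- rep(c("S1", "S2", "S3", "S4"), times = 4L)
  # columns: Uep, Lep, Pt, St, Xt, Mvt, LT, PSR -- means then SEs, row
  # order CK S1..S4, T1 S1..S4, T2 S1..S4, T3 S1..S4
  m <- matrix(c(
    14.5, 10.6, 82.1, 62.7, 77.1, 925.3, 170.5, 1.31,
    14.2, 10.1, 72.1, 57.1, 67.1, 862.5, 155.3, 1.26,
    13.5, 10.2, 66.8, 54.8, 52.4, 723.6, 147.5, 1.22,
    13.1,  8.9, 61.5, 49.2, 50.5, 716.3, 131.3, 1.25,
    14.2, 10.2, 82.3, 63.3, 77.2, 916.3, 168.1, 1.30,
    13.8,  9.6, 70.5, 55.2, 65.2, 855.2, 154.1, 1.28,
    12.8,  9.0, 64.2, 53.2, 50.2, 714.6, 143.8, 1.21,
    12.2,  8.8, 58.2, 48.6, 48.9, 714.2, 128.5, 1.20,
    14.1, 10.6, 82.5, 62.6, 76.4, 922.2, 171.6, 1.32,
    13.1,  8.8, 63.2, 48.6, 58.3, 836.8, 150.6, 1.30,
    11.3,  8.1, 56.6, 46.6, 46.7, 702.9, 140.3, 1.21,
    10.6,  7.3, 50.3, 43.2, 44.4, 703.6, 126.2, 1.16,
    14.2, 10.4, 82.2, 62.8, 76.1, 918.3, 170.9, 1.31,
    12.6,  8.3, 60.1, 46.2, 56.2, 821.4, 145.5, 1.30,
    10.2,  7.4, 51.2, 44.1, 43.2, 691.5, 134.3, 1.16,
     9.3,  7.1, 46.3, 38.6, 40.6, 687.6, 120.2, 1.20
  ), ncol = 8L, byrow = TRUE)
  s <- matrix(c(
    0.3, 0.7, 3.7, 3.6, 2.5, 1.6, 5.1,  0.02,
    0.1, 0.6, 1.1, 0.8, 1.3, 0.7, 2.0,  0.00,
    0.1, 0.8, 1.8, 2.4, 1.4, 7.6, 2.6,  0.02,
    0.2, 0.5, 0.9, 0.2, 0.3, 8.4, 2.1,  0.01,
    0.1, 0.8, 1.3, 2.3, 2.3, 5.6, 2.8,  0.03,
    0.3, 0.6, 2.4, 1.4, 1.8, 4.5, 5.7,  0.01,
    0.4, 0.5, 3.4, 1.2, 0.8, 3.3, 4.4,  0.04,
    0.2, 0.4, 2.6, 0.9, 0.5, 3.6, 4.6,  0.03,
    0.4, 0.6, 2.7, 2.8, 2.2, 5.1, 3.1,  0.02,
    0.3, 0.5, 3.3, 0.9, 1.1, 4.3, 2.7,  0.04,
    0.2, 0.7, 3.1, 0.8, 0.6, 2.8, 7.3,  0.05,
    0.2, 0.6, 2.3, 0.6, 0.4, 2.4, 9.7,  0.04,
    0.4, 0.4, 2.6, 2.2, 2.7, 5.1, 3.3,  0.01,
    0.3, 0.5, 3.4, 0.8, 1.3, 4.2, 1.8,  0.05,
    0.3, 0.6, 3.2, 0.7, 0.3, 2.9, 2.16, 0.06,
    0.1, 0.3, 1.6, 0.6, 0.3, 1.8, 6.87, 0.03
  ), ncol = 8L, byrow = TRUE)
  traits <- c("Uep", "Lep", "Pt", "St", "Xt", "Mvt", "LT", "PSR")
  data.frame(
    treatment = rep(tr, times = 8L),
    period = rep(pe, times = 8L),
    trait = rep(traits, each = 16L),
    mean = as.vector(m),
    se = as.vector(s),
    n = 3L,
    stringsAsFactors = FALSE
  )
}

# cell-mean helper: 16 values in row order CK S1..S4, T1 ..., T2 ..., T3 ...
.cells <- function(trait, unit, means, se) {
  data.frame(
    treatment = rep(c("CK", "T1", "T2", "T3"), each = 4L),
    period = rep(c("S1", "S2", "S3", "S4"), times = 4L),
    trait = trait, mean = means,
    se = if (length(se) == 1L) rep(se, 16L) else se,
    units = unit, stringsAsFactors = FALSE
  )
}

# Reconstructed figure-trait cell means (see file header note).
.figure_trait_cells <- function() {
  Lstar <- c(41.0, 38.5, 35.0, 44.0,
             40.8, 38.2, 37.5, 50.5,
             41.2, 38.8, 41.5, 54.0,
             40.9, 38.0, 36.5, 47.0)
  astar <- c(-12.0, -10.5,  3.7, 43.4,
             -11.8, -10.0, 13.0, 19.0,
             -12.2,  -9.0, 21.0, 16.0,
             -11.9,  -3.5, 29.6, 25.0)
  bstar <- c(22.0, 19.5, 17.5, 30.0,
             21.8, 19.8, 24.0, 42.0,
             22.2, 20.0, 25.5, 45.0,
             21.9, 19.2, 16.5, 33.0)
  Chl <- c(1.80, 1.55, 1.20, 0.85,
           1.78, 1.40, 1.00, 0.65,
           1.82, 1.25, 0.80, 0.50,
           1.79, 1.10, 0.60, 0.38)
  Ant <- c(0.050, 0.060, 0.100, 0.550,
           0.048, 0.080, 0.200, 0.150,
           0.052, 0.120, 0.300, 0.120,
           0.051, 0.150, 0.400, 0.250)
  Car <- c(0.360, 0.350, 0.340, 0.400,
           0.355, 0.345, 0.340, 0.600,
           0.365, 0.340, 0.335, 0.650,
           0.358, 0.330, 0.320, 0.500)
  POD <- c(400, 500, 420.0, 350.0,
           405, 550, 480.0, 400.0,
           398, 620, 662.3, 459.6,
           402, 690, 520.0, 390.0)
  SOD <- c(300, 320.0, 380.0, 330.0,
           302, 390.0, 429.0, 350.8,
           298, 500.0, 420.0, 340.0,
           301, 562.2, 400.0, 320.0)
  Pn <- c(10.00, 9.00, 7.50, 6.00,
           9.90, 8.40, 7.00, 5.60,
          10.10, 7.80, 6.50, 5.20,
           9.95, 7.07, 5.99, 4.80)
  Tr <- c(3.50, 3.300, 2.700, 2.400,
          3.48, 3.000, 2.500, 2.200,
          3.52, 2.600, 2.300, 2.050,
          3.49, 2.082, 2.030, 1.903)
  Kmax <- c(22.3, 21.0, 19.0, 17.80,
            22.1, 20.0, 18.0, 16.89,
            22.4, 18.5, 16.0, 13.47,
            22.2, 16.5, 13.0,  9.75)
  ge <- c(250, 230, 205, 185,
          248, 220, 195, 172,
          252, 210, 182, 158,
          249, 195, 165, 140)
  RWCtlp <- c(0.920, 0.905, 0.880, 0.850,
              0.918, 0.880, 0.845, 0.678,
              0.922, 0.860, 0.810, 0.676,
              0.919, 0.830, 0.760, 0.513)
  PsiTlp <- c(-1.60, -1.75, -1.90, -2.1000,
              -1.61, -1.80, -1.98, -2.2995,
              -1.59, -1.85, -2.05, -2.2008,
              -1.60, -1.95, -2.20, -2.4003)
  PsiSat <- c(-1.20, -1.30, -1.45, -1.6500,
              -1.21, -1.36, -1.52, -1.7408,
              -1.19, -1.42, -1.60, -1.8150,
              -1.20, -1.50, -1.72, -1.9223)
  rbind(
    .cells("Lstar", "CIELAB", Lstar, 1.2),
    .cells("astar", "CIELAB", astar, 1.0),
    .cells("bstar", "CIELAB", bstar, 1.2),
    .cells("Chl", "mg g-1 FW", Chl, 0.05),
    .cells("Ant", "dA g-1 FW", Ant, 0.015),
    .cells("Car", "mg g-1 FW", Car, 0.02),
    .cells("AntChl", "ratio", Ant / Chl, 0.05 * Ant / Chl),
    .cells("CarChl", "ratio", Car / Chl, 0.05 * Car / Chl),
    .cells("AntCar", "ratio", Ant / Car, 0.05 * Ant / Car),
    .cells("POD", "U g-1 min-1", POD, 15),
    .cells("SOD", "U g-1", SOD, 10),
    .cells("Pn", "umol m-2 s-1", Pn, 0.3),
    .cells("Tr", "mmol m-2 s-1", Tr, 0.12),
    .cells("Kmax", "mmol m-2 s-1 MPa-1", Kmax, 0.5),
    .cells("ge", "mmol m-2 s-1", ge, 8),
    .cells("RWCtlp", "fraction", RWCtlp, 0.012),
    .cells("PsiTlp", "MPa", PsiTlp, 0.05),
    .cells("PsiSat", "MPa", PsiSat, 0.04)
  )
}

#' Default synthetic-experiment configuration
#'
#' Cell means and standard errors for all 26 traits of the 4 treatment x
#' 4 period x 3 replicate drought experiment. Anatomical traits carry the
#' published means/SEs (see [anatomy_reference()]); figure-only traits
#' carry documented plausible calibrations. Replicate noise is Gaussian
#' with sd = SE * sqrt(n), which reproduces the published SEs in
#' expectation.
#'
#' @param replicates Replicates per cell (default 3, as in the experiment).
#' @return An object of class `experiment_config`: list with elements
#'   `treatments` (named soil-water bands), `periods`, `replicates`,
#'   `cell_means` (data frame trait/treatment/period/mean/se/units).
#' @examples
#' cfg <- default_experiment_config()
#' head(cfg$cell_means)
#' @export
default_experiment_config <- function(replicates = 3L) {
  an <- anatomy_reference()
  units <- c(Uep = "um", Lep = "um", Pt = "um", St = "um", Xt = "um",
             Mvt = "um", LT = "um", PSR = "ratio")
  an_cells <- data.frame(
    treatment = an$treatment, period = an$period, trait = an$trait,
    mean = an$mean, se = an$se, units = unname(units[an$trait]),
    stringsAsFactors = FALSE
  )
  cfg <- list(
    treatments = c(CK = "100% FC", T1 = "75-80% FC",
                   T2 = "50-55% FC", T3 = "35-40% FC"),
    periods = c("S1", "S2", "S3", "S4"),
    replicates = as.integer(replicates),
    se_n = 3L,   # the configured SEs are over n = 3 replicates
    cell_means = rbind(an_cells, .figure_trait_cells()),
    schema = "leafdrought-config-1"
  )
  class(cfg) <- "experiment_config"
  validate_experiment_config(cfg)
  cfg
}

#' Validate an experiment configuration
#'
#' Checks the structural invariants: at least two replicates, non-negative
#' SEs, complete and unduplicated cell coverage for every trait.
#'
#' @param config An `experiment_config` list.
#' @return The config, invisibly; errors name the offending cell.
#' @export
validate_experiment_config <- function(config) {
  cm <- config$cell_means
  stopifnot(is.data.frame(cm),
            all(c("treatment", "period", "trait", "mean", "se") %in% names(cm)))
  if (config$replicates < 2L) stop("replicates must be >= 2")
  if (any(cm$se < 0)) stop("negative SE in cell_means")
  key <- paste(cm$trait, cm$treatment, cm$period)
  if (anyDuplicated(key)) stop("duplicate cell: ", key[duplicated(key)][1L])
  grid <- expand.grid(treatment = names(config$treatments),
                      period = config$periods, stringsAsFactors = FALSE)
  for (tr in unique(cm$trait)) {
    have <- paste(cm$treatment[cm$trait == tr], cm$period[cm$trait == tr])
    miss <- setdiff(paste(grid$treatment, grid$period), have)
    if (length(miss))
      stop("trait ", tr, " missing cell mean for: ", paste(miss, collapse = ", "))
  }
  invisible(config)
}

#' Predictor sets reported for the red-green color coordinate
#'
#' The retained significant predictors of the red-green coordinate a*
#' in the published random-forest analysis, and the full candidate list
#' (all 23 non-color traits of the default configuration).
#'
#' @return List with `astar_predictors` and `candidates`.
#' @export
reported_predictor_sets <- function() {
  candidates <- setdiff(unique(default_experiment_config()$cell_means$trait),
                        c("Lstar", "astar", "bstar"))
  list(
    astar_predictors = c("PsiSat", "RWCtlp", "SOD", "CarChl", "AntChl",
                         "Ant", "Tr", "Pn", "Mvt"),
    candidates = candidates
  )
}
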