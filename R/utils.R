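#' @keywords internal
"_PACKAGE"

# Largest prime below 2^31 used for seed arithmetic; keeps derived seeds
# valid 32-bit integers.
.SEED_MOD <- 2147483629

#' Derive a reproducible substream seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its random numbers from a
#' seed derived from one master seed and a stage name, so stages can be
#' regenerated independently without perturbing each other.
#'
#' @param master Integer master seed.
#' @param stream Character stage name (e.g. `"trait_table"`).
#' @return A single integer seed.
#' @examples
#' substream_seed(1, "trait_table")
#' @export
substream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% .SEED_MOD
  as.integer((abs(as.numeric(master)) + h) %% .SEED_MOD)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# md5 of an arbitrary R object, via its serialization written to a temp file.
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Treatment and period levels of the factorial drought design
#'
#' The experiment has four soil-water treatments (CK = 100% of field
#' capacity, T1 = 75-80%, T2 = 50-55%, T3 = 35-40%) and four sampling
#' periods S1-S4 spaced 20 days apart.
#'
#' @return Named list with character vectors `treatments` and `periods`.
#' @export
design_levels <- function() {
  list(treatments = c("CK", "T1", "T2", "T3"),
       periods = c("S1", "S2", "S3", "S4"))
}
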