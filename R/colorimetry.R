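# Colorimetry and anatomical derived traits.

#' Aggregate raw CIELAB readings to a replicate-level color parameter set
#'
#' Leaves are the sampling unit of the color protocol, so readings are
#' averaged per leaf first and the replicate value is the unweighted mean
#' over leaves; the standard error is computed over leaf means. This makes
#' the aggregate invariant to duplicating readings within a leaf.
#'
#' @param readings Data frame with columns `leaf_id`, `L`, `a`, `b` (a
#'   `reading_index` column is ignored).
#' @return Data frame with one row per channel (`L`, `a`, `b`): columns
#'   `channel`, `mean`, `se`, `n_leaves`.
#' @examples
#' r <- generate_color_readings(c(35, 29.6, 18), noise_sd = 0, seed = 1)
#' aggregate_color(r)
#' @export
aggregate_color <- function(readings) {
  if (is.null(readings) || nrow(readings) == 0L)
    stop("no color readings supplied")
  stopifnot(all(c("leaf_id", "L", "a", "b") %in% names(readings)))
  agg <- function(ch) {
    leaf_means <- tapply(readings[[ch]], readings$leaf_id, mean)
    n <- length(leaf_means)
    se <- if (n > 1L) stats::sd(leaf_means) / sqrt(n) else 0
    c(mean = mean(leaf_means), se = se, n = n)
  }
  res <- t(vapply(c("L", "a", "b"), agg, numeric(3L)))
  data.frame(channel = rownames(res), mean = res[, "mean"], se = res[, "se"],
             n_leaves = as.integer(res[, "n"]), row.names = NULL)
}

#' Palisade-to-spongy tissue thickness ratio
#'
#' @param pt Palisade tissue thickness (micrometres).
#' @param st Spongy tissue thickness (micrometres, > 0).
#' @param digits Optional rounding (the published table prints 2 decimals).
#' @return `pt / st`, vectorized.
#' @examples
#' compute_psr(82.1, 62.7, digits = 2)  # 1.31
#' @export
compute_psr <- function(pt, st, digits = NULL) {
  if (any(st <= 0)) stop("spongy tissue thickness must be positive")
  if (any(pt <= 0)) stop("palisade tissue thickness must be positive")
  r <- pt / st
  if (!is.null(digits)) r <- round(r, digits)
  r
}

#' Assemble trait records into one long trait table
#'
#' Binds any number of record data frames (each with columns `treatment`,
#' `period`, `replicate`, `trait`, `value` and optionally `units`) into
#' the long trait table all downstream stages consume, refusing duplicate
#' (key, trait) collisions.
#'
#' @param ... Record data frames (NULL entries are dropped).
#' @return The combined trait table.
#' @export
assemble_trait_records <- function(...) {
  parts <- Filter(Negate(is.null), list(...))
  parts <- Filter(function(p) nrow(p) > 0L, parts)
  if (length(parts) == 0L)
    return(data.frame(treatment = character(), period = character(),
                      replicate = integer(), trait = character(),
                      value = numeric(), units = character(),
                      stringsAsFactors = FALSE))
  parts <- lapply(parts, function(p) {
    stopifnot(all(c("treatment", "period", "replicate", "trait", "value")
                  %in% names(p)))
    if (is.null(p$units)) p$units <- NA_character_
    p[c("treatment", "period", "replicate", "trait", "value", "units")]
  })
  tab <- do.call(rbind, parts)
  key <- paste(tab$treatment, tab$period, tab$replicate, tab$trait)
  if (anyDuplicated(key))
    stop("duplicate trait record: ", key[duplicated(key)][1L])
  rownames(tab) <- NULL
  tab
}

#' Read / write a trait table as CSV
#'
#' The on-disk format is one observation per row with the fixed columns
#' `treatment`, `period`, `replicate`, `trait`, `value`, `units`.
#'
#' @param path CSV path.
#' @return `read_trait_table` returns the data frame; `write_trait_table`
#'   returns `path` invisibly.
#' @export
read_trait_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("treatment", "period", "replicate", "trait", "value")
  if (!all(need %in% names(tab)))
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' @rdname read_trait_table
#' @param table Trait table data frame.
#' @export
write_trait_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Pivot a long trait table to a wide observation-by-trait matrix
#'
#' @param table Long trait table.
#' @param traits Optional subset of traits to keep.
#' @return Data frame with key columns `treatment`, `period`, `replicate`
#'   and one numeric column per trait.
#' @export
trait_wide <- function(table, traits = NULL) {
  if (!is.null(traits)) table <- table[table$trait %in% traits, , drop = FALSE]
  wide <- stats::reshape(
    table[c("treatment", "period", "replicate", "trait", "value")],
    idvar = c("treatment", "period", "replicate"),
    timevar = "trait", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
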