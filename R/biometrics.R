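#' Gonadosomatic index
#'
#' GSI in percent: gonad weight relative to the fish's somatic weight,
#' `100 * gonad / (ungutted - gonad)` by default (the "ovary-free" ungutted
#' weight in the denominator). Set `ovary_free = FALSE` to divide by the
#' plain ungutted weight instead.
#'
#' @param gonad_weight,ungutted_weight grams; vectorized, recycled.
#' @param ovary_free subtract the gonad from the denominator (default TRUE).
#' @return GSI in percent.
#' @export
#' @examples
#' gsi(10, 110)  # 10%
gsi <- function(gonad_weight, ungutted_weight, ovary_free = TRUE) {
  if (any(gonad_weight <= 0) || any(ungutted_weight <= 0))
    stop("weights must be positive")
  if (any(gonad_weight >= ungutted_weight))
    stop("gonad_weight must be smaller than ungutted_weight")
  denom <- if (ovary_free) ungutted_weight - gonad_weight else ungutted_weight
  100 * gonad_weight / denom
}

#' Nuclear / cytoplasmic ratio of an oocyte
#'
#' Diameter of the nucleus over the diameter of the follicle, in (0, 1].
#' The ratio falls as the cytoplasm grows: an oogonium sits near 0.8, and
#' the 0.5 boundary separates early (`po1`, N/C >= 0.5) from late (`po2`,
#' N/C < 0.5) primary-growth oocytes.
#'
#' @param nucleus_diameter,follicle_diameter micrometres; vectorized.
#' @return numeric ratio in (0, 1].
#' @export
#' @examples
#' nc_ratio(11.4, 14.3)          # oogonium, ~0.8
#' classify_primary_oocyte(0.45) # "po2"
nc_ratio <- function(nucleus_diameter, follicle_diameter) {
  if (any(nucleus_diameter <= 0))
    stop("nucleus_diameter must be positive")
  if (any(nucleus_diameter > follicle_diameter))
    stop("nucleus_diameter cannot exceed follicle_diameter")
  nucleus_diameter / follicle_diameter
}

#' @rdname nc_ratio
#' @param ratio N/C ratio(s).
#' @return `classify_primary_oocyte`: `"po1"` (N/C >= 0.5) or `"po2"`.
#' @export
classify_primary_oocyte <- function(ratio) {
  stopifnot(all(ratio > 0), all(ratio <= 1))
  ifelse(ratio < 0.5, "po2", "po1")
}

fish_record_columns <- c("fish_id", "month", "length_cm",
                         "ungutted_weight_g", "gonad_weight_g")

#' Read / write fish biometrics tables
#'
#' CSV with columns `fish_id`, `month`, `length_cm`, `ungutted_weight_g`,
#' `gonad_weight_g`, optionally `visual_phase` (A-F) and extras, one row per
#' fish. Basic validation: positive lengths/weights, gonad lighter than the
#' ungutted fish.
#'
#' @param path file path.
#' @return data frame of fish records.
#' @export
read_fish_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(fish_record_columns, names(df))
  if (length(miss)) stop("biometrics file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$fish_id)) stop("duplicate fish_id in ", path)
  with(df, {
    if (any(length_cm <= 0, na.rm = TRUE)) stop("non-positive length")
    ok <- !is.na(gonad_weight_g) & !is.na(ungutted_weight_g)
    if (any(gonad_weight_g[ok] <= 0) || any(ungutted_weight_g[ok] <= 0))
      stop("non-positive weight")
    if (any(gonad_weight_g[ok] >= ungutted_weight_g[ok]))
      stop("gonad_weight_g must be below ungutted_weight_g")
  })
  df
}

#' @rdname read_fish_records
#' @param records data frame of fish records.
#' @export
write_fish_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
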