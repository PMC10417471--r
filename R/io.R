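#' Read / write ASCII PGM images
#'
#' Plain (P2) portable graymap: a text-only raster format used here for
#' label images (integer labels as "gray" values) and as a PNG fallback for
#' masks and rendered sections.
#'
#' @param mat integer/numeric matrix (rows = y, columns = x).
#' @param path file path.
#' @param maxval maximum stored value (defaults to `max(mat)`).
#' @export
write_pgm <- function(mat, path, maxval = NULL) {
  m <- round(mat)
  if (any(m < 0)) stop("PGM values must be non-negative")
  maxval <- maxval %||% max(1, max(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  apply_rows <- apply(m, 1, paste, collapse = " ")
  writeLines(apply_rows, con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("not an ASCII (P2) PGM file: ", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: expected ", w * h, " values")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write / read a label image with its JSON sidecar
#'
#' The label matrix goes to `<prefix>.pgm` (ASCII, integer labels) and the
#' legend, exact ground-truth fractions, generation spec and seed to
#' `<prefix>.json`.
#'
#' @param img a `label_image`.
#' @param prefix output path prefix (without extension).
#' @export
write_label_image <- function(img, prefix) {
  stopifnot(inherits(img, "label_image"))
  write_pgm(img$labels, paste0(prefix, ".pgm"))
  side <- list(legend = img$legend, truth = as.list(img$truth),
               truth_groups = as.list(img$truth_groups),
               px_per_um = img$px_per_um,
               spec = img$spec[setdiff(names(img$spec), "max_attempts")],
               seed = img$spec$seed)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(prefix) {
  lab <- read_pgm(paste0(prefix, ".pgm"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  out <- list(labels = lab, legend = side$legend,
              truth = unlist(side$truth),
              truth_groups = unlist(side$truth_groups),
              px_per_um = side$px_per_um, spec = side$spec)
  class(out) <- "label_image"
  out
}

#' Write a grayscale image (PNG if available, else PGM)
#'
#' @param gray numeric matrix of gray levels in \[0, 255\].
#' @param path output path; extension is adjusted to the format used.
#' @return the path written.
#' @export
write_grayscale <- function(gray, path) {
  if (requireNamespace("png", quietly = TRUE)) {
    if (!grepl("\\.png$", path)) path <- paste0(path, ".png")
    png::writePNG(pmin(1, pmax(0, gray / 255)), path)
  } else {
    path <- sub("\\.png$", ".pgm", path)
    if (!grepl("\\.pgm$", path)) path <- paste0(path, ".pgm")
    write_pgm(gray, path, maxval = 255)
  }
  path
}

annotation_columns <- c("slide_id", "point_id", "x", "y", "structure")

#' Read a point-annotation table
#'
#' CSV with columns `slide_id`, `point_id`, `x`, `y`, `structure` (the
#' reading results of a stereology session). A label-mapping table
#' translates reader dialects into the controlled vocabulary, e.g. the
#' `"cap"` spelling of the cortical-alveoli stage maps to `"cao"`.
#'
#' @param path CSV path.
#' @param mapping named character vector, `names` = labels as found in the
#'   file, values = canonical labels. Defaults to `c(cap = "cao")`.
#' @param unknown_policy what to do with labels that are neither canonical
#'   nor mapped: `"error"` (default), `"drop"` rows, or `"unknown"`
#'   (relabel).
#' @return named list of per-slide annotation data frames.
#' @export
read_annotations <- function(path, mapping = c(cap = "cao"),
                             unknown_policy = c("error", "drop", "unknown")) {
  unknown_policy <- match.arg(unknown_policy)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(annotation_columns, names(df))
  if (length(miss)) stop("annotation file missing column(s): ",
                         paste(miss, collapse = ", "))
  hit <- df$structure %in% names(mapping)
  df$structure[hit] <- unname(mapping[df$structure[hit]])
  known <- c(germ_structures(), nongerm_structures(), "zp")
  bad <- !(df$structure %in% known)
  if (any(bad)) {
    labels <- unique(df$structure[bad])
    if (unknown_policy == "error")
      stop("unmapped structure label(s): ", paste(labels, collapse = ", "))
    if (unknown_policy == "drop") df <- df[!bad, , drop = FALSE]
    if (unknown_policy == "unknown") df$structure[bad] <- "unknown"
  }
  out <- split(df, df$slide_id)
  for (sl in names(out)) {
    if (anyDuplicated(out[[sl]]$point_id))
      stop("duplicate point_id in slide ", sl)
  }
  out
}

#' @rdname read_annotations
#' @param annotations data frame (or list of data frames) with the
#'   annotation columns.
#' @export
write_annotations <- function(annotations, path) {
  if (is.data.frame(annotations)) annotations <- list(annotations)
  df <- do.call(rbind, annotations)
  miss <- setdiff(annotation_columns, names(df))
  if (length(miss)) stop("annotations missing column(s): ",
                         paste(miss, collapse = ", "))
  utils::write.csv(df[annotation_columns], path, row.names = FALSE)
  invisible(path)
}

#' Load a run configuration
#'
#' YAML (if the `yaml` package is installed) or JSON file with the fields
#' of [run_pipeline()]'s `config` argument.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the maturity-assessment pipeline end to end
#'
#' Two modes. `synthetic`: generate a population from a [population_spec()],
#' simulate one stereology reading per fish, estimate compositions, stage
#' every fish, summarise by month, and fit the maturity ogive (both
#' maturity rules) with a bootstrap CI. `annotations`: read point
#' annotations and biometrics from CSV and run the same downstream stages.
#'
#' All randomness flows from `config$seed`; rerunning with the same config
#' produces byte-identical outputs including the manifest.
#'
#' @param config named list (or path to a YAML/JSON file) with entries:
#'   `mode` ("synthetic" or "annotations"); `seed`; `out_dir` (optional —
#'   outputs are written only if set); `population` (synthetic mode:
#'   arguments for [population_spec()], seed injected); `annotations_csv`,
#'   `biometrics_csv`, `label_mapping`, `unknown_policy` (annotations
#'   mode); `maturity_rule` ("vit_presence"/"cao_presence", default vit);
#'   `bootstrap_reps` (default 1000); `class_midpoints` (default FALSE);
#'   `n_range` (grid point range, default c(500, 600)).
#' @return list with `records` (staged table), `summary_month`,
#'   `ogive` (fits and bootstraps under both rules), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  mode <- match.arg(config$mode %||% "synthetic",
                    c("synthetic", "annotations"))
  if (is.null(config$seed)) stop("config$seed is required")
  seed <- as.integer(config$seed)
  rule <- config$maturity_rule %||% "vit_presence"
  reps <- config$bootstrap_reps %||% 1000
  seeds <- derive_seeds(seed, 4)

  if (mode == "synthetic") {
    pop_args <- config$population %||% list()
    pop_args$seed <- seeds[1]
    pop <- do.call(population_spec, pop_args)
    records <- generate_population(pop)
    count_seeds <- derive_seeds(seeds[2], nrow(records))
    comps <- lapply(seq_len(nrow(records)), function(i) {
      grp <- as.numeric(records[i, paste0("comp_", c("pca", "cao", "vit",
                                                     "pho", "ho", "POF"))])
      names(grp) <- c("pca", "cao", "vit", "pho", "ho", "POF")
      counts <- simulate_point_counts(grp[grp > 0],
                                      n_range = config$n_range %||% c(500, 600),
                                      seed = count_seeds[i])
      composition_from_counts(counts)
    })
  } else {
    if (is.null(config$annotations_csv) || is.null(config$biometrics_csv))
      stop("annotations mode needs annotations_csv and biometrics_csv")
    for (p in c(config$annotations_csv, config$biometrics_csv))
      if (!file.exists(p)) stop("missing input file: ", p)
    mapping <- unlist(config$label_mapping %||% c(cap = "cao"))
    slides <- read_annotations(config$annotations_csv, mapping = mapping,
                               unknown_policy = config$unknown_policy %||%
                                 "error")
    records <- read_fish_records(config$biometrics_csv)
    miss <- setdiff(records$fish_id, names(slides))
    if (length(miss)) stop("no annotations for fish: ",
                           paste(miss, collapse = ", "))
    comps <- lapply(records$fish_id,
                    function(id) estimate_composition(slides[[id]]))
  }

  staged <- stage_records(records, comps)
  staged$gsi <- gsi(staged$gonad_weight_g, staged$ungutted_weight_g)
  summary_month <- if ("month" %in% names(staged))
    summarize_records(staged, "month") else NULL
  mature_col <- if (rule == "vit_presence") staged$mature_vit
                else staged$mature_cao
  ogive <- list()
  for (r in c("vit_presence", "cao_presence")) {
    m <- if (r == "vit_presence") staged$mature_vit else staged$mature_cao
    fit <- fit_ogive(staged$length_cm, m,
                     class_midpoints = isTRUE(config$class_midpoints))
    boot <- bootstrap_L50(staged$length_cm, m, reps = reps, seed = seeds[3],
                          class_midpoints = isTRUE(config$class_midpoints))
    ogive[[r]] <- list(fit = fit, bootstrap = boot)
  }

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "ovistereo",
    version = as.character(utils::packageVersion("ovistereo")),
    mode = mode, seed = seed, derived_seeds = as.integer(seeds),
    maturity_rule = rule, bootstrap_reps = reps,
    config_hash = fnv1a_hash(as.character(cfg_json)),
    n_fish = nrow(staged)
  )
  result <- list(records = staged, summary_month = summary_month,
                 ogive = ogive, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    write_fish_records(staged, file.path(od, "staged_records.csv"))
    if (!is.null(summary_month))
      utils::write.csv(summary_month, file.path(od, "summary_month.csv"),
                       row.names = FALSE)
    report <- lapply(ogive, function(o) list(
      L50 = o$fit$L50, slope = o$fit$slope, intercept = o$fit$intercept,
      nagelkerke_r2 = o$fit$nagelkerke_r2, n = o$fit$n,
      converged = o$fit$converged,
      bootstrap = list(reps = o$bootstrap$reps,
                       L50_median = o$bootstrap$L50_median,
                       ci_low = o$bootstrap$ci_low,
                       ci_high = o$bootstrap$ci_high,
                       n_dropped = o$bootstrap$n_dropped)))
    jsonlite::write_json(list(ogive = report, manifest = manifest),
                         file.path(od, "ogive_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(
      data.frame(rep = seq_len(reps),
                 L50 = ogive[[rule]]$bootstrap$values),
      file.path(od, "bootstrap_L50.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
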