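#' Most advanced germ-cell stage present in an ovary
#'
#' Returns the display group (`pca`, `cao`, `vit`, `pho`, `ho`, `POF`) of
#' the highest-ranked germ structure with at least `min_count` points.
#' Post-ovulatory follicles rank above hydrated oocytes: a single POF point
#' is evidence the fish has already spawned, which trumps any developmental
#' stage still present.
#'
#' @param est a `composition_estimate`.
#' @param min_count minimum point count for a structure to count as present
#'   (default 1; raise to guard against single-point annotation noise).
#' @param pof_terminal if `FALSE`, POF is ranked below ho instead of at the
#'   top (alternative convention).
#' @return single character group label.
#' @export
most_advanced_stage <- function(est, min_count = 1, pof_terminal = TRUE) {
  stopifnot(inherits(est, "composition_estimate"))
  present <- names(est$gcs)[est$gcs * est$n_germ / 100 >= min_count - 1e-9]
  if (length(present) == 0)
    stop("no germ structure reaches min_count = ", min_count)
  rk <- stage_rank(present)
  if (!pof_terminal) rk[present == "POF"] <- 7.5  # between pho and ho
  stage_group(present[which.max(rk)])
}

#' Binary maturity from a composition
#'
#' Two presence rules are supported. `vit_presence` (the default, used for
#' the maturity ogive): a female is mature iff any vitellogenic or later
#' structure (`vit1`, `vit2`, `vit3`, `pho`, `ho`, `POF`) is present.
#' `cao_presence`: maturity starts at the cortical-alveoli stage, the first
#' gonadotropin-dependent stage, so `cao` or anything later counts. The
#' choice moves the size at first maturity by about 2 cm in plaice, which is
#' why both rules are first-class.
#'
#' @param est a `composition_estimate`.
#' @param rule `"vit_presence"` or `"cao_presence"`.
#' @param min_count presence threshold in points.
#' @return logical.
#' @export
is_mature <- function(est, rule = c("vit_presence", "cao_presence"),
                      min_count = 1) {
  stopifnot(inherits(est, "composition_estimate"))
  rule <- match.arg(rule)
  thresh_rank <- if (rule == "vit_presence") stage_rank("vit1")
                 else stage_rank("cao")
  counts <- est$gcs * est$n_germ / 100
  present <- names(est$gcs)[counts >= min_count - 1e-9]
  if (length(present) == 0) stop("no germ structure present")
  any(stage_rank(present) >= thresh_rank)
}

#' Assign an ICES maturity phase (A-D) from histological features
#'
#' Rule-based classification with precedence D > C > B > A:
#' \describe{
#'   \item{D (regressing/regenerating)}{post-ovulatory follicles present, or
#'     atresia present together with regression evidence in the ovarian
#'     wall.}
#'   \item{C (spawning)}{late vitellogenic (`vit3`), partially hydrated or
#'     hydrated oocytes present, no POF.}
#'   \item{B (developing)}{cortical alveoli or early/mid vitellogenic
#'     oocytes present, nothing later.}
#'   \item{A (immature)}{only oogonia and primary-growth oocytes.}
#' }
#' A regenerating ovary (sub-phase Db) contains only `pca` stages and is
#' indistinguishable from A on germ cells alone; `wall_features` (thick
#' ovarian wall, muscle bundles) separates them when provided.
#'
#' @param est a `composition_estimate`.
#' @param wall_features optional list with logicals `thick_wall`,
#'   `muscle_bundles`.
#' @param min_count presence threshold in points.
#' @return A `phase_call`: list with `phase` (one of `"A".."D"`),
#'   `rule_fired`, `evidence` (structures that drove the call).
#' @export
assign_phase <- function(est, wall_features = NULL, min_count = 1) {
  stopifnot(inherits(est, "composition_estimate"))
  counts <- est$gcs * est$n_germ / 100
  present <- names(est$gcs)[counts >= min_count - 1e-9]
  atresia <- intersect(names(est$counts)[est$counts >= min_count],
                       c("ao_alpha", "ao_beta"))
  regression_evidence <- !is.null(wall_features) &&
    (isTRUE(wall_features$thick_wall) || isTRUE(wall_features$muscle_bundles))
  call <- if ("POF" %in% present) {
    list(phase = "D", rule_fired = "D_pof", evidence = "POF")
  } else if (length(atresia) && regression_evidence) {
    list(phase = "D", rule_fired = "D_atresia_regression", evidence = atresia)
  } else if (any(c("vit3", "pho", "ho") %in% present)) {
    list(phase = "C", rule_fired = "C_late_vitellogenic_or_maturing",
         evidence = intersect(c("vit3", "pho", "ho"), present))
  } else if (any(c("cao", "vit1", "vit2") %in% present)) {
    list(phase = "B", rule_fired = "B_developing",
         evidence = intersect(c("cao", "vit1", "vit2"), present))
  } else if (regression_evidence) {
    list(phase = "D", rule_fired = "D_regenerating_wall",
         evidence = c("pca_only", names(which(unlist(wall_features))))
    )
  } else {
    list(phase = "A", rule_fired = "A_pca_only",
         evidence = intersect(c("og", "po1", "po2"), present))
  }
  class(call) <- "phase_call"
  call
}

#' @export
print.phase_call <- function(x, ...) {
  cat("<phase_call> phase ", x$phase, " (rule ", x$rule_fired, "; evidence: ",
      paste(x$evidence, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Stage a table of fish records
#'
#' Applies [most_advanced_stage()], [is_mature()] (both rules) and
#' [assign_phase()] to each record's composition estimate.
#'
#' @param records data frame with one row per fish (must carry `fish_id`).
#' @param compositions list of `composition_estimate`, one per row.
#' @param min_count presence threshold in points.
#' @return `records` with columns `most_advanced`, `mature_vit`,
#'   `mature_cao`, `phase`, `rule_fired` and `gcs_*` group percentages
#'   appended.
#' @export
stage_records <- function(records, compositions, min_count = 1) {
  stopifnot(nrow(records) == length(compositions))
  grp <- c("pca", "cao", "vit", "pho", "ho", "POF")
  records$most_advanced <- vapply(compositions, most_advanced_stage,
                                  character(1), min_count = min_count)
  records$mature_vit <- vapply(compositions, is_mature, logical(1),
                               rule = "vit_presence", min_count = min_count)
  records$mature_cao <- vapply(compositions, is_mature, logical(1),
                               rule = "cao_presence", min_count = min_count)
  calls <- lapply(compositions, assign_phase, min_count = min_count)
  records$phase <- vapply(calls, `[[`, character(1), "phase")
  records$rule_fired <- vapply(calls, `[[`, character(1), "rule_fired")
  gmat <- t(vapply(compositions,
                   function(e) aggregate_composition(e$gcs), numeric(6)))
  colnames(gmat) <- paste0("gcs_", grp)
  cbind(records, as.data.frame(gmat))
}

#' Summarise staged records by month, length class or visual phase
#'
#' For each group: the number of fish, the percentage distribution of the
#' most advanced stage group (sums to 100), and the mean %GCS per structure
#' group — the monthly / per-phase summary tables of the quantitative
#' maturity assessment.
#'
#' @param records a staged record table (see [stage_records()]); must carry
#'   the grouping column (`month`, `length_cm` for 1-cm classes, or
#'   `visual_phase`).
#' @param group_by `"month"`, `"length_class"` or `"visual_phase"`.
#' @return data frame, one row per non-empty group, with columns `group`,
#'   `n`, `adv_<group>` percentages and `mean_gcs_<group>` means.
#' @export
summarize_records <- function(records,
                              group_by = c("month", "length_class",
                                           "visual_phase")) {
  group_by <- match.arg(group_by)
  key <- switch(group_by,
                month = as.character(records$month),
                length_class = as.character(floor(records$length_cm)),
                visual_phase = as.character(records$visual_phase))
  if (is.null(key) || all(is.na(key)))
    stop("records lack the grouping column for ", group_by)
  keep <- !is.na(key)
  if (any(!keep)) message("dropping ", sum(!keep),
                          " record(s) with missing ", group_by)
  records <- records[keep, , drop = FALSE]; key <- key[keep]
  grp <- c("pca", "cao", "vit", "pho", "ho", "POF")
  rows <- lapply(split(seq_along(key), key), function(idx) {
    sub <- records[idx, , drop = FALSE]
    adv <- 100 * vapply(grp, function(g)
      mean(sub$most_advanced == g), numeric(1))
    mg <- vapply(paste0("gcs_", grp), function(cn)
      mean(sub[[cn]]), numeric(1))
    c(n = nrow(sub), setNames(adv, paste0("adv_", grp)),
      setNames(mg, paste0("mean_gcs_", grp)))
  })
  out <- data.frame(group = names(rows),
                    do.call(rbind, rows), row.names = NULL,
                    check.names = FALSE)
  if (group_by %in% c("month", "length_class")) {
    out <- out[order(as.numeric(out$group)), , drop = FALSE]
    row.names(out) <- NULL
  }
  out
}
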