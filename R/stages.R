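#' Germ-cell stage taxonomy for the plaice ovary
#'
#' Oogenesis in *Pleuronectes platessa* progresses through a fixed sequence of
#' germ-cell stages: oogonia (`og`), early and late primary-growth oocytes
#' (`po1`, `po2`), cortical alveoli oocytes (`cao`), three vitellogenic stages
#' (`vit1`--`vit3`), partially hydrated and hydrated oocytes (`pho`, `ho`),
#' and, after ovulation, the post-ovulatory follicle (`POF`). Atretic oocytes
#' (`ao_alpha`, `ao_beta`) and unidentifiable lysis areas are carried as
#' labels but take no part in the germ-cell surface denominator.
#'
#' `stage_prototypes()` returns the default per-stage morphometry: follicle
#' diameter mean and standard deviation (micrometres), zona pellucida
#' thickness where the stage has one, and the ordinal rank used to decide the
#' most advanced stage present in an ovary.
#'
#' @param overrides optional named list; each entry is itself a list with any
#'   of `mean_diameter`, `sd_diameter`, `zp_mean`, `zp_sd` to replace the
#'   defaults for that stage.
#' @return A data frame of class `stage_prototypes` with columns `stage_id`,
#'   `mean_diameter`, `sd_diameter`, `zp_mean`, `zp_sd`, `rank`, `group`.
#' @export
#' @examples
#' stages <- stage_prototypes()
#' stages[stages$stage_id == "ho", "mean_diameter"]  # 958.7 um
stage_prototypes <- function(overrides = NULL) {
  tab <- data.frame(
    stage_id      = c("og", "po1", "po2", "cao", "vit1", "vit2", "vit3",
                      "pho", "ho", "POF"),
    mean_diameter = c(14.3, 29.6, 82.7, 153.1, 191.5, 380.0, 629.5,
                      847.2, 958.7, 400.0),
    sd_diameter   = c(4.6, 5.4, 15.9, 17.8, 29.1, 57.2, 88.5,
                      104.0, 60.7, 80.0),
    zp_mean       = c(NA, NA, NA, NA, NA, 9.2, 53.81, 33.1, 40.4, NA),
    zp_sd         = c(NA, NA, NA, NA, NA, 1.6, 5.10, 3.5, 5.0, NA),
    rank          = 0:9,
    stringsAsFactors = FALSE
  )
  # POF has no measured diameter (a collapsing theca/granulosa shell); the
  # 400 um default is a rendering size for synthetic sections only.
  tab$group <- stage_group(tab$stage_id)
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    for (sid in names(overrides)) {
      i <- match(sid, tab$stage_id)
      if (is.na(i)) stop("unknown stage_id in overrides: ", sid)
      for (fld in names(overrides[[sid]])) {
        if (!fld %in% c("mean_diameter", "sd_diameter", "zp_mean", "zp_sd"))
          stop("unknown stage field: ", fld)
        tab[i, fld] <- overrides[[sid]][[fld]]
      }
    }
  }
  validate_stage_prototypes(tab)
  class(tab) <- c("stage_prototypes", "data.frame")
  tab
}

validate_stage_prototypes <- function(tab) {
  stopifnot(all(tab$mean_diameter > 0), all(tab$sd_diameter >= 0))
  if (anyDuplicated(tab$rank)) stop("stage ranks must form a strict total order")
  invisible(tab)
}

#' Controlled vocabularies for ovarian structures
#'
#' @return Character vectors: `germ_structures()` are the ten stages entering
#'   the germ-cell surface (%GCS) denominator; `nongerm_structures()` are the
#'   somatic / degenerative labels a stereology point may also hit.
#' @export
germ_structures <- function() {
  c("og", "po1", "po2", "cao", "vit1", "vit2", "vit3", "pho", "ho", "POF")
}

#' @rdname germ_structures
#' @export
nongerm_structures <- function() {
  c("ao_alpha", "ao_beta", "lysis", "wall", "epithelium", "lumen",
    "blood_vessel", "unknown")
}

#' Display group of a germ-cell stage
#'
#' `og`, `po1` and `po2` are summarised as precortical-alveoli (`pca`) stages
#' and `vit1`--`vit3` as `vit`; the other stages keep their own name. These
#' are the categories used for most-advanced-stage summaries.
#'
#' @param stage_id character vector of germ stage identifiers.
#' @return character vector in `{pca, cao, vit, pho, ho, POF}`.
#' @export
stage_group <- function(stage_id) {
  grp <- c(og = "pca", po1 = "pca", po2 = "pca", cao = "cao",
           vit1 = "vit", vit2 = "vit", vit3 = "vit",
           pho = "pho", ho = "ho", POF = "POF")
  bad <- setdiff(stage_id, names(grp))
  if (length(bad)) stop("unknown stage_id: ", paste(bad, collapse = ", "))
  unname(grp[stage_id])
}

#' Ordinal rank of germ stages
#'
#' @param stage_id character vector of stage identifiers.
#' @param stages a `stage_prototypes` table (defaults used otherwise).
#' @return integer ranks (og = 0 ... POF = 9).
#' @export
stage_rank <- function(stage_id, stages = stage_prototypes()) {
  i <- match(stage_id, stages$stage_id)
  if (anyNA(i)) stop("unknown stage_id: ",
                     paste(stage_id[is.na(i)], collapse = ", "))
  stages$rank[i]
}

#' Draw a follicle diameter for one germ-cell stage
#'
#' Diameters follow a normal distribution with the stage's mean and standard
#' deviation, truncated below at `max(mean - 3 sd, 1)` micrometres so that a
#' draw can never be non-positive. With `sd_diameter = 0` the mean is
#' returned exactly.
#'
#' @param stage_id a single stage identifier.
#' @param n number of draws.
#' @param stages a `stage_prototypes` table.
#' @return numeric vector of diameters in micrometres.
#' @export
#' @examples
#' set.seed(1)
#' sample_stage_diameter("og", 5)
sample_stage_diameter <- function(stage_id, n = 1, stages = stage_prototypes()) {
  i <- match(stage_id, stages$stage_id)
  if (is.na(i)) stop("unknown stage_id: ", stage_id)
  mu <- stages$mean_diameter[i]
  sd <- stages$sd_diameter[i]
  if (sd == 0) return(rep(mu, n))
  lo <- max(mu - 3 * sd, 1)
  # rejection sampling from the truncated normal; the truncation point is at
  # most 3 sd below the mean so acceptance is >= 99.8%
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 8, mu, sd)
    out <- c(out, draw[draw > lo])
  }
  out[seq_len(n)]
}
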