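#' Default monthly germ-cell composition templates for mature females
#'
#' Group-level (%GCS) templates tracing the annual oogenesis cycle of an
#' English Channel plaice: vitellogenic build-up in November-December, mass
#' spawning with post-ovulatory follicles peaking in January, progressive
#' POF resorption and renewed precortical growth through March. Anchors:
#' pca 31% in December rising to 56% in March; cao 22% in November falling
#' to 10% by January; hydrated oocytes (5%) concurrent with POF (38%) in
#' January.
#'
#' @return named list month -> named numeric over
#'   `{pca, cao, vit, pho, ho, POF}`, each summing to 1.
#' @export
default_composition_schedule <- function() {
  list(
    `11` = c(pca = 0.35, cao = 0.22, vit = 0.28, pho = 0.10, ho = 0.02, POF = 0.03),
    `12` = c(pca = 0.31, cao = 0.15, vit = 0.30, pho = 0.15, ho = 0.03, POF = 0.06),
    `1`  = c(pca = 0.33, cao = 0.10, vit = 0.10, pho = 0.04, ho = 0.05, POF = 0.38),
    `2`  = c(pca = 0.45, cao = 0.12, vit = 0.08, pho = 0.02, ho = 0.03, POF = 0.30),
    `3`  = c(pca = 0.56, cao = 0.14, vit = 0.10, pho = 0.02, ho = 0.02, POF = 0.16)
  )
}

#' Per-phase germ-cell composition profiles
#'
#' Mean %GCS by visually assigned maturity phase: immature ovaries (A)
#' dominated by precortical stages, developing ovaries (B) by stages up to
#' mid-vitellogenesis, spawning ovaries (C) by maturing oocytes (pho 70%,
#' vit 14%, ho 15%, POF 1%), regressing/regenerating ovaries (D) mixing
#' precortical stages with POF remnants.
#'
#' @return named list phase -> composition vector (sums to 1).
#' @export
phase_composition_profiles <- function() {
  list(
    A = c(pca = 0.80, cao = 0.17, ho = 0.01, POF = 0.02),
    B = c(pca = 0.40, cao = 0.16, vit = 0.20, pho = 0.12, ho = 0.03, POF = 0.09),
    C = c(vit = 0.14, pho = 0.70, ho = 0.15, POF = 0.01),
    D = c(pca = 0.34, cao = 0.08, vit = 0.22, pho = 0.06, ho = 0.05, POF = 0.25)
  )
}

#' Specification of a synthetic fish population
#'
#' Maturity by length follows a logistic curve: a fish of length `L` is
#' mature with probability `logistic(slope * (L - L50))`. Mature fish get a
#' germ-cell composition from the per-month schedule; immature fish carry
#' precortical stages only. Gonad and body weights are drawn so that the
#' gonadosomatic index reproduces a configurable phase -> GSI profile on
#' top of a standard length-weight allometry (`W = a L^b`).
#'
#' @param n_fish number of fish (default 151, a typical multi-year
#'   opportunistic sampling).
#' @param length_range total length range in cm, uniform sampling.
#' @param true_L50 true length at 50% maturity, cm; must lie inside
#'   `length_range`.
#' @param logistic_slope slope of the maturity curve, per cm.
#' @param months calendar months sampled (schedule keys).
#' @param composition_schedule month -> mature composition template.
#' @param immature_composition stage-level composition of immature ovaries.
#' @param spawning_fraction probability that a mature fish is caught while
#'   actively spawning (hydrating oocytes in the ovary, visual phase C);
#'   such fish carry the spawning composition profile instead of the
#'   monthly template. Default 0.02 — actively spawning females are rarely
#'   landed intact (a handful per ~150 fish).
#' @param gsi_profile named mean GSI percent by phase A/B/C/D.
#' @param gsi_cv lognormal coefficient of variation of individual GSI.
#' @param lw_a,lw_b length-weight allometry coefficients (g, cm).
#' @param seed integer seed, required.
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_fish = 151, length_range = c(14, 35),
                            true_L50 = 20.6, logistic_slope = 0.55,
                            months = c(11, 12, 1, 2, 3),
                            composition_schedule = default_composition_schedule(),
                            immature_composition = c(og = 0.10, po1 = 0.35,
                                                     po2 = 0.55),
                            spawning_fraction = 0.02,
                            gsi_profile = c(A = 0.5, B = 4, C = 22, D = 3),
                            gsi_cv = 0.3, lw_a = 0.0085, lw_b = 3.05,
                            seed) {
  if (missing(seed)) stop("population_spec requires a seed")
  stopifnot(n_fish >= 1, length(length_range) == 2,
            length_range[1] < length_range[2])
  if (true_L50 < length_range[1] || true_L50 > length_range[2])
    stop("true_L50 must lie within length_range")
  miss <- setdiff(as.character(months), names(composition_schedule))
  if (length(miss)) stop("composition_schedule missing month(s): ",
                         paste(miss, collapse = ", "))
  for (m in names(composition_schedule)) {
    cm <- composition_schedule[[m]]
    if (abs(sum(cm) - 1) > 1e-9)
      stop("schedule for month ", m, " does not sum to 1")
  }
  spec <- list(n_fish = as.integer(n_fish), length_range = length_range,
               true_L50 = true_L50, logistic_slope = logistic_slope,
               months = months, composition_schedule = composition_schedule,
               immature_composition = immature_composition /
                 sum(immature_composition),
               spawning_fraction = spawning_fraction,
               gsi_profile = gsi_profile, gsi_cv = gsi_cv,
               lw_a = lw_a, lw_b = lw_b, seed = as.integer(seed))
  class(spec) <- "population_spec"
  spec
}

# Nominal phase of a mature template: used only to pick a GSI level.
template_phase <- function(comp) {
  if ((comp["POF"] %||% 0) >= 0.2) "D"
  else if ((comp["pho"] %||% 0) + (comp["ho"] %||% 0) >= 0.5) "C"
  else "B"
}

#' Generate a synthetic fish population
#'
#' Draws lengths, months, true maturity (Bernoulli on the logistic curve),
#' per-fish germ-cell compositions and body/gonad weights according to a
#' [population_spec()].
#'
#' @param pop a `population_spec`.
#' @return data frame (class `fish_population`) with columns `fish_id`,
#'   `month`, `length_cm`, `ungutted_weight_g`, `gonad_weight_g`,
#'   `visual_phase`, `true_mature`, `gsi_true` and `comp_*` true
#'   group-composition columns; the spec is attached as attribute `spec`.
#' @export
generate_population <- function(pop) {
  stopifnot(inherits(pop, "population_spec"))
  with_seed(pop$seed, {
    n <- pop$n_fish
    len <- stats::runif(n, pop$length_range[1], pop$length_range[2])
    month <- sample(pop$months, n, replace = TRUE)
    p <- stats::plogis(pop$logistic_slope * (len - pop$true_L50))
    mature <- stats::runif(n) < p
    grp <- c("pca", "cao", "vit", "pho", "ho", "POF")
    comp <- matrix(0, n, length(grp), dimnames = list(NULL, grp))
    phase <- character(n)
    imm <- aggregate_composition(
      setNames(as.numeric(pop$immature_composition),
               names(pop$immature_composition)))
    spawning <- stats::runif(n) < pop$spawning_fraction
    for (i in seq_len(n)) {
      if (mature[i] && spawning[i]) {
        tmpl <- phase_composition_profiles()$C
        comp[i, names(tmpl)] <- tmpl
        phase[i] <- "C"
      } else if (mature[i]) {
        tmpl <- pop$composition_schedule[[as.character(month[i])]]
        comp[i, names(tmpl)] <- tmpl
        phase[i] <- template_phase(tmpl)
      } else {
        comp[i, names(imm)] <- imm
        phase[i] <- "A"
      }
    }
    soma <- pop$lw_a * len^pop$lw_b *
      exp(stats::rnorm(n, 0, 0.08))             # length-weight scatter
    mu <- pop$gsi_profile[phase]
    sdlog <- sqrt(log(1 + pop$gsi_cv^2))
    gsi_val <- stats::rlnorm(n, log(mu) - sdlog^2 / 2, sdlog)
    gonad <- soma * gsi_val / 100
    ungutted <- soma + gonad
    df <- data.frame(fish_id = sprintf("F%03d", seq_len(n)),
                     month = month, length_cm = len,
                     ungutted_weight_g = ungutted, gonad_weight_g = gonad,
                     visual_phase = phase, true_mature = mature,
                     gsi_true = gsi_val, stringsAsFactors = FALSE)
    colnames(comp) <- paste0("comp_", grp)
    df <- cbind(df, as.data.frame(comp))
    attr(df, "spec") <- pop
    class(df) <- c("fish_population", "data.frame")
    df
  })
}

#' Simulate a stereology reading from a known composition
#'
#' Multinomial point-count sampling: the statistical equivalent of laying a
#' 500-600-point grid on a well-mixed section with the given germ-cell
#' composition. Group-level entries are expanded over member stages.
#'
#' @param composition named fractions over stages or groups (sums to 1).
#' @param n_points total grid points (drawn uniformly in `n_range` if NULL).
#' @param n_range range for the total point count.
#' @param germ_share expected fraction of points hitting germ structures
#'   (the rest hit wall / lumen / epithelium).
#' @param seed integer seed, required.
#' @return named integer point counts (germ stages + somatic structures),
#'   suitable for [composition_from_counts()].
#' @export
simulate_point_counts <- function(composition, n_points = NULL,
                                  n_range = c(500, 600), germ_share = 0.45,
                                  seed) {
  if (missing(seed)) stop("simulate_point_counts requires a seed")
  comp <- expand_composition(composition / sum(composition))
  with_seed(seed, {
    if (is.null(n_points))
      n_points <- sample(seq(n_range[1], n_range[2]), 1)
    n_germ <- stats::rbinom(1, n_points, germ_share)
    germ <- if (n_germ > 0)
      stats::rmultinom(1, n_germ, comp)[, 1] else setNames(integer(0), NULL)
    somatic <- stats::rmultinom(1, n_points - n_germ,
                                c(wall = 0.35, lumen = 0.5,
                                  epithelium = 0.1, blood_vessel = 0.05))[, 1]
    counts <- c(germ, somatic)
    counts[counts > 0]
  })
}
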