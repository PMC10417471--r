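#' Specification of a synthetic ovarian cross-section
#'
#' Describes the label image to generate: canvas size, spatial scale,
#' target germ-cell composition, and the somatic-tissue budget. The realized
#' section is an ellipse with an ovarian wall ring, a thin germinal
#' epithelium, a lumen, scattered blood vessels, and non-overlapping oocyte
#' follicles whose diameters are drawn from the stage prototypes.
#'
#' @param width,height canvas size in pixels.
#' @param px_per_um spatial scale in pixels per micrometre (default 0.5, i.e.
#'   1 px = 2 um, so a hydrated oocyte of 958.7 um spans ~480 px).
#' @param composition named numeric vector of target germ-area fractions.
#'   Names may be stage ids (`og` ... `POF`) or display groups (`pca`,
#'   `vit`), which are expanded over their member stages; values must be
#'   non-negative and sum to 1.
#' @param germ_fraction fraction of the interior (lumen) area to fill with
#'   germ-cell structures (default 0.45; sequential random placement of
#'   non-overlapping discs jams near 55% coverage, so targets much above
#'   0.5 may be unreachable for single-stage compositions).
#' @param wall_um,epithelium_um thickness of the ovarian wall and of the
#'   germinal epithelium, micrometres.
#' @param n_vessels number of blood-vessel profiles to scatter.
#' @param tolerance maximum absolute deviation, per structure, between the
#'   realized germ-area fraction and its target (default 0.02, i.e. 2
#'   percentage points).
#' @param seed integer seed; required, all randomness flows from it.
#' @param group_weights named list giving the within-group stage split used
#'   when `composition` names a group (defaults: pca -> og 0.10 / po1 0.30 /
#'   po2 0.60; vit -> equal thirds).
#' @param max_attempts placement-attempt budget before giving up.
#' @return A `section_spec` list.
#' @export
section_spec <- function(width = 4000, height = 3000, px_per_um = 0.5,
                         composition = c(pca = 0.45, cao = 0.2, vit = 0.25,
                                         pho = 0.05, ho = 0.03, POF = 0.02),
                         germ_fraction = 0.45,
                         wall_um = 150, epithelium_um = 20,
                         n_vessels = 6, tolerance = 0.02,
                         seed, group_weights = NULL,
                         max_attempts = 200000) {
  if (missing(seed)) stop("section_spec requires a seed")
  stopifnot(width >= 50, height >= 50, px_per_um > 0)
  if (any(composition < 0)) stop("composition fractions must be >= 0")
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition must sum to 1 (got ", sum(composition), ")")
  spec <- list(width = as.integer(width), height = as.integer(height),
               px_per_um = px_per_um,
               composition = expand_composition(composition, group_weights),
               germ_fraction = germ_fraction, wall_um = wall_um,
               epithelium_um = epithelium_um, n_vessels = n_vessels,
               tolerance = tolerance, seed = as.integer(seed),
               max_attempts = max_attempts)
  class(spec) <- "section_spec"
  spec
}

# Expand group-level composition entries (pca, vit) over member stages.
expand_composition <- function(composition, group_weights = NULL) {
  gw <- list(pca = c(og = 0.10, po1 = 0.30, po2 = 0.60),
             vit = c(vit1 = 1, vit2 = 1, vit3 = 1) / 3)
  for (g in names(group_weights)) gw[[g]] <- group_weights[[g]] /
      sum(group_weights[[g]])
  out <- setNames(numeric(length(germ_structures())), germ_structures())
  for (nm in names(composition)) {
    if (nm %in% germ_structures()) {
      out[nm] <- out[nm] + composition[[nm]]
    } else if (nm %in% names(gw)) {
      w <- gw[[nm]] * composition[[nm]]
      out[names(w)] <- out[names(w)] + w
    } else stop("unknown composition entry: ", nm)
  }
  out[out > 0]
}

# Fixed label encoding shared by all synthetic sections.
#  0 background; 1 wall; 2 lumen; 3 epithelium; 4 blood vessel;
#  10 + rank: germ stage body; 30 + rank: its zona pellucida annulus;
#  21/22/23: ao_alpha / ao_beta / lysis.
#' Label legend for synthetic sections
#'
#' @return data frame with columns `label`, `structure`, `owner_stage`
#'   (`owner_stage` is the germ stage a zona pellucida annulus belongs to).
#' @export
label_legend <- function() {
  g <- germ_structures()
  data.frame(
    label = c(0L, 1L, 2L, 3L, 4L, 21L, 22L, 23L, 10L + 0:9, 30L + 0:9),
    structure = c("background", "wall", "lumen", "epithelium", "blood_vessel",
                  "ao_alpha", "ao_beta", "lysis", g, paste0(g, "_zp")),
    owner_stage = c(rep(NA_character_, 8), rep(NA_character_, 10), g),
    stringsAsFactors = FALSE
  )
}

stage_label_id <- function(stage_id) 10L + stage_rank(stage_id)
zp_label_id <- function(stage_id) 30L + stage_rank(stage_id)

# Pixels of a filled disc clipped to the canvas: matrix of (row, col) indices.
disc_cells <- function(cx, cy, r, W, H) {
  xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  keep <- which(d2 <= r^2, arr.ind = TRUE)
  cbind(row = ys[keep[, 1]], col = xs[keep[, 2]])
}

# Pixels of an annulus [r_in, r_out], optionally with an angular gap
# (an "open" shell, used for post-ovulatory follicles).
annulus_cells <- function(cx, cy, r_out, r_in, W, H,
                          gap_centre = NULL, gap_halfwidth = 0) {
  xs <- max(1L, floor(cx - r_out)):min(W, ceiling(cx + r_out))
  ys <- max(1L, floor(cy - r_out)):min(H, ceiling(cy + r_out))
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  d2 <- dx^2 + dy^2
  inside <- d2 <= r_out^2 & d2 >= r_in^2
  if (!is.null(gap_centre) && gap_halfwidth > 0) {
    ang <- atan2(dy, dx)
    delta <- abs(((ang - gap_centre + pi) %% (2 * pi)) - pi)
    inside <- inside & delta > gap_halfwidth
  }
  keep <- which(inside, arr.ind = TRUE)
  cbind(row = ys[keep[, 1]], col = xs[keep[, 2]])
}

#' Generate a synthetic labelled ovarian cross-section
#'
#' Renders an elliptical ovary (wall ring, germinal epithelium, lumen) and
#' fills it with non-overlapping germ-cell structures until each structure's
#' realized share of the germ area is within `spec$tolerance` of its target:
#' oocytes as discs with stage-sampled diameters (stages with a zona
#' pellucida get a labelled annulus of the stage's zp thickness),
#' post-ovulatory follicles as thin open shells. Placement is by rejection
#' sampling of disc centres in the free lumen; the last disc of a structure
#' may be shrunk to close the remaining area deficit, which keeps the
#' realized fractions on target while leaving the area bookkeeping exact.
#'
#' The returned ground truth is recomputed by exhaustively tabulating the
#' final label matrix, so it is exact by construction.
#'
#' @param spec a [section_spec()].
#' @param stages a [stage_prototypes()] table.
#' @return A `label_image`: list with `labels` (integer matrix, rows = y,
#'   columns = x), `legend`, `truth` (exact per-stage germ-area fractions,
#'   zona pellucida counted with its oocyte), `truth_groups` (aggregated to
#'   pca/cao/vit/pho/ho/POF), `px_per_um`, `spec`.
#' @export
generate_section <- function(spec, stages = stage_prototypes()) {
  stopifnot(inherits(spec, "section_spec"))
  with_seed(spec$seed, {
    W <- spec$width; H <- spec$height; ppu <- spec$px_per_um
    lab <- matrix(0L, nrow = H, ncol = W)
    cx <- (W + 1) / 2; cy <- (H + 1) / 2
    a <- W / 2 - 2; b <- H / 2 - 2
    w_px <- max(2, spec$wall_um * ppu)
    e_px <- max(1, spec$epithelium_um * ppu)
    fill_ellipse <- function(sa, sb, value) {
      if (sa <= 2 || sb <= 2) return(invisible(NULL))
      xs2 <- ((seq_len(W) - cx) / sa)^2
      ys2 <- ((seq_len(H) - cy) / sb)^2
      inside <- outer(ys2, xs2, "+") <= 1
      lab[inside] <<- value
      invisible(NULL)
    }
    fill_ellipse(a, b, 1L)                      # wall
    fill_ellipse(a - w_px, b - w_px, 3L)        # germinal epithelium
    fill_ellipse(a - w_px - e_px, b - w_px - e_px, 2L)  # lumen
    interior <- sum(lab == 2L)
    if (interior < 100) stop("canvas too small for an ovary interior")

    attempts <- 0L
    place_structure <- function(cells_fun) {
      # cells_fun(cx, cy) -> candidate pixel cells; returns cells on success
      bx <- c(cx - (a - w_px), cx + (a - w_px))
      by <- c(cy - (b - w_px), cy + (b - w_px))
      repeat {
        attempts <<- attempts + 1L
        if (attempts > spec$max_attempts) return(NULL)
        px <- stats::runif(1, bx[1], bx[2])
        py <- stats::runif(1, by[1], by[2])
        if (lab[round(py), round(px)] != 2L) next
        cells <- cells_fun(px, py)
        if (nrow(cells) == 0) next
        if (all(lab[cells] == 2L)) return(cells)
      }
    }

    # blood vessels: small discs (30-80 um across) in the lumen
    for (k in seq_len(spec$n_vessels)) {
      r <- stats::runif(1, 15, 40) * ppu
      cells <- place_structure(function(px, py) disc_cells(px, py, r, W, H))
      if (is.null(cells)) break
      lab[cells] <- 4L
    }

    comp <- spec$composition
    A_g <- spec$germ_fraction * interior
    tol_px <- spec$tolerance * A_g
    # largest stages first: big discs need contiguous free space
    ord <- order(-stages$mean_diameter[match(names(comp), stages$stage_id)])
    achieved <- setNames(numeric(length(comp)), names(comp))
    failed <- FALSE
    for (sid in names(comp)[ord]) {
      target <- comp[[sid]] * A_g
      srow <- stages[stages$stage_id == sid, ]
      area <- 0
      while (target - area > 4) {
        d_um <- sample_stage_diameter(sid, 1, stages)
        r <- d_um * ppu / 2
        deficit <- target - area
        if (pi * r^2 > deficit) r <- max(0.8, sqrt(deficit / pi))
        if (sid == "POF") {
          t_px <- max(1, 20 * ppu)   # shell thickness ~20 um
          r <- max(r, t_px + 1)
          gap_c <- stats::runif(1, 0, 2 * pi)
          cells <- place_structure(function(px, py)
            annulus_cells(px, py, r, r - t_px, W, H, gap_c, pi / 6))
        } else if (!is.na(srow$zp_mean)) {
          t_px <- max(1, stats::rnorm(1, srow$zp_mean, srow$zp_sd) * ppu)
          t_px <- min(t_px, r / 2)
          cells <- place_structure(function(px, py) disc_cells(px, py, r, W, H))
          if (!is.null(cells)) {
            ctr <- c(mean(range(cells[, 1])), mean(range(cells[, 2])))
            d2 <- (cells[, 1] - ctr[1])^2 + (cells[, 2] - ctr[2])^2
            zp <- d2 >= (r - t_px)^2
            lab[cells[zp, , drop = FALSE]] <- zp_label_id(sid)
            lab[cells[!zp, , drop = FALSE]] <- stage_label_id(sid)
            area <- area + nrow(cells)
            next
          }
        } else {
          cells <- place_structure(function(px, py) disc_cells(px, py, r, W, H))
        }
        if (is.null(cells)) { failed <- TRUE; break }
        lab[cells] <- stage_label_id(sid)
        area <- area + nrow(cells)
      }
      achieved[sid] <- area
      if (failed) break
    }

    truth <- section_truth(lab)
    realized <- truth[names(comp)]
    realized[is.na(realized)] <- 0
    off <- abs(realized - comp)
    if (failed || any(off > spec$tolerance)) {
      stop("generate_section: could not reach target composition within ",
           "tolerance; achieved fractions: ",
           paste(sprintf("%s=%.3f", names(comp), realized), collapse = ", "))
    }
    out <- list(labels = lab, legend = label_legend(), truth = truth,
                truth_groups = aggregate_composition(truth),
                px_per_um = ppu, spec = spec)
    class(out) <- "label_image"
    out
  })
}

# Exact per-stage germ-area fractions of a label matrix (zp annuli counted
# with their owner oocyte). This is the brute-force pixel-count ground truth.
section_truth <- function(lab) {
  leg <- label_legend()
  tab <- tabulate(lab + 1L, max(leg$label) + 1L)
  counts <- setNames(tab[leg$label + 1L], leg$structure)
  g <- germ_structures()
  per_stage <- counts[g] + counts[paste0(g, "_zp")]
  n <- sum(per_stage)
  if (n == 0) return(setNames(numeric(length(g)), g))
  setNames(as.numeric(per_stage) / n, g)
}

#' Aggregate a per-stage composition to display groups
#'
#' @param x named numeric over stage ids.
#' @return named numeric over `{pca, cao, vit, pho, ho, POF}`.
#' @export
aggregate_composition <- function(x) {
  grp <- stage_group(names(x))
  out <- setNames(numeric(6), c("pca", "cao", "vit", "pho", "ho", "POF"))
  for (i in seq_along(x)) out[grp[i]] <- out[grp[i]] + x[[i]]
  out
}

#' Default rendering palette
#'
#' Gray levels (0-255) per structure for [render_grayscale()]. Tissue is
#' dark, the slide background light, mimicking a thresholdable scan.
#' @return named numeric vector.
#' @export
default_palette <- function() {
  c(background = 240, wall = 90, lumen = 170, epithelium = 100,
    blood_vessel = 60, og = 110, po1 = 115, po2 = 120, cao = 125,
    vit1 = 130, vit2 = 135, vit3 = 140, pho = 150, ho = 155, POF = 105,
    zp = 80, ao_alpha = 95, ao_beta = 97, lysis = 99)
}

#' Render a label image to grayscale
#'
#' Deterministic palette lookup (zona pellucida annuli take the `zp` gray),
#' plus optional additive Gaussian noise clipped to \[0, 255\].
#'
#' @param img a `label_image`.
#' @param palette named gray levels; must cover every structure present.
#' @param noise_sd standard deviation of the additive noise (0 = none).
#' @param seed seed for the noise draw.
#' @return numeric matrix of gray levels in \[0, 255\].
#' @export
render_grayscale <- function(img, palette = default_palette(), noise_sd = 0,
                             seed = NULL) {
  stopifnot(inherits(img, "label_image"))
  leg <- img$legend
  key <- ifelse(is.na(leg$owner_stage), leg$structure, "zp")
  gray_of <- palette[key]
  present <- unique(as.vector(img$labels))
  need <- leg$label %in% present
  if (anyNA(gray_of[need]))
    stop("palette is missing entries for: ",
         paste(unique(key[need][is.na(gray_of[need])]), collapse = ", "))
  lut <- rep(NA_real_, max(leg$label) + 1L)
  lut[leg$label + 1L] <- gray_of
  gray <- matrix(lut[img$labels + 1L], nrow = nrow(img$labels))
  if (noise_sd > 0) {
    gray[] <- with_seed(seed, gray + stats::rnorm(length(gray), 0, noise_sd))
    gray[] <- pmin(255, pmax(0, gray))
  }
  gray
}

#' @export
print.label_image <- function(x, ...) {
  cat("<label_image> ", ncol(x$labels), "x", nrow(x$labels), " px, 1 px = ",
      signif(1 / x$px_per_um, 3), " um\n", sep = "")
  tg <- x$truth_groups
  cat("germ composition (truth): ",
      paste(sprintf("%s %.1f%%", names(tg), 100 * tg), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
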