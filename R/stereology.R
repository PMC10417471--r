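#' Otsu's threshold of a grayscale image
#'
#' Maximizes between-class variance over a 256-bin histogram; used to split
#' tissue (dark) from slide background (light).
#'
#' @param gray numeric matrix of gray levels in \[0, 255\].
#' @return threshold on the gray scale; pixels strictly below it are "dark".
#' @export
otsu_threshold <- function(gray) {
  h <- tabulate(pmin(255L, pmax(0L, as.integer(gray))) + 1L, 256L)
  n <- sum(h)
  if (n == 0) stop("empty image")
  levels <- 0:255
  w <- cumsum(h) / n
  mu <- cumsum(h * levels) / n
  mu_t <- mu[256]
  bcv <- (mu_t * w - mu)^2 / (w * (1 - w))
  bcv[!is.finite(bcv)] <- 0
  if (max(bcv) == 0) stop("no tissue found: image has a single gray level")
  # threshold between bin k and k+1 -> pixels <= k are the dark class
  levels[which.max(bcv)] + 1
}

#' Segment the tissue area of a scanned section
#'
#' Thresholds the gray-level image (tissue = darker pixels), keeps the
#' largest 4-connected component, and fills enclosed holes up to
#' `max_hole_px` pixels, so the mask covers the whole ovarian cross-section
#' including its lumen.
#'
#' @param gray numeric matrix of gray levels in \[0, 255\].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold threshold when `method = "fixed"`; pixels strictly
#'   below it are tissue.
#' @param max_hole_px holes (enclosed background components) of at most this
#'   many pixels are filled; `Inf` fills all enclosed holes (default).
#' @return A `tissue_mask`: list with `mask` (logical matrix),
#'   `threshold_used`, `method`.
#' @export
segment_tissue <- function(gray, method = c("otsu", "fixed"),
                           fixed_threshold = NULL, max_hole_px = Inf) {
  method <- match.arg(method)
  stopifnot(is.matrix(gray))
  thr <- if (method == "otsu") otsu_threshold(gray) else {
    if (is.null(fixed_threshold)) stop("fixed_threshold required")
    fixed_threshold
  }
  raw <- gray < thr
  if (!any(raw)) stop("no tissue found: no pixel below threshold ", thr)
  comp <- .cc_label(raw)
  sizes <- tabulate(comp[comp > 0L])
  mask <- comp == which.max(sizes)
  # fill holes: background components not touching the image border
  bg <- .cc_label(!mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  bg_sizes <- tabulate(bg[bg > 0L])
  hole_ids <- setdiff(which(bg_sizes <= max_hole_px), border)
  if (length(hole_ids)) mask[bg %in% hole_ids] <- TRUE
  out <- list(mask = mask, threshold_used = thr, method = method)
  class(out) <- "tissue_mask"
  out
}

#' Lay a systematic uniform random point grid over a tissue mask
#'
#' Points sit on a square lattice with a random offset uniform in
#' `[0, spacing)^2` (systematic uniform random sampling). The initial
#' spacing is `sqrt(tissue_area / n_target)`; if the number of in-mask
#' points falls outside `n_range` (500-600 by default) the spacing is
#' adjusted by bisection until it does.
#'
#' @param mask a `tissue_mask` or logical matrix.
#' @param n_target nominal number of in-mask points (default 550).
#' @param n_range acceptable range for the in-mask count (default
#'   `c(500, 600)`).
#' @param seed integer seed for the random offset.
#' @param max_iter bisection iteration cap.
#' @return A `point_grid`: list with `spacing` (px), `offset` (dx, dy in
#'   px), `points` (data frame of 0-based pixel coordinates `x`, `y`), `n`,
#'   `seed`.
#' @export
make_grid <- function(mask, n_target = 550, n_range = c(500, 600), seed,
                      max_iter = 200) {
  if (missing(seed)) stop("make_grid requires a seed")
  m <- if (inherits(mask, "tissue_mask")) mask$mask else mask
  stopifnot(is.matrix(m), is.logical(m))
  area <- sum(m)
  if (area < n_range[1])
    stop("mask too small: ", area, " px cannot hold ", n_range[1],
         " points at >= 1 px spacing")
  with_seed(seed, {
    u <- stats::runif(2)   # offset as a fraction of spacing, fixed across s
    H <- nrow(m); W <- ncol(m)
    count_at <- function(s) {
      dx <- u[1] * s; dy <- u[2] * s
      xs <- floor(seq(dx, W - 1e-9, by = s)) + 1L
      ys <- floor(seq(dy, H - 1e-9, by = s)) + 1L
      xs <- xs[xs <= W]; ys <- ys[ys <= H]
      inm <- m[ys, xs, drop = FALSE]
      idx <- which(inm, arr.ind = TRUE)
      list(n = nrow(idx),
           pts = data.frame(x = xs[idx[, 2]] - 1L, y = ys[idx[, 1]] - 1L))
    }
    s <- sqrt(area / n_target)
    res <- count_at(s)
    if (res$n < n_range[1] || res$n > n_range[2]) {
      # count decreases with spacing; bracket then bisect
      lo <- s; hi <- s
      for (i in seq_len(60)) {
        if (count_at(lo)$n >= n_range[1]) break
        lo <- max(lo / 1.3, 1)
        if (lo == 1) break   # count at 1 px spacing equals the mask area
      }
      for (i in seq_len(60)) {
        if (count_at(hi)$n <= n_range[2]) break
        hi <- hi * 1.3
      }
      if (lo < 1) stop("mask too small to fit ", n_range[1],
                       " points at >= 1 px spacing")
      it <- 0
      repeat {
        it <- it + 1
        mid <- (lo + hi) / 2
        res <- count_at(mid)
        if (res$n >= n_range[1] && res$n <= n_range[2]) { s <- mid; break }
        if (res$n > n_range[2]) lo <- mid else hi <- mid
        if (it >= max_iter)
          stop("make_grid: could not reach ", n_range[1], "-", n_range[2],
               " points (last count ", res$n, ")")
      }
    }
    out <- list(spacing = s, offset = c(dx = u[1] * s, dy = u[2] * s),
                points = res$pts, n = res$n, seed = as.integer(seed))
    class(out) <- "point_grid"
    out
  })
}

#' Assign each grid point the structure under it
#'
#' The sample locus is the pixel centre; each point takes the structure of
#' its pixel in the label image. Zona pellucida annuli count as their owner
#' oocyte's stage by default (the whole follicle is the counted surface);
#' with `zp_as_stage = FALSE` they are reported as `"zp"` (non-germ).
#' Background pixels map to `"unknown"`.
#'
#' @param grid a `point_grid` (or data frame with 0-based `x`, `y`).
#' @param img a `label_image`.
#' @param zp_as_stage logical, see above.
#' @return data frame `point_id`, `x`, `y`, `structure` — one structure per
#'   point.
#' @export
annotate_points <- function(grid, img, zp_as_stage = TRUE) {
  stopifnot(inherits(img, "label_image"))
  pts <- if (inherits(grid, "point_grid")) grid$points else grid
  H <- nrow(img$labels); W <- ncol(img$labels)
  if (any(pts$x < 0 | pts$x >= W | pts$y < 0 | pts$y >= H))
    stop("grid point outside label image bounds")
  leg <- img$legend
  struct <- if (zp_as_stage)
    ifelse(is.na(leg$owner_stage), leg$structure, leg$owner_stage)
  else ifelse(is.na(leg$owner_stage), leg$structure, "zp")
  struct[leg$structure == "background"] <- "unknown"
  lut <- rep(NA_character_, max(leg$label) + 1L)
  lut[leg$label + 1L] <- struct
  lab <- img$labels[cbind(pts$y + 1L, pts$x + 1L)]
  data.frame(point_id = seq_len(nrow(pts)), x = pts$x, y = pts$y,
             structure = lut[lab + 1L], stringsAsFactors = FALSE)
}

#' Estimate germ-cell surface composition from point annotations
#'
#' Point-count stereology: the share of points hitting a structure estimates
#' its area fraction. Percentages (%GCS) are taken over germ-cell points
#' only (`og` ... `POF`); somatic structures, atresia and lysis are counted
#' but excluded from the denominator. `og + po1 + po2` are aggregated as
#' `pca` and `vit1..vit3` as `vit`.
#'
#' @param annotations data frame with a `structure` column (one row per
#'   point), or a named count vector via [composition_from_counts()].
#' @return A `composition_estimate`: `counts` (all structures seen),
#'   `n_germ`, `n_total`, `gcs` (percent per germ structure, sums to 100),
#'   `pca`, `vit`.
#' @export
estimate_composition <- function(annotations) {
  stopifnot(nrow(annotations) >= 1, "structure" %in% names(annotations))
  counts <- table(annotations$structure)
  composition_from_counts(setNames(as.integer(counts), names(counts)))
}

#' @rdname estimate_composition
#' @param counts named integer vector of per-structure point counts.
#' @export
composition_from_counts <- function(counts) {
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts >= 0))
  known <- c(germ_structures(), nongerm_structures(), "zp", "background")
  bad <- setdiff(names(counts), known)
  if (length(bad)) stop("unknown structure label(s): ",
                        paste(bad, collapse = ", "))
  g <- germ_structures()
  germ_counts <- setNames(numeric(length(g)), g)
  germ_counts[intersect(names(counts), g)] <-
    counts[intersect(names(counts), g)]
  n_germ <- sum(germ_counts)
  if (n_germ == 0)
    stop("no germ-cell points: composition cannot be estimated ",
         "(record should be flagged and excluded from staging)")
  gcs <- 100 * germ_counts / n_germ
  out <- list(counts = counts, n_germ = n_germ, n_total = sum(counts),
              gcs = gcs,
              pca = sum(gcs[c("og", "po1", "po2")]),
              vit = sum(gcs[c("vit1", "vit2", "vit3")]))
  class(out) <- "composition_estimate"
  out
}

#' @export
print.composition_estimate <- function(x, ...) {
  cat("<composition_estimate> ", x$n_germ, " germ points / ", x$n_total,
      " total\n", sep = "")
  nz <- x$gcs[x$gcs > 0]
  cat("%GCS: ", paste(sprintf("%s %.1f", names(nz), nz), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("aggregates: pca %.1f, vit %.1f\n", x$pca, x$vit))
  invisible(x)
}

#' Replicate the point-count estimate over independent grid offsets
#'
#' Re-grids the same section `n_replicates` times with independent random
#' offsets and returns the per-structure mean and standard error of %GCS —
#' the sampling uncertainty of a single 500-600-point reading.
#'
#' @param img a `label_image`.
#' @param n_replicates number of independent grids (>= 2).
#' @param seed master seed; one child seed is derived per replicate.
#' @param seeds optional explicit vector of per-replicate seeds.
#' @param ... passed to [make_grid()].
#' @return list with `mean`, `se` (named over germ structures), `gcs`
#'   (replicates x structures matrix), `n_replicates`.
#' @export
replicate_composition <- function(img, n_replicates, seed = NULL,
                                  seeds = NULL, ...) {
  stopifnot(inherits(img, "label_image"), n_replicates >= 2)
  if (is.null(seeds)) {
    if (is.null(seed)) stop("provide seed or seeds")
    seeds <- derive_seeds(seed, n_replicates)
  }
  stopifnot(length(seeds) == n_replicates)
  mask <- img$labels > 0L
  g <- germ_structures()
  mat <- matrix(NA_real_, n_replicates, length(g),
                dimnames = list(NULL, g))
  for (i in seq_len(n_replicates)) {
    grid <- make_grid(mask, seed = seeds[i], ...)
    est <- estimate_composition(annotate_points(grid, img))
    mat[i, ] <- est$gcs[g]
  }
  list(mean = colMeans(mat),
       se = apply(mat, 2, stats::sd) / sqrt(n_replicates),
       gcs = mat, n_replicates = n_replicates)
}
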