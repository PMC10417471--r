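# Shared fixtures: three seeded synthetic sections with distinct
# compositions, generated once per test run (generation is a few seconds
# each). 1 px = 6.67 um keeps a hydrated oocyte at ~145 px so whole
# sections stay small.

.fixture_env <- new.env(parent = emptyenv())

fixture_section <- function(which = c("mixed", "phaseC", "phaseB")) {
  which <- match.arg(which)
  key <- paste0("section_", which)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  spec <- switch(which,
    mixed = section_spec(width = 900, height = 700, px_per_um = 0.15,
                         composition = c(pca = 0.45, cao = 0.20, vit = 0.25,
                                         pho = 0.05, ho = 0.03, POF = 0.02),
                         seed = 1),
    phaseC = section_spec(width = 900, height = 700, px_per_um = 0.15,
                          composition = c(pho = 0.70, vit = 0.14, ho = 0.15,
                                          POF = 0.01),
                          seed = 2),
    phaseB = section_spec(width = 900, height = 700, px_per_um = 0.15,
                          composition = c(pca = 0.40, cao = 0.16, vit = 0.20,
                                          pho = 0.12, ho = 0.03, POF = 0.09),
                          seed = 3)
  )
  .fixture_env[[key]] <- generate_section(spec)
  .fixture_env[[key]]
}

# Exhaustive pixel-count oracle: area fractions among germ pixels by direct
# tabulation, independent of section_truth()'s bookkeeping.
pixel_count_oracle <- function(img) {
  leg <- img$legend
  struct <- ifelse(is.na(leg$owner_stage), leg$structure, leg$owner_stage)
  lut <- rep(NA_character_, max(leg$label) + 1L)
  lut[leg$label + 1L] <- struct
  hits <- lut[as.vector(img$labels) + 1L]
  tab <- table(factor(hits, levels = germ_structures()))
  as.numeric(tab) / sum(tab)
}

# Brute-force maximum-likelihood logit fit by iterative grid refinement
# over (intercept, slope); independent of glm.
grid_logit_oracle <- function(len, y, a_range = c(-100, 100),
                              b_range = c(-15, 15), rounds = 9, k = 41) {
  loglik <- function(a, b) {
    eta <- a + b * len
    sum(y * eta - log1p(exp(eta)))
  }
  best <- c(mean(a_range), mean(b_range))
  for (r in seq_len(rounds)) {
    as <- seq(a_range[1], a_range[2], length.out = k)
    bs <- seq(b_range[1], b_range[2], length.out = k)
    ll <- outer(as, bs, Vectorize(loglik))
    idx <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(as[idx[1]], bs[idx[2]])
    da <- diff(a_range) / (k - 1); db <- diff(b_range) / (k - 1)
    a_range <- best[1] + c(-2, 2) * da
    b_range <- best[2] + c(-2, 2) * db
  }
  list(intercept = best[1], slope = best[2], loglik = loglik(best[1], best[2]))
}

# A small, overlapping (non-separated) maturity dataset for oracle tests.
small_maturity_data <- function() {
  data.frame(
    length = c(15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26),
    mature = c(0, 0, 0, 1, 0, 1, 0, 1, 1, 1, 1, 1)
  )
}
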