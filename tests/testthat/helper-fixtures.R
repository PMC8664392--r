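# Shared fixtures, built once per test run. Everything is generated in code;
# the simulator is the data source for all spectral/texture tests.

fix_acq <- acquisition_spec()
fix_pulse <- pulse_model()

# small phantom for normalization (5 frames, 18 x 9.6 mm, zero attenuation)
fix_refs <- make_reference_frames(fix_acq, fix_pulse, seed = 7L)

# coarse analysis config used in tests: same physics as the clinical
# protocol but a lighter window grid so suites stay fast
fix_cfg <- qus_config(overlap = 0.5)

# band-restricted normalized spectrum of a window of a simulated frame
fix_norm_spectrum <- function(frame, a0 = 151L, len = 300L,
                              band = c(4e6, 9e6)) {
  ps <- estimate_power_spectrum(frame$samples[a0:(a0 + len - 1L), ], fix_acq)
  ref <- qusrad:::.reference_spectrum(fix_refs, a0, len, fix_acq)
  normalize_spectrum(ps, ref, band = band)
}

# brute-force GLCM feature oracle: plain double loops, independent of the
# package implementation
oracle_glcm_features <- function(glcm) {
  ng <- nrow(glcm)
  con <- 0; ene <- 0; hom <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:ng) {
    mu_i <- mu_i + i * glcm[i, j]
    mu_j <- mu_j + j * glcm[i, j]
  }
  s_i <- 0; s_j <- 0; cov <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- glcm[i, j]
    con <- con + (i - j)^2 * p
    ene <- ene + p^2
    hom <- hom + p / (1 + abs(i - j))
    s_i <- s_i + (i - mu_i)^2 * p
    s_j <- s_j + (j - mu_j)^2 * p
    cov <- cov + (i - mu_i) * (j - mu_j) * p
  }
  cor <- if (s_i > 0 && s_j > 0) cov / sqrt(s_i * s_j) else 0
  c(con = con, cor = cor, ene = ene, hom = hom)
}

# brute-force symmetric normalized GLCM by pair enumeration
oracle_glcm <- function(lev, ng, angle, d = 1L) {
  off <- switch(as.character(angle),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
                "135" = c(-d, -d))
  m <- matrix(0, ng, ng)
  for (i in seq_len(nrow(lev))) for (j in seq_len(ncol(lev))) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 < 1 || i2 > nrow(lev) || j2 < 1 || j2 > ncol(lev)) next
    a <- lev[i, j]; b <- lev[i2, j2]
    if (is.na(a) || is.na(b)) next
    m[a, b] <- m[a, b] + 1
    m[b, a] <- m[b, a] + 1
  }
  m / sum(m)
}

# brute-force 1-NN LOOCV oracle with train-fold-only standardization
oracle_1nn_loocv <- function(x, y) {
  n <- length(x)
  sapply(seq_len(n), function(i) {
    tr <- x[-i]
    mu <- mean(tr); s <- stats::sd(tr); if (s == 0) s <- 1
    d <- abs((tr - mu) / s - (x[i] - mu) / s)
    y[-i][which.min(d)]
  })
}

# tiny RF cohort for end-to-end tests: small frames, fixed frame count
fix_mini_cohort <- function(n_r = 4L, n_nr = 5L, seed = 11L) {
  make_cohort(cohort_spec(n_recurrence = n_r, n_non_recurrence = n_nr,
                          frames_range = c(2L, 2L),
                          extent = c(0.012, 0.0064), seed = seed))
}
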