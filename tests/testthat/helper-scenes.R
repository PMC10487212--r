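# Shared fixture builders. Everything is generated in code; no binary data.

# Controlled optics: MC coupled only to 495/500 nm, CC negatively to 505 nm,
# SSC and TA spectrally silent. Band sigma 5 nm confines each response to
# about +/- 10 nm of its center.
controlled_optics <- function() {
  optics_model(bands = list(
    mc = data.frame(center = c(495, 500), width = c(5, 5),
                    amp = c(0.05, 0.05)),
    ssc = data.frame(center = numeric(0), width = numeric(0),
                     amp = numeric(0)),
    ta = data.frame(center = numeric(0), width = numeric(0),
                    amp = numeric(0)),
    cc = data.frame(center = 505, width = 5, amp = -0.06)))
}

# ROI spectra on the fused 420-1600 grid through a forward optics model,
# plus i.i.d. channel noise.
make_roi_spectra <- function(ref, optics, noise_sd = 0.002, seed = 1L) {
  grid <- seq(420, 1600, by = 5)
  chem <- list(mc = ref$mc_pct, ssc = ref$ssc_pct,
               ta = ref$ta_gpct, cc = ref$cc_mg100gdm)
  R <- forward_reflectance(optics, chem, grid)
  if (noise_sd > 0) {
    set.seed(seed)
    R <- R + matrix(stats::rnorm(length(R), 0, noise_sd), nrow(R))
  }
  colnames(R) <- sprintf("r%04d", grid)
  attr(R, "wavelengths") <- grid
  R
}

# a small affine distortion used across registration tests
test_affine <- function() {
  transform2d(matrix(c(1.04, 0.08, 3,
                       -0.05, 0.96, -2,
                       0, 0, 1), 3, 3, byrow = TRUE), "affine")
}

one_fruit_field <- function(seed = 1L, shape = c(160L, 160L),
                            mm_per_px = 1.0) {
  ref <- generate_reference_table(seed = seed)
  generate_chemistry_field(ref[ref$origin == 1 & ref$fruit == 1, ],
                           shape, mm_per_px)
}

# TRUE if every element of wl is within tol of some element of truth
all_near <- function(wl, truth, tol = 10) {
  all(vapply(wl, function(w) any(abs(w - truth) <= tol), logical(1)))
}

# naive quadratic-time RReliefF used as the independent oracle: literal
# per-instance loops, no vectorisation shared with the implementation
naive_rrelieff <- function(X, y, k = 10, sigma = 20) {
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) diff(range(v))); rng[rng == 0] <- 1
  Xn <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng, `/`)
  yn <- (y - min(y)) / diff(range(y))
  w_rank <- exp(-(seq_len(k) / sigma)^2); w_rank <- w_rank / sum(w_rank)
  NdY <- 0; NdF <- numeric(p); NdYdF <- numeric(p)
  for (i in seq_len(n)) {
    d <- rep(0, n)
    for (j in seq_len(n)) d[j] <- sum(abs(Xn[j, ] - Xn[i, ]))
    nb <- order(d)[2:(k + 1)]
    for (q in seq_len(k)) {
      j <- nb[q]
      dY <- abs(yn[j] - yn[i])
      NdY <- NdY + w_rank[q] * dY
      for (f in seq_len(p)) {
        dF <- abs(Xn[j, f] - Xn[i, f])
        NdF[f] <- NdF[f] + w_rank[q] * dF
        NdYdF[f] <- NdYdF[f] + w_rank[q] * dY * dF
      }
    }
  }
  NdYdF / NdY - (NdF - NdYdF) / (n - NdY)
}
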