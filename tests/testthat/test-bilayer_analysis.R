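# Leaflet assignment, insertion accounting, surface reconstruction,
# undulation spectra, bending-modulus fits, block averages.

test_that("leaflet assignment: flat, translated, and strongly bent bilayers", {
  cfg <- synthetic_bilayer_frame(n_side = 8, L = 8, d = 2)
  a <- assign_leaflets(cfg)
  expect_equal(as.integer(table(a$leaflet)), c(64, 64))
  expect_equal(as.character(a$leaflet), attr(cfg, "labels"))
  # rigid translation leaves the assignment unchanged
  sh <- cfg
  sh$positions[, 3] <- sh$positions[, 3] + 1
  expect_equal(assign_leaflets(sh)$leaflet, a$leaflet)
  # strongly bent (sinusoidal, amplitude 1.5 nm, thickness 4 nm)
  bent <- synthetic_bilayer_frame(n_side = 12, L = 12, d = 2, zmid = 6,
                                  hfun = function(x, y)
                                    1.5 * sin(2 * pi * x / 12))
  ab <- assign_leaflets(bent)
  expect_equal(as.character(ab$leaflet), attr(bent, "labels"))
  # bending larger than the half-thickness: the global-mean split breaks,
  # the grid-local midplane does not
  vbent <- synthetic_bilayer_frame(n_side = 16, L = 12, d = 2, zmid = 8,
                                   hfun = function(x, y)
                                     3 * sin(2 * pi * x / 12))
  expect_equal(as.character(assign_leaflets(vbent)$leaflet),
               attr(vbent, "labels"))
  ag <- assign_leaflets(vbent, method = "global")
  expect_gt(sum(as.character(ag$leaflet) != attr(vbent, "labels")), 0)
  # degenerate: all phosphates on one plane
  flat <- synthetic_bilayer_frame(n_side = 4, d = 0)
  expect_error(assign_leaflets(flat), "degenerate")
})

test_that("inserted-cation counting and the midplane tie-break", {
  # 38 ring beads between the surfaces of an 8x8-per-leaflet bilayer
  set.seed(2)
  cfg <- synthetic_bilayer_frame(n_side = 8, L = 8, d = 2, zmid = 5,
                                 cation_z = c(runif(38, 3.2, 6.8)))
  a <- assign_leaflets(cfg)
  row <- count_inserted_cations(cfg, a)
  expect_equal(row$lipids_upper, 64)
  expect_equal(row$inserted_upper + row$inserted_lower, 38)
  expect_equal(row$ratio_upper, row$inserted_upper / 64)
  # bulk cations count zero
  bulk <- synthetic_bilayer_frame(n_side = 8, L = 8, d = 2, zmid = 5,
                                  cation_z = rep(9.5, 10))
  ab <- assign_leaflets(bulk)
  rb <- count_inserted_cations(bulk, ab)
  expect_equal(rb$inserted_upper + rb$inserted_lower, 0)
  # a cation exactly on the midplane counts as upper (closed boundary)
  mid <- synthetic_bilayer_frame(n_side = 8, L = 8, d = 2, zmid = 5,
                                 cation_z = 5)
  am <- assign_leaflets(mid)
  rm_ <- count_inserted_cations(mid, am)
  expect_equal(rm_$inserted_upper, 1)
  expect_equal(rm_$inserted_lower, 0)
  # conserved under bead reordering and rigid translation
  set.seed(3)
  perm <- sample(nrow(cfg$positions))
  pm <- cfg
  pm$positions <- cfg$positions[perm, ]
  pm$topology <- cfg$topology[perm, ]
  rp <- count_inserted_cations(pm, assign_leaflets(pm))
  expect_equal(rp$ratio_upper, row$ratio_upper)
  tr <- cfg
  tr$positions[, 3] <- tr$positions[, 3] + 0.8
  rt <- count_inserted_cations(tr, assign_leaflets(tr))
  expect_equal(rt$ratio_upper, row$ratio_upper)
})

test_that("saturation detector: constant, logistic, and drifting series", {
  mk <- function(r) structure(list(time = seq_along(r) - 1,
                                   ratio_upper = r, ratio_lower = r * 0),
                              class = "insertion_series")
  s <- detect_saturation(mk(rep(0.6, 40)), window = 10)
  expect_true(s$saturated)
  expect_equal(s$saturation, 0.6)
  expect_equal(s$onset_frame, 1)
  # logistic rise to a known plateau, small noise
  set.seed(4)
  t <- 0:199
  p <- 0.61
  r <- p / (1 + exp(-(t - 60) / 12)) + rnorm(200, 0, 0.004)
  s2 <- detect_saturation(mk(r), window = 50)
  expect_true(s2$saturated)
  expect_lt(abs(s2$saturation - p) / p, 0.02)
  expect_gt(s2$onset_frame, 1)
  # strictly increasing series: no plateau
  s3 <- detect_saturation(mk(seq(0, 1, length.out = 60)), window = 20)
  expect_false(s3$saturated)
  expect_true(is.na(s3$saturation))
  expect_error(detect_saturation(mk(rep(0.5, 10)), window = 8), "twice")
})

test_that("surface reconstruction: flat, cosine, and hole filling", {
  flat <- synthetic_bilayer_frame(n_side = 16, L = 8, d = 2)
  a <- assign_leaflets(flat)
  s <- reconstruct_surface(flat, a, N = 16)
  expect_equal(max(abs(s$h)), 0)
  # dense lipid lattice sampling a single cosine mode
  L <- 16
  cos_frame <- synthetic_bilayer_frame(n_side = 64, L = L, d = 3, zmid = 8,
                                       hfun = function(x, y)
                                         cos(2 * pi * x / L))
  ac <- assign_leaflets(cos_frame)
  sc <- reconstruct_surface(cos_frame, ac, N = 32, leaflet = "upper")
  want <- cos(2 * pi * ((seq_len(64) - 0.5) / 64))
  # cell averages of the 64-point lattice (2 lipids per cell column)
  want32 <- colMeans(matrix(want, 2))
  expect_lt(max(abs(sweep(sc$h, 1, want32))), 1e-6)
  expect_equal(mean(sc$h), 0)
  # one missing cell in a flat surface fills to the neighbor mean
  one_gap <- synthetic_bilayer_frame(n_side = 8, L = 8, d = 2)
  drop <- which(one_gap$positions[, 3] > 6 &
                  one_gap$positions[, 1] < 1 & one_gap$positions[, 2] < 1)[1]
  keep <- setdiff(seq_len(nrow(one_gap$positions)), drop)
  gap <- system_configuration(one_gap$positions[keep, ],
                              one_gap$topology[keep, ], one_gap$box)
  ag <- assign_leaflets(gap)
  sg <- reconstruct_surface(gap, ag, N = 8)
  expect_equal(max(abs(sg$h)), 0) # filled to the flat value
  # too-coarse sampling for the grid -> resolution error
  sparse <- synthetic_bilayer_frame(n_side = 4, L = 8, d = 2)
  expect_error(reconstruct_surface(sparse, assign_leaflets(sparse), N = 32),
               "empty")
})

test_that("undulation spectrum: cosine mode, Parseval, z-offset invariance", {
  N <- 32; L <- 16; a <- 0.3
  x <- (seq_len(N) - 1) * L / N
  h <- outer(a * cos(2 * pi * x / L), rep(1, N))
  h <- h - mean(h)
  s <- undulation_surface(h, L)
  sp2 <- spectrum_2d(list(s))
  # closed-form Fourier coefficient: modes (+-1, 0) carry A a^2 / 4
  expect_equal(sp2$intensity[2, 1], L^2 * a^2 / 4, tolerance = 1e-10)
  expect_equal(sp2$intensity[N, 1], L^2 * a^2 / 4, tolerance = 1e-10)
  off_modes <- sp2$intensity
  off_modes[2, 1] <- off_modes[N, 1] <- 0
  expect_lt(max(off_modes[-1]), 1e-20)
  # radial spectrum: everything sits in the |k| = 1 bin
  rs <- undulation_spectrum(list(s))
  expect_equal(rs$q_values[1], 2 * pi / L)
  expect_true(all(rs$intensity[-1] < 1e-20))
  expect_gt(rs$intensity[1], 0)
  # Parseval: sum_q |h_q|^2 == mean square of h
  expect_equal(sum(sp2$intensity[-1]) / L^2 + sp2$intensity[1] / L^2,
               mean(h^2), tolerance = 1e-10)
  # all-zero surfaces give zero intensity
  z0 <- undulation_surface(matrix(0, N, N), L)
  expect_true(all(undulation_spectrum(list(z0))$intensity == 0))
  # uniform z-offset of the lipid field changes nothing (mean subtraction
  # happens at reconstruction); spectra of mean-centered surfaces shift-free
  expect_error(undulation_spectrum(list(s, undulation_surface(
    matrix(0, 16, 16), L))), "share")
})

test_that("bending fit inverts a manufactured Helfrich spectrum exactly", {
  kB <- 1.380649e-23
  Tk <- 303
  kappa0 <- 10e-20
  q <- seq(0.2, 0.9, length.out = 8)
  sp <- structure(list(q_values = q,
                       intensity = kB * Tk / (kappa0 * q^4),
                       stderr = rep(NA_real_, 8), n_modes = rep(4L, 8),
                       n_frames = 1), class = "fluctuation_spectrum")
  fit <- fit_bending_modulus(sp, temperature = Tk, q_max = 1.0)
  expect_equal(fit$kappa, kappa0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # doubling T at fixed spectrum halves kappa
  fit2 <- fit_bending_modulus(sp, temperature = 2 * Tk, q_max = 1.0)
  expect_equal(fit2$kappa, 2 * kappa0, tolerance = 1e-10)
  expect_error(fit_bending_modulus(sp, Tk, q_max = 0.25), ">= 3")
})

test_that("kappa recovery through the estimator chain and full lipid path", {
  spec <- helfrich_spec(kappa = 22.6e-20, temperature = 303, L = 25,
                        N = 32, n_frames = 500, seed = 101)
  fr <- sample_helfrich_surfaces(spec)
  fit <- fit_bending_modulus(undulation_spectrum(fr), 303, 1.0)
  expect_lt(abs(fit$kappa / 22.6e-20 - 1), 0.05)
  # fewer frames: looser bound, bias decreases with frames
  fit50 <- fit_bending_modulus(undulation_spectrum(fr[1:50]), 303, 1.0)
  expect_lt(abs(fit50$kappa / 22.6e-20 - 1), 0.15)
  # full path: sample lipid points from the surfaces, rebuild, refit
  set.seed(5)
  nlip <- 3000
  frames <- lapply(fr[1:120], function(s) {
    N <- 32
    xy <- cbind(runif(nlip, 0, s$L), runif(nlip, 0, s$L))
    ix <- floor(xy[, 1] / s$L * N) + 1; iy <- floor(xy[, 2] / s$L * N) + 1
    z <- 10 + s$h[cbind(pmin(ix, N), pmin(iy, N))]
    pos <- rbind(cbind(xy, z + 2), cbind(xy + 0.01, z - 2))
    top <- data.frame(molecule_id = seq_len(2 * nlip), species = "POPC",
                      bead_type = "PH")
    system_configuration(pos, top, c(s$L, s$L, 20))
  })
  surfaces <- lapply(frames, function(f) {
    a <- assign_leaflets(f)
    reconstruct_surface(f, a, N = 32, leaflet = "upper")
  })
  fit_full <- fit_bending_modulus(undulation_spectrum(surfaces), 303, 1.0)
  expect_lt(abs(fit_full$kappa / 22.6e-20 - 1), 0.10)
  # block-averaged errors behave
  bb <- bending_modulus_blocks(fr, 303, 1.0, n_blocks = 5)
  expect_length(bb$block_kappas, 5)
  expect_gt(bb$kappa_error, 0)
  expect_lt(abs(bb$kappa / 22.6e-20 - 1), 0.05)
})

test_that("block_average: constant, Gaussian, permutation in blocks", {
  ba <- block_average(rep(3.3, 50), 5)
  expect_equal(ba$mean, 3.3)
  expect_equal(ba$se, 0)
  set.seed(6)
  x <- rnorm(1e4, 2, 0.5)
  ba2 <- block_average(x, 10)
  expect_lt(abs(ba2$se / (0.5 / sqrt(1e4)) - 1), 0.5) # i.i.d. -> sigma/sqrt(n)
  # permuting within blocks leaves the mean untouched
  blocks <- attr(block_average(x, 10), "blocks")
  y <- x
  for (ix in blocks) y[ix] <- sample(y[ix])
  expect_equal(block_average(y, 10)$mean, ba2$mean)
  expect_error(block_average(x, 1), "n_blocks")
})
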