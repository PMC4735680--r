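# Mie/Coulomb energy model, pair-table validation, forces, neighbor list.

test_that("Mie forms vanish at sigma and have analytic minima of depth -eps", {
  for (form in c("9-6", "12-4")) {
    p <- mie_pair("A", "B", epsilon = 1.8, sigma = 0.47, form = form)
    expect_equal(mie_energy(0.47, p), 0)
    rmin <- if (form == "9-6") (3 / 2)^(1 / 3) * 0.47 else 3^(1 / 8) * 0.47
    expect_equal(mie_energy(rmin, p), -1.8, tolerance = 1e-12)
    # numeric minimization agrees with the analytic location
    opt <- optimize(function(r) mie_energy(r, p), c(0.3, 2), tol = 1e-10)
    expect_equal(opt$minimum, rmin, tolerance = 1e-5)
    expect_equal(opt$objective, -1.8, tolerance = 1e-9)
    # shape: single well, U -> 0- at large r
    r <- exp(seq(log(0.47), log(8), length.out = 400))
    u <- mie_energy(r, p)
    expect_true(all(u >= -1.8 - 1e-12))
    expect_lt(u[length(u)], 0)
    expect_gt(u[length(u)], -1e-3)
    sign_changes <- sum(diff(sign(diff(u))) != 0)
    expect_equal(sign_changes, 1) # one interior extremum on the grid
  }
  expect_error(mie_energy(0, mie_pair("A", "B", 1, 0.5)), "r must be > 0")
})

test_that("Coulomb energy follows f q1 q2 / (eps_r r)", {
  expect_equal(coulomb_energy(1, 1, 1, 16), 138.935485 / 16)
  expect_equal(coulomb_energy(2, 1, 1, 16), coulomb_energy(1, 1, 1, 16) / 2)
  expect_equal(coulomb_energy(0.7, 0, 1, 16), 0)
  expect_error(coulomb_energy(-1, 1, 1, 16), "r must be > 0")
  expect_error(coulomb_energy(1, 1, 1, 0), "dielectric")
})

test_that("parameter_set validates completeness, duplicates and form rule", {
  bts <- list(bead_type("A", 50, 0, "lipid-tail"),
              bead_type("W", 54, 0, "water"))
  ok <- list(mie_pair("A", "A", 1, 0.45), mie_pair("A", "W", 1, 0.46,
                                                   "12-4"),
             mie_pair("W", "W", 1, 0.47, "12-4"))
  expect_s3_class(parameter_set(bts, ok), "parameter_set")
  expect_error(parameter_set(bts, ok[1:2]), "incomplete")
  expect_error(parameter_set(bts, c(ok, ok[1])), "duplicate")
  bad <- ok
  bad[[2]] <- mie_pair("A", "W", 1, 0.46, "9-6")
  expect_error(parameter_set(bts, bad), "12-4")
  expect_error(parameter_set(bts, ok, cutoff = 0.4), "cutoff")
})

test_that("total nonbonded energy matches the brute-force oracle", {
  ps <- single_type_params(eps = 1.3, sigma = 0.45)
  # beyond cutoff -> 0
  expect_equal(total_nonbonded_energy(dimer_config(2.0), ps), 0)
  # 3-bead equilateral triangle = 3 x pairwise shifted value
  r <- 0.5
  pos <- rbind(c(2, 2, 2), c(2 + r, 2, 2),
               c(2 + r / 2, 2 + r * sqrt(3) / 2, 2))
  top <- data.frame(molecule_id = 1:3, species = "M", bead_type = "X")
  cfg <- system_configuration(pos, top, c(6, 6, 6))
  pairv <- mie_energy(r, ps$pairs[[1]]) - mie_energy(1.5, ps$pairs[[1]])
  expect_equal(total_nonbonded_energy(cfg, ps), 3 * pairv,
               tolerance = 1e-12)
  expect_equal(total_nonbonded_energy(cfg, ps), brute_force_energy(cfg, ps),
               tolerance = 1e-12)
  # mixed charged types against the oracle
  psq <- example_parameter_set()
  cfg2 <- random_config(40, box = c(4, 4, 4),
                        types = c("CT", "RG", "CL", "NA", "W"), seed = 7,
                        species = "ION")
  expect_equal(total_nonbonded_energy(cfg2, psq),
               brute_force_energy(cfg2, psq), tolerance = 1e-10)
  cfg3 <- cfg2
  cfg3$topology$bead_type[1] <- "ZZ"
  expect_error(total_nonbonded_energy(cfg3, psq), "not in parameter set")
})

test_that("energy is invariant under rigid translation and bead relabeling", {
  ps <- example_parameter_set()
  cfg <- random_config(30, box = c(4, 4, 4), types = c("CT", "RG", "CL"),
                       seed = 3)
  e0 <- total_nonbonded_energy(cfg, ps)
  sh <- cfg
  sh$positions <- wrap_positions(sweep(cfg$positions, 2, c(1.3, -0.7, 2.1),
                                       `+`), cfg$box)
  expect_equal(total_nonbonded_energy(sh, ps), e0, tolerance = 1e-10)
  set.seed(9)
  perm <- sample(30)
  pm <- cfg
  pm$positions <- cfg$positions[perm, ]
  pm$topology <- cfg$topology[perm, ]
  expect_equal(total_nonbonded_energy(pm, ps), e0, tolerance = 1e-10)
})

test_that("pair table is symmetric: energy(a,b) == energy(b,a)", {
  ps <- example_parameter_set()
  tn <- names(ps$bead_types)
  for (a in tn) for (b in tn) {
    top <- data.frame(molecule_id = 1:2, species = "M",
                      bead_type = c(a, b))
    cfg <- system_configuration(rbind(c(3, 3, 3), c(3.6, 3, 3)), top,
                                c(8, 8, 8))
    top2 <- top
    top2$bead_type <- c(b, a)
    cfg2 <- cfg
    cfg2$topology <- top2
    expect_equal(total_nonbonded_energy(cfg, ps),
                 total_nonbonded_energy(cfg2, ps), tolerance = 1e-14)
  }
})

test_that("analytic forces agree with central differences", {
  ps <- example_parameter_set()
  cfg <- random_config(20, box = c(4, 4, 4),
                       types = c("CT", "RG", "CL", "W"), seed = 5)
  f <- compute_forces(cfg, ps)
  expect_lt(max(abs(colSums(f))), 1e-9) # net force of isolated system
  h <- 1e-6
  for (i in c(1, 7, 15)) for (d in 1:3) {
    cp <- cfg; cp$positions[i, d] <- cp$positions[i, d] + h
    cm <- cfg; cm$positions[i, d] <- cm$positions[i, d] - h
    fd <- -(total_energy(cp, ps) - total_energy(cm, ps)) / (2 * h)
    expect_equal(f[i, d], fd,
                 tolerance = 1e-4 * max(1, abs(f[i, d])))
  }
  # dimer at the Mie minimum: stationary point
  psx <- single_type_params(eps = 2, sigma = 0.45)
  dm <- dimer_config((3 / 2)^(1 / 3) * 0.45)
  expect_lt(max(abs(compute_forces(dm, psx))), 1e-8)
  # isolated bead
  one <- system_configuration(matrix(c(2, 2, 2), 1, 3),
                              data.frame(molecule_id = 1, species = "M",
                                         bead_type = "X"), c(6, 6, 6))
  expect_equal(compute_forces(one, psx), matrix(0, 1, 3))
})

test_that("bonded terms contribute energy and consistent forces", {
  ps <- single_type_params(eps = 0, sigma = 0.45)
  ps$bonded$TRI <- list(bonded_term("bond", c(1, 2), 0.5, 1000),
                        bonded_term("bond", c(2, 3), 0.5, 1000),
                        bonded_term("angle", c(1, 2, 3), 120, 50))
  pos <- rbind(c(2, 2, 2), c(2.6, 2, 2), c(2.9, 2.5, 2))
  top <- data.frame(molecule_id = rep(1, 3), species = "TRI",
                    bead_type = "X")
  cfg <- system_configuration(pos, top, c(6, 6, 6))
  e <- total_energy(cfg, ps)
  expect_gt(e, 0)
  f <- compute_forces(cfg, ps)
  h <- 1e-6
  for (i in 1:3) for (d in 1:3) {
    cp <- cfg; cp$positions[i, d] <- cp$positions[i, d] + h
    cm <- cfg; cm$positions[i, d] <- cm$positions[i, d] - h
    fd <- -(total_energy(cp, ps) - total_energy(cm, ps)) / (2 * h)
    expect_equal(f[i, d], fd, tolerance = 1e-4 * max(1, abs(f[i, d])))
  }
  # 1-2 and 1-3 neighbors are excluded from the nonbonded sum
  ps2 <- single_type_params(eps = 5, sigma = 0.45)
  ps2$bonded$TRI <- ps$bonded$TRI
  expect_equal(total_nonbonded_energy(cfg, ps2), 0)
})

test_that("neighbor list matches brute-force enumeration", {
  cutoff <- 1.0; skin <- 0.2
  cfg <- dimer_config(0.9 * cutoff)
  expect_equal(nrow(build_neighbor_list(cfg, cutoff, skin)), 1)
  cfg2 <- dimer_config(1.1 * (cutoff + skin))
  expect_equal(nrow(build_neighbor_list(cfg2, cutoff, skin)), 0)
  # 100 random beads, cell-list path (box admits 4 cells/edge)
  cfg3 <- random_config(100, box = c(5, 5, 5), seed = 11)
  nl <- build_neighbor_list(cfg3, cutoff, skin)
  bf <- brute_force_pairs(cfg3, cutoff + skin)
  expect_equal(nl, bf[order(bf[, 1], bf[, 2]), , drop = FALSE],
               ignore_attr = TRUE)
  # every within-cutoff pair is present
  within <- brute_force_pairs(cfg3, cutoff)
  key <- function(m) paste(m[, 1], m[, 2])
  expect_true(all(key(within) %in% key(nl)))
})

test_that("cell-list and brute-force energies agree on a dense system", {
  ps <- example_parameter_set()
  cfg <- random_config(200, box = c(6, 6, 6),
                       types = c("CT", "GL", "NC", "PH"), seed = 13)
  expect_equal(total_nonbonded_energy(cfg, ps),
               brute_force_energy(cfg, ps),
               tolerance = 1e-10)
})

test_that("GRO round trip preserves coordinates to format precision", {
  cfg <- random_config(25, box = c(5, 5, 6), types = c("CT", "PH"),
                       seed = 2)
  cfg$velocities <- matrix(rnorm(75, sd = 0.3), 25, 3)
  path <- tempfile(fileext = ".gro")
  write_gro(cfg, path, time = 12.5)
  back <- read_gro(path)
  expect_length(back, 1)
  expect_lt(max(abs(back[[1]]$positions - cfg$positions)), 5.01e-4)
  expect_lt(max(abs(back[[1]]$velocities - cfg$velocities)), 5.01e-5)
  expect_equal(back[[1]]$box, cfg$box, tolerance = 1e-5)
  expect_equal(attr(back[[1]], "time"), 12.5)
  expect_equal(back[[1]]$topology$bead_type, cfg$topology$bead_type)
  # velocities absent
  cfg$velocities <- NULL
  write_gro(cfg, path)
  expect_null(read_gro(path)[[1]]$velocities)
  # empty file -> empty frame list
  writeLines(character(0), path)
  expect_length(read_gro(path), 0)
  # malformed columns flagged with a line number
  writeLines(c("title", "2", "bad line", "also bad", "1 1 1"), path)
  expect_error(read_gro(path), "malformed|columns")
})
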