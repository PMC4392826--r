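test_that("the 3-bead chain gives the path-graph Kirchhoff matrix", {
  K <- build_kirchhoff(three_bead_trace(), enm_params(cutoff = 7.0))
  expect_equal(unname(K$matrix),
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, byrow = TRUE))
  expect_equal(unname(rowSums(K$matrix)), c(0, 0, 0))
})

test_that("residues beyond the cutoff stay unconnected, with a warning", {
  tr <- calpha_trace(resnum = 1:2, aa = "ALA", x = c(0, 8), y = 0, z = 0)
  expect_warning(K <- build_kirchhoff(tr, enm_params(cutoff = 7.0)),
                 "no contacts")
  expect_true(all(K$contacts == 0))
  expect_true(all(K$matrix == 0))
})

test_that("contact matrices match a brute-force distance check", {
  for (seed in c(2, 5, 8)) {
    tr <- random_trace(50, seed)
    K <- suppressWarnings(build_kirchhoff(tr, enm_params(cutoff = 7.0)))
    xyz <- as.matrix(as.data.frame(tr)[, c("x", "y", "z")])
    expect_equal(unname(K$contacts), brute_contacts(xyz, 7.0))
    expect_equal(unname(rowSums(K$matrix)), rep(0, 50))
  }
})

test_that("analytic spectra are reproduced", {
  # path graph on 3 nodes: eigenvalues 0, 1, 3
  sp3 <- eigendecompose(build_kirchhoff(three_bead_trace()))
  expect_equal(sp3$values, c(0, 1, 3), tolerance = 1e-12)
  # regular tetrahedron, side 3.8: complete graph K4, eigenvalues 0, 4, 4, 4
  s <- 3.8
  tet <- calpha_trace(resnum = 1:4, aa = "ALA",
                      x = s * c(0, 1, 0.5, 0.5),
                      y = s * c(0, 0, sqrt(3) / 2, sqrt(3) / 6),
                      z = s * c(0, 0, 0, sqrt(2 / 3)))
  sp4 <- eigendecompose(build_kirchhoff(tet))
  expect_equal(sp4$values, c(0, 4, 4, 4), tolerance = 1e-12)
  expect_equal(sp4$n_zero_modes, 1L)
})

test_that("eigenvectors are orthonormal and zero modes count components", {
  for (seed in c(3, 9)) {
    tr <- random_trace(40, seed)
    K <- suppressWarnings(build_kirchhoff(tr))
    sp <- eigendecompose(K)
    expect_lt(max(abs(crossprod(sp$vectors) - diag(40))), 1e-8)
    expect_equal(sp$n_zero_modes, n_components(unname(K$contacts)))
    # positive semidefinite
    expect_gt(min(sp$values), -1e-8 * max(sp$values))
  }
})

test_that("all-nonzero correlation equals the Moore-Penrose pseudo-inverse", {
  tr <- generate_synthetic_trace(30, "helix", noise_sd = 0.2, seed = 13)
  K <- build_kirchhoff(tr)
  sp <- eigendecompose(K)
  M <- mode_restricted_inverse(sp, "all-nonzero", kT = 1)
  G <- K$matrix
  # pseudo-inverse identities
  expect_equal(G %*% unclass(M) %*% G, G, tolerance = 1e-6)
  expect_equal(unclass(M) %*% G %*% unclass(M), unclass(M), tolerance = 1e-6,
               ignore_attr = TRUE)
  # independent oracle
  expect_equal(unclass(M), MASS::ginv(G), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("a single selected mode yields a rank-1 symmetric matrix", {
  sp <- eigendecompose(build_kirchhoff(generate_synthetic_trace(
    20, "helix", noise_sd = 0.1, seed = 2)))
  M <- mode_restricted_inverse(sp, "fastest:1")
  expect_equal(unclass(M), t(unclass(M)))
  expect_equal(qr(unclass(M))$rank, 1L)
})

test_that("mode selection is validated", {
  sp <- eigendecompose(build_kirchhoff(three_bead_trace()))
  expect_error(mode_restricted_inverse(sp, "fastest:3"), "only 2 nonzero")
  expect_error(enm_params(mode_selection = "bogus"), "invalid mode selection")
  # fastest:k takes the k largest eigenvalues
  M1 <- mode_restricted_inverse(sp, "fastest:1")
  u <- sp$vectors[, 3]
  expect_equal(unclass(M1), (u %*% t(u)) / sp$values[3], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("predicted B-factors follow B = (8 pi^2 / 3) msf", {
  sp <- eigendecompose(build_kirchhoff(generate_synthetic_trace(
    15, "helix", noise_sd = 0.1, seed = 6)))
  M <- mode_restricted_inverse(sp, "all-nonzero")
  bf <- predicted_bfactors(M)
  expect_equal(bf$b_pred, (8 * pi^2 / 3) * bf$msf)
  expect_equal(bf$b_pred / bf$msf, rep(8 * pi^2 / 3, 15))
})

test_that("B-factor correlation is invariant to gamma and kT scales", {
  tr <- generate_synthetic_trace(25, "helix", noise_sd = 0.2, seed = 17,
                                 b_factors = NULL)
  b_exp <- seq(5, 29) + rep_len(c(2, -1), 25)  # synthetic experimental column
  r <- sapply(list(c(1, 1), c(3, 1), c(1, 0.5), c(2.5, 4)), function(gk) {
    K <- build_kirchhoff(tr, enm_params(gamma = gk[1], kT = gk[2]))
    M <- mode_restricted_inverse(eigendecompose(K), "all-nonzero",
                                 kT = gk[2])
    attr(predicted_bfactors(M, b_exp), "pearson")
  })
  expect_equal(r, rep(r[1], 4), tolerance = 1e-12)
  # least-squares scaling maps onto the experimental column
  K <- build_kirchhoff(tr)
  bf <- predicted_bfactors(mode_restricted_inverse(eigendecompose(K),
                                                   "all-nonzero"), b_exp)
  s <- attr(bf, "scale")
  expect_equal(sum(b_exp * bf$b_pred) / sum(bf$b_pred^2), s)
  expect_equal(bf$b_scaled, bf$b_pred * s)
})

test_that("distance fluctuations are symmetric, zero on the diagonal, and
           match the explicit pseudo-inverse", {
  K <- build_kirchhoff(three_bead_trace())
  M <- mode_restricted_inverse(eigendecompose(K), "all-nonzero")
  expect_equal(distance_fluctuation(M, 2, 2), 0)
  expect_equal(distance_fluctuation(M, 1, 2), distance_fluctuation(M, 2, 1))
  P <- MASS::ginv(K$matrix)
  expect_equal(distance_fluctuation(M, 2, 3),
               P[2, 2] - 2 * P[2, 3] + P[3, 3], tolerance = 1e-10)
  expect_error(distance_fluctuation(M, 1, 4), "out of range")
})

test_that("energy response is symmetric for the mirror-symmetric chain and
           non-negative everywhere", {
  K <- build_kirchhoff(three_bead_trace())
  M <- mode_restricted_inverse(eigendecompose(K), "all-nonzero")
  prof <- energy_response_profile(M, K)
  expect_equal(prof$energy_response[1], prof$energy_response[3])
  for (seed in c(1, 4)) {
    tr <- random_trace(35, seed)
    K <- suppressWarnings(build_kirchhoff(tr))
    sp <- eigendecompose(K)
    sel <- paste0("fastest:", min(5, 35 - sp$n_zero_modes))
    prof <- energy_response_profile(mode_restricted_inverse(sp, sel), K)
    expect_true(all(prof$energy_response >= 0))
  }
})

test_that("the profile equals a literal double-loop over the distance
           fluctuation formula", {
  tr <- generate_synthetic_trace(30, "helix", noise_sd = 0.2, seed = 19)
  K <- build_kirchhoff(tr)
  M <- mode_restricted_inverse(eigendecompose(K), "fastest:5")
  prof <- energy_response_profile(M, K)
  expect_equal(prof$energy_response,
               brute_energy_response(unclass(M), unname(K$contacts)),
               tolerance = 1e-12)
})

test_that("dimension mismatch between corr and Kirchhoff is an error", {
  K1 <- build_kirchhoff(generate_synthetic_trace(10, "helix", seed = 1))
  K2 <- build_kirchhoff(generate_synthetic_trace(12, "helix", seed = 1))
  M2 <- mode_restricted_inverse(eigendecompose(K2), "all-nonzero")
  expect_error(energy_response_profile(M2, K1), "dimensions differ")
})

test_that("profiles are invariant to rigid translation and rotation", {
  tr <- generate_synthetic_trace(24, "helix", noise_sd = 0.2, seed = 23)
  base <- enm_profile(tr)
  shift <- tr
  shift$x <- tr$x + 11.5; shift$y <- tr$y - 3.2; shift$z <- tr$z + 0.7
  expect_equal(enm_profile(shift)$energy_response, base$energy_response,
               tolerance = 1e-9)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(as.data.frame(tr)[, c("x", "y", "z")]) %*% R
  rot <- calpha_trace(resnum = tr$resnum, aa = tr$aa, x = xyz[, 1],
                      y = xyz[, 2], z = xyz[, 3])
  expect_equal(enm_profile(rot)$energy_response, base$energy_response,
               tolerance = 1e-9)
})

test_that("doubling gamma halves every msf and energy response", {
  tr <- generate_synthetic_trace(20, "helix", noise_sd = 0.2, seed = 29)
  p1 <- enm_profile(tr, enm_params(gamma = 1))
  p2 <- enm_profile(tr, enm_params(gamma = 2))
  expect_equal(p2$msf, p1$msf / 2, tolerance = 1e-12)
  expect_equal(p2$energy_response, p1$energy_response / 2,
               tolerance = 1e-12)
})

test_that("trace identity: sum of msf equals kT times sum of reciprocal
           selected eigenvalues", {
  tr <- generate_synthetic_trace(28, "helix", noise_sd = 0.2, seed = 31)
  sp <- eigendecompose(build_kirchhoff(tr, enm_params(kT = 2)))
  for (sel in c("all-nonzero", "fastest:5", "slowest:3")) {
    M <- mode_restricted_inverse(sp, sel, kT = 2)
    modes <- attr(M, "modes_used")
    expect_equal(sum(diag(unclass(M))), 2 * sum(1 / sp$values[modes]),
                 tolerance = 1e-10)
  }
})

test_that("full-spectrum fluctuations agree with an independent GNM
           implementation up to the overall scale", {
  skip_if_not_installed("bio3d")
  tr0 <- generate_synthetic_trace(40, "helix", noise_sd = 0.2, seed = 11)
  f <- tempfile(fileext = ".pdb")
  writeLines(strsplit(pdb_from_coords(tr0$resnum, tr0$x, tr0$y, tr0$z),
                      "\n")[[1]], f)
  ref <- suppressWarnings(bio3d::gnm(bio3d::read.pdb(f, verbose = FALSE),
                                     cutoff = 7.0))
  tr <- read_calpha_trace(f, "A")  # same rounded coordinates both routes
  M <- mode_restricted_inverse(
    eigendecompose(build_kirchhoff(tr, enm_params(cutoff = 7.0))),
    "all-nonzero")
  msf <- diag(unclass(M))
  ratio <- msf / ref$fluctuations
  expect_equal(stats::cor(msf, ref$fluctuations), 1, tolerance = 1e-9)
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
})
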