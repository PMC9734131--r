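test_that("superposition is exact on rigid copies and rejects degenerate input", {
  set.seed(3)
  ref <- matrix(rnorm(30, sd = 5), 10, 3)
  mob <- random_rigid(ref, seed = 4)
  sp <- superpose(mob, ref, seq_len(10))
  expect_lt(sp$rmsd, 1e-8)
  expect_lt(max(abs(sp$xyz - ref)), 1e-7)
  sp_id <- superpose(ref, ref, seq_len(10))
  expect_lt(sp_id$rmsd, 1e-12)
  expect_equal(sp_id$rotation, diag(3), tolerance = 1e-9)
  collinear <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(collinear, collinear, 1:5), "degenerate")
  expect_error(superpose(ref[1:2, ], ref[1:2, ], 1:2), "3 atoms")
})

test_that("superposition matches a rotation-grid brute force and bio3d", {
  set.seed(5)
  p <- matrix(rnorm(12, sd = 3), 4, 3)
  q <- p %*% matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3) +
    matrix(rnorm(12, sd = 0.4), 4, 3)
  sp <- superpose(p, q, 1:4)
  oracle <- oracle_grid_superpose(p, q)
  expect_lt(abs(sp$rmsd - oracle), 1e-3)
  expect_lte(sp$rmsd, oracle + 1e-9)  # closed form attains the minimum
  # independent cross-check against bio3d's Kabsch fit
  big <- matrix(rnorm(60, sd = 4), 20, 3)
  big2 <- random_rigid(big, seed = 6) + matrix(rnorm(60, sd = 0.3), 20, 3)
  fitted <- bio3d::fit.xyz(as.vector(t(big)), as.vector(t(big2)),
                           fixed.inds = 1:60, mobile.inds = 1:60)
  rmsd_bio3d <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) -
                                   big)^2)))
  expect_equal(superpose(big2, big, 1:20)$rmsd, rmsd_bio3d, tolerance = 1e-6)
  # fitting can never be worse than no transform at all
  expect_lte(sp$rmsd, sqrt(mean(rowSums((p - q)^2))))
})

test_that("region RMSD measures displacement after a core fit", {
  sys <- gen_toy_system(seed = 2)
  atoms <- sys$atoms
  fit_sel <- selection(sys$core_residues, "CA")
  mea_sel <- selection(sys$mobile_residues, "backbone")
  expect_equal(region_rmsd(sys$xyz_A, sys$xyz_A, fit_sel, mea_sel, atoms), 0)
  # rigid 10 A displacement of the measure region only
  b <- sys$xyz_A
  idx <- resolve_selection(atoms, selection(sys$mobile_residues, "all"))
  b[idx, 1] <- b[idx, 1] + 10
  expect_equal(region_rmsd(sys$xyz_A, b, fit_sel, mea_sel, atoms), 10,
               tolerance = 1e-9)
  # decomposed oracle: transform with bio3d, then measure
  set.seed(8)
  pert <- sys$xyz_B + matrix(rnorm(length(sys$xyz_B), sd = 0.2), ncol = 3)
  v <- region_rmsd(sys$xyz_A, pert, fit_sel, mea_sel, atoms)
  fi <- resolve_selection(atoms, fit_sel)
  mi <- resolve_selection(atoms, mea_sel)
  xyz_ind <- function(i) as.vector(rbind(3 * i - 2, 3 * i - 1, 3 * i))
  moved <- bio3d::fit.xyz(as.vector(t(sys$xyz_A)), as.vector(t(pert)),
                          fixed.inds = xyz_ind(fi), mobile.inds = xyz_ind(fi))
  moved <- matrix(moved, ncol = 3, byrow = TRUE)
  expect_equal(v, sqrt(mean(rowSums((moved[mi, ] - sys$xyz_A[mi, ])^2))),
               tolerance = 1e-6)
})

test_that("pairwise RMSD matrices are symmetric, zero-diagonal and permutable", {
  sys <- gen_toy_system(seed = 3)
  ens <- gen_reference_ensemble(sys, "A", n_models = 6, coord_noise = 0.4,
                                seed = 9)
  fit_sel <- selection(sys$core_residues, "CA")
  mea_sel <- selection(sys$mobile_residues, "backbone")
  m <- pairwise_rmsd_matrix(ens, fit_sel, mea_sel)
  expect_equal(m, t(m), tolerance = 1e-9)
  expect_equal(diag(m), rep(0, 6))
  expect_equal(m[2, 5], region_rmsd(ens$models[[2]], ens$models[[5]],
                                    fit_sel, mea_sel, ens$atoms))
  perm <- c(3, 1, 6, 2, 5, 4)
  ens_p <- conformer_ensemble(ens$models[perm], ens$atoms)
  m_p <- pairwise_rmsd_matrix(ens_p, fit_sel, mea_sel)
  expect_equal(m_p, m[perm, perm], tolerance = 1e-9)
  # n identical copies give the all-zero matrix
  ens_same <- conformer_ensemble(rep(ens$models[1], 4), ens$atoms)
  expect_equal(max(pairwise_rmsd_matrix(ens_same, fit_sel, mea_sel)), 0,
               tolerance = 1e-9)
})

test_that("Ward clustering recovers constructed clouds with correct medoids", {
  sys <- gen_toy_system(seed = 4)
  ens_a <- gen_reference_ensemble(sys, "A", 10, 0.3, seed = 11)
  ens_b <- gen_reference_ensemble(sys, "B", 10, 0.3, seed = 12)
  mix <- conformer_ensemble(c(ens_a$models, ens_b$models), sys$atoms)
  m <- pairwise_rmsd_matrix(mix, selection(sys$core_residues, "CA"),
                            selection(sys$mobile_residues, "backbone"))
  cl <- ward_cluster(m)
  expect_equal(cl$n_clusters, 2)
  expect_length(unique(cl$labels[1:10]), 1)
  expect_length(unique(cl$labels[11:20]), 1)
  expect_false(cl$labels[1] == cl$labels[11])
  for (ci in 1:2) {
    members <- which(cl$labels == ci)
    expected_medoid <- members[which.min(rowSums(m[members, members]))]
    expect_equal(cl$centroids[ci], expected_medoid)
    expect_equal(cl$spreads[ci], mean(m[members, cl$centroids[ci]]))
  }
  # fixed k = n gives singletons with zero spread
  cl_n <- ward_cluster(m, n_clusters = 20)
  expect_equal(cl_n$n_clusters, 20)
  expect_equal(max(cl_n$spreads), 0)
  # the all-zero matrix is one cluster with zero spread
  cl0 <- ward_cluster(matrix(0, 5, 5))
  expect_equal(cl0$n_clusters, 1)
  expect_equal(cl0$spreads, 0)
  expect_error(ward_cluster(matrix(0, 1, 1)), "2 models")
  expect_error(ward_cluster(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("RMSF profiles isolate local fluctuations and ignore global motion", {
  sys <- gen_toy_system(seed = 5)
  ens_same <- conformer_ensemble(rep(list(sys$xyz_A), 5), sys$atoms)
  prof0 <- rmsf_profile(ens_same, selection(sys$core_residues, "CA"))
  expect_equal(max(prof0$rmsf), 0, tolerance = 1e-9)
  # jitter a single residue's atoms with isotropic noise of std s
  s <- 0.4
  target <- 20
  set.seed(13)
  idx <- which(sys$atoms$resno == target)
  models <- lapply(1:400, function(i) {
    m <- sys$xyz_A
    m[idx, ] <- m[idx, ] + matrix(rnorm(3 * length(idx), 0, s), ncol = 3)
    m
  })
  ens_j <- conformer_ensemble(models, sys$atoms)
  fit_res <- setdiff(sys$core_residues, target)
  prof <- rmsf_profile(ens_j, selection(fit_res, "CA"))
  expect_equal(prof$rmsf[prof$resno == target], s * sqrt(3), tolerance = 0.1)
  expect_lt(max(prof$rmsf[prof$resno != target]), 0.1)
  # a global rigid transform of every model changes nothing
  models_rot <- lapply(models, random_rigid, seed = 14)
  prof_rot <- rmsf_profile(conformer_ensemble(models_rot, sys$atoms),
                           selection(fit_res, "CA"))
  expect_equal(prof_rot$rmsf, prof$rmsf, tolerance = 1e-6)
})
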