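# Geometric descriptors: superposition, RMSD, RMSF, Rg, clustering,
# site RMSD and the apo-resemblance filter.

test_that("kabsch_superpose recovers rigid motions and matches the grid oracle", {
  set.seed(11)
  ref <- matrix(rnorm(12, sd = 3), ncol = 3)

  ident <- kabsch_superpose(ref, ref)
  expect_equal(ident$rmsd, 0, tolerance = 1e-10)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-8)

  shifted <- sweep(ref, 2, c(5, 0, 0), "+")
  tr <- kabsch_superpose(shifted, ref)
  expect_equal(tr$translation, c(-5, 0, 0), tolerance = 1e-8)
  expect_equal(tr$rmsd, 0, tolerance = 1e-10)

  # rotated + translated + noisy copies vs the exhaustive rotation grid
  for (rep in 1:3) {
    set.seed(rep)
    n <- sample(4:6, 1)
    a <- matrix(rnorm(3 * n, sd = 2), ncol = 3)
    R <- mdtriage:::.rotation_matrix(rnorm(3), runif(1, 10, 170))
    b <- sweep(a %*% R, 2, rnorm(3, sd = 3), "+") +
      matrix(rnorm(3 * n, sd = 0.1), ncol = 3)
    fit <- kabsch_superpose(b, a)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
    oracle <- grid_min_rmsd(b, a)
    expect_lte(abs(fit$rmsd - oracle), 1e-3)
    expect_lte(fit$rmsd, oracle + 1e-9)   # SVD route is never worse
  }

  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("rmsd_series is zero for rigid motions and matches the direct formula", {
  base <- make_toy_structure(10, seed = 4)
  sel <- select_atoms(base, "backbone")

  static <- md_trajectory(base, rep(list(base$xyz), 4))
  expect_equal(rmsd_series(static, sel)$values, rep(0, 4), tolerance = 1e-10)

  drift <- simulate_trajectory(base, sim_spec(n_frames = 6, sigma = 0,
                                              drift_angle = 5,
                                              drift_translation = c(1, 0, 0),
                                              seed = 1))
  rs <- rmsd_series(drift, sel)
  expect_equal(rs$values, rep(0, 6), tolerance = 1e-6)
  expect_equal(rs$values[rs$reference_frame], 0, tolerance = 1e-10)

  # one atom displaced by 1 A among N = 10 calc atoms, exact fit unchanged:
  # RMSD = 1/sqrt(10)
  ca <- select_atoms(base, "protein", resname = "GLY")  # not used for fit
  calc <- select_atoms(base, "backbone")[1:10]
  f2 <- base$xyz
  f2[calc[4], ] <- f2[calc[4], ] + c(1, 0, 0)
  # fit on atoms far from the displacement, themselves identical
  fit_idx <- structure(seq(nrow(base$xyz) - 11, nrow(base$xyz)),
                       class = "atom_selection")
  traj2 <- md_trajectory(base, list(base$xyz, f2))
  rs2 <- rmsd_series(traj2, fit_idx, calc)
  expect_equal(rs2$values[2], 1 / sqrt(10), tolerance = 1e-9)

  expect_error(rmsd_series(static, integer(0)), "empty")
})

test_that("rmsd and rg are invariant under a global rigid motion", {
  base <- make_toy_structure(8, seed = 5)
  traj <- simulate_trajectory(base, sim_spec(n_frames = 5, sigma = 0.6,
                                             seed = 2))
  sel <- select_atoms(base, "backbone")
  moved <- md_trajectory(base, lapply(traj$frames, rigid_move))
  expect_equal(rmsd_series(moved, sel)$values, rmsd_series(traj, sel)$values,
               tolerance = 1e-6)
  expect_equal(radius_of_gyration(moved, sel)$series,
               radius_of_gyration(traj, sel)$series, tolerance = 1e-6)
})

test_that("radius of gyration matches closed forms", {
  at <- data.frame(serial = 1:2, name = c("CA", "CA"),
                   element = c("C", "C"), resno = 1:2,
                   resname = "ALA", chain = "A")
  two <- md_structure(at, rbind(c(0, 0, 0), c(2, 0, 0)))
  sel <- structure(1:2, class = "atom_selection")
  expect_equal(radius_of_gyration(md_trajectory(two, list(two$xyz)),
                                  sel)$mean, 1.0)

  same <- md_structure(at, rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(radius_of_gyration(md_trajectory(same, list(same$xyz)),
                                  sel)$mean, 0)

  cube <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  at8 <- data.frame(serial = 1:8, name = "CA", element = "C", resno = 1:8,
                    resname = "ALA", chain = "A")
  s8 <- md_structure(at8, cube)
  rg <- radius_of_gyration(md_trajectory(s8, list(cube)),
                           structure(1:8, class = "atom_selection"))
  expect_equal(rg$mean, sqrt(3), tolerance = 1e-12)
  expect_equal(rg$range, rg$maximum - rg$minimum)
  expect_equal(rg$width, rg$range)
  expect_error(radius_of_gyration(md_trajectory(s8, list(cube)),
                                  integer(0)), "empty")
})

test_that("rmsf recovers planted isotropic and per-residue amplitudes", {
  base <- make_toy_structure(12, seed = 6)
  # isotropic sigma = 0.5 A per axis -> per-atom RMSF = sqrt(3)*0.5
  traj <- simulate_trajectory(base, sim_spec(n_frames = 5000, sigma = 0.5,
                                             seed = 3))
  prof <- rmsf_per_residue(traj)
  atom_rmsf <- attr(prof, "atom_rmsf")
  expect_equal(mean(atom_rmsf), sqrt(3) * 0.5, tolerance = 0.05)
  # individual atoms wobble more (finite sampling + the 6 rigid DOF the
  # alignment absorbs); allow 10% per atom
  expect_true(all(abs(atom_rmsf - sqrt(3) * 0.5) / (sqrt(3) * 0.5) < 0.10))
  expect_equal(prof$mean_rmsf,
               rowMeans(cbind(prof$backbone_rmsf, prof$side_chain_rmsf),
                        na.rm = TRUE))

  # a residue with twice the amplitude shows ~2x the mean RMSF
  sig <- stats::setNames(rep(0.4, 12), 1:12)
  sig["6"] <- 0.8
  traj2 <- simulate_trajectory(base, sim_spec(n_frames = 4000, sigma = sig,
                                              seed = 4))
  prof2 <- rmsf_per_residue(traj2)
  ratio <- prof2$mean_rmsf[prof2$resno == 6] /
    mean(prof2$mean_rmsf[prof2$resno != 6])
  expect_equal(ratio, 2, tolerance = 0.1)

  static <- md_trajectory(base, rep(list(base$xyz), 3))
  expect_equal(max(rmsf_per_residue(static)$mean_rmsf), 0, tolerance = 1e-9)
  expect_error(rmsf_per_residue(md_trajectory(base, list(base$xyz))),
               "at least 2")
})

test_that("cluster_frames is deterministic with quantile initialisation", {
  const <- rep(1.5, 5)
  c1 <- cluster_frames(const, 1)
  expect_equal(c1$representatives, 1L)
  expect_warning(cr <- cluster_frames(const, 3), "distinct")
  expect_true(cr$reduced)
  expect_equal(cr$k, 1L)

  x <- c(0, 0, 0, 5, 5, 5)
  c2 <- cluster_frames(x, 2)
  expect_equal(unname(c2$labels), c(1, 1, 1, 2, 2, 2))
  expect_equal(c2$representatives, c(1L, 4L))

  # 3-component 1-D mixture: recovered means within 0.1
  set.seed(8)
  mix <- c(rnorm(100, 1, 0.05), rnorm(100, 3, 0.05), rnorm(100, 6, 0.05))
  c3 <- cluster_frames(mix, 3, seed = 9)
  expect_equal(sort(c3$centers), c(1, 3, 6), tolerance = 0.1)
  expect_length(c3$labels, 300L)
  # deterministic and a full partition
  c3b <- cluster_frames(mix, 3, seed = 9)
  expect_identical(c3$labels, c3b$labels)
  expect_identical(c3$representatives, c3b$representatives)
  expect_true(all(c3$labels %in% 1:3))
  for (cl in 1:3) {
    expect_true(c3$labels[c3$representatives[cl]] == cl)
  }
  expect_error(cluster_frames(x, 7), "exceeds")
})

test_that("site_rmsd isolates binding-site deviation after backbone fit", {
  base <- make_toy_structure(15, seed = 7)
  site <- 5:9
  expect_equal(site_rmsd(base, base, site), 0, tolerance = 1e-12)

  rot <- base
  rot$xyz <- rigid_move(base$xyz, angle_deg = 40)
  expect_equal(site_rmsd(base, rot, site), 0, tolerance = 1e-6)

  # move one site side-chain atom by 2 A: RMSD = 2/sqrt(n_site_heavy)
  m <- mdtriage:::.match_site_atoms(base, base, site)
  n_heavy <- length(m$a_idx)
  sc <- m$b_idx[!m$backbone][1]
  pert <- base
  pert$xyz[sc, ] <- pert$xyz[sc, ] + c(0, 0, 2)
  expect_equal(site_rmsd(base, pert, site), 2 / sqrt(n_heavy),
               tolerance = 1e-6)

  expect_error(site_rmsd(base, base, c(5, 99)), "missing")
  renamed <- base
  renamed$atoms$name[m$a_idx[!m$backbone][1]] <- "XX"
  expect_error(site_rmsd(base, renamed, site), "atom names differ")
})

test_that("apo percentage arithmetic reproduces both conventions", {
  tab <- apo_percentages(c(X = 53, Y = 26), filtered_total = 192,
                         total_frames = 3000)
  expect_equal(tab$percent_of_filtered, c(28L, 14L))
  expect_equal(tab$fraction_of_all_frames, c(53, 26) / 3000)
  z <- apo_percentages(c(A = 0, B = 0), 0, 100)
  expect_equal(z$percent_of_filtered, c(0L, 0L))
  expect_error(apo_percentages(c(A = -1), 10, 100), "non-negative")
})

test_that("apo_resemblance counts snapshots below the site-RMSD threshold", {
  base <- make_toy_structure(12, seed = 9)
  site <- 4:8
  apo <- simulate_trajectory(base, sim_spec(n_frames = 12, sigma = 0.05,
                                            seed = 5))
  near <- base                                  # resembles the apo ensemble
  far <- base
  msa <- mdtriage:::.match_site_atoms(base, base, site)
  far$xyz[msa$a_idx, ] <- far$xyz[msa$a_idx, ] +
    matrix(rnorm(length(msa$a_idx) * 3, sd = 4), ncol = 3)
  rep_ <- apo_resemblance(apo, list(near = near, far = far), site,
                          threshold = 2.5)
  expect_equal(rep_$table$match_count[rep_$table$system == "near"], 12L)
  expect_equal(rep_$table$match_count[rep_$table$system == "far"], 0L)
  expect_equal(rep_$filtered_total, 12L)
  # rigid motion of every input leaves the report unchanged
  apo2 <- md_trajectory(base, lapply(apo$frames, rigid_move))
  near2 <- near; near2$xyz <- rigid_move(near$xyz, 75, c(0, 1, 0), c(9, 9, 9))
  rep2 <- apo_resemblance(apo2, list(near = near2, far = far), site, 2.5)
  expect_equal(rep2$table$match_count, rep_$table$match_count)
})
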