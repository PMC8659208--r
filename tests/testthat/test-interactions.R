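# Contact detection and interaction-fraction fingerprints.

# Minimal complex: one Asn side chain plus a two-atom "carbonyl" ligand at
# a controllable distance from the side-chain nitrogen.
asn_ligand_complex <- function(o_dist) {
  at <- data.frame(
    serial = 1:7,
    name = c("N", "CA", "C", "O", "ND2", "O1", "C1"),
    element = c("N", "C", "C", "O", "N", "O", "C"),
    resno = c(1, 1, 1, 1, 1, 2, 2),
    resname = c(rep("ASN", 5), "LIG", "LIG"),
    chain = "A", stringsAsFactors = FALSE)
  xyz <- rbind(c(-3, 0, 0), c(-1.5, 0, 0), c(-1, 1.4, 0), c(-1, 2.6, 0),
               c(0, 0, 0),
               c(o_dist, 0, 0), c(o_dist + 1.4, 0.6, 0))
  md_structure(at, xyz)
}

test_that("hydrogen bonds honour the heavy-atom distance cutoff", {
  lig <- 6:7
  ev <- detect_contacts(asn_ligand_complex(3.0), lig)
  hb <- ev[ev$type == "hbond", ]
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$resname, "ASN")
  expect_equal(hb$channel, "O1:ND2")

  ev4 <- detect_contacts(asn_ligand_complex(4.0), lig)
  expect_equal(sum(ev4$type == "hbond"), 0L)

  expect_error(detect_contacts(asn_ligand_complex(3.0), integer(0)),
               "no ligand")
})

test_that("hydrogen-bond angle gates contacts when hydrogens are present", {
  mk <- function(h_pos) {
    at <- data.frame(serial = 1:4,
                     name = c("ND2", "HD21", "O1", "C1"),
                     element = c("N", "H", "O", "C"),
                     resno = c(1, 1, 2, 2),
                     resname = c("ASN", "ASN", "LIG", "LIG"),
                     chain = "A", stringsAsFactors = FALSE)
    md_structure(at, rbind(c(0, 0, 0), h_pos, c(3.0, 0, 0), c(4.4, 0.6, 0)))
  }
  # H pointing at the acceptor: angle ~180 -> bond
  ev_in <- detect_contacts(mk(c(1.0, 0, 0)), 3:4)
  expect_equal(sum(ev_in$type == "hbond"), 1L)
  # H pointing away: angle ~0 -> no bond
  ev_out <- detect_contacts(mk(c(-1.0, 0, 0)), 3:4)
  expect_equal(sum(ev_out$type == "hbond"), 0L)
})

test_that("aromatic ring centroids within the cutoff generate one event", {
  hexagon <- function(centre, r = 1.39) {
    t(vapply(0:5, function(k) centre +
               c(r * cos(k * pi / 3), r * sin(k * pi / 3), 0), numeric(3)))
  }
  phe_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  at <- data.frame(
    serial = 1:12,
    name = c(phe_names, paste0("C", 1:6)),
    element = "C",
    resno = c(rep(1, 6), rep(2, 6)),
    resname = c(rep("PHE", 6), rep("LIG", 6)),
    chain = "A", stringsAsFactors = FALSE)
  near <- md_structure(at, rbind(hexagon(c(0, 0, 0)),
                                 hexagon(c(0, 0, 4.0))))
  ev <- detect_contacts(near, 7:12)
  expect_equal(sum(ev$type == "aromatic"), 1L)
  far <- md_structure(at, rbind(hexagon(c(0, 0, 0)),
                                hexagon(c(0, 0, 6.0))))
  expect_equal(sum(detect_contacts(far, 7:12)$type == "aromatic"), 0L)
})

test_that("planted contact schedules are recovered exactly as fractions", {
  base <- make_toy_structure(12, seed = 10, ligand = TRUE)
  sched <- data.frame(resno = c(6, 8), type = c("hbond", "hydrophobic"),
                      fraction = c(0.60, 0.35))
  traj <- simulate_trajectory(base, sim_spec(n_frames = 100, sigma = 0.15,
                                             contact_schedule = sched,
                                             seed = 11))
  lig <- select_atoms(base, "ligand")
  fr <- interaction_fractions(traj, lig)
  hb <- fr$table[fr$table$resno == 6 & fr$table$type == "hbond", ]
  expect_equal(sum(hb$fraction), 0.60)
  hp <- fr$table[fr$table$resno == 8 & fr$table$type == "hydrophobic", ]
  expect_equal(sum(hp$fraction), 0.35)
  expect_true(all(fr$table$fraction >= 0 & fr$table$fraction <= 1))
})

test_that("two channels on one residue accumulate beyond 1", {
  base <- make_toy_structure(12, seed = 10, ligand = TRUE)
  sched <- data.frame(resno = c(6, 6), type = c("hbond", "hbond"),
                      fraction = c(0.8, 0.8))
  traj <- simulate_trajectory(base, sim_spec(n_frames = 50, sigma = 0,
                                             contact_schedule = sched,
                                             seed = 12))
  fr <- interaction_fractions(traj, select_atoms(base, "ligand"))
  cum6 <- fr$cumulative$cumulative_fraction[fr$cumulative$resno == 6]
  expect_equal(cum6, 1.6)
  expect_equal(nrow(fr$table[fr$table$resno == 6, ]), 2L)
})

test_that("contact-free trajectories yield an empty fingerprint", {
  base <- make_toy_structure(8, seed = 13, ligand = TRUE)
  # push the ligand far from the protein in every frame
  frames <- lapply(1:5, function(i) {
    f <- base$xyz
    f[base$atoms$resname == "LIG", ] <-
      f[base$atoms$resname == "LIG", ] + 50
    f
  })
  fr <- interaction_fractions(md_trajectory(base, frames),
                              select_atoms(base, "ligand"))
  expect_equal(nrow(fr$table), 0L)
  expect_equal(count_site_interactions(fr, 1:8), 0L)
})

test_that("count_site_interactions applies the 0.5 fraction rule to key residues", {
  fr <- structure(list(
    table = data.frame(),
    cumulative = data.frame(resno = c(44, 100, 106),
                            resname = c("PHE", "ASN", "TYR"),
                            cumulative_fraction = c(0.9, 0.6, 0.4)),
    n_frames = 100), class = "interaction_fractions")
  expect_equal(count_site_interactions(fr, c("Phe44", "Asn100", "Tyr106")), 2L)
  expect_equal(count_site_interactions(fr, c(44, 100, 106), threshold = 0.3), 3L)
  # monotone non-decreasing as the threshold drops
  ths <- seq(1, 0, by = -0.1)
  counts <- vapply(ths, function(t)
    count_site_interactions(fr, c(44, 100, 106), t), integer(1))
  expect_true(all(diff(counts) >= 0))
  # all residues persistently engaged
  fr$cumulative$cumulative_fraction <- 1.0
  expect_equal(count_site_interactions(fr, c(44, 100, 106)), 3L)
})

test_that("static_pose_contacts counts distinct site residues once", {
  base <- make_toy_structure(12, seed = 10, ligand = TRUE)
  sched <- data.frame(resno = c(5, 6, 8), type = c("hbond", "hbond",
                                                   "hydrophobic"),
                      fraction = c(1, 1, 1))
  traj <- simulate_trajectory(base, sim_spec(n_frames = 1, sigma = 0,
                                             contact_schedule = sched,
                                             seed = 14))
  pose <- mdtriage:::.frame_structure(traj, 1)
  n <- static_pose_contacts(pose, "LIG", 1:12)
  expect_gte(n, 3L)
  # restricting the site excludes off-site residues
  expect_equal(static_pose_contacts(pose, "LIG", c(5, 6)),
               min(2L, n))
  # a displaced ligand touches nothing
  off <- pose
  off$xyz[off$atoms$resname == "LIG", ] <-
    off$xyz[off$atoms$resname == "LIG", ] + 50
  expect_equal(static_pose_contacts(off, "LIG", 1:12), 0L)
  expect_error(static_pose_contacts(pose, "XYZ", 1:12), "not found")
})

test_that("adding contact-free frames dilutes every fraction", {
  base <- make_toy_structure(10, seed = 15, ligand = TRUE)
  sched <- data.frame(resno = 5, type = "hbond", fraction = 1)
  tr1 <- simulate_trajectory(base, sim_spec(n_frames = 10, sigma = 0,
                                            contact_schedule = sched,
                                            seed = 16))
  far <- base$xyz
  far[base$atoms$resname == "LIG", ] <- far[base$atoms$resname == "LIG", ] + 50
  tr2 <- md_trajectory(base, c(tr1$frames, rep(list(far), 10)))
  lig <- select_atoms(base, "ligand")
  f1 <- interaction_fractions(tr1, lig)
  f2 <- interaction_fractions(tr2, lig)
  key <- paste(f1$table$resno, f1$table$type, f1$table$channel)
  key2 <- paste(f2$table$resno, f2$table$type, f2$table$channel)
  common <- intersect(key, key2)
  expect_true(all(f2$table$fraction[match(common, key2)] <=
                    f1$table$fraction[match(common, key)]))
})
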