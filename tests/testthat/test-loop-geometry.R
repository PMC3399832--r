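# Solvent accessibility, conformational-state and omega-loop classification.

isolated_atoms <- function() {
  ca_structure(data.frame(
    chain = "A", resno = 1, ins = "", resname = "GLY",
    name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
    x = c(-100, 0, 100, 200), y = 0, z = 0))
}

test_that("isolated spheres reproduce the closed-form surface area", {
  s <- shrake_rupley_sasa(isolated_atoms())
  expected <- 4 * pi * (c(1.55, 1.70, 1.70, 1.52) + 1.4)^2
  expect_equal(s$atom, expected, tolerance = 0.01)
})

test_that("a fully enclosed atom has zero accessible surface", {
  # central CA inside a tight shell of carbons (one residue, named atoms)
  pts <- loopdyn:::sphere_points(60) * 2.5
  atoms <- data.frame(
    chain = "A", resno = 1, ins = "", resname = "ALA",
    name = c("CA", sprintf("S%02d", 1:60)), element = "C",
    x = c(0, pts[, 1]), y = c(0, pts[, 2]), z = c(0, pts[, 3]))
  s <- shrake_rupley_sasa(ca_structure(atoms), n_points = 480)
  expect_equal(s$atom[1], 0)
})

test_that("random clusters agree with a Monte-Carlo rejection oracle", {
  set.seed(31)
  for (rep in 1:3) {
    xyz <- matrix(stats::rnorm(15, sd = 1.6), ncol = 3)
    atoms <- data.frame(chain = "A", resno = 1, ins = "", resname = "LYS",
                        name = c("CA", "CB", "CG", "CD", "CE"), element = "C",
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    st <- ca_structure(atoms)
    s <- shrake_rupley_sasa(st, n_points = 960)
    # MC oracle: uniform random points on each inflated sphere, rejection
    # against all other inflated spheres
    R <- 1.70 + 1.4
    mc <- numeric(5)
    npts <- 1e5
    z <- stats::rnorm(npts * 3)
    dirs <- matrix(z, ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    for (i in 1:5) {
      pts <- sweep(dirs * R, 2, xyz[i, ], `+`)
      keep <- rep(TRUE, npts)
      for (j in setdiff(1:5, i)) {
        keep <- keep & rowSums(sweep(pts, 2, xyz[j, ])^2) >= R^2
      }
      mc[i] <- 4 * pi * R^2 * mean(keep)
    }
    expect_equal(sum(s$atom), sum(mc), tolerance = 0.02)
  }
})

test_that("SASA is invariant under rigid rotation and translation", {
  st <- two_residue_structure("ASP", "ARG", separation = 6)
  s0 <- sum(shrake_rupley_sasa(st, n_points = 1920)$atom)
  set.seed(5)
  for (rep in 1:3) {
    th <- stats::runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
                c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    xyz <- coords(st) %*% (Rx %*% Rz) + matrix(stats::runif(3, -50, 50),
                                               nrow(coords(st)), 3,
                                               byrow = TRUE)
    s1 <- sum(shrake_rupley_sasa(st, n_points = 1920, xyz = xyz)$atom)
    expect_equal(s1, s0, tolerance = 0.005)
  }
})

test_that("C-alpha-only input is rejected with a pointer to the distance classifier", {
  expect_error(shrake_rupley_sasa(make_chain(5, "extended")),
               "distance classifier")
})

test_that("planted state fractions are recovered exactly by the distance classifier", {
  out <- make_two_state_loop_trajectory(c(0.65, 0.09, 0.26), 2000, seed = 7)
  sp <- classify_states(out$ensemble, cys_residue = out$cys_residue,
                        loop_range = out$loop_range)
  expect_equal(unname(sp$fractions$distance), c(0.65, 0.09, 0.26))
  # per-frame labels equal the planted truth; labels are a partition
  expect_equal(sp$frames$label_distance, out$labels)
  expect_true(all(sp$frames$label_distance %in%
                    c("closed", "semi-open", "open")))
  expect_equal(sum(unname(sp$fractions$distance)), 1)
})

test_that("distances exactly at a cutoff fall in the semi-open class", {
  ch <- make_chain(5, "extended", resnames = c("GLY", "CYS", "GLY", "GLY", "GLY"))
  # place residue 4..5 centroid exactly 6 A (0.6 nm) from the Cys CA
  xyz <- coords(ch)
  base <- mat_to_frame_test(xyz)
  e <- ensemble(ch, matrix(base, nrow = 1))
  # loop = residues 4:5; shift so centroid-Cys distance is exactly 6.0
  cys <- xyz[2, ]
  cent <- colMeans(xyz[4:5, ])
  dir <- (cent - cys) / sqrt(sum((cent - cys)^2))
  target <- cys + 6.0 * dir
  shift <- target - cent
  xyz2 <- xyz
  xyz2[4:5, ] <- sweep(xyz[4:5, ], 2, shift, `+`)
  e$xyz <- matrix(mat_to_frame_test(xyz2), nrow = 1)
  sp <- classify_states(e, 2, c(4, 5))
  expect_equal(sp$frames$label_distance, "semi-open")
})

test_that("constructed omega loops pass and extended segments fail", {
  # planar arc of 13 residues with hinge separation ~6 A
  loop <- loopdyn:::semicircle_loop(13, hinge_sep = 6)
  st <- ca_structure(data.frame(
    chain = "A", resno = 1:13, ins = "", resname = "GLY", name = "CA",
    element = "C", x = loop[, 1], y = loop[, 2], z = loop[, 3]))
  rep1 <- classify_omega_loop(st, c(2, 12), matrix(c(1, 13), ncol = 2))
  expect_true(rep1$verdict)
  expect_equal(rep1$pairs$median_distance, 6, tolerance = 0.1)
  expect_true(rep1$pairs$median_distance <
                2 / 3 * rep1$pairs$max_span)

  ext <- make_chain(13, "extended")
  rep2 <- classify_omega_loop(ext, c(2, 12), matrix(c(1, 13), ncol = 2))
  expect_false(rep2$verdict)
  expect_false(rep2$pairs$crit_span)   # hinge distance equals the max span
})

test_that("omega verdict is monotone when criteria are relaxed", {
  loop <- loopdyn:::semicircle_loop(13, hinge_sep = 6)
  st <- ca_structure(data.frame(
    chain = "A", resno = 1:13, ins = "", resname = "GLY", name = "CA",
    element = "C", x = loop[, 1], y = loop[, 2], z = loop[, 3]))
  tight <- classify_omega_loop(st, c(2, 12), matrix(c(1, 13), ncol = 2),
                               omega_criteria(hinge_range = c(3.7, 6.5)))
  loose <- classify_omega_loop(st, c(2, 12), matrix(c(1, 13), ncol = 2),
                               omega_criteria(hinge_range = c(3.7, 20),
                                              length_range = c(2, 30)))
  expect_true(loose$verdict >= tight$verdict)
})

test_that("ideal backbones are assigned H, G and E; short 3-10 keeps a loop omega-eligible", {
  expect_equal(unique(simple_secondary_structure(
    make_backbone(10, phi = -57, psi = -47))[3:8]), "H")
  expect_equal(unique(simple_secondary_structure(
    make_backbone(8, phi = -120, psi = 120))[3:6]), "E")
  ss310 <- simple_secondary_structure(make_backbone(8, phi = -74, psi = -4))
  expect_equal(unique(ss310[3:6]), "G")

  # a loop whose only structure is a short 3-10 stretch still passes the
  # secondary-structure criterion of the omega classifier
  labels <- loopdyn:::labels_from_basins(
    c("c", "c", "g", "g", "g", "c", "c", "c", "c", "c", "c", "c", "c"))
  expect_false(any(labels %in% c("H", "E")))
})

test_that("relative accessibility separates exposed from buried side chains", {
  res <- loopdyn:::synthetic_residue("CYS", "A", 2, c(0, 0, 0))
  g1 <- loopdyn:::synthetic_residue("GLY", "A", 1, c(-4, 0, 0))
  g3 <- loopdyn:::synthetic_residue("GLY", "A", 3, c(4, 0, 0))
  open_st <- ca_structure(rbind(g1, res, g3))
  r_open <- rel_sidechain_sasa(open_st, 2, n_points = 240)
  expect_gt(r_open, 0.5)

  cage <- expand.grid(x = seq(-6, 6, 3), y = seq(-6, 6, 3), z = seq(-6, 6, 3))
  cage <- cage[sqrt(rowSums(cage^2)) > 2, ]
  cage_df <- data.frame(chain = "B", resno = seq_len(nrow(cage)), ins = "",
                        resname = "ALA", name = "CA", element = "C",
                        x = cage$x, y = cage$y - 1.5, z = cage$z - 1.3)
  buried_st <- ca_structure(rbind(g1, res, g3, cage_df))
  r_buried <- rel_sidechain_sasa(buried_st, 2, n_points = 240)
  expect_lt(r_buried, 0.05)
})

test_that("accessibility classifier labels frames independently and agreement is reported", {
  # two-frame all-atom ensemble: Cys exposed vs caged
  res <- loopdyn:::synthetic_residue("CYS", "A", 2, c(0, 0, 0))
  g1 <- loopdyn:::synthetic_residue("GLY", "A", 1, c(-4, 0, 0))
  g3 <- loopdyn:::synthetic_residue("GLY", "A", 3, c(4, 0, 0))
  loop <- loopdyn:::synthetic_residue("GLY", "A", 4, c(8, 0, 0))
  cage <- expand.grid(x = seq(-6, 6, 3), y = seq(-6, 6, 3), z = seq(-6, 6, 3))
  cage <- cage[sqrt(rowSums(cage^2)) > 2, ]
  cage_df <- data.frame(chain = "B", resno = 100 + seq_len(nrow(cage)), ins = "",
                        resname = "ALA", name = "CA", element = "C",
                        x = cage$x, y = cage$y - 1.5, z = cage$z - 1.3)
  st <- ca_structure(rbind(g1, res, g3, loop, cage_df))
  open_frame <- mat_to_frame_test(coords(st))
  closed_frame <- open_frame
  # move the cage far away in the open frame (exposed Cys)
  cage_atoms <- which(st$atoms$chain == "B")
  for (ax in 0:2) open_frame[3 * (cage_atoms - 1) + 1 + ax] <-
    open_frame[3 * (cage_atoms - 1) + 1 + ax] + 500
  e <- ensemble(st, rbind(closed_frame, open_frame), frame_spacing = 1)
  sp <- classify_states(e, 2, c(4, 4), n_points = 240)
  expect_equal(sp$frames$label_accessibility, c("closed", "open"))
  expect_false(is.na(sp$agreement))
  expect_equal(sp$buried10_fraction, 0.5)
})
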