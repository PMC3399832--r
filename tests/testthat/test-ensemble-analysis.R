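# RMSF/B-factors, PCA diagnostics, DCCM, chained correlations, hinges.

rigid_ensemble <- function(n_frames = 10) {
  ch <- helix5()
  ensemble(ch, matrix(rep(mat_to_frame_test(coords(ch)), n_frames),
                      nrow = n_frames, byrow = TRUE))
}

test_that("rigid ensembles have zero RMSF and isotropic jitter gives s*sqrt(3)", {
  pr0 <- rmsf_profile(rigid_ensemble(), fit = FALSE, filter_fraction = 1)
  expect_equal(pr0$rmsf, rep(0, 5))
  expect_equal(pr0$bfactor, rep(0, 5))

  s <- 0.3
  ch <- make_chain(6, "extended")
  set.seed(2)
  base <- matrix(rep(mat_to_frame_test(coords(ch)), 5000), nrow = 5000,
                 byrow = TRUE)
  e <- ensemble(ch, base + matrix(stats::rnorm(length(base), sd = s),
                                  nrow = 5000))
  pr <- rmsf_profile(e, fit = FALSE, filter_fraction = 1)
  expect_equal(pr$rmsf, rep(s * sqrt(3), 6), tolerance = 0.05)
  # B = 8 pi^2 / 3 rmsf^2 consistency
  expect_equal(pr$bfactor, 8 * pi^2 / 3 * pr$rmsf^2)
})

test_that("filter_fraction = 1 reproduces the unfiltered RMSF exactly", {
  m <- anm_modes(build_network(helix5()))
  e <- nma_ensemble(m, n_frames = 300, seed = 4)
  a <- rmsf_profile(e, fit = FALSE, filter_fraction = 1)
  b <- rmsf_profile(e, fit = FALSE, filter_fraction = 0.999999999)
  expect_equal(a$rmsf, b$rmsf, tolerance = 1e-6)
  expect_error(rmsf_profile(e, filter_fraction = 0), "filter_fraction")
  # filtering keeps at most the essential components
  c70 <- rmsf_profile(e, fit = FALSE, filter_fraction = 0.70)
  expect_lt(attr(c70, "n_components"), 3 * 5)
  expect_true(all(c70$rmsf <= a$rmsf + 1e-12))
})

test_that("PCA reports variance fractions, cosine content and RMSIP", {
  # motion along a single axis -> first eigenvector explains everything
  ch <- make_chain(4, "extended")
  base <- matrix(rep(mat_to_frame_test(coords(ch)), 100), nrow = 100,
                 byrow = TRUE)
  amp <- seq(-1, 1, length.out = 100)
  base[, 1] <- base[, 1] + amp       # x of first bead only
  e <- ensemble(ch, base)
  p <- pca_ensemble(e, fit = FALSE)
  expect_equal(p$cum_var[1], 1, tolerance = 1e-10)
  expect_equal(sum(p$values) / sum(p$values), 1)

  # projection that is a pure half-period cosine has cosine content 1
  Tn <- 400
  co <- cos(pi * (seq_len(Tn) - 0.5) / Tn)
  base2 <- matrix(rep(mat_to_frame_test(coords(ch)), Tn), nrow = Tn,
                  byrow = TRUE)
  base2[, 1] <- base2[, 1] + co
  p2 <- pca_ensemble(ensemble(ch, base2), fit = FALSE)
  expect_equal(cosine_content(p2$projections[, 1]), 1, tolerance = 1e-3)

  # identical ensemble halves -> RMSIP of 1
  half <- nma_ensemble(anm_modes(build_network(helix5())), n_frames = 50,
                       seed = 6)
  both <- ensemble(half$ref, rbind(half$xyz, half$xyz))
  p3 <- pca_ensemble(both, fit = FALSE)
  expect_equal(p3$rmsip_halves, 1, tolerance = 1e-8)
  expect_true(p3$rmsip_halves >= 0 && p3$rmsip_halves <= 1)
  expect_error(pca_ensemble(rigid_ensemble(2)), "at least 3")
})

test_that("DCCM is symmetric, unit-diagonal, bounded, and recovers planted correlations", {
  out <- make_planted_covariance_ensemble(
    8, data.frame(i = 2, j = 7, rho = 0.8), 10000, seed = 12)
  d <- dccm(out$ensemble, fit = FALSE)
  C <- d$average
  expect_equal(C, t(C))
  expect_equal(diag(C), rep(1, 8))
  expect_true(all(abs(C) <= 1 + 1e-12))
  expect_equal(C[2, 7], 0.8, tolerance = 0.05)
  # null pairs stay near zero
  expect_lt(abs(C[1, 5]), 0.05)

  # windowing: per-window matrices have the same invariants and the average
  # matches; consistency distances are reported per window
  dw <- dccm(out$ensemble, window_frames = 2500, fit = FALSE)
  expect_equal(length(dw$windows), 4)
  expect_equal(length(dw$consistency), 4)
  for (W in dw$windows) expect_equal(diag(W), rep(1, 8))
  expect_equal(dw$average[2, 7], 0.8, tolerance = 0.05)
})

test_that("duplicated-residue motion gives correlation one; zero variance warns", {
  ch <- make_chain(4, "extended")
  base <- matrix(rep(mat_to_frame_test(coords(ch)), 50), nrow = 50,
                 byrow = TRUE)
  z <- stats::rnorm(50)
  base[, 1] <- base[, 1] + z         # residue 1 x
  base[, 4] <- base[, 4] + z         # residue 2 x: identical displacement
  e <- ensemble(ch, base)
  expect_warning(d <- dccm(e, fit = FALSE), "zero-variance")
  expect_equal(d$average[1, 2], 1, tolerance = 1e-10)
  expect_equal(d$average[3, 4], 0)   # static residues zeroed
})

test_that("chained correlations equal the brute-force depth enumeration", {
  # hand-built chain a-b-c
  C <- diag(5)
  C[1, 2] <- C[2, 1] <- 0.7
  C[2, 3] <- C[3, 2] <- -0.6
  C[4, 5] <- C[5, 4] <- 0.9
  g <- chained_correlations(C, roots = 1, threshold = 0.5, max_depth = 5)
  expect_equal(sort(g$edges$child), c(2, 3))
  expect_equal(g$edges$depth[g$edges$child == 2], 1)
  expect_equal(g$edges$depth[g$edges$child == 3], 2)
  expect_false(4 %in% names(g$depth))

  # property: random 8x8 matrices against the adjacency-power oracle
  set.seed(42)
  for (rep in 1:25) {
    M <- matrix(stats::runif(64, -1, 1), 8)
    M <- (M + t(M)) / 2
    diag(M) <- 1
    roots <- sample(1:8, sample(1:2, 1))
    thr <- stats::runif(1, 0.3, 0.8)
    md <- sample(2:5, 1)
    g <- chained_correlations(M, roots, thr, md)
    oracle <- chain_depth_oracle(M, roots, thr, md)
    got <- rep(NA_integer_, 8)
    got[roots] <- 0L
    got[g$edges$child] <- g$edges$depth
    expect_identical(got, oracle)
    expect_true(all(abs(g$edges$correlation) >= thr))
  }

  # threshold above all off-diagonal values leaves only the roots
  g0 <- chained_correlations(C, roots = 1, threshold = 0.95)
  expect_equal(nrow(g0$edges), 0)
  expect_error(chained_correlations(C, roots = integer(0)), "roots")
})

test_that("hinges sit at the sharp slope change between fixed and floppy runs", {
  mk_prof <- function(b) {
    ch <- make_chain(length(b), "extended")
    structure(data.frame(chain = "A", resno = seq_along(b), resname = "ALA",
                         rmsf = sqrt(b / (8 * pi^2 / 3)), bfactor = b),
              class = c("flexibility_profile", "data.frame"))
  }
  # step profile: fixed residues 1-10 (B = 1), floppy 11-20 (B = 9)
  hp <- predict_hinges(mk_prof(c(rep(1, 10), rep(9, 10))), loop_range = c(11, 20))
  top <- hp$candidates[which.max(hp$candidates$score), ]
  expect_true(top$resno %in% c(10, 11))

  # ramp with a single kink: hinge at the kink, matching the max
  # |second difference| oracle on the raw profile
  b <- c(seq(1, 2, length.out = 12), seq(2.5, 14, length.out = 8))
  hp2 <- predict_hinges(mk_prof(b), loop_range = c(13, 20))
  kink <- which.max(abs(diff(b, differences = 2))) + 1
  top2 <- hp2$candidates[which.max(hp2$candidates$score), ]
  expect_lte(abs(top2$resno - kink), 1)

  # flat profile reports no hinge
  hp3 <- predict_hinges(mk_prof(rep(5, 20)), loop_range = c(5, 15))
  expect_equal(nrow(hp3$candidates), 0)
  expect_equal(attr(hp3, "message"), "no hinge detected")
})

test_that("replica consistency gives 1 for identical and -1 for reversed profiles", {
  mk <- function(v) structure(
    data.frame(chain = "A", resno = seq_along(v), resname = "ALA",
               rmsf = v, bfactor = 8 * pi^2 / 3 * v^2),
    class = c("flexibility_profile", "data.frame"))
  v <- seq(0.2, 2, length.out = 150)
  rc <- replica_consistency(list(mk(v), mk(v)))
  expect_equal(rc$min, 1)
  rc2 <- replica_consistency(list(mk(v), mk(rev(v))))
  expect_equal(rc2$min, -1)
  # jittered copies stay strongly correlated
  set.seed(9)
  noise <- stats::rnorm(150, sd = 0.1 * diff(range(v)))
  rc3 <- replica_consistency(list(mk(v), mk(v + noise)))
  expect_gt(rc3$min, 0.9)
  expect_warning(replica_consistency(list(mk(v), mk(rep(1, 150)))),
                 "zero-variance")
})
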