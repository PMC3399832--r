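# Contact detection, persistence filtering, macro-trajectories and graphs.

test_that("planted contact fractions are recovered exactly as persistence", {
  for (f in c(0.30, 0.07, 0.83)) {
    out <- make_planted_contact_trajectory(f, 100, seed = 11)
    rec <- detect_contacts(out$ensemble, list(chain = "A"), list(chain = "B"),
                           kind = "saltbridge")
    expect_equal(nrow(rec$records), 1)
    expect_equal(rec$records$persistence, f)
    expect_equal(which(rec$contacts[1, ]), out$truth$contact_frames)
  }
  # noiseless planted trajectories recover any fraction on a 0.01 grid
  for (f in c(0.01, 0.50, 0.99)) {
    out <- make_planted_contact_trajectory(f, 100, seed = 3)
    rec <- detect_contacts(out$ensemble, list(chain = "A"), list(chain = "B"),
                           kind = "saltbridge")
    expect_equal(rec$records$persistence, f)
  }
})

test_that("like-charged pairs are never salt bridges; hydrophobic cutoff at 0.55 nm", {
  st <- two_residue_structure("ASP", "GLU", separation = 3)
  e <- ensemble(st, matrix(mat_to_frame_test(coords(st)), nrow = 1))
  expect_error(detect_contacts(e, list(chain = "A"), list(chain = "B"),
                               kind = "saltbridge"),
               "no admissible")

  out <- make_planted_contact_trajectory(0.5, 10, seed = 2,
                                         kind = "hydrophobic")
  rec <- detect_contacts(out$ensemble, list(chain = "A"), list(chain = "B"),
                         kind = "hydrophobic")
  expect_equal(rec$records$persistence, 0.5)   # 4.0 A < 5.5 A; 8.0 A is not
})

test_that("contact detection is symmetric in the two selections", {
  out <- make_planted_contact_trajectory(0.4, 50, seed = 5)
  a <- detect_contacts(out$ensemble, list(chain = "A"), list(chain = "B"),
                       kind = "saltbridge")
  b <- detect_contacts(out$ensemble, list(chain = "B"), list(chain = "A"),
                       kind = "saltbridge")
  expect_equal(a$records$persistence, b$records$persistence)
})

test_that("enlarging the distance cutoff never decreases persistence", {
  out <- make_planted_contact_trajectory(0.3, 60, seed = 6)
  p1 <- detect_contacts(out$ensemble, list(chain = "A"), list(chain = "B"),
                        kind = "saltbridge",
                        params = network_params(saltbridge_cutoff = 0.45))
  p2 <- detect_contacts(out$ensemble, list(chain = "A"), list(chain = "B"),
                        kind = "saltbridge",
                        params = network_params(saltbridge_cutoff = 0.85))
  expect_true(all(p2$records$persistence >= p1$records$persistence))
})

test_that("persistence filtering keeps 0.30, drops 0.15, and builds the graph", {
  rec30 <- detect_contacts(make_planted_contact_trajectory(0.30, 100, 1)$ensemble,
                           list(chain = "A"), list(chain = "B"), "saltbridge")
  g30 <- filter_by_persistence(rec30)
  expect_equal(igraph::ecount(g30$graph), 1)
  expect_equal(igraph::E(g30$graph)$weight, 0.30)

  rec15 <- detect_contacts(make_planted_contact_trajectory(0.15, 100, 1)$ensemble,
                           list(chain = "A"), list(chain = "B"), "saltbridge")
  g15 <- filter_by_persistence(rec15)
  expect_equal(igraph::ecount(g15$graph), 0)
  expect_equal(sum(g15$histogram$counts), 1)   # histogram still reports it
})

test_that("macro-trajectories concatenate equilibrated portions with boundaries", {
  out <- make_planted_contact_trajectory(0.5, 100, seed = 8)
  e1 <- out$ensemble
  e2 <- ensemble(e1$ref, e1$xyz[1:100, ], frame_spacing = 1)
  mt <- macro_trajectory(list(e1, e2), discard = 20)
  expect_equal(n_frames(mt), 160)
  expect_equal(attr(mt, "replica_boundaries"), c(80, 160))
  # single replica: identity
  m1 <- macro_trajectory(list(e1))
  expect_equal(m1$xyz, e1$xyz)
  # incongruent replicas rejected
  ch <- make_chain(5, "extended")
  e3 <- ensemble(ch, matrix(mat_to_frame_test(coords(ch)), nrow = 1))
  expect_error(macro_trajectory(list(e1, e3)), "incongruent")
})

test_that("pooled persistence is the frame-weighted mean of replica persistences", {
  # replica 1: contact in 58% of 50 frames; replica 2: never
  o1 <- make_planted_contact_trajectory(0.58, 50, seed = 9)
  o2 <- make_planted_contact_trajectory(0.00, 50, seed = 10)
  mt <- macro_trajectory(list(o1$ensemble, o2$ensemble))
  rec <- detect_contacts(mt, list(chain = "A"), list(chain = "B"),
                         kind = "saltbridge")
  expect_equal(rec$records$persistence_rep1, 0.58)
  expect_equal(rec$records$persistence_rep2, 0)
  expect_equal(rec$records$persistence, 0.29)
  # property on random planted data
  set.seed(13)
  for (k in 1:5) {
    f1 <- sample(0:20, 1) / 20
    f2 <- sample(0:20, 1) / 20
    m <- macro_trajectory(list(
      make_planted_contact_trajectory(f1, 20, seed = k)$ensemble,
      make_planted_contact_trajectory(f2, 40, seed = k + 50)$ensemble))
    r <- detect_contacts(m, list(chain = "A"), list(chain = "B"), "saltbridge")
    expect_equal(r$records$persistence,
                 (20 * r$records$persistence_rep1 +
                    40 * r$records$persistence_rep2) / 60)
  }
})
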