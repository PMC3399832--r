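# Omega-loop classification, catalytic-cleft state classification and the
# solvent-accessibility machinery both rely on.

# van der Waals radii (A) by element; probe-inflated spheres use r + 1.4.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

#' @noRd
vdw_radius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Sphere-point quadrature: each atom is covered with a deterministic
#' quasi-uniform lattice of `n_points` points at radius `r_vdw + probe`, and
#' the accessible fraction is the fraction of points outside every
#' neighbouring probe-inflated sphere.
#'
#' @param x an all-atom [ca_structure()] (errors on C-alpha-only input: use
#'   the distance-based state classifier for C-alpha ensembles).
#' @param probe probe radius, A (default 1.4, a water molecule).
#' @param n_points quadrature points per atom (default 960).
#' @param xyz optional replacement coordinates (n x 3), e.g. one ensemble
#'   frame.
#' @return list with `atom` (per-atom SASA, A^2) and `residue` (data.frame
#'   `chain`, `resno`, `resname`, `sasa`).
#' @export
shrake_rupley_sasa <- function(x, probe = 1.4, n_points = 960, xyz = NULL) {
  if (x$calpha_only) {
    stopf("SASA needs an all-atom structure; for C-alpha ensembles use the distance classifier")
  }
  crd <- if (is.null(xyz)) coords(x) else as.matrix(xyz)
  radii <- vdw_radius(x$atoms$element) + probe
  S <- sphere_points(n_points)
  n <- nrow(crd)
  sasa <- numeric(n)
  # neighbour lists via squared distances
  d2 <- as.matrix(stats::dist(crd))^2
  for (i in seq_len(n)) {
    Ri <- radii[i]
    nb <- which(d2[i, ] < (Ri + radii)^2 & seq_len(n) != i)
    pts <- S * Ri
    pts <- sweep(pts, 2, crd[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- sweep(pts[acc, , drop = FALSE], 2, crd[j, ])
      acc[acc] <- rowSums(dj^2) >= radii[j]^2
    }
    sasa[i] <- 4 * pi * Ri^2 * sum(acc) / n_points
  }
  res_sasa <- tapply(sasa, x$atoms$res_index, sum)
  residue <- x$res[, c("chain", "resno", "resname")]
  residue$sasa <- as.numeric(res_sasa[as.character(seq_len(nrow(x$res)))])
  list(atom = sasa, residue = residue)
}

#' Relative side-chain solvent accessibility
#'
#' Side-chain SASA of a residue in context, divided by the side-chain SASA
#' of the same residue in an extended Gly-X-Gly tripeptide computed with the
#' identical algorithm.  The reference tripeptide uses an ideal extended
#' backbone; the residue's own side-chain conformation is grafted onto it by
#' superposing the N/CA/C atoms, keeping the reference self-consistent with
#' the query geometry.
#'
#' @param x all-atom [ca_structure()].
#' @param res_index residue index (row of `x$res`).
#' @inheritParams shrake_rupley_sasa
#' @return relative accessibility (fraction; may slightly exceed 1 for
#'   distorted geometries).
#' @export
rel_sidechain_sasa <- function(x, res_index, probe = 1.4, n_points = 960,
                               xyz = NULL) {
  a <- x$atoms
  crd <- if (is.null(xyz)) coords(x) else as.matrix(xyz)
  rows <- which(a$res_index == res_index)
  sc_names <- setdiff(a$name[rows], c(.BACKBONE_ATOMS, .BACKBONE_H))
  sc_names <- sc_names[!grepl("^[0-9]*H", sc_names)]
  if (length(sc_names) == 0) {
    stopf("residue %s%d has no side-chain atoms",
          x$res$resname[res_index], x$res$resno[res_index])
  }
  full <- shrake_rupley_sasa(x, probe, n_points, xyz = crd)
  sc_rows <- rows[a$name[rows] %in% sc_names]
  sc_sasa <- sum(full$atom[sc_rows])

  ref <- gxg_reference(a[rows, , drop = FALSE], crd[rows, , drop = FALSE])
  ref_full <- shrake_rupley_sasa(ref, probe, n_points)
  ref_sc <- which(ref$atoms$res_index == 2 & ref$atoms$name %in% sc_names)
  sc_sasa / sum(ref_full$atom[ref_sc])
}

#' @noRd
gxg_reference <- function(res_atoms, res_xyz) {
  bb <- extended_backbone(3)
  # graft the query residue onto the central backbone position
  q_n <- res_xyz[match(c("N", "CA", "C"), res_atoms$name), , drop = FALSE]
  if (any(is.na(q_n))) stopf("residue lacks backbone N/CA/C; cannot build Gly-X-Gly reference")
  t_n <- bb$xyz[bb$atoms$resno == 2 & bb$atoms$name %in% c("N", "CA", "C"), ]
  fit <- kabsch(q_n, t_n)
  grafted <- apply_kabsch(res_xyz, fit)
  atoms <- rbind(
    data.frame(chain = "A", resno = 1, ins = "", resname = "GLY",
               name = bb$atoms$name[bb$atoms$resno == 1],
               element = guess_element(bb$atoms$name[bb$atoms$resno == 1]),
               x = bb$xyz[bb$atoms$resno == 1, 1],
               y = bb$xyz[bb$atoms$resno == 1, 2],
               z = bb$xyz[bb$atoms$resno == 1, 3], stringsAsFactors = FALSE),
    data.frame(chain = "A", resno = 2, ins = "", resname = res_atoms$resname[1],
               name = res_atoms$name, element = res_atoms$element,
               x = grafted[, 1], y = grafted[, 2], z = grafted[, 3],
               stringsAsFactors = FALSE),
    data.frame(chain = "A", resno = 3, ins = "", resname = "GLY",
               name = bb$atoms$name[bb$atoms$resno == 3],
               element = guess_element(bb$atoms$name[bb$atoms$resno == 3]),
               x = bb$xyz[bb$atoms$resno == 3, 1],
               y = bb$xyz[bb$atoms$resno == 3, 2],
               z = bb$xyz[bb$atoms$resno == 3, 3], stringsAsFactors = FALSE)
  )
  ca_structure(atoms)
}

#' @noRd
extended_backbone <- function(n_res, phi = -139, psi = 135, omega = 180) {
  # ideal peptide geometry, NeRF chain construction
  bN_CA <- 1.458; bCA_C <- 1.525; bC_N <- 1.329; bC_O <- 1.231
  aN_CA_C <- 111.2; aCA_C_N <- 116.2; aC_N_CA <- 121.7; aCA_C_O <- 120.8
  names_per_res <- c("N", "CA", "C", "O")
  xyz <- matrix(NA_real_, n_res * 4, 3)
  atoms <- data.frame(resno = rep(seq_len(n_res), each = 4),
                      name = rep(names_per_res, n_res),
                      stringsAsFactors = FALSE)
  idx <- function(r, nm) which(atoms$resno == r & atoms$name == nm)
  xyz[idx(1, "N"), ] <- c(0, 0, 0)
  xyz[idx(1, "CA"), ] <- c(bN_CA, 0, 0)
  ang <- aN_CA_C * pi / 180
  xyz[idx(1, "C"), ] <- xyz[idx(1, "CA"), ] +
    bCA_C * c(-cos(ang), sin(ang), 0)
  for (r in seq_len(n_res)) {
    N <- xyz[idx(r, "N"), ]; CA <- xyz[idx(r, "CA"), ]; C <- xyz[idx(r, "C"), ]
    if (r < n_res) {
      Nn <- nerf_place(N, CA, C, bC_N, aCA_C_N, psi)
      xyz[idx(r + 1, "N"), ] <- Nn
      CAn <- nerf_place(CA, C, Nn, bN_CA, aC_N_CA, omega)
      xyz[idx(r + 1, "CA"), ] <- CAn
      xyz[idx(r + 1, "C"), ] <- nerf_place(C, Nn, CAn, bCA_C, aN_CA_C, phi)
    }
    xyz[idx(r, "O"), ] <- nerf_place(N, CA, C, bC_O, aCA_C_O, psi + 180)
  }
  list(atoms = atoms, xyz = xyz)
}

# ---------------------------------------------------------------------------
# Conformational-state classification

#' Conformational-state thresholds
#'
#' Distance cutoffs (nm) between the loop and the catalytic site, and
#' relative catalytic-Cys side-chain accessibility cutoffs (%), defining the
#' closed / semi-open / open states.  Values exactly at a cutoff fall in the
#' intermediate (semi-open) class, since closed and open are defined by
#' strict inequalities.
#'
#' @param dist_closed,dist_open distance cutoffs, nm (0.6 and 1.0).
#' @param acc_closed,acc_open accessibility cutoffs, % (20 and 35).
#' @export
state_thresholds <- function(dist_closed = 0.6, dist_open = 1.0,
                             acc_closed = 20, acc_open = 35) {
  if (!(dist_closed < dist_open) || !(acc_closed < acc_open)) {
    stopf("state cutoffs must be strictly ordered")
  }
  structure(list(dist_closed = dist_closed, dist_open = dist_open,
                 acc_closed = acc_closed, acc_open = acc_open),
            class = "state_thresholds")
}

#' @noRd
three_state_label <- function(v, lo, hi) {
  ifelse(v < lo, "closed", ifelse(v > hi, "open", "semi-open"))
}

#' Classify catalytic-cleft conformational states over an ensemble
#'
#' Distance classifier: per frame, the distance between the centre of mass
#' of the catalytic Cys (side-chain atoms when all-atom, else its C-alpha)
#' and the centre of the loop C-alphas, labelled closed (< 0.6 nm),
#' semi-open (0.6-1.0 nm) or open (> 1.0 nm).  For all-atom ensembles the
#' relative Cys side-chain accessibility labels each frame independently
#' (< 20 / 20-35 / > 35 %), the deeply buried sub-fraction (< 10 %) is
#' reported, and the two classifiers' agreement rate is measured.
#'
#' @param ens an [ensemble()].
#' @param cys_residue residue number of the catalytic cysteine.
#' @param loop_range length-2 residue-number range of the acidic loop.
#' @param thresholds a [state_thresholds()].
#' @param use_accessibility compute the accessibility classifier when the
#'   ensemble is all-atom (default TRUE).
#' @param n_points SASA quadrature points per atom.
#' @return object of class `state_populations`: per-frame labels and distance
#'   (`frames`), population `fractions` per classifier, `agreement`,
#'   `buried10_fraction`.
#' @export
classify_states <- function(ens, cys_residue, loop_range,
                            thresholds = state_thresholds(),
                            use_accessibility = TRUE, n_points = 240) {
  ref <- ens$ref
  loop_res <- which(ref$res$resno >= loop_range[1] & ref$res$resno <= loop_range[2])
  if (length(loop_res) == 0) stopf("loop_range selects no residues")
  cys_idx <- which(ref$res$resno == cys_residue)
  if (length(cys_idx) != 1) stopf("catalytic residue %s not found (or ambiguous)", cys_residue)

  all_atom <- !ref$calpha_only
  cys_rows <- if (all_atom) {
    rows <- which(ref$atoms$res_index == cys_idx &
                    !(ref$atoms$name %in% c(.BACKBONE_ATOMS, .BACKBONE_H)))
    if (length(rows) == 0) ref$res$ca_atom[cys_idx] else rows
  } else ref$res$ca_atom[cys_idx]
  loop_rows <- ref$res$ca_atom[loop_res]

  nf <- n_frames(ens)
  d_nm <- numeric(nf)
  for (f in seq_len(nf)) {
    xm <- frame_coords(ens, f)
    d_nm[f] <- sqrt(sum((colMeans(xm[cys_rows, , drop = FALSE]) -
                           colMeans(xm[loop_rows, , drop = FALSE]))^2)) / 10
  }
  lab_d <- three_state_label(d_nm, thresholds$dist_closed, thresholds$dist_open)

  lab_a <- NULL
  acc <- NULL
  if (all_atom && use_accessibility) {
    acc <- vapply(seq_len(nf), function(f) {
      100 * rel_sidechain_sasa(ref, cys_idx, n_points = n_points,
                               xyz = frame_coords(ens, f))
    }, numeric(1))
    lab_a <- three_state_label(acc, thresholds$acc_closed, thresholds$acc_open)
  }

  lev <- c("closed", "semi-open", "open")
  frac <- function(l) {
    tab <- table(factor(l, levels = lev))
    as.numeric(tab) / length(l)
  }
  out <- list(
    frames = data.frame(distance_nm = d_nm, label_distance = lab_d,
                        label_accessibility = lab_a %||% NA_character_,
                        accessibility_pct = acc %||% NA_real_,
                        stringsAsFactors = FALSE),
    fractions = list(distance = stats::setNames(frac(lab_d), lev),
                     accessibility = if (!is.null(lab_a))
                       stats::setNames(frac(lab_a), lev) else NULL),
    agreement = if (!is.null(lab_a)) mean(lab_d == lab_a) else NA_real_,
    buried10_fraction = if (!is.null(acc)) mean(acc < 10) else NA_real_,
    thresholds = thresholds
  )
  class(out) <- "state_populations"
  out
}

#' @export
print.state_populations <- function(x, ...) {
  f <- x$fractions$distance
  cat(sprintf("state_populations (distance): closed %.1f%%, semi-open %.1f%%, open %.1f%%\n",
              100 * f[1], 100 * f[2], 100 * f[3]))
  if (!is.null(x$fractions$accessibility)) {
    g <- x$fractions$accessibility
    cat(sprintf("          (accessibility): closed %.1f%%, semi-open %.1f%%, open %.1f%%; agreement %.1f%%\n",
                100 * g[1], 100 * g[2], 100 * g[3], 100 * x$agreement))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Omega-loop classification

#' Omega-loop acceptance criteria
#'
#' @param hinge_range allowed hinge C-alpha distance, A (default 3.7-10).
#' @param span_ratio hinge distance must be below this fraction of the
#'   longest C-alpha - C-alpha span across the segment (default 2/3).
#' @param length_range allowed number of residues strictly between the
#'   hinges (default 6-16).
#' @export
omega_criteria <- function(hinge_range = c(3.7, 10), span_ratio = 2 / 3,
                           length_range = c(6, 16)) {
  if (hinge_range[1] >= hinge_range[2]) stopf("hinge_range must be increasing")
  if (span_ratio <= 0 || span_ratio >= 1) stopf("span_ratio must be in (0, 1)")
  structure(list(hinge_range = hinge_range, span_ratio = span_ratio,
                 length_range = length_range),
            class = "omega_criteria")
}

#' Classify a loop as an omega loop
#'
#' For each candidate hinge pair the per-frame hinge C-alpha distance is
#' monitored and four criteria are evaluated on the median-distance frame:
#' (1) hinge distance within the allowed range, (2) hinge distance below
#' `span_ratio` of the longest C-alpha span across the segment in the same
#' frame, (3) loop length within bounds, (4) no regular alpha/beta secondary
#' structure inside the loop (turns and short 3-10 stretches tolerated).
#' The verdict is the conjunction; the best hinge pair maximizes the
#' fraction of frames satisfying criterion 1.
#'
#' @param x an [ensemble()] or [ca_structure()].
#' @param loop_range length-2 residue-number range of the loop.
#' @param hinge_candidates 2-column matrix/data.frame of residue numbers
#'   (N-side, C-side), e.g. built from [predict_hinges()] output.
#' @param criteria an [omega_criteria()].
#' @return object of class `omega_report`: per-pair table (`pairs`), best
#'   pair, per-frame distances of the best pair, and the overall `verdict`.
#' @export
classify_omega_loop <- function(x, loop_range, hinge_candidates,
                                criteria = omega_criteria()) {
  if (inherits(x, "ca_structure")) {
    x <- ensemble(x, matrix(mat_to_frame(coords(x)), nrow = 1))
  }
  hc <- as.matrix(hinge_candidates)
  if (is.null(dim(hc)) || ncol(hc) != 2 || nrow(hc) == 0) {
    stopf("hinge_candidates must be a 2-column matrix of residue numbers")
  }
  ref <- x$ref
  nf <- n_frames(x)
  rows <- vector("list", nrow(hc))
  dists_best <- NULL
  for (p in seq_len(nrow(hc))) {
    nres <- hc[p, 1]; cres <- hc[p, 2]
    i_n <- which(ref$res$resno == nres)
    i_c <- which(ref$res$resno == cres)
    if (length(i_n) != 1 || length(i_c) != 1) {
      stopf("hinge residue %d or %d not found", nres, cres)
    }
    seg <- which(ref$res$resno >= min(nres, cres) & ref$res$resno <= max(nres, cres))
    ca_rows <- ref$res$ca_atom
    d <- numeric(nf); span <- numeric(nf)
    for (f in seq_len(nf)) {
      xm <- frame_coords(x, f)
      d[f] <- sqrt(sum((xm[ca_rows[i_n], ] - xm[ca_rows[i_c], ])^2))
      span[f] <- max(stats::dist(xm[ca_rows[seg], , drop = FALSE]))
    }
    med <- order(d)[(nf + 1) %/% 2]
    in_range <- d >= criteria$hinge_range[1] & d <= criteria$hinge_range[2]
    c1 <- in_range[med]
    c2 <- d[med] < criteria$span_ratio * span[med]
    loop_len <- length(seg) - 2
    c3 <- loop_len >= criteria$length_range[1] & loop_len <= criteria$length_range[2]
    ss <- simple_secondary_structure(structure_at_frame(x, med))
    ss_loop <- ss[seg]
    c4 <- !any(ss_loop %in% c("H", "E"))
    rows[[p]] <- data.frame(
      hinge_n = nres, hinge_c = cres,
      median_distance = d[med], frac_in_range = mean(in_range),
      distance_min = min(d), distance_max = max(d),
      max_span = span[med], loop_length = loop_len,
      crit_distance = c1, crit_span = c2, crit_length = c3, crit_secondary = c4,
      omega = c1 && c2 && c3 && c4
    )
    rows[[p]]$distances <- I(list(d))
  }
  tab <- do.call(rbind, rows)
  best <- which.max(tab$frac_in_range)
  structure(list(pairs = tab, best = best,
                 best_pair = c(tab$hinge_n[best], tab$hinge_c[best]),
                 verdict = tab$omega[best], criteria = criteria,
                 loop_range = loop_range),
            class = "omega_report")
}

#' @export
print.omega_report <- function(x, ...) {
  b <- x$pairs[x$best, ]
  cat(sprintf("omega_report: best hinge pair (%d, %d), median distance %.2f A, %s\n",
              b$hinge_n, b$hinge_c, b$median_distance,
              if (x$verdict) "classified OMEGA" else "rejected"))
  invisible(x)
}

#' @noRd
structure_at_frame <- function(ens, f) {
  ref <- ens$ref
  xm <- frame_coords(ens, f)
  ref$atoms$x <- xm[, 1]; ref$atoms$y <- xm[, 2]; ref$atoms$z <- xm[, 3]
  ref
}

# ---------------------------------------------------------------------------
# Simplified secondary structure

#' Simplified secondary-structure assignment
#'
#' Dihedral-window assignment: with a full backbone, phi/psi pairs are
#' binned into alpha, 3-10 and beta basins; runs of >= 4 alpha residues are
#' H, runs of >= 3 in the 3-10 basin are G, runs of >= 3 beta residues are
#' E; shorter helical stretches are T (turn), everything else C.  C-alpha
#' only structures use the pseudo-dihedral of four consecutive C-alphas as a
#' surrogate (helical at |delta| ~ 50 deg, extended near 180 deg); the
#' surrogate distinguishes neither 3-10 from alpha nor helix handedness.
#'
#' @param x a [ca_structure()].
#' @return character vector of per-residue labels in H/G/E/T/C.
#' @export
simple_secondary_structure <- function(x) {
  nres <- n_residues(x)
  basin <- rep("c", nres)
  a <- x$atoms
  has_bb <- all(c("N", "C") %in% a$name) && !x$calpha_only
  crd <- coords(x)
  if (has_bb) {
    get_atom <- function(ri, nm) {
      row <- which(a$res_index == ri & a$name == nm)
      if (length(row) == 1) crd[row, ] else NULL
    }
    for (i in seq_len(nres)) {
      if (i == 1 || i == nres) next
      if (x$res$chain[i - 1] != x$res$chain[i] ||
          x$res$chain[i + 1] != x$res$chain[i]) next
      Cm <- get_atom(i - 1, "C"); N <- get_atom(i, "N")
      CA <- get_atom(i, "CA"); C <- get_atom(i, "C"); Np <- get_atom(i + 1, "N")
      if (is.null(Cm) || is.null(N) || is.null(C) || is.null(Np)) next
      phi <- dihedral(Cm, N, CA, C)
      psi <- dihedral(N, CA, C, Np)
      if (phi > -100 && phi < -30 && psi > -80 && psi <= -25) basin[i] <- "a"
      else if (phi > -100 && phi < -30 && psi > -25 && psi <= 30) basin[i] <- "g"
      else if (phi > -180 && phi < -45 && psi > 45 && psi <= 180) basin[i] <- "b"
    }
  } else {
    ca_rows <- x$res$ca_atom
    for (i in seq_len(nres)) {
      if (i < 2 || i > nres - 2) next
      delta <- dihedral(crd[ca_rows[i - 1], ], crd[ca_rows[i], ],
                        crd[ca_rows[i + 1], ], crd[ca_rows[i + 2], ])
      if (abs(delta) > 30 && abs(delta) < 70) basin[i] <- "a"
      else if (abs(delta) > 140) basin[i] <- "b"
    }
  }
  labels_from_basins(basin)
}

#' @noRd
labels_from_basins <- function(basin) {
  n <- length(basin)
  out <- rep("C", n)
  r <- rle(basin)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    span <- starts[k]:ends[k]
    v <- r$values[k]
    if (v == "a") {
      out[span] <- if (r$lengths[k] >= 4) "H" else "T"
    } else if (v == "g") {
      out[span] <- if (r$lengths[k] >= 3) "G" else "T"
    } else if (v == "b") {
      out[span] <- if (r$lengths[k] >= 3) "E" else "C"
    }
  }
  out
}
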