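# Seeded generators of synthetic structures, ensembles and alignments.
#
# Every generator records its ground truth so downstream analyses can be
# verified by closure: the planted quantity must be recovered by the stage
# that consumes the fixture.  All randomness is drawn from an explicit seed;
# the same seed reproduces outputs bit-exactly.

#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Ideal C-alpha chain geometries
#'
#' Builds a C-alpha-only structure with 3.8 A virtual bonds: a straight
#' extended chain, an ideal helix, or a two-strand hairpin whose termini are
#' close in space.
#'
#' @param n_residues chain length (>= 2).
#' @param geometry `"extended"`, `"helix"` or `"hairpin"`.
#' @param seed integer; only used when `jitter > 0`.
#' @param jitter optional Gaussian coordinate noise (A, standard deviation).
#' @param resnames optional vector of 3-letter residue names (recycled).
#' @return a [ca_structure()].
#' @export
make_chain <- function(n_residues, geometry = c("extended", "helix", "hairpin"),
                       seed = 1, jitter = 0, resnames = "ALA") {
  geometry <- match.arg(geometry)
  if (n_residues < 2) stopf("n_residues must be >= 2")
  i <- seq_len(n_residues)
  xyz <- switch(geometry,
    extended = cbind(3.8 * (i - 1), 0, 0),
    helix = {
      # ideal C-alpha helix: rise 1.5 A, 100 deg/residue, radius chosen so
      # that consecutive C-alpha distances are 3.8 A
      rise <- 1.5
      dtheta <- 100 * pi / 180
      radius <- sqrt(3.8^2 - rise^2) / (2 * sin(dtheta / 2))
      th <- dtheta * (i - 1)
      cbind(radius * cos(th), radius * sin(th), rise * (i - 1))
    },
    hairpin = {
      half <- ceiling(n_residues / 2)
      out <- cbind(3.8 * (seq_len(half) - 1), 0, 0)
      back <- cbind(3.8 * (half - seq_len(n_residues - half)) - 1.9, 4.8, 0)
      rbind(out, back)
    }
  )
  if (jitter > 0) {
    xyz <- xyz + with_seed(seed, matrix(stats::rnorm(3 * n_residues, sd = jitter),
                                        ncol = 3))
  }
  ca_structure(data.frame(
    chain = "A", resno = i, ins = "",
    resname = rep_len(resnames, n_residues),
    name = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  ))
}

#' Ensemble drawn from a planted correlation structure
#'
#' Frames are drawn from a zero-mean Gaussian whose inter-residue displacement
#' correlation matrix carries the requested planted values; all displacement
#' is along a single axis so the dynamical cross-correlation of a pair equals
#' the planted scalar correlation.  If the requested matrix is not positive
#' definite its negative eigenvalues are clipped (nearest-PD repair) and the
#' realized correlation matrix is recorded.
#'
#' @param n_atoms number of residues/beads.
#' @param planted data.frame with columns `i`, `j`, `rho`.
#' @param n_frames frames to draw.
#' @param seed integer seed.
#' @param sd displacement standard deviation per residue (A).
#' @return list with `ensemble`, `correlation` (realized matrix) and `planted`.
#' @export
make_planted_covariance_ensemble <- function(n_atoms, planted, n_frames,
                                             seed = 1, sd = 0.5) {
  R <- diag(n_atoms)
  if (!is.null(planted) && nrow(planted) > 0) {
    for (k in seq_len(nrow(planted))) {
      R[planted$i[k], planted$j[k]] <- planted$rho[k]
      R[planted$j[k], planted$i[k]] <- planted$rho[k]
    }
  }
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, 1e-8)
  R2 <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  L <- t(chol(R2))
  base <- make_chain(n_atoms, "extended")
  x0 <- coords(base)
  xyz <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n_frames * n_atoms), nrow = n_atoms)
    S <- sd * t(L %*% Z)          # n_frames x n_atoms displacements along x
    out <- matrix(rep(mat_to_frame(x0), n_frames), nrow = n_frames, byrow = TRUE)
    out[, seq(1, 3 * n_atoms, by = 3)] <-
      out[, seq(1, 3 * n_atoms, by = 3), drop = FALSE] + S
    out
  })
  list(ensemble = ensemble(base, xyz, provenance = "external"),
       correlation = R2, planted = planted)
}

#' Trajectory with a contact planted in an exact fraction of frames
#'
#' Builds an all-atom two-residue system (an Asp/Arg salt-bridge pair by
#' default) whose minimum inter-group atom distance is 4.0 A (0.40 nm) in
#' exactly `round(fraction * n_frames)` frames and 8.0 A otherwise.
#'
#' @param fraction planted contact fraction in `[0, 1]`.
#' @param n_frames number of frames.
#' @param seed seed used to shuffle which frames are in contact.
#' @param kind `"saltbridge"` (Asp/Arg) or `"hydrophobic"` (Leu/Ile).
#' @return list with `ensemble`, `truth` (contact frames, fraction, residues).
#' @export
make_planted_contact_trajectory <- function(fraction, n_frames, seed = 1,
                                            kind = c("saltbridge", "hydrophobic")) {
  kind <- match.arg(kind)
  if (fraction < 0 || fraction > 1) stopf("fraction must be in [0, 1]")
  if (kind == "saltbridge") {
    res_a <- synthetic_residue("ASP", chain = "A", resno = 1, origin = c(0, 0, 0))
    res_b <- synthetic_residue("ARG", chain = "B", resno = 1, origin = c(10, 0, 0))
    probe_a <- "OD1"; probe_b <- "NH1"
  } else {
    res_a <- synthetic_residue("LEU", chain = "A", resno = 1, origin = c(0, 0, 0))
    res_b <- synthetic_residue("ILE", chain = "B", resno = 1, origin = c(10, 0, 0))
    probe_a <- "CD1"; probe_b <- "CD1"
  }
  atoms <- rbind(res_a, res_b)
  ref <- ca_structure(atoms)
  nb <- nrow(res_b)
  ia <- which(atoms$chain == "A")
  ib <- which(atoms$chain == "B")

  # chain B is displaced along x; solve for the shift that makes the minimum
  # inter-GROUP atom distance exactly the target (4.0 A contact, 8.0 A apart),
  # with groups defined exactly as in contact detection
  ga <- residue_group_atoms(ref, 1, kind)
  gb <- residue_group_atoms(ref, 2, kind)
  xa <- as.matrix(atoms[ga, c("x", "y", "z")])
  xb <- as.matrix(atoms[gb, c("x", "y", "z")])
  dx <- outer(xb[, 1], xa[, 1], `-`)
  dyz2 <- outer(xb[, 2], xa[, 2], `-`)^2 + outer(xb[, 3], xa[, 3], `-`)^2
  dmin <- function(s) min(sqrt((dx + s)^2 + dyz2))
  shift_for <- function(target) {
    grid <- seq(-max(dx), 60, length.out = 2000)
    f <- vapply(grid, dmin, numeric(1)) - target
    ix <- which(diff(sign(f)) != 0)
    if (length(ix) == 0) stopf("cannot realize inter-group distance %.1f A", target)
    ix <- ix[length(ix)]   # outermost crossing: groups separate cleanly
    stats::uniroot(function(s) dmin(s) - target,
                   grid[c(ix, ix + 1)], tol = 1e-12)$root
  }
  s_contact <- shift_for(4.0)
  s_apart <- shift_for(8.0)

  n_contact <- round(fraction * n_frames)
  labels <- rep(FALSE, n_frames)
  if (n_contact > 0) {
    labels[with_seed(seed, sample.int(n_frames, n_contact))] <- TRUE
  }
  shift <- ifelse(labels, s_contact, s_apart)
  base <- mat_to_frame(as.matrix(atoms[, c("x", "y", "z")]))
  xyz <- matrix(rep(base, n_frames), nrow = n_frames, byrow = TRUE)
  xcols <- 3 * (ib - 1) + 1
  xyz[, xcols] <- xyz[, xcols, drop = FALSE] + shift
  list(ensemble = ensemble(ref, xyz, frame_spacing = 1, provenance = "external"),
       truth = list(fraction = n_contact / n_frames, contact_frames = which(labels),
                    probe_atoms = c(probe_a, probe_b), kind = kind))
}

#' @noRd
synthetic_residue <- function(resname, chain, resno, origin) {
  # minimal idealized all-atom residues (coordinates in A, local frame)
  templates <- list(
    ASP = rbind(N = c(-1.46, 0.0, 0.0), CA = c(0, 0, 0), C = c(0.55, 1.42, 0.0),
                O = c(1.65, 1.62, 0.5), CB = c(0.54, -0.78, -1.2),
                CG = c(0.22, -2.26, -1.2), OD1 = c(0.62, -2.95, -0.24),
                OD2 = c(-0.45, -2.75, -2.1)),
    ARG = rbind(N = c(-1.46, 0.0, 0.0), CA = c(0, 0, 0), C = c(0.55, 1.42, 0.0),
                O = c(1.65, 1.62, 0.5), CB = c(0.54, -0.78, -1.2),
                CG = c(0.1, -2.24, -1.3), CD = c(0.7, -2.95, -2.5),
                NE = c(0.3, -4.36, -2.55), CZ = c(0.85, -5.25, -3.38),
                NH1 = c(1.8, -4.89, -4.23), NH2 = c(0.45, -6.52, -3.36)),
    LEU = rbind(N = c(-1.46, 0.0, 0.0), CA = c(0, 0, 0), C = c(0.55, 1.42, 0.0),
                O = c(1.65, 1.62, 0.5), CB = c(0.54, -0.78, -1.2),
                CG = c(0.15, -2.26, -1.3), CD1 = c(0.8, -2.95, -2.5),
                CD2 = c(-1.36, -2.4, -1.4)),
    ILE = rbind(N = c(-1.46, 0.0, 0.0), CA = c(0, 0, 0), C = c(0.55, 1.42, 0.0),
                O = c(1.65, 1.62, 0.5), CB = c(0.54, -0.78, -1.2),
                CG1 = c(0.1, -2.24, -1.3), CG2 = c(2.06, -0.7, -1.2),
                CD1 = c(0.75, -3.0, -2.45)),
    GLU = rbind(N = c(-1.46, 0.0, 0.0), CA = c(0, 0, 0), C = c(0.55, 1.42, 0.0),
                O = c(1.65, 1.62, 0.5), CB = c(0.54, -0.78, -1.2),
                CG = c(0.1, -2.24, -1.3), CD = c(0.7, -2.95, -2.5),
                OE1 = c(1.55, -2.45, -3.25), OE2 = c(0.3, -4.12, -2.65)),
    LYS = rbind(N = c(-1.46, 0.0, 0.0), CA = c(0, 0, 0), C = c(0.55, 1.42, 0.0),
                O = c(1.65, 1.62, 0.5), CB = c(0.54, -0.78, -1.2),
                CG = c(0.1, -2.24, -1.3), CD = c(0.7, -2.95, -2.5),
                CE = c(0.25, -4.4, -2.6), NZ = c(0.85, -5.15, -3.7)),
    CYS = rbind(N = c(-1.46, 0.0, 0.0), CA = c(0, 0, 0), C = c(0.55, 1.42, 0.0),
                O = c(1.65, 1.62, 0.5), CB = c(0.54, -0.78, -1.2),
                SG = c(-0.06, -2.48, -1.4)),
    GLY = rbind(N = c(-1.46, 0.0, 0.0), CA = c(0, 0, 0), C = c(0.55, 1.42, 0.0),
                O = c(1.65, 1.62, 0.5))
  )
  tpl <- templates[[resname]]
  if (is.null(tpl)) stopf("no synthetic template for residue %s", resname)
  xyz <- sweep(tpl, 2, origin, `+`)
  data.frame(
    chain = chain, resno = resno, ins = "", resname = resname,
    name = rownames(tpl), element = guess_element(rownames(tpl)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
}

#' Two-population open/closed loop trajectory with planted state fractions
#'
#' Emulates the catalytic-cleft geometry of a family-3 E2: a catalytic Cys
#' bead and a 13-residue loop whose centre is placed, frame by frame, at a
#' distance from the Cys drawn inside the closed (0.30-0.55 nm), semi-open
#' (0.65-0.95 nm) or open (1.05-1.50 nm) band, with exact planted fractions.
#'
#' @param fractions numeric length-3 `(closed, semi_open, open)`, summing to 1.
#' @param n_frames number of frames.
#' @param seed integer seed (band positions and frame shuffling).
#' @param loop_length residues in the loop (default 13).
#' @return list with `ensemble` (C-alpha only), `labels` (truth per frame),
#'   `fractions` (realized), `distances_nm`, `cys_residue` and `loop_range`.
#' @export
make_two_state_loop_trajectory <- function(fractions, n_frames, seed = 1,
                                           loop_length = 13) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9) {
    stopf("fractions must be length 3 and sum to 1")
  }
  counts <- round(fractions * n_frames)
  counts[1] <- n_frames - sum(counts[-1])   # remainder goes to 'closed'
  if (any(counts < 0)) stopf("fractions incompatible with n_frames")
  labels <- rep(c("closed", "semi-open", "open"), counts)
  bands <- list(closed = c(3.0, 5.5), `semi-open` = c(6.5, 9.5),
                open = c(10.5, 15.0))     # A
  out <- with_seed(seed, {
    labels <- sample(labels)
    d <- vapply(labels, function(l) stats::runif(1, bands[[l]][1], bands[[l]][2]),
                numeric(1))
    list(labels = labels, d = unname(d))
  })
  labels <- out$labels
  d <- out$d

  # geometry: Cys bead at origin (plus flanking residues so the chain is
  # valid), loop of loop_length residues arranged on a semicircle whose
  # C-alpha centroid sits at distance d along +x
  loop_local <- semicircle_loop(loop_length)
  loop_local <- sweep(loop_local, 2, colMeans(loop_local))
  n_pre <- 3   # residues before the loop (Cys is residue 2)
  cys_xyz <- c(0, 0, -6)
  pre <- cbind(c(-3.8, 0, 3.8), rep(0, 3), rep(-6, 3))
  atoms <- data.frame(
    chain = "A",
    resno = seq_len(n_pre + loop_length),
    ins = "",
    resname = c("GLY", "CYS", "GLY", rep("GLY", loop_length)),
    name = "CA", element = "C",
    x = c(pre[, 1], loop_local[, 1]),
    y = c(pre[, 2], loop_local[, 2]),
    z = c(pre[, 3], loop_local[, 3]),
    stringsAsFactors = FALSE
  )
  ref <- ca_structure(atoms)

  loop_rows <- n_pre + seq_len(loop_length)
  base <- mat_to_frame(as.matrix(atoms[, c("x", "y", "z")]))
  xyz <- matrix(rep(base, n_frames), nrow = n_frames, byrow = TRUE)
  # place the loop C-alpha centroid at cys + d * x-hat, frame by frame
  cent0 <- colMeans(as.matrix(atoms[loop_rows, c("x", "y", "z")]))
  for (f in seq_len(n_frames)) {
    shift <- c(cys_xyz[1] + d[f], cys_xyz[2], cys_xyz[3]) - cent0
    for (ax in 1:3) {
      cols <- 3 * (loop_rows - 1) + ax
      xyz[f, cols] <- base[cols] + shift[ax]
    }
  }
  list(ensemble = ensemble(ref, xyz, frame_spacing = 1, provenance = "external"),
       labels = labels,
       fractions = counts / n_frames,
       distances_nm = d / 10,
       cys_residue = 2,
       loop_range = c(min(atoms$resno[loop_rows]), max(atoms$resno[loop_rows])))
}

#' @noRd
semicircle_loop <- function(n, hinge_sep = 6, span = NULL) {
  # n C-alphas on a circular arc in the xy plane; consecutive spacing 3.8 A
  # is approximated by choosing the arc so chord lengths are 3.8.
  # hinge_sep: straight-line distance between first and last C-alpha.
  # choose radius so that (n-1) chords of 3.8 A wrap an arc whose endpoints
  # are hinge_sep apart: chord angle a = 2 asin(1.9/R); total angle (n-1) a;
  # endpoint separation 2 R sin((n-1) a / 2) = hinge_sep.
  f <- function(R) {
    a <- 2 * asin(pmin(1, 1.9 / R))
    2 * R * sin(pmin(pi, (n - 1) * a / 2)) - hinge_sep
  }
  # search a radius where endpoints close to hinge_sep (loop wraps around)
  Rs <- seq(2.0, 20, by = 0.005)
  vals <- vapply(Rs, f, numeric(1))
  ix <- which(diff(sign(vals)) != 0)
  R <- if (length(ix) > 0) Rs[ix[length(ix)]] else 8
  a <- 2 * asin(min(1, 1.9 / R))
  th <- a * (seq_len(n) - 1)
  cbind(R * cos(th), R * sin(th), 0)
}

#' Toy multiple sequence alignment with designed column composition
#'
#' @param n_seqs number of sequences.
#' @param columns list of column designs; each element is a list with
#'   `type` one of `"literal"` (field `aa`), `"mix"` (field `freqs`, a named
#'   frequency vector), `"class"` (field `class`: `"h"`, `"u"` or `"n"`;
#'   members drawn uniformly), `"random"` (uniform over the 20 residues) or
#'   `"gap"` (field `gap_fraction`, remainder uniform).
#' @param seed integer seed.
#' @return list with `alignment` ([alignment_block()]) and `design`.
#' @export
make_toy_alignment <- function(n_seqs, columns, seed = 1) {
  classes <- list(h = c("A", "V", "L", "I", "M", "F", "W", "C", "Y"),
                  u = c("A", "G", "S"), n = c("D", "E"))
  mat <- with_seed(seed, {
    cols <- lapply(columns, function(cs) {
      col <- switch(cs$type,
        literal = rep(cs$aa, n_seqs),
        mix = {
          counts <- round(cs$freqs * n_seqs)
          while (sum(counts) > n_seqs) counts[which.max(counts)] <- counts[which.max(counts)] - 1
          while (sum(counts) < n_seqs) counts[which.max(cs$freqs)] <- counts[which.max(cs$freqs)] + 1
          rep(names(cs$freqs), counts)
        },
        class = sample(classes[[cs$class]], n_seqs, replace = TRUE),
        random = sample(.AA1, n_seqs, replace = TRUE),
        gap = {
          ng <- round(cs$gap_fraction * n_seqs)
          c(rep("-", ng), sample(.AA1, n_seqs - ng, replace = TRUE))
        },
        stopf("unknown column type '%s'", cs$type)
      )
      sample(col)   # shuffle rows within the column
    })
    do.call(cbind, cols)
  })
  seqs <- apply(mat, 1, paste, collapse = "")
  list(alignment = alignment_block(sprintf("seq%03d", seq_len(n_seqs)), seqs),
       design = columns)
}

#' Ideal all-atom backbone with uniform phi/psi
#'
#' Builds an N/CA/C/O backbone chain by natural-extension (NeRF) construction
#' with ideal peptide geometry and the requested backbone dihedrals; used to
#' construct helix, 3-10 and strand fixtures for the secondary-structure
#' assignment.
#'
#' @param n_residues chain length.
#' @param phi,psi backbone dihedrals, degrees (defaults: extended strand).
#' @param resnames 3-letter residue names (recycled).
#' @return an all-atom [ca_structure()].
#' @export
make_backbone <- function(n_residues, phi = -139, psi = 135, resnames = "ALA") {
  bb <- extended_backbone(n_residues, phi = phi, psi = psi)
  ca_structure(data.frame(
    chain = "A", resno = bb$atoms$resno, ins = "",
    resname = rep_len(resnames, n_residues)[bb$atoms$resno],
    name = bb$atoms$name, element = guess_element(bb$atoms$name),
    x = bb$xyz[, 1], y = bb$xyz[, 2], z = bb$xyz[, 3],
    stringsAsFactors = FALSE
  ))
}
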