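# Flexibility and correlation analysis of conformational ensembles.

#' Least-squares superposition of an ensemble
#'
#' Each frame is fitted onto the running average structure (all beads,
#' Kabsch), and the fit is iterated so the average is self-consistent.
#'
#' @param ens an [ensemble()].
#' @param iter number of mean-refit iterations (default 2).
#' @param ref optional n x 3 reference; when given, frames are fitted to it
#'   once and no iteration is done.
#' @return the superposed [ensemble()].
#' @export
superpose_ensemble <- function(ens, iter = 2, ref = NULL) {
  xyz <- ens$xyz
  nf <- nrow(xyz)
  fit_all <- function(xyz, target) {
    for (f in seq_len(nf)) {
      xyz[f, ] <- mat_to_frame(superpose_frame(frame_to_mat(xyz[f, ]), target))
    }
    xyz
  }
  if (!is.null(ref)) {
    xyz <- fit_all(xyz, ref)
  } else {
    target <- frame_to_mat(colMeans(xyz))
    for (it in seq_len(iter)) {
      xyz <- fit_all(xyz, target)
      target <- frame_to_mat(colMeans(xyz))
    }
  }
  out <- ens
  out$xyz <- xyz
  out
}

#' Per-residue RMSF and B-factor profile of an ensemble
#'
#' Fluctuations are measured from the average structure after least-squares
#' superposition, on the trajectory filtered on the leading principal
#' components covering at least `filter_fraction` of the variance (0.70 by
#' default, i.e. the essential space); `filter_fraction = 1` is exactly the
#' unfiltered profile.  B-factors follow `B = (8 pi^2 / 3) <dr^2>`.
#'
#' @param ens an [ensemble()] with >= 2 frames.
#' @param fit superpose frames first (default TRUE).
#' @param filter_fraction fraction of variance retained, in (0, 1].
#' @return a `flexibility_profile` data.frame with columns `chain`, `resno`,
#'   `resname`, `rmsf` (A), `bfactor` (A^2); attributes `provenance`,
#'   `filter_fraction`, `n_components`.
#' @export
rmsf_profile <- function(ens, fit = TRUE, filter_fraction = 0.70) {
  if (n_frames(ens) < 2) stopf("need at least 2 frames")
  if (filter_fraction <= 0 || filter_fraction > 1) {
    stopf("filter_fraction must be in (0, 1]")
  }
  if (fit) ens <- superpose_ensemble(ens)
  X <- ens$xyz
  D <- sweep(X, 2, colMeans(X))
  ncomp <- ncol(D)
  if (filter_fraction < 1) {
    cv <- crossprod(D) / (nrow(D) - 1)
    e <- eigen(cv, symmetric = TRUE)
    vals <- pmax(e$values, 0)
    cum <- cumsum(vals) / sum(vals)
    ncomp <- which(cum >= filter_fraction)[1]
    V <- e$vectors[, seq_len(ncomp), drop = FALSE]
    D <- D %*% V %*% t(V)
  }
  n <- n_atoms(ens$ref)
  msf <- colMeans(D^2)
  msf_res <- msf[seq(1, 3 * n, 3)] + msf[seq(2, 3 * n, 3)] + msf[seq(3, 3 * n, 3)]
  flexibility_profile(ens$ref, rmsf = sqrt(msf_res),
                      provenance = "ensemble",
                      filter_fraction = filter_fraction, n_components = ncomp)
}

#' @noRd
flexibility_profile <- function(ref, rmsf, provenance, ...) {
  ca <- as_calpha(ref)
  out <- data.frame(chain = ca$res$chain, resno = ca$res$resno,
                    resname = ca$res$resname,
                    rmsf = rmsf, bfactor = (8 * pi^2 / 3) * rmsf^2,
                    stringsAsFactors = FALSE)
  class(out) <- c("flexibility_profile", "data.frame")
  attr(out, "provenance") <- provenance
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' @export
plot.flexibility_profile <- function(x, ...) {
  graphics::plot(x$resno, x$bfactor, type = "l", xlab = "residue",
                 ylab = expression(B ~ (ring(A)^2)), ...)
  invisible(x)
}

#' Analytic B-factors from ANM modes
#'
#' `<dr_i^2> = kB T sum_m |v_{m,i}|^2 / lambda_m` over the non-rigid modes;
#' equals the RMSF^2 of a large mode-sampled ensemble.
#'
#' @param modes a [anm_modes()] result.
#' @param cg a [cg_params()].
#' @return a `flexibility_profile` (provenance "modes").
#' @export
anm_bfactors <- function(modes, cg = cg_params()) {
  if (length(modes$values) == 0) stopf("no non-rigid modes available")
  kT <- kBT_kcal(cg$temperature)
  n <- modes$n_atoms
  V2 <- modes$vectors^2
  per_coord <- V2 %*% (kT / modes$values)
  msf <- per_coord[seq(1, 3 * n, 3)] + per_coord[seq(2, 3 * n, 3)] +
    per_coord[seq(3, 3 * n, 3)]
  ref <- modes$structure %||% chain_from_xyz(modes$xyz0)
  flexibility_profile(ref, rmsf = sqrt(msf), provenance = "modes")
}

# ---------------------------------------------------------------------------
# Principal component analysis

#' PCA of the C-alpha positional covariance
#'
#' Eigendecomposition of the 3N covariance of the superposed ensemble (beads
#' carry equal mass, so mass weighting is a constant factor), with the two
#' sampling diagnostics used for coarse/MD ensembles: the cosine content of
#' the leading projections (1 = random-diffusion-like sampling) and the RMSIP
#' between the two ensemble halves over the top 10 eigenvectors (1 =
#' converged essential subspace).
#'
#' @param ens an [ensemble()] with >= 3 frames.
#' @param fit superpose first (default TRUE).
#' @param n_rmsip subspace size for RMSIP (default 10).
#' @return object of class `pca_result`: `values` (descending), `vectors`,
#'   `cum_var`, `cosine_content` (first 3), `rmsip_halves`, `projections`.
#' @export
pca_ensemble <- function(ens, fit = TRUE, n_rmsip = 10) {
  if (n_frames(ens) < 3) stopf("need at least 3 frames for PCA")
  if (fit) ens <- superpose_ensemble(ens)
  X <- ens$xyz
  D <- sweep(X, 2, colMeans(X))
  cv <- crossprod(D) / (nrow(D) - 1)
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  proj <- D %*% e$vectors[, 1:min(3, ncol(cv)), drop = FALSE]
  cc <- apply(proj, 2, cosine_content)
  # RMSIP between ensemble halves
  half <- nrow(D) %/% 2
  k <- min(n_rmsip, ncol(cv))
  sub <- function(rows) {
    Dh <- sweep(X[rows, , drop = FALSE], 2, colMeans(X[rows, , drop = FALSE]))
    eigen(crossprod(Dh) / (length(rows) - 1), symmetric = TRUE)$vectors[, 1:k, drop = FALSE]
  }
  rmsip_h <- if (half >= 3) rmsip(sub(1:half), sub((half + 1):nrow(D))) else NA_real_
  structure(list(values = vals, vectors = e$vectors,
                 cum_var = cumsum(vals) / sum(vals),
                 cosine_content = cc, rmsip_halves = rmsip_h,
                 projections = proj),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: PC1-3 explain %.1f%%; cosine content %s; half-RMSIP %.3f\n",
              100 * x$cum_var[min(3, length(x$cum_var))],
              paste(sprintf("%.2f", x$cosine_content), collapse = "/"),
              x$rmsip_halves))
  invisible(x)
}

#' Cosine content of a principal-component projection
#'
#' `c_i = (2/T) (sum_t cos(i pi (t - 1/2) / T) p_t)^2 / sum_t p_t^2` for the
#' i-th half-period cosine; a projection that is itself such a cosine scores
#' 1, a converged oscillatory projection scores near 0.
#'
#' @param p numeric projection time series.
#' @param i cosine index (default 1).
#' @export
cosine_content <- function(p, i = 1) {
  T <- length(p)
  t <- seq_len(T) - 0.5
  co <- cos(i * pi * t / T)
  (2 / T) * sum(co * p)^2 / sum(p^2)
}

#' Root mean square inner product between two eigenvector sets
#'
#' @param A,B matrices whose columns are orthonormal vectors (same row count).
#' @return RMSIP in [0, 1]; 1 for identical subspaces.
#' @export
rmsip <- function(A, B) {
  k <- min(ncol(A), ncol(B))
  M <- crossprod(A[, 1:k, drop = FALSE], B[, 1:k, drop = FALSE])
  sqrt(sum(M^2) / k)
}

# ---------------------------------------------------------------------------
# Dynamical cross-correlation matrices

#' Windowed dynamical cross-correlation matrix
#'
#' Per non-overlapping window, `C(i,j) = <dr_i . dr_j> /
#' sqrt(<dr_i^2><dr_j^2>)` with displacements relative to the window mean
#' after superposition; the reported matrix is the average over windows.
#' A zero-variance residue yields correlation 0 with a warning.  Windows are
#' expressed in frames; for trajectories stored every 4 ps the reference
#' 1 ns window is 250 frames.  A trailing partial window is dropped.
#'
#' @param ens an [ensemble()].
#' @param window_frames frames per window (`NULL` = one window over all
#'   frames); must be >= 2.
#' @param threshold significance cutoff on `|C|` (default 0.35).
#' @param seq_sep sequence-separation cutoff for the long-range mask
#'   (default 10).
#' @param fit superpose each window onto its mean (default TRUE).
#' @return object of class `dccm_matrix`: `average`, `windows` (list),
#'   `significant` (logical mask `|C| > threshold & |i-j| > seq_sep`),
#'   `consistency` (per-window Frobenius distance to the average),
#'   `window_frames`, `threshold`, `seq_sep`.
#' @export
dccm <- function(ens, window_frames = NULL, threshold = 0.35, seq_sep = 10,
                 fit = TRUE) {
  nf <- n_frames(ens)
  if (is.null(window_frames)) window_frames <- nf
  if (window_frames < 2) stopf("window_frames must be >= 2")
  n_win <- nf %/% window_frames
  if (n_win < 1) stopf("ensemble shorter than one window")
  n <- n_atoms(ens$ref)
  windows <- vector("list", n_win)
  warned <- FALSE
  for (w in seq_len(n_win)) {
    rows <- ((w - 1) * window_frames + 1):(w * window_frames)
    sub <- ensemble(ens$ref, ens$xyz[rows, , drop = FALSE],
                    frame_spacing = ens$frame_spacing, provenance = ens$provenance)
    if (fit) sub <- superpose_ensemble(sub)
    D <- sweep(sub$xyz, 2, colMeans(sub$xyz))
    # inner products of per-residue displacement vectors
    ix <- seq(1, 3 * n, 3)
    G <- crossprod(D[, ix, drop = FALSE]) +
      crossprod(D[, ix + 1, drop = FALSE]) +
      crossprod(D[, ix + 2, drop = FALSE])
    v <- diag(G)
    zero <- v <= 0
    if (any(zero) && !warned) {
      warnf("%d zero-variance residue(s) in window %d; correlations set to 0",
            sum(zero), w)
      warned <- TRUE
    }
    s <- sqrt(ifelse(zero, 1, v))
    C <- G / tcrossprod(s)
    C[zero, ] <- 0
    C[, zero] <- 0
    diag(C) <- 1
    C[C > 1] <- 1
    C[C < -1] <- -1
    windows[[w]] <- C
  }
  avg <- Reduce(`+`, windows) / n_win
  diag(avg) <- 1
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  signif_mask <- abs(avg) > threshold & sep > seq_sep
  consistency <- vapply(windows, function(C) sqrt(sum((C - avg)^2)), numeric(1))
  structure(list(average = avg, windows = windows, significant = signif_mask,
                 consistency = consistency, window_frames = window_frames,
                 threshold = threshold, seq_sep = seq_sep,
                 resno = as_calpha(ens$ref)$res$resno),
            class = "dccm_matrix")
}

#' @export
print.dccm_matrix <- function(x, ...) {
  cat(sprintf("dccm_matrix: %d residues, %d window(s) of %d frames; %d significant long-range pairs\n",
              nrow(x$average), length(x$windows), x$window_frames,
              sum(x$significant) / 2))
  invisible(x)
}

#' @export
plot.dccm_matrix <- function(x, ...) {
  n <- nrow(x$average)
  graphics::image(1:n, 1:n, x$average, zlim = c(-1, 1),
                  col = grDevices::hcl.colors(64, "Blue-Red"),
                  xlab = "residue", ylab = "residue", ...)
  invisible(x)
}

#' Chained (transitive) correlation search
#'
#' Breadth-first expansion from the root residues over edges with
#' `|C| >= threshold`: a residue's depth is the minimum number of
#' above-threshold correlation steps from any root, and the expansion stops
#' at `max_depth` (default 5, with the 0.5 threshold used for loop-7
#' hydrophobic roots).  Parent ties are resolved toward the strongest
#' correlation, then the lower residue index.
#'
#' @param d a [dccm()] result (the average matrix is used) or a plain
#'   correlation matrix.
#' @param roots root residue indices (matrix rows).
#' @param threshold minimum `|C|` for an edge (default 0.5).
#' @param max_depth maximum chain depth (default 5).
#' @return object of class `chain_graph`: `edges` data.frame (`parent`,
#'   `child`, `depth`, `correlation`), `depth` (named vector over reached
#'   residues), `roots`, `threshold`, `deep_partners` (residues at depth
#'   3..max_depth).
#' @export
chained_correlations <- function(d, roots, threshold = 0.5, max_depth = 5) {
  C <- if (inherits(d, "dccm_matrix")) d$average else as.matrix(d)
  n <- nrow(C)
  roots <- unique(as.integer(roots))
  if (length(roots) == 0 || any(roots < 1 | roots > n)) {
    stopf("roots must be non-empty indices within the matrix")
  }
  A <- abs(C) >= threshold
  diag(A) <- FALSE
  depth <- rep(NA_integer_, n)
  depth[roots] <- 0L
  edges <- list()
  frontier <- roots
  for (lev in seq_len(max_depth)) {
    nxt <- integer(0)
    for (child in which(is.na(depth))) {
      parents <- frontier[A[frontier, child]]
      if (length(parents) > 0) {
        cors <- C[parents, child]
        best <- parents[order(-abs(cors), parents)][1]
        edges[[length(edges) + 1]] <- data.frame(
          parent = best, child = child, depth = lev,
          correlation = C[best, child]
        )
        nxt <- c(nxt, child)
      }
    }
    depth[nxt] <- lev
    if (length(nxt) == 0) break
    frontier <- nxt
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(parent = integer(0), child = integer(0),
               depth = integer(0), correlation = numeric(0))
  reached <- which(!is.na(depth))
  dp <- depth[reached]
  names(dp) <- reached
  structure(list(edges = edges, depth = dp, roots = roots,
                 threshold = threshold, max_depth = max_depth,
                 deep_partners = as.integer(names(dp)[dp >= 3])),
            class = "chain_graph")
}

#' @export
print.chain_graph <- function(x, ...) {
  cat(sprintf("chain_graph: %d roots, %d chained residues (threshold %.2f, depth <= %d)\n",
              length(x$roots), nrow(x$edges), x$threshold, x$max_depth))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Hinge prediction

#' Hinge-point prediction from a B-factor profile
#'
#' Implements a B-factor slope-change rule: the smoothed profile (running
#' mean, window 3) is split at its median into fixed (low-B) and floppy
#' (high-B) stretches, and hinge candidates are the residues where the
#' discrete slope of the profile changes most sharply (local maxima of the
#' absolute second difference), scored by that slope change and assigned to
#' the N- or C-terminal side of the loop.  A suitable hinge structure shows
#' a fixed domain, a floppy domain, and hinges at the sharp slope change
#' between them.
#'
#' @param profile a `flexibility_profile` (from [rmsf_profile()] or
#'   [anm_bfactors()]) covering the loop and its flanks.
#' @param loop_range length-2 residue-number range of the loop.
#' @return object of class `hinge_prediction`: data.frame `candidates`
#'   (`resno`, `side`, `score`), `boundaries` (fixed/floppy label changes on
#'   the smoothed profile) and the smoothed profile.  Zero-row candidates
#'   with attribute `message = "no hinge detected"` for a flat profile.
#' @export
predict_hinges <- function(profile, loop_range) {
  b <- profile$bfactor
  resno <- profile$resno
  sm <- smooth3(b)
  no_hinge <- function() {
    out <- structure(list(candidates = data.frame(resno = integer(0),
                                                  side = character(0),
                                                  score = numeric(0)),
                          boundaries = integer(0), smoothed = sm,
                          resno = resno, loop_range = loop_range),
                     class = "hinge_prediction")
    attr(out, "message") <- "no hinge detected"
    out
  }
  if (diff(range(sm)) < 0.05 * mean(sm)) return(no_hinge())
  lab <- sm >= stats::median(sm)    # TRUE = floppy
  change <- which(diff(lab) != 0)   # boundary between k and k+1
  if (length(change) == 0) return(no_hinge())
  n <- length(b)
  curv <- abs(b[3:n] - 2 * b[2:(n - 1)] + b[1:(n - 2)])   # centred at 2..n-1
  is_max <- curv >= c(-Inf, curv[-length(curv)]) &
    curv >= c(curv[-1], -Inf) & curv > 0
  k <- which(is_max) + 1
  if (length(k) == 0) return(no_hinge())
  cand <- data.frame(
    resno = resno[k],
    side = ifelse(resno[k] < mean(loop_range), "N", "C"),
    score = curv[k - 1]
  )
  cand <- cand[order(cand$side, -cand$score), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(candidates = cand, boundaries = change, smoothed = sm,
                 resno = resno, loop_range = loop_range),
            class = "hinge_prediction")
}

#' @export
print.hinge_prediction <- function(x, ...) {
  msg <- attr(x, "message")
  if (!is.null(msg)) {
    cat("hinge_prediction:", msg, "\n")
  } else {
    top <- do.call(rbind, lapply(split(x$candidates, x$candidates$side),
                                 utils::head, 1))
    cat("hinge_prediction: top candidates\n")
    print(top)
  }
  invisible(x)
}

#' @noRd
smooth3 <- function(b) {
  n <- length(b)
  out <- b
  if (n >= 3) out[2:(n - 1)] <- (b[1:(n - 2)] + b[2:(n - 1)] + b[3:n]) / 3
  out
}

#' Pairwise Pearson consistency of replica flexibility profiles
#'
#' @param profiles list of `flexibility_profile`s of equal length.
#' @return list with `matrix` (pairwise Pearson r on RMSF), `min`, `mean`
#'   (off-diagonal summaries); zero-variance profiles give NA entries with a
#'   warning.
#' @export
replica_consistency <- function(profiles) {
  if (length(profiles) < 2) stopf("need at least 2 profiles")
  lens <- vapply(profiles, nrow, integer(1))
  if (length(unique(lens)) != 1) stopf("profiles have different lengths")
  M <- vapply(profiles, function(p) p$rmsf, numeric(lens[1]))
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) warnf("zero-variance profile(s): undefined pairs marked NA")
  R <- suppressWarnings(stats::cor(M))
  off <- R[upper.tri(R)]
  list(matrix = R,
       min = if (all(is.na(off))) NA_real_ else min(off, na.rm = TRUE),
       mean = if (all(is.na(off))) NA_real_ else mean(off, na.rm = TRUE))
}
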