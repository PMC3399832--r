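# Salt-bridge and hydrophobic contact detection, persistence filtering and
# interaction graphs over conformational ensembles.
#
# Definitions follow common salt-bridge practice: a frame is a contact when
# the MINIMUM inter-group atom distance is below the cutoff (0.45 nm for
# oppositely charged groups, 0.55 nm for hydrophobic side-chain carbons) and
# persistence is the contact fraction over the (macro-)trajectory; records
# below 20 % persistence are treated as noise and dropped.

#' Interaction-network parameters
#'
#' @param saltbridge_cutoff nm (default 0.45).
#' @param hydrophobic_cutoff nm (default 0.55).
#' @param persistence_cutoff minimum contact fraction retained (default 0.20).
#' @param angle_screen optional geometric screen on salt bridges (off by
#'   default: the distance rule is the definition; when on, contacts also
#'   require an N-O-C angle above `angle_min`).
#' @param angle_min degrees (default 90).
#' @param his_charged treat histidine as protonated/charged (default FALSE).
#' @export
network_params <- function(saltbridge_cutoff = 0.45, hydrophobic_cutoff = 0.55,
                           persistence_cutoff = 0.20, angle_screen = FALSE,
                           angle_min = 90, his_charged = FALSE) {
  if (saltbridge_cutoff <= 0 || hydrophobic_cutoff <= 0) {
    stopf("distance cutoffs must be positive")
  }
  if (persistence_cutoff < 0 || persistence_cutoff > 1) {
    stopf("persistence_cutoff must be in [0, 1]")
  }
  structure(list(saltbridge_cutoff = saltbridge_cutoff,
                 hydrophobic_cutoff = hydrophobic_cutoff,
                 persistence_cutoff = persistence_cutoff,
                 angle_screen = angle_screen, angle_min = angle_min,
                 his_charged = his_charged),
            class = "network_params")
}

#' @noRd
residue_group_atoms <- function(ref, res_index, kind, his_charged = FALSE) {
  a <- ref$atoms
  rows <- which(a$res_index == res_index)
  resname <- ref$res$resname[res_index]
  if (kind == "saltbridge") {
    grp <- .CHARGED_GROUPS
    if (!his_charged) grp$HIS <- NULL
    nm <- grp[[resname]]
    if (is.null(nm)) return(integer(0))
    rows[a$name[rows] %in% nm]
  } else {
    if (!(resname %in% .HYDROPHOBIC_RES)) return(integer(0))
    sc <- rows[!(a$name[rows] %in% c(.BACKBONE_ATOMS, .BACKBONE_H))]
    sc[a$element[sc] == "C"]
  }
}

#' Detect salt-bridge or hydrophobic contacts across an ensemble
#'
#' For every residue pair between the two selections (opposite formal charge
#' required for salt bridges), the per-frame contact state is recorded;
#' nothing is filtered at this stage.  If the ensemble carries replica
#' boundaries (see [macro_trajectory()]) per-replica persistences are
#' reported alongside the pooled one.
#'
#' @param ens an all-atom [ensemble()].
#' @param sel_a,sel_b residue selections: vectors of residue numbers, or
#'   lists `list(chain =, resno =)`.
#' @param kind `"saltbridge"` or `"hydrophobic"`.
#' @param params a [network_params()].
#' @return object of class `interaction_records`: `records` data.frame
#'   (`res_a`, `res_b`, `name_a`, `name_b`, `kind`, `persistence`, plus
#'   per-replica columns when applicable) and `contacts` (pairs x frames
#'   logical matrix).
#' @export
detect_contacts <- function(ens, sel_a, sel_b,
                            kind = c("saltbridge", "hydrophobic"),
                            params = network_params()) {
  kind <- match.arg(kind)
  ref <- ens$ref
  res_a <- resolve_residues(ref, sel_a)
  res_b <- resolve_residues(ref, sel_b)
  cutoff <- 10 * switch(kind, saltbridge = params$saltbridge_cutoff,
                        hydrophobic = params$hydrophobic_cutoff)   # nm -> A
  groups_a <- lapply(res_a, residue_group_atoms, ref = ref, kind = kind,
                     his_charged = params$his_charged)
  groups_b <- lapply(res_b, residue_group_atoms, ref = ref, kind = kind,
                     his_charged = params$his_charged)
  keep_a <- lengths(groups_a) > 0
  keep_b <- lengths(groups_b) > 0
  if (!any(keep_a) || !any(keep_b)) {
    stopf("selection resolves to no %s group atoms", kind)
  }
  res_a <- res_a[keep_a]; groups_a <- groups_a[keep_a]
  res_b <- res_b[keep_b]; groups_b <- groups_b[keep_b]

  pair_list <- list()
  for (ia in seq_along(res_a)) {
    for (ib in seq_along(res_b)) {
      if (res_a[ia] == res_b[ib]) next
      if (kind == "saltbridge") {
        sa <- .CHARGE_SIGN[ref$res$resname[res_a[ia]]]
        sb <- .CHARGE_SIGN[ref$res$resname[res_b[ib]]]
        if (is.na(sa) || is.na(sb) || sa * sb >= 0) next
      }
      pair_list[[length(pair_list) + 1]] <- list(a = res_a[ia], b = res_b[ib],
                                                 ga = groups_a[[ia]],
                                                 gb = groups_b[[ib]])
    }
  }
  if (length(pair_list) == 0) {
    stopf("no admissible %s residue pairs between the selections", kind)
  }
  nf <- n_frames(ens)
  contacts <- matrix(FALSE, length(pair_list), nf)
  for (f in seq_len(nf)) {
    xm <- frame_coords(ens, f)
    for (p in seq_along(pair_list)) {
      pl <- pair_list[[p]]
      da <- xm[pl$ga, , drop = FALSE]
      db <- xm[pl$gb, , drop = FALSE]
      d2 <- outer(rowSums(da^2), rowSums(db^2), `+`) - 2 * tcrossprod(da, db)
      contacts[p, f] <- min(d2) < cutoff^2
    }
  }
  res_label <- function(ri) sprintf("%s%d_%s", ref$res$resname[ri],
                                    ref$res$resno[ri], ref$res$chain[ri])
  rec <- data.frame(
    res_a = vapply(pair_list, `[[`, integer(1), "a"),
    res_b = vapply(pair_list, `[[`, integer(1), "b"),
    stringsAsFactors = FALSE
  )
  rec$name_a <- vapply(rec$res_a, res_label, character(1))
  rec$name_b <- vapply(rec$res_b, res_label, character(1))
  rec$kind <- kind
  rec$persistence <- rowMeans(contacts)
  bounds <- attr(ens, "replica_boundaries")
  if (!is.null(bounds)) {
    starts <- c(1, utils::head(bounds, -1) + 1)
    for (r in seq_along(starts)) {
      cols <- starts[r]:bounds[r]
      rec[[sprintf("persistence_rep%d", r)]] <-
        rowMeans(contacts[, cols, drop = FALSE])
    }
  }
  structure(list(records = rec, contacts = contacts, params = params),
            class = "interaction_records")
}

#' @noRd
resolve_residues <- function(ref, sel) {
  if (is.list(sel)) {
    idx <- seq_len(nrow(ref$res))
    if (!is.null(sel$chain)) idx <- idx[ref$res$chain[idx] %in% sel$chain]
    if (!is.null(sel$resno)) idx <- idx[ref$res$resno[idx] %in% sel$resno]
    idx
  } else {
    which(ref$res$resno %in% sel)
  }
}

#' @export
print.interaction_records <- function(x, ...) {
  cat(sprintf("interaction_records: %d %s pair(s) over %d frames\n",
              nrow(x$records), x$records$kind[1], ncol(x$contacts)))
  invisible(x)
}

#' Filter records by persistence and build the interaction graph
#'
#' Residues become nodes of an unrooted, unoriented graph; an arc connects
#' two residues when their contact persists in at least the cutoff fraction
#' of frames (arc weight = persistence).  The persistence histogram is
#' returned so the signal/noise separation behind the 20 % cutoff can be
#' inspected.
#'
#' @param x an [detect_contacts()] result.
#' @param params a [network_params()].
#' @return object of class `interaction_graph`: `graph` (igraph), `records`
#'   (retained rows), `histogram` (hist of all persistences).
#' @export
filter_by_persistence <- function(x, params = x$params %||% network_params()) {
  rec <- x$records
  keep <- rec$persistence >= params$persistence_cutoff
  kept <- rec[keep, , drop = FALSE]
  h <- graphics::hist(rec$persistence, breaks = seq(0, 1, by = 0.05),
                      plot = FALSE)
  g <- if (nrow(kept) > 0) {
    igraph::graph_from_data_frame(
      data.frame(from = kept$name_a, to = kept$name_b,
                 weight = kept$persistence, kind = kept$kind),
      directed = FALSE
    )
  } else {
    igraph::make_empty_graph(directed = FALSE)
  }
  structure(list(graph = g, records = kept, histogram = h,
                 persistence_cutoff = params$persistence_cutoff),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction_graph: %d node(s), %d arc(s) at persistence >= %.0f%%\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              100 * x$persistence_cutoff))
  invisible(x)
}

#' Join replica ensembles into a macro-trajectory
#'
#' Concatenates the equilibrated portion of each replica (after discarding
#' the requested leading frames) and records the replica boundaries so that
#' per-replica and pooled persistences are both computable; the pooled
#' persistence is by construction the frame-weighted mean of the per-replica
#' persistences.
#'
#' @param ensembles list of congruent [ensemble()]s.
#' @param discard integer vector (recycled): leading frames to drop per
#'   replica.
#' @return an [ensemble()] with attribute `replica_boundaries` (cumulative
#'   end-frame of each replica in the concatenation).
#' @export
macro_trajectory <- function(ensembles, discard = 0) {
  if (length(ensembles) == 0) stopf("no ensembles given")
  nat <- vapply(ensembles, function(e) n_atoms(e$ref), integer(1))
  if (length(unique(nat)) != 1) stopf("replicas are incongruent: atom counts %s",
                                      paste(unique(nat), collapse = ", "))
  discard <- rep_len(discard, length(ensembles))
  parts <- vector("list", length(ensembles))
  for (r in seq_along(ensembles)) {
    nf <- n_frames(ensembles[[r]])
    if (discard[r] >= nf) stopf("replica %d: discarding %d of %d frames", r,
                                discard[r], nf)
    parts[[r]] <- ensembles[[r]]$xyz[(discard[r] + 1):nf, , drop = FALSE]
  }
  xyz <- do.call(rbind, parts)
  out <- ensemble(ensembles[[1]]$ref, xyz,
                  frame_spacing = ensembles[[1]]$frame_spacing,
                  provenance = "external")
  attr(out, "replica_boundaries") <- cumsum(vapply(parts, nrow, integer(1)))
  out
}
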