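# Structure, ensemble and alignment containers plus readers/writers.
#
# Coordinates are stored in Angstrom.  Residue numbering follows the PDB
# (1-based, with insertion codes kept as part of the residue identity);
# internal atom/residue indices are plain R indices into the tables below.

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
.BACKBONE_H <- c("H", "H1", "H2", "H3", "HA", "HA2", "HA3", "HN")

# Atom names carrying the formal charge of ionizable side chains.
.CHARGED_GROUPS <- list(
  LYS = c("NZ"),
  ARG = c("NE", "NH1", "NH2"),
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2")
)
.CHARGE_SIGN <- c(LYS = +1, ARG = +1, ASP = -1, GLU = -1, HIS = +1)

.HYDROPHOBIC_RES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO", "TYR")

.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a protein structure object
#'
#' `ca_structure` is the coordinate container used throughout the package:
#' an ordered atom table plus a residue table, either all-atom or reduced to
#' C-alpha beads.  Every residue must expose exactly one CA atom and residue
#' numbers must be strictly increasing within a chain.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `ins`, `resname`,
#'   `name` (atom name), `element`, `x`, `y`, `z` (Angstrom).
#' @return an object of class `ca_structure` with components `atoms`
#'   (atom table including `res_index`), `res` (residue table with `ca_atom`
#'   pointing at the CA row of each residue) and `calpha_only`.
#' @export
ca_structure <- function(atoms) {
  need <- c("chain", "resno", "resname", "name", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stopf("atom table must have columns: %s", paste(need, collapse = ", "))
  }
  if (is.null(atoms$ins)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  if (is.null(atoms$element)) {
    atoms$element <- guess_element(atoms$name)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stopf("non-finite coordinates in atom table")

  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")
  res_index <- match(key, unique(key))
  atoms$res_index <- res_index
  first <- !duplicated(res_index)
  res <- data.frame(
    chain = atoms$chain[first], resno = atoms$resno[first],
    ins = atoms$ins[first], resname = atoms$resname[first],
    stringsAsFactors = FALSE
  )

  # residue order strictly increasing within each chain
  for (ch in unique(res$chain)) {
    rn <- res$resno[res$chain == ch]
    if (any(diff(rn) <= 0)) {
      stopf("residue numbers not strictly increasing in chain %s", ch)
    }
  }

  ca <- which(atoms$name == "CA")
  ca_res <- atoms$res_index[ca]
  if (anyDuplicated(ca_res) || length(ca) != nrow(res)) {
    stopf("every residue must have exactly one CA atom")
  }
  res$ca_atom <- ca[order(ca_res)]

  structure(
    list(atoms = atoms, res = res,
         calpha_only = all(atoms$name == "CA")),
    class = "ca_structure"
  )
}

#' @noRd
guess_element <- function(name) {
  el <- sub("^[0-9]*", "", name)
  substr(el, 1, 1)
}

#' @export
print.ca_structure <- function(x, ...) {
  cat(sprintf("ca_structure: %d residues, %d atoms (%s)\n",
              nrow(x$res), nrow(x$atoms),
              if (x$calpha_only) "C-alpha only" else "all-atom"))
  invisible(x)
}

#' Number of atoms / residues
#' @param x a `ca_structure`
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' @rdname n_atoms
#' @export
n_residues <- function(x) nrow(x$res)

#' Atom coordinates as an n x 3 matrix
#' @param x a `ca_structure`
#' @export
coords <- function(x) {
  m <- as.matrix(x$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Reduce a structure to its C-alpha trace
#' @param x a `ca_structure`
#' @return a C-alpha only `ca_structure` with one atom per residue.
#' @export
as_calpha <- function(x) {
  if (x$calpha_only) return(x)
  ca_structure(x$atoms[x$res$ca_atom, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# Ensembles

#' Construct a conformational ensemble
#'
#' An ensemble is an ordered set of coordinate frames congruent with a
#' reference structure.  All samplers (NMA, BD, DMD) and the multi-model PDB
#' reader produce this container, and all analyses consume it.
#'
#' @param ref reference `ca_structure` defining atom identity and ordering.
#' @param xyz frames as an `n_frames x 3*n_atoms` matrix (x1,y1,z1,x2,...).
#' @param frame_spacing time per frame in ps, or `NA` for ensembles without a
#'   time axis (e.g. normal-mode sampling).
#' @param provenance one of "NMA", "BD", "DMD", "external".
#' @return object of class `ensemble`.
#' @export
ensemble <- function(ref, xyz, frame_spacing = NA_real_, provenance = "external") {
  if (!inherits(ref, "ca_structure")) stopf("ref must be a ca_structure")
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms(ref)) {
    stopf("frame width %d does not match 3 x %d atoms", ncol(xyz), n_atoms(ref))
  }
  if (!all(is.finite(xyz))) stopf("non-finite coordinates in ensemble")
  if (!is.na(frame_spacing) && frame_spacing <= 0) {
    stopf("frame_spacing must be positive (or NA for non-time-based ensembles)")
  }
  structure(
    list(ref = ref, xyz = xyz, frame_spacing = frame_spacing,
         provenance = provenance),
    class = "ensemble"
  )
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d frames x %d atoms [%s], frame spacing %s\n",
              n_frames(x), n_atoms(x$ref), x$provenance,
              if (is.na(x$frame_spacing)) "arbitrary" else
                paste0(x$frame_spacing, " ps")))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param x an `ensemble`
#' @export
n_frames <- function(x) nrow(x$xyz)

#' Extract one frame as an n x 3 coordinate matrix
#' @param x an `ensemble`
#' @param i frame index
#' @export
frame_coords <- function(x, i) frame_to_mat(x$xyz[i, ])

# ---------------------------------------------------------------------------
# PDB I/O (via bio3d)

#' Read a PDB file
#'
#' Waters and heteroatoms are excluded; alternate locations are resolved by
#' keeping the highest-occupancy copy; residues lacking a CA atom are dropped
#' with a warning.
#'
#' @param path PDB file.
#' @param model_policy `"first"` returns a single [ca_structure()] (model 1);
#'   `"all"` returns an [ensemble()] over all models (provenance "external").
#' @return `ca_structure` or `ensemble`.
#' @export
read_pdb <- function(path, model_policy = c("first", "all")) {
  model_policy <- match.arg(model_policy)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = model_policy == "all", verbose = FALSE),
    error = function(e) stopf("cannot read PDB file '%s': %s", path, conditionMessage(e))
  )
  at <- pdb$atom
  keep <- at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT"))
  # altloc: keep blank or the highest-occupancy alternative per atom identity
  if (any(!is.na(at$alt) & at$alt != "")) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    id <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    best <- tapply(seq_len(nrow(at)), id, function(ii) ii[which.max(occ[ii])])
    keep <- keep & seq_len(nrow(at)) %in% unlist(best)
  }
  idx <- which(keep)
  at <- at[idx, , drop = FALSE]
  ins <- at$insert
  ins[is.na(ins)] <- ""
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno, ins = ins, resname = at$resid,
    name = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     guess_element(at$elety), at$elesy),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  # drop residues without a CA
  rkey <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")
  has_ca <- rkey %in% rkey[atoms$name == "CA"]
  if (any(!has_ca)) {
    dropped <- unique(rkey[!has_ca])
    warnf("dropping %d residue(s) without a CA atom: %s",
          length(dropped), paste(utils::head(dropped, 5), collapse = ", "))
    atoms <- atoms[has_ca, , drop = FALSE]
    idx <- idx[has_ca]
  }
  if (nrow(atoms) == 0) stopf("no protein atoms found in '%s'", path)
  ref <- ca_structure(atoms)
  if (model_policy == "first") return(ref)
  xyz_cols <- bio3d::atom2xyz(idx)
  xyz <- pdb$xyz[, xyz_cols, drop = FALSE]
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  ensemble(ref, xyz, frame_spacing = NA_real_, provenance = "external")
}

#' Write an ensemble (or structure) as a multi-model PDB file
#'
#' Multi-model PDB is the ensemble interchange format of the package: a
#' write/read round trip reproduces coordinates to PDB precision (1e-3 A).
#'
#' @param x an [ensemble()] or [ca_structure()].
#' @param path output file.
#' @export
write_ensemble <- function(x, path) {
  if (inherits(x, "ca_structure")) x <- ensemble(x, matrix(mat_to_frame(coords(x)), nrow = 1))
  if (!inherits(x, "ensemble")) stopf("x must be an ensemble or ca_structure")
  a <- x$ref$atoms
  bio3d::write.pdb(
    file = path, xyz = x$xyz,
    resno = a$resno, resid = a$resname, chain = a$chain,
    insert = ifelse(a$ins == "", NA, a$ins),
    elety = a$name, elesy = a$element
  )
  invisible(path)
}

# ---------------------------------------------------------------------------
# Atom group selection

#' Select an atom group from a structure
#'
#' Deterministic atom-index selection used by the interaction-network and
#' accessibility analyses.
#'
#' @param x a `ca_structure`.
#' @param chain chain identifier, or `NULL` for all chains.
#' @param resno residue numbers to include (vector), or `NULL` for all.
#' @param class one of `"calpha"`, `"sidechain"`, `"charged-group"`, `"all"`.
#'   `"charged-group"` resolves to NZ (Lys), NE/NH1/NH2 (Arg), OD1/OD2 (Asp),
#'   OE1/OE2 (Glu), optionally ND1/NE2 (His), plus the charged termini
#'   (backbone N of the first, O/OXT of the last residue of each chain).
#' @param his_charged include histidine among charged groups (default FALSE:
#'   neutral at standard pH).
#' @param include_termini include terminal backbone charges for
#'   `"charged-group"` selections (default TRUE).
#' @return integer vector of atom indices (rows of `x$atoms`).
#' @export
select_group <- function(x, chain = NULL, resno = NULL,
                         class = c("calpha", "sidechain", "charged-group", "all"),
                         his_charged = FALSE, include_termini = TRUE) {
  class <- match.arg(class)
  a <- x$atoms
  in_scope <- rep(TRUE, nrow(a))
  if (!is.null(chain)) in_scope <- in_scope & a$chain %in% chain
  if (!is.null(resno)) in_scope <- in_scope & a$resno %in% resno

  sel <- switch(class,
    "calpha" = in_scope & a$name == "CA",
    "all" = in_scope,
    "sidechain" = in_scope &
      !(a$name %in% c(.BACKBONE_ATOMS, .BACKBONE_H)) &
      !grepl("^[0-9]*H", a$name),
    "charged-group" = {
      grp <- .CHARGED_GROUPS
      if (!his_charged) grp$HIS <- NULL
      ok <- rep(FALSE, nrow(a))
      for (rn in names(grp)) {
        ok <- ok | (a$resname == rn & a$name %in% grp[[rn]])
      }
      if (include_termini) {
        for (ch in unique(a$chain)) {
          ri <- x$res[x$res$chain == ch, , drop = FALSE]
          first_res <- ri$resno[1]
          last_res <- ri$resno[nrow(ri)]
          ok <- ok | (a$chain == ch & a$resno == first_res & a$name == "N")
          ok <- ok | (a$chain == ch & a$resno == last_res & a$name %in% c("O", "OXT"))
        }
      }
      in_scope & ok
    }
  )
  idx <- which(sel)
  if (length(idx) == 0) {
    stopf("empty selection: chain=%s resno=%s class=%s",
          paste(chain %||% "*", collapse = ","),
          paste(range(resno %||% NA), collapse = "-"), class)
  }
  idx
}

# ---------------------------------------------------------------------------
# Alignments

#' Construct an alignment block
#'
#' @param ids sequence identifiers.
#' @param seqs gapped sequences (equal length, amino-acid one-letter codes,
#'   `-` for gaps; ambiguous codes are mapped to `X` with a warning).
#' @return object of class `alignment_block` with components `ids`, `seqs`,
#'   `ncol` and a character matrix `mat` (sequences x columns).
#' @export
alignment_block <- function(ids, seqs) {
  seqs <- toupper(seqs)
  seqs <- gsub("\\.", "-", seqs)
  len <- nchar(seqs)
  if (length(unique(len)) != 1) {
    stopf("ragged alignment: sequence lengths %s", paste(unique(len), collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  bad <- !(mat %in% c(.AA1, "-", "X"))
  if (any(bad)) {
    warnf("%d ambiguous residue code(s) mapped to X", sum(bad))
    mat[bad] <- "X"
    seqs <- apply(mat, 1, paste, collapse = "")
  }
  structure(list(ids = as.character(ids), seqs = seqs,
                 ncol = len[1], mat = mat),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("alignment_block: %d sequences x %d columns\n",
              length(x$ids), x$ncol))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return an [alignment_block()].
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- tryCatch(
    seqinr::read.alignment(path, format = format),
    error = function(e) stopf("cannot read %s alignment '%s': %s",
                              format, path, conditionMessage(e))
  )
  alignment_block(aln$nam, unlist(aln$seq))
}
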