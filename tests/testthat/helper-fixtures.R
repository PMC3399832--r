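# Shared fixtures built in code (no stored data files).

# five-bead helical chain: the standard small non-degenerate network
helix5 <- function() make_chain(5, "helix")

# hand-written minimal PDB text (3 residues, one with a side chain)
write_tiny_pdb <- function(path, models = 1, jitter_by_model = 0) {
  atoms <- list(
    c("N", "GLY", 1, 0.0, 0.0, 0.0, "N"),
    c("CA", "GLY", 1, 1.46, 0.0, 0.0, "C"),
    c("C", "GLY", 1, 2.0, 1.4, 0.0, "C"),
    c("O", "GLY", 1, 3.2, 1.6, 0.0, "O"),
    c("N", "CYS", 2, 1.2, 2.4, 0.0, "N"),
    c("CA", "CYS", 2, 1.6, 3.8, 0.0, "C"),
    c("CB", "CYS", 2, 0.9, 4.6, -1.1, "C"),
    c("SG", "CYS", 2, 1.1, 6.4, -1.0, "S"),
    c("C", "CYS", 2, 3.1, 3.9, 0.2, "C"),
    c("O", "CYS", 2, 3.9, 3.2, -0.4, "O"),
    c("N", "ARG", 3, 3.5, 4.8, 1.1, "N"),
    c("CA", "ARG", 3, 4.9, 5.0, 1.4, "C"),
    c("NE", "ARG", 3, 5.5, 6.4, 1.2, "N"),
    c("NH1", "ARG", 3, 7.0, 8.0, 1.5, "N"),
    c("NH2", "ARG", 3, 5.2, 8.6, 0.9, "N"),
    c("C", "ARG", 3, 5.6, 4.0, 2.3, "C"),
    c("O", "ARG", 3, 6.8, 3.9, 2.3, "O")
  )
  lines <- character(0)
  for (m in seq_len(models)) {
    if (models > 1) lines <- c(lines, sprintf("MODEL     %4d", m))
    for (k in seq_along(atoms)) {
      a <- atoms[[k]]
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        k, a[1], a[2], as.integer(a[3]),
        as.numeric(a[4]) + (m - 1) * jitter_by_model,
        as.numeric(a[5]), as.numeric(a[6]), a[7]))
    }
    if (models > 1) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# all-atom structure from two synthetic residues plus helpers
two_residue_structure <- function(resname_a = "ASP", resname_b = "ARG",
                                  separation = 10) {
  ra <- loopdyn:::synthetic_residue(resname_a, "A", 1, c(0, 0, 0))
  rb <- loopdyn:::synthetic_residue(resname_b, "B", 1, c(separation, 0, 0))
  ca_structure(rbind(ra, rb))
}

# independent depth oracle for chained correlations: boolean adjacency powers
chain_depth_oracle <- function(C, roots, threshold, max_depth) {
  A <- abs(C) >= threshold
  diag(A) <- FALSE
  n <- nrow(C)
  depth <- rep(NA_integer_, n)
  depth[roots] <- 0L
  reach <- rep(FALSE, n)
  reach[roots] <- TRUE
  for (d in seq_len(max_depth)) {
    new_reach <- as.logical((A %*% reach) > 0) & !reach
    depth[new_reach & is.na(depth)] <- d
    reach <- reach | new_reach
    if (!any(new_reach)) break
  }
  depth
}

mat_to_frame_test <- function(m) as.numeric(t(m))
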