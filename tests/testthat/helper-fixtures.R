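# Fixtures are built in code; nothing is read from disk.

# hand-written two-residue, one-chain PDB with an altloc pair and a water
toy_pdb_text <- function() {
  paste(c(
    "ATOM      1  N   ASP A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ASP A   1       1.460   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CG AASP A   1       2.500   1.000   0.000  0.60  0.00           C",
    "ATOM      4  CG BASP A   1       2.600   1.100   0.000  0.40  0.00           C",
    "ATOM      5  N   GLY A   2       4.000   0.000   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       5.460   0.000   0.000  1.00  0.00           C",
    "HETATM    7  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END"), collapse = "\n")
}

two_model_pdb_text <- function() {
  atom <- function(serial, xyz) sprintf(
    "ATOM  %5d  CA  GLY A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
    serial, xyz[1], xyz[2], xyz[3])
  paste(c("MODEL        1", atom(1, c(0, 0, 0)), "ENDMDL",
          "MODEL        2", atom(1, c(10, 0, 0)), "ENDMDL", "END"),
        collapse = "\n")
}

# n-residue poly-glycine along x (N, CA, C, O per residue)
polygly_pdb_text <- function(n = 3) {
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    x0 <- (i - 1) * 4
    data.frame(atom = c("N", "CA", "C", "O"), resname = "GLY",
               chain = "A", resnum = i,
               x = x0 + c(0, 1.46, 2.98, 3.6),
               y = c(0, 0, 0, 1.05), z = 0)
  }))
  phstab:::rows_to_pdb(rows)
}

# residue of the given kind enclosed in a dense synthetic carbon cage
caged_residue_pdb <- function(kind = "ASP", radius = 5.5, n_cage = 400) {
  tpl <- phstab:::template_atoms(kind)
  cage <- sweep(phstab:::sphere_points(n_cage) * radius, 2,
                c(0, -2, 0), "+")
  rows <- rbind(
    data.frame(atom = rownames(tpl), resname = kind, chain = "A",
               resnum = 1L, x = tpl[, 1], y = tpl[, 2], z = tpl[, 3]),
    data.frame(atom = "C", resname = "GLY", chain = "B",
               resnum = seq_len(n_cage), x = cage[, 1], y = cage[, 2],
               z = cage[, 3])
  )
  phstab:::rows_to_pdb(rows)
}

# independent Monte Carlo SASA oracle: random (not spiral) surface points
mc_sasa_total <- function(s, n_pts = 8000, probe = 1.4, seed = 1) {
  at <- s$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- phstab:::vdw_radius(at$element) + probe
  set.seed(seed)
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    v <- matrix(stats::rnorm(3 * n_pts), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    pts <- sweep(v * rad[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_pts)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      free <- free & d2 >= rad[j]^2
    }
    total <- total + 4 * pi * rad[i]^2 * mean(free)
  }
  total
}

# brute-force all-atom-pair contact oracle
brute_contacts <- function(s, acid_atoms, partner_sel, cutoff) {
  at <- as.data.frame(s$atoms)
  acids <- at[paste(at$resname, at$atom) %in% acid_atoms, ]
  partners <- at[partner_sel(at), ]
  hits <- list()
  for (i in seq_len(nrow(acids))) for (j in seq_len(nrow(partners))) {
    a <- acids[i, ]; p <- partners[j, ]
    if (a$chain == p$chain && a$resnum == p$resnum) next
    d <- sqrt((a$x - p$x)^2 + (a$y - p$y)^2 + (a$z - p$z)^2)
    if (d <= cutoff) {
      hits[[length(hits) + 1L]] <- data.frame(
        acid_chain = a$chain, acid_resnum = a$resnum,
        partner_chain = p$chain, partner_resnum = p$resnum, distance = d)
    }
  }
  if (!length(hits)) return(data.frame())
  h <- do.call(rbind, hits)
  # one row per residue pair at minimum distance
  key <- paste(h$acid_chain, h$acid_resnum, h$partner_chain,
               h$partner_resnum)
  h <- h[order(h$distance), ]
  h[!duplicated(paste(h$acid_chain, h$acid_resnum, h$partner_chain,
                      h$partner_resnum)), ]
}

acid_o_atoms <- c("ASP OD1", "ASP OD2", "GLU OE1", "GLU OE2")

# translate every atom of a structure
shift_structure <- function(s, dx = 0, dy = 0, dz = 0) {
  s$atoms$x <- s$atoms$x + dx
  s$atoms$y <- s$atoms$y + dy
  s$atoms$z <- s$atoms$z + dz
  s
}

# append a far-translated copy of a structure's atoms as new chains
duplicate_far <- function(s, offset = 500) {
  copy <- s$atoms
  copy$x <- copy$x + offset
  copy$chain <- paste0(copy$chain, "2")
  s$atoms <- rbind(s$atoms, copy)
  s
}

dg_at <- function(profile_tbl, ph) {
  profile_tbl$dG_per_aa[which.min(abs(profile_tbl$pH - ph))]
}

# Henderson-Hasselbalch mean protonation
hh_protonation <- function(pka, ph) 1 / (1 + 10^(ph - pka))
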