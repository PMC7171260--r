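# van der Waals radii (Angstrom) by element; 1.7 default for unknowns.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Express coordinates in a molecule-fixed principal-axes frame so the
# discrete sphere-point occlusion test is invariant under rigid motion of
# the input (the point set is applied in the canonical frame). Eigenvector
# signs are fixed by the third moment along each axis.
canonical_frame <- function(xyz) {
  if (nrow(xyz) < 3L) return(sweep(xyz, 2, colMeans(xyz)))
  xc <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(xc), symmetric = TRUE)$vectors
  proj <- xc %*% ev
  for (j in 1:3) {
    m3 <- sum(proj[, j]^3)
    if (abs(m3) > 1e-8 && m3 < 0) proj[, j] <- -proj[, j]
  }
  proj
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-residue solvent-accessible surface area
#'
#' Shrake-Rupley accessible surface with a 1.4 A probe and a deterministic
#' 960-point sphere per atom (Fibonacci spiral, so results are exactly
#' reproducible). Standard van der Waals radii by element; hydrogens, when
#' present, are included like any other atom.
#'
#' @param s A `phs_structure`.
#' @param probe Probe radius, A.
#' @param n_points Sphere points per atom.
#' @return Tibble with one row per residue: `chain`, `resnum`, `icode`,
#'   `resname`, `sasa` (A^2) and `sasa_sidechain` (non-backbone atoms).
#' @export
residue_sasa <- function(s, probe = 1.4, n_points = 960) {
  at <- s$atoms
  if (nrow(at) == 0L) abort("structure has no atoms")
  xyz <- canonical_frame(as.matrix(at[, c("x", "y", "z")]))
  rad <- vdw_radius(at$element) + probe
  pts <- sphere_points(n_points)

  atom_area <- atom_sasa(xyz, rad, pts)
  backbone <- at$atom %in% c("N", "CA", "C", "O", "OXT")
  key <- paste(at$chain, at$resnum, at$icode, sep = "|")

  res <- dplyr::distinct(at, .data$chain, .data$resnum, .data$icode,
                         .data$resname)
  rkey <- paste(res$chain, res$resnum, res$icode, sep = "|")
  res$sasa <- unname(vapply(rkey, function(k) sum(atom_area[key == k]), 0))
  res$sasa_sidechain <- unname(vapply(
    rkey, function(k) sum(atom_area[key == k & !backbone]), 0))
  as_tibble(res)
}

# exposed fraction of each atom's expanded sphere, times its area
atom_sasa <- function(xyz, rad, pts) {
  n <- nrow(xyz)
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    surf <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    if (length(nb) == 0L) {
      frac <- 1
    } else {
      buried <- rep(FALSE, nrow(surf))
      for (j in nb) {
        dj <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
          (surf[, 3] - xyz[j, 3])^2
        buried <- buried | dj < rad[j]^2
        if (all(buried)) break
      }
      frac <- mean(!buried)
    }
    area[i] <- 4 * pi * rad[i]^2 * frac
  }
  area
}

# Sidechain SASA of an isolated residue of the given kind, from the
# package's own idealised residue template; used as the reference for
# relative accessibility. Memoised per session.
.ref_sasa_env <- new.env(parent = emptyenv())

reference_sidechain_sasa <- function(kind) {
  cached <- .ref_sasa_env[[kind]]
  if (!is.null(cached)) return(cached)
  pdb <- make_single_residue(kind)
  s <- parse_structure(pdb, id = paste0("ref_", kind), source = "synthetic")
  v <- residue_sasa(s)$sasa_sidechain[1]
  .ref_sasa_env[[kind]] <- v
  v
}
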