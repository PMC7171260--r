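# Idealised heavy-atom residue templates in a local frame: CA at the
# origin, backbone along x, sidechain extended along -y. Chemically
# plausible bond lengths; electrostatics only depends on the charge-centre
# positions, so no rotamer realism is attempted.
RES_TEMPLATES <- local({
  bb <- rbind(N = c(-1.458, 0, 0), CA = c(0, 0, 0), C = c(1.524, 0, 0),
              O = c(2.155, 1.056, 0))
  sc <- list(
    GLY = NULL,
    ALA = rbind(CB = c(0, -1.53, 0)),
    ASP = rbind(CB = c(0, -1.53, 0), CG = c(0, -3.06, 0),
                OD1 = c(1.06, -3.72, 0), OD2 = c(-1.06, -3.72, 0)),
    GLU = rbind(CB = c(0, -1.53, 0), CG = c(0, -3.06, 0),
                CD = c(0, -4.59, 0),
                OE1 = c(1.06, -5.25, 0), OE2 = c(-1.06, -5.25, 0)),
    LYS = rbind(CB = c(0, -1.53, 0), CG = c(0, -3.06, 0),
                CD = c(0, -4.59, 0), CE = c(0, -6.12, 0),
                NZ = c(0, -7.61, 0)),
    ARG = rbind(CB = c(0, -1.53, 0), CG = c(0, -3.06, 0),
                CD = c(0, -4.59, 0), NE = c(0, -6.06, 0),
                CZ = c(0, -7.39, 0),
                NH1 = c(1.09, -8.06, 0), NH2 = c(-1.09, -8.06, 0)),
    HIS = rbind(CB = c(0, -1.53, 0), CG = c(0, -3.03, 0),
                ND1 = c(1.09, -3.85, 0), CD2 = c(-1.09, -3.85, 0),
                CE1 = c(0.69, -5.12, 0), NE2 = c(-0.69, -5.12, 0)),
    ASN = rbind(CB = c(0, -1.53, 0), CG = c(0, -3.06, 0),
                OD1 = c(1.06, -3.72, 0), ND2 = c(-1.06, -3.72, 0)),
    GLN = rbind(CB = c(0, -1.53, 0), CG = c(0, -3.06, 0),
                CD = c(0, -4.59, 0),
                OE1 = c(1.06, -5.25, 0), NE2 = c(-1.06, -5.25, 0)),
    SER = rbind(CB = c(0, -1.53, 0), OG = c(0, -2.95, 0)),
    THR = rbind(CB = c(0, -1.53, 0), OG1 = c(1.2, -2.3, 0),
                CG2 = c(-1.2, -2.3, 0))
  )
  lapply(sc, function(s) if (is.null(s)) bb else rbind(bb, s))
})

template_atoms <- function(kind) {
  tpl <- RES_TEMPLATES[[kind]]
  if (is.null(tpl)) abort(sprintf("no residue template for kind '%s'",
                                  paste(kind, collapse = ", ")))
  tpl
}

# reference point of a template: the charge centre for ionisable kinds
# (same rule as extract_ionisable_sites), the donor atom for polar kinds
PLACEMENT_ATOMS <- list(ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1")

template_centre <- function(kind) {
  tpl <- template_atoms(kind)
  wanted <- CENTRE_ATOMS[[kind]] %||% PLACEMENT_ATOMS[[kind]] %||% "CA"
  colMeans(tpl[rownames(tpl) %in% wanted, , drop = FALSE])
}

# run code under a seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

atoms_to_rows <- function(xyz, resname, chain, resnum) {
  tibble(atom = rownames(xyz), resname = resname, chain = chain,
         resnum = resnum, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

rows_to_pdb <- function(rows) {
  paste(fmt_atom_lines(
    serial = seq_len(nrow(rows)), atom = rows$atom, resname = rows$resname,
    chain = rows$chain, resnum = rows$resnum, icode = rep("", nrow(rows)),
    x = rows$x, y = rows$y, z = rows$z
  ), collapse = "\n")
}

# single isolated residue (used for SASA references and small fixtures)
make_single_residue <- function(kind, chain = "A", resnum = 1L) {
  rows_to_pdb(atoms_to_rows(template_atoms(kind), kind, chain, resnum))
}

#' Two-residue fixture at a controlled charge-centre separation
#'
#' Builds PDB-format text for two residues on separate chains, with full
#' charge-atom sets, placed so the distance between their charge centres
#' equals `separation` to within 0.01 A.
#'
#' @param kind_a,kind_b Three-letter residue kinds (ASP, GLU, HIS, LYS,
#'   ARG, ASN, GLN, SER, THR, ALA, GLY).
#' @param separation Centre-centre distance, A (>= 3).
#' @return Character scalar of PDB text.
#' @export
#' @examples
#' s <- parse_structure(make_pair("ASP", "LYS", 4))
#' extract_ionisable_sites(s)
make_pair <- function(kind_a, kind_b, separation) {
  if (separation < 3) abort("separation must be at least 3 A")
  a <- template_atoms(kind_a)
  ca <- template_centre(kind_a)
  # rotate B 180 degrees about z so its sidechain points back towards A
  b <- template_atoms(kind_b)
  b_rot <- b %*% diag(c(-1, -1, 1))
  cb <- drop(template_centre(kind_b) %*% diag(c(-1, -1, 1)))
  shift <- ca + c(separation, 0, 0) - cb
  b_rot <- sweep(b_rot, 2, shift, "+")
  rownames(b_rot) <- rownames(b)
  rows <- dplyr::bind_rows(atoms_to_rows(a, kind_a, "A", 1L),
                           atoms_to_rows(b_rot, kind_b, "B", 1L))
  rows_to_pdb(rows)
}

#' Specification for a toy pseudo-domain
#'
#' @param n_residues Total residues on the circular CA backbone.
#' @param n_salt_bridges Engineered Asp-Lys pairs (closest carboxylate O to
#'   NZ at 3.5 A).
#' @param n_polar_swaps Engineered Asp-Asn pairs (carboxylate O to ND2 at
#'   3.0 A, plus a 3.2 A carboxylate-to-mainchain-N contact).
#' @param seed Seed for the deterministic spacer jitter.
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(n_residues = 60, n_salt_bridges = 6,
                     n_polar_swaps = 0, seed = 1L) {
  if (3 * (n_salt_bridges + n_polar_swaps) > n_residues)
    abort("too many engineered pairs for the residue count")
  structure(list(n_residues = as.integer(n_residues),
                 n_salt_bridges = as.integer(n_salt_bridges),
                 n_polar_swaps = as.integer(n_polar_swaps),
                 seed = as.integer(seed)), class = "toy_spec")
}

#' Toy pseudo-domain with a controlled interaction surface
#'
#' A compact circular CA backbone with stub sidechains, carrying exactly
#' `n_salt_bridges` Asp-Lys salt bridges and `n_polar_swaps` Asp-Asn
#' hydrogen-bond pairs (each swap also engineering a carboxylate to
#' mainchain-N contact); remaining residues are glycine spacers. Emulates
#' the contrast between a neutral-pH-optimised surface (salt bridges) and
#' an acid-adapted surface (carboxylate/polar hydrogen bonding).
#'
#' @param spec A [toy_spec()].
#' @return PDB text (character scalar) with a `manifest` attribute: a
#'   tibble listing every engineered contact with its atoms and distance.
#' @export
#' @examples
#' pdb <- make_toy_domain(toy_spec(n_residues = 40, n_salt_bridges = 4))
#' attr(pdb, "manifest")
make_toy_domain <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  n <- spec$n_residues
  npair <- spec$n_salt_bridges + spec$n_polar_swaps
  radius <- n * 3.8 / (2 * pi)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  ca <- cbind(radius * cos(theta), radius * sin(theta), 0)
  u <- cbind(cos(theta), sin(theta), 0)            # outward normal
  tangent <- cbind(-sin(theta), cos(theta), 0)

  # engineered pairs occupy consecutive (i, i+1) slots so the charged
  # patch is dense, as on a real charged protein surface: neighbouring
  # like charges then repel at the pH where their partners neutralise
  acid_idx <- 3L * seq_len(npair) - 2L
  kind <- rep("GLY", n)
  jitter <- with_local_seed(spec$seed, stats::runif(n, -0.2, 0.2))

  rows <- vector("list", n)
  manifest <- list()
  unit <- function(v) v / sqrt(sum(v^2))

  place_backbone <- function(i, dz = 0) {
    rbind(N = ca[i, ] - 1.458 * tangent[i, ] + c(0, 0, dz),
          CA = ca[i, ] + c(0, 0, dz),
          C = ca[i, ] + 1.524 * tangent[i, ] + c(0, 0, dz),
          O = ca[i, ] + 1.524 * tangent[i, ] + c(0, 0, 1.23 + dz))
  }

  for (i in seq_len(n)) rows[[i]] <- place_backbone(i, jitter[i])

  for (p in seq_len(npair)) {
    i <- acid_idx[p]
    j <- i + 1L
    is_bridge <- p <= spec$n_salt_bridges
    kind[i] <- "ASP"
    kind[j] <- if (is_bridge) "LYS" else "ASN"
    rows[[i]] <- place_backbone(i)   # engineered residues: no jitter
    rows[[j]] <- place_backbone(j)

    cg <- ca[i, ] + 3.0 * u[i, ]
    od1 <- cg + 1.25 * unit(0.85 * u[i, ] + 0.9 * tangent[i, ])
    rows[[i]] <- rbind(rows[[i]],
                       CB = ca[i, ] + 1.53 * u[i, ], CG = cg, OD1 = od1)

    if (is_bridge) {
      nz <- od1 + 3.5 * unit(ca[j, ] + 3.5 * u[j, ] - od1)
      od2 <- cg + 1.25 * unit(0.85 * u[i, ] - 0.9 * tangent[i, ])
      w <- unit(nz - ca[j, ])
      rows[[i]] <- rbind(rows[[i]], OD2 = od2)
      rows[[j]] <- rbind(rows[[j]],
                         CB = ca[j, ] + 1.53 * w, CG = ca[j, ] + 3.06 * w,
                         CD = ca[j, ] + 4.59 * w, CE = nz - 1.49 * w,
                         NZ = nz)
      manifest[[length(manifest) + 1L]] <- tibble(
        class = "salt_bridge", acid_resnum = i, partner_resnum = j,
        acid_atom = "OD1", partner_atom = "NZ",
        distance = sqrt(sum((nz - od1)^2)))
    } else {
      nd2 <- od1 + 3.0 * unit(ca[j, ] + 3.0 * u[j, ] - od1)
      n_j <- rows[[j]]["N", ]
      od2 <- n_j + 3.2 * unit(cg - n_j)
      w <- unit(nd2 - ca[j, ])
      rows[[i]] <- rbind(rows[[i]], OD2 = od2)
      rows[[j]] <- rbind(rows[[j]],
                         CB = ca[j, ] + 1.53 * w, CG = nd2 - 1.33 * w,
                         OD1 = nd2 - 1.33 * w + c(0, 0, 1.1), ND2 = nd2)
      manifest[[length(manifest) + 1L]] <- tibble(
        class = c("sidechain_hbond", "mainchain_hbond"),
        acid_resnum = i, partner_resnum = j,
        acid_atom = c("OD1", "OD2"), partner_atom = c("ND2", "N"),
        distance = c(sqrt(sum((nd2 - od1)^2)), sqrt(sum((od2 - n_j)^2))))
    }
  }

  all_rows <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    atoms_to_rows(rows[[i]], kind[i], "A", i)
  }))
  out <- rows_to_pdb(all_rows)
  attr(out, "manifest") <- if (length(manifest)) {
    dplyr::bind_rows(manifest)
  } else {
    tibble(class = character(), acid_resnum = integer(),
           partner_resnum = integer(), acid_atom = character(),
           partner_atom = character(), distance = double())
  }
  out
}

#' Random carrier sequence with planted domain motifs
#'
#' Concatenates random non-motif linkers with one realisation of each
#' domain definition (its N-motif, a random interior, its C-motif),
#' guaranteeing a single match per motif. Deterministic given `seed`.
#'
#' @param defs List of [domain_definition()] objects.
#' @param linker_len Length of each random linker.
#' @param seed Integer seed.
#' @return Character scalar sequence, with attribute `intervals`: a tibble
#'   of the planted 0-based half-open intervals per domain.
#' @export
make_motif_sequence <- function(defs, linker_len = 12, seed = 1L) {
  stopifnot(length(defs) >= 1)
  # letters that avoid accidental motif hits in linkers/interiors
  pool <- c("A", "C", "F", "I", "M", "W", "Y")
  with_local_seed(seed, {
    for (attempt in 1:100) {
      pieces <- character(0)
      intervals <- list()
      pos <- 0L
      rand <- function(k) paste(sample(pool, k, replace = TRUE),
                                collapse = "")
      for (d in defs) {
        linker <- rand(linker_len)
        target_len <- max(d$min_len,
                          min(d$max_len,
                              round((d$min_len + d$max_len) / 2)))
        interior_len <- max(0L, target_len - motif_width(d$n_motif) -
                              motif_width(d$c_motif))
        dom <- paste0(realise_motif(d$n_motif), rand(interior_len),
                      realise_motif(d$c_motif))
        pieces <- c(pieces, linker, dom)
        start <- pos + nchar(linker)
        intervals[[length(intervals) + 1L]] <- tibble(
          domain = d$name, start = start, end = start + nchar(dom))
        pos <- start + nchar(dom)
      }
      seqn <- paste0(paste(pieces, collapse = ""),
                     rand(linker_len))
      ok <- all(vapply(defs, function(d) {
        length(gregexpr(motif_regex(d$n_motif), seqn)[[1]]) == 1 &&
          length(gregexpr(motif_regex(d$c_motif), seqn)[[1]]) == 1
      }, TRUE))
      if (ok) {
        attr(seqn, "intervals") <- dplyr::bind_rows(intervals)
        return(seqn)
      }
    }
    abort("could not realise a collision-free carrier sequence")
  })
}

#' Write named sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  nm <- names(seqs) %||% paste0("seq", seq_along(seqs))
  writeLines(unlist(lapply(seq_along(seqs), function(i) {
    c(paste0(">", nm[i]), as.character(seqs[i]))
  })), path)
  invisible(path)
}
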