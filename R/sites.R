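#' Configuration for ionisable-site extraction
#'
#' Model (solution) pKa values and which group kinds titrate. The defaults
#' are common model-compound values; Cys, Tyr and the chain termini are
#' disabled by default since the analysis concerns Asp, Glu, His, Lys and
#' Arg at the pH range of interest.
#'
#' @param model_pka Named numeric vector of model pKas; names from
#'   ASP, GLU, HIS, LYS, ARG, CYS, TYR, NTERM, CTERM. Values supplied here
#'   override the defaults.
#' @param enabled Character vector of kinds that titrate.
#' @return A `site_config` list.
#' @export
site_config <- function(model_pka = NULL,
                        enabled = c("ASP", "GLU", "HIS", "LYS", "ARG")) {
  pka <- c(ASP = 4.0, GLU = 4.4, HIS = 6.3, LYS = 10.4, ARG = 12.0,
           CYS = 8.3, TYR = 9.6, NTERM = 7.5, CTERM = 3.8)
  if (!is.null(model_pka)) {
    bad <- setdiff(names(model_pka), names(pka))
    if (length(bad)) abort(sprintf("unknown site kinds: %s",
                                   paste(bad, collapse = ", ")))
    pka[names(model_pka)] <- model_pka
  }
  if (any(pka <= 0 | pka >= 14)) abort("model pKas must lie in (0, 14)")
  bad <- setdiff(enabled, names(pka))
  if (length(bad)) abort(sprintf("unknown site kinds: %s",
                                 paste(bad, collapse = ", ")))
  structure(list(model_pka = pka, enabled = enabled), class = "site_config")
}

# charge of the deprotonated form: acids (and Cys/Tyr/C-terminus) -1,
# bases (and N-terminus) 0; protonated charge is q_deprotonated + 1.
Q_DEPROT <- c(ASP = -1, GLU = -1, CYS = -1, TYR = -1, CTERM = -1,
              HIS = 0, LYS = 0, ARG = 0, NTERM = 0)

# charge-centre atoms per kind; single-centre approximation.
CENTRE_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"),
  LYS = "NZ", ARG = "CZ", CYS = "SG", TYR = "OH"
)

#' Locate ionisable sites in a structure
#'
#' One site per enabled ionisable residue, plus chain termini when enabled.
#' The charge centre is the mean of the kind's named charge atoms (Asp
#' OD1/OD2, Glu OE1/OE2, His ND1/NE2, Lys NZ, Arg CZ, Cys SG, Tyr OH;
#' N-terminus backbone N, C-terminus O/OXT). When all charge atoms are
#' missing the centre falls back to CB, then CA, with a warning and a
#' `fallback` flag; residues with no usable atom at all are skipped with a
#' warning. Disulphide-bonded cysteines (SG-SG < 2.5 A) never titrate.
#'
#' @param s A `phs_structure`.
#' @param config A [site_config()].
#' @param chains Optional chain subset.
#' @return Tibble with one row per site: `site_id`, `kind`, `chain`,
#'   `resnum`, `icode`, `x`, `y`, `z`, `q_deprotonated`, `model_pka`,
#'   `fallback`.
#' @export
#' @examples
#' s <- parse_structure(make_pair("ASP", "LYS", 4))
#' extract_ionisable_sites(s)
extract_ionisable_sites <- function(s, config = site_config(),
                                    chains = NULL) {
  at <- s$atoms
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  res <- dplyr::distinct(at, .data$chain, .data$resnum, .data$icode,
                         .data$resname)

  ss_res <- disulphide_residues(at)

  rows <- list()
  push <- function(kind, chain, resnum, icode, centre, fallback) {
    rows[[length(rows) + 1L]] <<- tibble(
      site_id = paste0(kind, "_", chain, resnum,
                       ifelse(icode == "", "", icode)),
      kind = kind, chain = chain, resnum = resnum, icode = icode,
      x = centre[1], y = centre[2], z = centre[3],
      q_deprotonated = unname(Q_DEPROT[kind]),
      model_pka = unname(config$model_pka[kind]),
      fallback = fallback
    )
  }

  centre_of <- function(ratoms, names_wanted) {
    hit <- ratoms[ratoms$atom %in% names_wanted, , drop = FALSE]
    if (nrow(hit) == 0L) return(NULL)
    c(mean(hit$x), mean(hit$y), mean(hit$z))
  }

  for (k in seq_len(nrow(res))) {
    kind <- res$resname[k]
    if (!(kind %in% names(CENTRE_ATOMS)) || !(kind %in% config$enabled)) next
    ratoms <- at[at$chain == res$chain[k] & at$resnum == res$resnum[k] &
                   at$icode == res$icode[k], , drop = FALSE]
    if (kind == "CYS" && res_key(res[k, ]) %in% ss_res) next
    centre <- centre_of(ratoms, CENTRE_ATOMS[[kind]])
    fallback <- FALSE
    if (is.null(centre)) {
      centre <- centre_of(ratoms, "CB") %||% centre_of(ratoms, "CA")
      fallback <- TRUE
      if (is.null(centre)) {
        warn(sprintf("skipping %s %s%d: no charge atoms, CB or CA",
                     kind, res$chain[k], res$resnum[k]))
        next
      }
      warn(sprintf("%s %s%d: charge atoms missing, centred on CB/CA",
                   kind, res$chain[k], res$resnum[k]))
    }
    push(kind, res$chain[k], res$resnum[k], res$icode[k], centre, fallback)
  }

  for (term in intersect(c("NTERM", "CTERM"), config$enabled)) {
    for (ch in unique(res$chain)) {
      cres <- res[res$chain == ch, , drop = FALSE]
      r <- if (term == "NTERM") cres[1, ] else cres[nrow(cres), ]
      ratoms <- at[at$chain == ch & at$resnum == r$resnum &
                     at$icode == r$icode, , drop = FALSE]
      wanted <- if (term == "NTERM") "N" else c("O", "OXT")
      centre <- centre_of(ratoms, wanted) %||% centre_of(ratoms, "CA")
      if (is.null(centre)) next
      push(term, ch, r$resnum, r$icode, centre,
           fallback = !any(ratoms$atom %in% wanted))
    }
  }

  if (length(rows) == 0L) {
    return(tibble(site_id = character(), kind = character(),
                  chain = character(), resnum = integer(),
                  icode = character(), x = double(), y = double(),
                  z = double(), q_deprotonated = double(),
                  model_pka = double(), fallback = logical()))
  }
  dplyr::bind_rows(rows)
}

res_key <- function(r) paste(r$chain, r$resnum, r$icode, sep = "|")

# residues whose CYS SG is within 2.5 A of another CYS SG
disulphide_residues <- function(at) {
  sg <- at[at$resname == "CYS" & at$atom == "SG", , drop = FALSE]
  if (nrow(sg) < 2L) return(character())
  xyz <- as.matrix(sg[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  res_key(sg[apply(d < 2.5, 1, any), , drop = FALSE])
}

#' Write a site table to CSV
#'
#' Columns: site_id, kind, chain, resnum, x, y, z, q_deprot, model_pka.
#'
#' @param sites Tibble from [extract_ionisable_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_csv <- function(sites, path) {
  out <- sites[, c("site_id", "kind", "chain", "resnum", "x", "y", "z",
                   "q_deprotonated", "model_pka")]
  names(out)[names(out) == "q_deprotonated"] <- "q_deprot"
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
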