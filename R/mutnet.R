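#' Charge-neutralising mutation rule
#'
#' Selects ionisable sites for removal from the titrating set (the neutral
#' replacement's geometry is irrelevant to a screened-Coulomb model, so a
#' mutation is modelled as site removal). Selectors:
#' `"basic"` (Lys, Arg, His), `"acidic"` (Asp, Glu), a vector of site kinds
#' (e.g. `c("LYS", "ARG")`), or explicit residues as `"chain/Xresnum"`
#' strings, e.g. `"A/D96"` (one-letter residue code + author number).
#'
#' @param selector Character vector as above.
#' @return A `mutation_rule` list.
#' @export
#' @examples
#' mutation_rule("basic")
#' mutation_rule(c("A/D96", "A/E107"))
mutation_rule <- function(selector) {
  kinds3 <- c(ASP = "ASP", GLU = "GLU", HIS = "HIS", LYS = "LYS",
              ARG = "ARG", CYS = "CYS", TYR = "TYR")
  if (length(selector) == 1L && selector == "basic") {
    return(structure(list(kinds = c("LYS", "ARG", "HIS"), explicit = NULL),
                     class = "mutation_rule"))
  }
  if (length(selector) == 1L && selector == "acidic") {
    return(structure(list(kinds = c("ASP", "GLU"), explicit = NULL),
                     class = "mutation_rule"))
  }
  if (all(selector %in% kinds3)) {
    return(structure(list(kinds = selector, explicit = NULL),
                     class = "mutation_rule"))
  }
  if (all(grepl("^[^/]+/[A-Z][0-9]+$", selector))) {
    one2three <- c(D = "ASP", E = "GLU", H = "HIS", K = "LYS", R = "ARG",
                   C = "CYS", Y = "TYR")
    parts <- strsplit(selector, "/", fixed = TRUE)
    expl <- tibble(
      chain = vapply(parts, `[`, "", 1),
      kind = unname(one2three[substr(vapply(parts, `[`, "", 2), 1, 1)]),
      resnum = as.integer(sub("^[A-Z]", "",
                              vapply(parts, `[`, "", 2))),
      label = selector
    )
    if (any(is.na(expl$kind)))
      abort("explicit selectors must use ionisable one-letter codes")
    return(structure(list(kinds = NULL, explicit = expl),
                     class = "mutation_rule"))
  }
  abort(sprintf("cannot interpret selector: %s",
                paste(selector, collapse = ", ")))
}

#' Parse mutation rules from config syntax
#'
#' Lines of the form `mutate: basic->neutral` or
#' `mutate: A/D96,A/E107->neutral`.
#'
#' @param lines Character vector of config lines.
#' @return List of [mutation_rule()] objects.
#' @export
parse_mutation_rules <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(l) {
    m <- regmatches(l, regexec("^mutate:\\s*(.+)->neutral$", l))[[1]]
    if (length(m) == 0L) abort(sprintf("cannot parse rule line: '%s'", l))
    mutation_rule(trimws(strsplit(m[2], ",", fixed = TRUE)[[1]]))
  })
}

#' Apply charge-neutralising mutations to a site table
#'
#' Removes the selected sites from the ionisable set; all other sites and
#' their coordinates are untouched. Explicit selections that do not exist
#' in the site table are an error naming the residue.
#'
#' @param sites Site tibble ([extract_ionisable_sites()]).
#' @param rules List of [mutation_rule()] objects (a single rule is
#'   accepted).
#' @return The remaining sites, with attribute `removed`: an audit tibble
#'   of the removed sites.
#' @export
#' @examples
#' s <- parse_structure(make_pair("ASP", "LYS", 4))
#' sites <- extract_ionisable_sites(s)
#' apply_mutations(sites, mutation_rule("basic"))
apply_mutations <- function(sites, rules) {
  if (inherits(rules, "mutation_rule")) rules <- list(rules)
  drop <- rep(FALSE, nrow(sites))
  for (r in rules) {
    if (!is.null(r$kinds)) drop <- drop | sites$kind %in% r$kinds
    if (!is.null(r$explicit)) {
      for (k in seq_len(nrow(r$explicit))) {
        hit <- sites$chain == r$explicit$chain[k] &
          sites$resnum == r$explicit$resnum[k] &
          sites$kind == r$explicit$kind[k]
        if (!any(hit))
          abort(sprintf("mutation target not found: %s",
                        r$explicit$label[k]))
        drop <- drop | hit
      }
    }
  }
  out <- sites[!drop, , drop = FALSE]
  attr(out, "removed") <- sites[drop, , drop = FALSE]
  out
}

#' Buried acidic residues
#'
#' Asp/Glu residues whose sidechain accessibility, relative to the
#' free-residue reference (the same kind computed in isolation), is below
#' `rel_threshold`.
#'
#' @param s A `phs_structure`.
#' @param sasa Output of [residue_sasa()]; computed if missing.
#' @param rel_threshold Relative sidechain accessibility cutoff.
#' @return Tibble of buried acidics with `rel_sasa`.
#' @export
buried_acidic_sites <- function(s, sasa = NULL, rel_threshold = 0.10) {
  sasa <- sasa %||% residue_sasa(s)
  ac <- sasa[sasa$resname %in% c("ASP", "GLU"), , drop = FALSE]
  if (nrow(ac) == 0L) return(ac[, c("chain", "resnum", "icode", "resname")])
  ref <- vapply(ac$resname, reference_sidechain_sasa, 0)
  ac$rel_sasa <- ac$sasa_sidechain / ref
  ac <- ac[ac$rel_sasa < rel_threshold, , drop = FALSE]
  ac[, c("chain", "resnum", "icode", "resname", "rel_sasa")]
}

CARBOXYLATE_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                    HIS = c("ND1", "NE2"))
POLAR_DONOR_ATOMS <- list(SER = "OG", THR = "OG1", TYR = "OH",
                          ASN = "ND2", GLN = "NE2", TRP = "NE1",
                          HIS = c("ND1", "NE2"))

# all carboxylate-O / partner-atom distances under cutoff, one record per
# residue pair (minimum atom distance)
contact_scan <- function(s, partner_atoms, cutoff, class) {
  at <- s$atoms
  sel <- function(spec) {
    keep <- rep(FALSE, nrow(at))
    for (k in names(spec)) keep <- keep | (at$resname == k &
                                             at$atom %in% spec[[k]])
    at[keep, , drop = FALSE]
  }
  acid <- sel(CARBOXYLATE_ATOMS)
  part <- if (is.null(names(partner_atoms))) {
    at[at$atom %in% partner_atoms, , drop = FALSE]   # mainchain scan
  } else {
    sel(partner_atoms)
  }
  if (nrow(acid) == 0L || nrow(part) == 0L) return(empty_contacts())

  ax <- as.matrix(acid[, c("x", "y", "z")])
  px <- as.matrix(part[, c("x", "y", "z")])
  d <- sqrt(outer(rowSums(ax^2), rep(1, nrow(px))) +
              outer(rep(1, nrow(ax)), rowSums(px^2)) - 2 * ax %*% t(px))
  hits <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(empty_contacts())

  recs <- tibble(
    class = class,
    acid_chain = acid$chain[hits[, 1]], acid_resnum = acid$resnum[hits[, 1]],
    acid_resname = acid$resname[hits[, 1]], acid_atom = acid$atom[hits[, 1]],
    partner_chain = part$chain[hits[, 2]],
    partner_resnum = part$resnum[hits[, 2]],
    partner_resname = part$resname[hits[, 2]],
    partner_atom = part$atom[hits[, 2]],
    distance = d[hits]
  )
  recs <- recs[!(recs$acid_chain == recs$partner_chain &
                   recs$acid_resnum == recs$partner_resnum), , drop = FALSE]
  if (nrow(recs) == 0L) return(empty_contacts())
  recs <- dplyr::arrange(recs, .data$distance)
  recs <- dplyr::distinct(recs, .data$acid_chain, .data$acid_resnum,
                          .data$partner_chain, .data$partner_resnum,
                          .keep_all = TRUE)
  dplyr::arrange(recs, .data$acid_chain, .data$acid_resnum,
                 .data$partner_chain, .data$partner_resnum)
}

empty_contacts <- function() {
  tibble(class = character(), acid_chain = character(),
         acid_resnum = integer(), acid_resname = character(),
         acid_atom = character(), partner_chain = character(),
         partner_resnum = integer(), partner_resname = character(),
         partner_atom = character(), distance = double())
}

#' Detect salt bridges
#'
#' Residue pairs where any Asp/Glu carboxylate oxygen lies within `cutoff`
#' of a basic nitrogen (Lys NZ; Arg NH1/NH2/NE; His ND1/NE2); one record
#' per residue pair at the minimum atom distance. Heavy-atom distances
#' only.
#'
#' @param s A `phs_structure`.
#' @param cutoff Distance cutoff, A.
#' @return Contact tibble (`class = "salt_bridge"`).
#' @export
#' @examples
#' find_salt_bridges(parse_structure(make_toy_domain(
#'   toy_spec(n_residues = 30, n_salt_bridges = 3))))
find_salt_bridges <- function(s, cutoff = 4.0) {
  contact_scan(s, BASIC_ATOMS, cutoff, "salt_bridge")
}

#' Detect carboxylate hydrogen-bond networks
#'
#' For every Asp/Glu carboxylate oxygen: polar sidechain donors (Ser OG,
#' Thr OG1, Tyr OH, Asn ND2, Gln NE2, Trp NE1, His ring nitrogens) and
#' mainchain N within `d_cut`, classed `sidechain_hbond` /
#' `mainchain_hbond`. Distance-only criterion on heavy atoms (crystal
#' structures carry no hydrogens).
#'
#' @param s A `phs_structure`.
#' @param d_cut Distance cutoff, A.
#' @param partners Named list of sidechain donor atoms per residue kind.
#' @return Contact tibble.
#' @export
carboxylate_hbond_network <- function(s, d_cut = 3.5,
                                      partners = POLAR_DONOR_ATOMS) {
  dplyr::bind_rows(
    contact_scan(s, partners, d_cut, "sidechain_hbond"),
    contact_scan(s, "N", d_cut, "mainchain_hbond")
  )
}

#' Per-carboxylate interaction counts
#'
#' Counts of salt bridges and sidechain/mainchain hydrogen bonds around
#' each carboxylate residue, sorted by total interactions (descending),
#' ties broken by chain then ascending residue number.
#'
#' @param records Contact tibble ([find_salt_bridges()] and/or
#'   [carboxylate_hbond_network()] rows).
#' @param sites Optional site tibble; acidic sites with no contacts are
#'   then included with zero counts.
#' @return Tibble: `chain`, `resnum`, `resname`, `n_salt_bridge`,
#'   `n_sidechain_hbond`, `n_mainchain_hbond`, `total`.
#' @export
network_summary <- function(records, sites = NULL) {
  base <- if (nrow(records)) {
    counts <- dplyr::count(records, .data$acid_chain, .data$acid_resnum,
                           .data$acid_resname, .data$class)
    wide <- tidyr::pivot_wider(counts, names_from = "class",
                               values_from = "n", values_fill = 0L)
    names(wide)[1:3] <- c("chain", "resnum", "resname")
    wide
  } else {
    tibble(chain = character(), resnum = integer(), resname = character())
  }
  for (cl in c("salt_bridge", "sidechain_hbond", "mainchain_hbond")) {
    if (!cl %in% names(base)) base[[cl]] <- integer(nrow(base))
  }
  if (!is.null(sites)) {
    ac <- sites[sites$kind %in% c("ASP", "GLU"), , drop = FALSE]
    extra <- tibble(chain = ac$chain, resnum = ac$resnum,
                    resname = ac$kind, salt_bridge = 0L,
                    sidechain_hbond = 0L, mainchain_hbond = 0L)
    extra <- extra[!paste(extra$chain, extra$resnum) %in%
                     paste(base$chain, base$resnum), , drop = FALSE]
    base <- dplyr::bind_rows(base, extra)
  }
  names(base)[names(base) == "salt_bridge"] <- "n_salt_bridge"
  names(base)[names(base) == "sidechain_hbond"] <- "n_sidechain_hbond"
  names(base)[names(base) == "mainchain_hbond"] <- "n_mainchain_hbond"
  base$total <- base$n_salt_bridge + base$n_sidechain_hbond +
    base$n_mainchain_hbond
  dplyr::arrange(base, dplyr::desc(.data$total), .data$chain, .data$resnum)
}
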