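#' Define a domain by terminal sequence motifs
#'
#' A named domain delimited by an N-terminal and a C-terminal sequence
#' motif. Motifs are literal residues with optional single-position
#' alternation in brackets, e.g. `"SK[AT]K"` matches SKAK and SKTK.
#'
#' @param name Domain name.
#' @param n_motif,c_motif Motif patterns (non-empty).
#' @param min_len,max_len Accepted domain lengths (validation bounds).
#' @return A `domain_definition` list.
#' @export
#' @examples
#' igg_domain_definitions()    # CH2 and CH3 of the IgG Fc
domain_definition <- function(name, n_motif, c_motif,
                              min_len = 90, max_len = 130) {
  if (!nzchar(n_motif) || !nzchar(c_motif)) abort("motifs must be non-empty")
  if (min_len > max_len) abort("min_len must not exceed max_len")
  check_motif(n_motif); check_motif(c_motif)
  structure(list(name = name, n_motif = n_motif, c_motif = c_motif,
                 min_len = min_len, max_len = max_len),
            class = "domain_definition")
}

#' Built-in IgG Fc domain definitions
#'
#' The CH2 domain is delimited by PSVF / SK\[AT\]K and the CH3 domain by
#' GQPRE / LSL. Fab domain motifs are not built in and must be supplied by
#' the user via [domain_definition()].
#'
#' @return Named list of [domain_definition()] objects (`CH2`, `CH3`).
#' @export
igg_domain_definitions <- function() {
  list(CH2 = domain_definition("CH2", "PSVF", "SK[AT]K"),
       CH3 = domain_definition("CH3", "GQPRE", "LSL"))
}

check_motif <- function(m) {
  if (!grepl("^([A-Z]|\\[[A-Z]{2,}\\])+$", m))
    abort(sprintf("invalid motif '%s': letters and [..] alternation only", m))
  invisible(m)
}

motif_regex <- function(m) m          # the bracket syntax is valid regex
motif_width <- function(m) nchar(gsub("\\[[A-Z]+\\]", "X", m))
realise_motif <- function(m) {        # one concrete string matching m
  gsub("\\[([A-Z])[A-Z]*\\]", "\\1", m)
}

#' Locate a domain in a sequence by its terminal motifs
#'
#' The interval runs from the start of the first N-motif match to the end
#' of the first C-motif match beginning after it; the length is validated
#' against the definition's bounds. Additional matches of either motif are
#' reported as a warning.
#'
#' @param sequence One-letter sequence.
#' @param d A [domain_definition()].
#' @return One-row tibble: `domain`, `start`, `end` (0-based half-open
#'   indices), `length`, `sequence` (the domain subsequence).
#' @export
#' @examples
#' find_domain("AAPSVFLLGGSKAKTT", domain_definition("CH2", "PSVF",
#'                                                   "SK[AT]K", 5, 20))
find_domain <- function(sequence, d) {
  stopifnot(inherits(d, "domain_definition"))
  sequence <- as.character(sequence)
  attributes(sequence) <- NULL
  if (nchar(sequence) < motif_width(d$n_motif) + motif_width(d$c_motif))
    abort("sequence shorter than the two motifs combined")

  nm <- gregexpr(motif_regex(d$n_motif), sequence)[[1]]
  if (nm[1] == -1) abort(sprintf("N-motif '%s' not found", d$n_motif))
  cm <- gregexpr(motif_regex(d$c_motif), sequence)[[1]]
  if (cm[1] == -1) abort(sprintf("C-motif '%s' not found", d$c_motif))
  n_start <- nm[1]
  c_ok <- cm[cm > n_start]
  if (length(c_ok) == 0L)
    abort(sprintf("C-motif '%s' not found after the N-motif", d$c_motif))
  c_end <- c_ok[1] + attr(cm, "match.length")[match(c_ok[1], cm)] - 1L

  extra <- c(if (length(nm) > 1) sprintf("N-motif also at %s",
                                         paste(nm[-1], collapse = ",")),
             if (length(c_ok) > 1) sprintf("C-motif also at %s",
                                           paste(c_ok[-1], collapse = ",")))
  if (length(extra)) warn(paste("ambiguous motif matches:",
                                paste(extra, collapse = "; ")))

  len <- c_end - n_start + 1L
  if (len < d$min_len || len > d$max_len)
    abort(sprintf("domain '%s' length %d outside [%d, %d]",
                  d$name, len, d$min_len, d$max_len))
  tibble(domain = d$name, start = n_start - 1L, end = c_end,
         length = len,
         sequence = substr(sequence, n_start, c_end))
}

#' Cleave a structure to a sequence interval of one chain
#'
#' Returns a new structure containing only the residues of `chain` whose
#' 0-based sequence positions fall in `[start, end)`; coordinates are
#' unchanged.
#'
#' @param s A `phs_structure`.
#' @param chain Chain identifier.
#' @param start,end 0-based half-open interval into the chain's sequence
#'   (as returned by [find_domain()], which can also be passed directly as
#'   `start`).
#' @return A `phs_structure`.
#' @export
cleave_structure <- function(s, chain, start, end = NULL) {
  if (is.data.frame(start)) { end <- start$end[1]; start <- start$start[1] }
  res <- residue_table(s)
  res <- res[res$chain == chain, , drop = FALSE]
  if (nrow(res) == 0L) abort(sprintf("chain '%s' not present", chain))
  if (start < 0 || end > nrow(res) || start >= end)
    abort(sprintf("interval [%d, %d) out of range for %d residues",
                  start, end, nrow(res)))
  keep <- res[(start + 1L):end, , drop = FALSE]
  kkey <- paste(keep$chain, keep$resnum, keep$icode, sep = "|")
  at <- s$atoms
  akey <- paste(at$chain, at$resnum, at$icode, sep = "|")
  structure(list(id = paste0(s$id, "_", chain, start, "-", end),
                 source = s$source,
                 atoms = at[akey %in% kkey, , drop = FALSE]),
            class = "phs_structure")
}

#' Drop structures with duplicate sequences
#'
#' Keeps the first occurrence of each exact one-letter sequence
#' (all chains concatenated in chain order), preserving input order.
#'
#' @param structures List of `phs_structure` objects.
#' @return Filtered list.
#' @export
dedupe_by_sequence <- function(structures) {
  seqs <- vapply(structures, function(s) {
    res <- residue_table(s)
    paste(vapply(unique(res$chain), function(ch) structure_sequence(s, ch),
                 ""), collapse = "|")
  }, "")
  structures[!duplicated(seqs)]
}
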