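#' Charge-composition statistics of a sequence
#'
#' Fractions of charged (D, E, K, R, H at neutral pH), basic (K, R, H) and
#' acidic (D, E) residues. Non-standard letters count in the denominator
#' only. Rounding is left to the caller.
#'
#' @param sequence One-letter sequence (character scalar).
#' @return Tibble with `n_residues`, `frac_charged`, `frac_basic`,
#'   `frac_acidic`.
#' @export
#' @examples
#' composition_stats("DEKRH")   # all charged; 0.6 basic, 0.4 acidic
composition_stats <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) abort("sequence must be non-empty")
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  tibble(
    n_residues = n,
    frac_charged = sum(aa %in% c("D", "E", "K", "R", "H")) / n,
    frac_basic = sum(aa %in% c("K", "R", "H")) / n,
    frac_acidic = sum(aa %in% c("D", "E")) / n
  )
}

#' Read sequences from FASTA or raw text
#'
#' @param path Path to a FASTA file (or a file of raw sequence lines, which
#'   is treated as one unnamed record).
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("no sequence content found")
  if (!any(startsWith(lines, ">"))) {
    return(c(seq1 = paste(gsub("\\s", "", lines), collapse = "")))
  }
  hdr <- which(startsWith(lines, ">"))
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    paste(gsub("\\s", "", lines[(hdr[i] + 1L):ends[i]]), collapse = "")
  }, "")
  names(seqs) <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  seqs
}
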