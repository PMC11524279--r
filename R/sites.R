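# Cas9 target-site scanning and quantification-amplicon validation.
#
# Coordinate convention: 0-based, half-open intervals on the forward
# strand. cut_pos is an inter-base index: a cut between bases i-1 and i has
# cut_pos = i. SpCas9 cuts bluntly 3 bp 5' of the PAM, so a forward site
# with PAM starting at p cuts at p - 3, and a reverse site whose PAM
# occupies [q, q+3) cuts at q + 6.

.iupac <- c(A = "A", C = "C", G = "G", T = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Reverse complement of a DNA string
#'
#' @param x Character vector of A/C/G/T/N strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", toupper(x)), ""),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Scan a sequence for Cas9 target sites
#'
#' Finds every position, on one or both strands, where a spacer of
#' `spacer_len` bases is immediately followed (3' on the site's strand) by
#' a PAM matching `pam` (IUPAC codes allowed; the SpCas9 default is
#' `"NGG"`). For each site the predicted blunt double-strand-break
#' position is reported: exactly 3 bp 5' of the PAM on the site's strand,
#' expressed as a forward-strand inter-base coordinate (`cut_pos`).
#'
#' `N` is accepted in the input sequence but a site whose spacer or PAM
#' would contain an `N` is skipped with a warning — a qPCR primer or guide
#' cannot target an ambiguous base. Sites whose spacer would run off the
#' sequence end are skipped silently. Overlapping sites are all reported.
#'
#' @param sequence A character string, a [Biostrings::DNAString], or a
#'   [Biostrings::DNAStringSet] (scanned record by record, `seq_id` taken
#'   from its names).
#' @param spacer_len Spacer length in bases (default 20, minimum 17).
#' @param pam PAM pattern, IUPAC (default `"NGG"`).
#' @param strands `"both"` (default), `"forward"` or `"reverse"`.
#' @param seq_id Identifier used when `sequence` is a bare string.
#' @return A data frame of class `"tcep_sites"`, one row per site, sorted
#'   by `pam_start` then strand (`+` before `-`): `seq_id`, `strand`,
#'   `spacer` and `pam` (strand-local, 5' to 3'), `pam_start` (0-based
#'   forward-strand index of the leftmost PAM base), `cut_pos`,
#'   `spacer_start`/`spacer_end` (forward-strand half-open interval of the
#'   spacer footprint).
#' @examples
#' scan_pam_sites("ACGTACGTACGTACGTACGTTGG") # one forward site, cut_pos 17
#' @export
scan_pam_sites <- function(sequence, spacer_len = 20L, pam = "NGG",
                           strands = c("both", "forward", "reverse"),
                           seq_id = "seq") {
  strands <- match.arg(strands)
  if (inherits(sequence, "DNAStringSet")) {
    ids <- names(sequence)
    if (is.null(ids)) ids <- paste0("seq", seq_along(sequence))
    ids <- sub("\\s.*$", "", ids)
    parts <- lapply(seq_along(sequence), function(i) {
      scan_pam_sites(as.character(sequence[[i]]), spacer_len, pam, strands,
                     seq_id = ids[i])
    })
    out <- do.call(rbind, parts)
    class(out) <- c("tcep_sites", "data.frame")
    return(out)
  }
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1)
  spacer_len <- as.integer(spacer_len)
  if (spacer_len < 17) stop("spacer_len must be at least 17", call. = FALSE)
  seq <- toupper(sequence)
  ch <- strsplit(seq, "")[[1]]
  if (length(ch) && any(!ch %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence contains characters outside A/C/G/T/N", call. = FALSE)
  }
  L <- length(ch)
  empty <- data.frame(seq_id = character(0), strand = character(0),
                      spacer = character(0), pam = character(0),
                      pam_start = integer(0), cut_pos = integer(0),
                      spacer_start = integer(0), spacer_end = integer(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("tcep_sites", "data.frame")
  pam <- toupper(pam)
  P <- nchar(pam)
  if (L < spacer_len + P) return(empty)

  pam_ch <- strsplit(pam, "")[[1]]
  if (any(!pam_ch %in% names(.iupac))) stop("invalid PAM pattern", call. = FALSE)
  # match_starts(pattern): 1-based start positions of pattern on the
  # forward sequence; an N in the sequence never matches.
  match_starts <- function(pattern_ch) {
    ok <- lapply(pattern_ch, function(p) {
      ch %in% strsplit(.iupac[[p]], "")[[1]]
    })
    n <- length(pattern_ch)
    hits <- ok[[1]][seq_len(L - n + 1)]
    if (n > 1) for (j in 2:n) hits <- hits & ok[[j]][seq_len(L - n + 1) + j - 1L]
    which(hits)
  }

  rows <- list()
  n_skipped <- 0L
  if (strands %in% c("both", "forward")) {
    for (s1 in match_starts(pam_ch)) {       # s1: 1-based PAM start
      p0 <- s1 - 1L                          # 0-based
      if (p0 - spacer_len < 0) next
      spacer <- substr(seq, p0 - spacer_len + 1L, p0)
      if (grepl("N", spacer, fixed = TRUE)) { n_skipped <- n_skipped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = seq_id, strand = "+", spacer = spacer,
        pam = substr(seq, s1, s1 + P - 1L),
        pam_start = p0, cut_pos = p0 - 3L,
        spacer_start = p0 - spacer_len, spacer_end = p0,
        stringsAsFactors = FALSE)
    }
  }
  if (strands %in% c("both", "reverse")) {
    rc_pam_ch <- strsplit(revcomp(pam), "")[[1]]
    for (s1 in match_starts(rc_pam_ch)) {    # PAM complement on forward
      q0 <- s1 - 1L
      if (q0 + P + spacer_len > L) next
      spacer_fwd <- substr(seq, q0 + P + 1L, q0 + P + spacer_len)
      if (grepl("N", spacer_fwd, fixed = TRUE)) { n_skipped <- n_skipped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = seq_id, strand = "-", spacer = revcomp(spacer_fwd),
        pam = revcomp(substr(seq, s1, s1 + P - 1L)),
        pam_start = q0, cut_pos = q0 + P + 3L,
        spacer_start = q0 + P, spacer_end = q0 + P + spacer_len,
        stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0) {
    warning(sprintf("%d site(s) skipped: spacer contains N", n_skipped),
            call. = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$pam_start, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tcep_sites", "data.frame")
  out
}

#' @export
print.tcep_sites <- function(x, ...) {
  cat(nrow(x), "Cas9 target site(s)\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Describe a candidate qPCR amplicon
#'
#' The cutting assay needs two amplicons per target: one whose
#' amplification region spans the predicted cut site (so that broken DNA
#' fails to amplify) and one internal reference that avoids it. This
#' constructor records the primer-pair interval; [validate_amplicon()]
#' fills in the geometric checks against a scanned site.
#'
#' @param seq_id Source sequence identifier.
#' @param start,end 0-based half-open forward-strand interval.
#' @param purpose `"target_spanning"` or `"reference"`.
#' @param seq_length Optional source-sequence length used to check the
#'   interval lies inside the sequence.
#' @return A list of class `"amplicon_design"` with fields `seq_id`,
#'   `start`, `end`, `purpose`, and placeholders `spans_cut`,
#'   `contains_spacer`, `valid` (all `NA` until validated).
#' @export
amplicon_design <- function(seq_id, start, end,
                            purpose = c("target_spanning", "reference"),
                            seq_length = NULL) {
  purpose <- match.arg(purpose)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0 || end <= start) stop("need 0 <= start < end", call. = FALSE)
  if (!is.null(seq_length) && end > seq_length) {
    stop("amplicon extends past the end of the sequence", call. = FALSE)
  }
  structure(list(seq_id = seq_id, start = start, end = end, purpose = purpose,
                 spans_cut = NA, contains_spacer = NA, valid = NA),
            class = "amplicon_design")
}

#' Validate an amplicon against a target site
#'
#' Fills the geometric flags of an [amplicon_design()]: `spans_cut` is TRUE
#' when the predicted cut (`cut_pos`, an inter-base coordinate) falls
#' strictly inside the interval — an amplicon that starts or ends exactly
#' at the cut does not span it — and `contains_spacer` when the spacer's
#' forward-strand footprint is contained in the interval. A
#' `target_spanning` design is valid when both hold; a `reference` design
#' is valid when it does not span the cut.
#'
#' @param design An `"amplicon_design"`.
#' @param site One row of a [scan_pam_sites()] result (or any list with
#'   `seq_id`, `cut_pos`, `spacer_start`, `spacer_end`).
#' @return The design with `spans_cut`, `contains_spacer`, `valid` filled.
#' @export
validate_amplicon <- function(design, site) {
  stopifnot(inherits(design, "amplicon_design"))
  if (is.data.frame(site)) {
    if (nrow(site) != 1) stop("site must be a single row", call. = FALSE)
    site <- as.list(site)
  }
  if (!identical(as.character(design$seq_id), as.character(site$seq_id))) {
    stop("design and site refer to different sequences", call. = FALSE)
  }
  design$spans_cut <- site$cut_pos > design$start && site$cut_pos < design$end
  design$contains_spacer <- site$spacer_start >= design$start &&
    site$spacer_end <= design$end
  design$valid <- if (design$purpose == "target_spanning") {
    design$spans_cut && design$contains_spacer
  } else {
    !design$spans_cut
  }
  design
}

#' @export
print.amplicon_design <- function(x, ...) {
  cat(sprintf("%s amplicon on %s: [%d, %d)\n", x$purpose, x$seq_id, x$start, x$end))
  cat(sprintf("  spans_cut: %s  contains_spacer: %s  valid: %s\n",
              x$spans_cut, x$contains_spacer, x$valid))
  invisible(x)
}

#' Read a (multi-)FASTA file of candidate sequences
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet]; an error if the file is missing,
#'   malformed or contains no records.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA: ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0) stop("FASTA contains no records", call. = FALSE)
  set
}

#' Write a scanned site table as BED6
#'
#' One BED line per site covering the full spacer-plus-PAM footprint, with
#' the spacer sequence as the feature name.
#'
#' @param sites A [scan_pam_sites()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(sites, path) {
  fp_start <- ifelse(sites$strand == "+", sites$spacer_start, sites$pam_start)
  fp_end <- ifelse(sites$strand == "+", sites$pam_start + nchar(sites$pam),
                   sites$spacer_end)
  bed <- data.frame(chrom = sites$seq_id, start = fp_start, end = fp_end,
                    name = sites$spacer, score = 0L, strand = sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the detailed site table as TSV
#'
#' @param sites A [scan_pam_sites()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
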