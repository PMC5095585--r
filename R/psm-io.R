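#' Read a proteome from FASTA
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that returns the
#' named character representation used throughout this package.  FASTA
#' description lines are truncated at the first whitespace to give the
#' accession.
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return Named character vector, accession -> amino-acid sequence.
#' @export
read_proteome_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a proteome to FASTA
#'
#' @param proteome Named character vector or `AAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  proteome <- as_proteome(proteome)
  set <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Fixed column set of the PSM interchange table.
PSM_COLUMNS <- c("peptide", "accessions", "start", "charge", "xcorr",
                 "deltacn", "mods", "condition", "replicate")

# Parse one "pos:name;pos:name" modification string into a data.frame
# (pos, name).  Returns NULL with attr "error" on malformed input.
parse_mod_string <- function(s) {
  if (is.na(s) || s == "") return(data.frame(pos = integer(), name = character()))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+):([A-Za-z0-9-]+)$", parts))
  if (any(lengths(m) != 3L)) {
    out <- NULL
    attr(out, "error") <- sprintf("malformed mod string '%s'", s)
    return(out)
  }
  data.frame(pos = as.integer(vapply(m, `[`, "", 2L)),
             name = vapply(m, `[`, "", 3L))
}

format_mod_string <- function(mods) {
  if (is.null(mods) || nrow(mods) == 0L) return("")
  paste(sprintf("%d:%s", mods$pos, mods$name), collapse = ";")
}

validate_psm_row <- function(peptide, start, accs, mods, proteome = NULL) {
  n <- nchar(peptide)
  if (nrow(mods) > 0L) {
    if (any(mods$pos < 1L | mods$pos > n))
      return("mod position outside peptide")
    bad <- mods$name == "acetyl-K" &
      substring(peptide, mods$pos, mods$pos) != "K"
    if (any(bad)) return("acetyl on non-K")
  }
  if (!is.null(proteome)) {
    for (acc in accs) {
      if (!acc %in% names(proteome))
        return(sprintf("accession '%s' not in proteome", acc))
      if (substring(proteome[[acc]], start, start + n - 1L) != peptide)
        return(sprintf("peptide does not match '%s' at position %d", acc, start))
    }
  }
  NULL
}

#' Read a PSM table
#'
#' Reads a tab-separated peptide-spectrum-match table with the fixed header
#' `peptide, accessions, start, charge, xcorr, deltacn, mods, condition,
#' replicate`.  `accessions` is semicolon-joined; `mods` is a
#' `pos:name;pos:name` list of peptide-relative 1-based modification
#' positions (names among `acetyl-K`, `carbamidomethyl-C`, `oxidation-M`).
#'
#' Rows violating the record invariants (modification position outside the
#' peptide, acetyl on a non-lysine residue, or -- when `proteome` is given --
#' a peptide that does not match its protein at the stated start) are
#' dropped and reported in the `"rejected"` attribute of the result, a
#' data.frame with the offending line number and reason.  A missing column
#' is a hard error.
#'
#' @param path Path to the TSV file.
#' @param proteome Optional named character vector (or `AAStringSet`); when
#'   supplied, peptide/protein agreement is enforced.
#' @return A `psm_table` data.frame, one row per PSM, with a list-column
#'   `mods` of per-row data.frames `(pos, name)`.
#' @seealso [write_psm_table()], [filter_psms()]
#' @export
read_psm_table <- function(path, proteome = NULL) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(PSM_COLUMNS, names(raw))
  if (length(missing) > 0L)
    stop("PSM table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  raw <- raw[PSM_COLUMNS]
  if (!is.null(proteome)) proteome <- as_proteome(proteome)

  n <- nrow(raw)
  keep <- logical(n)
  reasons <- character(n)
  mods_list <- vector("list", n)
  for (i in seq_len(n)) {
    mods <- parse_mod_string(raw$mods[i])
    if (is.null(mods)) {
      reasons[i] <- attr(mods, "error") %||% "malformed mod string"
      next
    }
    err <- validate_psm_row(raw$peptide[i], as.integer(raw$start[i]),
                            strsplit(raw$accessions[i], ";", fixed = TRUE)[[1]],
                            mods, proteome)
    if (!is.null(err)) { reasons[i] <- err; next }
    keep[i] <- TRUE
    mods_list[[i]] <- mods
  }

  out <- data.frame(peptide = raw$peptide,
                    accessions = raw$accessions,
                    start = as.integer(raw$start),
                    charge = as.integer(raw$charge),
                    xcorr = as.numeric(raw$xcorr),
                    deltacn = as.numeric(raw$deltacn),
                    condition = raw$condition,
                    replicate = raw$replicate)[keep, , drop = FALSE]
  out$mods <- mods_list[keep]
  rownames(out) <- NULL
  class(out) <- c("psm_table", "data.frame")
  rejected <- data.frame(line = which(!keep) + 1L,  # +1 for the header line
                         reason = reasons[!keep])
  attr(out, "rejected") <- rejected
  if (nrow(rejected) > 0L)
    message(nrow(rejected), " row(s) rejected while reading ", path)
  out
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]: serializes the list-column of
#' modifications back to `pos:name;...` strings so that a write/read cycle
#' is lossless.
#'
#' @param psms A `psm_table` data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  stopifnot(is.data.frame(psms))
  out <- data.frame(peptide = psms$peptide,
                    accessions = psms$accessions,
                    start = psms$start,
                    charge = psms$charge,
                    xcorr = psms$xcorr,
                    deltacn = psms$deltacn,
                    mods = vapply(psms$mods, format_mod_string, ""),
                    condition = psms$condition,
                    replicate = psms$replicate)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
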