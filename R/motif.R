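#' Extract sequence windows around acetylated lysines
#'
#' Cuts a window of `flank` residues upstream and downstream of each site's
#' lysine (21 characters for the default `flank = 10`).  Where a protein
#' terminus truncates the flank, the window is padded with `'X'`; padded
#' positions are excluded from frequency denominators downstream, so
#' near-terminal sites are kept without biasing the position frequencies.
#'
#' @param sites data.frame with `accession` and `position` (1-based).
#' @param proteome Named character vector or `AAStringSet`.
#' @param flank Residues on each side of the central K.
#' @return Character vector of windows (length `2 * flank + 1` each), named
#'   `accession_position`.
#' @export
extract_windows <- function(sites, proteome, flank = 10L) {
  stopifnot(is.data.frame(sites),
            all(c("accession", "position") %in% names(sites)), flank >= 1)
  proteome <- as_proteome(proteome)
  missing <- setdiff(unique(sites$accession), names(proteome))
  if (length(missing) > 0L)
    stop("accession(s) absent from proteome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  seqs <- proteome[sites$accession]
  len <- nchar(seqs)
  pos <- as.integer(sites$position)
  if (any(pos < 1L | pos > len))
    stop("site position outside protein", call. = FALSE)
  centre <- substring(seqs, pos, pos)
  if (any(centre != "K"))
    stop("site residue is not K at ",
         paste(sites$accession[centre != "K"], pos[centre != "K"],
               collapse = ", "), call. = FALSE)
  lo <- pmax(1L, pos - flank)
  hi <- pmin(len, pos + flank)
  core <- substring(seqs, lo, hi)
  out <- paste0(strrep(PAD, lo - (pos - flank)), core,
                strrep(PAD, (pos + flank) - hi))
  names(out) <- paste(sites$accession, pos, sep = "_")
  out
}

#' Sample a background of random lysine-centred windows
#'
#' Draws windows centred on lysines sampled uniformly without replacement
#' from the whole proteome, for use as the comparison set in logo analyses.
#' The sample size defaults to `round(fraction * total K)` with
#' `fraction = 0.0005` (0.05% of all lysines).
#'
#' @param proteome Named character vector or `AAStringSet`.
#' @param fraction Fraction of all K positions to sample.
#' @param n Explicit sample size, overriding `fraction`.
#' @param flank Residues on each side of the central K.
#' @param exclude_sites Optional data.frame (`accession`, `position`) of K
#'   positions to exclude from the sampling frame (e.g. known acetyl
#'   sites).
#' @param seed Integer seed for reproducible sampling.
#' @return Character vector of windows, named `accession_position`.
#' @export
sample_background_windows <- function(proteome, fraction = 0.0005, n = NULL,
                                      flank = 10L, exclude_sites = NULL,
                                      seed = NULL) {
  proteome <- as_proteome(proteome)
  stopifnot(is.numeric(fraction), fraction > 0, fraction <= 1)
  hits <- gregexpr("K", proteome, fixed = TRUE)
  ks <- data.frame(
    accession = rep(names(proteome), vapply(hits, function(m) sum(m > 0L), 0L)),
    position = unlist(lapply(hits, function(m) m[m > 0L]), use.names = FALSE))
  if (!is.null(exclude_sites)) {
    drop <- paste(exclude_sites$accession, exclude_sites$position) |>
      match(paste(ks$accession, ks$position)) |> stats::na.omit()
    if (length(drop) > 0L) ks <- ks[-drop, , drop = FALSE]
  }
  total_k <- nrow(ks)
  if (total_k < 1L) stop("proteome contains no (eligible) K", call. = FALSE)
  if (is.null(n)) n <- round(fraction * total_k)
  if (n < 1L) stop("requested background sample is empty", call. = FALSE)
  if (n > total_k)
    stop("requested ", n, " background windows but only ", total_k,
         " K positions are available", call. = FALSE)
  idx <- with_seed(seed, sample.int(total_k, n))
  extract_windows(ks[idx, , drop = FALSE], proteome, flank = flank)
}

#' Position frequency matrix of sequence windows
#'
#' Tallies amino-acid occurrences per window offset and normalizes by the
#' number of non-pad characters at that offset (`'X'` pads from truncated
#' termini are excluded from the denominators).  The central K column is
#' computed like any other but flagged for exclusion from display, since a
#' constant column carries no information.
#'
#' @param windows Character vector of equal-length windows with a central
#'   K (from [extract_windows()] or [sample_background_windows()]).
#' @return A `pfm` object: list with `freq` and `counts` (20 x width
#'   matrices, rows = amino acids, columns = offsets), `eff_counts`
#'   (non-pad count per offset), `n_windows`, and `centre_col`.
#' @export
position_frequency_matrix <- function(windows) {
  stopifnot(is.character(windows), length(windows) >= 1L)
  width <- unique(nchar(windows))
  if (length(width) != 1L) stop("windows must share one length", call. = FALSE)
  if (width %% 2L != 1L) stop("window length must be odd", call. = FALSE)
  flank <- (width - 1L) %/% 2L
  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(windows), ncol = width, byrow = TRUE)
  if (any(chars[, flank + 1L] != "K"))
    stop("central residue must be K in every window", call. = FALSE)
  offsets <- seq.int(-flank, flank)
  counts <- vapply(seq_len(width), function(j)
    table(factor(chars[, j], levels = AA20)), integer(length(AA20)))
  dimnames(counts) <- list(AA20, offsets)
  eff <- colSums(counts)          # pads are not in AA20, so drop out here
  freq <- sweep(counts, 2L, pmax(eff, 1L), "/")
  structure(list(freq = freq, counts = counts, eff_counts = eff,
                 n_windows = length(windows), centre_col = flank + 1L),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("pfm: ", x$n_windows, " windows, offsets ",
      colnames(x$freq)[1L], "..", colnames(x$freq)[ncol(x$freq)],
      " (centre column excluded from display)\n", sep = "")
  invisible(x)
}

shannon_entropy <- function(f) {
  f <- f[f > 0]
  -sum(f * log2(f))
}

#' Sequence-logo tracks from position frequency matrices
#'
#' Computes logo data in two modes.  Absolute mode (`bg = NULL`): the stack
#' height at each offset is the information content `log2(20) - H` (Shannon
#' entropy in bits) and each letter's height is its frequency times the
#' stack height.  Relative mode (`bg` supplied): each letter's height is
#' the log2 enrichment `log2(fg / bg)`; zero frequencies on either side are
#' replaced by the pseudo-frequency `1 / (n_windows + 20)` of their own
#' matrix so the track is finite and antisymmetric under foreground /
#' background exchange.  The central K column is omitted unless
#' `include_centre = TRUE`.
#'
#' @param fg Foreground `pfm`.
#' @param bg Optional background `pfm` (same width).
#' @param include_centre Include the (constant-K) centre column.
#' @param small_sample_correction In absolute mode, subtract the standard
#'   small-sample entropy bias `(20 - 1) / (2 ln(2) n)` per position.
#' @return data.frame `offset`, `letter`, `height`, `stack_height`, with a
#'   `mode` attribute (`"absolute"` or `"relative"`).  In relative mode
#'   `stack_height` is the sum of absolute letter heights.
#' @export
logo_tracks <- function(fg, bg = NULL, include_centre = FALSE,
                        small_sample_correction = FALSE) {
  stopifnot(inherits(fg, "pfm"))
  width <- ncol(fg$freq)
  offsets <- as.integer(colnames(fg$freq))
  cols <- if (include_centre) seq_len(width) else setdiff(seq_len(width),
                                                          fg$centre_col)
  if (is.null(bg)) {
    stack <- vapply(seq_len(width), function(j) {
      h <- log2(length(AA20)) - shannon_entropy(fg$freq[, j])
      if (small_sample_correction && fg$eff_counts[j] > 0L)
        h <- max(0, h - (length(AA20) - 1) / (2 * log(2) * fg$eff_counts[j]))
      h
    }, 0)
    out <- data.frame(
      offset = rep(offsets[cols], each = length(AA20)),
      letter = rep(AA20, length(cols)),
      height = as.vector(fg$freq[, cols, drop = FALSE] *
                           rep(stack[cols], each = length(AA20))),
      stack_height = rep(stack[cols], each = length(AA20)))
    attr(out, "mode") <- "absolute"
  } else {
    stopifnot(inherits(bg, "pfm"), ncol(bg$freq) == width)
    p_fg <- 1 / (fg$n_windows + length(AA20))
    p_bg <- 1 / (bg$n_windows + length(AA20))
    f <- fg$freq; f[f == 0] <- p_fg
    b <- bg$freq; b[b == 0] <- p_bg
    enr <- log2(f / b)
    out <- data.frame(
      offset = rep(offsets[cols], each = length(AA20)),
      letter = rep(AA20, length(cols)),
      height = as.vector(enr[, cols, drop = FALSE]),
      stack_height = rep(colSums(abs(enr[, cols, drop = FALSE])),
                         each = length(AA20)))
    attr(out, "mode") <- "relative"
  }
  rownames(out) <- NULL
  out
}
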