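#' SEQUEST-style PSM filter thresholds
#'
#' Identification filters for ion-trap SEQUEST searches: charge-dependent
#' XCorr minima, a deltaCn ceiling, a minimum peptide length, and rejection
#' of tryptic peptides carrying an acetylated lysine at their C-terminus
#' (trypsin does not cleave after acetyl-K, so such identifications are
#' implausible).  The defaults are the classic ion-trap pass marks:
#' XCorr >= 1.5 (1+), 2.5 (2+), 3.0 (3+), 3.2 (>3+), deltaCn <= 0.3,
#' length >= 7.
#'
#' Missed-cleavage counts are recorded on the records but not enforced
#' unless `enforce_missed_cleavages = TRUE` (the permitted maximum during
#' database search, 3, is the search engine's responsibility).
#'
#' @param xcorr_by_charge Named numeric, thresholds for charges `"1"`,
#'   `"2"`, `"3"` and the `">3"` bucket.
#' @param max_delta_cn Maximum deltaCn retained.
#' @param min_length Minimum peptide length retained.
#' @param reject_cterm_acetyl_k Reject peptides whose last residue is an
#'   acetylated K.
#' @param max_missed_cleavages Recorded limit; enforced only in strict mode.
#' @param enforce_missed_cleavages Enforce `max_missed_cleavages` as an
#'   additional filter rule.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(xcorr_by_charge = c("1" = 1.5, "2" = 2.5,
                                                  "3" = 3.0, ">3" = 3.2),
                              max_delta_cn = 0.3,
                              min_length = 7L,
                              reject_cterm_acetyl_k = TRUE,
                              max_missed_cleavages = 3L,
                              enforce_missed_cleavages = FALSE) {
  stopifnot(all(c("1", "2", "3", ">3") %in% names(xcorr_by_charge)),
            all(xcorr_by_charge >= 0), max_delta_cn >= 0, min_length >= 1)
  structure(list(xcorr_by_charge = xcorr_by_charge,
                 max_delta_cn = max_delta_cn,
                 min_length = as.integer(min_length),
                 reject_cterm_acetyl_k = isTRUE(reject_cterm_acetyl_k),
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 enforce_missed_cleavages = isTRUE(enforce_missed_cleavages)),
            class = "filter_thresholds")
}

xcorr_threshold <- function(charge, thresholds) {
  key <- ifelse(charge > 3L, ">3", as.character(charge))
  unname(thresholds$xcorr_by_charge[key])
}

# Tryptic missed cleavages: internal K/R (C-terminal residue excluded).
count_missed_cleavages <- function(peptide) {
  internal <- substring(peptide, 1L, nchar(peptide) - 1L)
  vapply(gregexpr("[KR]", internal), function(m) sum(m > 0L), 0L)
}

has_cterm_acetyl_k <- function(peptide, mods) {
  n <- nchar(peptide)
  substring(peptide, n, n) == "K" &&
    nrow(mods) > 0L && any(mods$pos == n & mods$name == "acetyl-K")
}

#' Filter PSMs on identification-quality rules
#'
#' Applies the [filter_thresholds()] rules in a fixed order (charge-bucket
#' XCorr, deltaCn, minimum length, C-terminal acetyl-K, optionally missed
#' cleavages) and tallies rejections by the *first* failing rule, so that
#' per-rule rejects plus the retained count always sum to the input size.
#' All comparisons are boundary-inclusive: a PSM scoring exactly at its
#' charge's XCorr pass mark is retained.
#'
#' @param psms A `psm_table` data.frame (see [read_psm_table()]).
#' @param thresholds A [filter_thresholds()] object.
#' @return List with `retained` (a `psm_table`), `rejected` (a `psm_table`
#'   with a `reason` column) and `tally` (named integer vector: one entry
#'   per rule, plus `retained`).
#' @export
filter_psms <- function(psms, thresholds = filter_thresholds()) {
  stopifnot(is.data.frame(psms), inherits(thresholds, "filter_thresholds"))
  n <- nrow(psms)
  rules <- c("xcorr", "delta_cn", "min_length", "cterm_acetyl_k",
             "missed_cleavages")
  reason <- rep(NA_character_, n)
  if (n > 0L) {
    len <- nchar(psms$peptide)
    fail_x <- psms$xcorr < xcorr_threshold(psms$charge, thresholds)
    fail_d <- psms$deltacn > thresholds$max_delta_cn
    fail_l <- len < thresholds$min_length
    fail_c <- thresholds$reject_cterm_acetyl_k &
      mapply(has_cterm_acetyl_k, psms$peptide, psms$mods)
    fail_m <- if (thresholds$enforce_missed_cleavages)
      count_missed_cleavages(psms$peptide) > thresholds$max_missed_cleavages
    else rep(FALSE, n)
    reason[fail_m] <- "missed_cleavages"
    reason[fail_c] <- "cterm_acetyl_k"
    reason[fail_l] <- "min_length"
    reason[fail_d] <- "delta_cn"
    reason[fail_x] <- "xcorr"     # assigned last: first rule in order wins
  }
  keep <- is.na(reason)
  retained <- psms[keep, , drop = FALSE]
  rejected <- psms[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  rownames(retained) <- rownames(rejected) <- NULL
  tally <- c(table(factor(reason, levels = rules)), retained = sum(keep))
  missed <- if (n > 0L) count_missed_cleavages(psms$peptide) else integer()
  retained$missed_cleavages <- missed[keep]
  list(retained = retained, rejected = rejected, tally = tally)
}

#' Map acetylated peptides to protein acetyl sites
#'
#' Converts each acetyl-K modification of each (filtered) PSM into a
#' protein-coordinate site record: `position = start + mod_pos - 1`
#' (1-based).  A peptide shared by several accessions emits one record per
#' accession (set `unique_only = TRUE` to drop shared peptides instead).
#' Each record carries its PSM's condition and replicate labels and a
#' spectral count of 1, so downstream aggregation is a plain sum.
#'
#' @param psms A `psm_table` data.frame.
#' @param proteome Named character vector (or `AAStringSet`) containing
#'   every accession referenced by `psms`.
#' @param unique_only Drop PSMs mapping to more than one accession.
#' @return data.frame with columns `accession`, `position`, `residue`,
#'   `peptide`, `condition`, `replicate`, `spectral_count`.
#' @export
map_acetyl_sites <- function(psms, proteome, unique_only = FALSE) {
  stopifnot(is.data.frame(psms))
  proteome <- as_proteome(proteome)
  acc_list <- strsplit(psms$accessions, ";", fixed = TRUE)
  unknown <- setdiff(unique(unlist(acc_list)), names(proteome))
  if (length(unknown) > 0L) {
    offending <- which(vapply(acc_list, function(a) any(a %in% unknown), TRUE))
    stop("accession(s) absent from proteome: ",
         paste(unknown, collapse = ", "),
         " (PSM rows ", paste(offending, collapse = ", "), ")", call. = FALSE)
  }
  out <- vector("list", nrow(psms))
  for (i in seq_len(nrow(psms))) {
    accs <- acc_list[[i]]
    if (unique_only && length(accs) > 1L) next
    mods <- psms$mods[[i]]
    ac <- mods[mods$name == "acetyl-K", , drop = FALSE]
    if (nrow(ac) == 0L) next
    pos <- psms$start[i] + ac$pos - 1L
    grid <- expand.grid(accession = accs, position = pos,
                        stringsAsFactors = FALSE)
    res <- substring(proteome[grid$accession], grid$position, grid$position)
    if (any(res != "K"))
      stop("acetyl site maps to non-K residue in ",
           paste(unique(grid$accession[res != "K"]), collapse = ", "),
           call. = FALSE)
    out[[i]] <- data.frame(accession = grid$accession,
                           position = grid$position,
                           residue = "K",
                           peptide = psms$peptide[i],
                           condition = psms$condition[i],
                           replicate = psms$replicate[i],
                           spectral_count = 1L)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(accession = character(), position = integer(),
                      residue = character(), peptide = character(),
                      condition = character(), replicate = character(),
                      spectral_count = integer())
  rownames(out) <- NULL
  out
}
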