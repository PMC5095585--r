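#' Replicate presence/absence calling rule
#'
#' A site is called acetyltransferase-dependent when it is seen in at least
#' `min_ctrl_present` of the `n_ctrl` control replicates and in at most
#' `max_kd_present` of the `n_kd` knockdown replicates.  The defaults encode
#' the stringent 3-of-5 control / 0-of-3 knockdown design.
#'
#' @param min_ctrl_present Minimum control replicates with the site.
#' @param max_kd_present Maximum knockdown replicates with the site.
#' @param n_ctrl,n_kd Replicate counts per condition.
#' @return A `calling_rule` list.
#' @export
calling_rule <- function(min_ctrl_present = 3L, max_kd_present = 0L,
                         n_ctrl = 5L, n_kd = 3L) {
  stopifnot(min_ctrl_present >= 0, min_ctrl_present <= n_ctrl,
            max_kd_present >= 0, max_kd_present <= n_kd)
  structure(list(min_ctrl_present = as.integer(min_ctrl_present),
                 max_kd_present = as.integer(max_kd_present),
                 n_ctrl = as.integer(n_ctrl), n_kd = as.integer(n_kd)),
            class = "calling_rule")
}

#' Build the per-site replicate evidence matrix
#'
#' Aggregates site-level records (one row per PSM, see
#' [map_acetyl_sites()]) into one row per acetyl site, with spectral counts
#' summed per replicate and presence flags derived as `count >= 1`.
#' Replicates without any record still occupy (all-zero) columns.
#'
#' @param site_records data.frame with `accession`, `position`,
#'   `condition` (`"ctrl"` or `"kd"`), `replicate` (coercible to an integer
#'   in `1..n_*`) and `spectral_count`.
#' @param n_ctrl,n_kd Number of replicate columns per condition.
#' @return A `site_evidence` object: list with `sites` (data.frame
#'   accession/position), `ctrl_counts`, `kd_counts` (integer matrices),
#'   `ctrl_presence`, `kd_presence` (0/1 matrices).
#' @export
build_evidence_matrix <- function(site_records, n_ctrl = 5L, n_kd = 3L) {
  req <- c("accession", "position", "condition", "replicate", "spectral_count")
  stopifnot(all(req %in% names(site_records)))
  bad <- setdiff(unique(site_records$condition), c("ctrl", "kd"))
  if (length(bad) > 0L)
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  rep_idx <- as.integer(gsub("[^0-9]", "", as.character(site_records$replicate)))
  n_rep <- ifelse(site_records$condition == "ctrl", n_ctrl, n_kd)
  if (anyNA(rep_idx) || any(rep_idx < 1L | rep_idx > n_rep))
    stop("replicate labels must map to 1..n replicates of their condition",
         call. = FALSE)

  key <- paste(site_records$accession, site_records$position, sep = "\r")
  sites <- unique(data.frame(accession = site_records$accession,
                             position = site_records$position,
                             key = key))
  sites <- sites[order(sites$accession, sites$position), , drop = FALSE]
  row <- match(key, sites$key)

  tab <- function(cond, n_col) {
    m <- matrix(0L, nrow(sites), n_col,
                dimnames = list(NULL, paste0(cond, "_", seq_len(n_col))))
    sel <- site_records$condition == cond
    if (any(sel)) {
      agg <- tapply(site_records$spectral_count[sel],
                    list(row[sel], rep_idx[sel]), sum)
      m[cbind(rep(as.integer(rownames(agg)), ncol(agg)),
              rep(as.integer(colnames(agg)), each = nrow(agg)))] <-
        as.integer(ifelse(is.na(agg), 0L, agg))
    }
    m
  }
  ctrl_counts <- tab("ctrl", n_ctrl)
  kd_counts <- tab("kd", n_kd)
  structure(list(sites = sites[c("accession", "position")],
                 ctrl_counts = ctrl_counts, kd_counts = kd_counts,
                 ctrl_presence = 1L * (ctrl_counts >= 1L),
                 kd_presence = 1L * (kd_counts >= 1L)),
            class = "site_evidence")
}

#' @export
print.site_evidence <- function(x, ...) {
  cat("site_evidence: ", nrow(x$sites), " acetyl sites, ",
      ncol(x$ctrl_counts), " ctrl + ", ncol(x$kd_counts),
      " kd replicates\n", sep = "")
  invisible(x)
}

#' Call acetyltransferase-dependent sites
#'
#' Applies a [calling_rule()] to a [build_evidence_matrix()] result: a site
#' is called iff its control presences reach `min_ctrl_present` and its
#' knockdown presences do not exceed `max_kd_present`.  Output is sorted by
#' `(accession, position)` for reproducible diffs.
#'
#' @param evidence A `site_evidence` object.
#' @param rule A `calling_rule`.
#' @return data.frame `accession`, `position`, `n_ctrl_present`,
#'   `n_kd_present`, restricted to called sites.
#' @export
call_kat_dependent_sites <- function(evidence, rule = calling_rule()) {
  stopifnot(inherits(evidence, "site_evidence"), inherits(rule, "calling_rule"))
  if (ncol(evidence$ctrl_presence) != rule$n_ctrl ||
      ncol(evidence$kd_presence) != rule$n_kd)
    stop("rule replicate counts do not match the evidence matrix", call. = FALSE)
  nc <- rowSums(evidence$ctrl_presence)
  nk <- rowSums(evidence$kd_presence)
  called <- nc >= rule$min_ctrl_present & nk <= rule$max_kd_present
  out <- cbind(evidence$sites, n_ctrl_present = nc, n_kd_present = nk)
  out <- out[called, , drop = FALSE]
  out <- out[order(out$accession, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate called sites to proteins and intersect with a reference
#'
#' Summarizes a called-site list to per-protein site counts and computes
#' the overlap with a reference acetylome, either at the protein level
#' (reference = accessions) or at the site level (reference = accession,
#' position pairs).  The in-reference percentage is reported to 1 decimal,
#' `100 * in_reference / targets`.
#'
#' @param called_sites data.frame with `accession` (and `position` for
#'   site-level mode), e.g. from [call_kat_dependent_sites()].
#' @param reference Character vector of accessions, or a data.frame with
#'   `accession` and `position` columns.
#' @param level `"protein"` or `"site"`.
#' @return List with `per_protein` (accession, n_sites), `n_targets`,
#'   `n_in_reference`, `n_novel`, `pct_in_reference`.
#' @export
aggregate_and_overlap <- function(called_sites, reference,
                                  level = c("protein", "site")) {
  level <- match.arg(level)
  stopifnot(is.data.frame(called_sites), "accession" %in% names(called_sites))
  tab <- table(called_sites$accession)
  per_protein <- data.frame(accession = as.character(names(tab) %||%
                                                       character(0)),
                            n_sites = as.integer(tab))
  per_protein <- per_protein[order(per_protein$accession), , drop = FALSE]
  rownames(per_protein) <- NULL

  if (level == "protein") {
    ref <- if (is.data.frame(reference)) unique(reference$accession)
           else unique(as.character(reference))
    targets <- unique(called_sites$accession)
    hit <- targets %in% ref
  } else {
    stopifnot("position" %in% names(called_sites), is.data.frame(reference),
              all(c("accession", "position") %in% names(reference)))
    targets <- unique(paste(called_sites$accession, called_sites$position,
                            sep = "\r"))
    ref <- unique(paste(reference$accession, reference$position, sep = "\r"))
    hit <- targets %in% ref
  }
  n_targets <- length(targets)
  n_in <- sum(hit)
  list(per_protein = per_protein,
       n_targets = n_targets,
       n_in_reference = n_in,
       n_novel = n_targets - n_in,
       pct_in_reference = if (n_targets == 0L) NA_real_
                          else round(100 * n_in / n_targets, 1L))
}

#' Acetylation abundance factor
#'
#' Spectral-count normalization for comparing a protein's acetylation
#' across conditions (e.g. *in vitro* acetyltransferase assays analysed in
#' independent MS runs): for each condition, every acetylated peptide's
#' spectral count is divided by the condition's total spectral count for
#' the protein (modified plus unmodified), and the normalized values are
#' summed.  Peptide identity is the sequence plus the set of acetylated
#' positions; charge states are collapsed.  The factor is invariant under
#' uniform scaling of a condition's counts and additive over disjoint
#' peptide sets.
#'
#' @param peptide_counts data.frame with `condition`, `peptide`,
#'   `acetyl_positions` (comma-joined 1-based positions, or ""), `count`.
#' @param total_counts Named numeric vector: total protein spectral count
#'   per condition (must be positive for any condition with peptides).
#' @return List with `factors` (named numeric per condition) and `table`
#'   (data.frame peptide x condition of normalized values, conditions as
#'   columns, plus the per-condition factor as the last row).
#' @export
acetylation_abundance_factor <- function(peptide_counts, total_counts) {
  req <- c("condition", "peptide", "acetyl_positions", "count")
  stopifnot(is.data.frame(peptide_counts), all(req %in% names(peptide_counts)),
            is.numeric(total_counts), !is.null(names(total_counts)))
  conds <- unique(c(as.character(peptide_counts$condition),
                    names(total_counts)))
  norm_pos <- vapply(strsplit(as.character(peptide_counts$acetyl_positions),
                              ","), function(p) {
    p <- sort(as.integer(p[nzchar(trimws(p))]))
    paste(p, collapse = ",")
  }, "")
  id <- sprintf("%s [%s]", peptide_counts$peptide, norm_pos)
  have <- tapply(peptide_counts$count, peptide_counts$condition, sum) > 0
  for (cond in names(have)[have]) {
    tot <- total_counts[cond]
    if (is.na(tot) || tot <= 0)
      stop("condition '", cond,
           "' has acetylated peptides but no positive total spectral count",
           call. = FALSE)
    if (any(peptide_counts$count[peptide_counts$condition == cond] > tot))
      stop("peptide count exceeds total protein count in '", cond, "'",
           call. = FALSE)
  }
  ids <- sort(unique(id))
  mat <- matrix(0, length(ids), length(conds), dimnames = list(ids, conds))
  for (i in seq_along(id)) {
    cond <- peptide_counts$condition[i]
    mat[id[i], cond] <- mat[id[i], cond] +
      peptide_counts$count[i] / total_counts[cond]
  }
  factors <- colSums(mat)
  tab <- as.data.frame(rbind(mat, abundance_factor = factors))
  list(factors = factors, table = tab)
}

#' Count distinct sites and proteins in a deposited site list
#'
#' Utility for summarizing a published acetyl-site result list (TSV with
#' `accession` and `position` columns): returns the number of distinct
#' (accession, position) sites and of distinct proteins.
#'
#' @param path TSV path, or a data.frame already in memory.
#' @return List with `n_sites` and `n_proteins`.
#' @export
read_site_list <- function(path) {
  df <- if (is.data.frame(path)) path
        else utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "position") %in% names(df)))
  list(n_sites = nrow(unique(df[c("accession", "position")])),
       n_proteins = length(unique(df$accession)))
}
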