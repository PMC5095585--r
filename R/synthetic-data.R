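# Synthetic-data generators.  Every input the pipeline consumes can be
# produced here with planted ground truth, so each analysis stage is
# testable end-to-end without external downloads.

# Rounded UniProt/Swiss-Prot amino-acid frequencies, for the optional
# human-like composition.
HUMAN_AA_FREQ <- c(A = 0.0825, C = 0.0137, D = 0.0545, E = 0.0675,
                   F = 0.0386, G = 0.0707, H = 0.0227, I = 0.0596,
                   K = 0.0584, L = 0.0966, M = 0.0242, N = 0.0406,
                   P = 0.0470, Q = 0.0393, R = 0.0553, S = 0.0656,
                   T = 0.0534, V = 0.0687, W = 0.0108, Y = 0.0292)

#' Configuration for a synthetic replicate acetylome experiment
#'
#' Encodes the replicate design of a presence/absence differential
#' acetylome: 5 control and 3 knockdown replicates by default, with
#' "dependent" sites (detected in control, lost on knockdown) and
#' "independent" sites (detected in both).  Detection is Bernoulli per
#' site per replicate; spectral counts on detection are zero-truncated
#' Poisson, decoupling detection from abundance.
#'
#' @param n_proteins Number of proteins.
#' @param protein_length_range Min/max protein length (residues).
#' @param n_ctrl_reps,n_kd_reps Replicates per condition.
#' @param n_dependent_sites,n_independent_sites Planted site counts.
#' @param p_detect_ctrl Detection probability per control replicate (both
#'   site categories).
#' @param p_detect_kd_dependent,p_detect_kd_independent Detection
#'   probabilities per knockdown replicate.
#' @param mean_spectral_count Poisson rate of the zero-truncated spectral
#'   count on detection.
#' @param composition `"uniform"` (known null for logo tests) or
#'   `"human"` (Swiss-Prot-like frequencies).
#' @param k_rich_flank_prob Optional probability with which residues
#'   flanking a dependent site (within 5 positions) are set to K, planting
#'   a lysine-rich sequence context.
#' @param decoy_fraction Fraction of emitted PSMs degraded to fail the
#'   default score thresholds.
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @return An `acetylome_sim_config` list.
#' @export
acetylome_sim_config <- function(n_proteins = 100L,
                                 protein_length_range = c(200L, 500L),
                                 n_ctrl_reps = 5L, n_kd_reps = 3L,
                                 n_dependent_sites = 50L,
                                 n_independent_sites = 50L,
                                 p_detect_ctrl = 0.9,
                                 p_detect_kd_dependent = 0,
                                 p_detect_kd_independent = 0.9,
                                 mean_spectral_count = 2,
                                 composition = c("uniform", "human"),
                                 k_rich_flank_prob = NULL,
                                 decoy_fraction = 0,
                                 seed = 1L) {
  composition <- match.arg(composition)
  stopifnot(is_count(n_proteins, positive = TRUE),
            length(protein_length_range) == 2L,
            protein_length_range[1] >= 20L,
            protein_length_range[1] <= protein_length_range[2],
            is_count(n_ctrl_reps, positive = TRUE),
            is_count(n_kd_reps, positive = TRUE),
            is_count(n_dependent_sites), is_count(n_independent_sites),
            is_probability(p_detect_ctrl),
            is_probability(p_detect_kd_dependent),
            is_probability(p_detect_kd_independent),
            is_probability(decoy_fraction),
            mean_spectral_count > 0)
  if (!is.null(k_rich_flank_prob)) stopifnot(is_probability(k_rich_flank_prob))
  structure(list(n_proteins = as.integer(n_proteins),
                 protein_length_range = as.integer(protein_length_range),
                 n_ctrl_reps = as.integer(n_ctrl_reps),
                 n_kd_reps = as.integer(n_kd_reps),
                 n_dependent_sites = as.integer(n_dependent_sites),
                 n_independent_sites = as.integer(n_independent_sites),
                 p_detect_ctrl = p_detect_ctrl,
                 p_detect_kd_dependent = p_detect_kd_dependent,
                 p_detect_kd_independent = p_detect_kd_independent,
                 mean_spectral_count = mean_spectral_count,
                 composition = composition,
                 k_rich_flank_prob = k_rich_flank_prob,
                 decoy_fraction = decoy_fraction,
                 seed = as.integer(seed)),
            class = "acetylome_sim_config")
}

#' Generate a synthetic proteome with planted acetyl sites
#'
#' Draws protein sequences from the configured amino-acid composition and
#' plants `n_dependent_sites + n_independent_sites` acetylation sites,
#' each on a lysine (the chosen residue is set to K), at distinct
#' positions, each in exactly one category.  Sites avoid the first and
#' last residue so that every site admits a tryptic-like host peptide
#' whose acetyl-K is internal.
#'
#' @param config An [acetylome_sim_config()].
#' @return List with `proteome` (named character; write with
#'   [write_proteome_fasta()]) and `truth` (data.frame `accession`,
#'   `position`, `category`).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "acetylome_sim_config"))
  prob <- if (config$composition == "uniform") rep(1 / 20, 20)
          else unname(HUMAN_AA_FREQ[AA20])
  n_sites <- config$n_dependent_sites + config$n_independent_sites
  with_seed(config$seed, {
    lens <- sample(seq.int(config$protein_length_range[1],
                           config$protein_length_range[2]),
                   config$n_proteins, replace = TRUE)
    accs <- sprintf("SYN%04d", seq_len(config$n_proteins))
    proteome <- vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE, prob = prob), collapse = ""), "")
    names(proteome) <- accs

    capacity <- sum(lens - 2L)
    if (n_sites > capacity)
      stop("protein length range too short to host ", n_sites,
           " planted sites (capacity ", capacity, ")", call. = FALSE)
    pool_acc <- rep(accs, lens - 2L)
    pool_pos <- unlist(lapply(lens, function(L) seq.int(2L, L - 1L)))
    pick <- sample.int(length(pool_acc), n_sites)
    truth <- data.frame(accession = pool_acc[pick], position = pool_pos[pick],
                        category = rep(c("dependent", "independent"),
                                       c(config$n_dependent_sites,
                                         config$n_independent_sites)))
    # force the planted residues to K
    for (i in seq_len(nrow(truth))) {
      acc <- truth$accession[i]; p <- truth$position[i]
      substr(proteome[[acc]], p, p) <- "K"
    }
    if (!is.null(config$k_rich_flank_prob)) {
      dep <- truth[truth$category == "dependent", , drop = FALSE]
      for (i in seq_len(nrow(dep))) {
        acc <- dep$accession[i]; p <- dep$position[i]
        L <- nchar(proteome[[acc]])
        flank <- setdiff(seq.int(max(2L, p - 5L), min(L - 1L, p + 5L)), p)
        hit <- flank[stats::runif(length(flank)) < config$k_rich_flank_prob]
        for (q in hit) substr(proteome[[acc]], q, q) <- "K"
      }
    }
    truth <- truth[order(truth$accession, truth$position), , drop = FALSE]
    rownames(truth) <- NULL
    list(proteome = proteome, truth = truth)
  })
}

# Tryptic-like host peptide for a site at `pos`: starts after a K/R (or at
# the N-terminus), ends at the first K/R at or after pos + 1 (acetyl-K is
# not cleaved, so the modified residue stays internal), extended until the
# peptide has >= 8 residues.
host_peptide <- function(seq, pos) {
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  cleav <- which(chars %in% c("K", "R"))
  starts <- c(1L, cleav[cleav < pos] + 1L)
  ends <- c(cleav[cleav >= pos + 1L], L)
  for (e in ends) {
    ok <- starts[e - starts + 1L >= 8L]
    if (length(ok) > 0L) {
      s <- max(ok)
      return(list(start = s, end = e,
                  peptide = substring(seq, s, e)))
    }
  }
  list(start = 1L, end = L, peptide = seq)
}

psm_scores <- function(n, thresholds = filter_thresholds(), decoy = logical(n)) {
  charge <- sample(2:3, n, replace = TRUE)
  thr <- xcorr_threshold(charge, thresholds)
  xcorr <- ifelse(decoy, pmax(0.1, thr - stats::runif(n, 0.5, 1)),
                  thr + stats::rexp(n, 2))
  data.frame(charge = charge, xcorr = round(xcorr, 4),
             deltacn = round(stats::runif(n, 0, 0.29), 4))
}

#' Generate per-replicate PSM tables for a synthetic acetylome experiment
#'
#' For every planted site and every replicate, the site is detected
#' independently with its category's probability (`p_detect_ctrl` in
#' controls; `p_detect_kd_*` in knockdowns); a detection emits one PSM row
#' per spectral count (zero-truncated Poisson) for a tryptic-like host
#' peptide carrying the acetyl-K.  Each protein additionally emits one
#' unmodified peptide per replicate so protein totals are nonzero.  All
#' PSMs pass the default [filter_thresholds()] unless `decoy_fraction > 0`.
#'
#' @param proteome,truth From [generate_proteome()].
#' @param config The same [acetylome_sim_config()] (its seed, offset by
#'   one, drives this stage, so proteome and experiment draws are
#'   independent streams).
#' @return Named list of `n_ctrl_reps + n_kd_reps` PSM data.frames
#'   (`ctrl_1` ... `kd_3`), each round-trippable through
#'   [write_psm_table()]/[read_psm_table()].  `do.call(rbind, x)` gives
#'   the combined table.
#' @export
generate_acetylome_experiment <- function(proteome, truth, config) {
  stopifnot(inherits(config, "acetylome_sim_config"))
  proteome <- as_proteome(proteome)
  if (!all(truth$accession %in% names(proteome)))
    stop("truth refers to accessions absent from the proteome", call. = FALSE)
  ok_k <- substring(proteome[truth$accession], truth$position,
                    truth$position) == "K"
  if (!all(ok_k)) stop("truth sites must be K residues", call. = FALSE)

  peps <- lapply(seq_len(nrow(truth)), function(i)
    host_peptide(proteome[[truth$accession[i]]], truth$position[i]))
  unmod <- lapply(names(proteome), function(acc) {
    seq <- proteome[[acc]]
    chars <- strsplit(seq, "")[[1]]
    cleav <- which(chars %in% c("K", "R"))
    ends <- c(cleav, nchar(seq))
    e <- ends[ends >= 8L][1L]
    if (is.na(e)) e <- nchar(seq)
    list(start = 1L, end = e, peptide = substring(seq, 1L, e))
  })
  names(unmod) <- names(proteome)

  reps <- c(paste0("ctrl_", seq_len(config$n_ctrl_reps)),
            paste0("kd_", seq_len(config$n_kd_reps)))
  with_seed(config$seed + 1L, {
    tables <- lapply(reps, function(rep_id) {
      parts <- strsplit(rep_id, "_", fixed = TRUE)[[1]]
      cond <- parts[1L]; rep_no <- parts[2L]
      p <- ifelse(truth$category == "dependent",
                  if (cond == "ctrl") config$p_detect_ctrl
                  else config$p_detect_kd_dependent,
                  if (cond == "ctrl") config$p_detect_ctrl
                  else config$p_detect_kd_independent)
      detected <- stats::runif(nrow(truth)) < p
      rows <- list()
      if (any(detected)) {
        idx <- which(detected)
        counts <- rztpois(length(idx), config$mean_spectral_count)
        site_rows <- rep(idx, counts)
        pep <- vapply(site_rows, function(i) peps[[i]]$peptide, "")
        start <- vapply(site_rows, function(i) peps[[i]]$start, 0L)
        modpos <- truth$position[site_rows] - start + 1L
        n <- length(site_rows)
        sc <- psm_scores(n, decoy = stats::runif(n) < config$decoy_fraction)
        rows$mod <- data.frame(peptide = pep,
                               accessions = truth$accession[site_rows],
                               start = start, charge = sc$charge,
                               xcorr = sc$xcorr, deltacn = sc$deltacn,
                               condition = cond, replicate = rep_no)
        rows$mod$mods <- lapply(modpos, function(p)
          data.frame(pos = p, name = "acetyl-K"))
      }
      nprot <- length(proteome)
      ucount <- rztpois(nprot, config$mean_spectral_count)
      prot_rows <- rep(seq_len(nprot), ucount)
      n <- length(prot_rows)
      sc <- psm_scores(n, decoy = stats::runif(n) < config$decoy_fraction)
      rows$unmod <- data.frame(
        peptide = vapply(prot_rows, function(i) unmod[[i]]$peptide, ""),
        accessions = names(proteome)[prot_rows],
        start = 1L, charge = sc$charge, xcorr = sc$xcorr,
        deltacn = sc$deltacn, condition = cond, replicate = rep_no)
      rows$unmod$mods <- replicate(n, data.frame(pos = integer(),
                                                 name = character()),
                                   simplify = FALSE)
      tab <- rbind(rows$mod, rows$unmod)
      rownames(tab) <- NULL
      class(tab) <- c("psm_table", "data.frame")
      tab
    })
    names(tables) <- reps
    tables
  })
}

#' Configuration for a synthetic trajectory ensemble
#'
#' Replicate trajectories fluctuate i.i.d. Gaussian around a reference
#' conformation; designated donor/acceptor pairs are toggled per frame to
#' hit prescribed hydrogen-bond occupancies.  The defaults emulate a
#' 4 x 50 ns replicate design sampled every ns.
#'
#' @param topology data.frame (`atom`, `element`, `resid`, `resname`).
#' @param reference_coords_a,reference_coords_b `atoms x 3` matrices; the
#'   two reference conformations (B optional).
#' @param fluctuation_sd Per-atom per-frame Gaussian displacement SD
#'   (Angstrom).
#' @param n_replicates,n_frames,frame_interval Replicates, frames per
#'   replicate, and frame spacing (ns); frames run from 0 ns.
#' @param hbond_switch_schedule Optional data.frame `donor`, `acceptor`
#'   (topology row indices), `occupancy` and optionally per-form columns
#'   `occupancy_a` / `occupancy_b`.
#' @param seed Integer seed.
#' @return A `trajectory_sim_config` list.
#' @export
trajectory_sim_config <- function(topology, reference_coords_a,
                                  reference_coords_b = NULL,
                                  fluctuation_sd = 0.3,
                                  n_replicates = 4L, n_frames = 51L,
                                  frame_interval = 1,
                                  hbond_switch_schedule = NULL,
                                  seed = 1L) {
  stopifnot(is.data.frame(topology),
            all(c("atom", "element", "resid", "resname") %in% names(topology)),
            is.matrix(reference_coords_a),
            nrow(reference_coords_a) == nrow(topology),
            ncol(reference_coords_a) == 3L,
            all(is.finite(reference_coords_a)),
            fluctuation_sd >= 0,
            is_count(n_replicates, positive = TRUE),
            is_count(n_frames, positive = TRUE), frame_interval > 0)
  if (!is.null(reference_coords_b))
    stopifnot(is.matrix(reference_coords_b),
              all(dim(reference_coords_b) == dim(reference_coords_a)),
              all(is.finite(reference_coords_b)))
  if (!is.null(hbond_switch_schedule)) {
    stopifnot(is.data.frame(hbond_switch_schedule),
              all(c("donor", "acceptor") %in% names(hbond_switch_schedule)))
    idx <- unlist(hbond_switch_schedule[c("donor", "acceptor")])
    if (any(idx < 1L | idx > nrow(topology)))
      stop("hbond schedule refers to atoms absent from the topology",
           call. = FALSE)
  }
  structure(list(topology = topology,
                 reference_coords_a = reference_coords_a,
                 reference_coords_b = reference_coords_b,
                 fluctuation_sd = fluctuation_sd,
                 n_replicates = as.integer(n_replicates),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 hbond_switch_schedule = hbond_switch_schedule,
                 seed = as.integer(seed)),
            class = "trajectory_sim_config")
}

#' Generate a synthetic replicate trajectory ensemble
#'
#' Each replicate is `reference + N(0, fluctuation_sd^2)` per atom per
#' frame.  For each scheduled hydrogen bond, every frame is drawn on/off
#' by a Bernoulli trial at the scheduled occupancy, and the acceptor atom
#' is placed 2.8 Angstrom (on) or 6.0 Angstrom (off) from the donor, so
#' the realized occupancy under the default heavy-atom 3.5 Angstrom
#' criterion matches the schedule up to binomial noise.
#'
#' @param config A [trajectory_sim_config()].
#' @param form `"a"` or `"b"`: which reference conformation (and, when
#'   per-form schedule columns exist, which occupancy column) to use.
#' @return A [trajectory_ensemble()].
#' @export
generate_trajectory_ensemble <- function(config, form = c("a", "b")) {
  stopifnot(inherits(config, "trajectory_sim_config"))
  form <- match.arg(form)
  ref <- if (form == "a") config$reference_coords_a
         else config$reference_coords_b %||%
           stop("config has no reference_coords_b", call. = FALSE)
  times <- (seq_len(config$n_frames) - 1L) * config$frame_interval
  n_atoms <- nrow(config$topology)
  sched <- config$hbond_switch_schedule
  occ_col <- if (!is.null(sched) && paste0("occupancy_", form) %in% names(sched))
    paste0("occupancy_", form) else "occupancy"
  with_seed(config$seed + (if (form == "a") 0L else 1000L), {
    replicates <- lapply(seq_len(config$n_replicates), function(r) {
      arr <- array(rep(ref, each = config$n_frames) +
                     stats::rnorm(config$n_frames * n_atoms * 3L,
                                  sd = config$fluctuation_sd),
                   dim = c(config$n_frames, n_atoms, 3L))
      if (!is.null(sched)) {
        for (b in seq_len(nrow(sched))) {
          on <- stats::runif(config$n_frames) < sched[[occ_col]][b]
          d <- ifelse(on, 2.8, 6.0)
          for (f in seq_len(config$n_frames))
            arr[f, sched$acceptor[b], ] <- arr[f, sched$donor[b], ] +
              c(d[f], 0, 0)
        }
      }
      arr
    })
    trajectory_ensemble(config$topology, replicates, times)
  })
}

# Internal natural-extension (NeRF) placement: position atom D given A, B,
# C, the C-D bond length, the B-C-D angle and the A-B-C-D torsion (deg).
place_atom <- function(a, b, c_, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- c_ - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  as.vector(c_ + cbind(bc, m, n) %*% d_local)
}

#' Build an ideal polypeptide backbone with prescribed dihedrals
#'
#' Constructs N, CA, C atoms for `n_res` residues with ideal bond lengths
#' and angles and the requested phi/psi torsions (omega fixed at 180), for
#' use as a reference conformation with a planted dihedral basin.
#'
#' @param n_res Number of residues.
#' @param phi,psi Torsions in degrees, recycled to `n_res` (phi of residue
#'   1 and psi of residue `n_res` are undefined and ignored).
#' @return List with `topology` (glycine-free alanine-like backbone:
#'   atoms N, CA, C) and `coords` (`atoms x 3` matrix).
#' @export
build_backbone <- function(n_res, phi = -60, psi = -45) {
  stopifnot(n_res >= 2L)
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.0; a_cacn <- 116.2; a_cnca <- 121.7
  coords <- matrix(NA_real_, 3L * n_res, 3L)
  coords[1L, ] <- c(0, 0, 0)                       # N1
  coords[2L, ] <- c(b_nca, 0, 0)                   # CA1
  ang <- a_ncac * pi / 180
  coords[3L, ] <- coords[2L, ] +
    b_cac * c(-cos(ang), sin(ang), 0)              # C1
  for (i in seq.int(2L, n_res)) {
    nn <- 3L * (i - 1L) + 1L
    coords[nn, ] <- place_atom(coords[nn - 3L, ], coords[nn - 2L, ],
                               coords[nn - 1L, ], b_cn, a_cacn, psi[i - 1L])
    coords[nn + 1L, ] <- place_atom(coords[nn - 2L, ], coords[nn - 1L, ],
                                    coords[nn, ], b_nca, a_cnca, 180)
    coords[nn + 2L, ] <- place_atom(coords[nn - 1L, ], coords[nn, ],
                                    coords[nn + 1L, ], b_cac, a_ncac, phi[i])
  }
  topology <- data.frame(atom = rep(c("N", "CA", "C"), n_res),
                         element = rep(c("N", "C", "C"), n_res),
                         resid = rep(seq_len(n_res), each = 3L),
                         resname = "ALA")
  list(topology = topology, coords = coords)
}

#' Configuration for synthetic two-channel cell images
#'
#' Cells are disjoint discs on a dark field; the signal channel carries a
#' constant in-cell background, discrete 2-D Gaussian foci each
#' integrating to `focus_total_intensity`, a constant outside-cell
#' background, and Gaussian read noise (clamped at zero).  The marker
#' channel carries matching foci for detection.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param n_cells Number of cells (0 gives a pure background image).
#' @param cell_radius Cell disc radius (px).
#' @param foci_per_cell Integer vector, recycled across cells.
#' @param focus_total_intensity Integrated intensity per focus (counts).
#' @param focus_sigma Gaussian focus SD (px), > 0.
#' @param background_level In-cell background (counts).
#' @param outside_level Outside-cell background (counts).
#' @param noise_sd Read-noise SD (counts).
#' @param reposition_border_foci Resample foci that would fall within
#'   3 sigma of the image border (error if `FALSE`).
#' @param seed Integer seed.
#' @return An `image_sim_config` list.
#' @export
image_sim_config <- function(image_shape = c(256L, 256L), n_cells = 4L,
                             cell_radius = 40, foci_per_cell = 2L,
                             focus_total_intensity = 20000,
                             focus_sigma = 2, background_level = 100,
                             outside_level = 20, noise_sd = 3,
                             reposition_border_foci = TRUE, seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 16L),
            is_count(n_cells), cell_radius >= 2,
            all(foci_per_cell >= 0), focus_sigma > 0,
            focus_total_intensity >= 0, background_level >= 0,
            outside_level >= 0, noise_sd >= 0)
  structure(list(image_shape = as.integer(image_shape),
                 n_cells = as.integer(n_cells), cell_radius = cell_radius,
                 foci_per_cell = as.integer(foci_per_cell),
                 focus_total_intensity = focus_total_intensity,
                 focus_sigma = focus_sigma,
                 background_level = background_level,
                 outside_level = outside_level, noise_sd = noise_sd,
                 reposition_border_foci = isTRUE(reposition_border_foci),
                 seed = as.integer(seed)),
            class = "image_sim_config")
}

add_gaussian_focus <- function(img, row0, col0, total, sigma) {
  half <- ceiling(6 * sigma)
  rows <- max(1L, floor(row0 - half)):min(nrow(img), ceiling(row0 + half))
  cols <- max(1L, floor(col0 - half)):min(ncol(img), ceiling(col0 + half))
  dr2 <- outer((rows - row0)^2, (cols - col0)^2, "+")
  img[rows, cols] <- img[rows, cols] +
    total / (2 * pi * sigma^2) * exp(-dr2 / (2 * sigma^2))
  img
}

#' Generate a synthetic two-channel fluorescence image
#'
#' @param config An [image_sim_config()].
#' @return List with `signal` and `marker` (numeric matrices), `masks`
#'   (integer label matrix, 0 outside cells), `foci` (data.frame `cell`,
#'   `row`, `col`, `intensity`) and `config`.
#' @export
generate_cell_image <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  nr <- config$image_shape[1L]; nc <- config$image_shape[2L]
  with_seed(config$seed, {
    masks <- matrix(0L, nr, nc)
    centres <- matrix(numeric(0), 0L, 2L)
    margin <- config$cell_radius + 1
    if (config$n_cells > 0L) {
      if (2 * margin >= min(nr, nc))
        stop("cells do not fit in the image", call. = FALSE)
      tries <- 0L
      while (nrow(centres) < config$n_cells) {
        cand <- c(stats::runif(1, margin, nr - margin),
                  stats::runif(1, margin, nc - margin))
        ok <- nrow(centres) == 0L ||
          all((centres[, 1L] - cand[1L])^2 + (centres[, 2L] - cand[2L])^2 >
                (2 * config$cell_radius + 2)^2)
        if (ok) centres <- rbind(centres, cand)
        tries <- tries + 1L
        if (tries > 20000L)
          stop("could not place ", config$n_cells,
               " non-overlapping cells; reduce n_cells or cell_radius",
               call. = FALSE)
      }
      rr <- row(masks); cc <- col(masks)
      for (i in seq_len(nrow(centres)))
        masks[(rr - centres[i, 1L])^2 + (cc - centres[i, 2L])^2 <=
                config$cell_radius^2] <- i
    }

    signal <- matrix(config$outside_level, nr, nc)
    signal[masks > 0L] <- config$background_level
    marker <- matrix(0, nr, nc)

    foci <- data.frame(cell = integer(), row = numeric(), col = numeric(),
                       intensity = numeric())
    if (config$n_cells > 0L) {
      nfoci <- rep_len(config$foci_per_cell, config$n_cells)
      border_margin <- 3 * config$focus_sigma
      for (i in seq_len(config$n_cells)) {
        for (k in seq_len(nfoci[i])) {
          repeat {
            ang <- stats::runif(1, 0, 2 * pi)
            rad <- config$cell_radius * 0.6 * sqrt(stats::runif(1))
            pos <- centres[i, ] + rad * c(cos(ang), sin(ang))
            inside <- pos[1L] > border_margin & pos[1L] < nr - border_margin &
              pos[2L] > border_margin & pos[2L] < nc - border_margin
            if (inside) break
            if (!config$reposition_border_foci)
              stop("focus would overlap the image border", call. = FALSE)
          }
          signal <- add_gaussian_focus(signal, pos[1L], pos[2L],
                                       config$focus_total_intensity,
                                       config$focus_sigma)
          marker <- add_gaussian_focus(marker, pos[1L], pos[2L],
                                       config$focus_total_intensity,
                                       config$focus_sigma)
          foci <- rbind(foci, data.frame(cell = i, row = pos[1L],
                                         col = pos[2L],
                                         intensity = config$focus_total_intensity))
        }
      }
    }
    if (config$noise_sd > 0) {
      signal <- pmax(signal + stats::rnorm(nr * nc, sd = config$noise_sd), 0)
      marker <- pmax(marker + stats::rnorm(nr * nc, sd = config$noise_sd), 0)
    }
    list(signal = signal, marker = marker, masks = masks, foci = foci,
         config = config)
  })
}
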