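#' Replicate trajectory ensemble container
#'
#' Bundles N replicate trajectories of one protein form with their shared
#' minimal topology.  Coordinates are plain numeric arrays
#' `frames x atoms x 3` in Angstrom; times are in ns and must be strictly
#' increasing and shared across replicates.
#'
#' @param topology data.frame with columns `atom` (atom name, e.g. "CA"),
#'   `element` ("H", "C", "N", "O", "S"), `resid` (integer residue id),
#'   `resname` (three-letter residue name).
#' @param replicates List of `frames x atoms x 3` numeric arrays.
#' @param times Numeric vector of frame times (ns), length = frames.
#' @return A `trajectory_ensemble` object.
#' @export
trajectory_ensemble <- function(topology, replicates, times) {
  stopifnot(is.data.frame(topology),
            all(c("atom", "element", "resid", "resname") %in% names(topology)),
            is.list(replicates), length(replicates) >= 1L)
  n_atoms <- nrow(topology)
  for (r in replicates) {
    stopifnot(is.array(r), length(dim(r)) == 3L, dim(r)[2] == n_atoms,
              dim(r)[3] == 3L, all(is.finite(r)))
    stopifnot(dim(r)[1] == length(times))
  }
  stopifnot(is.numeric(times), all(diff(times) > 0))
  structure(list(topology = topology, replicates = replicates,
                 times = as.numeric(times)),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("trajectory_ensemble: ", length(x$replicates), " replicates, ",
      length(x$times), " frames (", x$times[1L], "-",
      x$times[length(x$times)], " ns), ", nrow(x$topology), " atoms\n",
      sep = "")
  invisible(x)
}

frames_in_window <- function(times, window) {
  stopifnot(length(window) == 2L, window[1] >= 0, window[1] < window[2])
  if (window[2] > max(times) + 1e-9)
    stop("analysis window [", window[1], ", ", window[2],
         "] ns exceeds the trajectory span", call. = FALSE)
  which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
}

# Optimal rigid-body superposition (Kabsch, via SVD) of P onto Q
# (n x 3 matrices); returns the RMSD after the fit.
kabsch_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P <- sweep(P, 2L, cp); Q <- sweep(Q, 2L, cq)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Pr <- P %*% t(R)
  sqrt(mean(rowSums((Pr - Q)^2)))
}

#' Per-frame RMSD to a reference after optimal superposition
#'
#' Computes, for every frame, the root-mean-square deviation of the
#' selected atoms from the reference structure after a rigid-body
#' (rotation + translation) least-squares fit, so global motion does not
#' contribute.  Used to verify that trajectories have equilibrated before
#' the analysis window.
#'
#' @param traj `frames x atoms x 3` array (one replicate).
#' @param reference `atoms x 3` matrix with the same atom ordering.
#' @param selection Integer atom indices to fit and measure (default: all).
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference, selection = NULL) {
  stopifnot(is.array(traj), length(dim(traj)) == 3L,
            is.matrix(reference), ncol(reference) == 3L,
            dim(traj)[2] == nrow(reference))
  if (is.null(selection)) selection <- seq_len(dim(traj)[2])
  if (length(selection) == 0L) stop("empty atom selection", call. = FALSE)
  ref <- reference[selection, , drop = FALSE]
  vapply(seq_len(dim(traj)[1]), function(f)
    kabsch_rmsd(traj[f, selection, , drop = TRUE], ref), 0)
}

#' Hydrogen-bond geometric criteria
#'
#' @param heavy_distance_max Donor--acceptor heavy-atom distance cutoff
#'   (Angstrom).
#' @param h_acceptor_distance_max Hydrogen--acceptor distance cutoff
#'   (Angstrom), hydrogen-explicit mode only.
#' @param angle_min Minimum donor--hydrogen--acceptor angle (degrees),
#'   hydrogen-explicit mode only.
#' @param mode `"heavy"` (distance-only) or `"hydrogen"` (explicit H).
#' @return An `hbond_criteria` list.
#' @export
hbond_criteria <- function(heavy_distance_max = 3.5,
                           h_acceptor_distance_max = 2.4,
                           angle_min = 120, mode = c("heavy", "hydrogen")) {
  stopifnot(heavy_distance_max > 0, h_acceptor_distance_max > 0,
            angle_min > 0, angle_min <= 180)
  structure(list(heavy_distance_max = heavy_distance_max,
                 h_acceptor_distance_max = h_acceptor_distance_max,
                 angle_min = angle_min, mode = match.arg(mode)),
            class = "hbond_criteria")
}

vec_angle_deg <- function(a, b) {
  cosang <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

hbond_frame_on <- function(coords, donor, acceptor, hydrogen, criteria) {
  d <- sqrt(sum((coords[donor, ] - coords[acceptor, ])^2))
  if (d > criteria$heavy_distance_max) return(FALSE)
  if (criteria$mode == "hydrogen") {
    ha <- sqrt(sum((coords[hydrogen, ] - coords[acceptor, ])^2))
    if (ha > criteria$h_acceptor_distance_max) return(FALSE)
    ang <- vec_angle_deg(coords[donor, ] - coords[hydrogen, ],
                         coords[acceptor, ] - coords[hydrogen, ])
    if (ang < criteria$angle_min) return(FALSE)
  }
  TRUE
}

#' Hydrogen-bond occupancy over an analysis window
#'
#' Occupancy of each donor/acceptor pair = fraction of window frames in
#' which the pair satisfies the geometric criterion, computed per replicate
#' and averaged across the ensemble.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param bonds data.frame with integer atom-index columns `donor`,
#'   `acceptor` and, for hydrogen-explicit criteria, `hydrogen`.  An
#'   optional `name` column labels the output.
#' @param criteria An [hbond_criteria()] object.
#' @param window `c(start, end)` in ns (default 20--50).
#' @return List with `per_replicate` (bonds x replicates occupancy matrix)
#'   and `mean` (named numeric).
#' @export
hbond_occupancy <- function(ensemble, bonds, criteria = hbond_criteria(),
                            window = c(20, 50)) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"), is.data.frame(bonds),
            all(c("donor", "acceptor") %in% names(bonds)))
  n_atoms <- nrow(ensemble$topology)
  idx_cols <- intersect(c("donor", "acceptor", "hydrogen"), names(bonds))
  idx <- unlist(bonds[idx_cols])
  if (any(idx < 1L | idx > n_atoms))
    stop("bond refers to atom index outside the topology", call. = FALSE)
  if (criteria$mode == "hydrogen") {
    if (!any(ensemble$topology$element == "H"))
      stop("topology contains no hydrogens; use heavy-atom mode ",
           "(hbond_criteria(mode = \"heavy\"))", call. = FALSE)
    if (!"hydrogen" %in% names(bonds))
      stop("hydrogen-explicit criteria need a `hydrogen` column", call. = FALSE)
  }
  frames <- frames_in_window(ensemble$times, window)
  labels <- if ("name" %in% names(bonds)) bonds$name
            else paste0(bonds$donor, "-", bonds$acceptor)
  occ <- matrix(NA_real_, nrow(bonds), length(ensemble$replicates),
                dimnames = list(labels,
                                paste0("rep", seq_along(ensemble$replicates))))
  for (r in seq_along(ensemble$replicates)) {
    traj <- ensemble$replicates[[r]]
    for (b in seq_len(nrow(bonds))) {
      on <- vapply(frames, function(f)
        hbond_frame_on(traj[f, , , drop = TRUE], bonds$donor[b],
                       bonds$acceptor[b],
                       if ("hydrogen" %in% names(bonds)) bonds$hydrogen[b]
                       else NA_integer_,
                       criteria), TRUE)
      occ[b, r] <- mean(on)
    }
  }
  list(per_replicate = occ, mean = rowMeans(occ))
}

# Centre of mass of the heavy side-chain atoms of one residue; NULL for
# residues without heavy side-chain atoms (glycine).
sidechain_atoms <- function(topology, resid) {
  backbone <- c("N", "CA", "C", "O", "OXT")
  which(topology$resid == resid & !(topology$atom %in% backbone) &
          topology$element != "H")
}

#' Mean Calpha to side-chain centre-of-mass distances
#'
#' For requested (or all) residue pairs, computes the per-frame distance
#' between the Calpha atom of residue i and the mass-weighted centre of the
#' heavy side-chain atoms of residue j, averaged over the analysis window
#' and across replicates.  Sensitive to subtle local conformational
#' rearrangements that global RMSD misses.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param pairs Optional data.frame with `ca_resid`, `sc_resid`; default is
#'   the full residue x residue matrix.
#' @param window `c(start, end)` in ns.
#' @return If `pairs` is given, a data.frame `ca_resid`, `sc_resid`,
#'   `mean_distance` plus one column per replicate; otherwise a
#'   residue x residue matrix of ensemble-mean distances (rows = Calpha
#'   residue, columns = side-chain residue; glycine columns are `NA`).
#' @export
backbone_sidechain_distance <- function(ensemble, pairs = NULL,
                                        window = c(20, 50)) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  topo <- ensemble$topology
  frames <- frames_in_window(ensemble$times, window)
  resids <- sort(unique(topo$resid))
  ca_idx <- vapply(resids, function(r) {
    i <- which(topo$resid == r & topo$atom == "CA")
    if (length(i) != 1L) NA_integer_ else i
  }, 0L)
  sc_idx <- lapply(resids, sidechain_atoms, topology = topo)
  sc_mass <- lapply(sc_idx, function(i) ELEMENT_MASS[topo$element[i]])

  pair_mean <- function(ca_r, sc_r) {
    i <- match(ca_r, resids); j <- match(sc_r, resids)
    if (is.na(i) || is.na(j)) stop("unknown residue id", call. = FALSE)
    if (is.na(ca_idx[i])) stop("residue ", ca_r, " has no CA atom", call. = FALSE)
    if (length(sc_idx[[j]]) == 0L)
      stop("residue ", sc_r, " (", topo$resname[topo$resid == sc_r][1L],
           ") has no side chain", call. = FALSE)
    w <- sc_mass[[j]] / sum(sc_mass[[j]])
    vapply(seq_along(ensemble$replicates), function(rr) {
      traj <- ensemble$replicates[[rr]]
      mean(vapply(frames, function(f) {
        xyz <- matrix(traj[f, sc_idx[[j]], ], ncol = 3L)
        com <- colSums(xyz * w)
        sqrt(sum((traj[f, ca_idx[i], ] - com)^2))
      }, 0))
    }, 0)
  }

  if (!is.null(pairs)) {
    stopifnot(all(c("ca_resid", "sc_resid") %in% names(pairs)))
    per_rep <- t(mapply(pair_mean, pairs$ca_resid, pairs$sc_resid))
    colnames(per_rep) <- paste0("rep", seq_along(ensemble$replicates))
    out <- cbind(pairs[c("ca_resid", "sc_resid")],
                 mean_distance = rowMeans(per_rep), per_rep)
    rownames(out) <- NULL
    return(out)
  }
  m <- matrix(NA_real_, length(resids), length(resids),
              dimnames = list(resids, resids))
  for (i in seq_along(resids)) for (j in seq_along(resids)) {
    if (is.na(ca_idx[i]) || length(sc_idx[[j]]) == 0L) next
    m[i, j] <- mean(pair_mean(resids[i], resids[j]))
  }
  m
}

#' Signed four-atom torsion angle
#'
#' IUPAC convention (clockwise positive looking from atom 2 to atom 3),
#' reported in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 Length-3 coordinate vectors.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m <- c(n1[2] * n2[3] - n1[3] * n2[2],
         n1[3] * n2[1] - n1[1] * n2[3],
         n1[1] * n2[2] - n1[2] * n2[1])
  ang <- atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Backbone dihedral series and Ramachandran histogram
#'
#' Extracts phi (`C(i-1)-N-CA-C`) and/or psi (`N-CA-C-N(i+1)`) of one
#' residue from every window frame of every replicate, and bins the pooled
#' (phi, psi) samples on a square grid for Ramachandran-style display.
#' Residues missing a flanking backbone atom (chain termini) yield a
#' partial result with a warning.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param resid Residue id.
#' @param angles Subset of `c("phi", "psi")`.
#' @param window `c(start, end)` in ns.
#' @param bin_deg Histogram bin width in degrees (default 10).
#' @return List with `phi` and/or `psi` (replicates x frames matrices, or
#'   `NULL` with a warning when undefined) and, when both angles are
#'   available, `histogram` (counts on the grid, with break attributes).
#' @export
dihedral_series <- function(ensemble, resid, angles = c("phi", "psi"),
                            window = c(20, 50), bin_deg = 10) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"),
            all(angles %in% c("phi", "psi")))
  topo <- ensemble$topology
  frames <- frames_in_window(ensemble$times, window)
  atom_of <- function(r, a) {
    i <- which(topo$resid == r & topo$atom == a)
    if (length(i) == 1L) i else NA_integer_
  }
  quads <- list(
    phi = c(atom_of(resid - 1L, "C"), atom_of(resid, "N"),
            atom_of(resid, "CA"), atom_of(resid, "C")),
    psi = c(atom_of(resid, "N"), atom_of(resid, "CA"),
            atom_of(resid, "C"), atom_of(resid + 1L, "N")))
  out <- list()
  for (a in angles) {
    q <- quads[[a]]
    if (anyNA(q)) {
      warning("residue ", resid, " lacks the atoms needed for ", a,
              "; returning NULL for it", call. = FALSE)
      out[[a]] <- NULL
      next
    }
    out[[a]] <- t(vapply(seq_along(ensemble$replicates), function(r) {
      traj <- ensemble$replicates[[r]]
      vapply(frames, function(f)
        dihedral_angle(traj[f, q[1], ], traj[f, q[2], ],
                       traj[f, q[3], ], traj[f, q[4], ]), 0)
    }, numeric(length(frames))))
  }
  if (all(c("phi", "psi") %in% names(out)) &&
      !is.null(out$phi) && !is.null(out$psi)) {
    breaks <- seq(-180, 180, by = bin_deg)
    bin <- function(x) findInterval(x, breaks, rightmost.closed = TRUE,
                                    left.open = TRUE)
    h <- matrix(0L, length(breaks) - 1L, length(breaks) - 1L)
    bi <- bin(as.vector(out$phi)); bj <- bin(as.vector(out$psi))
    for (k in seq_along(bi)) h[bi[k], bj[k]] <- h[bi[k], bj[k]] + 1L
    attr(h, "breaks") <- breaks
    out$histogram <- h
  }
  out
}

#' Detect reproducible differences between two replicate ensembles
#'
#' A feature (H-bond occupancy, mean distance, ...) differs reproducibly
#' between ensembles A and B when the two sets of per-replicate summaries
#' occupy disjoint ranges (every A replicate on one side of every B
#' replicate) *and* the ensemble means differ by at least `delta_min`.
#' Under exchangeability the disjoint-ranges event alone has probability
#' `2 / choose(nA + nB, nA)` (0.0286 for 4 vs 4), which bounds the false
#' -flag rate at `delta_min = 0`.
#'
#' @param a,b Numeric matrices, features x replicates (>= 2 replicates per
#'   side), with matching rownames (feature ids).
#' @param delta_min Minimum absolute difference of ensemble means.
#' @return data.frame of flagged features (`feature`, `mean_a`, `mean_b`,
#'   `effect` = mean_b - mean_a, plus per-replicate value columns).  The
#'   full audit table, including unflagged features, is in the `"audit"`
#'   attribute.
#' @export
compare_ensembles <- function(a, b, delta_min = 0) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("reproducibility needs at least 2 replicates per ensemble",
         call. = FALSE)
  if (nrow(a) != nrow(b))
    stop("ensembles expose different feature sets", call. = FALSE)
  feat <- rownames(a) %||% as.character(seq_len(nrow(a)))
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  min_a <- apply(a, 1L, min); max_a <- apply(a, 1L, max)
  min_b <- apply(b, 1L, min); max_b <- apply(b, 1L, max)
  disjoint <- (max_a < min_b) | (max_b < min_a)
  flagged <- disjoint & abs(mean_b - mean_a) >= delta_min
  audit <- data.frame(feature = feat, mean_a = mean_a, mean_b = mean_b,
                      effect = mean_b - mean_a, disjoint = disjoint,
                      flagged = flagged)
  colnames(a) <- paste0("a_rep", seq_len(ncol(a)))
  colnames(b) <- paste0("b_rep", seq_len(ncol(b)))
  audit <- cbind(audit, a, b)
  rownames(audit) <- NULL
  out <- audit[audit$flagged, setdiff(names(audit), c("disjoint", "flagged")),
               drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}
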