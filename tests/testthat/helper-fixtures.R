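# Shared fixtures built in code.

# One PSM row with sensible defaults; mods as data.frame(pos, name).
make_psm <- function(peptide, accessions = "P1", start = 1L, charge = 2L,
                     xcorr = 3.0, deltacn = 0.1,
                     mods = data.frame(pos = integer(), name = character()),
                     condition = "ctrl", replicate = "1") {
  out <- data.frame(peptide = peptide, accessions = accessions,
                    start = as.integer(start), charge = as.integer(charge),
                    xcorr = xcorr, deltacn = deltacn,
                    condition = condition, replicate = replicate)
  out$mods <- list(mods)
  class(out) <- c("psm_table", "data.frame")
  out
}

bind_psms <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  class(out) <- c("psm_table", "data.frame")
  out
}

acetyl_at <- function(pos) data.frame(pos = as.integer(pos), name = "acetyl-K")

# A protein carrying the conserved kinase-domain peptide
# TGLEVAIKMIDKKAMYKAGMVDQR at residues 34-57, with K45/K46 acetylatable.
kinase_domain_protein <- function() {
  prefix <- "MATSSELLRSFAVPPVRAGHGGAHSTPAAVAGS"   # residues 1-33
  peptide <- "TGLEVAIKMIDKKAMYKAGMVDQR"           # residues 34-57
  suffix <- "SLEAFNEVVAAGHTPR"
  c(PLK4 = paste0(prefix, peptide, suffix))
}

# Evidence matrix with one site per requested ctrl/kd presence pattern.
evidence_from_patterns <- function(ctrl_patterns, kd_patterns) {
  stopifnot(nrow(ctrl_patterns) == nrow(kd_patterns))
  rows <- list()
  for (i in seq_len(nrow(ctrl_patterns))) {
    acc <- sprintf("S%04d", i)
    for (r in which(ctrl_patterns[i, ] == 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc, position = 10L, condition = "ctrl",
        replicate = r, spectral_count = 1L)
    for (r in which(kd_patterns[i, ] == 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc, position = 10L, condition = "kd",
        replicate = r, spectral_count = 1L)
    # sites absent everywhere still need a row to be registered; give them
    # a zero-count ctrl record so they occupy a row
    if (all(ctrl_patterns[i, ] == 0L) && all(kd_patterns[i, ] == 0L))
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc, position = 10L, condition = "ctrl",
        replicate = 1L, spectral_count = 0L)
  }
  build_evidence_matrix(do.call(rbind, rows))
}

# Independent signed-torsion oracle: acos magnitude + triple-product sign.
torsion_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(min(1, max(-1, cosang))) * 180 / pi
  s <- sign(sum(n1 * b3))
  if (s < 0) -ang else ang
}

# Random rigid-body transform applied to every frame of an array.
random_rigid <- function(arr, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- rnorm(3, sd = 10)
  out <- arr
  for (f in seq_len(dim(arr)[1]))
    out[f, , ] <- arr[f, , ] %*% q + rep(shift, each = dim(arr)[2])
  out
}
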