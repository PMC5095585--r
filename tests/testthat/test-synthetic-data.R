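test_that("proteome generation is deterministic and plants sites as specified", {
  cfg <- acetylome_sim_config(n_proteins = 50, n_dependent_sites = 10,
                              n_independent_sites = 5, seed = 1)
  a <- generate_proteome(cfg)
  b <- generate_proteome(cfg)
  expect_identical(a, b)

  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_proteome_fasta(a$proteome, f1)
  write_proteome_fasta(b$proteome, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  dep <- a$truth[a$truth$category == "dependent", ]
  expect_equal(nrow(dep), 10)
  res <- substring(a$proteome[a$truth$accession], a$truth$position,
                   a$truth$position)
  expect_true(all(res == "K"))
  # each planted site in exactly one category
  expect_false(any(duplicated(a$truth[c("accession", "position")])))
})

test_that("uniform composition gives the expected K frequency", {
  cfg <- acetylome_sim_config(n_proteins = 300,
                              protein_length_range = c(300, 400),
                              n_dependent_sites = 0, n_independent_sites = 0,
                              seed = 11)
  pr <- generate_proteome(cfg)
  chars <- strsplit(paste(pr$proteome, collapse = ""), "")[[1]]
  n <- length(chars)
  expect_gt(n, 1e5)
  k_freq <- mean(chars == "K")
  expect_lt(abs(k_freq - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("length range too short to host the requested sites is rejected", {
  cfg <- acetylome_sim_config(n_proteins = 1,
                              protein_length_range = c(20, 20),
                              n_dependent_sites = 30, n_independent_sites = 0)
  expect_error(generate_proteome(cfg), "too short")
})

test_that("degenerate detection probabilities give perfect presence/absence", {
  cfg <- acetylome_sim_config(n_proteins = 20, n_dependent_sites = 15,
                              n_independent_sites = 0, p_detect_ctrl = 1,
                              p_detect_kd_dependent = 0, seed = 3)
  pr <- generate_proteome(cfg)
  tabs <- generate_acetylome_experiment(pr$proteome, pr$truth, cfg)
  expect_named(tabs, c(paste0("ctrl_", 1:5), paste0("kd_", 1:3)))
  key <- function(df) {
    sites <- map_acetyl_sites(df, pr$proteome)
    unique(paste(sites$accession, sites$position))
  }
  truth_key <- paste(pr$truth$accession, pr$truth$position)
  for (r in paste0("ctrl_", 1:5))
    expect_setequal(key(tabs[[r]]), truth_key)
  for (r in paste0("kd_", 1:3))
    expect_length(key(tabs[[r]]), 0)
})

test_that("per-replicate detected fraction matches the Bernoulli rate", {
  cfg <- acetylome_sim_config(n_proteins = 100,
                              protein_length_range = c(300, 500),
                              n_dependent_sites = 1000,
                              n_independent_sites = 0,
                              p_detect_ctrl = 0.9, seed = 5)
  pr <- generate_proteome(cfg)
  tabs <- generate_acetylome_experiment(pr$proteome, pr$truth, cfg)
  sites <- map_acetyl_sites(tabs$ctrl_1, pr$proteome)
  frac <- length(unique(paste(sites$accession, sites$position))) / 1000
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / 1000))
  # same seed, same tables
  tabs2 <- generate_acetylome_experiment(pr$proteome, pr$truth, cfg)
  expect_identical(tabs, tabs2)
})

test_that("emitted PSMs pass the default filters and round-trip the reader", {
  cfg <- acetylome_sim_config(n_proteins = 15, n_dependent_sites = 10,
                              n_independent_sites = 5, seed = 9)
  pr <- generate_proteome(cfg)
  tabs <- generate_acetylome_experiment(pr$proteome, pr$truth, cfg)
  all_psms <- do.call(rbind, tabs)
  res <- filter_psms(all_psms)
  expect_equal(unname(res$tally["retained"]), nrow(all_psms))

  path <- tempfile(fileext = ".tsv")
  write_psm_table(tabs$ctrl_1, path)
  back <- read_psm_table(path, pr$proteome)
  expect_equal(nrow(attr(back, "rejected")), 0)
  orig <- tabs$ctrl_1
  rownames(orig) <- NULL
  for (col in c("peptide", "accessions", "start", "charge", "condition"))
    expect_equal(back[[col]], orig[[col]])
  expect_equal(back$xcorr, orig$xcorr, tolerance = 1e-12)
  expect_equal(lapply(back$mods, as.list), lapply(orig$mods, as.list))
})

test_that("decoy fraction produces filter-failing PSMs", {
  cfg <- acetylome_sim_config(n_proteins = 30, n_dependent_sites = 20,
                              n_independent_sites = 0, decoy_fraction = 0.5,
                              seed = 13)
  pr <- generate_proteome(cfg)
  tabs <- generate_acetylome_experiment(pr$proteome, pr$truth, cfg)
  res <- filter_psms(do.call(rbind, tabs))
  expect_gt(res$tally[["xcorr"]], 0)
})

test_that("zero-noise trajectories equal the reference and seeds reproduce", {
  bb <- build_backbone(8)
  cfg <- trajectory_sim_config(bb$topology, bb$coords, fluctuation_sd = 0,
                               n_frames = 11, frame_interval = 5, seed = 2)
  ens <- generate_trajectory_ensemble(cfg)
  expect_length(ens$replicates, 4)
  for (r in ens$replicates)
    for (f in seq_len(dim(r)[1]))
      expect_equal(r[f, , ], unname(bb$coords), ignore_attr = TRUE)
  ens2 <- generate_trajectory_ensemble(cfg)
  expect_identical(ens$replicates, ens2$replicates)
})

test_that("hbond schedule occupancy is realized within binomial error", {
  bb <- build_backbone(8)
  sched <- data.frame(donor = 2L, acceptor = 20L, occupancy = 0.5)
  cfg <- trajectory_sim_config(bb$topology, bb$coords, fluctuation_sd = 0.1,
                               n_frames = 201, frame_interval = 0.25,
                               hbond_switch_schedule = sched, seed = 21)
  ens <- generate_trajectory_ensemble(cfg)
  occ <- hbond_occupancy(ens, sched, window = c(0, 50))
  n <- 201 * 4
  expect_lt(abs(mean(occ$per_replicate) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("schedule referring to unknown atoms is rejected", {
  bb <- build_backbone(4)
  sched <- data.frame(donor = 1L, acceptor = 999L, occupancy = 0.5)
  expect_error(trajectory_sim_config(bb$topology, bb$coords,
                                     hbond_switch_schedule = sched),
               "absent from the topology")
})

test_that("noise-free image conserves planted focus intensity", {
  cfg <- image_sim_config(n_cells = 1, foci_per_cell = 1, noise_sd = 0,
                          focus_total_intensity = 30000, focus_sigma = 2,
                          background_level = 100, outside_level = 20,
                          seed = 6)
  img <- generate_cell_image(cfg)
  n_in <- sum(img$masks > 0)
  n_out <- sum(img$masks == 0)
  baseline <- 100 * n_in + 20 * n_out
  recovered <- sum(img$signal) - baseline
  expect_lt(abs(recovered - 30000) / 30000, 0.01)
  expect_true(all(img$masks[cbind(round(img$foci$row),
                                  round(img$foci$col))] == img$foci$cell))
})

test_that("an image without cells is pure background and seeds reproduce", {
  cfg <- image_sim_config(n_cells = 0, noise_sd = 0, outside_level = 20,
                          seed = 8)
  img <- generate_cell_image(cfg)
  expect_true(all(img$signal == 20))
  expect_equal(nrow(img$foci), 0)
  cfg2 <- image_sim_config(n_cells = 3, seed = 10)
  expect_identical(generate_cell_image(cfg2)$signal,
                   generate_cell_image(cfg2)$signal)
})
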