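test_that("config invariants are enforced", {
  expect_error(synthetic_config(chain_length = 1), "chain_length")
  expect_error(synthetic_config(n_entries = 0), "n_entries")
  expect_error(synthetic_config(n_models = 0), "n_models")
  expect_error(synthetic_config(aromatic_fraction = 1.2), "aromatic_fraction")
  expect_error(synthetic_config(restraint_cutoff = 0), "restraint_cutoff")
})

test_that("minimal structure: one model, one amide proton, no rings", {
  cfg <- synthetic_config(n_entries = 1, chain_length = 2,
                          aromatic_fraction = 0, n_models = 1, seed = 2)
  e <- generate_structure(cfg, 1)
  expect_equal(unique(e$atoms$model), 1L)
  expect_equal(sum(e$atoms$atom_name == "H"), 1)  # first residue has none
  expect_equal(nrow(ring_instances(e)), 0)
})

test_that("models share one atom roster", {
  cfg <- synthetic_config(n_entries = 1, chain_length = 12, n_models = 3,
                          seed = 4)
  e <- generate_structure(cfg, 1)
  rosters <- split(paste(e$atoms$seq_id, e$atoms$atom_name), e$atoms$model)
  expect_length(rosters, 3)
  expect_equal(rosters[[1]], rosters[[2]])
  expect_equal(rosters[[1]], rosters[[3]])
})

test_that("generated rings are planar with 1.39 A bonds and exact anchors", {
  cfg <- synthetic_config(n_entries = 1, chain_length = 24,
                          aromatic_fraction = 0.5, n_models = 2, seed = 8)
  e <- generate_structure(cfg, 1)
  defs <- ring_definitions()
  anchors <- e$ring_anchors
  expect_gt(nrow(anchors), 0)
  for (i in seq_len(nrow(anchors))) {
    res <- e$atoms[e$atoms$seq_id == anchors$seq_id[i], ]
    members <- defs$members[[which(defs$residue_type == res$residue_type[1] &
                                     defs$ring_id == anchors$ring_id[i])]]
    for (m in unique(res$model)) {
      rm <- res[res$model == m, ]
      coords <- as.matrix(rm[match(members, rm$atom_name), c("x", "y", "z")])
      ctr <- colMeans(coords)
      # centroid equals the stored anchor to < 1e-9
      expect_lt(sqrt(sum((ctr - unlist(anchors[i, c("x", "y", "z")]))^2)),
                1e-9)
      # planarity: every vertex within 1e-6 of the best plane
      sv <- svd(sweep(coords, 2, ctr))
      nrm <- sv$v[, 3]
      expect_lt(max(abs(sweep(coords, 2, ctr) %*% nrm)), 1e-6)
      # bond lengths ~1.39 around the six-membered rings
      if (anchors$ring_id[i] == "six") {
        adj <- if (res$residue_type[1] == "TRP")
          c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
        else c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
        hexc <- as.matrix(rm[match(adj, rm$atom_name), c("x", "y", "z")])
        d <- sqrt(rowSums((hexc - hexc[c(2:6, 1), ])^2))
        expect_equal(unname(d), rep(1.39, 6), tolerance = 1e-6)
      }
    }
  }
})

test_that("ring_current_delta matches the point-dipole closed form", {
  # magic angle zero
  expect_equal(ring_current_delta(3, 54.7356, 1, 30.42), 0, tolerance = 1e-4)
  # direct evaluation: 30.42 * (1 - 3) / 27
  expect_equal(ring_current_delta(3, 0, 1, 30.42), -30.42 * 2 / 27,
               tolerance = 1e-12)
  expect_equal(ring_current_delta(3, 0, 1, 30.42), -2.2533, tolerance = 1e-4)
  # 1/r^3 scaling
  expect_equal(ring_current_delta(6, 0, 1, 30.42),
               ring_current_delta(3, 0, 1, 30.42) / 8, tolerance = 1e-12)
  # sign: shielding on axis, deshielding in plane
  expect_lt(ring_current_delta(4, 10), 0)
  expect_gt(ring_current_delta(4, 80), 0)
  expect_error(ring_current_delta(0, 0), "r must be")
  expect_error(ring_current_delta(-1, 0), "r must be")
})

test_that("plant_shifts reproduces reference means with no noise, no rings", {
  cfg <- synthetic_config(n_entries = 1, chain_length = 8,
                          aromatic_fraction = 0, noise_sd_scale = 0,
                          n_models = 1, seed = 3)
  e <- generate_structure(cfg, 1)
  st <- default_reference_stats()
  out <- plant_shifts(e, st, cfg)
  i <- match(out$shifts$residue_type, st$residue_type)
  expect_equal(out$shifts$value, st$mean[i], tolerance = 1e-12)
  expect_true(all(out$ground_truth$perturbation == 0))
})

test_that("an on-axis amide at 3 A from a PHE ring shifts by -2.2533", {
  ens <- toy_ring_ensemble(h_pos = c(0, 0, 3))
  cfg <- synthetic_config(n_entries = 1, chain_length = 2,
                          noise_sd_scale = 0, seed = 1)
  st <- default_reference_stats()
  out <- plant_shifts(ens, st, cfg)
  mu <- st$mean[st$residue_type == "ALA"]
  expect_equal(out$shifts$value, mu - 2.2533, tolerance = 1e-4)
  expect_equal(out$ground_truth$perturbation, -2.2533, tolerance = 1e-4)
  expect_equal(out$ground_truth$ring_type, "PHE")
})

test_that("plant_shifts is deterministic and errors on missing stats", {
  cfg <- synthetic_config(n_entries = 1, chain_length = 10, seed = 6)
  e <- generate_structure(cfg, 1)
  st <- default_reference_stats()
  a <- plant_shifts(e, st, cfg, seed = 99)
  b <- plant_shifts(e, st, cfg, seed = 99)
  expect_identical(a$shifts$value, b$shifts$value)
  types <- unique(e$atoms$residue_type[e$atoms$atom_name == "H"])
  st2 <- st[st$residue_type != types[1], ]
  expect_error(plant_shifts(e, st2, cfg), types[1])
})

test_that("planted-effect signs follow the ring-current geometry", {
  cfg <- synthetic_config(n_entries = 4, chain_length = 24,
                          aromatic_fraction = 0.4, noise_sd_scale = 0,
                          n_models = 2, seed = 13)
  st <- default_reference_stats()
  checked <- 0
  for (i in 1:4) {
    e <- generate_structure(cfg, i)
    out <- plant_shifts(e, st, cfg)
    gt <- out$ground_truth
    mu <- st$mean[match(gt$residue_type, st$residue_type)]
    on_axis <- !is.na(gt$ring_type) & gt$ring_type %in% c("PHE", "TYR", "TRP") &
      gt$avg_azimuth < 30 & gt$avg_distance < 5
    in_plane <- !is.na(gt$ring_type) & gt$avg_azimuth > 80 &
      gt$avg_distance < 5
    expect_true(all(out$shifts$value[on_axis] < mu[on_axis]))
    expect_true(all(out$shifts$value[in_plane] > mu[in_plane]))
    checked <- checked + sum(on_axis) + sum(in_plane)
  }
  expect_gt(checked, 0)
})

test_that("restraint generation matches brute-force pair enumeration", {
  cfg <- synthetic_config(n_entries = 1, chain_length = 20,
                          aromatic_fraction = 0.3, n_models = 2, seed = 21)
  e <- generate_structure(cfg, 1)
  r <- generate_restraints(e, cutoff = 5, seed = 1)
  aa <- r[classify_restraint(r), ]

  # independent enumeration over all (amide H, ring proton) pairs
  defs <- ring_definitions()
  ring_protons <- unlist(lapply(seq_len(nrow(defs)), function(i)
    paste0(defs$residue_type[i], ":", defs$protons[[i]])))
  atoms <- e$atoms
  hs <- unique(atoms[atoms$atom_name == "H", c("chain_id", "seq_id")])
  rp <- unique(atoms[paste0(atoms$residue_type, ":", atoms$atom_name) %in%
                       ring_protons, c("chain_id", "seq_id", "atom_name")])
  n_expected <- 0
  for (i in seq_len(nrow(hs))) for (j in seq_len(nrow(rp))) {
    d <- c()
    for (m in unique(atoms$model)) {
      a1 <- atoms[atoms$model == m & atoms$seq_id == hs$seq_id[i] &
                    atoms$atom_name == "H", ]
      a2 <- atoms[atoms$model == m & atoms$seq_id == rp$seq_id[j] &
                    atoms$atom_name == rp$atom_name[j], ]
      d <- c(d, sqrt((a1$x - a2$x)^2 + (a1$y - a2$y)^2 + (a1$z - a2$z)^2))
    }
    if (mean(d) <= 5) n_expected <- n_expected + 1
  }
  expect_equal(nrow(aa), n_expected)

  # decoys exist and are rejected by the classifier
  decoys <- r[!classify_restraint(r), ]
  expect_gt(nrow(decoys), 0)
  expect_true(all(decoys$atom_name_1 == "HA"))

  # tiny cutoff: no amide-aromatic restraints
  r0 <- generate_restraints(e, cutoff = 0.1, seed = 1)
  expect_equal(sum(classify_restraint(r0)), 0)
})

test_that("a single constructed amide-aromatic pair yields one restraint", {
  ens <- toy_ring_ensemble(h_pos = c(0, 0, 3))
  r <- generate_restraints(ens, cutoff = 5, seed = 1, decoy_fraction = 0)
  aa <- r[classify_restraint(r), ]
  # H at (0,0,3): ring protons lie in-plane at radius 2.39, distance
  # sqrt(2.39^2 + 9) = 3.85 < 5 for all five PHE ring protons
  expect_equal(nrow(aa), 5)
  expect_true(all(aa$residue_type_2 == "PHE" | aa$residue_type_1 == "PHE"))
})

test_that("the fixture corpus is complete, lossless and deterministic", {
  cfg <- synthetic_config(n_entries = 3, chain_length = 12, n_models = 2,
                          seed = 31)
  d1 <- file.path(tempdir(), "corpus-a")
  d2 <- file.path(tempdir(), "corpus-b")
  unlink(c(d1, d2), recursive = TRUE)
  out <- write_fixture_corpus(cfg, d1)
  write_fixture_corpus(cfg, d2)

  expect_length(list.files(file.path(d1, "shifts")), 3)
  expect_length(list.files(file.path(d1, "structures")), 3)
  expect_length(list.files(file.path(d1, "restraints")), 3)
  pairs <- load_entry_pairs(file.path(d1, "mapping.json"))
  expect_equal(nrow(pairs), 3)

  # byte-identical regeneration
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }

  # ground truth lists one row per amide proton
  gt <- attr(out, "ground_truth")
  n_amides <- 3 * (cfg$chain_length - 1)
  expect_equal(nrow(gt), n_amides)

  # round trip: written shifts match planted values to 3 decimals
  ens1 <- generate_structure(cfg, 1)
  ens1$entry_id <- "PDB0001"
  planted <- plant_shifts(ens1, default_reference_stats(), cfg,
                          seed = (cfg$seed * 1009 + 1 * 3571) %% 2147483647)
  back <- read_shift_records(file.path(d1, "shifts", "BMR0001.str"))
  expect_equal(back$value, planted$shifts$value, tolerance = 5e-4)
})
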