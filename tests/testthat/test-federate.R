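test_that("entry-pair mapping loads, deduplicates and validates", {
  p <- tempfile(fileext = ".json")
  jsonlite::write_json(data.frame(
    shift_id = c("B1", "B2", "B3"), structure_id = c("P1", "P2", "P3")),
    p, dataframe = "rows")
  pairs <- load_entry_pairs(p)
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$shift_entry_id, c("B1", "B2", "B3"))

  jsonlite::write_json(data.frame(
    shift_id = c("B1", "B1", "B2"), structure_id = c("P1", "P1", "")),
    p, dataframe = "rows")
  expect_warning(expect_warning(pairs2 <- load_entry_pairs(p), "rejected"),
                 "duplicated")
  expect_equal(nrow(pairs2), 1)

  writeLines("{not json", p)
  expect_error(load_entry_pairs(p), "malformed")
  jsonlite::write_json(list(), p)
  expect_warning(empty <- load_entry_pairs(p), "no pairs")
  expect_equal(nrow(empty), 0)
})

test_that("restraint classification requires one amide and one ring proton", {
  r <- rbind(
    make_restraint_df("E", "ALA", "H", 1, "PHE", "HZ", 11),
    make_restraint_df("E", "ALA", "H", 2, "PHE", "HB2", 12),
    make_restraint_df("E", "ALA", "HA", 3, "PHE", "HZ", 13),
    make_restraint_df("E", "PHE", "HZ", 14, "ALA", "H", 4),
    make_restraint_df("E", "ALA", "H", 5, "PHE", "HD1", 15))
  # (ALA H, PHE HZ) true; HB2 not a ring proton; HA not the amide proton;
  # order-insensitive; HD1 is a PHE ring proton
  expect_equal(classify_restraint(r), c(TRUE, FALSE, FALSE, TRUE, TRUE))
  # nitrogen-bound ring protons toggled by carbon_only
  rh <- make_restraint_df("E", "ALA", "H", 1, "HIS", "HD1", 11)
  expect_true(classify_restraint(rh))
  expect_false(classify_restraint(rh, carbon_only = TRUE))
  rw <- make_restraint_df("E", "TRP", "HE1", 11, "ALA", "H", 1)
  expect_true(classify_restraint(rw))
  expect_false(classify_restraint(rw, carbon_only = TRUE))
  expect_length(classify_restraint(r[0, ]), 0)
})

test_that("merge produces one record per amide with shift and coordinates", {
  st <- default_reference_stats()
  pair <- data.frame(shift_entry_id = "B", structure_entry_id = "P")

  # 1-residue toy without rings or restraints
  e <- ensemble("P", data.frame(
    model = 1L, chain_id = "A", seq_id = 1L, residue_type = "ALA",
    atom_name = c("N", "H"), x = c(1, 0), y = 0, z = 0,
    stringsAsFactors = FALSE))
  sh <- make_shift_df("B", 1, "ALA", 8.5)
  res <- merge_entry(pair, sh, e, make_restraint_df("P", "A", "H", 1,
                                                    "A", "H", 2)[0, ], st)
  expect_equal(nrow(res$merged), 1)
  m <- res$merged
  expect_true(is.na(m$ring_type))
  expect_true(is.na(m$avg_distance))
  expect_false(m$restrained)
  expect_equal(m$z, (8.5 - st$mean[st$residue_type == "ALA"]) /
                 st$sd[st$residue_type == "ALA"])
  expect_equal(m$z_bin, z_bin(m$z))

  # toy with one amide-aromatic restraint -> restrained, n_restraints = 1
  e2 <- toy_ring_ensemble(h_pos = c(0, 0, 3), entry_id = "P")
  sh2 <- make_shift_df("B", 1, "ALA", 6.0)
  r2 <- make_restraint_df("P", "ALA", "H", 1, "PHE", "HZ", 2)
  res2 <- merge_entry(pair, sh2, e2, r2, st)
  expect_true(res2$merged$restrained)
  expect_equal(res2$merged$n_restraints, 1L)
  expect_equal(res2$merged$ring_type, "PHE")
  expect_equal(res2$merged$avg_distance, 3, tolerance = 1e-9)

  # decoy-only restraints leave the entry ineligible
  r3 <- make_restraint_df("P", "ALA", "HA", 1, "PHE", "HB2", 2)
  res3 <- merge_entry(pair, sh2, e2, r3, st)
  expect_false(res3$merged$restrained)
  expect_false(res3$merged$entry_eligible)
})

test_that("merge accounting is exact against a set-intersection oracle", {
  corp <- shared_corpus()
  pairs <- load_entry_pairs(file.path(corp$dir, "mapping.json"))
  st <- read_reference_stats(file.path(corp$dir, "reference_stats.tsv"))
  for (i in seq_len(nrow(pairs))) {
    sh <- read_shift_records(file.path(corp$dir, "shifts",
                                       paste0(pairs$shift_entry_id[i], ".str")))
    ens <- read_ensemble(file.path(corp$dir, "structures",
                                   paste0(pairs$structure_entry_id[i], ".cif")))
    rst <- read_restraints(file.path(corp$dir, "restraints",
                                     paste0(pairs$structure_entry_id[i], ".str")))
    res <- merge_entry(pairs[i, ], sh, ens, rst, st)
    rep <- res$report

    skey <- unique(paste(sh$chain_id[sh$atom_name == "H"],
                         sh$seq_id[sh$atom_name == "H"]))
    ca <- ens$atoms[ens$atoms$atom_name == "H" & ens$atoms$polymer, ]
    ckey <- unique(paste(ca$chain_id, ca$seq_id))
    expect_equal(rep$n_merged, length(intersect(skey, ckey)) - rep$n_skipped)
    expect_equal(rep$n_shift_only, length(setdiff(skey, ckey)))
    expect_equal(rep$n_coord_only, length(setdiff(ckey, skey)))
    expect_equal(rep$n_candidates,
                 rep$n_merged + rep$n_shift_only + rep$n_coord_only +
                   rep$n_skipped)
    # (pair, chain, seq) uniquely keys records
    expect_equal(anyDuplicated(paste(res$merged$chain_id, res$merged$seq_id)),
                 0)
  }
})

test_that("amides lacking reference statistics are skipped with accounting", {
  st <- default_reference_stats()
  st <- st[st$residue_type != "GLY", ]
  pair <- data.frame(shift_entry_id = "B", structure_entry_id = "P")
  e <- ensemble("P", data.frame(
    model = 1L, chain_id = "A", seq_id = c(1L, 1L, 2L, 2L),
    residue_type = c("ALA", "ALA", "GLY", "GLY"),
    atom_name = c("N", "H", "N", "H"),
    x = c(1, 0, 5, 6), y = 0, z = 0, stringsAsFactors = FALSE))
  sh <- rbind(make_shift_df("B", 1, "ALA", 8.2), make_shift_df("B", 2, "GLY", 8.3))
  res <- merge_entry(pair, sh, e, make_restraint_df("P", "A", "H", 1,
                                                    "A", "H", 2)[0, ], st)
  expect_equal(res$report$n_skipped, 1L)
  expect_equal(nrow(res$merged), 1)
  expect_equal(res$merged$residue_type, "ALA")
})
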