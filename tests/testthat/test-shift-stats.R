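test_that("reference stats use the population SD and exact counts", {
  rec <- make_shift_df("E1", 1:2, "ALA", c(8.0, 8.4))
  st <- compute_reference_stats(rec, "full")
  expect_equal(st$mean, 8.2)
  expect_equal(st$sd, 0.2)            # population denominator
  expect_equal(st$count, 2L)
  # count = 1 -> sd 0 with a flag
  one <- compute_reference_stats(make_shift_df("E1", 1, "GLY", 8.1), "full")
  expect_equal(one$sd, 0)
  expect_true(one$sd_flag)
})

test_that("histogram totals equal counts", {
  set.seed(11)
  rec <- rbind(make_shift_df("E1", 1:50, "ALA", rnorm(50, 8.2, 0.6)),
               make_shift_df("E1", 51:70, "LEU", rnorm(20, 8.2, 0.6)))
  st <- compute_reference_stats(rec, "full")
  hists <- attr(st, "histograms")
  for (i in seq_len(nrow(st))) {
    h <- hists[[paste(st$residue_type[i], st$atom_name[i])]]
    expect_equal(sum(h$count), st$count[i])
  }
})

test_that("carbon-bound rule excludes entries and spares amide protons", {
  full <- data.frame(residue_type = c("ALA", "ALA"), atom_name = c("H", "HA"),
                     count = 100L, mean = c(8.2, 4.3), sd = c(0.6, 0.4),
                     stringsAsFactors = FALSE)
  # HA = 12 ppm (carbon-bound, > 10) -> excluded
  r1 <- make_shift_df("E1", 1, "ALA", 12.0, atom_name = "HA")
  rep1 <- entry_filter(r1, full)
  expect_true(rep1$excluded)
  expect_match(rep1$reasons, "extreme_carbon_bound_proton")
  # backbone H = 11.5 ppm is not carbon-bound -> not excluded
  r2 <- make_shift_df("E2", 1, "ALA", 11.5)
  expect_false(entry_filter(r2, full)$excluded)
  # HA = -3 ppm (< -2.5) -> excluded
  r3 <- make_shift_df("E3", 1, "ALA", -3.0, atom_name = "HA")
  expect_true(entry_filter(r3, full)$excluded)
})

test_that("eight-SD rule is shift-level and strict", {
  full <- data.frame(residue_type = "ALA", atom_name = "H", count = 1000L,
                     mean = 8.0, sd = 0.5, stringsAsFactors = FALSE)
  rec <- make_shift_df("E1", 1:3, "ALA", c(12.0, 12.0005, 8.1))
  rep <- entry_filter(rec, full)
  dropped <- attr(rep, "shift_dropped")
  expect_false(rep$excluded)                 # amide H: entry survives
  expect_equal(dropped, c(FALSE, TRUE, FALSE))  # 8.000 SD kept, 8.001 dropped
})

test_that("ligand flags exclude entries with recorded reasons", {
  full <- data.frame(residue_type = "ALA", atom_name = "H", count = 10L,
                     mean = 8.2, sd = 0.6, stringsAsFactors = FALSE)
  rec <- rbind(make_shift_df("E1", 1, "ALA", 8.2),
               make_shift_df("E2", 1, "ALA", 8.3))
  flags <- data.frame(entry_id = "E2", aromatic_ligand = TRUE,
                      paramagnetic_ligand = TRUE)
  rep <- entry_filter(rec, full, flags)
  expect_equal(rep$excluded, c(FALSE, TRUE))
  expect_match(rep$reasons[2], "aromatic_ligand")
  expect_match(rep$reasons[2], "paramagnetic_ligand")
})

test_that("filtered stats bookkeeping is exact on a planted fixture", {
  set.seed(5)
  # 10 entries; entries 3 and 7 violate the carbon-bound rule
  recs <- do.call(rbind, lapply(1:10, function(i) {
    r <- make_shift_df(sprintf("E%02d", i), 1:5, "ALA", rnorm(5, 8.2, 0.3))
    if (i %in% c(3, 7))
      r <- rbind(r, make_shift_df(sprintf("E%02d", i), 6, "ALA", 11.0,
                                  atom_name = "HA"))
    r
  }))
  full <- compute_reference_stats(recs, "full")
  rep <- entry_filter(recs, full)
  expect_equal(sum(rep$excluded), 2)
  filt <- compute_reference_stats(recs, "filtered")
  h_row <- filt[filt$atom_name == "H", ]
  expect_equal(h_row$count, 40L)            # 8 surviving entries x 5 shifts
  # exact bookkeeping: filtered + excluded = full
  full_h <- full[full$atom_name == "H", ]
  expect_equal(h_row$count + 2L * 5L, full_h$count)
  # full vs filtered means differ only via excluded entries
  keep <- !(recs$entry_id %in% c("E03", "E07")) & recs$atom_name == "H"
  expect_equal(h_row$mean, mean(recs$value[keep]))
})

test_that("z_score follows the stated convention and errors on sd = 0", {
  st <- data.frame(residue_type = "ALA", atom_name = "H", mean = 8.2, sd = 0.6)
  expect_equal(z_score(8.2, st), 0)
  st2 <- data.frame(residue_type = "ALA", atom_name = "H", mean = 8.2, sd = 0.6)
  st2$mean <- 9.0; st2$sd <- 0.6
  expect_equal(z_score(9.0 - 1.2, st2), -2)
  # upfield (smaller ppm) => negative
  expect_lt(z_score(7.0, st), 0)
  st0 <- data.frame(residue_type = "GLY", atom_name = "H", mean = 8.3, sd = 0)
  expect_error(z_score(8.0, st0), "GLY")
})

test_that("z over the stats-building corpus standardises per class", {
  set.seed(9)
  rec <- rbind(make_shift_df("E1", 1:80, "ALA", rnorm(80, 8.2, 0.6)),
               make_shift_df("E1", 81:140, "TRP", rnorm(60, 8.3, 0.8)))
  st <- compute_reference_stats(rec, "full")
  for (tp in c("ALA", "TRP")) {
    s <- st[st$residue_type == tp, ]
    z <- (rec$value[rec$residue_type == tp] - s$mean) / s$sd
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)  # population SD
  }
})

test_that("z_bin rounds half away from zero and clamps", {
  expect_equal(z_bin(0.2), 0L)
  expect_equal(z_bin(2.5), 3L)
  expect_equal(z_bin(-2.5), -3L)
  expect_equal(z_bin(11), 8L)
  expect_equal(z_bin(-11), -8L)
  expect_equal(z_bin(c(-0.49, 0.5, 1.49, -1.5)), c(0L, 1L, 1L, -2L))
})

test_that("reference stats round-trip through TSV", {
  st <- default_reference_stats()
  st$sd_flag <- FALSE
  p <- tempfile(fileext = ".tsv")
  write_reference_stats(st, p)
  back <- read_reference_stats(p)
  expect_equal(back$mean, st$mean)
  expect_equal(back$sd, st$sd)
  expect_equal(back$residue_type, st$residue_type)
})
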