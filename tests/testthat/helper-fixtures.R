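# shared fixture builders; everything is generated in code

options(amidering.verbose = FALSE)

# regular polygon ring coordinates in the z = 0 plane
polygon_ring <- function(n = 6, radius = 1.39, center = c(0, 0, 0),
                         phase = 0) {
  ang <- phase + (seq_len(n) - 1) * 2 * pi / n
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang),
        center[3] + rep(0, n))
}

# hand-built ensemble: one PHE ring in the z = 0 plane centered at
# `ring_center`, plus an ALA residue whose amide proton sits at `h_pos`
# (per model when a matrix with one row per model)
toy_ring_ensemble <- function(h_pos = c(0, 0, 3), ring_center = c(0, 0, 0),
                              entry_id = "TOY", n_models = NULL) {
  if (is.null(dim(h_pos))) h_pos <- matrix(h_pos, nrow = 1)
  if (is.null(n_models)) n_models <- nrow(h_pos)
  ring <- polygon_ring(center = ring_center)
  members <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")  # adjacency order
  protons <- c("HD1", "HE1", "HZ", "HE2", "HD2")        # bonded to 2:6
  ringh <- polygon_ring(radius = 2.39, center = ring_center)[2:6, ]
  rows <- list()
  for (m in seq_len(n_models)) {
    hp <- h_pos[min(m, nrow(h_pos)), ]
    rows[[m]] <- data.frame(
      model = m,
      chain_id = "A",
      seq_id = c(rep(1L, 2), rep(2L, 11)),
      residue_type = c(rep("ALA", 2), rep("PHE", 11)),
      atom_name = c("N", "H", members, protons),
      x = c(hp[1] + 1, hp[1], ring[, 1], ringh[, 1]),
      y = c(hp[2], hp[2], ring[, 2], ringh[, 2]),
      z = c(hp[3], hp[3], ring[, 3], ringh[, 3]),
      stringsAsFactors = FALSE)
  }
  ensemble(entry_id, do.call(rbind, rows))
}

make_shift_df <- function(entry_id, seq_id, residue_type, value,
                          atom_name = "H", chain_id = "A") {
  data.frame(entry_id = entry_id, chain_id = chain_id,
             seq_id = as.integer(seq_id), residue_type = residue_type,
             atom_name = atom_name, value = value,
             ambiguity_code = NA_integer_, stringsAsFactors = FALSE)
}

make_restraint_df <- function(entry_id, res1, atom1, seq1, res2, atom2, seq2,
                              chain = "A", upper = 5) {
  n <- max(length(seq1), length(seq2))
  data.frame(restraint_id = as.character(seq_len(n)), entry_id = entry_id,
             chain_id_1 = chain, seq_id_1 = as.integer(seq1),
             residue_type_1 = res1, atom_name_1 = atom1,
             chain_id_2 = chain, seq_id_2 = as.integer(seq2),
             residue_type_2 = res2, atom_name_2 = atom2,
             upper_bound = upper, stringsAsFactors = FALSE)
}

# brute-force nearest-ring oracle, independent of the package's path:
# enumerates rings from raw atom rows and averages plain Euclidean
# distances over models
brute_nearest_ring <- function(amide_chain, amide_seq, ens) {
  atoms <- ens$atoms[ens$atoms$polymer, ]
  defs <- ring_definitions()
  h <- atoms[atoms$chain_id == amide_chain & atoms$seq_id == amide_seq &
               atoms$atom_name == "H", ]
  if (nrow(h) == 0) return(NULL)
  best <- NULL
  arom <- unique(atoms[atoms$residue_type %in% defs$residue_type,
                       c("chain_id", "seq_id", "residue_type")])
  for (i in seq_len(nrow(arom))) {
    rd <- defs[defs$residue_type == arom$residue_type[i], ]
    for (j in seq_len(nrow(rd))) {
      ds <- c()
      for (m in unique(atoms$model)) {
        ra <- atoms[atoms$chain_id == arom$chain_id[i] &
                      atoms$seq_id == arom$seq_id[i] & atoms$model == m, ]
        idx <- match(rd$members[[j]], ra$atom_name)
        hm <- h[h$model == m, ]
        if (anyNA(idx) || nrow(hm) == 0) next
        ctr <- colMeans(as.matrix(ra[idx, c("x", "y", "z")]))
        ds <- c(ds, sqrt(sum((c(hm$x, hm$y, hm$z) - ctr)^2)))
      }
      if (length(ds) == 0) next
      cand <- list(chain = arom$chain_id[i], seq = arom$seq_id[i],
                   ring_id = rd$ring_id[j], d = mean(ds))
      if (is.null(best) || cand$d < best$d) best <- cand
    }
  }
  best
}

# small shared synthetic corpus, built once per test run
shared_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_entries = 5, chain_length = 24,
                              aromatic_fraction = 0.25, n_models = 3,
                              noise_sd_scale = 1, restraint_cutoff = 5,
                              seed = 42)
      dir <- file.path(tempdir(), "amidering-shared-corpus")
      out <- write_fixture_corpus(cfg, dir)
      cache <<- list(config = cfg, dir = dir,
                     ground_truth = attr(out, "ground_truth"))
    }
    cache
  }
})
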