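#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the four inputs of the federated analysis —
#' multi-model coordinate ensembles, assigned amide shifts with planted
#' ring-current perturbations, NOE-style distance restraints, and the
#' shift-entry/structure-entry mapping — with recorded ground truth.
#'
#' @param n_entries number of entry pairs to generate.
#' @param chain_length residues per chain (>= 2).
#' @param aromatic_fraction proportion of PHE/TYR/TRP/HIS residues.
#' @param n_models models per ensemble.
#' @param noise_sd_scale multiplier on the reference SD for per-shift
#'   Gaussian noise.
#' @param effect_amplitude_B point-dipole intensity constant (ppm A^3);
#'   0 disables the planted effect (negative control).
#' @param ring_intensity named numeric of dimensionless per-ring-type
#'   intensities, keyed `"RES:ring_id"`.
#' @param restraint_cutoff model-averaged proton-proton distance cutoff
#'   (Angstrom) for emitting a restraint.
#' @param effect_radius rings farther than this (Angstrom, ensemble
#'   average) plant no perturbation.
#' @param decoy_fraction fraction of emitted restraints that are decoy
#'   (non-amide-aromatic) pairs.
#' @param calibrate_target_z when non-`NULL`, switches the generator to
#'   calibrated planting: amides on-axis (azimuth <= `calibrate_theta_max`)
#'   within `calibrate_r_max` of a PHE/TYR/TRP ring get a perturbation of
#'   exactly `-calibrate_target_z` reference SDs, and amides in-plane
#'   (azimuth >= 90 - `calibrate_theta_max`) near a HIS ring get
#'   `+calibrate_target_z` SDs; every other amide keeps the graded
#'   point-dipole background. This is the "planted |delta| = k sigma"
#'   world used by the recovery tests; the calibrated subset is flagged
#'   in the ground truth.
#' @param calibrate_r_max,calibrate_theta_max calibration gates (Angstrom,
#'   degrees).
#' @param seed integer seed; identical config + seed gives a byte-identical
#'   corpus.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_entries = 10, chain_length = 32,
                             aromatic_fraction = 0.25, n_models = 3,
                             noise_sd_scale = 1, effect_amplitude_B = 30.42,
                             ring_intensity = default_ring_intensities(),
                             restraint_cutoff = 5, effect_radius = 8,
                             decoy_fraction = 0.2,
                             calibrate_target_z = NULL,
                             calibrate_r_max = 4, calibrate_theta_max = 30,
                             seed = 1) {
  if (n_entries < 1) stopf("invalid config: n_entries must be >= 1")
  if (chain_length < 2) stopf("invalid config: chain_length must be >= 2")
  if (n_models < 1) stopf("invalid config: n_models must be >= 1")
  if (aromatic_fraction < 0 || aromatic_fraction > 1)
    stopf("invalid config: aromatic_fraction must be in [0, 1]")
  if (restraint_cutoff <= 0) stopf("invalid config: restraint_cutoff must be > 0")
  structure(list(
    n_entries = as.integer(n_entries), chain_length = as.integer(chain_length),
    aromatic_fraction = aromatic_fraction, n_models = as.integer(n_models),
    noise_sd_scale = noise_sd_scale, effect_amplitude_B = effect_amplitude_B,
    ring_intensity = ring_intensity, restraint_cutoff = restraint_cutoff,
    effect_radius = effect_radius, decoy_fraction = decoy_fraction,
    calibrate_target_z = calibrate_target_z,
    calibrate_r_max = calibrate_r_max,
    calibrate_theta_max = calibrate_theta_max,
    seed = as.integer(seed)), class = "synthetic_config")
}

#' Default per-ring point-dipole intensities
#'
#' Dimensionless intensity factors relative to a six-membered carbon ring:
#' 1.00 for PHE/TYR, 1.04 and 0.90 for the TRP six- and five-membered
#' rings, 0.53 for the HIS imidazole. Generator defaults only; ground
#' truth is recorded so downstream checks do not depend on these values.
#'
#' @return Named numeric vector keyed `"RES:ring_id"`.
#' @export
default_ring_intensities <- function() {
  c("PHE:six" = 1.00, "TYR:six" = 1.00, "TRP:six" = 1.04,
    "TRP:five" = 0.90, "HIS:five" = 0.53)
}

#' Point-dipole ring-current shift
#'
#' `delta = intensity * B * (1 - 3 cos^2 theta) / r^3` (ppm): shielding
#' (negative, upfield) on the ring axis, deshielding (positive, downfield)
#' in the ring plane, zero at the magic angle, decaying as 1/r^3. Used
#' only to plant effects with a known sign and magnitude; fidelity to any
#' published ring-current model is a non-goal.
#'
#' @param r distance from ring center (Angstrom, > 0), vectorised.
#' @param theta azimuth angle in degrees (0 = on axis), vectorised.
#' @param intensity dimensionless ring intensity.
#' @param B intensity constant (ppm A^3).
#' @return Shift perturbation in ppm.
#' @export
#' @examples
#' ring_current_delta(3, 0)           # -2.2533 ppm on axis
#' ring_current_delta(3, 54.7356)     # ~0 at the magic angle
ring_current_delta <- function(r, theta, intensity = 1, B = 30.42) {
  if (any(r <= 0)) stopf("ring_current_delta: r must be > 0")
  intensity * B * (1 - 3 * cos(theta * pi / 180)^2) / r^3
}

# ---- residue geometry templates -------------------------------------------

# in-plane 2D coordinates (Angstrom) for ring members and ring protons,
# per aromatic residue type; six-ring centered at the origin
ring_template <- function(residue_type) {
  hex <- function(names6) {
    ang <- (0:5) * 60 * pi / 180
    data.frame(atom_name = names6, x = 1.39 * cos(ang), y = 1.39 * sin(ang),
               ring_id = "six", stringsAsFactors = FALSE)
  }
  pent <- function(names5, radius = 1.39 / (2 * sin(36 * pi / 180))) {
    ang <- (90 + (0:4) * 72) * pi / 180
    data.frame(atom_name = names5, x = radius * cos(ang),
               y = radius * sin(ang), ring_id = "five",
               stringsAsFactors = FALSE)
  }
  radial_proton <- function(members, map, center) {
    do.call(rbind, lapply(names(map), function(h) {
      m <- members[members$atom_name == map[[h]], ]
      d <- unit_vector(c(m$x - center[1], m$y - center[2]), "C-H direction")
      data.frame(atom_name = h, x = m$x + d[1], y = m$y + d[2],
                 ring_id = m$ring_id, stringsAsFactors = FALSE)
    }))
  }
  if (residue_type %in% c("PHE", "TYR")) {
    # adjacency order around the hexagon
    mem <- hex(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))
    map <- list(HD1 = "CD1", HD2 = "CD2", HE1 = "CE1", HE2 = "CE2")
    if (residue_type == "PHE") map$HZ <- "CZ"
    pro <- radial_proton(mem, map, c(0, 0))
    return(list(members = mem, protons = pro,
                centers = data.frame(ring_id = "six", x = 0, y = 0)))
  }
  if (residue_type == "HIS") {
    mem <- pent(c("CG", "ND1", "CE1", "NE2", "CD2"))
    mem$ring_id <- "five"
    pro <- radial_proton(mem, list(HD1 = "ND1", HD2 = "CD2",
                                   HE1 = "CE1", HE2 = "NE2"), c(0, 0))
    return(list(members = mem, protons = pro,
                centers = data.frame(ring_id = "five", x = 0, y = 0)))
  }
  if (residue_type == "TRP") {
    mem6 <- hex(c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
    cd2 <- as.numeric(mem6[mem6$atom_name == "CD2", c("x", "y")])
    ce2 <- as.numeric(mem6[mem6$atom_name == "CE2", c("x", "y")])
    mid <- (cd2 + ce2) / 2
    u <- unit_vector(mid, "fused-edge direction")
    apo5 <- 1.39 / (2 * tan(36 * pi / 180))
    r5 <- 1.39 / (2 * sin(36 * pi / 180))
    c5 <- mid + u * apo5
    phi_cd2 <- atan2(cd2[2] - c5[2], cd2[1] - c5[1])
    phi_ce2 <- atan2(ce2[2] - c5[2], ce2[1] - c5[1])
    # walk CD2 -> CG -> CD1 -> NE1 -> CE2 with the 72-degree step whose
    # fourth application lands on CE2
    step <- 72 * pi / 180
    ok <- function(s) {
      d <- (phi_cd2 + 4 * s * step - phi_ce2) %% (2 * pi)
      min(d, 2 * pi - d) < 1e-6
    }
    s <- if (ok(1)) 1 else -1
    other <- data.frame(
      atom_name = c("CG", "CD1", "NE1"),
      x = c5[1] + r5 * cos(phi_cd2 + s * step * 1:3),
      y = c5[2] + r5 * sin(phi_cd2 + s * step * 1:3),
      ring_id = "five", stringsAsFactors = FALSE)
    mem5 <- rbind(mem6[mem6$atom_name %in% c("CD2", "CE2"),
                       c("atom_name", "x", "y")],
                  other[, c("atom_name", "x", "y")])
    mem5$ring_id <- "five"
    members <- rbind(mem6, other)
    pro6 <- radial_proton(mem6, list(HE3 = "CE3", HZ2 = "CZ2",
                                     HZ3 = "CZ3", HH2 = "CH2"), c(0, 0))
    pro5 <- radial_proton(mem5, list(HD1 = "CD1", HE1 = "NE1"), c5)
    return(list(members = members, protons = rbind(pro6, pro5),
                centers = data.frame(ring_id = c("six", "five"),
                                     x = c(0, c5[1]), y = c(0, c5[2]))))
  }
  NULL
}

.nonaromatic_pool <- c("ALA", "GLY", "SER", "LEU", "VAL", "THR", "LYS",
                       "ASP", "GLU", "ARG", "ASN", "GLN", "ILE", "MET")
.aromatic_pool <- c("PHE", "TYR", "TRP", "HIS")

#' Generate one synthetic coordinate ensemble
#'
#' Residues are placed on a coarse 3D grid (5 Angstrom spacing) — not a
#' physically realistic polymer — with backbone N, H (amide proton, absent
#' on the first residue), CA and HA sites, and, for aromatic residues, a
#' geometrically exact planar ring at a randomised orientation and offset
#' (bond lengths 1.39 Angstrom, TRP as a fused planar indole). Models
#' differ by small Gaussian jitter (SD 0.05 Angstrom) of all non-ring-member
#' atoms; ring member atoms are shared across models so planarity holds in
#' every model.
#'
#' @param config a [synthetic_config()].
#' @param entry_index 1-based entry index (decorrelates entries).
#' @return An `ensemble` with an extra `ring_anchors` field (data frame
#'   `chain_id`, `seq_id`, `ring_id`, `x`, `y`, `z`: the exact center of
#'   each planted ring).
#' @export
generate_structure <- function(config, entry_index = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed((config$seed * 104729 + entry_index * 7919) %% 2147483647L)
  L <- config$chain_length
  grid <- function(i) 5 * c((i - 1) %% 4, ((i - 1) %/% 4) %% 4, (i - 1) %/% 16)

  n_arom <- round(config$aromatic_fraction * L)
  arom_pos <- if (n_arom > 0) sort(sample(seq_len(L), n_arom)) else integer(0)
  types <- sample(.nonaromatic_pool, L, replace = TRUE)
  types[arom_pos] <- sample(.aromatic_pool, length(arom_pos), replace = TRUE)

  base <- vector("list", L)
  anchors <- vector("list", L)
  ring_flag <- vector("list", L)
  for (i in seq_len(L)) {
    p <- grid(i)
    at <- data.frame(atom_name = c("N", "CA", "HA"),
                     x = p[1] + c(0, 1.45, 1.45),
                     y = p[2] + c(0, 0, 1.10),
                     z = p[3] + c(0, 0, 0), stringsAsFactors = FALSE)
    if (i > 1) {
      uh <- unit_vector(stats::rnorm(3), "amide H direction")
      at <- rbind(at, data.frame(atom_name = "H", x = p[1] + uh[1],
                                 y = p[2] + uh[2], z = p[3] + uh[3]))
    }
    is_ring <- rep(FALSE, nrow(at))
    if (types[i] %in% .aromatic_pool) {
      tpl <- ring_template(types[i])
      u <- unit_vector(stats::rnorm(3), "ring offset")
      ctr <- p + u * stats::runif(1, 2.5, 4.0)
      R <- random_rotation()
      embed <- function(df) {
        xyz <- t(R %*% rbind(df$x, df$y, 0))
        data.frame(atom_name = df$atom_name, x = ctr[1] + xyz[, 1],
                   y = ctr[2] + xyz[, 2], z = ctr[3] + xyz[, 3],
                   stringsAsFactors = FALSE)
      }
      memb <- embed(unique(tpl$members[, c("atom_name", "x", "y")]))
      prot <- embed(tpl$protons[, c("atom_name", "x", "y")])
      cen <- embed(data.frame(atom_name = tpl$centers$ring_id,
                              x = tpl$centers$x, y = tpl$centers$y))
      at <- rbind(at, memb, prot)
      is_ring <- c(is_ring, rep(TRUE, nrow(memb)), rep(FALSE, nrow(prot)))
      anchors[[i]] <- data.frame(chain_id = "A", seq_id = i,
                                 ring_id = cen$atom_name, x = cen$x,
                                 y = cen$y, z = cen$z,
                                 stringsAsFactors = FALSE)
    }
    at$seq_id <- i
    at$residue_type <- types[i]
    base[[i]] <- at
    ring_flag[[i]] <- is_ring
  }
  base <- do.call(rbind, base)
  is_ring <- unlist(ring_flag)

  models <- lapply(seq_len(config$n_models), function(m) {
    a <- base
    jit <- matrix(stats::rnorm(3 * nrow(a), sd = 0.05), ncol = 3)
    jit[is_ring, ] <- 0
    a$x <- a$x + jit[, 1]; a$y <- a$y + jit[, 2]; a$z <- a$z + jit[, 3]
    a$model <- m
    a
  })
  atoms <- do.call(rbind, models)
  atoms$chain_id <- "A"
  atoms$polymer <- TRUE
  e <- ensemble(sprintf("SYN%04d", entry_index), atoms)
  e$ring_anchors <- do.call(rbind, anchors[!vapply(anchors, is.null, TRUE)])
  e
}

#' Plant amide shifts with ring-current perturbations
#'
#' Every amide proton's shift is its reference mean plus Gaussian noise
#' (`noise_sd_scale` times the reference SD) plus a perturbation from the
#' nearest ring within `effect_radius` (0 when none). In the default
#' (formula) mode the perturbation is the per-model point-dipole shift
#' [ring_current_delta()] averaged over models; in calibrated mode (see
#' [synthetic_config()]) qualifying amides get exactly
#' `calibrate_target_z` reference SDs with the ring-type-appropriate sign.
#'
#' @param ens an `ensemble` from [generate_structure()].
#' @param stats reference statistics with the amide `H` class for every
#'   residue type present (see [default_reference_stats()]).
#' @param config a [synthetic_config()].
#' @param seed RNG seed for the noise (defaults to `config$seed`).
#' @return List with `shifts` (chemical-shift data frame) and
#'   `ground_truth` (one row per amide: perturbation, true nearest ring,
#'   averaged distance/azimuth; per-model distances and azimuths in the
#'   `"per_model"` attribute).
#' @export
plant_shifts <- function(ens, stats, config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed((seed * 2654435761 + sum(utf8ToInt(ens$entry_id))) %% 2147483647)
  atoms <- ens$atoms
  amides <- unique(atoms[atoms$atom_name == "H" & atoms$polymer,
                         c("chain_id", "seq_id", "residue_type")])
  amides <- amides[order(amides$chain_id, amides$seq_id), , drop = FALSE]
  rings <- ring_instances(ens)
  cal <- !is.null(config$calibrate_target_z)

  n <- nrow(amides)
  shift_val <- numeric(n); perturb <- numeric(n)
  ring_type <- rep(NA_character_, n); ring_id <- rep(NA_character_, n)
  ring_seq <- rep(NA_integer_, n)
  avg_d <- rep(NA_real_, n); avg_a <- rep(NA_real_, n)
  calibrated <- rep(FALSE, n)
  per_model <- vector("list", n)

  for (i in seq_len(n)) {
    a <- amides[i, ]
    st <- stat_lookup(stats, a$residue_type, "H")
    if (is.null(st))
      stopf("residue type %s has no amide H reference statistic", a$residue_type)
    nr <- nearest_ring(a, ens, rings, max_distance = config$effect_radius)
    delta <- 0
    if (!is.null(nr)) {
      pm <- attr(nr, "per_model")
      ring_type[i] <- nr$ring_type; ring_id[i] <- nr$ring_id
      ring_seq[i] <- nr$ring_seq
      avg_d[i] <- nr$avg_distance; avg_a[i] <- nr$avg_azimuth
      per_model[[i]] <- cbind(chain_id = a$chain_id, seq_id = a$seq_id, pm)
      if (config$effect_amplitude_B != 0) {
        inten <- config$ring_intensity[[paste0(nr$ring_type, ":", nr$ring_id)]] %||% 1
        delta <- mean(ring_current_delta(pm$distance, pm$azimuth, inten,
                                         config$effect_amplitude_B))
      }
      if (cal) {
        tz <- config$calibrate_target_z
        on_axis <- nr$avg_azimuth <= config$calibrate_theta_max
        in_plane <- nr$avg_azimuth >= 90 - config$calibrate_theta_max
        close <- nr$avg_distance <= config$calibrate_r_max
        if (close && nr$ring_type %in% c("PHE", "TYR", "TRP") && on_axis) {
          delta <- -tz * st$sd; calibrated[i] <- TRUE
        } else if (close && nr$ring_type == "HIS" && in_plane) {
          delta <- tz * st$sd; calibrated[i] <- TRUE
        }
      }
    }
    perturb[i] <- delta
    shift_val[i] <- st$mean + delta +
      stats::rnorm(1, 0, config$noise_sd_scale * st$sd)
  }
  shifts <- data.frame(
    entry_id = ens$entry_id, chain_id = amides$chain_id,
    seq_id = amides$seq_id, residue_type = amides$residue_type,
    atom_name = "H", value = shift_val, ambiguity_code = 1L,
    stringsAsFactors = FALSE)
  gt <- data.frame(
    entry_id = ens$entry_id, chain_id = amides$chain_id,
    seq_id = amides$seq_id, residue_type = amides$residue_type,
    perturbation = perturb, calibrated = calibrated,
    ring_type = ring_type, ring_id = ring_id,
    ring_seq = ring_seq, avg_distance = avg_d, avg_azimuth = avg_a,
    stringsAsFactors = FALSE)
  attr(gt, "per_model") <- do.call(rbind,
                                   per_model[!vapply(per_model, is.null, TRUE)])
  list(shifts = shifts, ground_truth = gt)
}


#' Generate distance restraints for a synthetic ensemble
#'
#' Emits one restraint per (amide proton, aromatic ring proton) pair whose
#' model-averaged distance is at or below the cutoff, plus decoy restraints
#' between non-amide, non-aromatic proton pairs (HA-HA) so that restraint
#' classification is exercised on negatives. Decoys make up
#' `decoy_fraction` of the emitted set when enough close pairs exist.
#'
#' @param ens an `ensemble`.
#' @param cutoff Angstrom, on the model-averaged proton-proton distance.
#' @param seed RNG seed for decoy sampling.
#' @param decoy_fraction target fraction of decoys among emitted restraints.
#' @return Restraint data frame (see [read_restraints()]).
#' @export
generate_restraints <- function(ens, cutoff, seed = 1, decoy_fraction = 0.2) {
  set.seed((seed * 7129 + sum(utf8ToInt(ens$entry_id))) %% 2147483647)
  atoms <- ens$atoms
  defs <- ring_definitions()
  ring_key <- unlist(lapply(seq_len(nrow(defs)), function(i)
    paste0(defs$residue_type[i], ":", defs$protons[[i]])))

  # one coordinate matrix per model, rows aligned on the shared atom roster
  all_key <- paste(atoms$chain_id, atoms$seq_id, atoms$atom_name, sep = "\r")
  ukeys <- unique(all_key)
  meta_i <- match(ukeys, all_key)
  models <- sort(unique(atoms$model))
  coords <- lapply(models, function(m) {
    idx <- which(atoms$model == m)
    out <- matrix(NA_real_, length(ukeys), 3)
    out[match(all_key[idx], ukeys), ] <-
      cbind(atoms$x[idx], atoms$y[idx], atoms$z[idx])
    out
  })
  # model-averaged cross-distance matrix between two roster index sets
  avg_dist <- function(ia, ib) {
    D <- matrix(0, length(ia), length(ib))
    for (cm in coords) {
      D <- D + sqrt(outer(cm[ia, 1], cm[ib, 1], "-")^2 +
                      outer(cm[ia, 2], cm[ib, 2], "-")^2 +
                      outer(cm[ia, 3], cm[ib, 3], "-")^2)
    }
    D / length(coords)
  }
  pair_rows <- function(ia, ib) {
    if (length(ia) == 0 || length(ib) == 0) return(NULL)
    D <- avg_dist(ia, ib)
    hit <- which(D <= cutoff & outer(ia, ib, "!="), arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    i <- meta_i[ia[hit[, 1]]]; j <- meta_i[ib[hit[, 2]]]
    data.frame(
      chain_id_1 = atoms$chain_id[i], seq_id_1 = atoms$seq_id[i],
      residue_type_1 = atoms$residue_type[i],
      atom_name_1 = atoms$atom_name[i],
      chain_id_2 = atoms$chain_id[j], seq_id_2 = atoms$seq_id[j],
      residue_type_2 = atoms$residue_type[j],
      atom_name_2 = atoms$atom_name[j],
      upper_bound = cutoff, stringsAsFactors = FALSE)
  }
  akey <- paste0(atoms$residue_type[meta_i], ":", atoms$atom_name[meta_i])
  poly <- atoms$polymer[meta_i]
  amide_idx <- which(atoms$atom_name[meta_i] == "H" & poly)
  ringp_idx <- which(akey %in% ring_key & poly)
  ha_idx <- which(atoms$atom_name[meta_i] == "HA" & poly)

  aa <- pair_rows(amide_idx, ringp_idx)
  n_aa <- if (is.null(aa)) 0L else nrow(aa)

  decoys <- NULL
  if (decoy_fraction > 0 && length(ha_idx) >= 2 && n_aa > 0) {
    cand <- pair_rows(ha_idx, ha_idx)
    if (!is.null(cand)) {
      # drop mirrored duplicates (i-j and j-i)
      k <- paste(pmin(cand$seq_id_1, cand$seq_id_2),
                 pmax(cand$seq_id_1, cand$seq_id_2))
      cand <- cand[!duplicated(k), , drop = FALSE]
      n_decoy <- min(nrow(cand),
                     round(n_aa * decoy_fraction / (1 - decoy_fraction)))
      if (n_decoy > 0)
        decoys <- cand[sample(nrow(cand), n_decoy), , drop = FALSE]
    }
  }
  out <- rbind(aa, decoys)
  if (is.null(out))
    out <- data.frame(chain_id_1 = character(), seq_id_1 = integer(),
                      residue_type_1 = character(), atom_name_1 = character(),
                      chain_id_2 = character(), seq_id_2 = integer(),
                      residue_type_2 = character(), atom_name_2 = character(),
                      upper_bound = numeric(), stringsAsFactors = FALSE)
  out <- cbind(restraint_id = as.character(seq_len(nrow(out))),
               entry_id = rep(ens$entry_id, nrow(out)), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a complete synthetic fixture corpus
#'
#' Generates `n_entries` entry pairs and writes the corpus directory
#' layout consumed by [run_pipeline()]:
#' `shifts/<shift_id>.str` (NMR-STAR), `restraints/<structure_id>.str`,
#' `structures/<structure_id>.cif` (multi-model mmCIF), `mapping.json`,
#' `reference_stats.tsv` (the statistics used for planting) and the
#' ground-truth sidecars `ground_truth.tsv` / `ground_truth_models.tsv`.
#' All files round-trip losslessly through the package readers at the
#' written precision (3 decimals).
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @param stats reference statistics used for planting.
#' @return `out_dir`, invisibly; ground truth is also returned in the
#'   `"ground_truth"` attribute.
#' @export
write_fixture_corpus <- function(config, out_dir,
                                 stats = default_reference_stats()) {
  stopifnot(inherits(config, "synthetic_config"))
  for (d in c("", "shifts", "restraints", "structures"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE, recursive = TRUE)
  pairs <- data.frame(
    shift_id = sprintf("BMR%04d", seq_len(config$n_entries)),
    structure_id = sprintf("PDB%04d", seq_len(config$n_entries)),
    stringsAsFactors = FALSE)
  gt_all <- vector("list", config$n_entries)
  gtm_all <- vector("list", config$n_entries)
  for (i in seq_len(config$n_entries)) {
    ens <- generate_structure(config, i)
    ens$entry_id <- pairs$structure_id[i]
    planted <- plant_shifts(ens, stats, config,
                            seed = (config$seed * 1009 + i * 3571) %% 2147483647)
    shifts <- planted$shifts
    shifts$entry_id <- pairs$shift_id[i]
    restr <- generate_restraints(ens, config$restraint_cutoff,
                                 seed = config$seed + i,
                                 decoy_fraction = config$decoy_fraction)
    write_shift_records(shifts,
                        file.path(out_dir, "shifts",
                                  paste0(pairs$shift_id[i], ".str")))
    write_restraints(restr,
                     file.path(out_dir, "restraints",
                               paste0(pairs$structure_id[i], ".str")))
    write_ensemble(ens,
                   file.path(out_dir, "structures",
                             paste0(pairs$structure_id[i], ".cif")))
    gt <- planted$ground_truth
    gt$entry_id <- pairs$shift_id[i]
    gt_all[[i]] <- gt
    pm <- attr(planted$ground_truth, "per_model")
    if (!is.null(pm)) {
      pm <- cbind(entry_id = pairs$shift_id[i], pm)
      gtm_all[[i]] <- pm
    }
  }
  jsonlite::write_json(pairs, file.path(out_dir, "mapping.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write_reference_stats(stats, file.path(out_dir, "reference_stats.tsv"))
  gt <- do.call(rbind, gt_all)
  utils::write.table(gt, file.path(out_dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gtm <- do.call(rbind, gtm_all[!vapply(gtm_all, is.null, TRUE)])
  if (!is.null(gtm))
    utils::write.table(gtm, file.path(out_dir, "ground_truth_models.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  out <- invisible(out_dir)
  attr(out, "ground_truth") <- gt
  out
}
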