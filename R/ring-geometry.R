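#' Aromatic ring definitions for the standard amino acids
#'
#' Ring member atoms and ring-bonded protons for the four aromatic residue
#' types considered in the nearest-ring search. Tryptophan contributes two
#' independent rings (the six- and five-membered cycles of the indole),
#' which compete separately in the nearest-ring search. Ring protons
#' include the nitrogen-bound HD1/HE2 (HIS) and HE1 (TRP) by default; see
#' [classify_restraint()] for the carbon-only switch.
#'
#' @return A data frame with one row per (residue type, ring), columns
#'   `residue_type`, `ring_id`, `members` (list of ordered member atom
#'   names), `protons` (list of ring proton names).
#' @export
#' @examples
#' ring_definitions()
ring_definitions <- function() {
  data.frame(
    residue_type = c("PHE", "TYR", "HIS", "TRP", "TRP"),
    ring_id = c("six", "six", "five", "six", "five"),
    members = I(list(
      c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
      c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
      c("CG", "ND1", "CD2", "CE1", "NE2"),
      c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
      c("CG", "CD1", "NE1", "CE2", "CD2")
    )),
    protons = I(list(
      c("HD1", "HD2", "HE1", "HE2", "HZ"),
      c("HD1", "HD2", "HE1", "HE2"),
      c("HD1", "HD2", "HE1", "HE2"),
      c("HE3", "HZ2", "HZ3", "HH2"),
      c("HD1", "HE1")
    )),
    stringsAsFactors = FALSE
  )
}

# ring protons that are nitrogen-bound (excluded under carbon_only)
.nitrogen_ring_protons <- c("HIS:HD1", "HIS:HE2", "TRP:HE1")

#' Centroid of ring member coordinates
#'
#' @param member_coords numeric matrix, one row per ring member atom,
#'   columns x, y, z (Angstrom). All members must be present.
#' @return Numeric length-3 centroid.
#' @export
ring_center <- function(member_coords) {
  member_coords <- as.matrix(member_coords)
  if (nrow(member_coords) < 3 || any(!is.finite(member_coords)))
    stopf("ring center needs >= 3 finite member coordinates")
  colMeans(member_coords)
}

#' Unit normal of a ring plane
#'
#' Cross product of the vectors from the centroid to the first and second
#' member atoms (in the defined member order), normalised. For non-planar
#' rings this approximates the plane normal; the sign is arbitrary and is
#' removed downstream by folding the azimuth to \[0, 90\] degrees.
#'
#' @inheritParams ring_center
#' @return Unit length-3 normal vector.
#' @export
ring_normal <- function(member_coords) {
  ctr <- ring_center(member_coords)
  v1 <- as.numeric(member_coords[1, ]) - ctr
  v2 <- as.numeric(member_coords[2, ]) - ctr
  n <- cross3(v1, v2)
  if (sqrt(sum(n^2)) < 1e-9)
    stopf("degenerate ring: first two member vectors are colinear")
  unit_vector(n, "ring normal")
}

#' Euclidean distance from a proton to a ring center
#'
#' @param proton,center numeric length-3 points (Angstrom).
#' @return Distance in Angstrom.
#' @export
proton_ring_distance <- function(proton, center) {
  sqrt(sum((as.numeric(proton) - as.numeric(center))^2))
}

#' Azimuth angle between ring normal and proton direction
#'
#' Angle between the ring-plane normal and the vector from the ring center
#' to the proton, folded to \[0, 90\] degrees because the normal's sign
#' depends on the (unspecified) cross-product operand order. 0 degrees is
#' on the ring axis, 90 degrees in the ring plane.
#'
#' @param proton numeric length-3 proton position.
#' @param center numeric length-3 ring center.
#' @param normal numeric length-3 ring normal (need not be unit length).
#' @return Angle in degrees in \[0, 90\].
#' @export
azimuth <- function(proton, center, normal) {
  v <- as.numeric(proton) - as.numeric(center)
  if (sqrt(sum(v^2)) < 1e-9)
    stopf("undefined azimuth: proton coincides with ring center")
  v <- unit_vector(v, "proton-center vector")
  n <- unit_vector(as.numeric(normal), "ring normal")
  cosang <- min(1, max(-1, sum(v * n)))
  ang <- acos(abs(cosang)) * 180 / pi   # fold to [0, 90]
  ang
}

#' Enumerate ring instances in an ensemble
#'
#' Builds per-model ring geometry (center and unit normal) for every
#' aromatic residue in the polymer part of the ensemble. A ring is defined
#' in a model only when all member atoms are present there; incomplete
#' rings are skipped in that model.
#'
#' @param ensemble an `ensemble` object (see [read_ensemble()]).
#' @return Data frame with columns `chain_id`, `seq_id`, `residue_type`,
#'   `ring_id`, `model`, `cx`, `cy`, `cz`, `nx`, `ny`, `nz`.
#' @export
ring_instances <- function(ensemble) {
  atoms <- ensemble$atoms
  atoms <- atoms[atoms$polymer, , drop = FALSE]
  defs <- ring_definitions()
  out <- vector("list", 64L)
  k <- 0L
  arom <- unique(atoms[atoms$residue_type %in% defs$residue_type,
                       c("chain_id", "seq_id", "residue_type")])
  if (nrow(arom) == 0)
    return(data.frame(chain_id = character(), seq_id = integer(),
                      residue_type = character(), ring_id = character(),
                      model = integer(), cx = numeric(), cy = numeric(),
                      cz = numeric(), nx = numeric(), ny = numeric(),
                      nz = numeric(), stringsAsFactors = FALSE))
  for (i in seq_len(nrow(arom))) {
    res <- arom[i, ]
    rdefs <- defs[defs$residue_type == res$residue_type, , drop = FALSE]
    ratoms <- atoms[atoms$chain_id == res$chain_id &
                      atoms$seq_id == res$seq_id, , drop = FALSE]
    for (j in seq_len(nrow(rdefs))) {
      members <- rdefs$members[[j]]
      for (m in unique(ratoms$model)) {
        matoms <- ratoms[ratoms$model == m, , drop = FALSE]
        idx <- match(members, matoms$atom_name)
        if (anyNA(idx)) next   # incomplete ring in this model
        coords <- as.matrix(matoms[idx, c("x", "y", "z")])
        ctr <- ring_center(coords)
        nrm <- ring_normal(coords)
        k <- k + 1L
        out[[k]] <- data.frame(
          chain_id = res$chain_id, seq_id = res$seq_id,
          residue_type = res$residue_type, ring_id = rdefs$ring_id[j],
          model = m, cx = ctr[1], cy = ctr[2], cz = ctr[3],
          nx = nrm[1], ny = nrm[2], nz = nrm[3],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Nearest aromatic ring for an amide proton, ensemble-averaged
#'
#' For each candidate ring the proton-to-ring-center distance is averaged
#' over the ensemble models in which both the proton and the complete ring
#' are defined; the ring minimising this averaged distance is returned,
#' together with the mean per-model azimuth for that ring. Selection
#' operates on the ensemble average (not per-model nearest) because the
#' distance of record is itself the ensemble average. Ties below 1e-6
#' Angstrom resolve to the lexicographically smallest
#' (chain, seq_id, ring_id).
#'
#' @param amide list or one-row data frame with `chain_id`, `seq_id`; the
#'   amide proton atom name is taken as `"H"`.
#' @param ensemble an `ensemble` object.
#' @param rings ring instance table from [ring_instances()]; computed from
#'   the ensemble when `NULL`.
#' @param max_distance optional cutoff (Angstrom); rings with averaged
#'   distance above it are not returned. `Inf` disables the cutoff.
#' @return A one-row data frame with `chain_id`, `seq_id`, `ring_chain`,
#'   `ring_seq`, `ring_type`, `ring_id`, `avg_distance`, `avg_azimuth`,
#'   `n_models`, or `NULL` when no candidate ring exists.
#' @export
nearest_ring <- function(amide, ensemble, rings = NULL,
                         max_distance = Inf) {
  if (is.null(rings)) rings <- ring_instances(ensemble)
  if (is.null(rings) || nrow(rings) == 0) return(NULL)
  atoms <- ensemble$atoms
  h <- atoms[atoms$chain_id == amide$chain_id &
               atoms$seq_id == amide$seq_id &
               atoms$atom_name == "H", , drop = FALSE]
  if (nrow(h) == 0) return(NULL)

  im <- match(rings$model, h$model)
  ok <- !is.na(im)
  if (!any(ok)) return(NULL)
  rk <- rings[ok, , drop = FALSE]
  hx <- h$x[im[ok]]; hy <- h$y[im[ok]]; hz <- h$z[im[ok]]
  vx <- hx - rk$cx; vy <- hy - rk$cy; vz <- hz - rk$cz
  d <- sqrt(vx^2 + vy^2 + vz^2)
  if (any(d < 1e-9))
    stopf("undefined azimuth: proton coincides with ring center")
  cosang <- abs((vx * rk$nx + vy * rk$ny + vz * rk$nz) / d)
  az <- acos(pmin(1, cosang)) * 180 / pi

  key <- paste(rk$chain_id, sprintf("%09d", rk$seq_id), rk$ring_id)
  ukey <- sort(unique(key))
  gi <- match(key, ukey)
  cnt <- tabulate(gi, length(ukey))
  avg_d <- as.numeric(rowsum(d, gi)) / cnt
  avg_a <- as.numeric(rowsum(az, gi)) / cnt
  # minimum averaged distance; ties (<1e-6) resolve to the smallest
  # (chain, seq, ring_id), which is ukey's sort order
  cand <- which(avg_d <= min(avg_d) + 1e-6)
  bi <- cand[1]
  if (avg_d[bi] > max_distance) return(NULL)
  sel <- gi == bi
  first <- which(sel)[1]
  best <- data.frame(
    chain_id = amide$chain_id, seq_id = amide$seq_id,
    ring_chain = rk$chain_id[first], ring_seq = rk$seq_id[first],
    ring_type = rk$residue_type[first], ring_id = rk$ring_id[first],
    avg_distance = avg_d[bi], avg_azimuth = avg_a[bi],
    n_models = cnt[bi], stringsAsFactors = FALSE)
  attr(best, "per_model") <- data.frame(model = rk$model[sel],
                                        distance = d[sel], azimuth = az[sel])
  best
}
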