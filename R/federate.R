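#' Load the shift-entry / structure-entry mapping
#'
#' Parses a JSON array of `{shift_id, structure_id}` objects (the local
#' stand-in for the archive's entry-pair mapping list). Duplicate pairs
#' are collapsed with a warning; pairs with an empty id are rejected with
#' a reason.
#'
#' @param path JSON mapping file.
#' @return Data frame with columns `shift_entry_id`, `structure_entry_id`.
#' @export
load_entry_pairs <- function(path) {
  if (!file.exists(path)) stopf("mapping file not found: %s", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                  error = function(e) stopf("malformed mapping file %s: %s",
                                            path, conditionMessage(e)))
  if (length(raw) == 0) {
    warnf("mapping file %s contains no pairs", path)
    return(data.frame(shift_entry_id = character(),
                      structure_entry_id = character(),
                      stringsAsFactors = FALSE))
  }
  if (!is.data.frame(raw) || !all(c("shift_id", "structure_id") %in% names(raw)))
    stopf("malformed mapping file %s: expected objects with shift_id and structure_id",
          path)
  out <- data.frame(shift_entry_id = as.character(raw$shift_id),
                    structure_entry_id = as.character(raw$structure_id),
                    stringsAsFactors = FALSE)
  bad <- is.na(out$shift_entry_id) | !nzchar(out$shift_entry_id) |
    is.na(out$structure_entry_id) | !nzchar(out$structure_entry_id)
  if (any(bad)) {
    warnf("%d pair(s) rejected: empty shift or structure id", sum(bad))
    out <- out[!bad, , drop = FALSE]
  }
  dup <- duplicated(paste(out$shift_entry_id, out$structure_entry_id))
  if (any(dup)) {
    warnf("%d duplicated pair(s) collapsed", sum(dup))
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Classify restraints as amide-aromatic
#'
#' `TRUE` iff one member is a backbone amide proton (canonical atom name
#' `H`) and the other is an aromatic ring proton of PHE/TYR/TRP/HIS per
#' [ring_definitions()], in either member order. Nitrogen-bound ring
#' protons (HIS HD1/HE2, TRP HE1) count as ring protons by default; set
#' `carbon_only = TRUE` to restrict to carbon-bound ring protons.
#'
#' @param restraints restraint data frame (see [read_restraints()]).
#' @param ring_defs ring definition table, by default [ring_definitions()].
#' @param carbon_only exclude nitrogen-bound ring protons.
#' @return Logical vector, one element per restraint row.
#' @export
classify_restraint <- function(restraints, ring_defs = ring_definitions(),
                               carbon_only = FALSE) {
  if (nrow(restraints) == 0) return(logical(0))
  ring_key <- unlist(lapply(seq_len(nrow(ring_defs)), function(i)
    paste0(ring_defs$residue_type[i], ":", ring_defs$protons[[i]])))
  if (carbon_only) ring_key <- setdiff(ring_key, .nitrogen_ring_protons)
  is_amide_1 <- restraints$atom_name_1 == "H"
  is_amide_2 <- restraints$atom_name_2 == "H"
  is_ring_1 <- paste0(restraints$residue_type_1, ":",
                      restraints$atom_name_1) %in% ring_key
  is_ring_2 <- paste0(restraints$residue_type_2, ":",
                      restraints$atom_name_2) %in% ring_key
  (is_amide_1 & is_ring_2) | (is_amide_2 & is_ring_1)
}

#' Federate shifts, coordinates and restraints for one entry pair
#'
#' Produces one merged record per amide proton that has both a reported
#' shift and a coordinate in at least one model, keyed by the atom
#' identifiers (chain id, sequence id, residue, atom). Each record carries
#' the shift, its Z-score and Z-bin against the supplied reference
#' statistics, the nearest aromatic ring with ensemble-averaged distance
#' and azimuth (absent when the structure has no ring), and the count of
#' amide-aromatic restraints attached to the amide by (chain, seq) of its
#' amide member. Amides with a shift but no coordinates (or vice versa)
#' are counted in the accounting report, not merged; amides whose residue
#' type has no reference statistic are skipped with a reason.
#'
#' @param pair one-row data frame with `shift_entry_id`,
#'   `structure_entry_id`.
#' @param shifts chemical-shift data frame for the shift entry.
#' @param ens `ensemble` for the structure entry.
#' @param restraints restraint data frame for the structure entry.
#' @param stats reference statistics used for Z-scoring.
#' @param carbon_only_ring_protons see [classify_restraint()].
#' @return List with `merged` (data frame) and `report` (one-row
#'   accounting data frame: `n_candidates = n_merged + n_shift_only +
#'   n_coord_only + n_skipped`, plus `n_aromatic_restraints`).
#' @export
merge_entry <- function(pair, shifts, ens, restraints, stats,
                        carbon_only_ring_protons = FALSE) {
  sh <- shifts[shifts$atom_name == "H", , drop = FALSE]
  atoms <- ens$atoms
  coord_amides <- unique(atoms[atoms$atom_name == "H" & atoms$polymer,
                               c("chain_id", "seq_id")])
  skey <- paste(sh$chain_id, sh$seq_id, sep = "\r")
  ckey <- paste(coord_amides$chain_id, coord_amides$seq_id, sep = "\r")

  is_aromatic <- classify_restraint(restraints,
                                    carbon_only = carbon_only_ring_protons)
  ar <- restraints[is_aromatic, , drop = FALSE]
  # (chain, seq) key of the amide member of each amide-aromatic restraint
  amide_member_key <- ifelse(ar$atom_name_1 == "H",
                             paste(ar$chain_id_1, ar$seq_id_1, sep = "\r"),
                             paste(ar$chain_id_2, ar$seq_id_2, sep = "\r"))
  entry_eligible <- nrow(ar) > 0

  rings <- ring_instances(ens)
  both <- skey %in% ckey
  n_shift_only <- sum(!both)
  n_coord_only <- sum(!(ckey %in% skey))
  merged <- vector("list", sum(both))
  skipped <- 0L
  k <- 0L
  for (i in which(both)) {
    st <- stat_lookup(stats, sh$residue_type[i], "H")
    if (is.null(st) || st$sd <= 0) {
      skipped <- skipped + 1L
      next
    }
    z <- z_score(sh$value[i], st)
    nr <- nearest_ring(list(chain_id = sh$chain_id[i], seq_id = sh$seq_id[i]),
                       ens, rings)
    nres <- sum(amide_member_key == skey[i])
    k <- k + 1L
    merged[[k]] <- data.frame(
      shift_entry_id = pair$shift_entry_id,
      structure_entry_id = pair$structure_entry_id,
      chain_id = sh$chain_id[i], seq_id = sh$seq_id[i],
      residue_type = sh$residue_type[i], value = sh$value[i],
      z = z, z_bin = z_bin(z),
      ring_type = if (is.null(nr)) NA_character_ else nr$ring_type,
      ring_chain = if (is.null(nr)) NA_character_ else nr$ring_chain,
      ring_seq = if (is.null(nr)) NA_integer_ else nr$ring_seq,
      ring_id = if (is.null(nr)) NA_character_ else nr$ring_id,
      avg_distance = if (is.null(nr)) NA_real_ else nr$avg_distance,
      avg_azimuth = if (is.null(nr)) NA_real_ else nr$avg_azimuth,
      restrained = nres >= 1, n_restraints = nres,
      entry_eligible = entry_eligible,
      stringsAsFactors = FALSE)
  }
  merged <- if (k > 0) do.call(rbind, merged[seq_len(k)])
  else data.frame(shift_entry_id = character(), structure_entry_id = character(),
                  chain_id = character(), seq_id = integer(),
                  residue_type = character(), value = numeric(), z = numeric(),
                  z_bin = integer(), ring_type = character(),
                  ring_chain = character(), ring_seq = integer(),
                  ring_id = character(), avg_distance = numeric(),
                  avg_azimuth = numeric(), restrained = logical(),
                  n_restraints = integer(), entry_eligible = logical(),
                  stringsAsFactors = FALSE)
  report <- data.frame(
    shift_entry_id = pair$shift_entry_id,
    structure_entry_id = pair$structure_entry_id,
    n_candidates = length(unique(c(skey, ckey))),
    n_merged = k, n_shift_only = n_shift_only,
    n_coord_only = n_coord_only, n_skipped = skipped,
    n_aromatic_restraints = nrow(ar), status = "ok",
    stringsAsFactors = FALSE)
  list(merged = merged, report = report)
}
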