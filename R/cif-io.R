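#' Construct a coordinate ensemble
#'
#' Container for a multi-model structure: an atom table keyed by
#' (model, chain, sequence, residue, atom) with Cartesian coordinates in
#' Angstrom and a polymer flag (waters/ligands are loaded but excluded
#' from the ring search). Models are required to share one atom roster;
#' when they do not, the roster is intersected with a warning.
#'
#' @param entry_id structure entry identifier.
#' @param atoms data frame with columns `model`, `chain_id`, `seq_id`,
#'   `residue_type`, `atom_name`, `x`, `y`, `z` and optionally `polymer`.
#' @return An object of class `ensemble`: a list with `entry_id`, `atoms`.
#' @export
ensemble <- function(entry_id, atoms) {
  assert_columns(atoms, c("model", "chain_id", "seq_id", "residue_type",
                          "atom_name", "x", "y", "z"), "atom table")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stopf("non-finite coordinates in entry %s", entry_id)
  if (is.null(atoms$polymer)) atoms$polymer <- TRUE
  atoms$model <- as.integer(atoms$model)
  atoms$seq_id <- as.integer(atoms$seq_id)
  key <- paste(atoms$chain_id, atoms$seq_id, atoms$residue_type,
               atoms$atom_name, sep = "\r")
  models <- sort(unique(atoms$model))
  if (length(models) > 1) {
    per_model <- split(key, atoms$model)
    common <- Reduce(intersect, per_model)
    if (any(lengths(per_model) != length(common))) {
      warnf("entry %s: atom roster differs across models; intersecting",
            entry_id)
      atoms <- atoms[key %in% common, , drop = FALSE]
    }
  }
  atoms <- atoms[order(atoms$model, atoms$chain_id, atoms$seq_id,
                       atoms$atom_name), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(entry_id = entry_id, atoms = atoms), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble %s: %d model(s), %d atoms/model, %d chain(s)>\n",
              x$entry_id, length(unique(x$atoms$model)),
              nrow(x$atoms) / max(1, length(unique(x$atoms$model))),
              length(unique(x$atoms$chain_id))))
  invisible(x)
}

#' Read a multi-model ensemble from an mmCIF file
#'
#' Loads the `_atom_site` category. Chains and sequence numbers are taken
#' from the author fields when present, else the label fields; models come
#' from `pdbx_PDB_model_num` (a single-model file yields one model).
#' `HETATM` sites (waters, ligands) are loaded with `polymer = FALSE`.
#' Alternate locations keep the highest occupancy, first on ties.
#'
#' @param path mmCIF file.
#' @return An `ensemble` object.
#' @export
read_ensemble <- function(path) {
  loops <- star_read_loops(path)
  hit <- which(vapply(loops, function(l)
    any(startsWith(tolower(l$tags), "_atom_site.")), logical(1)))
  if (length(hit) == 0) stopf("no _atom_site category in %s", path)
  loop <- loops[[hit[1]]]
  v <- function(name) loop_col(loop, name, required = FALSE)
  pick <- function(a, b) if (!is.null(a) && !all(a %in% c(".", "?"))) a else b

  n <- nrow(loop$values)
  group <- v("group_PDB") %||% rep("ATOM", n)
  chain <- pick(v("auth_asym_id"), v("label_asym_id"))
  seqid <- pick(v("auth_seq_id"), v("label_seq_id"))
  comp <- pick(v("auth_comp_id"), v("label_comp_id"))
  atom <- pick(v("auth_atom_id"), v("label_atom_id"))
  model <- v("pdbx_PDB_model_num") %||% rep("1", n)
  occ <- suppressWarnings(as.numeric(v("occupancy") %||% rep("1", n)))
  occ[!is.finite(occ)] <- 1
  alt <- v("label_alt_id") %||% rep(".", n)
  if (is.null(chain) || is.null(seqid) || is.null(atom) || is.null(comp))
    stopf("%s: _atom_site lacks identifier columns", path)

  atoms <- data.frame(
    model = as.integer(model),
    chain_id = as.character(chain),
    seq_id = as.integer(seqid),
    residue_type = toupper(comp),
    atom_name = canonical_atom_name(as.character(atom)),
    x = as.numeric(v("Cartn_x")),
    y = as.numeric(v("Cartn_y")),
    z = as.numeric(v("Cartn_z")),
    polymer = toupper(group) == "ATOM",
    stringsAsFactors = FALSE
  )
  # altloc: highest occupancy wins, tie -> first occurrence
  if (any(!(alt %in% c(".", "?")))) {
    ord <- order(-occ, seq_len(n))
    atoms <- atoms[ord, , drop = FALSE]
    key <- paste(atoms$model, atoms$chain_id, atoms$seq_id,
                 atoms$atom_name, sep = "\r")
    atoms <- atoms[!duplicated(key), , drop = FALSE]
  }
  block <- loop$block %||% sub("\\.cif$", "", basename(path))
  ensemble(block, atoms)
}

#' Write an ensemble as mmCIF
#'
#' Emits a standard `_atom_site` loop with model numbers; coordinates are
#' written to 3 decimal places, so `read_ensemble(write_ensemble(e))`
#' reproduces coordinates at that precision and preserves model order.
#'
#' @param e an `ensemble` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(e, path) {
  a <- e$atoms
  a <- a[order(a$model, a$chain_id, a$seq_id, a$atom_name), , drop = FALSE]
  elem <- substr(sub("^[0-9]*", "", a$atom_name), 1, 1)
  lines <- c(
    paste0("data_", e$entry_id),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    paste(ifelse(a$polymer, "ATOM  ", "HETATM"),
          seq_len(nrow(a)), elem, a$atom_name, ".", a$residue_type,
          a$chain_id, a$seq_id,
          num_fmt(a$x, 3), num_fmt(a$y, 3), num_fmt(a$z, 3),
          "1.00", "0.00", a$seq_id, a$residue_type, a$chain_id,
          a$atom_name, a$model),
    "#"
  )
  writeLines(lines, path)
  invisible(path)
}
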