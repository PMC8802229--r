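# Minimal STAR-syntax reader/writer for the assigned-chemical-shift and
# distance-restraint loops. Scope: one matching loop per file (first wins,
# with a warning), bare or save-frame-wrapped, quoted values, '#' comments,
# ';'-delimited multiline values. Full dictionary validation is out of scope.

star_tokenize <- function(lines) {
  # fast path: no multiline values or quotes anywhere -> strip comment
  # tokens and split on whitespace (covers machine-written files)
  if (!any(grepl("[;'\"]", lines))) {
    hash <- grepl("#", lines, fixed = TRUE)
    if (any(hash)) lines[hash] <- sub("(^|[ \t])#.*$", "", lines[hash])
    toks <- unlist(strsplit(trimws(lines), "[ \t]+"), use.names = FALSE)
    return(toks[nzchar(toks)])
  }
  tokens <- character(0)
  in_semi <- FALSE
  buf <- character(0)
  tokpat <- "'[^']*'|\"[^\"]*\"|\\S+"
  for (ln in lines) {
    if (in_semi) {
      if (startsWith(ln, ";")) {
        tokens <- c(tokens, paste(buf, collapse = "\n"))
        in_semi <- FALSE
      } else buf <- c(buf, ln)
      next
    }
    if (startsWith(ln, ";")) {
      in_semi <- TRUE
      buf <- character(0)
      rest <- substring(ln, 2)
      if (nzchar(rest)) buf <- rest
      next
    }
    m <- regmatches(ln, gregexpr(tokpat, ln))[[1]]
    if (length(m) == 0) next
    cm <- which(startsWith(m, "#") & !startsWith(m, "'") & !startsWith(m, "\""))
    if (length(cm) > 0) m <- m[seq_len(cm[1] - 1L)]
    quoted <- (startsWith(m, "'") & endsWith(m, "'") & nchar(m) >= 2) |
      (startsWith(m, "\"") & endsWith(m, "\"") & nchar(m) >= 2)
    m[quoted] <- substr(m[quoted], 2, nchar(m[quoted]) - 1L)
    tokens <- c(tokens, m)
  }
  tokens
}

# parse tokens into a list of loops: each has $tags, $values (char matrix),
# plus the data-block name active when the loop was seen
star_parse_loops <- function(tokens) {
  n <- length(tokens)
  if (n == 0) return(list())
  is_data <- startsWith(tokens, "data_")
  is_tag <- startsWith(tokens, "_")
  is_kw <- is_data | startsWith(tokens, "save_") |
    tokens %in% c("loop_", "stop_")
  loop_at <- which(tokens == "loop_")
  stops <- which(is_kw | is_tag)
  data_at <- which(is_data)
  loops <- vector("list", length(loop_at))
  for (li in seq_along(loop_at)) {
    i <- loop_at[li] + 1L
    j <- i
    while (j <= n && is_tag[j]) j <- j + 1L  # tag header
    tags <- tokens[seq.int(i, length.out = j - i)]
    # values run until the next keyword or tag token
    after <- stops[stops >= j]
    vend <- if (length(after) > 0) after[1] else n + 1L
    vals <- if (vend > j) tokens[j:(vend - 1L)] else character(0)
    nt <- length(tags)
    if (nt == 0) next
    nr <- length(vals) %/% nt
    mat <- if (nr > 0) matrix(vals[seq_len(nr * nt)], ncol = nt, byrow = TRUE)
    else matrix(character(0), ncol = nt)
    colnames(mat) <- tags
    before <- data_at[data_at < loop_at[li]]
    block <- if (length(before) > 0)
      substring(tokens[before[length(before)]], 6) else NA_character_
    loops[[li]] <- list(block = block, tags = tags, values = mat)
  }
  loops[!vapply(loops, is.null, TRUE)]
}

star_read_loops <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  star_parse_loops(star_tokenize(readLines(path, warn = FALSE)))
}

# select the first loop whose tags share the given category prefix
star_select_loop <- function(loops, category, path) {
  hit <- which(vapply(loops, function(l)
    any(startsWith(tolower(l$tags), paste0(tolower(category), "."))),
    logical(1)))
  if (length(hit) == 0)
    stopf("no %s loop found in %s", category, path)
  if (length(hit) > 1)
    warnf("%s: %d %s loops; using the first", path, length(hit), category)
  loops[[hit[1]]]
}

loop_col <- function(loop, name, required = TRUE) {
  i <- match(tolower(name), tolower(sub("^[^.]*\\.", "", loop$tags)))
  if (is.na(i)) {
    if (required) stopf("required tag %s absent from loop", name)
    return(NULL)
  }
  loop$values[, i]
}

star_quote <- function(x) {
  x <- as.character(x)
  x[!nzchar(x)] <- "."
  need <- grepl("[ \t']", x)
  x[need] <- paste0("\"", x[need], "\"")
  x
}

#' Canonicalise an atom name
#'
#' Maps the amide-proton dialect `HN` to the canonical `H` so that shift,
#' restraint and coordinate records merge on one key.
#'
#' @param atom_name character vector of atom names.
#' @return Canonicalised atom names.
#' @export
canonical_atom_name <- function(atom_name) {
  ifelse(toupper(atom_name) == "HN", "H", atom_name)
}

#' Read assigned chemical shifts from an NMR-STAR file
#'
#' Parses the first assigned-chemical-shift (`_Atom_chem_shift`) loop of
#' the file into one record per data row. Atom names are canonicalised
#' (`HN` to `H`); rows with missing (`.`/`?`) or non-numeric shift values
#' are skipped and counted.
#'
#' @param path NMR-STAR file.
#' @return Data frame with columns `entry_id`, `chain_id`, `seq_id`,
#'   `residue_type`, `atom_name`, `value`, `ambiguity_code`; the number of
#'   skipped rows is in the `"n_skipped"` attribute.
#' @export
read_shift_records <- function(path) {
  loop <- star_select_loop(star_read_loops(path), "_Atom_chem_shift", path)
  entry <- loop_col(loop, "Entry_ID", required = FALSE)
  entry_id <- if (!is.null(entry) && length(entry) > 0) entry
  else rep(loop$block %||% NA_character_, nrow(loop$values))
  chain <- loop_col(loop, "Entity_assembly_ID", required = FALSE)
  if (is.null(chain)) chain <- loop_col(loop, "Auth_asym_ID", required = FALSE)
  if (is.null(chain)) chain <- rep("A", nrow(loop$values))
  seq_id <- loop_col(loop, "Comp_index_ID")
  res <- loop_col(loop, "Comp_ID")
  atom <- loop_col(loop, "Atom_ID")
  val_raw <- loop_col(loop, "Val")
  amb <- loop_col(loop, "Ambiguity_code", required = FALSE)

  val <- suppressWarnings(as.numeric(ifelse(val_raw %in% c(".", "?"),
                                            NA_character_, val_raw)))
  keep <- is.finite(val)
  n_skip <- sum(!keep)
  if (n_skip > 0)
    ar_message(sprintf("%s: skipped %d shift row(s) with missing/non-numeric values",
                       basename(path), n_skip))
  out <- data.frame(
    entry_id = as.character(entry_id)[keep],
    chain_id = as.character(chain)[keep],
    seq_id = as.integer(seq_id[keep]),
    residue_type = toupper(res[keep]),
    atom_name = canonical_atom_name(atom[keep]),
    value = val[keep],
    ambiguity_code = if (!is.null(amb))
      suppressWarnings(as.integer(ifelse(amb %in% c(".", "?"), NA, amb)))[keep]
    else rep(NA_integer_, sum(keep)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- n_skip
  out
}

#' Write assigned chemical shifts as NMR-STAR
#'
#' Emits a single `_Atom_chem_shift` loop inside a save frame; values are
#' written to 3 decimal places. `read_shift_records(write_shift_records(x))`
#' reproduces `x` at that precision.
#'
#' @param records shift data frame (see [read_shift_records()]).
#' @param path output file.
#' @param entry_id data-block name; defaults to the records' entry id.
#' @return `path`, invisibly.
#' @export
write_shift_records <- function(records, path, entry_id = NULL) {
  entry_id <- entry_id %||%
    (if (nrow(records) > 0) records$entry_id[1] else "entry")
  lines <- c(
    paste0("data_", entry_id),
    "",
    "save_assigned_chemical_shifts",
    "   _Assigned_chem_shift_list.Sf_category assigned_chemical_shifts",
    "   loop_",
    "      _Atom_chem_shift.ID",
    "      _Atom_chem_shift.Entity_assembly_ID",
    "      _Atom_chem_shift.Comp_index_ID",
    "      _Atom_chem_shift.Comp_ID",
    "      _Atom_chem_shift.Atom_ID",
    "      _Atom_chem_shift.Val",
    "      _Atom_chem_shift.Ambiguity_code",
    "      _Atom_chem_shift.Entry_ID"
  )
  if (nrow(records) > 0) {
    amb <- ifelse(is.na(records$ambiguity_code), ".",
                  as.character(records$ambiguity_code))
    rows <- paste("     ", seq_len(nrow(records)),
                  star_quote(records$chain_id), records$seq_id,
                  star_quote(records$residue_type),
                  star_quote(records$atom_name),
                  num_fmt(records$value, 3), amb,
                  star_quote(records$entry_id))
    lines <- c(lines, rows)
  }
  lines <- c(lines, "   stop_", "save_", "")
  writeLines(lines, path)
  invisible(path)
}

#' Read distance restraints from an NMR-STAR file
#'
#' Parses the first `_Gen_dist_constraint` loop into one record per
#' restraint row, both members identified by (chain, sequence, residue,
#' atom). Atom names are canonicalised; rows with a missing member atom
#' name are rejected and counted; duplicated restraint ids are kept with a
#' warning.
#'
#' @param path NMR-STAR restraint file.
#' @return Data frame with columns `restraint_id`, `entry_id`,
#'   `chain_id_1`, `seq_id_1`, `residue_type_1`, `atom_name_1`,
#'   `chain_id_2`, `seq_id_2`, `residue_type_2`, `atom_name_2`,
#'   `upper_bound`; rejected-row count in attribute `"n_rejected"`.
#' @export
read_restraints <- function(path) {
  loop <- star_select_loop(star_read_loops(path), "_Gen_dist_constraint", path)
  v <- function(name, required = TRUE) loop_col(loop, name, required)
  n <- nrow(loop$values)
  entry <- v("Entry_ID", required = FALSE)
  entry_id <- if (!is.null(entry) && length(entry) > 0) as.character(entry)
  else rep(loop$block %||% NA_character_, n)
  up_raw <- v("Distance_upper_bound_val", required = FALSE)
  out <- data.frame(
    restraint_id = as.character(v("ID")),
    entry_id = entry_id,
    chain_id_1 = as.character(v("Entity_assembly_ID_1")),
    seq_id_1 = as.integer(v("Comp_index_ID_1")),
    residue_type_1 = toupper(v("Comp_ID_1")),
    atom_name_1 = as.character(v("Atom_ID_1")),
    chain_id_2 = as.character(v("Entity_assembly_ID_2")),
    seq_id_2 = as.integer(v("Comp_index_ID_2")),
    residue_type_2 = toupper(v("Comp_ID_2")),
    atom_name_2 = as.character(v("Atom_ID_2")),
    upper_bound = if (!is.null(up_raw))
      suppressWarnings(as.numeric(ifelse(up_raw %in% c(".", "?"), NA, up_raw)))
    else rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  bad <- out$atom_name_1 %in% c(".", "?", "") | is.na(out$atom_name_1) |
    out$atom_name_2 %in% c(".", "?", "") | is.na(out$atom_name_2)
  if (any(bad))
    ar_message(sprintf("%s: rejected %d restraint row(s) with missing member atom names",
                       basename(path), sum(bad)))
  out <- out[!bad, , drop = FALSE]
  out$atom_name_1 <- canonical_atom_name(out$atom_name_1)
  out$atom_name_2 <- canonical_atom_name(out$atom_name_2)
  if (anyDuplicated(out$restraint_id) > 0)
    warnf("%s: duplicate restraint id(s); all rows kept", basename(path))
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write distance restraints as NMR-STAR
#'
#' @param restraints restraint data frame (see [read_restraints()]).
#' @param path output file.
#' @param entry_id data-block name; defaults to the restraints' entry id.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(restraints, path, entry_id = NULL) {
  entry_id <- entry_id %||%
    (if (nrow(restraints) > 0) restraints$entry_id[1] else "entry")
  lines <- c(
    paste0("data_", entry_id),
    "",
    "save_distance_restraints",
    "   _Gen_dist_constraint_list.Sf_category general_distance_constraints",
    "   loop_",
    "      _Gen_dist_constraint.ID",
    "      _Gen_dist_constraint.Entity_assembly_ID_1",
    "      _Gen_dist_constraint.Comp_index_ID_1",
    "      _Gen_dist_constraint.Comp_ID_1",
    "      _Gen_dist_constraint.Atom_ID_1",
    "      _Gen_dist_constraint.Entity_assembly_ID_2",
    "      _Gen_dist_constraint.Comp_index_ID_2",
    "      _Gen_dist_constraint.Comp_ID_2",
    "      _Gen_dist_constraint.Atom_ID_2",
    "      _Gen_dist_constraint.Distance_upper_bound_val",
    "      _Gen_dist_constraint.Entry_ID"
  )
  if (nrow(restraints) > 0) {
    ub <- ifelse(is.na(restraints$upper_bound), ".",
                 num_fmt(restraints$upper_bound, 3))
    rows <- paste("     ", star_quote(restraints$restraint_id),
                  star_quote(restraints$chain_id_1), restraints$seq_id_1,
                  star_quote(restraints$residue_type_1),
                  star_quote(restraints$atom_name_1),
                  star_quote(restraints$chain_id_2), restraints$seq_id_2,
                  star_quote(restraints$residue_type_2),
                  star_quote(restraints$atom_name_2),
                  ub, star_quote(restraints$entry_id))
    lines <- c(lines, rows)
  }
  lines <- c(lines, "   stop_", "save_", "")
  writeLines(lines, path)
  invisible(path)
}
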