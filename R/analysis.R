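#' Fraction of restrained amides per Z-score bin
#'
#' For every integer Z bin, the number of amide protons in the bin and the
#' number with at least one amide-aromatic restraint. Eligibility follows
#' the caption convention: by default only amides from entries possessing
#' at least one amide-aromatic restraint enter the denominators
#' (`eligibility = "entry"`); `"all"` keeps every merged amide. The
#' default denominator is per bin; `denominator = "global"` divides each
#' bin's restrained count by the total eligible count instead.
#'
#' @param merged merged-amide data frame from [merge_entry()].
#' @param eligibility `"entry"` or `"all"`.
#' @param denominator `"per_bin"` or `"global"`.
#' @return Data frame `z_bin`, `n_total`, `n_restrained`, `fraction`,
#'   sorted by bin. Empty (with a warning) when no amide is eligible.
#' @export
bin_fractions <- function(merged, eligibility = c("entry", "all"),
                          denominator = c("per_bin", "global")) {
  eligibility <- match.arg(eligibility)
  denominator <- match.arg(denominator)
  m <- merged
  if (eligibility == "entry") m <- m[m$entry_eligible, , drop = FALSE]
  if (nrow(m) == 0) {
    warnf("no eligible amides; empty Z-bin table")
    return(data.frame(z_bin = integer(), n_total = integer(),
                      n_restrained = integer(), fraction = numeric()))
  }
  bins <- sort(unique(m$z_bin))
  n_total <- vapply(bins, function(b) sum(m$z_bin == b), integer(1))
  n_res <- vapply(bins, function(b) sum(m$z_bin == b & m$restrained),
                  integer(1))
  denom <- if (denominator == "per_bin") n_total else rep(nrow(m), length(bins))
  data.frame(z_bin = bins, n_total = n_total, n_restrained = n_res,
             fraction = ifelse(denom > 0, n_res / denom, NA_real_))
}

#' Distance / Z-score records near aromatic rings
#'
#' One record per merged amide whose nearest ring is of type
#' HIS/TRP/PHE/TYR with ensemble-averaged distance strictly below the
#' cutoff (default 8 Angstrom; a record at exactly 8.000 is excluded).
#'
#' @param merged merged-amide data frame.
#' @param cutoff Angstrom, strict upper bound on the averaged distance.
#' @return Data frame `aromatic_type`, `avg_distance`, `z`, `restrained`.
#' @export
distance_z_table <- function(merged, cutoff = 8) {
  keep <- !is.na(merged$ring_type) &
    merged$ring_type %in% c("HIS", "TRP", "PHE", "TYR") &
    merged$avg_distance < cutoff
  out <- merged[keep, c("ring_type", "avg_distance", "z", "restrained"),
                drop = FALSE]
  names(out)[1] <- "aromatic_type"
  rownames(out) <- NULL
  out
}

#' Per-aromatic-type shift-direction summary
#'
#' For each aromatic type, counts of records with Z <= -2 (strong
#' upfield), -2 < Z < 2, and Z >= 2 (strong downfield), and the median Z
#' among the |Z| >= 2 records (absent when there are none). Near PHE, TYR
#' and TRP the extreme records are expected upfield (negative median);
#' near HIS, downfield (positive median).
#'
#' @param records output of [distance_z_table()].
#' @return Data frame `aromatic_type`, `n_upfield`, `n_mid`,
#'   `n_downfield`, `median_extreme_z`.
#' @export
type_direction_summary <- function(records) {
  types <- c("HIS", "TRP", "PHE", "TYR")
  out <- lapply(types, function(tp) {
    z <- records$z[records$aromatic_type == tp]
    ext <- z[abs(z) >= 2]
    data.frame(aromatic_type = tp,
               n_upfield = sum(z <= -2), n_mid = sum(z > -2 & z < 2),
               n_downfield = sum(z >= 2),
               median_extreme_z = if (length(ext) > 0) stats::median(ext)
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the full federated analysis over a corpus directory
#'
#' Orchestrates the pipeline: load the entry-pair mapping, read each
#' pair's shift, restraint and coordinate files, build or load reference
#' statistics, merge per entry, and write the summary tables. Entries
#' that fail any stage are dropped with a per-entry report line rather
#' than aborting the run. The run is deterministic: identical inputs give
#' byte-identical outputs.
#'
#' Outputs in `out_dir`: `merged.tsv`, `zbin_fractions.tsv`,
#' `distance_z.tsv`, `type_summary.tsv`, `run_report.tsv`, `run.log`.
#'
#' @param corpus_dir corpus directory (layout of [write_fixture_corpus()]).
#' @param out_dir output directory (created if needed).
#' @param mapping path to the mapping JSON; defaults to
#'   `corpus_dir/mapping.json`.
#' @param stats_mode `"filtered"` or `"full"` (reference statistics
#'   computed from the corpus shifts with [compute_reference_stats()]),
#'   or `"reference"` (read from `stats_path`).
#' @param stats_path reference-statistics TSV used when
#'   `stats_mode = "reference"`; defaults to
#'   `corpus_dir/reference_stats.tsv`.
#' @param cutoff Angstrom cutoff for the distance/Z table (strict).
#' @param denominator,eligibility see [bin_fractions()].
#' @param carbon_only_ring_protons see [classify_restraint()].
#' @return Invisibly, a list with `merged`, `zbin`, `distance_z`,
#'   `type_summary`, `report`, `stats`.
#' @export
run_pipeline <- function(corpus_dir, out_dir,
                         mapping = file.path(corpus_dir, "mapping.json"),
                         stats_mode = c("filtered", "full", "reference"),
                         stats_path = file.path(corpus_dir, "reference_stats.tsv"),
                         cutoff = 8,
                         denominator = "per_bin", eligibility = "entry",
                         carbon_only_ring_protons = FALSE) {
  stats_mode <- match.arg(stats_mode)
  if (!dir.exists(corpus_dir)) stopf("corpus directory not found: %s", corpus_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    ar_message(msg)
  }
  pairs <- load_entry_pairs(mapping)
  logf("loaded %d entry pair(s) from %s", nrow(pairs), basename(mapping))

  read_or_null <- function(fun, path) {
    if (!file.exists(path)) return(NULL)
    tryCatch(fun(path), error = function(e) {
      logf("ERROR reading %s: %s", basename(path), conditionMessage(e))
      NULL
    })
  }

  shift_sets <- lapply(seq_len(nrow(pairs)), function(i)
    read_or_null(read_shift_records,
                 file.path(corpus_dir, "shifts",
                           paste0(pairs$shift_entry_id[i], ".str"))))

  stats <- switch(stats_mode,
    reference = read_reference_stats(stats_path),
    {
      all_shifts <- do.call(rbind, shift_sets[!vapply(shift_sets, is.null, TRUE)])
      if (is.null(all_shifts) || nrow(all_shifts) == 0)
        stopf("no shift records readable; cannot build corpus statistics")
      compute_reference_stats(all_shifts, mode = stats_mode)
    })
  logf("reference statistics: %s (%d classes)", stats_mode, nrow(stats))

  merged_all <- list()
  reports <- list()
  for (i in seq_len(nrow(pairs))) {
    pair <- pairs[i, ]
    sh <- shift_sets[[i]]
    ens <- read_or_null(read_ensemble,
                        file.path(corpus_dir, "structures",
                                  paste0(pair$structure_entry_id, ".cif")))
    rst <- read_or_null(read_restraints,
                        file.path(corpus_dir, "restraints",
                                  paste0(pair$structure_entry_id, ".str")))
    if (is.null(sh) || is.null(ens)) {
      reports[[i]] <- data.frame(
        shift_entry_id = pair$shift_entry_id,
        structure_entry_id = pair$structure_entry_id,
        n_candidates = 0L, n_merged = 0L, n_shift_only = 0L,
        n_coord_only = 0L, n_skipped = 0L, n_aromatic_restraints = 0L,
        status = if (is.null(sh)) "shift_file_unreadable"
        else "structure_file_unreadable",
        stringsAsFactors = FALSE)
      logf("entry %s/%s dropped: %s", pair$shift_entry_id,
           pair$structure_entry_id, reports[[i]]$status)
      next
    }
    if (is.null(rst)) rst <- read_restraints_empty()
    res <- merge_entry(pair, sh, ens, rst, stats,
                       carbon_only_ring_protons = carbon_only_ring_protons)
    merged_all[[i]] <- res$merged
    reports[[i]] <- res$report
    logf("entry %s/%s: %d merged, %d shift-only, %d coord-only, %d skipped",
         pair$shift_entry_id, pair$structure_entry_id, res$report$n_merged,
         res$report$n_shift_only, res$report$n_coord_only,
         res$report$n_skipped)
  }
  merged <- do.call(rbind, merged_all[!vapply(merged_all, is.null, TRUE)])
  if (is.null(merged))
    stopf("no entries merged; see run report")
  report <- do.call(rbind, reports)

  zbin <- bin_fractions(merged, eligibility = eligibility,
                        denominator = denominator)
  dz <- distance_z_table(merged, cutoff = cutoff)
  ts <- type_direction_summary(dz)

  wt <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(merged, "merged.tsv")
  wt(zbin, "zbin_fractions.tsv")
  wt(dz, "distance_z.tsv")
  wt(ts, "type_summary.tsv")
  wt(report, "run_report.tsv")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(merged = merged, zbin = zbin, distance_z = dz,
                 type_summary = ts, report = report, stats = stats))
}

# empty restraint table with the reader's schema
read_restraints_empty <- function() {
  data.frame(restraint_id = character(), entry_id = character(),
             chain_id_1 = character(), seq_id_1 = integer(),
             residue_type_1 = character(), atom_name_1 = character(),
             chain_id_2 = character(), seq_id_2 = integer(),
             residue_type_2 = character(), atom_name_2 = character(),
             upper_bound = numeric(), stringsAsFactors = FALSE)
}
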