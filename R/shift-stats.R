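#' Entry-level and shift-level corpus filtering
#'
#' Implements the reference-corpus filtering rules used for "filtered"
#' chemical-shift statistics: an entry is excluded when it carries an
#' aromatic or paramagnetic ligand flag, or when any carbon-bound proton in
#' it has a shift greater than 10 ppm or less than -2.5 ppm (a signature of
#' unusual referencing). Independently, individual shifts lying strictly
#' outside eight standard deviations from the full-corpus mean for their
#' (residue type, atom) class are dropped from the filtered corpus; a shift
#' at exactly 8.000 SD is retained.
#'
#' @param records chemical-shift data frame (see [read_shift_records()]);
#'   may span several entries.
#' @param full_stats reference statistics computed on the *full* corpus
#'   (for the eight-SD rule); see [compute_reference_stats()].
#' @param ligand_flags optional data frame `entry_id`, `aromatic_ligand`,
#'   `paramagnetic_ligand` (logical). Entries absent from it are unflagged.
#' @return Data frame with one row per entry: `entry_id`, `excluded`
#'   (logical), `reasons` (comma-separated, empty when retained). The
#'   attribute `"shift_dropped"` is a logical vector aligned with
#'   `records`, `TRUE` where the eight-SD shift-level rule drops the shift.
#' @export
entry_filter <- function(records, full_stats, ligand_flags = NULL) {
  assert_columns(records, c("entry_id", "residue_type", "atom_name", "value"),
                 "shift records")
  entries <- unique(records$entry_id)
  cb <- is_carbon_bound_proton(records$residue_type, records$atom_name)
  extreme <- cb & (records$value > 10 | records$value < -2.5)

  reasons <- lapply(entries, function(e) {
    r <- character()
    if (!is.null(ligand_flags)) {
      i <- match(e, ligand_flags$entry_id)
      if (!is.na(i)) {
        if (isTRUE(ligand_flags$aromatic_ligand[i])) r <- c(r, "aromatic_ligand")
        if (isTRUE(ligand_flags$paramagnetic_ligand[i])) r <- c(r, "paramagnetic_ligand")
      }
    }
    if (any(extreme & records$entry_id == e)) r <- c(r, "extreme_carbon_bound_proton")
    r
  })
  report <- data.frame(
    entry_id = entries,
    excluded = lengths(reasons) > 0,
    reasons = vapply(reasons, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )

  # shift-level eight-SD rule against the full-corpus statistics (strict >8)
  key <- paste(records$residue_type, records$atom_name)
  skey <- paste(full_stats$residue_type, full_stats$atom_name)
  i <- match(key, skey)
  mu <- full_stats$mean[i]
  sd <- full_stats$sd[i]
  dropped <- !is.na(mu) & sd > 0 & abs(records$value - mu) / sd > 8
  dropped[is.na(dropped)] <- FALSE
  attr(report, "shift_dropped") <- dropped
  report
}

#' Per-(residue type, atom) chemical-shift reference statistics
#'
#' Aggregates a corpus of assigned shifts into mean, standard deviation,
#' count and a histogram per (residue type, atom name). In `"filtered"`
#' mode the entry-level and shift-level rules of [entry_filter()] are
#' applied first, with the eight-SD rule evaluated against the full-mode
#' statistics of the same corpus.
#'
#' @param records chemical-shift data frame (may span entries).
#' @param mode `"full"` or `"filtered"`.
#' @param ligand_flags see [entry_filter()].
#' @param sd_denominator `"population"` (divide by n, the convention of
#'   large-corpus statistics) or `"sample"` (n-1).
#' @param hist_bin histogram bin width in ppm.
#' @return A `reference_stats` data frame with columns `residue_type`,
#'   `atom_name`, `count`, `mean`, `sd`, `sd_flag` (`TRUE` when count = 1
#'   and the SD of 0 is a placeholder). Histograms are stored in the
#'   `"histograms"` attribute, a named list (`"RES ATOM"`) of data frames
#'   `bin_left`, `count`; each histogram total equals the class count.
#' @export
compute_reference_stats <- function(records,
                                    mode = c("full", "filtered"),
                                    ligand_flags = NULL,
                                    sd_denominator = c("population", "sample"),
                                    hist_bin = 0.1) {
  mode <- match.arg(mode)
  sd_denominator <- match.arg(sd_denominator)
  assert_columns(records, c("entry_id", "residue_type", "atom_name", "value"),
                 "shift records")
  if (mode == "filtered") {
    full <- compute_reference_stats(records, "full",
                                    sd_denominator = sd_denominator,
                                    hist_bin = hist_bin)
    rep <- entry_filter(records, full, ligand_flags)
    keep_entry <- records$entry_id %in% rep$entry_id[!rep$excluded]
    keep <- keep_entry & !attr(rep, "shift_dropped")
    records <- records[keep, , drop = FALSE]
  }
  if (nrow(records) == 0) {
    out <- data.frame(residue_type = character(), atom_name = character(),
                      count = integer(), mean = numeric(), sd = numeric(),
                      sd_flag = logical(), stringsAsFactors = FALSE)
    attr(out, "histograms") <- list()
    class(out) <- c("reference_stats", "data.frame")
    return(out)
  }
  key <- paste(records$residue_type, records$atom_name)
  groups <- split(records$value, key)
  n <- lengths(groups)
  mu <- vapply(groups, mean, numeric(1))
  sd <- vapply(groups, function(v) {
    if (length(v) == 1) return(0)
    if (sd_denominator == "population")
      sqrt(mean((v - mean(v))^2))
    else stats::sd(v)
  }, numeric(1))
  hists <- lapply(groups, function(v) {
    bl <- floor(v / hist_bin) * hist_bin
    tt <- table(format(bl, nsmall = 6, trim = TRUE, scientific = FALSE))
    data.frame(bin_left = as.numeric(names(tt)), count = as.integer(tt))
  })
  ids <- do.call(rbind, strsplit(names(groups), " ", fixed = TRUE))
  out <- data.frame(residue_type = ids[, 1], atom_name = ids[, 2],
                    count = as.integer(n), mean = unname(mu), sd = unname(sd),
                    sd_flag = unname(n == 1), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "histograms") <- hists
  class(out) <- c("reference_stats", "data.frame")
  out
}

# lookup one (residue_type, atom_name) row; NULL when absent
stat_lookup <- function(stats, residue_type, atom_name) {
  i <- which(stats$residue_type == residue_type & stats$atom_name == atom_name)
  if (length(i) == 0) return(NULL)
  stats[i[1], , drop = FALSE]
}

#' Z-score of a chemical shift against a reference class
#'
#' `Z = (value - mean) / sd`; an upfield shift (smaller ppm than the mean)
#' yields a negative Z.
#'
#' @param value observed shift (ppm), vectorised.
#' @param stat one-row reference statistic (fields `mean`, `sd`), or a
#'   list with those fields.
#' @return Dimensionless Z, same length as `value`.
#' @export
z_score <- function(value, stat) {
  if (is.null(stat) || !is.finite(stat$sd[1]) || stat$sd[1] <= 0)
    stopf("undefined Z-score for %s %s: reference SD is zero or missing",
          stat$residue_type[1] %||% "?", stat$atom_name[1] %||% "?")
  (value - stat$mean[1]) / stat$sd[1]
}

#' Z-score bin
#'
#' Integer bin used for the fraction-restrained summary: Z rounded half
#' away from zero and clamped to \[-8, 8\] (so Z = 2.5 bins to 3 and
#' Z = -2.5 to -3).
#'
#' @param z numeric Z-scores.
#' @return Integer bins.
#' @export
z_bin <- function(z) {
  as.integer(pmax(-8, pmin(8, round_half_away(z))))
}

#' Write / read a reference-statistics table as TSV
#'
#' The main table is a TSV (`residue_type`, `atom_name`, `count`, `mean`,
#' `sd`, `sd_flag`); histograms, when present, go to a sidecar
#' `<path>.hist.tsv` with columns `residue_type`, `atom_name`, `bin_left`,
#' `count`.
#'
#' @param stats a `reference_stats` data frame.
#' @param path output TSV path.
#' @return `write_reference_stats()`: `path`, invisibly.
#'   `read_reference_stats()`: the `reference_stats` data frame.
#' @export
write_reference_stats <- function(stats, path) {
  utils::write.table(as.data.frame(stats)[, c("residue_type", "atom_name",
                                              "count", "mean", "sd")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  hists <- attr(stats, "histograms")
  if (!is.null(hists) && length(hists) > 0) {
    rows <- lapply(names(hists), function(k) {
      id <- strsplit(k, " ", fixed = TRUE)[[1]]
      cbind(residue_type = id[1], atom_name = id[2], hists[[k]])
    })
    utils::write.table(do.call(rbind, rows), paste0(path, ".hist.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_reference_stats
#' @export
read_reference_stats <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(residue_type = "character",
                                          atom_name = "character"))
  hp <- paste0(path, ".hist.tsv")
  if (file.exists(hp)) {
    h <- utils::read.table(hp, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    attr(out, "histograms") <- split(h[, c("bin_left", "count")],
                                     paste(h$residue_type, h$atom_name))
  }
  class(out) <- c("reference_stats", "data.frame")
  out
}
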