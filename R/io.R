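#' Read a per-droplet amplitude CSV
#'
#' Reads an instrument-export-style comma-separated table with one
#' droplet per row and a header naming the two amplitude columns. Column
#' names vary across export software versions, so a set of aliases is
#' accepted per channel (case-insensitive); extra columns such as a
#' pre-assigned cluster label are ignored.
#'
#' @param source Path to a CSV file (or a connection).
#' @param well_id Identifier to attach; defaults to the file name.
#' @param ch1_aliases,ch2_aliases Accepted header names per channel.
#' @return A `droplet_table` with columns `ch1_amplitude` and
#'   `ch2_amplitude`, row order preserved.
#' @export
read_amplitude_csv <- function(source, well_id = NULL,
                               ch1_aliases = c("ch1_amplitude",
                                               "ch1.amplitude",
                                               "ch1 amplitude",
                                               "fam", "assigned.ch1"),
                               ch2_aliases = c("ch2_amplitude",
                                               "ch2.amplitude",
                                               "ch2 amplitude",
                                               "hex", "vic")) {
  df <- tryCatch(
    utils::read.csv(source, check.names = FALSE, strip.white = TRUE),
    error = function(e) stop("cannot read amplitude CSV: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0L) {
    stop("amplitude CSV is empty (no droplet rows)", call. = FALSE)
  }
  find_col <- function(aliases, label) {
    hit <- which(tolower(names(df)) %in% tolower(aliases))
    if (length(hit) == 0L) {
      stop("amplitude CSV is missing a ", label, " column (accepted names: ",
           paste(aliases, collapse = ", "), ")", call. = FALSE)
    }
    hit[1L]
  }
  c1 <- df[[find_col(ch1_aliases, "channel-1 amplitude")]]
  c2 <- df[[find_col(ch2_aliases, "channel-2 amplitude")]]
  check_numeric <- function(v, label) {
    v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop("non-numeric ", label, " amplitude at data line ", bad[1L],
           call. = FALSE)
    }
    if (any(v < 0)) {
      stop("negative ", label, " amplitude at data line ",
           which(v < 0)[1L], call. = FALSE)
    }
    v
  }
  out <- data.frame(ch1_amplitude = check_numeric(c1, "channel-1"),
                    ch2_amplitude = check_numeric(c2, "channel-2"))
  if (is.null(well_id)) {
    well_id <- if (is.character(source)) {
      sub("\\.[Cc][Ss][Vv]$", "", basename(source))
    } else {
      NA_character_
    }
  }
  new_droplet_table(out, well_id)
}

#' Write a droplet table to the amplitude CSV dialect
#'
#' Comma-separated, UTF-8, mandatory header, no index column. Latent
#' truth columns from the simulator are written when present (they are
#' ignored on read), so simulated wells round-trip.
#'
#' @param table A `droplet_table` or compatible data frame.
#' @param destination Output file path.
#' @return `destination`, invisibly.
#' @export
write_amplitude_csv <- function(table, destination) {
  utils::write.csv(as.data.frame(table), destination, row.names = FALSE)
  invisible(destination)
}

#' Read pre-classified per-well droplet counts
#'
#' Counts-level entry point: published per-well tallies can be replayed
#' through quantification and calling without amplitude data. The header
#' must name `well_id`, `n_total`, `n_ch1_pos`, `n_ch2_pos` and
#' `n_double_pos`; `n_neg` is validated when present and derived
#' otherwise. The conservation identity is enforced on load.
#'
#' @param source Path to a CSV file.
#' @return A list of [classified_counts], named by well.
#' @export
read_counts_csv <- function(source) {
  df <- tryCatch(
    utils::read.csv(source, strip.white = TRUE),
    error = function(e) stop("cannot read counts CSV: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0L) {
    stop("counts CSV is empty", call. = FALSE)
  }
  required <- c("well_id", "n_total", "n_ch1_pos", "n_ch2_pos",
                "n_double_pos")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("counts CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    classified_counts(
      n_total = df$n_total[i],
      n_ch1_pos = df$n_ch1_pos[i],
      n_ch2_pos = df$n_ch2_pos[i],
      n_double_pos = df$n_double_pos[i],
      n_neg = if ("n_neg" %in% names(df)) df$n_neg[i] else NULL,
      well_id = as.character(df$well_id[i])
    )
  })
  stats::setNames(out, vapply(out, `[[`, "", "well_id"))
}

#' Write classified counts to CSV
#'
#' @param counts A [classified_counts] object or list of them.
#' @param destination Output file path.
#' @return `destination`, invisibly.
#' @export
write_counts_csv <- function(counts, destination) {
  if (inherits(counts, "classified_counts")) counts <- list(counts)
  rows <- do.call(rbind, lapply(counts, function(x) {
    data.frame(well_id = x$well_id, n_total = x$n_total,
               n_ch1_pos = x$n_ch1_pos, n_ch2_pos = x$n_ch2_pos,
               n_double_pos = x$n_double_pos, n_neg = x$n_neg)
  }))
  utils::write.csv(rows, destination, row.names = FALSE)
  invisible(destination)
}

call_result_record <- function(res) {
  list(
    well_id = res$well_id,
    assay = res$assay,
    maternal_genotype = res$maternal_genotype,
    fetal_genotype_call = if (is.na(res$fetal_genotype_call)) NULL
      else res$fetal_genotype_call,
    status = res$status,
    fsp = res$fsp,
    msp = res$msp,
    fetus_specific_channel = res$fetus_specific_channel,
    fetus_specific_allele = res$fetus_specific_allele,
    fetal_fraction = if (!is.null(res$fetal_fraction)) list(
      fraction = res$fetal_fraction$fraction,
      percent = res$fetal_fraction$percent,
      percent_label = res$fetal_fraction$percent_label,
      method = res$fetal_fraction$method,
      ci_lower = if (!is.null(res$fetal_fraction$ci))
        res$fetal_fraction$ci[["lower"]],
      ci_upper = if (!is.null(res$fetal_fraction$ci))
        res$fetal_fraction$ci[["upper"]]
    ),
    qc_flags = as.list(res$qc_flags),
    thresholds = unclass(res$thresholds),
    cutoffs = if (!is.null(res$cutoffs)) list(
      ch1_cutoff = res$cutoffs$ch1_cutoff,
      ch2_cutoff = res$cutoffs$ch2_cutoff,
      ch1_method = res$cutoffs$ch1_method,
      ch2_method = res$cutoffs$ch2_method
    )
  )
}

#' Write a machine-readable genotyping report
#'
#' Emits one JSON record per well with the call, status, FSP/MSP, fetal
#' fraction (point, rounded percent and interval), the exact thresholds
#' and cutoff provenance used (full provenance, no silent defaults),
#' plus the package version and optional simulation seed.
#'
#' @param results A `fetal_call_result` or non-empty list of them.
#' @param destination Output JSON path.
#' @param seed Optional simulation seed to record.
#' @return `destination`, invisibly.
#' @export
write_report <- function(results, destination, seed = NULL) {
  if (inherits(results, "fetal_call_result")) results <- list(results)
  if (length(results) == 0L) {
    stop("cannot write a report with no results", call. = FALSE)
  }
  statuses <- vapply(results, `[[`, "", "status")
  report <- list(
    software = "ddfetal",
    version = as.character(utils::packageVersion("ddfetal")),
    seed = seed,
    n_wells = length(results),
    status_summary = as.list(table(statuses)),
    wells = lapply(results, call_result_record)
  )
  jsonlite::write_json(report, destination, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(destination)
}

#' Read a genotyping report back into a list
#'
#' @param source Path to a report written by [write_report()].
#' @return The report as a nested list.
#' @export
read_report <- function(source) {
  jsonlite::read_json(source)
}

#' Human-readable summary of call results
#'
#' @param results A list of `fetal_call_result` objects.
#' @return A data frame mirroring the per-well report columns (one row
#'   per well: genotype call, status, FSP, MSP, fetal-fraction label).
#' @export
summarize_calls <- function(results) {
  if (inherits(results, "fetal_call_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      well_id = r$well_id,
      assay = r$assay,
      maternal = r$maternal_genotype,
      fetal_call = ifelse(is.na(r$fetal_genotype_call), "-",
                          r$fetal_genotype_call),
      status = r$status,
      fsp = r$fsp, msp = r$msp,
      fetal_fraction = if (!is.null(r$fetal_fraction))
        r$fetal_fraction$percent_label else "-",
      stringsAsFactors = FALSE
    )
  }))
}

#' Replay published per-well droplet counts through the pipeline
#'
#' Runs a counts CSV (wells annotated with assay and maternal genotype)
#' through [fetal_fraction()] and [call_fetal_genotype()]. The bundled
#' file `system.file("extdata", "published_counts.csv", package =
#' "ddfetal")` carries the two per-sample wells published for the
#' maternal-cc group (the only group with per-sample counts) together
#' with a clean NTC.
#'
#' @param counts_csv Path to a counts CSV with additional `assay` and
#'   `maternal_genotype` columns; rows with kind `ntc` are used as the
#'   paired control.
#' @param thresholds A [decision_thresholds] object.
#' @return A list of `fetal_call_result` objects, one per sample well.
#' @export
replay_published_counts <- function(counts_csv = system.file(
                                      "extdata", "published_counts.csv",
                                      package = "ddfetal"),
                                    thresholds = decision_thresholds()) {
  df <- utils::read.csv(counts_csv, strip.white = TRUE)
  required <- c("well_id", "kind", "assay", "maternal_genotype", "n_total",
                "n_ch1_pos", "n_ch2_pos", "n_double_pos")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("counts CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mk_counts <- function(i) {
    classified_counts(df$n_total[i], df$n_ch1_pos[i], df$n_ch2_pos[i],
                      df$n_double_pos[i], well_id = as.character(df$well_id[i]))
  }
  ntc_rows <- which(df$kind == "ntc")
  if (length(ntc_rows) == 0L) {
    stop("counts CSV has no NTC well to pair with the samples", call. = FALSE)
  }
  ntc <- mk_counts(ntc_rows[1L])
  sample_rows <- which(df$kind == "sample")
  lapply(sample_rows, function(i) {
    ctx <- maternal_context(df$assay[i], df$maternal_genotype[i])
    call_fetal_genotype(mk_counts(i), ntc, ctx, thresholds)
  })
}
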