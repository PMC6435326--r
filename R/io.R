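#' Read a glycopeptide quantification table
#'
#' Reads a TSV/CSV of peptide-spectrum matches into the canonical
#' GlycopeptideRecord schema. Foreign layouts (e.g. a deposited
#' supplementary table) are ingested unmodified via `column_map`, a named
#' character vector mapping canonical names to the file's column names.
#' Rows failing validation (unknown residue, non-positive position or
#' intensity, unknown glycoform) are dropped into a rejects table, attached
#' as the `rejects` attribute, with one reason per row.
#'
#' Glycoform spellings `HexNAc` and `HexHexNAc` are normalized to `Tn` and
#' `T`. A missing `paired` column is derived from the presence of both
#' channel intensities.
#'
#' @param path delimited text file; tab-separated unless the extension is
#'   `.csv`.
#' @param column_map optional named character vector, e.g.
#'   `c(protein_id = "Protein Accession", ...)`.
#' @return validated records data.frame with attribute `rejects`
#'   (data.frame: row, reason).
#' @export
read_glycopeptide_table <- function(path, column_map = NULL) {
  raw <- read_delim_auto(path)
  if (nrow(raw) == 0L) {
    stop_invalid("input table has no rows", class = "gt_schema_error")
  }
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src)) {
      stop_invalid(paste("mapped columns absent from file:",
                         paste(missing_src, collapse = ", ")),
                   class = "gt_schema_error")
    }
    for (canon in names(column_map)) raw[[canon]] <- raw[[column_map[[canon]]]]
  }
  needed <- c("protein_id", "peptide", "site_position", "residue",
              "glycoform", "intensity_medium", "intensity_light")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop_invalid(paste("missing mandatory columns:",
                       paste(missing_cols, collapse = ", ")),
                 class = "gt_schema_error")
  }
  raw$glycoform <- ifelse(raw$glycoform == "HexNAc", "Tn",
                          ifelse(raw$glycoform == "HexHexNAc", "T",
                                 as.character(raw$glycoform)))
  raw$site_position <- suppressWarnings(as.numeric(raw$site_position))
  raw$intensity_medium <- suppressWarnings(as.numeric(raw$intensity_medium))
  raw$intensity_light <- suppressWarnings(as.numeric(raw$intensity_light))
  if (!"paired" %in% names(raw)) {
    raw$paired <- !is.na(raw$intensity_medium) & !is.na(raw$intensity_light)
  }

  reason <- rep(NA_character_, nrow(raw))
  flag <- function(bad, why) ifelse(bad & is.na(reason), why, reason)
  reason <- flag(!raw$residue %in% RESIDUES, "residue not one of S/T/Y")
  reason <- flag(!raw$glycoform %in% GLYCOFORMS,
                 "glycoform not HexNAc/HexHexNAc (Tn/T)")
  reason <- flag(!is.finite(raw$site_position) | raw$site_position < 1,
                 "site_position not a positive integer")
  reason <- flag((!is.na(raw$intensity_medium) & raw$intensity_medium <= 0) |
                   (!is.na(raw$intensity_light) & raw$intensity_light <= 0),
                 "non-positive intensity")
  reason <- flag(is.na(raw$intensity_medium) & is.na(raw$intensity_light),
                 "no channel intensity present")

  keep <- is.na(reason)
  rejects <- data.frame(row = which(!keep), reason = reason[!keep],
                        stringsAsFactors = FALSE)
  records <- raw[keep, c(needed, "paired")]
  rownames(records) <- NULL
  if (nrow(records)) records <- validate_records(records)
  attr(records, "rejects") <- rejects
  records
}

#' Write a glycopeptide record table as TSV
#' @param records GlycopeptideRecord data.frame.
#' @param path output file.
#' @export
write_glycopeptide_table <- function(records, path) {
  records <- validate_records(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read cell tracks from a delimited table
#'
#' Expects columns `track_id, frame, t_seconds, x_um, y_um, z_um`; rows are
#' ordered by frame within each track.
#'
#' @param path TSV (or CSV by extension) track table.
#' @return list of [track()] objects.
#' @export
read_tracks <- function(path) {
  raw <- read_delim_auto(path)
  needed <- c("track_id", "frame", "t_seconds", "x_um", "y_um", "z_um")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop_invalid(paste("track table missing columns:",
                       paste(missing_cols, collapse = ", ")),
                 class = "gt_schema_error")
  }
  lapply(split(raw, raw$track_id), function(d) {
    d <- d[order(d$frame), ]
    track(d$track_id[1L], d$frame, d$t_seconds,
          as.matrix(d[, c("x_um", "y_um", "z_um")]))
  })
}

#' Write cell tracks as TSV
#' @param tracks list of [track()] objects.
#' @param path output file.
#' @export
write_tracks <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    data.frame(track_id = tr$track_id, frame = tr$frames,
               t_seconds = tr$times, x_um = tr$positions[, 1L],
               y_um = tr$positions[, 2L], z_um = tr$positions[, 3L])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop_invalid(paste("file not found:", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Write a report as JSON (or flat TSV)
#'
#' JSON output (`.json` extension) preserves the full nested report;
#' any other extension writes a flat two-column key/value TSV of the scalar
#' entries. Output is deterministic for identical reports.
#'
#' @param report a `glyco_report` or any named list.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    flat <- unlist(unclass(report))
    utils::write.table(
      data.frame(key = names(flat), value = as.character(flat)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' @param records_path glycopeptide table (TSV/CSV), or `NULL` if `records`
#'   is given directly.
#' @param flowthrough_path file with one log10 ratio per line (header
#'   `log_ratio` optional), or `NULL` if `flowthrough` is given directly.
#' @param records,flowthrough in-memory alternatives to the paths.
#' @param column_map passed to [read_glycopeptide_table()].
#' @param t3,t10 classification thresholds (log10).
#' @param coverage null-model coverage (see [fit_null_model()]).
#' @param cutoff optional override of the fitted candidate cutoff.
#' @param out_dir output directory; created if needed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(records_path = NULL, flowthrough_path = NULL,
                            records = NULL, flowthrough = NULL,
                            column_map = NULL, t3 = log10(3), t10 = 1,
                            coverage = 0.9973, cutoff = NULL,
                            out_dir = tempfile("glycotrack")) {
  if (is.null(records_path) && is.null(records)) {
    stop_invalid("either records_path or records is required")
  }
  if (is.null(flowthrough_path) && is.null(flowthrough) && is.null(cutoff)) {
    stop_invalid("either a flow-through source or an explicit cutoff is required")
  }
  structure(list(records_path = records_path,
                 flowthrough_path = flowthrough_path,
                 records = records, flowthrough = flowthrough,
                 column_map = column_map, t3 = t3, t10 = t10,
                 coverage = coverage, cutoff = cutoff, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full differential glycoproteomics pipeline
#'
#' Stages: ingest records, fit the flow-through null (or apply the cutoff
#' override), compute PSM ratios, select candidates, aggregate glycosites,
#' summarize proteins, emit the report. Writes `sites.tsv`, `proteins.tsv`,
#' `report.json` and `rejects.tsv` under `config$out_dir`, logging one line
#' per stage with row counts. Deterministic given config.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage logging.
#' @return the `glyco_report`, invisibly, with attributes `site_table`,
#'   `protein_table`, `null_model` and `candidates`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    stop_invalid("config must be created with pipeline_config()")
  }
  log_stage <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  stage_wrap <- function(stage, expr) {
    tryCatch(expr, gt_error = function(e) {
      stop(errorCondition(paste0("stage '", stage, "': ", conditionMessage(e)),
                          class = c(class(e)[1L], "gt_stage_error", "gt_error")))
    })
  }

  records <- stage_wrap("ingest", {
    r <- if (!is.null(config$records)) validate_records(config$records)
      else read_glycopeptide_table(config$records_path, config$column_map)
    if (nrow(r) == 0L) {
      stop_invalid("no valid records after ingestion", class = "gt_schema_error")
    }
    r
  })
  log_stage("ingest", "%d records (%d rejected)", nrow(records),
            NROW(attr(records, "rejects")))

  model <- stage_wrap("null-fit", {
    ft <- config$flowthrough
    if (is.null(ft) && !is.null(config$flowthrough_path)) {
      d <- utils::read.table(config$flowthrough_path, header = TRUE, sep = "\t")
      ft <- d[[1L]]
    }
    if (!is.null(ft)) {
      m <- fit_null_model(ft, config$coverage)
      if (!is.null(config$cutoff)) m$cutoff <- config$cutoff
      m
    } else {
      structure(list(mu = 0, sigma = config$cutoff / 3,
                     cutoff = config$cutoff, coverage = config$coverage,
                     z = 3, n = 0L),
                class = "null_ratio_model")
    }
  })
  log_stage("null-fit", "mu=%.4f sigma=%.4f cutoff=%.4f", model$mu,
            model$sigma, model$cutoff)

  ratios <- stage_wrap("ratios", compute_log_ratio(records))
  log_stage("ratios", "%d quantified, %d singletons", sum(!is.na(ratios)),
            sum(is.na(ratios)))

  cand <- stage_wrap("candidates", select_candidates(ratios, model))
  log_stage("candidates", "%d PSMs beyond +/-%.3f", sum(cand), model$cutoff)

  sites <- stage_wrap("sites", aggregate_glycosites(records, config$t3, config$t10))
  log_stage("sites", "%d glycosites", nrow(sites))

  proteins <- stage_wrap("proteins", summarize_proteins(sites, config$t3, config$t10))
  log_stage("proteins", "%d proteins", nrow(proteins))

  report <- stage_wrap("report",
                       glycoproteome_report(sites, proteins, config$t3,
                                            config$t10, null_model = model))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sites, file.path(config$out_dir, "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(proteins, file.path(config$out_dir, "proteins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rejects <- attr(records, "rejects")
  if (!is.null(rejects)) {
    utils::write.table(rejects, file.path(config$out_dir, "rejects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_report(report, file.path(config$out_dir, "report.json"))
  log_stage("report", "written to %s", config$out_dir)

  attr(report, "site_table") <- sites
  attr(report, "protein_table") <- proteins
  attr(report, "null_model") <- model
  attr(report, "candidates") <- cand
  invisible(report)
}
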