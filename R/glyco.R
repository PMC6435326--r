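#' @title Differential O-glycoproteomics pipeline
#' @description Ratio computation, empirical-null candidate selection,
#'   fold-change classification and site/protein summaries for dimethyl
#'   isotope-doublet glycopeptide quantification. The mutant genotype is
#'   labelled with light formaldehyde (COH2) and the control with medium
#'   deuterated formaldehyde (COD2), so every ratio below is oriented
#'   mutant/control: negative log ratios mean lower glycosylation in the
#'   mutant.
#' @name glyco-pipeline
NULL

GLYCOFORMS <- c("Tn", "T")
RESIDUES <- c("S", "T", "Y")
CATEGORIES <- c("unchanged", "up3", "down3", "up10", "down10", "unquantified")

# Validate a GlycopeptideRecord table; returns it with canonical column order.
validate_records <- function(records) {
  needed <- c("protein_id", "peptide", "site_position", "residue",
              "glycoform", "intensity_medium", "intensity_light", "paired")
  if (!is.data.frame(records)) stop_invalid("records must be a data.frame")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop_invalid(paste("records is missing columns:",
                       paste(missing_cols, collapse = ", ")),
                 class = "gt_schema_error")
  }
  bad_res <- !records$residue %in% RESIDUES
  bad_form <- !records$glycoform %in% GLYCOFORMS
  bad_pos <- !is.finite(records$site_position) | records$site_position < 1
  bad_int <- (!is.na(records$intensity_medium) & records$intensity_medium <= 0) |
    (!is.na(records$intensity_light) & records$intensity_light <= 0)
  if (any(bad_res | bad_form | bad_pos | bad_int)) {
    stop_invalid("records contain invalid residue/glycoform/position/intensity values",
                 class = "gt_data_integrity")
  }
  records[, needed]
}

#' Compute log10 mutant/control ratios for glycopeptide records
#'
#' Returns `log10(intensity_light / intensity_medium)` per record: light is
#' the mutant channel, medium the control channel, so negative values mean
#' lower glycopeptide abundance in the mutant. Records without both channel
#' intensities (singleton precursors with no isotope partner) are
#' unquantifiable and yield `NA`, which downstream stages treat as "no
#' ratio", never as zero.
#'
#' @param records GlycopeptideRecord data.frame (see
#'   [simulate_glyco_dataset()] for the schema).
#' @return numeric vector of log10 ratios, `NA` for unpaired records.
#' @examples
#' rec <- data.frame(protein_id = "P1", peptide = "AASPK", site_position = 3,
#'                   residue = "S", glycoform = "Tn",
#'                   intensity_medium = 200, intensity_light = 100,
#'                   paired = TRUE)
#' compute_log_ratio(rec)  # log10(1/2) = -0.30103
#' @export
compute_log_ratio <- function(records) {
  records <- validate_records(records)
  ok <- records$paired & !is.na(records$intensity_medium) &
    !is.na(records$intensity_light)
  out <- rep(NA_real_, nrow(records))
  out[ok] <- log10(records$intensity_light[ok] / records$intensity_medium[ok])
  out
}

#' Select candidate glycopeptides beyond the empirical-null cutoff
#'
#' Keeps exactly the quantified ratios whose distance from the null location
#' exceeds the model cutoff (strict inequality, so a ratio exactly on the
#' cutoff is not a candidate). Unquantifiable (`NA`) ratios are excluded and
#' tallied in the `n_unquantifiable` attribute.
#'
#' @param log_ratios numeric vector of log10 ratios (may contain `NA`).
#' @param model a [fit_null_model()] fit.
#' @return logical vector marking candidates (`NA` ratios give `FALSE`),
#'   with attribute `n_unquantifiable`.
#' @export
select_candidates <- function(log_ratios, model) {
  if (!inherits(model, "null_ratio_model")) {
    stop_invalid("model must be a null_ratio_model from fit_null_model()")
  }
  if (!is.numeric(log_ratios)) stop_invalid("log_ratios must be numeric")
  sel <- !is.na(log_ratios) & abs(log_ratios - model$mu) > model$cutoff
  attr(sel, "n_unquantifiable") <- sum(is.na(log_ratios))
  sel
}

#' Classify a log10 fold change into the 3x / 10x tiers
#'
#' Two-tier classification used throughout the glycosite summaries:
#' `|r| < t3` is `unchanged`, `t3 <= |r| < t10` is a three-fold change
#' (`up3`/`down3` by sign), `|r| >= t10` a ten-fold change (`up10`/`down10`).
#' Boundaries are inclusive towards the stronger category. `down` means the
#' mutant is lower than the control.
#'
#' @param log_ratio numeric vector of finite log10 ratios.
#' @param t3 three-fold threshold in log10 units (default `log10(3)`).
#' @param t10 ten-fold threshold (default 1).
#' @return character vector of categories.
#' @examples
#' classify_fold_change(c(0, -log10(13), -log10(5), 0.3))
#' @export
classify_fold_change <- function(log_ratio, t3 = log10(3), t10 = 1) {
  if (!is.numeric(log_ratio) || any(!is.finite(log_ratio))) {
    stop_invalid("log_ratio must be finite numeric")
  }
  if (!is.numeric(t3) || !is.numeric(t10) || t3 <= 0 || t10 <= t3) {
    stop_invalid("need 0 < t3 < t10")
  }
  a <- abs(log_ratio)
  tier <- ifelse(a >= t10, "10", ifelse(a >= t3, "3", "0"))
  ifelse(tier == "0", "unchanged",
         paste0(ifelse(log_ratio > 0, "up", "down"), tier))
}

#' Aggregate PSM-level records into a glycosite summary table
#'
#' One row per glycosite (protein accession, 1-based position, residue).
#' Within a site, each glycoform's ratio is the median of its paired PSM log
#' ratios — robust to a single outlier spectrum. The glycoform class is the
#' union of glycoforms observed at the site (paired or singleton records
#' both count as observations). A glycoform observed only through singletons
#' is `unquantified`; a glycoform never observed has `NA` ratio and
#' category.
#'
#' @param records GlycopeptideRecord data.frame.
#' @param t3,t10 thresholds passed to [classify_fold_change()].
#' @return data.frame with columns protein_id, site_position, residue,
#'   glycoform_class, log_ratio_Tn, log_ratio_T, category_Tn, category_T,
#'   n_psm, n_paired.
#' @export
aggregate_glycosites <- function(records, t3 = log10(3), t10 = 1) {
  records <- validate_records(records)
  if (nrow(records) == 0L) stop_invalid("records table is empty")
  key <- paste(records$protein_id, records$site_position, sep = "\r")
  res_by_key <- tapply(records$residue, key, unique)
  if (any(lengths(res_by_key) > 1L)) {
    stop_invalid("conflicting residue letters at one glycosite key",
                 class = "gt_data_integrity")
  }
  records$log_ratio <- compute_log_ratio(records)
  site_key <- paste(key, records$residue, sep = "\r")
  sites <- split(records, site_key)
  rows <- lapply(sites, function(s) {
    per_form <- lapply(GLYCOFORMS, function(gf) {
      sub <- s[s$glycoform == gf, , drop = FALSE]
      if (nrow(sub) == 0L) {
        return(list(ratio = NA_real_, category = NA_character_, seen = FALSE))
      }
      r <- sub$log_ratio[!is.na(sub$log_ratio)]
      if (length(r) == 0L) {
        list(ratio = NA_real_, category = "unquantified", seen = TRUE)
      } else {
        m <- stats::median(r)
        list(ratio = m, category = classify_fold_change(m, t3, t10),
             seen = TRUE)
      }
    })
    names(per_form) <- GLYCOFORMS
    seen <- vapply(per_form, `[[`, logical(1), "seen")
    klass <- if (all(seen)) "both" else if (seen[["Tn"]]) "Tn-only" else "T-only"
    data.frame(
      protein_id = s$protein_id[1L], site_position = s$site_position[1L],
      residue = s$residue[1L], glycoform_class = klass,
      log_ratio_Tn = per_form$Tn$ratio, log_ratio_T = per_form$T$ratio,
      category_Tn = per_form$Tn$category, category_T = per_form$T$category,
      n_psm = nrow(s), n_paired = sum(!is.na(s$log_ratio)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id, out$site_position), ]
  rownames(out) <- NULL
  out
}

#' Summarize glycosites per protein
#'
#' Per protein: the number of distinct glycosites, the protein glycoform
#' class (`Tn-only` / `T-only` if every site carries a single glycoform,
#' otherwise `both`), the strongest site-level change, and the direct-target
#' flag: `TRUE` iff some glycosite decreased at least `t3`-fold while another
#' glycosite on the same protein is unchanged or increased. The flag marks
#' proteins whose loss of glycopeptide signal cannot be explained by reduced
#' protein expression alone.
#'
#' @param site_table output of [aggregate_glycosites()].
#' @param t3,t10 thresholds in log10 units.
#' @return data.frame with columns protein_id, n_glycosites,
#'   glycoform_class, max_abs_log_ratio, category, direct_target.
#' @export
summarize_proteins <- function(site_table, t3 = log10(3), t10 = 1) {
  if (!is.data.frame(site_table) || nrow(site_table) == 0L) {
    stop_invalid("site_table must be a non-empty data.frame")
  }
  prots <- split(site_table, site_table$protein_id)
  rows <- lapply(prots, function(p) {
    klass <- if (all(p$glycoform_class == "Tn-only")) "Tn-only"
      else if (all(p$glycoform_class == "T-only")) "T-only"
      else "both"
    ratios <- c(p$log_ratio_Tn, p$log_ratio_T)
    ratios <- ratios[!is.na(ratios)]
    if (length(ratios)) {
      max_abs <- max(abs(ratios))
      extreme <- ratios[which.max(abs(ratios))]
      category <- classify_fold_change(extreme, t3, t10)
    } else {
      max_abs <- NA_real_
      category <- "unquantified"
    }
    # per-site decrease/non-decrease evidence, any glycoform
    site_min <- pmin(p$log_ratio_Tn, p$log_ratio_T, na.rm = TRUE)
    site_min[is.infinite(site_min)] <- NA_real_
    decreased <- !is.na(site_min) & site_min <= -t3
    not_decreased <- !is.na(site_min) & site_min > -t3
    direct <- nrow(p) >= 2L && any(decreased) && any(not_decreased)
    data.frame(
      protein_id = p$protein_id[1L], n_glycosites = nrow(p),
      glycoform_class = klass, max_abs_log_ratio = max_abs,
      category = category, direct_target = direct,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Largest-remainder rounding: percentages that sum exactly to 100.
round_pct_to_sum <- function(x, digits = 0) {
  if (!length(x)) return(x)
  scale <- 10 ^ digits
  pct <- 100 * x / sum(x)
  lo <- floor(pct * scale)
  rem <- pct * scale - lo
  short <- round(100 * scale - sum(lo))
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    lo[bump] <- lo[bump] + 1
  }
  lo / scale
}

#' Full glycoproteome report
#'
#' Counts and percentages describing a site and protein table: totals,
#' glycoform class composition at both levels, glycosite multiplicity
#' distribution, residue composition, proteins past the 3x and 10x
#' thresholds, a direction-resolved overlap of T-changed vs Tn-changed
#' proteins, and the singleton-record tally. Percentages within one
#' classification axis are largest-remainder rounded so each axis sums to
#' 100 exactly (class and multiplicity axes to integer percent, the residue
#' split to 0.1%).
#'
#' @param site_table output of [aggregate_glycosites()].
#' @param protein_table output of [summarize_proteins()].
#' @param t3,t10 thresholds in log10 units.
#' @param null_model optional [fit_null_model()] fit; if supplied its cutoff
#'   and the fold change it corresponds to are echoed in the report so the
#'   candidate cutoff and the classification thresholds can be compared.
#' @return a list of class `glyco_report`.
#' @export
glycoproteome_report <- function(site_table, protein_table,
                                 t3 = log10(3), t10 = 1, null_model = NULL) {
  if (!is.data.frame(site_table) || !is.data.frame(protein_table) ||
      nrow(site_table) == 0L || nrow(protein_table) == 0L) {
    stop_invalid("site_table and protein_table must be non-empty data.frames")
  }
  classes <- c("Tn-only", "T-only", "both")
  site_class_n <- vapply(classes, function(k) sum(site_table$glycoform_class == k),
                         numeric(1))
  prot_class_n <- vapply(classes, function(k) sum(protein_table$glycoform_class == k),
                         numeric(1))
  mult_n <- table(factor(protein_table$n_glycosites,
                         levels = seq_len(max(protein_table$n_glycosites))))
  res_n <- vapply(RESIDUES, function(r) sum(site_table$residue == r), numeric(1))
  names(res_n) <- RESIDUES

  changed3 <- !is.na(protein_table$max_abs_log_ratio) &
    protein_table$max_abs_log_ratio >= t3
  changed10 <- !is.na(protein_table$max_abs_log_ratio) &
    protein_table$max_abs_log_ratio >= t10

  # direction-resolved protein-level changes per glycoform (3x threshold)
  per_prot_form <- function(col) {
    r <- split(site_table[[col]], site_table$protein_id)
    up <- vapply(r, function(v) any(!is.na(v) & v >= t3), logical(1))
    down <- vapply(r, function(v) any(!is.na(v) & v <= -t3), logical(1))
    list(up = names(r)[up], down = names(r)[down])
  }
  t_chg <- per_prot_form("log_ratio_T")
  tn_chg <- per_prot_form("log_ratio_Tn")
  t_any <- union(t_chg$up, t_chg$down)
  tn_any <- union(tn_chg$up, tn_chg$down)

  thresholds <- list(
    t3 = t3, t10 = t10, fold3 = 10 ^ t3, fold10 = 10 ^ t10
  )
  if (!is.null(null_model)) {
    thresholds$null_cutoff <- null_model$cutoff
    thresholds$null_cutoff_fold <- 10 ^ null_model$cutoff
  }

  structure(list(
    n_sites = nrow(site_table),
    n_proteins = nrow(protein_table),
    site_class_counts = site_class_n,
    site_class_pct = stats::setNames(round_pct_to_sum(site_class_n), classes),
    protein_class_counts = prot_class_n,
    protein_class_pct = stats::setNames(round_pct_to_sum(prot_class_n), classes),
    multiplicity_counts = as.numeric(mult_n),
    multiplicity_pct = stats::setNames(round_pct_to_sum(as.numeric(mult_n)),
                                       names(mult_n)),
    residue_counts = res_n,
    residue_pct = stats::setNames(round_pct_to_sum(res_n, digits = 1), RESIDUES),
    n_proteins_changed_3x = sum(changed3),
    n_proteins_changed_10x = sum(changed10),
    venn_3x = list(
      T_up = length(t_chg$up), T_down = length(t_chg$down),
      Tn_up = length(tn_chg$up), Tn_down = length(tn_chg$down),
      T_only = length(setdiff(t_any, tn_any)),
      Tn_only = length(setdiff(tn_any, t_any)),
      T_and_Tn = length(intersect(t_any, tn_any))
    ),
    n_direct_targets = sum(protein_table$direct_target),
    n_singleton_psm = sum(site_table$n_psm - site_table$n_paired),
    thresholds = thresholds
  ), class = "glyco_report")
}

#' @export
print.glyco_report <- function(x, ...) {
  cat("Glycoproteome report\n")
  cat(sprintf("  %d glycosites on %d proteins\n", x$n_sites, x$n_proteins))
  cat("  site classes (%):   ",
      paste(names(x$site_class_pct), x$site_class_pct, sep = "=",
            collapse = "  "), "\n")
  cat("  protein classes (%):",
      paste(names(x$protein_class_pct), x$protein_class_pct, sep = "=",
            collapse = "  "), "\n")
  cat("  residue split (%):  ",
      paste(names(x$residue_pct), x$residue_pct, sep = "=", collapse = "  "),
      "\n")
  cat(sprintf("  proteins changed >= %.2g-fold: %d; >= %.2g-fold: %d\n",
              x$thresholds$fold3, x$n_proteins_changed_3x,
              x$thresholds$fold10, x$n_proteins_changed_10x))
  if (!is.null(x$thresholds$null_cutoff)) {
    cat(sprintf("  null candidate cutoff: %.3f log10 (= %.2f-fold)\n",
                x$thresholds$null_cutoff, x$thresholds$null_cutoff_fold))
  }
  cat(sprintf("  direct-target proteins: %d; singleton PSMs: %d\n",
              x$n_direct_targets, x$n_singleton_psm))
  invisible(x)
}

#' Convert a peptide-relative site position to protein coordinates
#'
#' Glycosites are keyed by their 1-based residue index within the protein
#' (UniProt convention). Search engines report modification positions
#' relative to the peptide; given the peptide's 1-based start within the
#' protein this helper converts between the two.
#'
#' @param peptide_position 1-based position of the modified residue within
#'   the peptide.
#' @param peptide_start 1-based position of the peptide's first residue
#'   within the protein.
#' @return 1-based residue index within the protein.
#' @examples
#' site_position_in_protein(7, 101)  # 107
#' @export
site_position_in_protein <- function(peptide_position, peptide_start) {
  if (any(peptide_position < 1) || any(peptide_start < 1)) {
    stop_invalid("positions are 1-based and must be >= 1")
  }
  peptide_start + peptide_position - 1
}

#' Compare glycosite multiplicity of altered proteins vs the glycoproteome
#'
#' Two-sided Mann-Whitney U test (normal approximation with continuity and
#' tie correction) on per-protein glycosite counts: do proteins with altered
#' glycosylation carry more glycosites than the glycoproteome at large?
#'
#' @param altered_site_counts glycosite counts of the altered proteins.
#' @param all_site_counts glycosite counts of the reference set.
#' @return two-sided p-value.
#' @export
compare_multiplicity <- function(altered_site_counts, all_site_counts) {
  if (!length(altered_site_counts) || !length(all_site_counts)) {
    stop_invalid("both samples must be non-empty")
  }
  stats::wilcox.test(altered_site_counts, all_site_counts,
                     alternative = "two.sided", exact = FALSE,
                     correct = TRUE)$p.value
}
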