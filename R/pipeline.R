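# End-to-end orchestration: filter -> markers -> labels -> per-stratum
# accuracy evaluation, plus table rendering and best-marker comparisons.

#' Run configuration
#'
#' @param input A cohort data.frame, a CSV path, or a [cohort_spec()]
#'   (a spec is simulated on the fly).
#' @param criteria Subset of `c("ATP_III", "IDF")`.
#' @param markers Subset of [marker_ids()]; default all ten.
#' @param bootstrap_B Bootstrap replicates for CIs (0 disables bootstrap
#'   CIs).  A seed is required whenever `bootstrap_B > 0`.
#' @param seed Integer master seed; per-(stratum, criterion, marker)
#'   sub-seeds are derived from it, so results do not depend on
#'   evaluation order.
#' @param vai_women_as_printed Passed to [compute_panel()].
#' @param out_dir Optional output directory for per-stage artifacts.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(input, criteria = c("ATP_III", "IDF"),
                       markers = marker_ids(), bootstrap_B = 2000,
                       seed = NULL, vai_women_as_printed = FALSE,
                       out_dir = NULL) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  stopifnot(all(markers %in% marker_ids()))
  if (bootstrap_B > 0 && is.null(seed))
    stop("a seed is required when the bootstrap is enabled")
  structure(list(input = input, criteria = criteria, markers = markers,
                 bootstrap_B = bootstrap_B, seed = seed,
                 vai_women_as_printed = vai_women_as_printed,
                 out_dir = out_dir),
            class = "run_config")
}

.resolve_input <- function(input) {
  if (inherits(input, "cohort_spec")) return(generate_cohort(input))
  if (is.character(input)) return(load_cohort(input))
  if (is.data.frame(input)) return(input)
  stop("input must be a data.frame, a CSV path, or a cohort_spec")
}

#' Run the full evaluation pipeline
#'
#' Filters the cohort, computes the ten-marker panel and both criteria's
#' labels, then evaluates every configured marker against every configured
#' criterion within each sex-by-age stratum.  A stratum where a criterion
#' yields a single class is reported as non-evaluable and the run
#' continues.
#'
#' @param config A [run_config()].
#' @return An object of class `"mets_run"`: list with `filter_log`,
#'   `cohort` (kept records incl. stratum), `panel`, `labels`, and
#'   `results` — one entry per (stratum, criterion) with `n_pos`, `n_neg`,
#'   `evaluable`, per-marker `"mets_accuracy"` reports and `best_marker`
#'   (highest Youden index).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- .resolve_input(config$input)
  flt <- apply_eligibility(cohort)
  kept <- flt$kept
  kept$stratum <- assign_stratum(kept$sex, kept$age)
  panel <- compute_panel(kept, vai_women_as_printed = config$vai_women_as_printed)
  labels <- mets_labels(kept)
  orients <- marker_orientations()

  results <- list()
  for (crit in config$criteria) {
    lab_all <- if (crit == "ATP_III") labels$atp3_positive else labels$idf_positive
    for (st in all_strata()) {
      in_st <- kept$stratum == st
      lab <- lab_all[in_st]
      key <- paste(crit, st, sep = " | ")
      if (sum(in_st) == 0 || !any(lab) || all(lab)) {
        results[[key]] <- list(stratum = st, criterion = crit,
                               n_pos = sum(lab), n_neg = sum(!lab),
                               evaluable = FALSE, reports = list(),
                               best_marker = NA_character_,
                               scores = NULL, labels = lab)
        next
      }
      reports <- list()
      for (mk in config$markers) {
        sc <- panel[[mk]][in_st]
        sd_seed <- if (is.null(config$seed)) NULL
                   else derive_seed(config$seed, paste(crit, st, mk))
        reports[[mk]] <- evaluate_marker(sc, lab, orients[[mk]],
                                         B = config$bootstrap_B, seed = sd_seed)
      }
      yis <- vapply(reports, function(r) r$yi, numeric(1))
      results[[key]] <- list(stratum = st, criterion = crit,
                             n_pos = sum(lab), n_neg = sum(!lab),
                             evaluable = TRUE, reports = reports,
                             best_marker = names(which.max(yis)),
                             scores = panel[in_st, config$markers, drop = FALSE],
                             labels = lab)
    }
  }

  run <- structure(list(filter_log = flt$log, cohort = kept, panel = panel,
                        labels = labels, results = results, config = config),
                   class = "mets_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

# ---- rendering ---------------------------------------------------------

.fmt_ci <- function(x, digits) {
  sprintf(paste0("(%.", digits, "f\u2013%.", digits, "f)"), x[1], x[2])
}

.report_row <- function(mk, r) {
  dir <- if (r$orientation == "higher_is_positive") "\u2265" else "\u2264"
  data.frame(
    `Index` = mk,
    `Cut-Off Point` = sprintf("%s%.2f", dir, r$cutoff),
    `AUC(95% CI)` = sprintf("%.3f %s", r$auc,
                            if (all(is.na(r$auc_ci))) "(NA)" else .fmt_ci(r$auc_ci, 3)),
    `Se (%)` = sprintf("%.1f %s", r$se, .fmt_ci(r$se_ci, 1)),
    `Sp (%)` = sprintf("%.1f %s", r$sp, .fmt_ci(r$sp_ci, 1)),
    `PPV (%)` = sprintf("%.1f %s", r$ppv, .fmt_ci(r$ppv_ci, 1)),
    `NPV (%)` = sprintf("%.1f %s", r$npv, .fmt_ci(r$npv_ci, 1)),
    `LRP` = sprintf("%.2f %s", r$lrp, .fmt_ci(r$lrp_ci, 2)),
    `LRN` = sprintf("%.2f %s", r$lrn, .fmt_ci(r$lrn_ci, 2)),
    `Youden Index` = sprintf("%.1f %s", r$yi,
                             if (all(is.na(r$yi_ci))) "(NA)" else .fmt_ci(r$yi_ci, 1)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

#' Render per-stratum accuracy tables
#'
#' One table per (criterion, stratum), rows sorted by descending Youden
#' index, with the canonical ten-column header.
#'
#' @param run A `"mets_run"` from [run_pipeline()].
#' @param dir Output directory (created if needed); `NULL` returns the
#'   tables without writing.
#' @param fmt `"csv"` or `"markdown"`.
#' @return Named list of data.frames, invisibly when writing.
#' @export
render_tables <- function(run, dir = NULL, fmt = c("csv", "markdown")) {
  stopifnot(inherits(run, "mets_run"))
  fmt <- match.arg(fmt)
  tables <- list()
  for (res in run$results) {
    if (!res$evaluable) next
    rows <- do.call(rbind, lapply(names(res$reports), function(mk)
      .report_row(mk, res$reports[[mk]])))
    yis <- vapply(res$reports, function(r) r$yi, numeric(1))
    rows <- rows[order(-yis), , drop = FALSE]
    rownames(rows) <- NULL
    tables[[paste(res$criterion, res$stratum, sep = " | ")]] <- rows
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (key in names(tables)) {
      slug <- gsub("[^A-Za-z0-9]+", "_", tolower(key))
      if (fmt == "csv") {
        utils::write.csv(tables[[key]], file.path(dir, paste0(slug, ".csv")),
                         row.names = FALSE, fileEncoding = "UTF-8")
      } else {
        tb <- tables[[key]]
        lines <- c(paste0("| ", paste(names(tb), collapse = " | "), " |"),
                   paste0("|", paste(rep("---", ncol(tb)), collapse = "|"), "|"),
                   apply(tb, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
        writeLines(lines, file.path(dir, paste0(slug, ".md")), useBytes = TRUE)
      }
    }
    return(invisible(tables))
  }
  tables
}

#' Compare AUCs of the leading markers in a stratum
#'
#' Applies the paired-bootstrap correlated-AUC test to marker pairs within
#' one (stratum, criterion) result.  By default the pairs are the three
#' consecutive pairs among the top three markers by Youden index (the
#' usual reporting pattern); `pairs = "all"` compares every pair.
#'
#' @param result One entry of `run$results` from [run_pipeline()].
#' @param pairs `NULL` (top-3 pattern), `"all"`, or a list of
#'   length-2 character vectors of marker ids.
#' @param B Bootstrap replicates.
#' @param seed Integer seed.
#' @return data.frame with `marker_a`, `marker_b`, `delta_auc`, `p_value`.
#' @export
compare_best_markers <- function(result, pairs = NULL, B = 2000, seed = NULL) {
  if (!isTRUE(result$evaluable)) stop("stratum is not evaluable")
  orients <- marker_orientations()
  if (is.null(pairs)) {
    yis <- vapply(result$reports, function(r) r$yi, numeric(1))
    top <- names(sort(yis, decreasing = TRUE))[seq_len(min(3, length(yis)))]
    pairs <- utils::combn(top, 2, simplify = FALSE)
  } else if (identical(pairs, "all")) {
    pairs <- utils::combn(names(result$reports), 2, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    if (!all(pr %in% names(result$scores)))
      stop("marker not present in result: ", paste(setdiff(pr, names(result$scores)), collapse = ", "))
    sd_pair <- if (is.null(seed)) NULL else derive_seed(seed, paste(pr, collapse = " vs "))
    cmp <- compare_auc_paired_bootstrap(result$scores[[pr[1]]], result$scores[[pr[2]]],
                                        result$labels,
                                        orientations = c(orients[[pr[1]]], orients[[pr[2]]]),
                                        B = B, seed = sd_pair)
    data.frame(marker_a = pr[1], marker_b = pr[2],
               delta_auc = cmp$delta_auc, p_value = cmp$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- persistence -------------------------------------------------------

.accuracy_as_list <- function(r) {
  lapply(unclass(r)[c("orientation", "n_pos", "n_neg", "cutoff", "auc",
                      "auc_ci", "se", "se_ci", "sp", "sp_ci", "ppv", "ppv_ci",
                      "npv", "npv_ci", "lrp", "lrp_ci", "lrn", "lrn_ci",
                      "yi", "yi_ci")], identity)
}

#' Write run artifacts to a directory
#'
#' Emits the filter log (JSON), the kept cohort, marker panel and label
#' CSVs, rendered tables, and a machine-readable `results.json`.
#'
#' @param run A `"mets_run"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_filter_log(run$filter_log, file.path(dir, "filter_log.json"))
  utils::write.csv(run$cohort, file.path(dir, "cohort_kept.csv"), row.names = FALSE)
  utils::write.csv(run$panel, file.path(dir, "markers.csv"), row.names = FALSE)
  utils::write.csv(run$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  render_tables(run, file.path(dir, "tables"))
  res <- lapply(run$results, function(r) {
    out <- r[c("stratum", "criterion", "n_pos", "n_neg", "evaluable", "best_marker")]
    out$reports <- lapply(r$reports, .accuracy_as_list)
    out
  })
  jsonlite::write_json(res, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(dir)
}
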