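#' Read and validate a cohort CSV
#'
#' Parses one row per patient-timepoint. Required columns: `patient_id`,
#' `timepoint` (admission/discharge), the ten `asgo_*` selection columns
#' (levels, multi-select entries separated by `|`) and the ten `bi_*`
#' Barthel item columns; demographic columns are carried through if
#' present. Rows failing instrument validation are rejected with
#' row-numbered diagnostics (reported via a warning and the `rejected`
#' element); patients lacking one of the two timepoints are listed as
#' unpaired and excluded from paired statistics. A malformed header or a
#' duplicated patient-timepoint is an error.
#'
#' @param path CSV file path.
#' @param instrument The `asgo_instrument` rows are validated against.
#' @return Object of class `paired_cohort`: `assessments` (data frame of
#'   valid rows with parsed `raw_score`, `fd_index`, `bi_total` and the ten
#'   per-variable item values), `paired_ids`, `unpaired` (data frame),
#'   `rejected` (data frame of row numbers and messages), `instrument`.
#' @export
read_cohort <- function(path, instrument = asgo_instrument()) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  asgo_cols <- paste0("asgo_", asgo_variable_names(instrument))
  bi_cols <- paste0("bi_", names(barthel_items()))
  required <- c("patient_id", "timepoint", asgo_cols, bi_cols)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("malformed header: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (!all(df$timepoint %in% c("admission", "discharge")))
    stop("timepoint must be 'admission' or 'discharge'")
  key <- paste(df$patient_id, df$timepoint)
  if (any(duplicated(key)))
    stop("duplicate patient-timepoint row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  parse_row <- function(i) {
    sel <- lapply(df[i, asgo_cols], function(s)
      as.integer(strsplit(as.character(s), "|", fixed = TRUE)[[1]]))
    names(sel) <- asgo_variable_names(instrument)
    a <- asgo_assessment(sel, timepoint = df$timepoint[i],
                         instrument = instrument)
    bi <- as.numeric(df[i, bi_cols])
    names(bi) <- names(barthel_items())
    b <- barthel_assessment(bi)
    res <- score_asgo(a, instrument)
    c(list(raw_score = res$raw_score, fd_index = res$fd_index,
           bi_total = score_barthel(b)),
      as.list(res$per_variable))
  }
  parsed <- vector("list", nrow(df))
  rejected <- data.frame(row = integer(), message = character())
  for (i in seq_len(nrow(df))) {
    parsed[[i]] <- tryCatch(parse_row(i), error = function(e) {
      rejected <<- rbind(rejected,
                         data.frame(row = i, message = conditionMessage(e)))
      NULL
    })
  }
  ok <- !vapply(parsed, is.null, logical(1))
  if (any(!ok))
    warning(sum(!ok), " row(s) rejected by instrument validation; ",
            "see the 'rejected' element for row-numbered diagnostics")
  vals <- do.call(rbind, lapply(parsed[ok], function(x)
    as.data.frame(x, check.names = FALSE)))
  names(vals)[-(1:3)] <- paste0("iv_", asgo_variable_names(instrument))
  out <- cbind(df[ok, setdiff(names(df), c(asgo_cols, bi_cols)),
                  drop = FALSE],
               df[ok, c(asgo_cols, bi_cols)], vals)
  rownames(out) <- NULL
  tab <- table(out$patient_id)
  paired_ids <- names(tab)[tab == 2L]
  unpaired <- out[!(out$patient_id %in% paired_ids),
                  c("patient_id", "timepoint")]
  rownames(unpaired) <- NULL
  structure(list(assessments = out, paired_ids = paired_ids,
                 unpaired = unpaired, rejected = rejected,
                 instrument = instrument),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat("cohort:", nrow(x$assessments), "valid assessment rows,",
      length(x$paired_ids), "paired patients,",
      nrow(x$unpaired), "unpaired rows,",
      nrow(x$rejected), "rejected rows\n")
  invisible(x)
}

#' Per-variable ASGO item matrix from cohort rows
#'
#' Builds the n x 10 matrix that feeds Cronbach's alpha and the factor
#' analysis: each cell is the variable's summed selected ranking values
#' (`values = "weighted"`, default) or summed raw levels
#' (`values = "levels"`).
#'
#' @param df Data frame of cohort rows holding the `asgo_*` selection
#'   columns.
#' @param instrument The instrument definition.
#' @param values `"weighted"` or `"levels"`.
#' @return Numeric matrix with one column per ASGO variable.
#' @export
asgo_item_matrix <- function(df, instrument = asgo_instrument(),
                             values = c("weighted", "levels")) {
  values <- match.arg(values)
  vars <- instrument$variables
  out <- sapply(names(vars), function(nm) {
    col <- df[[paste0("asgo_", nm)]]
    m <- vars[[nm]]$modalities
    vapply(col, function(s) {
      lv <- as.integer(strsplit(as.character(s), "|", fixed = TRUE)[[1]])
      if (values == "weighted") sum(m$ranking_value[match(lv, m$level)])
      else sum(lv)
    }, numeric(1), USE.NAMES = FALSE)
  })
  colnames(out) <- names(vars)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full instrument-validation analysis
#'
#' Replicates the study pipeline on a parsed cohort: per timepoint (paired
#' patients only) the ASGO/Barthel descriptives, Spearman correlation,
#' Cronbach's alpha, ROC curve with AUC, Youden-optimal cut-off, and the
#' confusion table with sensitivity/specificity at the working cut-off;
#' plus a cohort-level factor block (KMO, Bartlett's sphericity,
#' eigenvalue table, varimax-rotated loadings with dominant-factor flags).
#' Descriptives are also reported for all assessed rows (including
#' unpaired ones) when those differ from the paired subset.
#'
#' @param cohort A `paired_cohort` from [read_cohort()], or an
#'   `asgo_cohort` from [generate_cohort()] (converted internally).
#' @param cutoff Fixed ASGO dependence cut-off; `NULL` (default) uses the
#'   Youden-optimal cut-off per timepoint.
#' @param efa_timepoint Which assessments feed the factor analysis:
#'   `"admission"` (default), `"discharge"` or `"pooled"`.
#' @param item_values Item matrix entries for alpha/EFA: `"weighted"`
#'   summed ranking values (default) or `"levels"`.
#' @param placement ROC threshold placement, see [roc_curve()].
#' @return Object of class `validation_report`.
#' @export
run_validation <- function(cohort, cutoff = NULL,
                           efa_timepoint = c("admission", "discharge",
                                             "pooled"),
                           item_values = c("weighted", "levels"),
                           placement = c("unique", "midpoint")) {
  efa_timepoint <- match.arg(efa_timepoint)
  item_values <- match.arg(item_values)
  placement <- match.arg(placement)
  if (inherits(cohort, "asgo_cohort")) {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp))
    write_cohort(cohort, tmp)
    cohort <- read_cohort(tmp)
  }
  stopifnot(inherits(cohort, "paired_cohort"))
  rows <- cohort$assessments
  if (length(cohort$paired_ids) < 2L)
    stop("need at least 2 paired records")
  paired <- rows[rows$patient_id %in% cohort$paired_ids, ]
  tp_block <- function(tp) {
    sub <- paired[paired$timepoint == tp, ]
    all_sub <- rows[rows$timepoint == tp, ]
    desc <- function(d) list(
      n = nrow(d),
      asgo_mean = mean(d$raw_score), asgo_sd = stats::sd(d$raw_score),
      asgo_min = min(d$raw_score), asgo_max = max(d$raw_score),
      barthel_mean = mean(d$bi_total), barthel_sd = stats::sd(d$bi_total))
    sp <- spearman_rho(sub$raw_score, sub$bi_total)
    iv <- as.matrix(sub[, paste0("iv_", asgo_variable_names(cohort$instrument))])
    if (item_values == "levels")
      iv <- asgo_item_matrix(sub, cohort$instrument, values = "levels")
    alpha <- cronbach_alpha(iv)
    dependent <- sub$bi_total < 60
    block <- list(timepoint = tp, descriptives_paired = desc(sub),
                  descriptives_all = desc(all_sub),
                  spearman = sp[c("rho", "p_value", "n")],
                  cronbach_alpha = alpha$alpha)
    if (all(dependent) || !any(dependent)) {
      block$roc <- "unavailable"
      block$cutoff <- "unavailable"
      return(block)
    }
    curve <- roc_curve(sub$raw_score, dependent, placement = placement)
    yj <- youden_cutoff(curve)
    cut_used <- cutoff %||% yj$cutoff
    pred <- unclass(classify_asgo(sub$raw_score, cut_used)) == "dependence"
    tab <- confusion_table(predicted = as.logical(pred), truth = dependent)
    ss <- sensitivity_specificity(tab)
    block$roc <- as.data.frame(curve)
    block$auc <- auc(curve)
    block$youden <- yj
    block$cutoff <- list(cutoff_used = cut_used,
                         source = if (is.null(cutoff)) "youden" else "fixed",
                         confusion = tab[c("tp", "fp", "fn", "tn")],
                         sensitivity = ss$sensitivity,
                         specificity = ss$specificity)
    block
  }
  efa_rows <- if (efa_timepoint == "pooled") rows
              else rows[rows$timepoint == efa_timepoint, ]
  factor_block <- tryCatch({
    iv <- as.matrix(efa_rows[, paste0("iv_",
                                      asgo_variable_names(cohort$instrument))])
    if (item_values == "levels")
      iv <- asgo_item_matrix(efa_rows, cohort$instrument, values = "levels")
    colnames(iv) <- asgo_variable_names(cohort$instrument)
    R <- stats::cor(iv)
    fs <- pca_efa(iv)
    rot <- fs$rotated
    dominant <- if (ncol(rot) >= 2L) apply(abs(rot), 1L, which.max)
                else rep(1L, nrow(rot))
    list(
      efa_timepoint = efa_timepoint, n = nrow(iv), item_values = item_values,
      kmo = kmo(R),
      bartlett = bartlett_sphericity(R, nrow(iv)),
      eigen_table = data.frame(component = seq_len(fs$p),
                               eigenvalue = fs$eigenvalues,
                               pct_variance = fs$variance_pct,
                               cumulative_pct = fs$cumulative_pct),
      n_retained = fs$n_retained,
      rotated_loadings = data.frame(variable = rownames(rot),
                                    as.data.frame(rot),
                                    dominant_factor = dominant))
  }, error = function(e)
    paste("unavailable:", conditionMessage(e)))
  structure(list(
    header = list(tool = "asgo validation pipeline",
                  n_rows = nrow(rows),
                  n_paired = length(cohort$paired_ids),
                  n_unpaired = nrow(cohort$unpaired),
                  n_rejected = nrow(cohort$rejected),
                  cutoff = if (is.null(cutoff)) "youden" else cutoff,
                  efa_timepoint = efa_timepoint,
                  item_values = item_values, placement = placement),
    admission = tp_block("admission"),
    discharge = tp_block("discharge"),
    factor_structure = factor_block), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("ASGO validation report:", x$header$n_paired, "paired patients\n")
  for (tp in c("admission", "discharge")) {
    b <- x[[tp]]
    cat(sprintf("  %-9s rho %.2f  alpha %.2f", tp,
                b$spearman$rho, b$cronbach_alpha))
    if (!identical(b$roc, "unavailable"))
      cat(sprintf("  AUC %.2f  cut-off %.2f (sens %.2f, spec %.2f)",
                  b$auc, b$cutoff$cutoff_used, b$cutoff$sensitivity,
                  b$cutoff$specificity))
    cat("\n")
  }
  fb <- x$factor_structure
  if (is.character(fb)) cat("  factor block:", fb, "\n")
  else cat(sprintf("  factors: KMO %.2f, Bartlett chi2 %.1f (df %d), %d retained\n",
                   fb$kmo, fb$bartlett$chi2, fb$bartlett$df, fb$n_retained))
  invisible(x)
}

# round all numerics in a nested structure to 6 significant digits so the
# rendered JSON is byte-stable; infinite sentinels (the +Inf ROC threshold)
# become NA and are written as JSON null
.signif6 <- function(x) {
  num <- function(v) { v <- signif(v, 6); v[is.infinite(v)] <- NA; v }
  if (is.list(x)) {
    if (is.data.frame(x)) {
      x[] <- lapply(x, function(col) if (is.numeric(col)) num(col) else col)
      x
    } else lapply(x, .signif6)
  } else if (is.numeric(x)) num(x) else x
}

#' Render a validation report to files
#'
#' Writes `report.json` (machine-readable, numerics fixed at 6 significant
#' digits so identical inputs give byte-identical output), `report.md`
#' (human-readable tables mirroring the study's correlation, reliability,
#' cut-off, eigenvalue and loading tables) and one `roc_<timepoint>.csv`
#' per available ROC curve. Blocks that could not be computed are rendered
#' with an explicit "unavailable" marker.
#'
#' @param report A `validation_report`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("json", "markdown", "csv")`.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, dir,
                          formats = c("json", "markdown", "csv")) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if ("json" %in% formats) {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(.signif6(unclass(report)), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    written <- c(written, path)
  }
  if ("csv" %in% formats) {
    for (tp in c("admission", "discharge")) {
      if (identical(report[[tp]]$roc, "unavailable")) next
      path <- file.path(dir, paste0("roc_", tp, ".csv"))
      utils::write.csv(.signif6(report[[tp]]$roc), path, row.names = FALSE)
      written <- c(written, path)
    }
    if (!is.character(report$factor_structure)) {
      path <- file.path(dir, "loadings.csv")
      utils::write.csv(.signif6(report$factor_structure$rotated_loadings),
                       path, row.names = FALSE)
      written <- c(written, path)
    }
  }
  if ("markdown" %in% formats) {
    path <- file.path(dir, "report.md")
    writeLines(.report_markdown(report), path)
    written <- c(written, path)
  }
  invisible(written)
}

.report_markdown <- function(report) {
  f1 <- function(x) sprintf("%.1f", x)
  f2 <- function(x) sprintf("%.2f", x)
  lines <- c("# ASGO validation report", "",
             sprintf("- paired patients: %d (of %d assessment rows; %d unpaired, %d rejected)",
                     report$header$n_paired, report$header$n_rows,
                     report$header$n_unpaired, report$header$n_rejected),
             sprintf("- cut-off rule: %s; EFA timepoint: %s; item values: %s",
                     paste(report$header$cutoff, collapse = ""),
                     report$header$efa_timepoint, report$header$item_values),
             "", "## Correlation and descriptives (paired)", "",
             "| Timing | ASGO mean (SD) | Barthel mean (SD) | Spearman rho | p |",
             "|---|---|---|---|---|")
  for (tp in c("admission", "discharge")) {
    b <- report[[tp]]; d <- b$descriptives_paired
    lines <- c(lines, sprintf(
      "| %s | %s (%s) | %s (%s) | %s | %.3g |", tp,
      f1(d$asgo_mean), f1(d$asgo_sd), f1(d$barthel_mean), f1(d$barthel_sd),
      f2(b$spearman$rho), b$spearman$p_value))
  }
  lines <- c(lines, "", "## Reliability", "",
             "| Timing | Score range | Cronbach alpha |", "|---|---|---|")
  for (tp in c("admission", "discharge")) {
    b <- report[[tp]]; d <- b$descriptives_paired
    lines <- c(lines, sprintf("| %s | %s-%s | %s |", tp,
                              f1(d$asgo_min), f1(d$asgo_max),
                              f2(b$cronbach_alpha)))
  }
  lines <- c(lines, "", "## Dependence classification", "")
  for (tp in c("admission", "discharge")) {
    b <- report[[tp]]
    if (identical(b$roc, "unavailable")) {
      lines <- c(lines, sprintf("- %s: ROC/cut-off block unavailable (single truth class)", tp))
      next
    }
    ct <- b$cutoff$confusion
    lines <- c(lines,
      sprintf("### %s (ASGO >= %s is dependence; Barthel < 60 is dependence)",
              tp, f2(b$cutoff$cutoff_used)), "",
      "| | BI dependence | BI independence |", "|---|---|---|",
      sprintf("| ASGO dependence | %d | %d |", ct$tp, ct$fp),
      sprintf("| ASGO independence | %d | %d |", ct$fn, ct$tn), "",
      sprintf("sensitivity %s, specificity %s, Youden J %s, AUC %s",
              f2(b$cutoff$sensitivity), f2(b$cutoff$specificity),
              f2(b$youden$J), f2(b$auc)), "")
  }
  fb <- report$factor_structure
  if (is.character(fb))
    return(c(lines, "## Factor structure", "", paste("-", fb)))
  lines <- c(lines, "## Factor structure", "",
             sprintf("- EFA on %s assessments (n = %d): KMO %s, Bartlett chi2 %s (df %d, p %.3g); %d factor(s) retained",
                     fb$efa_timepoint, fb$n, f2(fb$kmo),
                     f1(fb$bartlett$chi2), fb$bartlett$df,
                     fb$bartlett$p_value, fb$n_retained), "",
             "| Component | Eigenvalue | % variance | Cumulative % |",
             "|---|---|---|---|")
  et <- fb$eigen_table
  for (i in seq_len(nrow(et)))
    lines <- c(lines, sprintf("| %d | %s | %s | %s |", et$component[i],
                              f2(et$eigenvalue[i]), f2(et$pct_variance[i]),
                              f2(et$cumulative_pct[i])))
  rl <- fb$rotated_loadings
  kcols <- setdiff(names(rl), c("variable", "dominant_factor"))
  lines <- c(lines, "",
             paste0("| ", paste(c("Item", kcols, "dominant"), collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(kcols) + 2), collapse = "|"), "|"))
  for (i in seq_len(nrow(rl)))
    lines <- c(lines, paste0("| ", rl$variable[i], " | ",
                             paste(f2(as.numeric(rl[i, kcols])), collapse = " | "),
                             " | ", rl$dominant_factor[i], " |"))
  lines
}
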