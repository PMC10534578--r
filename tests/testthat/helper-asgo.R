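# shared fixtures and independent oracles

instr <- asgo_instrument()

# assessment with every variable at a given level index (1 = first modality)
uniform_selections <- function(idx = 1L) {
  lapply(instr$variables, function(v) v$modalities$level[[idx]])
}

# pairwise Mann-Whitney AUC oracle: concordant pairs + half ties
mw_auc <- function(scores, dependent) {
  pos <- scores[dependent]; neg <- scores[!dependent]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive Youden scan over every unique score threshold (plus +Inf)
scan_youden <- function(scores, dependent) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  J <- vapply(thr, function(t) {
    sens <- sum(scores >= t & dependent) / sum(dependent)
    spec <- sum(scores < t & !dependent) / sum(!dependent)
    sens + spec - 1
  }, numeric(1))
  best <- max(J)
  cand <- thr[J >= best - 1e-12]
  list(J = best, cutoff = min(cand[is.finite(cand)], na.rm = TRUE))
}

# a tiny well-formed cohort data frame (n patients, both timepoints):
# every ASGO variable sits at level 1 + (i + discharge) mod 3 and each
# Barthel item at its (same index)-th allowed value, so totals cycle 0/50/90
tiny_cohort_df <- function(n = 3) {
  items <- barthel_items()
  rows <- list()
  for (i in seq_len(n)) for (tp in c("admission", "discharge")) {
    f <- (i + (tp == "discharge")) %% 3L
    asgo <- setNames(as.list(rep(as.character(1L + f), 10)),
                     paste0("asgo_", names(instr$variables)))
    bi <- setNames(lapply(items, function(a) a[min(f + 1L, length(a))]),
                   paste0("bi_", names(items)))
    rows[[length(rows) + 1]] <- c(list(patient_id = sprintf("P%02d", i),
                                       timepoint = tp), asgo, bi)
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}

# Table-6-style printed eigenvalue sequence
printed_eigenvalues <- c(3.86, 1.08, 0.96, 0.76, 0.72, 0.66, 0.56, 0.52,
                         0.48, 0.35)
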