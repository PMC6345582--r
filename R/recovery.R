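## Parameter-recovery report: compares pipeline outputs against the planted
## ground truth of a synthetic dataset.

.jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NaN)
  sum(a & b) / u
}

## Greedy one-to-one match of truth templates to recovered features
## (exact assignment via match_features when the counts agree).
.match_to_truth <- function(features, truth_templates) {
  kt <- nrow(truth_templates)
  if (nrow(features) == kt) {
    m <- match_features(truth_templates, features)
    return(list(assignment = m$assignment, cosine = m$cosine))
  }
  tn <- truth_templates / pmax(sqrt(rowSums(truth_templates^2)), .Machine$double.eps)
  fn <- features / pmax(sqrt(rowSums(features^2)), .Machine$double.eps)
  sim <- tn %*% t(fn)
  assignment <- integer(kt); cosine <- numeric(kt)
  avail <- rep(TRUE, nrow(features))
  for (i in order(apply(sim, 1, max), decreasing = TRUE)) {
    j <- which(avail)[which.max(sim[i, avail])]
    assignment[i] <- j; cosine[i] <- sim[i, j]; avail[j] <- FALSE
    if (!any(avail)) break
  }
  list(assignment = assignment, cosine = cosine)
}

#' Parameter-recovery report for a synthetic dataset
#'
#' Scores every pipeline stage against the planted truth: Jaccard overlap of
#' significant diagnostic pixels with the planted template supports (plus
#' per-template recall), cosine similarity of matched recovered brain
#' features, agreement of the diagnostic/nondiagnostic classification,
#' junction-time error, the complexity-peak window, and (when provided)
#' decision-specific redundancy selectivity. Chance-level recoveries (as from
#' a shuffled-decision negative control) are flagged.
#'
#' @param dataset A `sir_dataset`.
#' @param outputs Named list of stage outputs: `diag_nuns`, `diag_voltaire`
#'   ([diagnostic_map()]), `basis` ([nmf_basis()]), `labels`
#'   ([classify_features()]), `junction` ([junction()]), `complexity`
#'   ([representational_complexity()]); optionally `red_nuns`, `red_voltaire`
#'   ([decision_specific_redundancy()]).
#' @return Object of class `sir_recovery` with the metrics above.
#' @export
recovery_report <- function(dataset, outputs) {
  stopifnot(inherits(dataset, "sir_dataset"))
  required <- c("diag_nuns", "diag_voltaire", "basis", "labels", "junction",
                "complexity")
  missing <- setdiff(required, names(outputs))
  if (length(missing))
    stop("missing stage output: ", paste(missing, collapse = ", "))
  truth <- dataset$truth
  meta <- truth$feature_meta
  supports <- truth$templates > 0

  ## diagnostic-map recovery
  diag_metrics <- lapply(c(nuns = "nuns", voltaire = "voltaire"), function(p) {
    map <- outputs[[paste0("diag_", p)]]
    sig <- as.vector(map$significant)
    ids <- which(meta$percept %in% p)
    union_supp <- colSums(supports[ids, , drop = FALSE]) > 0
    recall <- vapply(ids, function(i) {
      ns <- sum(supports[i, ])
      if (ns == 0) NaN else sum(sig & supports[i, ]) / ns
    }, numeric(1))
    names(recall) <- meta$feature[ids]
    list(jaccard = .jaccard(sig, union_supp), recall = recall)
  })

  ## brain-feature recovery
  basis <- outputs$basis
  m <- .match_to_truth(basis$features, truth$templates)
  labels <- outputs$labels
  matched_labels <- as.character(labels[m$assignment])
  diag_ok <- meta$diagnostic &
    matched_labels %in% c("diagnostic_nuns", "diagnostic_voltaire")
  nondiag_ok <- !meta$diagnostic & matched_labels == "nondiagnostic"
  label_agreement <- c(
    diagnostic = mean(diag_ok[meta$diagnostic]),
    nondiagnostic = mean(nondiag_ok[!meta$diagnostic]))

  ## dynamics and complexity
  junction_error <- abs(outputs$junction$marker_ms - truth$junction_ms)
  ctot <- colSums(outputs$complexity$counts)
  peak_window <- if (all(ctot == 0)) NA_integer_ else which.max(ctot)

  ## decision-specific redundancy selectivity
  selectivity <- NULL
  if (all(c("red_nuns", "red_voltaire") %in% names(outputs))) {
    sel_one <- function(red, percept) {
      ids_own <- which(meta$percept[red$features] %in% percept)
      ids_other <- which(meta$percept[red$features] %in%
                           setdiff(c("nuns", "voltaire"), percept))
      own <- sum(red$significant[ids_own, , , drop = FALSE])
      oth <- sum(red$significant[ids_other, , , drop = FALSE])
      if (own + oth == 0) NaN else own / (own + oth)
    }
    selectivity <- c(nuns = sel_one(outputs$red_nuns, "nuns"),
                     voltaire = sel_one(outputs$red_voltaire, "voltaire"))
  }

  flags <- character(0)
  if (all(vapply(diag_metrics, function(z) is.nan(z$jaccard) || z$jaccard < 0.05,
                 logical(1))))
    flags <- c(flags, "diagnostic maps at chance level")
  if (stats::median(m$cosine) < 0.3)
    flags <- c(flags, "brain-feature recovery at chance level")

  structure(list(
    template_jaccard = vapply(diag_metrics, `[[`, numeric(1), "jaccard"),
    template_recall = lapply(diag_metrics, `[[`, "recall"),
    feature_cosine = m$cosine, feature_assignment = m$assignment,
    label_agreement = label_agreement,
    junction_error_ms = junction_error,
    complexity_peak_window = peak_window,
    complexity_peak_truth = truth$complexity_peak_window,
    selectivity = selectivity, flags = flags),
    class = "sir_recovery")
}

#' @export
print.sir_recovery <- function(x, ...) {
  cat("Recovery report\n")
  cat(sprintf("  template Jaccard: nuns %.3f, voltaire %.3f\n",
              x$template_jaccard["nuns"], x$template_jaccard["voltaire"]))
  cat(sprintf("  feature cosines (matched): %s (median %.3f)\n",
              paste(sprintf("%.2f", x$feature_cosine), collapse = " "),
              stats::median(x$feature_cosine)))
  cat(sprintf("  label agreement: diagnostic %.2f, nondiagnostic %.2f\n",
              x$label_agreement["diagnostic"], x$label_agreement["nondiagnostic"]))
  cat(sprintf("  junction error: %.1f ms; complexity peak window %s (planted %d)\n",
              x$junction_error_ms, x$complexity_peak_window,
              x$complexity_peak_truth))
  if (!is.null(x$selectivity))
    cat(sprintf("  decision-specific selectivity: nuns %.2f, voltaire %.2f\n",
                x$selectivity["nuns"], x$selectivity["voltaire"]))
  if (length(x$flags)) cat("  FLAGS:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
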