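#' Feature-by-donor signal container
#'
#' Holds a features x donors numeric matrix together with feature intervals
#' (0-based half-open), assay/cell-type labels and a `stage` marker recording
#' where the matrix sits in the normalisation pipeline. Stages advance only in
#' the order `raw -> log2rpm -> filtered -> factor_corrected ->
#' quantile_normalised`; each transform checks the stage of its input so a
#' mis-ordered pipeline fails loudly.
#'
#' @param values Numeric matrix, features in rows, donors in columns, with
#'   dimnames.
#' @param features Tibble with `feature_id`, `chrom`, `start`, `end` and
#'   optionally `assay`, `cell_type`.
#' @param stage One of the stage labels above.
#' @param library_sizes Optional named vector of per-donor library sizes.
#' @return An object of class `signal_matrix`.
#' @export
signal_matrix <- function(values, features, stage = "raw", library_sizes = NULL) {
  stages <- signal_stages()
  stopifnot(is.matrix(values), stage %in% stages,
            !is.null(rownames(values)), !is.null(colnames(values)))
  features <- as_tibble(features)
  if (!all(rownames(values) == features$feature_id)) {
    abort_invalid("row names of `values` must match `features$feature_id`.")
  }
  if (any(features$end <= features$start)) {
    abort_invalid("feature intervals must satisfy end > start.")
  }
  if (stage != "raw" && anyNA(values)) {
    abort_invalid("normalised signal matrices must not contain NA.")
  }
  structure(
    list(values = values, features = features, donors = colnames(values),
         stage = stage, library_sizes = library_sizes),
    class = "signal_matrix"
  )
}

signal_stages <- function() {
  c("raw", "log2rpm", "filtered", "factor_corrected", "quantile_normalised")
}

check_stage <- function(signal, allowed, op) {
  if (!inherits(signal, "signal_matrix")) {
    abort_invalid(sprintf("`%s` expects a signal_matrix.", op))
  }
  if (!signal$stage %in% allowed) {
    abort_invalid(sprintf(
      "`%s` requires stage %s but got '%s' (stages advance raw -> log2rpm -> filtered -> factor_corrected -> quantile_normalised).",
      op, paste(sQuote(allowed), collapse = " or "), signal$stage))
  }
  invisible(signal)
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d features x %d donors, stage '%s'\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
tidy.signal_matrix <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "feature_id")
  tidyr::pivot_longer(long, -"feature_id",
                      names_to = "donor_id", values_to = "value")
}

#' @export
glance.signal_matrix <- function(x, ...) {
  tibble(n_features = nrow(x$values), n_donors = ncol(x$values),
         stage = x$stage,
         mean = mean(x$values), sd = sd(as.numeric(x$values)))
}
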