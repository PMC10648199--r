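#' Q measure: percentage of residues predicted correctly
#'
#' 100 * (number of correctly labelled residues) / (residues scored).  The
#' definition is independent of the alphabet size, so the same function
#' yields Q3, Q8 and Q16.
#'
#' @param truth,predicted character vectors of equal length.
#' @param alphabet optional alphabet; when given, labels are validated
#'   against it.
#' @return percentage in [0, 100].
#' @examples
#' q_measure(c("H", "H", "E", "C"), c("H", "H", "E", "E"))  # 75
#' @export
q_measure <- function(truth, predicted, alphabet = NULL) {
  if (length(truth) != length(predicted)) {
    abort("truth and predicted must have equal length")
  }
  if (!is.null(alphabet)) {
    if (!all(c(truth, predicted) %in% alphabet)) {
      abort("labels outside the declared alphabet")
    }
  }
  100 * mean(truth == predicted)
}

#' Confusion matrix with row-normalized percentages
#'
#' Rows are true classes, columns predicted classes.  `percent` holds each
#' row as percentages summing to 100; rows for classes absent from the truth
#' are flagged and excluded from the diagonal mean.
#'
#' @param truth,predicted character vectors of equal length.
#' @param alphabet class alphabet (default: sorted union of observed labels).
#' @return a `pb_confusion` object: list with `counts`, `percent`,
#'   `empty_rows`, `diagonal_mean`, `n`.  [tidy()] gives a long tibble,
#'   [autoplot()] a heatmap.
#' @export
pb_confusion <- function(truth, predicted, alphabet = NULL) {
  if (length(truth) != length(predicted)) {
    abort("truth and predicted must have equal length")
  }
  alphabet <- alphabet %||% sort(unique(c(truth, predicted)))
  if (!all(c(truth, predicted) %in% alphabet)) {
    abort("labels outside the declared alphabet")
  }
  counts <- table(factor(truth, levels = alphabet),
                  factor(predicted, levels = alphabet))
  counts <- matrix(as.integer(counts), nrow = length(alphabet),
                   dimnames = list(true = alphabet, predicted = alphabet))
  rs <- rowSums(counts)
  percent <- counts * 0
  nz <- rs > 0
  percent[nz, ] <- 100 * counts[nz, , drop = FALSE] / rs[nz]
  structure(list(
    alphabet = alphabet,
    counts = counts,
    percent = percent,
    empty_rows = alphabet[!nz],
    diagonal_mean = mean(diag(percent)[nz]),
    n = sum(counts)
  ), class = "pb_confusion")
}

#' @export
tidy.pb_confusion <- function(x, ...) {
  tibble(
    true = rep(x$alphabet, times = length(x$alphabet)),
    predicted = rep(x$alphabet, each = length(x$alphabet)),
    count = as.vector(x$counts),
    percent = as.vector(x$percent)
  )
}

#' @export
glance.pb_confusion <- function(x, ...) {
  tibble(n = x$n, q = 100 * sum(diag(x$counts)) / x$n,
         diagonal_mean = x$diagonal_mean,
         n_classes = length(x$alphabet),
         n_empty_rows = length(x$empty_rows))
}

#' @export
autoplot.pb_confusion <- function(object, ...) {
  df <- tidy.pb_confusion(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$percent)),
                       size = 2.2) +
    ggplot2::scale_fill_viridis_c(name = "% of true class") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' @export
print.pb_confusion <- function(x, ...) {
  cat("Confusion over", x$n, "residues,", length(x$alphabet), "classes; Q =",
      sprintf("%.2f%%", 100 * sum(diag(x$counts)) / x$n), "\n")
  print(round(x$percent, 1))
  invisible(x)
}

#' Correlation between observed and predicted RMSD profiles
#'
#' For each protein block, the Pearson correlation between the observed and
#' predicted RMSD-to-prototype profiles over fragment positions (profiles
#' are indexed by the fragment's central residue).  Profiles with fewer than
#' 3 positions or zero variance are flagged and get `r = NA`.
#'
#' @param observed,predicted numeric matrices (fragments x 16, columns in
#'   block order) or tibbles with `rmsd_*`/`sc_*` columns.
#' @param chain_id optional per-fragment chain ids; when given, per-chain
#'   correlations are attached as attribute `"per_chain"`.
#' @return tibble with columns `pb`, `r`, `n`, `flagged`.
#' @export
profile_correlation <- function(observed, predicted, chain_id = NULL) {
  O <- feature_matrix(observed)
  P <- feature_matrix(predicted)
  if (!all(dim(O) == dim(P))) abort("observed and predicted must have matching dimensions")
  pbs <- sub("^(rmsd_|sc_)", "", colnames(O) %||% PB_LETTERS[seq_len(ncol(O))])
  one <- function(O, P) {
    tibble(
      pb = pbs,
      r = vapply(seq_len(ncol(O)), function(j) {
        if (nrow(O) < 3 || sd(O[, j]) < 1e-12 || sd(P[, j]) < 1e-12) return(NA_real_)
        cor(O[, j], P[, j])
      }, numeric(1)),
      n = nrow(O)
    ) |> mutate(flagged = is.na(.data$r))
  }
  out <- one(O, P)
  if (!is.null(chain_id)) {
    per <- lapply(split(seq_len(nrow(O)), chain_id), function(ix) {
      one(O[ix, , drop = FALSE], P[ix, , drop = FALSE])
    })
    attr(out, "per_chain") <- bind_rows(per, .id = "chain_id")
  }
  out
}
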