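#' Configuration for stepwise feature selection
#'
#' `f_enter`/`f_remove` drive the bidirectional stepwise iteration (a
#' candidate enters when its partial F-statistic is at least `f_enter`; an
#' included feature is removed when its partial F drops below `f_remove`).
#' After the per-target runs, only features with partial F above
#' `final_f_threshold` survive, and correlated survivors (|Pearson r| >
#' `corr_threshold`) are deduplicated keeping the higher-F member.
#'
#' @param f_enter,f_remove entry/removal partial-F thresholds
#'   (`f_remove <= f_enter`).
#' @param final_f_threshold final F filter applied after selection.
#' @param corr_threshold correlation threshold in (0, 1] for deduplication.
#' @param max_features optional cap on the number of features entered per
#'   target.
#' @return a `pb_selection_config` list.
#' @export
selection_config <- function(f_enter = 4, f_remove = 3.9,
                             final_f_threshold = 100,
                             corr_threshold = 0.9, max_features = NULL) {
  if (f_remove > f_enter) abort("f_remove must not exceed f_enter")
  if (f_enter <= 0 || final_f_threshold <= 0) abort("F thresholds must be positive")
  if (corr_threshold <= 0 || corr_threshold > 1) abort("corr_threshold must be in (0, 1]")
  structure(list(f_enter = f_enter, f_remove = f_remove,
                 final_f_threshold = final_f_threshold,
                 corr_threshold = corr_threshold,
                 max_features = max_features),
            class = "pb_selection_config")
}

# partial F of each coefficient (t^2) in the OLS fit of y on X[, active]
refit_partial_f <- function(Xs, active, y) {
  A <- cbind(`(Intercept)` = 1, Xs[, active, drop = FALSE])
  fit <- stats::lm.fit(A, y)
  n <- length(y)
  p <- length(active)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p - 1)
  R <- qr.R(fit$qr)
  XtX_inv <- chol2inv(R)
  se2 <- sigma2 * diag(XtX_inv)[-1]
  (fit$coefficients[-1]^2) / se2
}

#' Stepwise regression selection with bidirectional elimination
#'
#' Greedy forward selection with backward removal, both driven by the
#' partial F-statistic of the nested-model residual-sum-of-squares
#' comparison (1 numerator degree of freedom).  At each step the candidate
#' with the largest partial F enters if it reaches `f_enter`; any included
#' feature whose partial F has fallen below `f_remove` is then removed.
#' Iteration stops at a fixed point (or at `max_features`).  Columns are
#' standardized internally so F-statistics are comparable across
#' heterogeneous transforms; constant columns are excluded with a warning
#' and candidates that are numerically collinear with the active set are
#' rejected.
#'
#' @param X numeric matrix or data frame of candidate predictors (named
#'   columns).
#' @param y numeric response (one regression target).
#' @param config a [selection_config()].
#' @return tibble with columns `feature`, `F` (final partial F in the full
#'   kept model) and `step` (entry order); attribute `"log"` records every
#'   add/remove event.
#' @export
stepwise_select <- function(X, y, config = selection_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (length(y) != n) abort("X and y must have the same number of rows")
  sds <- apply(X, 2, sd)
  const <- sds < 1e-12 | !is.finite(sds)
  if (any(const)) {
    warn(paste0("excluding constant column(s): ",
                paste(colnames(X)[const], collapse = ", ")))
    X <- X[, !const, drop = FALSE]
  }
  Xs <- scale(X)
  feat <- colnames(Xs)
  yc <- y - mean(y)
  max_feat <- config$max_features %||% ncol(Xs)

  active <- integer(0)
  Z <- Xs
  r <- yc
  log <- list()
  step <- 0L
  repeat {
    changed <- FALSE
    # ---- entry ----
    if (length(active) < max_feat && length(active) < ncol(Xs)) {
      cand <- setdiff(seq_len(ncol(Xs)), active)
      zz <- colSums(Z[, cand, drop = FALSE]^2)
      zr <- as.vector(crossprod(Z[, cand, drop = FALSE], r))
      num <- ifelse(zz > 1e-8 * n, zr^2 / zz, -Inf)
      rss0 <- sum(r^2)
      rss1 <- rss0 - num
      df <- n - length(active) - 2
      Fval <- num / (rss1 / df)
      best <- which.max(Fval)
      if (is.finite(Fval[best]) && Fval[best] >= config$f_enter && df > 1) {
        j <- cand[best]
        z <- Z[, j]
        r <- r - z * (sum(z * r) / sum(z^2))
        proj <- as.vector(crossprod(Z, z)) / sum(z^2)
        Z <- Z - outer(z, proj)
        active <- c(active, j)
        step <- step + 1L
        log[[length(log) + 1]] <- tibble(step = step, action = "add",
                                         feature = feat[j], F = Fval[best])
        changed <- TRUE
      }
    }
    # ---- removal ----
    if (length(active) > 0) {
      pf <- refit_partial_f(Xs, active, yc)
      worst <- which.min(pf)
      if (pf[worst] < config$f_remove) {
        j <- active[worst]
        active <- active[-worst]
        step <- step + 1L
        log[[length(log) + 1]] <- tibble(step = step, action = "remove",
                                         feature = feat[j], F = pf[worst])
        # rebuild working residual and candidate matrix against the new set
        if (length(active) > 0) {
          A <- cbind(1, Xs[, active, drop = FALSE])
          qa <- qr(A)
          r <- qr.resid(qa, yc)
          Z <- qr.resid(qa, Xs)
        } else {
          r <- yc
          Z <- Xs
        }
        changed <- TRUE
      }
    }
    if (!changed || step > 4L * ncol(Xs)) break
  }
  Ffinal <- if (length(active) > 0) refit_partial_f(Xs, active, yc) else numeric(0)
  entered <- bind_rows(log)
  order_in <- if (nrow(entered) > 0) {
    entered |> filter(.data$action == "add", .data$feature %in% feat[active])
  } else {
    tibble(feature = character(), step = integer())
  }
  out <- tibble(feature = feat[active], F = unname(Ffinal)) |>
    left_join(order_in |> select("feature", "step"), by = "feature")
  attr(out, "log") <- entered
  out
}

#' Merge per-target selections and deduplicate correlated features
#'
#' Takes the kept sets of all regression targets, keeps each feature's
#' maximum partial F over targets, applies the final F threshold, ranks by
#' descending F, and then greedily drops any feature whose |Pearson
#' correlation| with an already-kept, higher-ranked feature exceeds the
#' threshold (the higher-F member of each correlated pair survives).
#'
#' @param reports named list of per-target tibbles from [stepwise_select()].
#' @param X the candidate matrix the selections were run on (used for the
#'   correlation screen).
#' @param config a [selection_config()].
#' @return a `pb_selection` object: list with `kept` (ranked tibble:
#'   feature, F, target), `dropped` (feature, kept_competitor, r),
#'   `per_target`, `config`.  [tidy()] returns the kept table, [glance()]
#'   the counts.
#' @export
merge_and_dedup <- function(reports, X, config = selection_config()) {
  merged <- bind_rows(reports, .id = "target") |>
    group_by(.data$feature) |>
    slice_max(.data$F, n = 1, with_ties = FALSE) |>
    ungroup() |>
    filter(.data$F >= config$final_f_threshold) |>
    arrange(desc(.data$F))
  X <- as.matrix(X)
  kept_idx <- character(0)
  dropped <- list()
  for (i in seq_len(nrow(merged))) {
    f <- merged$feature[i]
    if (length(kept_idx) > 0) {
      rs <- suppressWarnings(abs(cor(X[, f], X[, kept_idx, drop = FALSE])))
      rs[is.na(rs)] <- 0
      hit <- which(rs > config$corr_threshold)
      if (length(hit) > 0) {
        dropped[[length(dropped) + 1]] <- tibble(
          feature = f, kept_competitor = kept_idx[hit[1]], r = rs[hit[1]]
        )
        next
      }
    }
    kept_idx <- c(kept_idx, f)
  }
  structure(list(
    kept = merged |> filter(.data$feature %in% kept_idx) |>
      select("feature", "F", "target"),
    dropped = if (length(dropped) > 0) bind_rows(dropped) else
      tibble(feature = character(), kept_competitor = character(), r = numeric()),
    per_target = reports,
    config = config
  ), class = "pb_selection")
}

#' @export
tidy.pb_selection <- function(x, ...) x$kept

#' @export
glance.pb_selection <- function(x, ...) {
  tibble(n_kept = nrow(x$kept), n_dropped_correlated = nrow(x$dropped),
         n_targets = length(x$per_target))
}

#' @export
print.pb_selection <- function(x, ...) {
  cat("Stepwise selection: ", nrow(x$kept), " features kept (F >= ",
      x$config$final_f_threshold, "), ", nrow(x$dropped),
      " dropped as correlated duplicates\n", sep = "")
  print(head(x$kept, 10))
  invisible(x)
}
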