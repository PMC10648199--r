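#' Coarse mapping from protein blocks to three secondary-structure states
#'
#' Blocks covering the central helix ('l', 'm', 'n') map to H, the extended
#' strand core ('c', 'd', 'e') to E, everything else to C.  Used to derive
#' demonstration labels for the one-hot classification mode of the pipeline;
#' it is a coarse correspondence, not a DSSP re-implementation.
#'
#' @param pb character vector of block letters.
#' @return character vector of H/E/C labels.
#' @export
pb_to_ss3 <- function(pb) {
  out <- rep("C", length(pb))
  out[pb %in% c("l", "m", "n")] <- "H"
  out[pb %in% c("c", "d", "e")] <- "E"
  out[is.na(pb)] <- NA_character_
  out
}

#' Full sequence-to-structure prediction pipeline
#'
#' Runs the complete workflow on a set of backbone chains: fragment
#' extraction, RMSD assignment (observed structural coordinates and labels),
#' leakage-free 6:3:1 chain-level split, occurrence statistics from the
#' training split only, candidate feature generation, per-target stepwise
#' F-selection with correlation deduplication at the fragment level,
#' expansion of the selected set over the 9-residue view field (selected x 5
#' network inputs), network training, and Q/confusion/profile evaluation on
#' all three splits.
#'
#' Occurrence statistics for the training rows are cross-fitted: the
#' training chains are divided into `occ_folds` folds and each fold's
#' features use the occurrence tables of the other folds, so the selection
#' F-statistics and the network see occurrence features with the same
#' out-of-table behaviour they have on held-out chains.  Held-out features
#' (and the deployed model) use tables built from the full training split.
#'
#' The plateau rule of the optimizer monitors the test split and the
#' validation split is reserved for reporting, matching the naming used
#' throughout the package.  If no feature survives the final F filter the
#' pipeline falls back to an intercept-only constant predictor (no signal,
#' no skill).
#'
#' @param chains residue tibble ([read_structure()] /
#'   [generate_dataset()] shape).
#' @param task `"structural_coordinates"` (16 RMSD outputs, Q16 by argmin)
#'   or `"one_hot"` (classification over `label_col` classes by argmax).
#' @param label_col for `one_hot`: name of a per-residue label column of
#'   `chains` (e.g. a DSSP track); fragment labels are taken at the central
#'   residue.
#' @param ratio,seed chain-split ratio and seed (also seeds selection
#'   subsampling, cross-fitting folds and training).
#' @param registry,scales feature configuration.
#' @param selection a [selection_config()].
#' @param hidden hidden-layer widths of the network (desk-scale default).
#' @param schedule a [training_schedule()]; its seed is overridden by
#'   `seed`.
#' @param selection_rows training rows subsampled for the stepwise phase
#'   (the F filter is computed on this subsample; selection cost grows
#'   linearly in rows).
#' @param occ_folds cross-fitting folds for training-row occurrence
#'   features (2 by default; 1 disables cross-fitting).
#' @param prototypes block prototypes.
#' @return a `pb_pipeline_fit` list: `split`, `occurrence`, `selection`,
#'   `model`, `metrics` (per-split tibble), `predictions`, `confusions`,
#'   `profile` (per-split correlation tables).  [glance()] gives one row of
#'   headline accuracies; [tidy()] the per-split metric table.
#' @export
pb_pipeline <- function(chains,
                        task = c("structural_coordinates", "one_hot"),
                        label_col = NULL,
                        ratio = c(6, 3, 1), seed = 1,
                        registry = feature_registry(),
                        scales = aa_scales(),
                        selection = selection_config(),
                        hidden = c(128, 96, 64, 48),
                        schedule = training_schedule(max_epochs = 600,
                                                     batch_size = 512,
                                                     patience = 12,
                                                     min_delta = 1e-5),
                        selection_rows = 8000,
                        occ_folds = 2,
                        prototypes = pb_prototypes()) {
  task <- match.arg(task)
  frags <- extract_fragments(chains)
  if (nrow(frags) == 0) abort("no complete fragments in the input chains")
  assigned <- assign_pb(frags, prototypes)
  rmsd_cols <- paste0("rmsd_", prototypes$letter)

  split <- split_chains(unique(chains$chain_id), ratio, seed)
  assigned <- left_join(assigned, split, by = "chain_id")
  idx_train <- which(assigned$split == "train")
  idx_test <- which(assigned$split == "test")

  train <- assigned[idx_train, ]
  occurrence <- occurrence_tables(train, registry)

  # deploy-time features: full-training-split occurrence tables
  base_full <- fragment_features(assigned, registry, scales, occurrence)
  keys <- intersect(c("chain_id", "start", "center", "seq5"), names(base_full))
  feat_ids <- setdiff(names(base_full), keys)

  # cross-fitted features for the training rows
  base_train <- base_full[idx_train, ]
  if (occ_folds > 1) {
    tr_ch <- unique(train$chain_id)
    fold <- withr::with_seed(seed, sample(rep(seq_len(occ_folds),
                                              length.out = length(tr_ch))))
    names(fold) <- tr_ch
    pieces <- lapply(seq_len(occ_folds), function(k) {
      in_fold <- train$chain_id %in% tr_ch[fold == k]
      occ_k <- occurrence_tables(train[!in_fold, ], registry)
      fragment_features(train[in_fold, ], registry, scales, occ_k)
    })
    cross <- bind_rows(pieces)
    ord <- match(paste(train$chain_id, train$start),
                 paste(cross$chain_id, cross$start))
    base_train <- cross[ord, ]
  }

  if (task == "structural_coordinates") {
    Y <- as.matrix(assigned[, rmsd_cols])
    truth <- assigned$pb
    alphabet <- prototypes$letter
    mode <- "rmsd"
  } else {
    if (is.null(label_col) || !(label_col %in% names(chains))) {
      abort("one_hot task needs `label_col` naming a per-residue column of `chains`")
    }
    lab_key <- paste(chains$chain_id, chains$pos, sep = "\r")
    truth <- chains[[label_col]][match(
      paste(assigned$chain_id, assigned$center + 1L, sep = "\r"), lab_key)]
    if (anyNA(truth)) abort("missing labels at some fragment centers")
    alphabet <- sort(unique(truth))
    Y <- one_hot(truth, alphabet)
    colnames(Y) <- paste0("sc_", alphabet)
    mode <- "one_hot"
  }

  Xb_train <- as.matrix(base_train[, feat_ids])
  sel_rows <- if (length(idx_train) > selection_rows) {
    withr::with_seed(seed + 1, sample(length(idx_train), selection_rows))
  } else seq_along(idx_train)
  reports <- lapply(seq_len(ncol(Y)), function(j) {
    suppressWarnings(
      stepwise_select(Xb_train[sel_rows, , drop = FALSE],
                      Y[idx_train[sel_rows], j], selection)
    )
  })
  names(reports) <- colnames(Y)
  sel <- merge_and_dedup(reports, Xb_train[sel_rows, , drop = FALSE], selection)
  kept <- sel$kept$feature

  # expand only the selected base features over the view field
  schedule$seed <- seed
  if (length(kept) == 0) {
    # no informative features: degenerate to the no-information classifier
    # (majority training label; structural coordinates at the training mean)
    model <- constant_model(Y[idx_train, , drop = FALSE])
    model$majority <- names(sort(table(truth[idx_train]), decreasing = TRUE))[1]
    pred <- predict(model, assigned)
  } else {
    wide_full <- window_expand(bind_cols(base_full[, keys],
                                         base_full[, kept]))
    Xfull <- as.matrix(wide_full[, setdiff(names(wide_full), keys)])
    wide_train <- window_expand(bind_cols(base_train[, keys],
                                          base_train[, kept]))
    Xtrain <- as.matrix(wide_train[, setdiff(names(wide_train), keys)])
    model <- train_mlp(
      Xtrain, Y[idx_train, , drop = FALSE],
      spec = mlp_spec(ncol(Xtrain), ncol(Y), hidden = hidden,
                      task = if (mode == "rmsd") "rmsd_regression" else "one_hot"),
      standardize_targets = mode == "rmsd",
      schedule = schedule,
      validation = if (length(idx_test) > 0) {
        list(x = Xfull[idx_test, , drop = FALSE],
             y = Y[idx_test, , drop = FALSE])
      } else NULL)
    pred <- predict(model, Xfull)
  }
  pred_labels <- if (inherits(model, "pb_constant_model")) {
    rep(model$majority, nrow(pred))
  } else {
    classify_predictions(pred, mode = mode, alphabet = alphabet)$label
  }

  predictions <- bind_cols(
    assigned[, c(keys, "split")],
    tibble(truth = truth, predicted = pred_labels)
  )
  splits <- c("train", "test", "validation")
  confusions <- list()
  profiles <- list()
  metrics <- list()
  for (s in splits) {
    ix <- which(assigned$split == s)
    if (length(ix) == 0) next
    cm <- pb_confusion(truth[ix], pred_labels[ix], alphabet)
    pr <- if (mode == "rmsd") {
      profile_correlation(Y[ix, , drop = FALSE], pred[ix, , drop = FALSE])
    } else NULL
    confusions[[s]] <- cm
    profiles[[s]] <- pr
    metrics[[s]] <- tibble(
      split = s, n_fragments = length(ix),
      q = q_measure(truth[ix], pred_labels[ix]),
      diagonal_mean = cm$diagonal_mean,
      profile_r_mean = if (!is.null(pr)) mean(pr$r, na.rm = TRUE) else NA_real_,
      profile_r_min = if (!is.null(pr)) suppressWarnings(min(pr$r, na.rm = TRUE)) else NA_real_
    )
  }

  structure(list(
    task = task, alphabet = alphabet,
    split = split, occurrence = occurrence, selection = sel, model = model,
    metrics = bind_rows(metrics), predictions = predictions,
    confusions = confusions, profile = profiles,
    sc_observed = Y, sc_predicted = pred, assigned_split = assigned$split
  ), class = "pb_pipeline_fit")
}

#' @export
tidy.pb_pipeline_fit <- function(x, ...) x$metrics

#' @export
glance.pb_pipeline_fit <- function(x, ...) {
  m <- x$metrics
  tibble(
    task = x$task,
    n_classes = length(x$alphabet),
    n_features = if (inherits(x$model, "pb_mlp")) length(x$model$features) else 0L,
    q_train = m$q[m$split == "train"][1] %||% NA_real_,
    q_test = m$q[m$split == "test"][1] %||% NA_real_,
    q_validation = m$q[m$split == "validation"][1] %||% NA_real_,
    profile_r_validation = m$profile_r_mean[m$split == "validation"][1] %||% NA_real_
  )
}

#' @export
print.pb_pipeline_fit <- function(x, ...) {
  cat("Sequence-to-structure pipeline (", x$task, ", ",
      length(x$alphabet), " classes)\n", sep = "")
  print(x$metrics)
  invisible(x)
}
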