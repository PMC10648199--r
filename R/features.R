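#' Periodicity feature of a property profile
#'
#' Magnitude of the discrete harmonic component of period `T` in a property
#' profile H_1..H_n along the fragment:
#' sqrt( (sum_k H_k cos(2 pi k / T))^2 + (sum_k H_k sin(2 pi k / T))^2 ).
#' For a hydrophobicity scale and T = 3.6 this measures how closely the
#' fragment's hydrophobicity alternation matches the alpha-helix period; the
#' value is invariant to the phase of a harmonic input.
#'
#' @param values numeric property profile (one value per residue).
#' @param period period T in residues, positive.
#' @return non-negative scalar.
#' @examples
#' periodicity_feature(cos(2 * pi * (1:5) / 3.6), 3.6)
#' @export
periodicity_feature <- function(values, period) {
  if (length(period) != 1 || !is.finite(period) || period <= 0) {
    abort("period must be a single positive number")
  }
  k <- seq_along(values)
  sqrt(sum(values * cos(2 * pi * k / period))^2 +
         sum(values * sin(2 * pi * k / period))^2)
}

#' Candidate feature registry
#'
#' Declares the pool of per-fragment predictors as one row per feature, each
#' fully parameterized (transform + scale/position/period/window/block) so
#' any feature value can be recomputed deterministically.  Families:
#'
#' * `positional` — one scale value per residue position;
#' * `window_mean` — scale mean over the five residues;
#' * `periodicity` — harmonic magnitude of a scale profile at period T
#'   (see [periodicity_feature()]);
#' * `product_mean` — positionwise product of two scales, averaged;
#' * `autocorr` — mean product of a scale at adjacent positions;
#' * `occ_mean` / `occ_sd` / `occ_unseen` — occurrence statistics of the 16
#'   RMSDs for fragments grouped by a subsequence window of the 5-mer
#'   (full 5-mer and the three trimers by default; coarser windows give the
#'   occurrence statistics useful coverage on 5-mers never seen in
#'   training).
#'
#' The registry is an extensible representation of a much larger candidate
#' catalogue; the stepwise selection stage decides what actually enters the
#' model.
#'
#' @param scales long scale table as from [aa_scales()].
#' @param positions residue positions (1-5) for positional features.
#' @param mean_scales scale ids to use for window means (default: all).
#' @param periodicity tibble with columns `scale_id`, `period` (default:
#'   every scale at the strand alternation period 2 and the alpha-helix
#'   period 3.6).
#' @param products logical: include pairwise scale products and
#'   adjacent-position autocorrelations.
#' @param occ_windows character vector of occurrence grouping windows
#'   ("start-end" within the 5-mer); `NULL` disables occurrence features.
#' @return tibble with columns `feature_id`, `transform`, `scale_id`,
#'   `scale_id2`, `position`, `period`, `window`, `pb`, `provenance`.
#' @export
feature_registry <- function(scales = aa_scales(),
                             positions = 1:5,
                             mean_scales = unique(scales$scale_id),
                             periodicity = tidyr::expand_grid(
                               scale_id = unique(scales$scale_id),
                               period = c(2, 3.6)),
                             products = TRUE,
                             occ_windows = c("1-5", "1-3", "2-4", "3-5")) {
  ids <- unique(scales$scale_id)
  blank <- function(df) {
    for (col in c("scale_id", "scale_id2", "pb", "window")) {
      if (!col %in% names(df)) df[[col]] <- NA_character_
    }
    for (col in c("position")) if (!col %in% names(df)) df[[col]] <- NA_integer_
    for (col in c("period")) if (!col %in% names(df)) df[[col]] <- NA_real_
    df
  }
  parts <- list(
    blank(tidyr::expand_grid(scale_id = ids, position = positions) |>
            mutate(feature_id = paste0("pos", .data$position, "_", .data$scale_id),
                   transform = "positional", provenance = "physchem")),
    blank(tibble(scale_id = mean_scales) |>
            mutate(feature_id = paste0("mean_", .data$scale_id),
                   transform = "window_mean", provenance = "physchem"))
  )
  if (nrow(periodicity) > 0) {
    parts <- c(parts, list(
      blank(periodicity |>
              mutate(feature_id = paste0("per", .data$period, "_", .data$scale_id),
                     transform = "periodicity", provenance = "physchem"))
    ))
  }
  if (products) {
    pairs <- utils::combn(ids, 2)
    parts <- c(parts, list(
      blank(tibble(scale_id = pairs[1, ], scale_id2 = pairs[2, ]) |>
              mutate(feature_id = paste0("prod_", .data$scale_id, "_", .data$scale_id2),
                     transform = "product_mean", provenance = "physchem")),
      blank(tibble(scale_id = ids) |>
              mutate(feature_id = paste0("acorr_", .data$scale_id),
                     transform = "autocorr", provenance = "physchem"))
    ))
  }
  for (w in occ_windows %||% character(0)) {
    tag <- if (w == "1-5") "" else paste0(gsub("-", "", w), "_")
    parts <- c(parts, list(
      blank(tibble(pb = PB_LETTERS, window = w) |>
              mutate(feature_id = paste0("occmean_", tag, .data$pb),
                     transform = "occ_mean", provenance = "occurrence")),
      blank(tibble(pb = PB_LETTERS, window = w) |>
              mutate(feature_id = paste0("occsd_", tag, .data$pb),
                     transform = "occ_sd", provenance = "occurrence")),
      blank(tibble(window = w) |>
              mutate(feature_id = paste0("occ_unseen_", gsub("-", "", w)),
                     transform = "occ_unseen", provenance = "occurrence"))
    ))
  }
  reg <- bind_rows(parts) |>
    select("feature_id", "transform", "scale_id", "scale_id2", "position",
           "period", "window", "pb", "provenance")
  if (anyDuplicated(reg$feature_id)) abort("duplicate feature ids in registry")
  reg
}

#' Occurrence statistics of structural coordinates per 5-mer sequence
#'
#' Groups assigned fragments by their amino-acid 5-mer and records, for each
#' of the 16 blocks, the mean and population standard deviation of the RMSD
#' to that block's prototype within the group.  Classes observed once get
#' sd = 0 and are flagged.  When used inside a prediction pipeline the input
#' should come from the training split only, to avoid information leakage
#' into held-out chains.
#'
#' @param assigned fragment tibble with `seq5` and `rmsd_a` ... `rmsd_p`
#'   columns, as returned by [assign_pb()].
#' @param window positions of the 5-mer used as the grouping key, as a
#'   "start-end" string; the default "1-5" groups by the full sequence,
#'   coarser windows (e.g. the central trimer "2-4") pool more fragments
#'   per class.
#' @return tibble keyed by `seq5` (the grouping subsequence) with `n`,
#'   `singleton`, `mean_a..p`, `sd_a..p`; the window is kept as an
#'   attribute.
#' @export
build_occurrence_table <- function(assigned, window = "1-5") {
  rmsd_cols <- paste0("rmsd_", PB_LETTERS)
  rng <- as.integer(strsplit(window, "-")[[1]])
  if (length(rng) != 2 || anyNA(rng) || rng[1] < 1 || rng[2] > 5 || rng[1] > rng[2]) {
    abort("window must be of the form \"start-end\" within 1-5")
  }
  if (nrow(assigned) == 0) {
    out <- tibble(seq5 = character(), n = integer(), singleton = logical())
    attr(out, "window") <- window
    return(out)
  }
  if (!all(rmsd_cols %in% names(assigned))) {
    abort("input must carry rmsd_a ... rmsd_p columns (run assign_pb first)")
  }
  out <- assigned |>
    mutate(seq5 = substr(.data$seq5, rng[1], rng[2])) |>
    group_by(.data$seq5) |>
    summarise(
      n = dplyr::n(),
      across(all_of(rmsd_cols), mean, .names = "mean.{.col}"),
      across(all_of(rmsd_cols), pop_sd, .names = "sd.{.col}"),
      .groups = "drop"
    ) |>
    mutate(singleton = .data$n == 1L)
  names(out) <- sub("^(mean|sd)\\.rmsd_", "\\1_", names(out))
  attr(out, "window") <- window
  out
}

#' Build the occurrence tables required by a feature registry
#'
#' One [build_occurrence_table()] call per distinct occurrence window in the
#' registry, returned as a named list.
#'
#' @param assigned assigned fragment tibble.
#' @param registry feature registry.
#' @return named list of occurrence tables (names are window strings).
#' @export
occurrence_tables <- function(assigned, registry = feature_registry()) {
  wins <- unique(registry$window[registry$provenance == "occurrence"])
  wins <- wins[!is.na(wins)]
  setNames(lapply(wins, function(w) build_occurrence_table(assigned, w)), wins)
}

# named value vector for one scale, with 'X' imputed as the 20-residue mean
scale_lookup <- function(scales, id) {
  v <- scales$value[scales$scale_id == id]
  names(v) <- scales$aa[scales$scale_id == id]
  if (length(v) != 20 || !all(AAINDEX_ORDER %in% names(v))) {
    abort(paste0("unknown or incomplete scale: ", id))
  }
  c(v, X = mean(v))
}

#' Compute the per-fragment candidate feature matrix
#'
#' Evaluates every registry feature on every fragment.  Physicochemical
#' features of unknown residues ('X') use the scale mean; occurrence features
#' of 5-mers absent from the occurrence table (or containing 'X') back off to
#' the table-wide mean profile, set the `occ_unseen` indicator, and are
#' recorded in the `"mask"` attribute.
#'
#' @param fragments tibble with at least `seq5` (plus `chain_id`/`start` keys
#'   if present, which are carried through).
#' @param registry tibble from [feature_registry()].
#' @param scales long scale table.
#' @param occurrence named list of occurrence tables from
#'   [occurrence_tables()] (a single table is accepted for a registry using
#'   only the "1-5" window); required when the registry contains occurrence
#'   features.
#' @return tibble of key columns plus one numeric column per feature, with
#'   attributes `"mask"` (logical matrix, TRUE where a value was imputed) and
#'   `"registry"`.
#' @export
fragment_features <- function(fragments, registry = feature_registry(),
                              scales = aa_scales(), occurrence = NULL) {
  n <- nrow(fragments)
  aa_mat <- matrix(unlist(strsplit(fragments$seq5, "")), nrow = 5)
  vals <- matrix(NA_real_, n, nrow(registry),
                 dimnames = list(NULL, registry$feature_id))
  mask <- matrix(FALSE, n, nrow(registry),
                 dimnames = list(NULL, registry$feature_id))
  lookups <- list()
  get_lookup <- function(id) {
    if (is.null(lookups[[id]])) lookups[[id]] <<- scale_lookup(scales, id)
    lookups[[id]]
  }
  # one lookup state per occurrence window: row index, unseen flag, matrix
  occ_state <- list()
  get_occ <- function(w) {
    if (!is.null(occ_state[[w]])) return(occ_state[[w]])
    if (is.null(occurrence)) {
      abort("registry contains occurrence features but no occurrence tables given")
    }
    tabs <- if (is.data.frame(occurrence)) list("1-5" = occurrence) else occurrence
    tab <- tabs[[w]]
    if (is.null(tab)) abort(paste0("no occurrence table for window ", w))
    rng <- as.integer(strsplit(w, "-")[[1]])
    key <- substr(fragments$seq5, rng[1], rng[2])
    hit <- match(key, tab$seq5)
    unseen <- is.na(hit) | grepl("X", key, fixed = TRUE)
    M <- as.matrix(tab[, c(paste0("mean_", PB_LETTERS), paste0("sd_", PB_LETTERS))])
    st <- list(hit = hit, unseen = unseen, M = M, global = colMeans(M))
    occ_state[[w]] <<- st
    st
  }
  any_x <- colSums(aa_mat == "X") > 0
  for (j in seq_len(nrow(registry))) {
    f <- registry[j, ]
    vals[, j] <- switch(
      f$transform,
      positional = {
        v <- get_lookup(f$scale_id)
        mask[, j] <- aa_mat[f$position, ] == "X"
        unname(v[aa_mat[f$position, ]])
      },
      window_mean = {
        v <- get_lookup(f$scale_id)
        mask[, j] <- any_x
        colMeans(matrix(v[aa_mat], nrow = 5))
      },
      periodicity = {
        v <- get_lookup(f$scale_id)
        V <- matrix(v[aa_mat], nrow = 5)
        k <- 1:5
        mask[, j] <- any_x
        sqrt(colSums(V * cos(2 * pi * k / f$period))^2 +
               colSums(V * sin(2 * pi * k / f$period))^2)
      },
      product_mean = {
        v1 <- get_lookup(f$scale_id)
        v2 <- get_lookup(f$scale_id2)
        mask[, j] <- any_x
        colMeans(matrix(v1[aa_mat] * v2[aa_mat], nrow = 5))
      },
      autocorr = {
        v <- get_lookup(f$scale_id)
        V <- matrix(v[aa_mat], nrow = 5)
        mask[, j] <- any_x
        colMeans(V[-1, , drop = FALSE] * V[-5, , drop = FALSE])
      },
      occ_mean = {
        st <- get_occ(f$window)
        col <- paste0("mean_", f$pb)
        x <- st$M[st$hit, col]
        x[st$unseen] <- st$global[col]
        mask[, j] <- st$unseen
        x
      },
      occ_sd = {
        st <- get_occ(f$window)
        col <- paste0("sd_", f$pb)
        x <- st$M[st$hit, col]
        x[st$unseen] <- st$global[col]
        mask[, j] <- st$unseen
        x
      },
      occ_unseen = as.numeric(get_occ(f$window)$unseen),
      abort(paste0("unknown transform: ", f$transform))
    )
  }
  keys <- intersect(c("chain_id", "start", "center", "seq5"), names(fragments))
  out <- bind_cols(fragments[, keys], as_tibble(vals))
  attr(out, "mask") <- mask
  attr(out, "registry") <- registry
  out
}

#' Expand per-fragment features over a sliding view field
#'
#' Widens the view around each fragment to 9 residues by concatenating the
#' base feature vectors of the fragments shifted by -2, -1, 0, +1, +2
#' positions in the same chain.  A shift that falls off the chain (or onto a
#' dropped window) repeats the nearest valid window's features; such blocks
#' are recorded in the `"pad"` attribute.  With the default 76-feature
#' registry this produces 76 x 5 = 380 columns.
#'
#' @param features tibble from [fragment_features()] carrying `chain_id` and
#'   `start` key columns.
#' @param offsets integer window shifts, default -2:2.
#' @return tibble of key columns plus one column per (feature, offset),
#'   named `<feature_id>@<offset>`; attribute `"pad"` is a logical matrix
#'   (fragments x offsets) marking padded blocks.
#' @export
window_expand <- function(features, offsets = -2:2) {
  keys <- intersect(c("chain_id", "start", "center", "seq5"), names(features))
  if (!all(c("chain_id", "start") %in% keys)) {
    abort("features must carry chain_id and start columns")
  }
  feat_cols <- setdiff(names(features), keys)
  M <- as.matrix(features[, feat_cols])
  n <- nrow(features)
  key <- paste(features$chain_id, features$start, sep = "\r")
  pad <- matrix(FALSE, n, length(offsets),
                dimnames = list(NULL, paste0("offset", offsets)))
  blocks <- vector("list", length(offsets))
  for (k in seq_along(offsets)) {
    target <- features$start + offsets[k]
    idx <- match(paste(features$chain_id, target, sep = "\r"), key)
    missing <- which(is.na(idx))
    if (length(missing) > 0) {
      # nearest valid window within the same chain
      for (i in missing) {
        same <- which(features$chain_id == features$chain_id[i])
        j <- same[which.min(abs(features$start[same] - target[i]))]
        idx[i] <- j
      }
      pad[missing, k] <- TRUE
    }
    B <- M[idx, , drop = FALSE]
    colnames(B) <- paste0(feat_cols, "@", offsets[k])
    blocks[[k]] <- B
  }
  out <- bind_cols(features[, keys], as_tibble(do.call(cbind, blocks)))
  attr(out, "pad") <- pad
  attr(out, "offsets") <- offsets
  out
}
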