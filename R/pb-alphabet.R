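#' The 16 protein-block dihedral definitions
#'
#' Each protein block (letters 'a'-'p') is a five-residue backbone prototype
#' defined by its eight dihedral angles psi1, phi2, psi2, phi3, psi3, phi4,
#' psi4, phi5.  The packaged table is the canonical 16-letter structural
#' alphabet of de Brevern and colleagues; an alternative alphabet can be
#' supplied as a TSV file with the same columns.
#'
#' @param path optional path to a user TSV (columns `letter` plus the eight
#'   angle columns); default uses the packaged table.
#' @return tibble with 16 rows: `letter` and eight angle columns (degrees).
#' @examples
#' pb_definitions()
#' @export
pb_definitions <- function(path = NULL) {
  path <- path %||% pblocks_file("extdata", "pb_dihedrals.tsv")
  defs <- as_tibble(read.delim(path, check.names = FALSE))
  angle_cols <- c("psi1", "phi2", "psi2", "phi3", "psi3", "phi4", "psi4", "phi5")
  if (!all(c("letter", angle_cols) %in% names(defs))) {
    abort(paste0("malformed PB definition file: need columns letter, ",
                 paste(angle_cols, collapse = ", ")))
  }
  if (anyDuplicated(defs$letter)) abort("duplicate PB letters in definition file")
  defs[order(defs$letter), c("letter", angle_cols)]
}

#' Build the 3D prototypes of the protein blocks
#'
#' Converts each block's dihedral series into 15 N/Calpha/C coordinates under
#' a fixed backbone geometry.
#'
#' @param definitions tibble from [pb_definitions()].
#' @param geometry a [backbone_geometry()].
#' @return tibble with columns `letter`, `dihedrals` (list of named
#'   8-vectors) and `coords` (list of 15 x 3 matrices).
#' @export
pb_prototypes <- function(definitions = pb_definitions(),
                          geometry = backbone_geometry()) {
  angle_cols <- c("psi1", "phi2", "psi2", "phi3", "psi3", "phi4", "psi4", "phi5")
  ang <- as.matrix(definitions[, angle_cols])
  tibble(
    letter = definitions$letter,
    dihedrals = lapply(seq_len(nrow(ang)), function(i) setNames(ang[i, ], angle_cols)),
    coords = lapply(seq_len(nrow(ang)), function(i) {
      as_coord_matrix(build_backbone(ang[i, ], geometry))
    })
  )
}

#' Pairwise RMSD matrix between protein-block prototypes
#'
#' Kabsch-superposed RMSD between every pair of prototype backbones.  The
#' matrix is symmetric with a zero diagonal; structurally similar blocks
#' (e.g. 'c'/'d') sit well below 1 Angstrom while the most dissimilar pair
#' exceeds 3 Angstrom.
#'
#' @param prototypes tibble from [pb_prototypes()].
#' @return a symmetric 16 x 16 matrix (class `pb_distmat`) in Angstrom.
#' @examples
#' D <- pb_distance_matrix()
#' D["c", "d"]
#' @export
pb_distance_matrix <- function(prototypes = pb_prototypes()) {
  n <- nrow(prototypes)
  D <- matrix(0, n, n, dimnames = list(prototypes$letter, prototypes$letter))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- kabsch_rmsd(prototypes$coords[[i]], prototypes$coords[[j]])
    }
  }
  class(D) <- c("pb_distmat", class(D))
  D
}

#' @export
tidy.pb_distmat <- function(x, ...) {
  tibble(
    from = rep(rownames(x), times = ncol(x)),
    to = rep(colnames(x), each = nrow(x)),
    rmsd = as.vector(unclass(x))
  )
}

#' @export
autoplot.pb_distmat <- function(object, ...) {
  df <- tidy.pb_distmat(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from, fill = .data$rmsd)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rmsd)), size = 2.2) +
    ggplot2::scale_fill_viridis_c(name = "RMSD (Å)") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "protein block", y = "protein block") +
    ggplot2::theme_minimal()
}

# 16 RMSDs from one fragment coordinate matrix to all prototypes.
# Uses the trace identity for the Kabsch minimum:
#   min RMSD^2 = (|Pc|^2 + |Qc|^2 - 2 (d1 + d2 + sign(det H) d3)) / n
# with d the singular values of the cross-covariance H, so only singular
# values (not the rotation) are computed per pair.
sc_vector <- function(P, prototypes) {
  Pc <- P - rep(colMeans(P), each = nrow(P))
  pn <- sum(Pc * Pc)
  qcs <- attr(prototypes, "centered") %||% lapply(prototypes$coords, function(Q) {
    Q - rep(colMeans(Q), each = nrow(Q))
  })
  vapply(qcs, function(Qc) {
    H <- crossprod(Pc, Qc)
    d <- svd(H, nu = 0, nv = 0)$d
    s <- if (det(H) < 0) d[1] + d[2] - d[3] else sum(d)
    sqrt(max(0, (pn + sum(Qc * Qc) - 2 * s) / nrow(P)))
  }, numeric(1))
}

# cache centered prototype coordinates (and their norms) on the tibble
with_centered_prototypes <- function(prototypes) {
  if (is.null(attr(prototypes, "centered"))) {
    attr(prototypes, "centered") <- lapply(prototypes$coords, function(Q) {
      Q - rep(colMeans(Q), each = nrow(Q))
    })
  }
  prototypes
}

#' Assign protein blocks by minimum RMSD ("structural coordinates")
#'
#' For each five-residue fragment, computes the RMSD to all 16 prototypes
#' (the fragment's structural coordinates) and assigns the letter of the
#' nearest prototype.  Ties within 1e-6 Angstrom go to the alphabetically
#' first letter and are flagged.
#'
#' @param fragments a fragment tibble from [extract_fragments()] (list-column
#'   `coords` of 15 x 3 matrices), or a single 15 x 3 matrix.
#' @param prototypes tibble from [pb_prototypes()].
#' @return the input tibble with columns `pb` (assigned letter), `pb_tie`
#'   (logical) and `rmsd_a` ... `rmsd_p` (Angstrom) appended.
#' @export
assign_pb <- function(fragments, prototypes = pb_prototypes()) {
  if (is.matrix(fragments) || (is.data.frame(fragments) && !("coords" %in% names(fragments)))) {
    fragments <- tibble(coords = list(as_coord_matrix(fragments)))
  }
  bad <- vapply(fragments$coords, function(m) anyNA(m) || nrow(m) != 15, logical(1))
  if (any(bad)) abort("incomplete fragment: every fragment needs 15 finite backbone coordinates")
  prototypes <- with_centered_prototypes(prototypes)
  S <- t(vapply(fragments$coords, sc_vector, numeric(nrow(prototypes)), prototypes = prototypes))
  colnames(S) <- paste0("rmsd_", prototypes$letter)
  idx <- max.col(-S, ties.method = "first")
  mins <- S[cbind(seq_len(nrow(S)), idx)]
  n_close <- rowSums(S <= mins + 1e-6)
  out <- fragments
  out$pb <- prototypes$letter[idx]
  out$pb_tie <- n_close > 1
  bind_cols(out, as_tibble(S))
}

#' Assign protein blocks by minimum RMSDA on dihedral series
#'
#' Angular-space analogue of [assign_pb()]: the fragment's eight dihedrals are
#' compared to each block definition with [rmsda()] and the nearest letter
#' returned.  Agrees with the RMSD assignment for regular, compact blocks;
#' the two metrics can differ for irregular conformations.
#'
#' @param dihedrals numeric vector of 8 angles, or an n x 8 matrix (one row
#'   per fragment), ordered psi1, phi2, ..., phi5.
#' @param definitions tibble from [pb_definitions()].
#' @return tibble with columns `pb`, `pb_tie` and `rmsda_a` ... `rmsda_p`.
#' @export
assign_pb_rmsda <- function(dihedrals, definitions = pb_definitions()) {
  if (is.null(dim(dihedrals))) dihedrals <- matrix(dihedrals, nrow = 1)
  if (ncol(dihedrals) != 8) abort("expected 8 dihedral angles per fragment")
  ref <- as.matrix(definitions[, c("psi1", "phi2", "psi2", "phi3", "psi3", "phi4", "psi4", "phi5")])
  S <- t(apply(dihedrals, 1, function(a) {
    vapply(seq_len(nrow(ref)), function(k) rmsda(a, ref[k, ]), numeric(1))
  }))
  colnames(S) <- paste0("rmsda_", definitions$letter)
  idx <- max.col(-S, ties.method = "first")
  mins <- S[cbind(seq_len(nrow(S)), idx)]
  tibble(
    pb = definitions$letter[idx],
    pb_tie = rowSums(S <= mins + 1e-6) > 1
  ) |> bind_cols(as_tibble(S))
}
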