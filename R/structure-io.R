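#' Read backbone chains from a PDB or mmCIF file
#'
#' Extracts the N/Calpha/C backbone of every polymer chain.  Only the first
#' model of multi-model (NMR) files is used.  When an atom has alternate
#' locations, the highest-occupancy one is kept (ties resolved towards
#' altloc 'A').  Residues missing any of the three backbone atoms are kept in
#' the chain but flagged `coords_known = FALSE`; non-standard residues map to
#' amino-acid code 'X'.
#'
#' @param path path to a `.pdb`, `.ent`, `.cif` or `.mmcif` file.
#' @param chain_filter optional character vector of chain identifiers to keep.
#' @return a tibble with one row per residue: `chain_id`, `pos` (ordinal
#'   position, 1-based), `resno`, `insert`, `res_name`, `aa`, `coords_known`
#'   and the nine coordinate columns `n_x` ... `c_z` (Angstrom).
#' @export
read_structure <- function(path, chain_filter = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read structure file: ", path))
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  parsed <- tryCatch(
    suppressWarnings(
      if (is_cif) bio3d::read.cif(path) else {
        bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE)
      }
    ),
    error = function(e) abort(paste0("parse error in ", path, ": ", conditionMessage(e)))
  )
  atoms <- as_tibble(parsed$atom)
  atoms <- filter(atoms, .data$type == "ATOM", .data$elety %in% c("N", "CA", "C"))
  if (!is.null(chain_filter)) atoms <- filter(atoms, .data$chain %in% chain_filter)
  if (nrow(atoms) == 0) abort(paste0("no chains selected from ", path))
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  # altloc policy: highest occupancy, ties towards 'A' (then alphabetical)
  atoms <- atoms |>
    mutate(.ord = row_number()) |>
    group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    arrange(desc(.data$o), .data$alt, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$.ord)

  res <- atoms |>
    group_by(chain_id = .data$chain, resno = .data$resno, insert = .data$insert) |>
    summarise(
      .ord = min(.data$.ord),
      res_name = .data$resid[1],
      n_x = .data$x[match("N", .data$elety)], n_y = .data$y[match("N", .data$elety)],
      n_z = .data$z[match("N", .data$elety)],
      ca_x = .data$x[match("CA", .data$elety)], ca_y = .data$y[match("CA", .data$elety)],
      ca_z = .data$z[match("CA", .data$elety)],
      c_x = .data$x[match("C", .data$elety)], c_y = .data$y[match("C", .data$elety)],
      c_z = .data$z[match("C", .data$elety)],
      .groups = "drop"
    ) |>
    arrange(.data$.ord)
  res$aa <- suppressWarnings(bio3d::aa321(res$res_name))
  res$aa[is.na(res$aa) | !(res$aa %in% c(LETTERS[!LETTERS %in% c("B", "J", "O", "U", "X", "Z")]))] <- "X"
  coord_cols <- c("n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z", "c_x", "c_y", "c_z")
  res$coords_known <- !apply(is.na(res[, coord_cols]), 1, any)
  res |>
    group_by(.data$chain_id) |>
    mutate(pos = row_number()) |>
    ungroup() |>
    select("chain_id", "pos", "resno", "insert", "res_name", "aa",
           "coords_known", all_of(coord_cols))
}

#' Write backbone chains to a PDB file
#'
#' Writes the N/Calpha/C records of a chain tibble (only residues with known
#' coordinates).  Coordinates survive a write/read round trip to PDB precision
#' (3 decimal places).
#'
#' @param chains tibble in the shape returned by [read_structure()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_backbone_pdb <- function(chains, path) {
  known <- filter(chains, .data$coords_known)
  if (nrow(known) == 0) abort("no residues with known coordinates to write")
  coord_cols <- c("n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z", "c_x", "c_y", "c_z")
  A <- as.matrix(known[, coord_cols])
  M <- matrix(t(A), ncol = 3, byrow = TRUE)  # 3 atom rows per residue
  xyz <- as.vector(t(M))
  n_at <- 3L
  aa3 <- known$res_name
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    resno = rep(known$resno, each = n_at),
    resid = rep(aa3, each = n_at),
    elety = rep(c("N", "CA", "C"), nrow(known)),
    chain = rep(known$chain_id, each = n_at)
  )
  invisible(path)
}

#' Extract all complete five-residue fragments from backbone chains
#'
#' Slides a five-residue window along each chain (step 1).  A window is kept
#' only if all five residues have known coordinates and the residue numbering
#' is consecutive (chain breaks, like unresolved residues, invalidate every
#' window that touches them).  A fully resolved chain of length L therefore
#' yields L - 4 fragments, and no fragment is centered on the two terminal
#' residues at either end.
#'
#' @param chains tibble from [read_structure()] (or the synthetic generator).
#' @return tibble with one row per fragment: `chain_id`, `start` (0-based
#'   offset of the first residue), `center` (0-based, `start + 2`), `seq5`
#'   and a list-column `coords` of 15 x 3 matrices (atoms N, CA, C per
#'   residue).
#' @export
extract_fragments <- function(chains) {
  coord_cols <- c("n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z", "c_x", "c_y", "c_z")
  out <- lapply(split(chains, chains$chain_id), function(ch) {
    ch <- ch[order(ch$pos), ]
    L <- nrow(ch)
    if (L < 5) return(NULL)
    ok <- ch$coords_known
    step <- diff(ch$resno)
    consec <- step == 1 | (step == 0 & ch$insert[-1] != ch$insert[-L])
    starts <- which(vapply(seq_len(L - 4), function(s) {
      all(ok[s:(s + 4)]) && all(consec[s:(s + 3)])
    }, logical(1)))
    if (length(starts) == 0) return(NULL)
    M <- as.matrix(ch[, coord_cols])
    tibble(
      chain_id = ch$chain_id[1],
      start = starts - 1L,
      center = starts + 1L,
      seq5 = vapply(starts, function(s) paste(ch$aa[s:(s + 4)], collapse = ""), character(1)),
      coords = lapply(starts, function(s) {
        matrix(t(M[s:(s + 4), ]), ncol = 3, byrow = TRUE)
      })
    )
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(chain_id = character(), start = integer(), center = integer(),
                  seq5 = character(), coords = list()))
  }
  out
}

#' Read a per-residue secondary-structure label track
#'
#' Accepts either a classic DSSP output file or a two-column TSV
#' (`seq_index`, `label`).  Labels are validated against the declared scheme
#' alphabet: DSSP-8 (H, G, I, E, B, T, S, C), DSSP-3 (H, E, C) or protein
#' blocks (a-p).  In DSSP files a blank structure code is read as coil 'C'.
#'
#' @param path input file.
#' @param scheme one of `"dssp8"`, `"dssp3"`, `"pb"`.
#' @return tibble with columns `chain_id` (NA for plain TSV), `seq_index`,
#'   `label`; the scheme is stored in attribute `"scheme"`.
#' @export
read_labels <- function(path, scheme = c("dssp8", "dssp3", "pb")) {
  scheme <- match.arg(scheme)
  alphabet <- switch(scheme, dssp8 = DSSP8, dssp3 = DSSP3, pb = PB_LETTERS)
  if (!file.exists(path)) abort(paste0("cannot read label file: ", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 1) {
    body <- lines[(hdr + 1):length(lines)]
    body <- body[nchar(body) >= 17]
    resno <- suppressWarnings(as.integer(substr(body, 6, 10)))
    chain <- trimws(substr(body, 12, 12))
    ss <- substr(body, 17, 17)
    keep <- !is.na(resno) & substr(body, 14, 14) != "!"
    ss <- ifelse(ss == " ", "C", ss)
    track <- tibble(chain_id = chain[keep], seq_index = resno[keep], label = ss[keep])
  } else {
    df <- read.delim(path, header = FALSE, sep = "", comment.char = "#",
                     col.names = c("seq_index", "label"),
                     colClasses = c("integer", "character"))
    track <- tibble(chain_id = NA_character_, seq_index = df$seq_index, label = df$label)
  }
  bad <- which(!(track$label %in% alphabet))
  if (length(bad) > 0) {
    abort(paste0("labels outside the ", scheme, " alphabet at rows: ",
                 paste(head(bad, 10), collapse = ", "),
                 if (length(bad) > 10) " ..." else ""))
  }
  attr(track, "scheme") <- scheme
  track
}

#' Collapse DSSP 8-state labels to 3 states
#'
#' Default mapping: H, G, I -> H (helix); E, B -> E (strand); T, S, C -> C
#' (coil).  The mapping is configurable since several conventions exist.
#'
#' @param labels character vector of DSSP-8 labels.
#' @param mapping named character vector from 8-state to 3-state codes.
#' @return character vector of 3-state labels.
#' @examples
#' collapse_dssp(strsplit("HGIEBTSC", "")[[1]])
#' @export
collapse_dssp <- function(labels,
                          mapping = c(H = "H", G = "H", I = "H",
                                      E = "E", B = "E",
                                      T = "C", S = "C", C = "C")) {
  if (!all(labels %in% names(mapping))) {
    abort("labels outside the domain of the collapse mapping")
  }
  unname(mapping[labels])
}

#' Split chains into training, test and validation sets
#'
#' Assigns whole chains (never individual fragments) to the three sets, so
#' overlapping five-residue windows can never end up in different sets.
#' Counts follow the requested ratio by largest-remainder apportionment and
#' the assignment is deterministic for a fixed seed.
#'
#' @param chain_ids character vector of unique chain identifiers.
#' @param ratio three non-negative integers (train : test : validation).
#' @param seed integer seed.
#' @return tibble with columns `chain_id` and `split`
#'   (train/test/validation); `ratio` and `seed` kept as attributes.
#' @examples
#' split_chains(sprintf("c%03d", 1:100), c(6, 3, 1), seed = 1)
#' @export
split_chains <- function(chain_ids, ratio = c(6, 3, 1), seed = 1) {
  if (anyDuplicated(chain_ids)) abort("chain ids must be unique")
  if (length(ratio) != 3 || any(ratio < 0) || sum(ratio) == 0) {
    abort("ratio must be three non-negative numbers with positive total")
  }
  n <- length(chain_ids)
  exact <- n * ratio / sum(ratio)
  counts <- floor(exact)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  shuffled <- withr::with_seed(seed, sample(chain_ids))
  split <- rep(c("train", "test", "validation"), times = counts)
  out <- tibble(chain_id = shuffled, split = split) |> arrange(match(.data$chain_id, chain_ids))
  attr(out, "ratio") <- ratio
  attr(out, "seed") <- seed
  out
}

#' Write chain sequences to a FASTA file
#'
#' @param sequences named character vector (names become FASTA headers).
#' @param path output file.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sequences)) {
    writeLines(paste0(">", nm), con)
    s <- sequences[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
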