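# canonical residue order of AAindex1 value blocks
AAINDEX_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Packaged amino-acid property scales
#'
#' A small working set of standard published scales (hydropathy,
#' hydrophilicity, flexibility, volume, polarity, isoelectric point and
#' helix propensity), stored in long form.  Additional scales can be read
#' from AAindex1 flat files with [read_aaindex()] and bound onto this table.
#'
#' @return tibble with columns `scale_id`, `description`, `aa`, `value`.
#' @examples
#' aa_scales()
#' @export
aa_scales <- function() {
  wide <- as_tibble(read.delim(pblocks_file("extdata", "aa_scales.tsv"),
                               check.names = FALSE))
  tidyr::pivot_longer(wide, cols = all_of(AAINDEX_ORDER),
                      names_to = "aa", values_to = "value")
}

#' Read amino-acid scales from an AAindex1 flat file
#'
#' Parses the standard AAindex1 format: `H` lines give the accession, `D`
#' lines the description, and the two rows after each `I` line hold the 20
#' values in the canonical A R N D C Q E G H I / L K M F P S T W Y V order.
#'
#' @param path path to an AAindex1-format file.
#' @return tibble with columns `scale_id`, `description`, `aa`, `value`.
#' @export
read_aaindex <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read AAindex file: ", path))
  lines <- readLines(path, warn = FALSE)
  entries <- list()
  acc <- NULL
  desc <- ""
  i <- 1
  while (i <= length(lines)) {
    ln <- lines[i]
    tag <- substr(ln, 1, 1)
    if (tag == "H") {
      acc <- trimws(substr(ln, 2, nchar(ln)))
    } else if (tag == "D") {
      desc <- trimws(substr(ln, 2, nchar(ln)))
    } else if (tag == "I") {
      if (i + 2 > length(lines)) abort(paste0("truncated value block for ", acc))
      vals <- suppressWarnings(as.numeric(unlist(
        strsplit(trimws(c(lines[i + 1], lines[i + 2])), "\\s+")
      )))
      if (length(vals) != 20) {
        abort(paste0("expected 20 values for ", acc %||% "entry", ", got ", length(vals)))
      }
      entries[[length(entries) + 1]] <- tibble(
        scale_id = acc %||% paste0("scale", length(entries) + 1),
        description = desc,
        aa = AAINDEX_ORDER,
        value = vals
      )
      i <- i + 2
      desc <- ""
    }
    i <- i + 1
  }
  if (length(entries) == 0) abort(paste0("no AAindex entries found in ", path))
  bind_rows(entries)
}
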