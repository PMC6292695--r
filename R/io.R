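# ms-format replicate text: "//" blocks with segsites / positions /
# haplotype rows. Used to exchange replicates with ms-compatible
# simulators and for audit dumps.

# parse a character vector of ms-format lines into replicates of
# list(alleles = 0/1 matrix (haplotypes x sites), positions = fractions)
parse_ms_blocks <- function(lines) {
  starts <- which(lines == "//")
  if (length(starts) == 0L) stop("no ms replicate blocks ('//') found")
  bounds <- c(starts, length(lines) + 1L)
  lapply(seq_along(starts), function(b) {
    block <- lines[(bounds[b] + 1L):(bounds[b + 1L] - 1L)]
    seg_line <- block[startsWith(block, "segsites:")]
    S <- as.integer(sub("segsites:\\s*", "", seg_line[1]))
    if (S == 0L)
      return(list(alleles = matrix(integer(0), nrow = 0), positions = numeric(0)))
    pos_line <- block[startsWith(block, "positions:")]
    positions <- as.numeric(strsplit(sub("positions:\\s*", "", pos_line[1]),
                                     "\\s+")[[1]])
    hapl <- block[grepl("^[01]+$", block)]
    alleles <- do.call(rbind, lapply(strsplit(hapl, "", fixed = TRUE),
                                     as.integer))
    if (ncol(alleles) != S) stop("malformed ms block: width != segsites")
    list(alleles = alleles, positions = positions)
  })
}

#' Read ms-format replicates
#'
#' Parses `//` / `segsites:` / `positions:` blocks as written by
#' ms-compatible coalescent simulators.
#'
#' @param path File of ms-format text.
#' @return A list of replicates, each `list(alleles, positions)` with a
#'   haplotypes x sites 0/1 matrix and positions as locus fractions.
#' @export
read_ms <- function(path) {
  parse_ms_blocks(readLines(path))
}

#' Write replicates in ms format
#'
#' @param reps List of [haplotype_matrix()] objects (or
#'   `list(alleles, positions)` with integer positions).
#' @param path Output path.
#' @param locus_length Locus length used to scale integer positions to
#'   `[0, 1)` fractions.
#' @param command Header line to record (defaults to a note).
#' @return `path`, invisibly.
#' @export
write_ms <- function(reps, path, locus_length, command = "gminscan") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(command, ""), con)
  for (r in reps) {
    al <- if (inherits(r, "haplotype_matrix")) r$alleles else r$alleles
    pos <- if (inherits(r, "haplotype_matrix")) r$positions else r$positions
    al <- al > 0 # collapse multiallelic codes to derived presence
    storage.mode(al) <- "integer"
    writeLines("//", con)
    writeLines(paste0("segsites: ", ncol(al)), con)
    if (ncol(al) > 0L) {
      writeLines(paste0("positions: ",
                        paste(sprintf("%.5f", (pos + 0.5) / locus_length),
                              collapse = " ")), con)
      writeLines(apply(al, 1, paste, collapse = ""), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a genetic map of per-window crossover estimates
#'
#' @param path TSV with header columns `chrom`, `window_start`, `cm`
#'   (crossover estimate in centimorgans for the window).
#' @return Data frame with those columns.
#' @export
read_genetic_map <- function(path) {
  map <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "window_start", "cm") %in% names(map)))
  map
}

#' @rdname read_genetic_map
#' @param map Data frame to write.
#' @export
write_genetic_map <- function(map, path) {
  write.table(map[, c("chrom", "window_start", "cm")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
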