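#' Write regions as BED6
#'
#' Emits 0-based half-open intervals sorted by (chrom, start, end), with the
#' region id in the name column and 0 in the score column.
#'
#' @param regions data.frame with `chrom`, `start`, `end`, `strand`, and
#'   `region_id` columns.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("chrom", "start", "end", "strand", "region_id") %in%
                  names(regions)))
  o <- order(regions$chrom, regions$start, regions$end)
  bed <- regions[o, , drop = FALSE]
  utils::write.table(
    data.frame(bed$chrom, bed$start, bed$end, bed$region_id, 0L, bed$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (first six columns)
#'
#' Parses BED3-BED6 keeping the native 0-based half-open coordinates.
#' Malformed lines (too few fields, non-integer or negative coordinates,
#' end not greater than start) raise an error naming the offending line
#' number.
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end`, and, when present,
#'   `region_id` (name), `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) stop("empty BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED at line ", which(nf < 3L)[1], ": fewer than 3 fields")
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start < 0L | end <= start
  if (any(bad))
    stop("malformed BED at line ", which(bad)[1],
         ": coordinates must be non-negative integers with end > start")
  out <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                    start = start, end = end, stringsAsFactors = FALSE)
  if (all(nf >= 4L)) out$region_id <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L)) out$score <- vapply(fields, `[[`, "", 5L)
  if (all(nf >= 6L)) out$strand <- vapply(fields, `[[`, "", 6L)
  out
}

#' Transcription start site of a gene interval
#'
#' BED convention: for a plus-strand (or unstranded) interval the TSS is
#' `start`; for a minus-strand interval it is `end - 1` (the last covered
#' base of the 0-based half-open interval).
#'
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"`, `"-"` or `"."`.
#' @return integer TSS positions.
#' @export
region_tss <- function(start, end, strand) {
  ifelse(strand == "-", end - 1L, start)
}
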