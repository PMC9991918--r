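#' Counts-per-million normalization of screen count matrices
#'
#' Scales every sample (column) to one million, then adds the pseudocount,
#' so log fold changes stay finite at zero counts without distorting high
#' counts.
#'
#' @param counts non-negative integer matrix, shRNA x sample.
#' @param pseudocount value added after scaling (default 0.5).
#' @return strictly positive numeric matrix of the same shape.
#' @examples
#' m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
#' normalize_cpm(m, pseudocount = 0)
#' @export
normalize_cpm <- function(counts, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- colSums(counts)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0]
    if (is.null(bad)) bad <- which(tot == 0)
    stop("all-zero sample(s): ", paste(bad, collapse = ", "))
  }
  sweep(counts, 2, tot / 1e6, "/") + pseudocount
}

#' Per-shRNA mean log2 fold change of output over input
#'
#' For each shRNA, computes log2(output CPM / input CPM) for every output
#' replicate against its paired input sample and averages the replicate
#' log ratios (averaging after the log transform).
#'
#' @param normalized strictly positive matrix from [normalize_cpm()].
#' @param pairing data.frame with columns `output` and `input` mapping every
#'   output replicate column to an input column.
#' @return data.frame with `shrna_id` and `mean_log2fc`.
#' @export
shrna_log2fc <- function(normalized, pairing) {
  stopifnot(all(c("output", "input") %in% names(pairing)))
  missing_out <- setdiff(pairing$output, colnames(normalized))
  missing_in <- setdiff(pairing$input, colnames(normalized))
  if (length(missing_out) || length(missing_in))
    stop("pairing refers to unknown sample(s): ",
         paste(c(missing_out, missing_in), collapse = ", "))
  lfc <- vapply(seq_len(nrow(pairing)), function(k) {
    log2(normalized[, pairing$output[k]] / normalized[, pairing$input[k]])
  }, numeric(nrow(normalized)))
  data.frame(shrna_id = rownames(normalized),
             mean_log2fc = rowMeans(matrix(lfc, nrow = nrow(normalized))),
             stringsAsFactors = FALSE)
}

## Default pairing: every output replicate against the first input, or the
## matching input replicate when input replicates are as numerous.
default_pairing <- function(samples) {
  outs <- samples$sample[samples$role == "output"]
  ins <- samples$sample[samples$role == "input"]
  if (length(ins) == 0L || length(outs) == 0L)
    stop("need at least one input and one output sample")
  input_for <- if (length(ins) >= length(outs)) ins[seq_along(outs)]
               else rep(ins[1], length(outs))
  data.frame(output = outs, input = input_for, stringsAsFactors = FALSE)
}

#' Rank direction-filtered shRNAs and flag top-percentile qualifiers
#'
#' Filters to the requested direction (enriched: mean log2 fold change
#' greater than 0; depleted: less than 0), ranks by fold-change magnitude in
#' decreasing order (ties broken by shRNA id, lexicographic), and flags the
#' hairpins whose rank is at most `floor(percentile/100 * n_filtered)` -- the
#' "top 25th percentile of enriched shRNAs" rule.
#'
#' @param stats data.frame from [shrna_log2fc()].
#' @param direction `"enriched"` or `"depleted"`.
#' @param percentile top percentile cut, in (0, 100).
#' @return the direction-filtered rows with `rank` and `qualifies` added
#'   (empty data.frame, with a warning, if nothing passes the filter).
#' @examples
#' st <- data.frame(shrna_id = letters[1:6], mean_log2fc = c(3, 2.5, 2, 1, .5, .1))
#' rank_and_qualify(st, "enriched", percentile = 50)  # top 3 qualify
#' @export
rank_and_qualify <- function(stats, direction = c("enriched", "depleted"),
                             percentile = 25) {
  direction <- match.arg(direction)
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly between 0 and 100")
  keep <- if (direction == "enriched") stats$mean_log2fc > 0
          else stats$mean_log2fc < 0
  sub <- stats[keep, , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning("no shRNAs in direction '", direction, "'")
    sub$rank <- integer(0); sub$qualifies <- logical(0)
    return(sub)
  }
  o <- order(-abs(sub$mean_log2fc), sub$shrna_id)
  sub <- sub[o, , drop = FALSE]
  sub$rank <- seq_len(nrow(sub))
  n_top <- floor(percentile / 100 * nrow(sub))
  sub$qualifies <- sub$rank <= n_top
  rownames(sub) <- NULL
  sub
}

#' Gene-level hit calling from qualifying shRNAs
#'
#' A gene is a hit when at least `min_multiple` of its hairpins qualify
#' (rank within the top percentile of the direction-filtered set). Control
#' hairpins never contribute to gene calls. Output covers every targeted
#' gene in the manifest and is sorted by the number of qualifying hairpins
#' (decreasing), then gene.
#'
#' @param stats data.frame from [rank_and_qualify()] (must carry
#'   `qualifies`).
#' @param manifest library manifest (`shrna_id`, `gene`, `is_control`).
#' @param min_multiple minimal number of qualifying hairpins ("multiple
#'   shRNAs" = at least 2 by default).
#' @param direction direction label recorded in the output.
#' @return data.frame with `gene`, `n_shrnas`, `n_qualifying`, `hit`,
#'   `direction`.
#' @export
call_hits <- function(stats, manifest, min_multiple = 2,
                      direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  if (is.null(stats$qualifies)) stop("stats must carry qualifies flags")
  unknown <- setdiff(stats$shrna_id, manifest$shrna_id)
  if (length(unknown))
    stop("shRNA(s) absent from manifest: ", paste(unknown, collapse = ", "))
  targeting <- manifest[!manifest$is_control, , drop = FALSE]
  genes <- sort(unique(targeting$gene))
  n_shrnas <- as.integer(table(factor(targeting$gene, levels = genes)))
  qual_ids <- stats$shrna_id[stats$qualifies]
  qual_genes <- targeting$gene[match(qual_ids, targeting$shrna_id)]
  qual_genes <- qual_genes[!is.na(qual_genes)]  # controls never count
  n_qual <- as.integer(table(factor(qual_genes, levels = genes)))
  out <- data.frame(gene = genes, n_shrnas = n_shrnas, n_qualifying = n_qual,
                    hit = n_qual >= min_multiple, direction = direction,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_qualifying, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full screen scoring pipeline
#'
#' Chains [normalize_cpm()], [shrna_log2fc()], [rank_and_qualify()] and
#' [call_hits()] with the defaults the analysis uses (CPM with pseudocount
#' 0.5, top 25th percentile, at least 2 qualifying hairpins).
#'
#' @param counts shRNA x sample count matrix.
#' @param samples sample sheet with `sample`, `role`, `replicate`.
#' @param manifest library manifest.
#' @param direction `"enriched"` (candidate tumor suppressors) or
#'   `"depleted"`.
#' @param percentile,min_multiple,pseudocount see the stage functions.
#' @return list with `shrna_stats` (ranked, filtered) and `gene_calls`.
#' @export
screen_pipeline <- function(counts, samples, manifest,
                            direction = c("enriched", "depleted"),
                            percentile = 25, min_multiple = 2,
                            pseudocount = 0.5) {
  direction <- match.arg(direction)
  cpm <- normalize_cpm(counts, pseudocount)
  stats <- shrna_log2fc(cpm, default_pairing(samples))
  ranked <- rank_and_qualify(stats, direction, percentile)
  list(shrna_stats = ranked,
       gene_calls = call_hits(ranked, manifest, min_multiple, direction))
}
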