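# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

#' Derive a deterministic child seed
#'
#' Mixes a base seed with an index and an optional salt so that every
#' patient / focus / stage gets its own reproducible stream. The result is
#' kept below 2^31 so it is always a valid R integer seed.
#'
#' @param base integer base seed.
#' @param index integer index (e.g. patient number).
#' @param salt integer salt distinguishing uses of the same index.
#' @return an integer seed.
#' @export
derive_seed <- function(base, index, salt = 0L) {
  as.integer((abs(as.numeric(base)) + 7919 * abs(as.numeric(index)) +
                104729 * abs(as.numeric(salt))) %% 2147483629)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# canonical variant key used everywhere variants are compared
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# query points and segments as GRanges on a shared contig universe (the
# two tables may legitimately cover different contigs)
point_segment_granges <- function(chrom, pos, segments) {
  lv <- unique(c(as.character(chrom), as.character(segments$contig)))
  list(q = GenomicRanges::GRanges(factor(chrom, levels = lv),
                                  IRanges::IRanges(pos, pos)),
       s = GenomicRanges::GRanges(factor(segments$contig, levels = lv),
                                  IRanges::IRanges(segments$start + 1,
                                                   segments$end)))
}

# 1-based point positions against 0-based half-open segments
points_in_segments <- function(chrom, pos, segments) {
  if (is.null(segments) || nrow(segments) == 0) {
    return(rep(FALSE, length(chrom)))
  }
  gr <- point_segment_granges(chrom, pos, segments)
  IRanges::overlapsAny(gr$q, gr$s)
}

# index (row of `segments`) of the segment covering each point, NA if none;
# first covering segment wins (sets are validated non-overlapping upstream)
segment_index_at <- function(chrom, pos, segments) {
  if (is.null(segments) || nrow(segments) == 0) {
    return(rep(NA_integer_, length(chrom)))
  }
  gr <- point_segment_granges(chrom, pos, segments)
  hits <- GenomicRanges::findOverlaps(gr$q, gr$s, select = "first")
  as.integer(hits)
}
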