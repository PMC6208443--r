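#' Read a per-cytosine methylation report
#'
#' Parses a CX-report-style TSV with columns chrom, 1-based position, strand,
#' context (CG/CHG/CHH), methylated read count and total read count. Records
#' violating `count_methylated <= count_total` are rejected with the
#' offending line number.
#'
#' @param path Path to a tab-separated file without header.
#' @return A `data.table` with columns `chrom`, `pos`, `strand`, `context`,
#'   `count_methylated`, `count_total`.
#' @export
read_cytosine_report <- function(path) {
  cols <- c("chrom", "pos", "strand", "context",
            "count_methylated", "count_total")
  if (file.size(path) == 0) {
    dt <- data.table::data.table(
      chrom = character(), pos = integer(), strand = character(),
      context = character(), count_methylated = integer(),
      count_total = integer())
    return(dt)
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = cols,
                          colClasses = list(character = c(1, 3, 4),
                                            integer = c(2, 5, 6)))
  validate_cytosine_table(dt)
  dt
}

validate_cytosine_table <- function(dt) {
  if (nrow(dt) == 0) return(invisible(dt))
  bad <- which(!(dt$strand %in% c("+", "-")))
  if (length(bad)) stop("invalid strand on line ", bad[1], call. = FALSE)
  bad <- which(!(dt$context %in% c("CG", "CHG", "CHH")))
  if (length(bad)) stop("invalid context on line ", bad[1], call. = FALSE)
  bad <- which(dt$pos < 1 | dt$count_methylated < 0 | dt$count_total < 0)
  if (length(bad)) stop("invalid field on line ", bad[1], call. = FALSE)
  bad <- which(dt$count_methylated > dt$count_total)
  if (length(bad)) {
    stop(sprintf(
      "count_methylated > count_total on line %d (%s:%d)",
      bad[1], dt$chrom[bad[1]], dt$pos[bad[1]]), call. = FALSE)
  }
  invisible(dt)
}

#' @rdname read_cytosine_report
#' @param table A cytosine table as returned by [read_cytosine_report()].
#' @export
write_cytosine_report <- function(table, path) {
  validate_cytosine_table(data.table::as.data.table(table))
  data.table::fwrite(table, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read and write BED interval files
#'
#' BED convention: 0-based half-open intervals. Columns beyond the first
#' three (`name`, `score`, `strand`) are optional and preserved when present.
#' When `chrom_sizes` is supplied, out-of-bounds intervals are an error.
#'
#' @param path File path.
#' @param chrom_sizes Optional chromosome-size table for bounds checking.
#' @return Data frame with columns `chrom`, `start`, `end` and any of
#'   `name`, `score`, `strand` present in the file.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, seq_len(min(ncol(dt), 6L)),
                       nm[seq_len(min(ncol(dt), 6L))])
  df <- as.data.frame(dt)
  if (any(df$start < 0) || any(df$start >= df$end)) {
    stop("malformed BED interval (start < 0 or start >= end)", call. = FALSE)
  }
  if (!is.null(chrom_sizes)) {
    check_chrom_sizes(chrom_sizes)
    len <- setNames(chrom_sizes$length, chrom_sizes$chrom)
    if (any(!(df$chrom %in% names(len))) ||
        any(df$end > len[df$chrom])) {
      stop("BED interval outside chromosome bounds", call. = FALSE)
    }
  }
  df
}

#' @rdname read_bed
#' @param regions Region data frame to write.
#' @export
write_bed <- function(regions, path) {
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(regions))
  # BED columns are positional: truncate at the first absent one
  want <- c("chrom", "start", "end", "name", "score", "strand")
  upto <- which(!(want %in% keep))
  if (length(upto)) want <- want[seq_len(min(upto) - 1L)]
  data.table::fwrite(regions[, want, drop = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path Path to a 4-column bedGraph (chrom, start, end, value).
#' @param total_mapped Optional scalar of total mapped reads for per-million
#'   normalization; stored on the returned track.
#' @return A `coverage_track` object (see [coverage_track()]).
#' @export
read_bedgraph <- function(path, total_mapped = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  coverage_track(as.data.frame(dt), total_mapped = total_mapped)
}

#' @rdname read_bedgraph
#' @param track A `coverage_track`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  data.table::fwrite(track$intervals, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to whitespace-separated chromosome/length file.
#' @return Data frame with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "length"))
  df <- as.data.frame(dt)
  check_chrom_sizes(df)
  df
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes Chromosome-size data frame.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  check_chrom_sizes(chrom_sizes)
  data.table::fwrite(chrom_sizes[, c("chrom", "length")], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Tile a genome into fixed-width bins
#'
#' Each chromosome is tiled left to right; the last bin is truncated at the
#' chromosome end.
#'
#' @param chrom_sizes Chromosome-size data frame (`chrom`, `length`).
#' @param bin_size Bin width in bp (default 100).
#' @return Data frame of bins (`chrom`, `start`, `end`, `bin_id`), 0-based
#'   half-open, ordered by chromosome then position.
#' @export
make_bins <- function(chrom_sizes, bin_size = 100L) {
  check_chrom_sizes(chrom_sizes)
  stopifnot(bin_size > 0)
  pieces <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    len <- chrom_sizes$length[i]
    starts <- seq.int(0L, len - 1L, by = bin_size)
    data.frame(chrom = chrom_sizes$chrom[i], start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$bin_id <- seq_len(nrow(bins))
  bins
}

#' Aggregate per-cytosine counts into per-bin methylation summaries
#'
#' Pools methylated and total read counts of all cytosines of one context
#' falling in each bin, and tallies how many of those cytosines are covered
#' by at least `read_floor` reads. Under-covered cytosines still contribute
#' their reads to the pooled counts; the tally is used downstream only as a
#' bin-eligibility filter. A cytosine at 1-based position p is assigned to
#' the bin containing 0-based position p-1.
#'
#' @param cytosines Cytosine table ([read_cytosine_report()]).
#' @param bins Bin grid from [make_bins()].
#' @param context One of "CG", "CHG", "CHH".
#' @param read_floor Minimum total reads for a cytosine to count as covered
#'   (default 4).
#' @return Data frame with one row per bin (empty bins included):
#'   `chrom`, `start`, `end`, `bin_id`, `meth_reads`, `total_reads`,
#'   `n_cytosines_covered`, `level` (NA where `total_reads` is 0).
#' @export
aggregate_bins <- function(cytosines, bins, context, read_floor = 4L) {
  stopifnot(context %in% c("CG", "CHG", "CHH"))
  cy <- data.table::as.data.table(cytosines)
  keep_ctx <- cy[["context"]] == context
  cy <- cy[which(keep_ctx)]
  bin_size <- max(bins$end - bins$start)
  bt <- data.table::as.data.table(bins)

  chrom_end <- bt[, list(len = max(end)), by = "chrom"]
  if (nrow(cy)) {
    m <- merge(cy, chrom_end, by = "chrom", all.x = TRUE)
    if (any(is.na(m$len)) || any(m$pos > m$len)) {
      stop("cytosine beyond chromosome end", call. = FALSE)
    }
  }

  cy$start <- ((cy$pos - 1L) %/% bin_size) * bin_size
  agg <- cy[, list(
    meth_reads = sum(count_methylated),
    total_reads = sum(count_total),
    n_cytosines_covered = sum(count_total >= read_floor)
  ), by = c("chrom", "start")]

  out <- merge(bt, agg, by = c("chrom", "start"), all.x = TRUE)
  for (col in c("meth_reads", "total_reads", "n_cytosines_covered")) {
    data.table::set(out, which(is.na(out[[col]])), col, 0L)
  }
  out$level <- ifelse(out$total_reads > 0,
                      out$meth_reads / out$total_reads, NA_real_)
  data.table::setorderv(out, "bin_id")
  as.data.frame(out)
}
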