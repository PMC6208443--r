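#' DMR-calling parameters
#'
#' Defaults follow the binwise Fisher-exact recipe used for plant bisulfite
#' data: 100-bp bins; minimum absolute methylation difference of 0.4 (CG),
#' 0.2 (CHG) and 0.1 (CHH); BH-corrected FDR below 0.01; and a coverage
#' filter keeping only bins with at least `min_cytosines` cytosines covered
#' by at least `read_floor` reads in both samples.
#'
#' @param bin_size Bin width in bp.
#' @param delta_min Named numeric of per-context minimum absolute level
#'   differences.
#' @param fdr_max Maximum BH-adjusted q-value.
#' @param min_cytosines Minimum covered cytosines per bin, each sample.
#' @param read_floor Reads needed for a cytosine to count as covered.
#' @return A list of class `dmr_params`.
#' @export
dmr_params <- function(bin_size = 100L,
                       delta_min = c(CG = 0.4, CHG = 0.2, CHH = 0.1),
                       fdr_max = 0.01,
                       min_cytosines = 4L,
                       read_floor = 4L) {
  stopifnot(all(delta_min > 0), all(delta_min <= 1),
            fdr_max > 0, fdr_max < 1, bin_size > 0,
            all(c("CG", "CHG", "CHH") %in% names(delta_min)))
  structure(list(bin_size = as.integer(bin_size), delta_min = delta_min,
                 fdr_max = fdr_max, min_cytosines = as.integer(min_cytosines),
                 read_floor = as.integer(read_floor)),
            class = "dmr_params")
}

#' Two-sided Fisher's exact test on a methylation 2x2 table
#'
#' Tests the table \code{[[methA, totalA-methA], [methB, totalB-methB]]} of
#' pooled methylated versus unmethylated read counts for one bin. The
#' two-sided p-value follows the point-probability rule: the sum of all
#' hypergeometric outcomes whose probability does not exceed that of the
#' observed table (within a 1 + 1e-7 relative tolerance, the convention used
#' by [stats::fisher.test()]).
#'
#' @param meth_a,total_a Methylated and total read counts in sample A.
#' @param meth_b,total_b Methylated and total read counts in sample B.
#' @return Two-sided p-value; `NA` if either total is zero.
#' @export
fisher_bin <- function(meth_a, total_a, meth_b, total_b) {
  stopifnot(meth_a <= total_a, meth_b <= total_b,
            meth_a >= 0, meth_b >= 0)
  if (total_a == 0 || total_b == 0) return(NA_real_)
  m <- meth_a + meth_b              # white balls: methylated reads
  n <- (total_a - meth_a) + (total_b - meth_b)
  k <- total_a                      # draws: reads in sample A
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  d <- dhyper(support, m, n, k)
  p_obs <- d[meth_a - lo + 1L]
  p <- sum(d[d <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in \[0, 1\]; `NA`s propagate.
#' @return q-values: `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1,
#'   returned in the input order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(q)
  stopifnot(all(pv >= 0 & pv <= 1))
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  q
}

#' Call differentially methylated 100-bp bins between two samples
#'
#' The tested set consists of bins where both samples have at least
#' `min_cytosines` cytosines covered by at least `read_floor` reads and
#' non-zero pooled totals. Each tested bin gets a two-sided Fisher exact
#' p-value on pooled read counts; BH adjustment is applied across the tested
#' set of this context genome-wide. Bins with `q <= fdr_max` and
#' `|delta| >= delta_min[context]` are reported as DMRs, hypo where the
#' level in `sample_b` is below `sample_a` (A is the wild-type reference).
#'
#' @param sample_a,sample_b Per-bin aggregates from [aggregate_bins()] on
#'   the same bin grid (A = reference / wild-type).
#' @param context Cytosine context the aggregates were computed for.
#' @param params A [dmr_params()] object.
#' @return A list with `dmrs` (significant bins with `direction`, `delta`,
#'   `p_value`, `q_value` and per-sample counts) and `audit` (every bin with
#'   its filter status and statistics).
#' @export
call_dmrs <- function(sample_a, sample_b, context, params = dmr_params()) {
  stopifnot(context %in% c("CG", "CHG", "CHH"))
  if (nrow(sample_a) != nrow(sample_b) ||
      !all(sample_a$bin_id == sample_b$bin_id) ||
      !all(sample_a$start == sample_b$start) ||
      !all(sample_a$chrom == sample_b$chrom)) {
    stop("samples are not aggregated on the same bin grid", call. = FALSE)
  }
  audit <- data.frame(
    chrom = sample_a$chrom, start = sample_a$start, end = sample_a$end,
    bin_id = sample_a$bin_id, context = context,
    meth_a = sample_a$meth_reads, total_a = sample_a$total_reads,
    cyt_a = sample_a$n_cytosines_covered,
    meth_b = sample_b$meth_reads, total_b = sample_b$total_reads,
    cyt_b = sample_b$n_cytosines_covered,
    stringsAsFactors = FALSE
  )
  audit$level_a <- ifelse(audit$total_a > 0, audit$meth_a / audit$total_a, NA)
  audit$level_b <- ifelse(audit$total_b > 0, audit$meth_b / audit$total_b, NA)
  audit$delta <- audit$level_b - audit$level_a
  audit$tested <- audit$cyt_a >= params$min_cytosines &
    audit$cyt_b >= params$min_cytosines &
    audit$total_a > 0 & audit$total_b > 0

  audit$p_value <- NA_real_
  idx <- which(audit$tested)
  if (length(idx)) {
    audit$p_value[idx] <- mapply(
      fisher_bin,
      audit$meth_a[idx], audit$total_a[idx],
      audit$meth_b[idx], audit$total_b[idx]
    )
  }
  audit$q_value <- NA_real_
  audit$q_value[idx] <- bh_adjust(audit$p_value[idx])

  dmin <- params$delta_min[[context]]
  sig <- audit$tested & !is.na(audit$q_value) &
    audit$q_value <= params$fdr_max & abs(audit$delta) >= dmin
  audit$called <- sig
  dmrs <- audit[sig, , drop = FALSE]
  dmrs$direction <- ifelse(dmrs$delta < 0, "hypo", "hyper")
  rownames(dmrs) <- NULL
  list(dmrs = dmrs, audit = audit)
}

#' Merge adjacent same-direction DMR bins
#'
#' Unions runs of significant bins of the same context and direction whose
#' gap is at most `max_gap` bp; the merged delta is recomputed from pooled
#' read counts. Bin-level counts remain the primary reporting unit; merging
#' is a convenience for genome-browser style output.
#'
#' @param dmrs The `dmrs` data frame from [call_dmrs()].
#' @param max_gap Maximum gap in bp between merged bins (default 0).
#' @return Data frame of merged regions with pooled counts and deltas.
#' @export
merge_adjacent <- function(dmrs, max_gap = 0L) {
  cols <- c("chrom", "start", "end", "context", "direction",
            "meth_a", "total_a", "meth_b", "total_b")
  if (nrow(dmrs) == 0) {
    out <- dmrs[, intersect(cols, names(dmrs)), drop = FALSE]
    out$delta <- numeric(0)
    return(out)
  }
  d <- dmrs[order(dmrs$chrom, dmrs$start), cols, drop = FALSE]
  new_run <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
                 d$direction[-1] != d$direction[-nrow(d)] |
                 d$start[-1] - d$end[-nrow(d)] > max_gap)
  run <- cumsum(new_run)
  dt <- data.table::as.data.table(d)
  dt$run <- run
  out <- dt[, list(
    chrom = chrom[1], start = min(start), end = max(end),
    context = context[1], direction = direction[1],
    meth_a = sum(meth_a), total_a = sum(total_a),
    meth_b = sum(meth_b), total_b = sum(total_b),
    n_bins = .N
  ), by = "run"]
  out$delta <- out$meth_b / out$total_b - out$meth_a / out$total_a
  out$run <- NULL
  as.data.frame(out)
}
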