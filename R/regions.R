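#' Overlap statistics between two region sets
#'
#' Counts, both ways, the elements of one set sharing at least `min_bp` with
#' any element of the other, the style of statistic behind "91% (11 of 12)"
#' reporting. Percentages are returned at full precision together with their
#' nearest-integer rounding.
#'
#' @param a,b Region data frames (`chrom`, `start`, `end`, BED convention).
#' @param min_bp Minimum shared bp for an element to count as overlapping.
#' @param chrom_sizes Optional chromosome sizes; supplying different genomes
#'   for the two sets is an error caught by bounds checking.
#' @return List with element counts, overlap counts, percentages
#'   (`pct_a`, `pct_b` full precision; `pct_a_int`, `pct_b_int` rounded) and
#'   the shared/unique row indices of each set.
#' @export
overlap_sets <- function(a, b, min_bp = 1L, chrom_sizes = NULL) {
  gr_a <- regions_to_gr(a, chrom_sizes)
  gr_b <- regions_to_gr(b, chrom_sizes)
  # harmonize seqlevels so fully disjoint chromosome sets compare silently
  lv <- union(GenomeInfoDb::seqlevels(gr_a), GenomeInfoDb::seqlevels(gr_b))
  GenomeInfoDb::seqlevels(gr_a) <- lv
  GenomeInfoDb::seqlevels(gr_b) <- lv
  hits_a <- GenomicRanges::findOverlaps(gr_a, gr_b, minoverlap = min_bp,
                                        ignore.strand = TRUE)
  ov_a <- unique(S4Vectors::queryHits(hits_a))
  ov_b <- unique(S4Vectors::subjectHits(hits_a))
  n_a <- nrow(a); n_b <- nrow(b)
  pct_a <- if (n_a) 100 * length(ov_a) / n_a else NA_real_
  pct_b <- if (n_b) 100 * length(ov_b) / n_b else NA_real_
  list(
    n_a = n_a, n_b = n_b,
    n_a_overlapping_b = length(ov_a),
    n_b_overlapping_a = length(ov_b),
    pct_a = pct_a, pct_b = pct_b,
    pct_a_int = if (is.na(pct_a)) NA_integer_ else as.integer(round(pct_a)),
    pct_b_int = if (is.na(pct_b)) NA_integer_ else as.integer(round(pct_b)),
    # truncated display variant ("91% (11 of 12)" style reporting)
    pct_a_floor = if (is.na(pct_a)) NA_integer_ else as.integer(floor(pct_a)),
    pct_b_floor = if (is.na(pct_b)) NA_integer_ else as.integer(floor(pct_b)),
    shared_a = sort(ov_a), unique_a = setdiff(seq_len(n_a), ov_a),
    shared_b = sort(ov_b), unique_b = setdiff(seq_len(n_b), ov_b)
  )
}

#' Genomic-context composition of a region set
#'
#' Assigns each region to exactly one category - TE, gene, or intergenic -
#' by the majority of its bp, with ties broken toward TE (then gene). bp
#' covered by both a TE and a gene count toward TE.
#'
#' @param regions Regions to classify.
#' @param genes,tes Annotation region sets.
#' @param chrom_sizes Chromosome sizes used to build per-bp masks.
#' @return List with `assignment` (per-region category) and `fractions`
#'   (named fractions summing to 1).
#' @export
annotate_composition <- function(regions, genes, tes, chrom_sizes) {
  stopifnot(nrow(regions) > 0)
  te_mask <- region_mask(tes, chrom_sizes)
  gene_mask <- region_mask(genes, chrom_sizes)
  gr <- regions_to_gr(regions, chrom_sizes)
  te_bp <- bp_in_mask(gr, te_mask)
  gene_only_bp <- bp_in_mask(gr, gene_mask * (te_mask == 0L))
  width <- GenomicRanges::width(gr)
  inter_bp <- width - te_bp - gene_only_bp
  cat <- character(nrow(regions))
  for (i in seq_along(cat)) {
    v <- c(TE = te_bp[i], gene = gene_only_bp[i], intergenic = inter_bp[i])
    cat[i] <- names(v)[which.max(v)]  # which.max keeps first max: TE > gene
  }
  frac <- table(factor(cat, levels = c("TE", "gene", "intergenic")))
  fractions <- setNames(as.numeric(frac) / nrow(regions), names(frac))
  list(assignment = cat, fractions = fractions)
}

# bp of each range covered by a 0/1 (or small-integer, clamped) RleList mask
bp_in_mask <- function(gr, mask) {
  mask <- S4Vectors::endoapply(mask, function(r) S4Vectors::Rle(
    pmin(S4Vectors::runValue(r), 1L), S4Vectors::runLength(r)))
  out <- numeric(length(gr))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    if (!(ch %in% names(mask))) next
    r <- mask[[ch]]
    need <- max(GenomicRanges::end(gr)[idx])
    if (length(r) < need) {  # pad: masks built without seqlengths stop early
      r <- c(r, S4Vectors::Rle(0L, need - length(r)))
    }
    v <- IRanges::Views(r,
                        IRanges::IRanges(GenomicRanges::start(gr)[idx],
                                         GenomicRanges::end(gr)[idx]))
    out[idx] <- IRanges::viewSums(v)
  }
  out
}

#' Transposable-element family enrichment in a DMR set
#'
#' For each TE family, fold enrichment is the family's bp share among
#' DMR-overlapped TE bp divided by its bp share among all TE bp, with a
#' hypergeometric p-value on TE counts (family TEs among DMR-overlapped TEs
#' versus the genome). The choice of statistic is a reconstruction of
#' standard practice; treat the p-values as screening values.
#'
#' @param dmrs DMR (or any region) set.
#' @param tes TE regions with a `family` column.
#' @return Data frame per family: TE counts, bp shares, `fold`, `p_value`.
#'   Empty `dmrs` give an empty result.
#' @export
te_family_enrichment <- function(dmrs, tes) {
  stopifnot("family" %in% names(tes))
  fams <- sort(unique(tes$family))
  if (nrow(dmrs) == 0) {
    return(data.frame(family = character(), n_te = integer(),
                      n_hit = integer(), fold = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  gr_te <- regions_to_gr(tes)
  gr_dmr <- regions_to_gr(dmrs)
  hit <- IRanges::overlapsAny(gr_te, gr_dmr, ignore.strand = TRUE)
  te_len <- tes$end - tes$start
  # bp of each TE intersected by the DMR union
  ov <- GenomicRanges::intersect(gr_te, GenomicRanges::reduce(gr_dmr),
                                 ignore.strand = TRUE)
  cov_bp <- bp_in_mask(gr_te, GenomicRanges::coverage(ov))
  tot_hit_bp <- sum(cov_bp)
  tot_bp <- sum(te_len)
  n_hit_all <- sum(hit)
  out <- lapply(fams, function(f) {
    in_f <- tes$family == f
    fam_bp <- sum(te_len[in_f])
    fam_hit_bp <- sum(cov_bp[in_f])
    fold <- if (fam_bp == 0 || tot_hit_bp == 0) NA_real_ else
      (fam_hit_bp / tot_hit_bp) / (fam_bp / tot_bp)
    # P(X >= observed) drawing n_hit_all TEs without replacement
    p <- stats::phyper(sum(hit & in_f) - 1, sum(in_f),
                       sum(!in_f), n_hit_all, lower.tail = FALSE)
    data.frame(family = f, n_te = sum(in_f), n_hit = sum(hit & in_f),
               fold = fold, p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Occupancy parameters for bound-TE classification
#'
#' @param bound_te_min_overlap_fraction A TE is bound iff strictly more than
#'   this fraction of its length is covered by the peak union (default 0.8).
#' @param long_te_threshold Long/short TE length cutoff in bp (default 4000).
#' @param n_control_sets Number of shuffled control sets (default 3).
#' @return List of class `occupancy_params`.
#' @export
occupancy_params <- function(bound_te_min_overlap_fraction = 0.8,
                             long_te_threshold = 4000L,
                             n_control_sets = 3L) {
  stopifnot(bound_te_min_overlap_fraction > 0,
            bound_te_min_overlap_fraction <= 1,
            long_te_threshold > 0)
  structure(list(bound_te_min_overlap_fraction = bound_te_min_overlap_fraction,
                 long_te_threshold = as.integer(long_te_threshold),
                 n_control_sets = as.integer(n_control_sets)),
            class = "occupancy_params")
}

#' Classify TEs as peak-bound by fractional coverage
#'
#' A TE is "bound" iff the bp of the TE covered by the union of peaks,
#' divided by the TE length, strictly exceeds the threshold fraction
#' (default 0.8: a TE at exactly 80% coverage is not bound).
#'
#' @param tes TE regions.
#' @param peaks Peak regions.
#' @param params [occupancy_params()].
#' @return List with the annotated `tes` data frame (columns
#'   `covered_fraction`, `bound`, `long`), plus length summaries of bound
#'   and all TEs.
#' @export
classify_bound_tes <- function(tes, peaks, params = occupancy_params()) {
  te_len <- tes$end - tes$start
  if (nrow(peaks) == 0) {
    frac <- rep(0, nrow(tes))
  } else {
    gr_te <- regions_to_gr(tes)
    frac <- bp_in_mask(gr_te, region_mask(peaks, NULL)) / te_len
  }
  out <- tes
  out$length <- te_len
  out$covered_fraction <- frac
  out$bound <- frac > params$bound_te_min_overlap_fraction
  out$long <- te_len > params$long_te_threshold
  list(
    tes = out,
    n_bound = sum(out$bound),
    bound_lengths = te_len[out$bound],
    all_lengths = te_len,
    median_bound_length = if (any(out$bound)) median(te_len[out$bound]) else NA,
    median_all_length = median(te_len)
  )
}

#' Length-matched shuffled control regions
#'
#' Generates `n_sets` region sets carrying the identical multiset of input
#' lengths, placed uniformly at random: a chromosome is chosen with
#' probability proportional to its length, then a start uniform over the
#' positions keeping the region inside the chromosome. Mirrors the semantics
#' of `bedtools shuffle`. Controls may overlap one another unless
#' `allow_self_overlap = FALSE` (rejection sampling).
#'
#' @param regions Regions whose lengths are matched.
#' @param chrom_sizes Chromosome sizes.
#' @param seed Integer seed.
#' @param n_sets Number of control sets.
#' @param exclude Optional regions that controls must not touch.
#' @param allow_self_overlap Allow controls within a set to overlap
#'   (default TRUE).
#' @param max_tries Rejection-sampling cap per region.
#' @return List of `n_sets` region data frames.
#' @export
shuffle_regions <- function(regions, chrom_sizes, seed, n_sets = 1L,
                            exclude = NULL, allow_self_overlap = TRUE,
                            max_tries = 1000L) {
  check_chrom_sizes(chrom_sizes)
  lens <- regions$end - regions$start
  if (length(lens) && max(lens) > max(chrom_sizes$length)) {
    stop("a region is longer than every chromosome", call. = FALSE)
  }
  # per-chromosome exclusion intervals as plain vectors (fast clash checks)
  excl <- list()
  if (!is.null(exclude) && nrow(exclude)) {
    red <- gr_to_regions(GenomicRanges::reduce(regions_to_gr(exclude)))
    excl <- split(red[, c("start", "end")], red$chrom)
  }
  with_seed(split_seed(seed, "shuffle"), {
    lapply(seq_len(n_sets), function(s) {
      chroms <- character(length(lens))
      starts <- numeric(length(lens))
      placed <- lapply(chrom_sizes$chrom, function(x)
        list(start = numeric(0), end = numeric(0)))
      names(placed) <- chrom_sizes$chrom
      for (i in seq_along(lens)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          fits <- chrom_sizes$length >= lens[i]
          w <- chrom_sizes$length * fits
          ci <- sample.int(nrow(chrom_sizes), 1L, prob = w / sum(w))
          ch <- chrom_sizes$chrom[ci]
          st <- floor(runif(1, 0, chrom_sizes$length[ci] - lens[i] + 1))
          en <- st + lens[i]
          ex <- excl[[ch]]
          clash <- (!is.null(ex) && any(st < ex$end & en > ex$start)) ||
            (!allow_self_overlap &&
               any(st < placed[[ch]]$end & en > placed[[ch]]$start))
          if (!clash) {
            chroms[i] <- ch
            starts[i] <- st
            if (!allow_self_overlap) {
              placed[[ch]]$start <- c(placed[[ch]]$start, st)
              placed[[ch]]$end <- c(placed[[ch]]$end, en)
            }
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not place region ", i,
                      " after ", max_tries, " tries", call. = FALSE)
      }
      data.frame(chrom = chroms, start = as.integer(starts),
                 end = as.integer(starts + lens),
                 name = sprintf("shuffle%d_%d", s, seq_along(lens)),
                 stringsAsFactors = FALSE)
    })
  })
}

#' Per-window region density along chromosomes
#'
#' Assigns each region to the tiling window containing its midpoint, so the
#' window counts sum to the number of regions; used for chromosome-wide
#' distribution plots (pericentromeric concentration of DMRs or peaks).
#'
#' @param regions Region set.
#' @param chrom_sizes Chromosome sizes.
#' @param window Window width in bp (default 1e5).
#' @return Data frame of windows with a `count` column.
#' @export
chromosome_density <- function(regions, chrom_sizes, window = 100000L) {
  stopifnot(window > 0)
  wins <- make_bins(chrom_sizes, window)
  mid <- floor((regions$start + regions$end) / 2)
  key <- paste(regions$chrom, (mid %/% window) * window)
  tab <- table(key)
  wins$count <- as.integer(tab[paste(wins$chrom, wins$start)])
  wins$count[is.na(wins$count)] <- 0L
  wins
}
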