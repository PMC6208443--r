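# Internal helpers: seed splitting, validation, interval conversion.

# All randomness in the synthetic-data module flows from one integer master
# seed. Sub-streams are derived as (seed * 1009 + offset) mod 2^31 - 1, with a
# fixed named offset per stream, so that independent components (genome
# layout, cytosine map, per-genotype counts, ChIP noise, isotherm noise) are
# reproducible in isolation and never share a stream.
.SEED_OFFSETS <- c(
  genome    = 11L,
  cytosines = 23L,
  wildtype  = 37L,
  mutant    = 41L,
  chip      = 53L,
  itc       = 67L,
  shuffle   = 79L
)

split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  off <- .SEED_OFFSETS[[stream]]
  as.integer((as.double(seed) * 1009 + off) %% (2^31 - 1))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

# Region data frames use BED convention (0-based half-open). GRanges is
# 1-based closed; convert at the boundary and nowhere else.
regions_to_gr <- function(regions, chrom_sizes = NULL) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end") %in% names(regions)))
  if (nrow(regions) > 0 && any(regions$start >= regions$end)) {
    stop("invalid interval: start must be < end", call. = FALSE)
  }
  seqlen <- NULL
  if (!is.null(chrom_sizes)) {
    seqlen <- setNames(chrom_sizes$length, chrom_sizes$chrom)
    bad <- !(regions$chrom %in% chrom_sizes$chrom)
    if (any(bad)) {
      stop("interval on unknown chromosome: ", regions$chrom[which(bad)[1]],
           call. = FALSE)
    }
    oob <- regions$end > seqlen[regions$chrom] | regions$start < 0
    if (any(oob)) {
      stop("interval out of chromosome bounds at row ", which(oob)[1],
           call. = FALSE)
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    seqlengths = seqlen
  )
  if ("strand" %in% names(regions)) {
    st <- regions$strand
    st[!(st %in% c("+", "-"))] <- "*"
    GenomicRanges::strand(gr) <- st
  }
  gr
}

gr_to_regions <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Per-base numeric coverage of `regions` (union, clamped to 0/1) as RleList.
region_mask <- function(regions, chrom_sizes) {
  gr <- GenomicRanges::reduce(regions_to_gr(regions, chrom_sizes))
  GenomicRanges::coverage(gr)
}

check_chrom_sizes <- function(chrom_sizes) {
  stopifnot(is.data.frame(chrom_sizes),
            all(c("chrom", "length") %in% names(chrom_sizes)))
  if (any(chrom_sizes$length <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(chrom_sizes$chrom)) stop("duplicated chromosome names")
  invisible(chrom_sizes)
}
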