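#' Toy genome specification
#'
#' @param chromosomes Named integer vector of chromosome lengths in bp
#'   (default two 1-Mb chromosomes; real genome scale is irrelevant to the
#'   correctness of downstream statistics and desk-scale tests run in
#'   seconds).
#' @param centromere_center Per-chromosome centromere position as a fraction
#'   of length (recycled; default 0.5). The pericentromeric zone is the
#'   central third of the chromosome around this point.
#' @param seed Master integer seed; all randomness derives from it.
#' @return List of class `genome_spec`.
#' @export
genome_spec <- function(chromosomes = c(chr1 = 1000000L, chr2 = 1000000L),
                        centromere_center = 0.5, seed = 1L) {
  stopifnot(length(chromosomes) >= 1, all(chromosomes > 0),
            all(centromere_center > 0), all(centromere_center < 1))
  cc <- rep_len(centromere_center, length(chromosomes))
  structure(list(chromosomes = chromosomes, centromere_center = cc,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a toy annotated genome
#'
#' Emits a chromosome-size table, pericentromeric zones (the central third
#' of each chromosome), a TE annotation with family labels and a long/short
#' class, and a gene annotation. Long TEs (length strictly greater than
#' `long_te_threshold`) are placed with elevated probability inside the
#' pericentromeric zone, and heterochromatin-associated families
#' (LTR/Gypsy, LTR/Copia, DNA/En-Spm) dominate the long class - the
#' genomic structure the downstream analyses assume. Identical seeds give
#' identical output.
#'
#' @param spec A [genome_spec()].
#' @param long_te_threshold Long-TE length cutoff, bp (default 4000).
#' @param te_per_mb,gene_per_mb Approximate feature densities.
#' @param long_te_fraction Fraction of TEs drawn from the long class.
#' @param p_long_pericentromeric,p_short_pericentromeric Placement
#'   probabilities into the pericentromeric zone by class.
#' @param bin_size Minimum resolution; chromosomes shorter than 10 bins are
#'   rejected.
#' @return List of class `synthetic_genome`: `chrom_sizes`, `tes`, `genes`,
#'   `pericentromere`, and the parameters used.
#' @export
generate_genome <- function(spec, long_te_threshold = 4000L,
                            te_per_mb = 120, gene_per_mb = 150,
                            long_te_fraction = 0.25,
                            p_long_pericentromeric = 0.85,
                            p_short_pericentromeric = 0.4,
                            bin_size = 100L) {
  stopifnot(inherits(spec, "genome_spec"))
  if (any(spec$chromosomes < 10 * bin_size)) {
    stop("chromosome shorter than 10x bin size", call. = FALSE)
  }
  chrom_sizes <- data.frame(chrom = names(spec$chromosomes),
                            length = unname(as.integer(spec$chromosomes)),
                            stringsAsFactors = FALSE)
  peri <- data.frame(
    chrom = chrom_sizes$chrom,
    start = as.integer(pmax(0, round(chrom_sizes$length *
                                       (spec$centromere_center - 1 / 6)))),
    end = as.integer(pmin(chrom_sizes$length,
                          round(chrom_sizes$length *
                                  (spec$centromere_center + 1 / 6)))),
    stringsAsFactors = FALSE
  )
  long_fams <- c("LTR/Gypsy" = 0.5, "LTR/Copia" = 0.25,
                 "DNA/En-Spm" = 0.15, "other" = 0.1)
  short_fams <- c("LTR/Gypsy" = 0.15, "LTR/Copia" = 0.2,
                  "DNA/En-Spm" = 0.15, "other" = 0.5)

  res <- with_seed(split_seed(spec$seed, "genome"), {
    place <- function(n, lens, in_peri, ch_len, peri_zone, occupied) {
      # sequential uniform placement with rejection against prior features
      out <- matrix(NA_integer_, n, 2)
      for (i in seq_len(n)) {
        for (try in 1:200) {
          if (in_peri[i]) {
            lo <- peri_zone[1]; hi <- peri_zone[2] - lens[i]
          } else {
            lo <- 0L; hi <- ch_len - lens[i]
          }
          if (hi <= lo) break
          st <- floor(runif(1, lo, hi))
          cand <- IRanges::IRanges(st + 1, st + lens[i])
          if (length(IRanges::findOverlaps(cand, occupied)) == 0) {
            out[i, ] <- c(st, st + lens[i])
            occupied <- c(occupied, cand)
            break
          }
        }
      }
      list(pos = out, occupied = occupied)
    }
    tes <- list(); genes <- list()
    for (ci in seq_len(nrow(chrom_sizes))) {
      ch <- chrom_sizes$chrom[ci]; len <- chrom_sizes$length[ci]
      pz <- c(peri$start[ci], peri$end[ci])
      n_te <- max(2L, round(te_per_mb * len / 1e6))
      is_long <- runif(n_te) < long_te_fraction
      te_len <- integer(n_te)
      te_len[is_long] <- as.integer(round(runif(sum(is_long), 4500, 12000)))
      te_len[!is_long] <- as.integer(pmax(200, pmin(
        round(rlnorm(sum(!is_long), log(800), 0.6)), long_te_threshold)))
      in_peri <- runif(n_te) < ifelse(is_long, p_long_pericentromeric,
                                      p_short_pericentromeric)
      fam <- character(n_te)
      fam[is_long] <- sample(names(long_fams), sum(is_long), TRUE,
                             prob = long_fams)
      fam[!is_long] <- sample(names(short_fams), sum(!is_long), TRUE,
                              prob = short_fams)
      occupied <- IRanges::IRanges()
      p <- place(n_te, te_len, in_peri, len, pz, occupied)
      keep <- !is.na(p$pos[, 1])
      tes[[ch]] <- data.frame(
        chrom = ch, start = p$pos[keep, 1], end = p$pos[keep, 2],
        name = sprintf("%s_TE%d", ch, which(keep)),
        score = 0L,
        strand = sample(c("+", "-"), sum(keep), TRUE),
        family = fam[keep],
        stringsAsFactors = FALSE)
      n_gene <- max(2L, round(gene_per_mb * len / 1e6))
      g_len <- as.integer(pmax(500, round(rlnorm(n_gene, log(2000), 0.5))))
      g_peri <- runif(n_gene) < 0.1   # genes mostly on the arms
      pg <- place(n_gene, g_len, g_peri, len, pz, p$occupied)
      keep <- !is.na(pg$pos[, 1])
      genes[[ch]] <- data.frame(
        chrom = ch, start = pg$pos[keep, 1], end = pg$pos[keep, 2],
        name = sprintf("%s_gene%d", ch, which(keep)),
        score = 0L,
        strand = sample(c("+", "-"), sum(keep), TRUE),
        stringsAsFactors = FALSE)
    }
    list(tes = do.call(rbind, tes), genes = do.call(rbind, genes))
  })
  tes <- res$tes
  tes$length <- tes$end - tes$start
  tes$long <- tes$length > long_te_threshold
  rownames(tes) <- NULL
  genes <- res$genes
  rownames(genes) <- NULL
  structure(list(chrom_sizes = chrom_sizes, tes = tes, genes = genes,
                 pericentromere = peri,
                 long_te_threshold = as.integer(long_te_threshold),
                 seed = spec$seed),
            class = "synthetic_genome")
}

#' Methylome simulation model
#'
#' Baseline methylation probabilities reflect plant heterochromatin:
#' high CG/CHG and moderate CHH inside heterochromatin (TEs and
#' pericentromeres), low everywhere else. The mutant genotype loses
#' non-CG methylation inside the planted regions only: `mutant_delta` is a
#' signed per-context change (negative = hypomethylation) with CG
#' unchanged by default, emulating a non-CG-specific silencing mutant.
#'
#' @param baseline_het,baseline_arm Named per-context methylation
#'   probabilities inside and outside heterochromatin.
#' @param mutant_delta Named signed per-context change applied inside
#'   planted regions in the mutant.
#' @param coverage_mean Mean reads per cytosine (Poisson).
#' @param cytosine_density Named expected cytosines per 100 bp per context.
#' @return List of class `methylome_model`.
#' @export
methylome_model <- function(
    baseline_het = c(CG = 0.85, CHG = 0.7, CHH = 0.2),
    baseline_arm = c(CG = 0.1, CHG = 0.05, CHH = 0.03),
    mutant_delta = c(CG = 0, CHG = -0.5, CHH = -0.15),
    coverage_mean = 20,
    cytosine_density = c(CG = 6, CHG = 6, CHH = 10)) {
  for (v in list(baseline_het, baseline_arm)) {
    stopifnot(all(c("CG", "CHG", "CHH") %in% names(v)),
              all(v >= 0), all(v <= 1))
  }
  stopifnot(coverage_mean >= 0, all(cytosine_density > 0),
            all(abs(mutant_delta) <= 1))
  structure(list(baseline_het = baseline_het, baseline_arm = baseline_arm,
                 mutant_delta = mutant_delta, coverage_mean = coverage_mean,
                 cytosine_density = cytosine_density),
            class = "methylome_model")
}

# Cytosine positions are uniform at the configured density (the DMR caller
# consumes counts, not sequence) and shared between genotypes: the map is
# drawn from its own sub-seed so wild-type and mutant report the same sites.
cytosine_map <- function(genome, model, seed) {
  with_seed(split_seed(seed, "cytosines"), {
    out <- list()
    for (ci in seq_len(nrow(genome$chrom_sizes))) {
      ch <- genome$chrom_sizes$chrom[ci]
      len <- genome$chrom_sizes$length[ci]
      for (ctx in c("CG", "CHG", "CHH")) {
        n <- round(len * model$cytosine_density[[ctx]] / 100)
        pos <- sort(sample.int(len, n, replace = FALSE))
        out[[paste(ch, ctx)]] <- data.table::data.table(
          chrom = ch, pos = pos,
          strand = sample(c("+", "-"), n, TRUE),
          context = ctx)
      }
    }
    data.table::rbindlist(out)
  })
}

#' Simulate a per-cytosine methylome for one genotype
#'
#' Every cytosine's total read count is Poisson(`coverage_mean`) and its
#' methylated count Binomial(total, p), where p is the heterochromatin or
#' arm baseline for its context, lowered (or raised) by `mutant_delta`
#' inside the planted regions for the mutant genotype. The cytosine map is
#' shared between genotypes; count draws use a genotype-specific
#' sub-seed. The planted regions (default: the genome's long TEs) are
#' recorded ground truth, attached as the `planted_dmrs` attribute.
#'
#' @param genome A [generate_genome()] result.
#' @param model A [methylome_model()].
#' @param genotype "wildtype" or "mutant".
#' @param seed Master seed (use the same seed for both genotypes).
#' @param planted_dmrs Regions receiving the mutant delta (default: long
#'   TEs).
#' @return Cytosine `data.table` (chrom, pos, strand, context,
#'   count_methylated, count_total) with attribute `planted_dmrs`.
#' @export
simulate_methylome <- function(genome, model, genotype = c("wildtype",
                                                           "mutant"),
                               seed = 1L, planted_dmrs = NULL) {
  genotype <- match.arg(genotype)
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(model, "methylome_model"))
  if (is.null(planted_dmrs)) {
    planted_dmrs <- genome$tes[genome$tes$long, c("chrom", "start", "end")]
  }
  cy <- cytosine_map(genome, model, seed)

  het <- rbind(genome$tes[, c("chrom", "start", "end")],
               genome$pericentromere[, c("chrom", "start", "end")])
  in_het <- positions_in(cy, het)
  p <- numeric(nrow(cy))
  for (ctx in c("CG", "CHG", "CHH")) {
    sel <- cy$context == ctx
    p[sel] <- ifelse(in_het[sel], model$baseline_het[[ctx]],
                     model$baseline_arm[[ctx]])
  }
  if (genotype == "mutant" && nrow(planted_dmrs)) {
    in_planted <- positions_in(cy, planted_dmrs)
    for (ctx in c("CG", "CHG", "CHH")) {
      sel <- cy$context == ctx & in_planted
      p[sel] <- pmin(pmax(p[sel] + model$mutant_delta[[ctx]], 0), 1)
    }
  }
  counts <- with_seed(split_seed(seed, genotype), {
    total <- rpois(nrow(cy), model$coverage_mean)
    meth <- rbinom(nrow(cy), total, p)
    list(total = total, meth = meth)
  })
  cy$count_methylated <- counts$meth
  cy$count_total <- counts$total
  data.table::setcolorder(cy, c("chrom", "pos", "strand", "context",
                                "count_methylated", "count_total"))
  data.table::setorderv(cy, c("chrom", "pos"))
  attr(cy, "planted_dmrs") <- planted_dmrs
  cy[]
}

# TRUE for cytosines whose 0-based position pos-1 lies in any region
positions_in <- function(cy, regions) {
  if (nrow(regions) == 0) return(rep(FALSE, nrow(cy)))
  gr_cy <- GenomicRanges::GRanges(cy$chrom,
                                  IRanges::IRanges(cy$pos, width = 1))
  IRanges::overlapsAny(gr_cy, regions_to_gr(regions), ignore.strand = TRUE)
}

#' ChIP simulation model
#'
#' @param window Track window width, bp.
#' @param rate_het,rate_arm Expected H3K9me2 read counts per window inside
#'   and outside the target heterochromatin.
#' @param h3_rate Baseline H3 rate per window.
#' @param h3_peak_boost Mild multiplicative H3 elevation over the target
#'   (nucleosome density is slightly higher in heterochromatin).
#' @param agdp1_scale Scale a of the reader track: agdp1 = a x H3K9me2 x
#'   noise.
#' @param noise_sdlog Log-normal multiplicative noise sdlog applied per
#'   window per track (matches read-count overdispersion without a read
#'   simulator).
#' @param target "heterochromatin" (TEs plus pericentromere) or "long_tes"
#'   (signal only over long TEs, the preferential-binding scenario).
#' @return List of class `chip_model`.
#' @export
chip_model <- function(window = 100L, rate_het = 8, rate_arm = 1,
                       h3_rate = 5, h3_peak_boost = 0.3, agdp1_scale = 1,
                       noise_sdlog = 0.25,
                       target = c("heterochromatin", "long_tes")) {
  target <- match.arg(target)
  stopifnot(window > 0, rate_het > rate_arm, rate_arm >= 0, h3_rate > 0,
            noise_sdlog >= 0)
  structure(list(window = as.integer(window), rate_het = rate_het,
                 rate_arm = rate_arm, h3_rate = h3_rate,
                 h3_peak_boost = h3_peak_boost, agdp1_scale = agdp1_scale,
                 noise_sdlog = noise_sdlog, target = target),
            class = "chip_model")
}

#' Simulate ChIP coverage tracks and peaks
#'
#' Emits windowed bedGraph-style tracks: an H3K9me2 track elevated over the
#' target heterochromatin, an H3 track with a slight elevation there, an
#' AGDP1-like reader track equal to `agdp1_scale x H3K9me2` times
#' log-normal noise (so with zero noise the two are perfectly correlated),
#' and a flat input track. Peaks are the merged windows whose noiseless
#' target coverage is at least half the window, and the ground-truth bound
#' TEs (those the generator targeted) are emitted alongside.
#'
#' @param genome A [generate_genome()] result.
#' @param model A [chip_model()].
#' @param seed Master seed.
#' @return List of class `synthetic_chip`: `tracks` (named
#'   [coverage_track()]s: h3k9me2, h3, agdp1, input), `peaks`,
#'   `bound_tes` (ground truth), `target_mask` regions.
#' @export
simulate_chip <- function(genome, model = chip_model(), seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(model, "chip_model"))
  wins <- make_bins(genome$chrom_sizes, model$window)
  target_regions <- switch(model$target,
    heterochromatin = rbind(genome$tes[, c("chrom", "start", "end")],
                            genome$pericentromere[, c("chrom", "start",
                                                      "end")]),
    long_tes = genome$tes[genome$tes$long, c("chrom", "start", "end")])
  mask <- region_mask(target_regions, genome$chrom_sizes)
  frac <- bp_in_mask(regions_to_gr(wins, genome$chrom_sizes), mask) /
    (wins$end - wins$start)
  rate_k9 <- model$rate_arm + (model$rate_het - model$rate_arm) * frac
  rate_h3 <- model$h3_rate * (1 + model$h3_peak_boost * frac)

  vals <- with_seed(split_seed(seed, "chip"), {
    noise <- function(n) if (model$noise_sdlog > 0)
      rlnorm(n, -model$noise_sdlog^2 / 2, model$noise_sdlog) else rep(1, n)
    k9 <- rate_k9 * noise(nrow(wins))
    agdp1 <- model$agdp1_scale * k9 * noise(nrow(wins))
    h3 <- rate_h3 * noise(nrow(wins))
    input <- model$rate_arm * noise(nrow(wins))
    list(k9 = k9, agdp1 = agdp1, h3 = h3, input = input)
  })
  mk <- function(v) coverage_track(
    data.frame(chrom = wins$chrom, start = wins$start, end = wins$end,
               value = v),
    total_mapped = sum(v))

  peak_wins <- wins[frac >= 0.5, c("chrom", "start", "end")]
  peaks <- if (nrow(peak_wins)) {
    gr <- GenomicRanges::reduce(regions_to_gr(peak_wins,
                                              genome$chrom_sizes))
    df <- gr_to_regions(gr)
    df$name <- sprintf("peak%d", seq_len(nrow(df)))
    df
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), stringsAsFactors = FALSE)
  }
  bound <- classify_bound_tes(genome$tes, target_regions,
                              occupancy_params())$tes
  structure(list(
    tracks = list(h3k9me2 = mk(vals$k9), h3 = mk(vals$h3),
                  agdp1 = mk(vals$agdp1), input = mk(vals$input)),
    peaks = peaks,
    bound_tes = genome$tes[bound$bound, , drop = FALSE],
    target_mask = target_regions,
    window = model$window),
    class = "synthetic_chip")
}

#' Write a synthetic dataset to disk
#'
#' Emits chrom.sizes, BED files for TEs, genes, pericentromeres, planted
#' DMRs and peaks, CX-report TSVs per genotype, bedGraph tracks, and a JSON
#' ground-truth sidecar. Identical seeds give byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param genome [generate_genome()] result.
#' @param methylomes Named list of cytosine tables (e.g. wildtype, mutant).
#' @param chip Optional [simulate_chip()] result.
#' @param truth Optional list serialized to `ground_truth.json`.
#' @return Invisibly, the vector of files written.
#' @export
write_synthetic_dataset <- function(dir, genome, methylomes = list(),
                                    chip = NULL, truth = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  f <- function(name) file.path(dir, name)
  write_chrom_sizes(genome$chrom_sizes, f("genome.chrom.sizes"))
  write_bed(genome$tes, f("tes.bed"))
  write_bed(genome$genes, f("genes.bed"))
  write_bed(genome$pericentromere, f("pericentromere.bed"))
  files <- c(files, f(c("genome.chrom.sizes", "tes.bed", "genes.bed",
                        "pericentromere.bed")))
  truth$te_families <- as.list(table(genome$tes$family))
  for (nm in names(methylomes)) {
    write_cytosine_report(methylomes[[nm]],
                          f(sprintf("%s.cx.tsv", nm)))
    files <- c(files, f(sprintf("%s.cx.tsv", nm)))
    pd <- attr(methylomes[[nm]], "planted_dmrs")
    if (!is.null(pd)) {
      write_bed(pd, f("planted_dmrs.bed"))
      files <- c(files, f("planted_dmrs.bed"))
    }
  }
  if (!is.null(chip)) {
    for (nm in names(chip$tracks)) {
      write_bedgraph(chip$tracks[[nm]], f(sprintf("%s.bedgraph", nm)))
      files <- c(files, f(sprintf("%s.bedgraph", nm)))
    }
    write_bed(chip$peaks, f("peaks.bed"))
    write_bed(chip$bound_tes[, c("chrom", "start", "end", "name")],
              f("bound_tes.bed"))
    files <- c(files, f(c("peaks.bed", "bound_tes.bed")))
  }
  jsonlite::write_json(truth, f("ground_truth.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files <- c(files, f("ground_truth.json"))
  invisible(files)
}
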