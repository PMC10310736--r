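# Deterministic synthetic-fixture generator: a toy genome with gene models,
# dosage-sensitivity records, benign-CNV databases (all coordinate flavors),
# population variants, HI-predictor calls and labeled CNV sets with planted
# expected evidence, so every other module is testable without downloads.
#
# One integer seed drives everything; each file type draws from its own
# sub-seed (fixed offsets) so adding a record type never perturbs existing
# fixtures. Chromosomes are small (1e7 bp) to keep brute-force test oracles
# fast.

#' Specification of a synthetic fixture bundle
#'
#' @param seed Integer master seed; identical seeds give byte-identical files.
#' @param n_chromosomes Number of chromosomes (>= 3; chr1 carries background
#'   genes and a gene desert, chr2 the dosage/benign/population zones, chr3 a
#'   dense gene cluster).
#' @param chrom_length Chromosome length in bp (default 1e7).
#' @param n_background_genes Genes scattered over chr1/chr2.
#' @param n_cluster_genes Genes in the dense chr3 cluster (must exceed the
#'   highest Section-3 band so band-3C CNVs can be planted).
#' @param n_dosage_genes,n_dosage_regions Dosage-sensitivity records over
#'   genes / standalone regions.
#' @param n_benign_records Curated benign CNVs (each emitted in inner and
#'   outer flavors plus plain DGV/GnomAD sets).
#' @param n_population_records Population-variant records.
#' @param n_cnvs Size of the basic labeled CNV set.
#' @param planted_mix Named fractions (summing to 1) of basic-set CNVs
#'   constructed to hit `2A`, `benign_contained` (2F for losses, 2C for
#'   gains), `4O`, the upper gene-count bands (`3C`, alternating with `3B`),
#'   or `none` (gene desert).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1,
                         n_chromosomes = 3,
                         chrom_length = 1e7,
                         n_background_genes = 40,
                         n_cluster_genes = 60,
                         n_dosage_genes = 12,
                         n_dosage_regions = 4,
                         n_benign_records = 20,
                         n_population_records = 24,
                         n_cnvs = 60,
                         planted_mix = c("2A" = 0.15, benign_contained = 0.15,
                                         "4O" = 0.10, "3C" = 0.10, none = 0.50)) {
  if (n_chromosomes < 3) stop("need at least 3 chromosomes", call. = FALSE)
  if (chrom_length < 1e6) stop("chromosomes must be at least 1 Mb", call. = FALSE)
  need <- c("2A", "benign_contained", "4O", "3C", "none")
  if (!setequal(names(planted_mix), need)) {
    stop(sprintf("planted_mix must name exactly: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (abs(sum(planted_mix) - 1) > 1e-9 || any(planted_mix < 0)) {
    stop("planted_mix fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (n_cluster_genes > 0 && 0.3 * chrom_length / n_cluster_genes < 1000) {
    # the cluster zone is 30% of a chromosome; genes need >= 1 kb spacing
    stop("impossible spec: too many cluster genes for the chromosome length",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
         chrom_length = chrom_length,
         n_background_genes = n_background_genes,
         n_cluster_genes = n_cluster_genes,
         n_dosage_genes = n_dosage_genes, n_dosage_regions = n_dosage_regions,
         n_benign_records = n_benign_records,
         n_population_records = n_population_records,
         n_cnvs = n_cnvs, planted_mix = planted_mix[need]),
    class = "fixture_spec"
  )
}

with_subseed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed + offset)
  expr
}

fixture_zones <- function(spec) {
  L <- spec$chrom_length
  list(
    background1 = c(round(0.01 * L), round(0.66 * L)),  # chr1
    desert = c(round(0.70 * L), L),                     # chr1, kept empty
    dosage = c(round(0.01 * L), round(0.20 * L)),       # chr2
    benign = c(round(0.30 * L), round(0.60 * L)),       # chr2
    population = c(round(0.70 * L), round(0.90 * L)),   # chr2
    cluster = c(round(0.20 * L), round(0.50 * L))       # chr3
  )
}

rand_int <- function(n, lo, hi) floor(runif(n, lo, hi + 1))

make_transcripts <- function(gene_id, symbol, biotype, chrom, gstart, gend) {
  n_tx <- rand_int(1, 1, 3)
  rows <- vector("list", n_tx)
  for (t in seq_len(n_tx)) {
    shrink_l <- rand_int(1, 0, max(1, floor((gend - gstart) * 0.15)))
    shrink_r <- rand_int(1, 0, max(1, floor((gend - gstart) * 0.15)))
    ts <- gstart + shrink_l
    te <- max(ts + 200, gend - shrink_r)
    n_ex <- rand_int(1, 2, 5)
    cuts <- sort(unique(c(ts, sort(rand_int(2 * n_ex, ts + 1, te - 1)), te)))
    # pick alternating segments as exons
    segs <- cbind(cuts[-length(cuts)], cuts[-1] - 1)
    segs[nrow(segs), 2] <- te
    take <- seq(1, nrow(segs), by = 2)
    es <- segs[take, 1]
    ee <- segs[take, 2]
    ee <- pmax(ee, es)
    rows[[t]] <- data.frame(
      gene_id = gene_id, symbol = symbol, biotype = biotype,
      transcript_id = sprintf("%s.t%d", gene_id, t),
      chrom = chrom, start = ts, end = te,
      cds_side = sample(c("left", "right"), 1),
      stringsAsFactors = FALSE
    )
    rows[[t]]$exon_starts <- list(es)
    rows[[t]]$exon_ends <- list(ee)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic annotation bundle
#'
#' Builds a self-consistent toy genome and, when `dir` is given, writes every
#' annotation file in its documented TSV dialect.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory (created if needed).
#' @return A list with `registries` (genes, elements, dosage, benign — the
#'   unfiltered pool —, population, predictors), `layout` (anchor coordinates
#'   the CNV planter uses), `paths` (when written) and `spec`.
#' @export
generate_annotation_bundle <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  zones <- fixture_zones(spec)
  L <- spec$chrom_length

  # ---- genes (sub-seed offset 1) ----
  genes <- with_subseed(spec$seed, 1L, {
    rows <- list()
    gi <- 0L
    add_gene <- function(chrom, gstart, gend, biotype) {
      gi <<- gi + 1L
      id <- sprintf("g%04d", gi)
      rows[[length(rows) + 1L]] <<-
        make_transcripts(id, sprintf("GENE%04d", gi), biotype, chrom, gstart, gend)
      id
    }
    # background genes on chr1 (outside the desert) and the chr2 dosage zone
    for (i in seq_len(spec$n_background_genes)) {
      if (i %% 2 == 1) {
        z <- zones$background1; chrom <- "chr1"
      } else {
        z <- zones$dosage; chrom <- "chr2"
      }
      w <- rand_int(1, 5e3, 5e4)
      s <- rand_int(1, z[1], z[2] - w)
      add_gene(chrom, s, s + w, if (runif(1) < 0.85) "protein_coding" else "other")
    }
    # dense cluster on chr3
    cluster_ids <- character(0)
    if (spec$n_cluster_genes > 0) {
      spacing <- floor((zones$cluster[2] - zones$cluster[1]) / spec$n_cluster_genes)
      w <- max(500, floor(spacing * 0.4))
      for (i in seq_len(spec$n_cluster_genes)) {
        s <- zones$cluster[1] + (i - 1L) * spacing
        cluster_ids <- c(cluster_ids, add_gene("chr3", s, s + w, "protein_coding"))
      }
    }
    # two anchor genes inside the benign zone (used by planted gain CNVs)
    anchor_gene_pos <- list(
      c(zones$benign[1] + 0.02 * diff(zones$benign),
        zones$benign[1] + 0.02 * diff(zones$benign) + 2e4),
      c(zones$benign[1] + 0.40 * diff(zones$benign),
        zones$benign[1] + 0.40 * diff(zones$benign) + 2e4)
    )
    anchor_gene_ids <- vapply(anchor_gene_pos, function(p) {
      add_gene("chr2", round(p[1]), round(p[2]), "protein_coding")
    }, character(1))
    list(records = do.call(rbind, rows), cluster_ids = cluster_ids,
         anchor_gene_ids = anchor_gene_ids, anchor_gene_pos = anchor_gene_pos)
  })
  gene_registry <- build_gene_registry(genes$records)

  # ---- functional elements (offset 2) ----
  elements <- with_subseed(spec$seed, 2L, {
    z <- zones$population
    el <- data.frame(
      chrom = c("chr1", "chr2"),
      start = c(rand_int(1, zones$background1[1], zones$background1[2] - 2e3),
                rand_int(1, z[1], z[2] - 2e3)),
      element_class = c("enhancer", "enhancer"),
      stringsAsFactors = FALSE
    )
    el$end <- el$start + rand_int(2, 500, 2e3)
    el[, c("chrom", "start", "end", "element_class")]
  })
  element_registry <- new_registry(sort_records(elements), "element_registry")

  # ---- dosage records (offset 3) ----
  gene_spans <- do.call(rbind, lapply(split(genes$records, genes$records$gene_id),
    function(g) data.frame(gene_id = g$gene_id[1], symbol = g$symbol[1],
                           biotype = g$biotype[1], chrom = g$chrom[1],
                           start = min(g$start), end = max(g$end),
                           stringsAsFactors = FALSE)))
  dosage <- with_subseed(spec$seed, 3L, {
    # dosage targets live in the chr2 dosage zone
    zone_genes <- gene_spans[gene_spans$chrom == "chr2" &
                               gene_spans$start >= zones$dosage[1] &
                               gene_spans$end <= zones$dosage[2] &
                               gene_spans$biotype == "protein_coding", , drop = FALSE]
    zone_genes <- zone_genes[order(zone_genes$start), , drop = FALSE]
    n <- min(spec$n_dosage_genes, nrow(zone_genes))
    if (n < 4) stop("impossible spec: too few genes in the dosage zone", call. = FALSE)
    picked <- zone_genes[seq_len(n), , drop = FALSE]
    # deterministic score layout: established HI, established TS, then lower
    # scores and the recessive/insensitive codes
    score_plan <- rep(list(c(3, NA), c(NA, 3), c(2, NA), c(1, NA), c(NA, 2),
                           c(30, NA), c(NA, 40), c(0, 0)), length.out = n)
    recs <- data.frame(
      symbol = picked$symbol, target_kind = "gene", chrom = picked$chrom,
      start = picked$start, end = picked$end,
      hi_score = vapply(score_plan, `[`, numeric(1), 1),
      ts_score = vapply(score_plan, `[`, numeric(1), 2),
      stringsAsFactors = FALSE
    )
    # standalone regions (score 3) further along the dosage zone
    if (spec$n_dosage_regions > 0) {
      zw <- diff(zones$dosage)
      for (i in seq_len(spec$n_dosage_regions)) {
        s <- zones$dosage[1] + round((0.55 + 0.1 * (i - 1)) * zw)
        w <- rand_int(1, 3e4, 8e4)
        recs <- rbind(recs, data.frame(
          symbol = sprintf("REGION%02d", i), target_kind = "region",
          chrom = "chr2", start = s, end = s + w,
          hi_score = ifelse(i %% 2 == 1, 3, NA),
          ts_score = ifelse(i %% 2 == 1, NA, 3),
          stringsAsFactors = FALSE
        ))
      }
    }
    recs
  })
  dosage_registry <- new_registry(sort_records(dosage, "symbol"), "dosage_registry")

  # ---- benign CNVs (offset 4) ----
  benign <- with_subseed(spec$seed, 4L, {
    if (spec$n_benign_records == 0) {
      rec <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                        cnv_type = character(), frequency = numeric(),
                        coordinate_flavor = character(), source = character(),
                        stringsAsFactors = FALSE)
      list(records = rec, anchors = rec)
    } else {
      z <- zones$benign
      zw <- diff(z)
      freq_pool <- c(0.00005, 0.0005, 0.002, 0.008, 0.03, 0.15)
      # four anchors with planting-friendly frequency: two losses, two gains;
      # the gain anchors each contain one anchor gene
      anchors <- data.frame(
        chrom = "chr2",
        start = round(z[1] + c(0.00, 0.20, 0.38, 0.60) * zw),
        end = round(z[1] + c(0.10, 0.30, 0.50, 0.72) * zw),
        cnv_type = c("gain", "loss", "gain", "loss"),
        frequency = 0.02, stringsAsFactors = FALSE
      )
      n_extra <- max(0, spec$n_benign_records - nrow(anchors))
      extra <- data.frame(
        chrom = "chr2",
        start = rand_int(n_extra, z[1], z[2] - 1e5),
        end = NA_real_,
        cnv_type = sample(c("loss", "gain"), n_extra, replace = TRUE),
        frequency = sample(freq_pool, n_extra, replace = TRUE),
        stringsAsFactors = FALSE
      )
      if (n_extra > 0) extra$end <- extra$start + rand_int(n_extra, 2e4, 1e5)
      curated <- rbind(anchors, extra)
      n <- nrow(curated)
      margin <- rand_int(n, 5e3, 2e4)
      outer <- transform(curated, start = pmax(1, start - margin),
                         end = pmin(L, end + margin))
      inner <- curated
      emit <- function(df, flavor, source) {
        df$coordinate_flavor <- flavor
        df$source <- source
        df
      }
      gnomad <- data.frame(
        chrom = "chr2",
        start = rand_int(n, z[1], z[2] - 1e5),
        end = NA_real_,
        cnv_type = sample(c("loss", "gain"), n, replace = TRUE),
        frequency = sample(freq_pool, n, replace = TRUE),
        stringsAsFactors = FALSE
      )
      gnomad$end <- gnomad$start + rand_int(n, 2e4, 1e5)
      records <- rbind(
        emit(inner, "inner", "DGV_GOLD"),
        emit(outer, "outer", "DGV_GOLD"),
        emit(outer, "plain", "DGV"),
        emit(gnomad, "plain", "GnomAD")
      )
      list(records = records,
           anchors = emit(outer[seq_len(nrow(anchors)), ], "outer", "DGV_GOLD"))
    }
  })
  benign_registry <- new_registry(sort_records(benign$records), "benign_registry")

  # ---- population variants (offset 5) ----
  population <- with_subseed(spec$seed, 5L, {
    z <- zones$population
    zw <- diff(z)
    anchors <- data.frame(
      chrom = "chr2",
      start = round(z[1] + c(0.00, 0.25, 0.50, 0.75) * zw),
      end = round(z[1] + c(0.15, 0.40, 0.65, 0.90) * zw),
      cnv_type = c("loss", "gain", "loss", "gain"),
      allele_frequency = 0.03, stringsAsFactors = FALSE
    )
    n_extra <- max(0, spec$n_population_records - nrow(anchors))
    extra <- data.frame(
      chrom = "chr2",
      start = rand_int(n_extra, z[1], z[2] - 5e4),
      end = NA_real_,
      cnv_type = sample(c("loss", "gain"), n_extra, replace = TRUE),
      allele_frequency = sample(c(0.0001, 0.002, 0.008, 0.02, 0.08), n_extra,
                                replace = TRUE),
      stringsAsFactors = FALSE
    )
    if (n_extra > 0) extra$end <- extra$start + rand_int(n_extra, 1e4, 5e4)
    records <- if (spec$n_population_records == 0) anchors[0, ] else
      rbind(anchors, extra)
    list(records = records,
         anchors = if (spec$n_population_records == 0) anchors[0, ] else anchors)
  })
  population_registry <- new_registry(sort_records(population$records),
                                      "population_registry")

  # ---- HI predictor calls (offset 6) ----
  predictors <- with_subseed(spec$seed, 6L, {
    syms <- sort(unique(genes$records$symbol))
    calls <- lapply(syms, function(s) runif(5) < 0.25)
    names(calls) <- syms
    # force a couple of clearly predicted-HI genes outside the dosage zone
    hi_forced <- gene_spans$symbol[gene_spans$chrom == "chr1" &
                                     gene_spans$biotype == "protein_coding"]
    for (s in utils::head(hi_forced, 2)) calls[[s]] <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
    df <- data.frame(
      symbol = syms,
      predictor_calls = vapply(calls, function(x) paste(as.integer(x), collapse = ","),
                               character(1)),
      stringsAsFactors = FALSE
    )
    df$calls <- unname(calls)
    df
  })
  predictor_registry <- structure(list(records = predictors),
                                  class = "predictor_registry")

  layout <- list(
    zones = zones,
    dosage_hi3 = dosage[!is.na(dosage$hi_score) & dosage$hi_score == 3, , drop = FALSE],
    dosage_ts3 = dosage[!is.na(dosage$ts_score) & dosage$ts_score == 3, , drop = FALSE],
    benign_anchors = benign$anchors,
    population_anchors = population$anchors,
    cluster = list(
      zone = zones$cluster,
      spacing = if (spec$n_cluster_genes > 0)
        floor(diff(zones$cluster) / spec$n_cluster_genes) else NA,
      n = spec$n_cluster_genes
    ),
    anchor_gene_pos = genes$anchor_gene_pos
  )

  bundle <- list(
    registries = list(genes = gene_registry, elements = element_registry,
                      dosage = dosage_registry, benign = benign_registry,
                      population = population_registry,
                      predictors = predictor_registry),
    layout = layout, spec = spec, paths = NULL
  )

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      genes = file.path(dir, "genes.tsv"),
      elements = file.path(dir, "elements.tsv"),
      dosage = file.path(dir, "dosage.tsv"),
      benign = file.path(dir, "benign.tsv"),
      population = file.path(dir, "population.tsv"),
      predictors = file.path(dir, "hi_predictors.tsv")
    )
    write_gene_models(gene_registry, paths$genes)
    write_functional_elements(element_registry, paths$elements)
    write_dosage_records(dosage_registry, paths$dosage)
    write_benign_cnvs(benign_registry, paths$benign)
    write_population_variants(population_registry, paths$population)
    write_hi_predictors(predictor_registry, paths$predictors)
    bundle$paths <- paths
  }
  bundle
}

#' Load a written annotation bundle back into registries
#'
#' @param dir Directory produced by [generate_annotation_bundle()] (or the
#'   `fixtures` CLI subcommand).
#' @return Named list of registries suitable for [score_cnv()] after the
#'   benign pool is filtered with [build_benign_db()].
#' @export
load_annotation_bundle <- function(dir) {
  list(
    genes = load_gene_models(file.path(dir, "genes.tsv")),
    elements = load_functional_elements(file.path(dir, "elements.tsv")),
    dosage = load_dosage_records(file.path(dir, "dosage.tsv")),
    benign = load_benign_cnvs(file.path(dir, "benign.tsv")),
    population = load_population_variants(file.path(dir, "population.tsv")),
    predictors = load_hi_predictors(file.path(dir, "hi_predictors.tsv"))
  )
}

#' Registries ready for scoring, with the benign pool filtered per options
#'
#' @param bundle Output of [generate_annotation_bundle()], or a registry list
#'   from [load_annotation_bundle()].
#' @param options An [engine_options()]; its benign-database fields select and
#'   filter the benign pool.
#' @return Registry list whose `benign` entry is the filtered registry.
#' @export
scoring_registries <- function(bundle, options = engine_options()) {
  regs <- if (!is.null(bundle$registries)) bundle$registries else bundle
  regs$benign <- build_benign_db(regs$benign,
                                 maf_threshold = options$maf_threshold,
                                 type_filter = options$benign_type_filter,
                                 flavor = options$benign_flavor,
                                 source = options$benign_source)
  regs
}

plant_one <- function(kind, cnv_type, layout, L, id, idx = 1L) {
  z <- layout$zones
  mk <- function(chrom, s, e, label, option) {
    data.frame(id = id, chrom = chrom, start = round(max(1, s)),
               end = round(min(L, e)), cnv_type = cnv_type,
               copy_number = ifelse(cnv_type == "loss", 1L, 3L),
               truth_label = label, planted_option = option,
               stringsAsFactors = FALSE)
  }
  if (kind == "2A") {
    pool <- if (cnv_type == "loss") layout$dosage_hi3 else layout$dosage_ts3
    rec <- pool[sample(nrow(pool), 1), ]
    m1 <- rand_int(1, 5e3, 3e5)
    m2 <- rand_int(1, 5e3, 3e5)
    return(mk(rec$chrom, rec$start - m1, rec$end + m2, "pathogenic", "2A"))
  }
  if (kind == "benign_contained") {
    anchors <- layout$benign_anchors
    pool <- anchors[anchors$cnv_type == cnv_type, , drop = FALSE]
    rec <- pool[sample(nrow(pool), 1), ]
    if (cnv_type == "loss") {
      w <- rec$end - rec$start
      s <- rec$start + rand_int(1, round(0.05 * w), round(0.2 * w))
      e <- rec$end - rand_int(1, round(0.05 * w), round(0.2 * w))
      return(mk(rec$chrom, s, e, "benign", "2F"))
    }
    # gain: shrink around the anchor gene so gene content matches the record
    gpos <- layout$anchor_gene_pos[[sample(length(layout$anchor_gene_pos), 1)]]
    gpos <- if (gpos[1] >= rec$start && gpos[2] <= rec$end) gpos else
      layout$anchor_gene_pos[[which(vapply(layout$anchor_gene_pos, function(p)
        p[1] >= rec$start && p[2] <= rec$end, logical(1)))[1]]]
    s <- max(rec$start + 1, gpos[1] - rand_int(1, 1e3, 5e3))
    e <- min(rec$end - 1, gpos[2] + rand_int(1, 1e3, 5e3))
    return(mk(rec$chrom, s, e, "benign", "2C"))
  }
  if (kind == "4O") {
    anchors <- layout$population_anchors
    pool <- anchors[anchors$cnv_type == cnv_type, , drop = FALSE]
    rec <- pool[sample(nrow(pool), 1), ]
    w <- rec$end - rec$start
    s <- rec$start + rand_int(1, round(0.05 * w), round(0.2 * w))
    e <- rec$end - rand_int(1, round(0.05 * w), round(0.2 * w))
    return(mk(rec$chrom, s, e, "benign", "4O"))
  }
  if (kind == "3C") {
    # alternate between the top band (3C) and the middle band (3B) so the
    # basic set exercises every gene-count band
    cl <- layout$cluster
    top <- idx %% 2 == 1
    need <- if (cnv_type == "loss") {
      if (top) 36 else 26
    } else {
      if (top) 51 else 36
    }
    s <- cl$zone[1] - rand_int(1, 1e3, 5e3)
    e <- cl$zone[1] + need * cl$spacing + rand_int(1, 1e3, 5e3)
    return(mk("chr3", s, e, "pathogenic", if (top) "3C" else "3B"))
  }
  # gene desert
  w <- rand_int(1, 1e3, 5e5)
  s <- rand_int(1, z$desert[1] + 5e4, z$desert[2] - w - 5e4)
  mk("chr1", s, s + w, sample(c("benign", "pathogenic"), 1), "none")
}

#' Generate the labeled CNV sets
#'
#' Produces the three study sets: `basic` (1 kb to 5 Mb, single-copy events,
#' copy numbers 1 and 3, with the planted-evidence mix), `large` (longer than
#' 5 Mb) and `multiple` (homozygous deletions / double gains, copy numbers 0
#' and 4). Every basic-set CNV carries its planted expected option and truth
#' label for oracle tests.
#'
#' @param spec A [fixture_spec()].
#' @param bundle The matching [generate_annotation_bundle()] output.
#' @param dir Optional directory; when given each set is written as
#'   `cnvs_<set>.tsv`.
#' @return List of data frames `basic`, `large`, `multiple`.
#' @export
generate_cnv_sets <- function(spec, bundle, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  layout <- bundle$layout
  L <- spec$chrom_length

  basic <- with_subseed(spec$seed, 10L, {
    counts <- round(spec$planted_mix * spec$n_cnvs)
    counts["none"] <- spec$n_cnvs - sum(counts[names(counts) != "none"])
    if (nrow(layout$benign_anchors) == 0 && counts["benign_contained"] > 0) {
      counts["none"] <- counts["none"] + counts["benign_contained"]
      counts["benign_contained"] <- 0
    }
    if (nrow(layout$population_anchors) == 0 && counts["4O"] > 0) {
      counts["none"] <- counts["none"] + counts["4O"]
      counts["4O"] <- 0
    }
    rows <- list()
    k <- 0L
    for (kind in names(counts)) {
      for (i in seq_len(counts[[kind]])) {
        k <- k + 1L
        cnv_type <- if (i %% 2 == 1) "loss" else "gain"
        rows[[k]] <- plant_one(kind, cnv_type, layout, L, sprintf("basic%04d", k),
                               idx = i)
      }
    }
    df <- do.call(rbind, rows)
    # enforce the study size window
    df$end <- pmin(df$end, df$start + 5e6 - 1)
    df$end <- pmax(df$end, df$start + 1e3 - 1)
    rownames(df) <- NULL
    df
  })

  large <- with_subseed(spec$seed, 11L, {
    n <- 10L
    len <- rand_int(n, 5e6 + 1e3, min(8e6, L - 2e5))
    chrom <- sample(sprintf("chr%d", seq_len(min(3, spec$n_chromosomes))), n,
                    replace = TRUE)
    start <- vapply(len, function(l) rand_int(1, 1e5, L - l - 1e4), numeric(1))
    cnv_type <- rep(c("loss", "gain"), length.out = n)
    data.frame(id = sprintf("large%04d", seq_len(n)), chrom = chrom,
               start = start, end = start + len - 1, cnv_type = cnv_type,
               copy_number = ifelse(cnv_type == "loss", 1L, 3L),
               truth_label = "pathogenic", planted_option = NA_character_,
               stringsAsFactors = FALSE)
  })

  multiple <- with_subseed(spec$seed, 12L, {
    n <- 10L
    len <- rand_int(n, 1e3, 3e6)
    chrom <- sample(sprintf("chr%d", seq_len(min(3, spec$n_chromosomes))), n,
                    replace = TRUE)
    start <- vapply(len, function(l) rand_int(1, 1e5, L - l - 1e4), numeric(1))
    cnv_type <- rep(c("loss", "gain"), length.out = n)
    data.frame(id = sprintf("mult%04d", seq_len(n)), chrom = chrom,
               start = start, end = start + len - 1, cnv_type = cnv_type,
               copy_number = ifelse(cnv_type == "loss", 0L, 4L),
               truth_label = sample(c("benign", "pathogenic"), n, replace = TRUE),
               planted_option = NA_character_, stringsAsFactors = FALSE)
  })

  sets <- list(basic = basic, large = large, multiple = multiple)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(sets)) {
      write_tsv(sets[[nm]], file.path(dir, sprintf("cnvs_%s.tsv", nm)))
    }
  }
  sets
}
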