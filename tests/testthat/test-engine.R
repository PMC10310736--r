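# Small hand-built registries: one protein-coding gene at chr1:100001-140000
# (5' end on the left), one established HI/TS gene at chr1:500001-540000.
base_genes <- function() {
  mk_gene_registry(rbind(
    mk_simple_gene_df("g0001", "GENE0001", "chr1", 100001, 140000),
    mk_simple_gene_df("g0002", "GENE0002", "chr1", 500001, 540000),
    mk_simple_gene_df("g0003", "GENE0003", "chr1", 800001, 810000, biotype = "other")
  ))
}

base_dosage <- function(hi = 3, ts = NA) {
  mk_dosage_registry(data.frame(
    symbol = "GENE0002", target_kind = "gene", chrom = "chr1",
    start = 500001, end = 540000, hi_score = hi, ts_score = ts,
    stringsAsFactors = FALSE
  ))
}

test_that("Section 1 keys on protein-coding genes and functional elements", {
  genes <- base_genes()
  tab <- shared_table
  ev <- evaluate_section1(cnv_call("chr1", 90001, 150000, "loss"), genes, NULL, tab)
  expect_equal(ev$option, "1A")
  ev <- evaluate_section1(cnv_call("chr2", 1, 1e6, "loss"), genes, NULL, tab)
  expect_equal(ev$option, "1B")
  expect_equal(ev$points, option_points(tab, "1B", "loss"))
  # an "other"-biotype gene alone does not satisfy 1A ...
  ev <- evaluate_section1(cnv_call("chr1", 800001, 805000, "loss"), genes, NULL, tab)
  expect_equal(ev$option, "1B")
  # ... but a functional element does
  el <- local({
    path <- withr::local_tempfile(fileext = ".tsv")
    write.table(data.frame(chrom = "chr2", start = 5000, end = 6000,
                           element_class = "enhancer"),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    load_functional_elements(path)
  })
  ev <- evaluate_section1(cnv_call("chr2", 4000, 7000, "loss"), genes, el, tab)
  expect_equal(ev$option, "1A")
})

test_that("established HI overlap yields 2A/2B and responds to score widening", {
  genes <- base_genes()
  tab <- shared_table
  cnv <- cnv_call("chr1", 450001, 600000, "loss")  # contains the HI gene

  ev <- evaluate_section2_loss(cnv, base_dosage(hi = 3), empty_benign(), genes,
                               NULL, engine_options(), tab)
  expect_equal(ev$option, "2A")
  expect_equal(ev$points, option_points(tab, "2A", "loss"))

  # score-2 record is ignored under defaults, admitted when widened
  ev <- evaluate_section2_loss(cnv, base_dosage(hi = 2), empty_benign(), genes,
                               NULL, engine_options(), tab)
  expect_false("2A" %in% ev$option)
  ev <- evaluate_section2_loss(cnv, base_dosage(hi = 2), empty_benign(), genes,
                               NULL, engine_options(dosage_min_scores = c(1, 2, 3)), tab)
  expect_equal(ev$option, "2A")

  expect_error(evaluate_section2_loss(cnv_call("chr1", 1, 10, "gain"),
                                      base_dosage(), empty_benign(), genes,
                                      NULL, engine_options(), tab),
               "requires a loss")
  expect_error(engine_options(dosage_min_scores = c(1, 2)), "score 3")
})

test_that("loss breakpoint geometry resolves 2C/2D/2E over transcripts", {
  genes <- base_genes()  # GENE0002 at 500001-540000, cds_side left
  dos <- base_dosage(hi = 3)
  tab <- shared_table
  opts <- engine_options()
  # clips the left (5') end only
  ev <- evaluate_section2_loss(cnv_call("chr1", 490001, 520000, "loss"),
                               dos, empty_benign(), genes, NULL, opts, tab)
  expect_equal(ev$option[1], "2C")
  # clips the right (3') end only
  ev <- evaluate_section2_loss(cnv_call("chr1", 520001, 560000, "loss"),
                               dos, empty_benign(), genes, NULL, opts, tab)
  expect_equal(ev$option[1], "2D")
  # fully intragenic
  ev <- evaluate_section2_loss(cnv_call("chr1", 510001, 530000, "loss"),
                               dos, empty_benign(), genes, NULL, opts, tab)
  expect_equal(ev$option[1], "2E")
  # cds_side right flips 5'/3'
  genes_r <- mk_gene_registry(
    mk_simple_gene_df("g0002", "GENE0002", "chr1", 500001, 540000, cds_side = "right"))
  ev <- evaluate_section2_loss(cnv_call("chr1", 490001, 520000, "loss"),
                               dos, empty_benign(), genes_r, NULL, opts, tab)
  expect_equal(ev$option[1], "2D")
})

test_that("benign containment gives 2F and boundary extension gives 2G", {
  genes <- base_genes()
  tab <- shared_table
  ben <- mk_benign_registry(data.frame(
    chrom = "chr1", start = 200001, end = 400000, cnv_type = "loss",
    frequency = 0.02, coordinate_flavor = "outer", source = "DGV_GOLD",
    stringsAsFactors = FALSE
  ), maf_threshold = 0.005, flavor = "outer", source = "DGV_GOLD")

  ev <- evaluate_section2_loss(cnv_call("chr1", 250001, 350000, "loss"),
                               empty_dosage(), ben, genes, NULL,
                               engine_options(), tab)
  expect_equal(ev$option, "2F")
  expect_equal(ev$points, option_points(tab, "2F", "loss"))

  # extends beyond the benign record over GENE0001 -> 2G, not 2F
  ev <- evaluate_section2_loss(cnv_call("chr1", 90001, 350000, "loss"),
                               empty_dosage(), ben, genes, NULL,
                               engine_options(), tab)
  expect_equal(ev$option, "2G")

  # frequency below the threshold removes the record entirely
  ben_rare <- mk_benign_registry(data.frame(
    chrom = "chr1", start = 200001, end = 400000, cnv_type = "loss",
    frequency = 0.001, coordinate_flavor = "outer", source = "DGV_GOLD",
    stringsAsFactors = FALSE
  ), maf_threshold = 0.005, flavor = "outer", source = "DGV_GOLD")
  ev <- evaluate_section2_loss(cnv_call("chr1", 250001, 350000, "loss"),
                               empty_dosage(), ben_rare, genes, NULL,
                               engine_options(), tab)
  expect_equal(nrow(ev), 0)
})

test_that("2H fires only without established-HI evidence", {
  genes <- base_genes()
  tab <- shared_table
  pred <- mk_predictor_registry(data.frame(
    symbol = c("GENE0001", "GENE0002"),
    predictor_calls = c("1,1,1,0,0", "1,1,0,0,0"), stringsAsFactors = FALSE
  ))
  cnv <- cnv_call("chr1", 90001, 150000, "loss")  # contains GENE0001 only
  ev <- evaluate_section2_loss(cnv, empty_dosage(), empty_benign(), genes,
                               pred, engine_options(), tab)
  expect_equal(ev$option, "2H")
  # with the HI gene inside the CNV, 2A wins and 2H is suppressed
  cnv2 <- cnv_call("chr1", 90001, 600000, "loss")
  ev <- evaluate_section2_loss(cnv2, base_dosage(hi = 3), empty_benign(), genes,
                               pred, engine_options(), tab)
  expect_equal(ev$option, "2A")
  expect_false("2H" %in% ev$option)
})

test_that("gain evidence covers TS overlap, benign-gain comparisons, 2H and 2L", {
  genes <- base_genes()
  tab <- shared_table
  opts <- engine_options()
  ts <- mk_dosage_registry(data.frame(
    symbol = "GENE0002", target_kind = "gene", chrom = "chr1",
    start = 500001, end = 540000, hi_score = NA, ts_score = 3,
    stringsAsFactors = FALSE
  ))
  ev <- evaluate_section2_gain(cnv_call("chr1", 450001, 600000, "gain"),
                               ts, empty_benign(), genes, opts, tab)
  expect_true("2A" %in% ev$option)

  # identical gene content to a benign gain -> 2C with negative points
  ben <- mk_benign_registry(data.frame(
    chrom = "chr1", start = 90001, end = 160000, cnv_type = "gain",
    frequency = 0.02, coordinate_flavor = "outer", source = "DGV_GOLD",
    stringsAsFactors = FALSE
  ), maf_threshold = 0.005, flavor = "outer", source = "DGV_GOLD")
  ev <- evaluate_section2_gain(cnv_call("chr1", 95001, 150000, "gain"),
                               empty_dosage(), ben, genes, opts, tab)
  expect_true("2C" %in% ev$option)
  expect_lt(ev$points[ev$option == "2C"], 0)

  # established HI gene fully inside the gain -> 2H flag
  ev <- evaluate_section2_gain(cnv_call("chr1", 450001, 600000, "gain"),
                               base_dosage(hi = 3), empty_benign(), genes, opts, tab)
  expect_true("2H" %in% ev$option)

  # breakpoint inside a gene -> 2L
  ev <- evaluate_section2_gain(cnv_call("chr1", 520001, 560000, "gain"),
                               empty_dosage(), empty_benign(), genes, opts, tab)
  expect_true("2L" %in% ev$option)

  expect_error(evaluate_section2_gain(cnv_call("chr1", 1, 10, "loss"),
                                      empty_dosage(), empty_benign(), genes,
                                      opts, tab),
               "requires a gain")
})

test_that("Section 3 bands are inclusive on their lower bounds", {
  tab <- shared_table
  # 25 genes spaced 10 kb apart on chr2 (loss bands: 25 and 35)
  gdf <- do.call(rbind, lapply(1:25, function(i) {
    mk_simple_gene_df(sprintf("h%04d", i), sprintf("CL%04d", i), "chr2",
                      1e6 + (i - 1) * 1e4, 1e6 + (i - 1) * 1e4 + 5e3)
  }))
  genes <- mk_gene_registry(gdf)
  all25 <- cnv_call("chr2", 1, 2e6, "loss")
  ev <- evaluate_section3(all25, genes, tab)
  expect_equal(ev$option, "3B")  # exactly at the lower bound
  ev <- evaluate_section3(cnv_call("chr2", 1, 1e6 + 23 * 1e4 + 5e3, "loss"), genes, tab)
  expect_equal(ev$option, "3A")  # 24 genes
  ev <- evaluate_section3(all25, genes, shared_table)
  expect_equal(ev$points, option_points(tab, "3B", "loss"))
  ev <- evaluate_section3(cnv_call("chr3", 1, 100, "loss"), genes, tab)
  expect_equal(ev$option, "3A")
  # the gain bands start higher: 25 genes is still 3A for a gain
  ev <- evaluate_section3(cnv_call("chr2", 1, 2e6, "gain"), genes, tab)
  expect_equal(ev$option, "3A")
})

test_that("4O requires containment in a sufficiently common same-type record", {
  tab <- shared_table
  pop <- mk_population_registry(data.frame(
    chrom = "chr1", start = c(1e6, 3e6), end = c(2e6, 4e6),
    cnv_type = c("loss", "loss"), allele_frequency = c(0.05, 0.001),
    stringsAsFactors = FALSE
  ))
  ev <- evaluate_section4o(cnv_call("chr1", 1.2e6, 1.8e6, "loss"), pop,
                           engine_options(), tab)
  expect_equal(ev$option, "4O")
  expect_lt(ev$points, 0)
  # below the common-AF threshold
  ev <- evaluate_section4o(cnv_call("chr1", 3.2e6, 3.8e6, "loss"), pop,
                           engine_options(), tab)
  expect_equal(nrow(ev), 0)
  # wrong type
  ev <- evaluate_section4o(cnv_call("chr1", 1.2e6, 1.8e6, "gain"), pop,
                           engine_options(), tab)
  expect_equal(nrow(ev), 0)
  # overlapping but not contained
  ev <- evaluate_section4o(cnv_call("chr1", 0.5e6, 1.8e6, "loss"), pop,
                           engine_options(), tab)
  expect_equal(nrow(ev), 0)
})

test_that("total score assembles evidence and classifies against thresholds", {
  regs <- shared_regs
  # a planted 2A loss from the shared set classifies P under the default table
  plant <- shared_sets$basic[shared_sets$basic$planted_option == "2A" &
                               shared_sets$basic$cnv_type == "loss", ][1, ]
  res <- score_cnv(cnv_call(plant$chrom, plant$start, plant$end, "loss"), regs)
  expect_true("2A" %in% res$evidence$option)
  expect_equal(res$classification, "P")
  expect_equal(res$total_score, sum(res$evidence$points))
  expect_setequal(res$unevaluated_options, c("2J", "2K"))

  # desert CNV: {1B, 3A} only, VUS
  res <- score_cnv(cnv_call("chr1", 7.2e6, 7.4e6, "loss"), regs)
  expect_equal(sort(res$evidence$option), c("1B", "3A"))
  expect_equal(res$classification, "VUS")

  # missing registry errors name the blocked section
  expect_error(score_cnv(cnv_call("chr1", 1, 100, "loss"),
                         regs[c("genes", "dosage", "benign")]),
               "4O")
})

test_that("2F plus 4O under defaults classifies benign", {
  genes <- base_genes()
  ben <- mk_benign_registry(data.frame(
    chrom = "chr1", start = 200001, end = 400000, cnv_type = "loss",
    frequency = 0.02, coordinate_flavor = "outer", source = "DGV_GOLD",
    stringsAsFactors = FALSE
  ), maf_threshold = 0.005, flavor = "outer", source = "DGV_GOLD")
  pop <- mk_population_registry(data.frame(
    chrom = "chr1", start = 200001, end = 400000, cnv_type = "loss",
    allele_frequency = 0.05, stringsAsFactors = FALSE
  ))
  regs <- list(genes = genes, dosage = empty_dosage(), benign = ben,
               population = pop)
  res <- score_cnv(cnv_call("chr1", 250001, 350000, "loss"), regs)
  expect_setequal(res$evidence$option, c("1B", "2F", "3A", "4O"))
  expect_equal(res$classification, "B")
})

test_that("engine equals the exhaustive rule-by-rule oracle on 200 seeded CNVs", {
  cnvs <- random_cnvs(200, seed = 11)
  raw <- shared_bundle$registries
  res <- score_cnv_batch(cnvs, shared_regs, shared_table)
  for (i in seq_len(nrow(cnvs))) {
    o <- oracle_score(cnvs$chrom[i], cnvs$start[i], cnvs$end[i],
                      cnvs$cnv_type[i], raw, shared_table)
    got <- sort(strsplit(res$options[i], ",")[[1]])
    expect_identical(got, o$options)
    expect_equal(res$total_score[i], o$total)
  }
})

test_that("widening dosage scores never removes Section 2 evidence", {
  cnvs <- random_cnvs(60, seed = 13)
  narrow <- score_cnv_batch(cnvs, shared_regs, shared_table,
                            engine_options(dosage_min_scores = 3))
  wide <- score_cnv_batch(cnvs, shared_regs, shared_table,
                          engine_options(dosage_min_scores = c(1, 2, 3)))
  has_s2 <- function(opts) vapply(strsplit(opts, ","), function(o)
    any(grepl("^2", o)), logical(1))
  expect_true(all(has_s2(wide$options) >= has_s2(narrow$options)))
})

test_that("raising the benign frequency threshold never moves scores down", {
  cnvs <- random_cnvs(60, seed = 17)
  raw <- shared_bundle$registries
  prev <- NULL
  for (th in c(0.001, 0.005, 0.02, 0.10)) {
    regs <- shared_regs
    regs$benign <- build_benign_db(raw$benign, maf_threshold = th,
                                   flavor = "outer", source = "DGV_GOLD")
    cur <- score_cnv_batch(cnvs, regs, shared_table)$total_score
    if (!is.null(prev)) expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})
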