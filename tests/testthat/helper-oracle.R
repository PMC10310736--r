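# Independent oracles: flat per-record loops and per-base set intersections,
# written without any of the package's query helpers, so implementation and
# oracle stay on separate routes.

# Per-base intersection for small coordinates (the ground-truth definition).
o_intersect_perbase <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0)
  length(intersect(seq(s1, e1), seq(s2, e2)))
}

o_overlaps <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 && s1 <= e2 && s2 <= e1
}

o_inside <- function(ci, si, ei, co, so, eo) {
  ci == co && so <= si && ei <= eo
}

# Distinct gene ids overlapping an interval (linear scan over transcripts).
o_gene_ids <- function(tx, chrom, s, e, biotype = "protein_coding") {
  ids <- character(0)
  for (i in seq_len(nrow(tx))) {
    if (!is.null(biotype) && tx$biotype[i] != biotype) next
    if (o_overlaps(tx$chrom[i], tx$start[i], tx$end[i], chrom, s, e)) {
      ids <- c(ids, tx$gene_id[i])
    }
  }
  sort(unique(ids))
}

o_breakpoint_in_gene <- function(tx, chrom, pos) {
  for (i in seq_len(nrow(tx))) {
    if (tx$chrom[i] == chrom && tx$start[i] <= pos && pos <= tx$end[i]) return(TRUE)
  }
  FALSE
}

# Filter the pooled benign records the way one database "setting" would,
# using plain subsetting (independent of build_benign_db).
o_filter_benign <- function(ben, source, flavor, maf, type_filter = "both") {
  keep <- ben$coordinate_flavor == flavor & ben$source == source
  if (!is.null(maf)) keep <- keep & ben$frequency >= maf
  if (type_filter == "losses_only") keep <- keep & ben$cnv_type == "loss"
  ben[keep, , drop = FALSE]
}

# Exhaustive re-derivation of the selected options and the total score for
# one CNV, applying each rule in the documented priority order with flat
# loops. Returns list(options = sorted character vector, total = numeric).
oracle_score <- function(chrom, s, e, type, regs_raw, table,
                         opts = engine_options()) {
  tx <- regs_raw$genes$records
  dos <- regs_raw$dosage$records
  ben <- o_filter_benign(regs_raw$benign$records, opts$benign_source,
                         opts$benign_flavor, opts$maf_threshold,
                         opts$benign_type_filter)
  pop <- regs_raw$population$records
  el <- regs_raw$elements$records
  pred <- regs_raw$predictors$records
  pts <- function(o) option_points(table, o, type)
  picked <- character(0)

  # Section 1
  pc <- o_gene_ids(tx, chrom, s, e)
  has_el <- FALSE
  for (i in seq_len(nrow(el))) {
    if (o_overlaps(el$chrom[i], el$start[i], el$end[i], chrom, s, e)) has_el <- TRUE
  }
  picked <- c(picked, if (length(pc) || has_el) "1A" else "1B")

  pick_severe <- function(cands) {
    # cands: data.frame(option, points)
    if (!nrow(cands)) return(NULL)
    ord <- order(-abs(cands$points), -cands$points, cands$option)
    cands$option[ord[1]]
  }

  if (type == "loss") {
    cands <- data.frame(option = character(), points = numeric())
    saw_hit <- FALSE
    for (i in seq_len(nrow(dos))) {
      if (is.na(dos$hi_score[i]) || !dos$hi_score[i] %in% opts$dosage_min_scores) next
      if (!o_overlaps(dos$chrom[i], dos$start[i], dos$end[i], chrom, s, e)) next
      saw_hit <- TRUE
      if (o_inside(dos$chrom[i], dos$start[i], dos$end[i], chrom, s, e)) {
        cands <- rbind(cands, data.frame(option = "2A", points = pts("2A")))
      } else if (dos$target_kind[i] == "region") {
        cands <- rbind(cands, data.frame(option = "2B", points = pts("2B")))
      } else {
        geo <- data.frame(option = character(), points = numeric())
        gtx <- tx[tx$symbol == dos$symbol[i], , drop = FALSE]
        for (j in seq_len(nrow(gtx))) {
          if (!o_overlaps(gtx$chrom[j], gtx$start[j], gtx$end[j], chrom, s, e)) next
          cl <- s <= gtx$start[j]
          cr <- e >= gtx$end[j]
          if (cl && cr) next
          if (!cl && !cr) {
            o <- "2E"
          } else {
            left5 <- gtx$cds_side[j] == "left"
            o <- if ((cl && left5) || (cr && !left5)) "2C" else "2D"
          }
          geo <- rbind(geo, data.frame(option = o, points = pts(o)))
        }
        g <- pick_severe(geo)
        if (!is.null(g)) cands <- rbind(cands, data.frame(option = g, points = pts(g)))
      }
    }
    dopt <- pick_severe(cands)
    if (!is.null(dopt)) picked <- c(picked, dopt)
    if (is.null(dopt) && !saw_hit) {
      # 2H: contained protein-coding gene with enough concordant predictors
      syms <- character(0)
      for (i in seq_len(nrow(tx))) {
        if (tx$biotype[i] == "protein_coding" &&
            o_inside(tx$chrom[i], tx$start[i], tx$end[i], chrom, s, e)) {
          syms <- c(syms, tx$symbol[i])
        }
      }
      for (sym in sort(unique(syms))) {
        k <- match(sym, pred$symbol)
        if (!is.na(k) && sum(pred$calls[[k]]) >= opts$hi_predictor_min) {
          picked <- c(picked, "2H")
          break
        }
      }
    }
    # benign line
    ov <- which(vapply(seq_len(nrow(ben)), function(i)
      o_overlaps(ben$chrom[i], ben$start[i], ben$end[i], chrom, s, e), logical(1)))
    if (length(ov)) {
      contained <- any(vapply(ov, function(i)
        o_inside(chrom, s, e, ben$chrom[i], ben$start[i], ben$end[i]), logical(1)))
      if (contained) {
        picked <- c(picked, "2F")
      } else {
        cov <- vapply(ov, function(i)
          (min(ben$end[i], e) - max(ben$start[i], s) + 1) / (e - s + 1), numeric(1))
        best <- ov[which.max(cov)]
        rec_genes <- o_gene_ids(tx, ben$chrom[best], ben$start[best], ben$end[best])
        if (length(setdiff(pc, rec_genes))) picked <- c(picked, "2G")
      }
    }
  } else {
    cands <- data.frame(option = character(), points = numeric())
    for (i in seq_len(nrow(dos))) {
      if (is.na(dos$ts_score[i]) || !dos$ts_score[i] %in% opts$dosage_min_scores) next
      if (!o_overlaps(dos$chrom[i], dos$start[i], dos$end[i], chrom, s, e)) next
      o <- if (o_inside(dos$chrom[i], dos$start[i], dos$end[i], chrom, s, e)) "2A" else "2B"
      cands <- rbind(cands, data.frame(option = o, points = pts(o)))
    }
    dopt <- pick_severe(cands)
    if (!is.null(dopt)) picked <- c(picked, dopt)
    # benign-gain comparisons
    cands <- data.frame(option = character(), points = numeric())
    for (i in seq_len(nrow(ben))) {
      if (ben$cnv_type[i] != "gain") next
      if (!o_overlaps(ben$chrom[i], ben$start[i], ben$end[i], chrom, s, e)) next
      rg <- o_gene_ids(tx, ben$chrom[i], ben$start[i], ben$end[i])
      extra <- setdiff(pc, rg)
      if (setequal(pc, rg)) {
        o <- "2C"
      } else if (o_inside(chrom, s, e, ben$chrom[i], ben$start[i], ben$end[i])) {
        brk <- o_breakpoint_in_gene(tx, chrom, s) || o_breakpoint_in_gene(tx, chrom, e)
        o <- if (brk) "2E" else "2D"
      } else if (o_inside(ben$chrom[i], ben$start[i], ben$end[i], chrom, s, e)) {
        o <- if (length(extra)) "2G" else "2F"
      } else if (length(extra)) {
        o <- "2G"
      } else next
      cands <- rbind(cands, data.frame(option = o, points = pts(o)))
    }
    bopt <- pick_severe(cands)
    if (!is.null(bopt)) picked <- c(picked, bopt)
    # 2H: fully contained established HI gene
    for (i in seq_len(nrow(dos))) {
      if (!is.na(dos$hi_score[i]) && dos$hi_score[i] %in% opts$dosage_min_scores &&
          dos$target_kind[i] == "gene" &&
          o_inside(dos$chrom[i], dos$start[i], dos$end[i], chrom, s, e)) {
        picked <- c(picked, "2H")
        break
      }
    }
    if (o_breakpoint_in_gene(tx, chrom, s) || o_breakpoint_in_gene(tx, chrom, e)) {
      picked <- c(picked, "2L")
    }
  }

  # Section 3
  bands <- table$gene_count_bands[[type]]
  n <- length(pc)
  picked <- c(picked, if (n >= bands[2]) "3C" else if (n >= bands[1]) "3B" else "3A")

  # 4O
  af <- 0
  for (i in seq_len(nrow(pop))) {
    if (pop$cnv_type[i] == type &&
        o_inside(chrom, s, e, pop$chrom[i], pop$start[i], pop$end[i])) {
      af <- max(af, pop$allele_frequency[i])
    }
  }
  if (af >= opts$common_af_threshold) picked <- c(picked, "4O")

  list(options = sort(picked), total = sum(vapply(picked, pts, numeric(1))))
}
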