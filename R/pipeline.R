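## End-to-end orchestration: simulate -> finish -> survey -> trscan ->
## markers -> authenticate, with a run manifest (parameters, seed, output
## checksums) for reproducibility.

PIPELINE_STAGES <- c("simulate", "finish", "survey", "trscan", "markers",
                     "authenticate")

#' Pipeline configuration
#'
#' @param profile Cohort profile ("mini" or "full").
#' @param seed Root seed; every stage derives named sub-seeds from it.
#' @param out_dir Output directory.
#' @param stages Stages to run (order fixed; dependencies validated).
#' @param finish_accessions Accessions to re-assemble from contigs in the
#'   finish stage (default: a representative subset; "all" = every
#'   distinct accession).
#' @param n_fragments,overlap Contig fragmentation parameters.
#' @param depth Read depth for the polishing reads.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(profile = "mini", seed = 1L,
                            out_dir = tempfile("cpkit_run_"),
                            stages = PIPELINE_STAGES,
                            finish_accessions = c("ChP", "SH", "GU"),
                            n_fragments = 4L, overlap = 250L, depth = 30) {
  stopifnot(all(stages %in% PIPELINE_STAGES))
  structure(list(profile = profile, seed = as.integer(seed),
                 out_dir = out_dir, stages = stages,
                 finish_accessions = finish_accessions,
                 n_fragments = as.integer(n_fragments),
                 overlap = as.integer(overlap), depth = depth),
            class = "pipeline_config")
}

#' Run the pipeline
#'
#' Executes the enabled stages in order; each stage consumes only
#' prior-stage results. The returned manifest records parameters, seeds and
#' md5 checksums of every written artifact; identical config and seed give
#' identical manifests.
#'
#' @param config A [pipeline_config()].
#' @return list(manifest, results) where `results` holds per-stage objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  need <- function(stage, dep)
    if (stage %in% stages && !dep %in% stages)
      stop(sprintf("config error: stage '%s' requires stage '%s'",
                   stage, dep), call. = FALSE)
  need("finish", "simulate"); need("survey", "simulate")
  need("trscan", "simulate"); need("markers", "survey")
  need("authenticate", "markers")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(); written <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }

  if ("simulate" %in% stages) {
    res$cohort <- build_cohort(config$profile, config$seed)
    emit(res$cohort$cp$truth, "truth_cp.tsv")
    emit(res$cohort$nrdna$truth, "truth_nrdna.tsv")
    emit(res$cohort$cp$reference$annotation, "annotation.tsv")
  }

  if ("finish" %in% stages) {
    co <- res$cohort
    accs <- config$finish_accessions
    if (identical(accs, "all")) accs <- setdiff(names(co$cp$sequences),
                                                CHINESE_ACCESSIONS)
    fin <- list()
    for (acc in accs) {
      g <- co$cp$sequences[[acc]]
      cs <- fragment_into_contigs(g, config$n_fragments, config$overlap,
                                  seed = derive_seed(config$seed, acc))
      reads <- simulate_reads(g, config$depth,
                              seed = derive_seed(config$seed, paste0(acc, "_r")))
      fg <- finish_genome(cs, co$cp$reference$sequence, reads = reads,
                          min_overlap = min(200L, config$overlap))
      fin[[acc]] <- list(sequence = fg$sequence,
                         exact = identical(fg$sequence, g),
                         joins = fg$draft$joins)
    }
    res$finished <- fin
    emit(data.frame(accession = names(fin),
                    reassembled_exactly = vapply(fin, `[[`, TRUE, "exact")),
         "finish_report.tsv")
  }

  if ("survey" %in% stages) {
    co <- res$cohort
    ## finished sequences replace the simulated ones where available
    seqs <- co$cp$sequences
    for (acc in names(res$finished))
      seqs[[acc]] <- res$finished[[acc]]$sequence
    res$cp_table <- survey_cohort(co$cp$reference$sequence, seqs,
                                  co$cp$reference$annotation,
                                  co$cp$reference$layout)
    res$nrdna_table <- survey_cohort(co$nrdna$reference$sequence,
                                     co$nrdna$sequences)
    emit(res$cp_table, "cohort_table_cp.tsv")
    emit(res$nrdna_table, "cohort_table_nrdna.tsv")
  }

  if ("trscan" %in% stages) {
    co <- res$cohort
    res$tr_summary <- summarize_trs(co$cp$reference$sequence)
    emit(res$tr_summary$repeats, "tandem_repeats.tsv")
    seg <- co$nrdna$reference$segments
    igs <- substr(co$nrdna$reference$sequence,
                  seg$start[seg$name == "IGS"], seg$end[seg$name == "IGS"])
    lu <- find_tandem_repeats(igs, min_unit = 100L, max_unit = 700L)
    res$igs_subrepeat <- lu[which.max(lu$span), ]
    cnv <- list()
    for (nm in names(co$cp$reference$layout$loci)) {
      lc <- co$cp$reference$layout$loci[[nm]]
      if (lc$kind != "tr_cnv" || !length(lc$carriers)) next
      cnv[[nm]] <- compare_tr_locus(
        co$cp$reference$sequence, lc$pos,
        lc$pos + lc$unit_length * lc$ref_copies - 1L, lc$unit_length,
        co$cp$sequences)
    }
    res$cnv_calls <- cnv
    emit(do.call(rbind, lapply(names(cnv), function(nm)
      data.frame(locus = nm, t(cnv[[nm]]$copies_per_accession)))),
      "tr_cnv_calls.tsv")
  }

  if ("markers" %in% stages) {
    co <- res$cohort
    ref <- co$cp$reference$sequence
    lay <- co$cp$reference$layout
    vpos <- res$cp_table$pos
    loci <- lay$loci
    locus_iv <- function(lc) switch(lc$kind,
      tr_cnv = c(lc$pos, lc$pos + lc$unit_length * lc$ref_copies - 1L),
      insertion = c(lc$pos, lc$pos + 1L),
      homopolymer = c(lc$pos, lc$pos + lc$ref_len - 1L))
    indel_targets <- c("tr57_ycf1", "tr7_rpl32_trnUAG", "tr13_rps16_trnUUG",
                       "ins59_trnUUC_trnGGU")
    markers <- list()
    for (nm in indel_targets) {
      iv <- locus_iv(loci[[nm]])
      markers[[nm]] <- design_indel_marker(ref, iv[1], iv[2],
                                           co$cp$sequences,
                                           setdiff(vpos, iv[1] - 1L))
    }
    for (nm in c("snp_rpoC1", "snp_rpoC2")) {
      lc <- loci[[nm]]
      d <- design_dcaps(ref, lc$pos, lc$ref, lc$alt)
      if (inherits(d, "dcaps_design")) markers[[nm]] <- d
    }
    res$markers <- markers
    emit(data.frame(
      marker = names(markers),
      kind = vapply(markers, function(m) class(m)[1], character(1)),
      detail = vapply(markers, function(m)
        if (inherits(m, "indel_marker"))
          paste(sort(unique(m$product_sizes)), collapse = "/")
        else paste0(m$enzyme$name, ":", m$cut_allele), character(1))),
      "markers.tsv")
  }

  if ("authenticate" %in% stages) {
    co <- res$cohort
    markers <- res$markers
    dcaps_names <- intersect(c("snp_rpoC1", "snp_rpoC2"), names(markers))
    assayed_pos <- vapply(dcaps_names, function(nm)
      co$cp$reference$layout$loci[[nm]]$pos, numeric(1))
    for (p in setdiff(res$cp_table$pos[res$cp_table$type == "SNP"], assayed_pos))
      markers[[paste0("site_cp_", p)]] <- list(type = "site", pos = p,
                                               genome = "cp")
    for (p in res$cp_table$pos[res$cp_table$context == "homopolymer"])
      markers[[paste0("site_cp_", p)]] <- list(type = "site", pos = p,
                                               genome = "cp")
    for (p in res$nrdna_table$pos)
      markers[[paste0("site_nrdna_", p)]] <- list(type = "site", pos = p,
                                                  genome = "nrdna")
    res$auth <- build_auth_matrix(
      list(cp = res$cp_table, nrdna = res$nrdna_table), markers,
      co$cp$sequences)
    emit(cbind(accession = rownames(res$auth$genotypes), res$auth$genotypes),
         "auth_matrix.tsv")
  }

  sums <- tools::md5sum(written)
  manifest <- list(package_version = as.character(utils::packageVersion("cpkit")),
                   seed = config$seed, profile = config$profile,
                   stages = stages,
                   parameters = config[c("n_fragments", "overlap", "depth",
                                         "finish_accessions")],
                   outputs = as.list(sums))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(manifest = manifest, results = res)
}
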