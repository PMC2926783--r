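# End-to-end orchestration: simulate -> filter -> profile -> ecr ->
# identity -> orf/dnds -> motifs, with per-stage TSV outputs, a manifest,
# and a consolidated report. Every number in the report is taken from a
# stage table, never recomputed report-side.

#' Pipeline run configuration
#'
#' @param seed integer seed forwarded to the synthetic generators.
#' @param outdir output directory for stage TSVs (`NULL` = in-memory only).
#' @param stages character vector of stages to run, in dependency order.
#' @param sim a [sim_config()] used by the `simulate` stage (its `seed` is
#'   overridden by `seed`).
#' @param min_distance proximity filter threshold, bp.
#' @param samples,flank metagene schema parameters.
#' @param min_length,min_identity ECR definition.
#' @param min_score local-alignment acceptance score.
#' @param idp_window,idp_step windowed identity profile parameters
#'   (alignment columns).
#' @param orf_long_aa strict "long ORF" amino-acid threshold.
#' @return a list of class `lincons_run_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = NULL,
                            stages = c("simulate", "filter", "profile", "ecr",
                                       "identity", "orf", "dnds", "motifs"),
                            sim = sim_config(seed = seed),
                            min_distance = 5000L,
                            samples = 200L, flank = 200L,
                            min_length = 100L, min_identity = 0.70,
                            min_score = 30, idp_window = 100L, idp_step = 10L,
                            orf_long_aa = 100L) {
  sim$seed <- as.integer(seed)
  structure(as.list(environment()), class = "lincons_run_config")
}

#' Run the full conservation analysis
#'
#' @param config a [pipeline_config()].
#' @return a list of class `lincons_report` holding every stage table plus
#'   a one-row `summary` tibble; stage TSVs and a manifest are written when
#'   `config$outdir` is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "lincons_run_config"))
  res <- list()
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(outdir)) write_tsv_report(df, file.path(outdir, paste0(name, ".tsv")))
    df
  }
  on <- function(stage) stage %in% config$stages

  sim <- NULL
  if (on("simulate")) {
    ann <- sim_annotation(config$sim)
    trk <- sim_score_track(config$sim, ann$lncrna)
    aln <- sim_alignment(config$sim)
    pair <- sim_ortholog_pair(config$sim)
    sim <- list(ann = ann, trk = trk, aln = aln, pair = pair)
    if (!is.null(outdir)) {
      write_bed12(ann$lncrna, file.path(outdir, "lncrna.bed"))
      write_bed12(ann$coding, file.path(outdir, "coding.bed"))
      write_bedgraph(trk$track, file.path(outdir, "conservation.bedgraph"))
      write_bed6(trk$elements, file.path(outdir, "elements.bed"))
      write_maf(aln$blocks, file.path(outdir, "alignment.maf"))
      write_fasta(dplyr::bind_rows(pair$query, pair$subject),
                  file.path(outdir, "ortholog_pair.fa"))
      emit(ann$truth, "truth_filter")
      emit(aln$truth, "truth_ecr")
      emit(pair$truth, "truth_ortholog")
    }
  }
  if (is.null(sim) && length(setdiff(config$stages, "simulate")) > 0) {
    abort("only simulated inputs are wired into run_pipeline(); run stages individually for external files")
  }

  if (on("filter")) {
    res$filter <- emit(filter_noncoding(sim$ann$lncrna, sim$ann$coding,
                                        config$min_distance), "filter_report")
    ov <- overlap_fraction(sim$ann$lncrna, sim$trk$elements)
    res$overlap <- emit(ov, "overlap_fractions")
    res$overlap_summary <- emit(summarize_overlap(ov), "overlap_summary")
    res$overlap_histogram <- emit(overlap_histogram(ov), "overlap_histogram")
  }
  if (on("profile")) {
    schema <- region_schema(samples_per_region = config$samples,
                            flank_length = config$flank)
    kept_ids <- if (!is.null(res$filter)) res$filter$tx_id[res$filter$kept]
                else sim$ann$lncrna$tx_id
    cohort <- sim$ann$lncrna[sim$ann$lncrna$tx_id %in% kept_ids, ]
    prof <- build_metagene(cohort, sim$trk$track, schema)
    res$profile <- emit(tidy(prof), "metagene_profile")
    res$peak <- emit(call_peak(prof, schema$regions[1]), "promoter_peak")
    res$profile_obj <- prof
  }
  if (on("ecr")) {
    res$ecrs <- emit(scan_ecrs(sim$aln$blocks, config$min_length,
                               config$min_identity), "ecrs")
  }
  if (on("identity")) {
    res$identity <- emit(overall_identity(sim$pair$query, sim$pair$subject,
                                          min_score = config$min_score), "identity")
    res$idprofile <- emit(windowed_identity_profile(sim$aln$blocks,
                                                    config$idp_window,
                                                    config$idp_step), "identity_profile")
  }
  if (on("orf")) {
    res$orf <- emit(find_longest_orf(dplyr::bind_rows(sim$pair$query, sim$pair$subject),
                                     config$orf_long_aa), "orf_report")
  }
  if (on("dnds")) {
    pair <- sim_neutral_codon_pair(seed = config$seed)
    res$dnds <- emit(glance(ng86_dnds(pair$a, pair$b)), "dnds")
  }
  if (on("motifs")) {
    res$polya <- emit(polya_offset(dplyr::bind_rows(sim$pair$query, sim$pair$subject)),
                      "polya_report")
    genome <- sim_genome_seq(sim$ann$lncrna, seed = config$seed)
    res$splice <- emit(splice_consensus_report(sim$ann$lncrna, genome),
                       "splice_report")
  }

  res$summary <- emit(pipeline_summary(res), "report")
  if (!is.null(outdir)) {
    manifest <- tibble::tibble(
      key = c("seed", "stages", "min_distance", "samples", "flank",
              "min_length", "min_identity", "min_score"),
      value = c(config$seed, paste(config$stages, collapse = ","),
                config$min_distance, config$samples, config$flank,
                config$min_length, config$min_identity, config$min_score))
    write_tsv_report(manifest, file.path(outdir, "manifest.tsv"))
  }
  structure(res, class = "lincons_report")
}

pipeline_summary <- function(res) {
  g <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  tibble::tibble(
    n_lncrna = g(if (!is.null(res$filter)) nrow(res$filter)),
    n_kept = g(if (!is.null(res$filter)) sum(res$filter$kept)),
    pct_constrained = g(res$overlap_summary$pct_constrained[1]),
    mean_exonic_overlap = g(res$overlap_summary$mean_exonic_fraction[1]),
    mean_genic_overlap = g(res$overlap_summary$mean_genic_fraction[1]),
    peak_offset_bp = g(res$peak$offset_bp[1]),
    peak_height = g(res$peak$height[1]),
    n_ecrs = g(if (!is.null(res$ecrs)) nrow(res$ecrs)),
    ortholog_percent_identity = g(res$identity$percent[1]),
    longest_orf_aa = g(if (!is.null(res$orf)) max(res$orf$aa_length, na.rm = TRUE)),
    dnds_ratio = g(res$dnds$ratio[1])
  )
}

#' @export
print.lincons_report <- function(x, ...) {
  cat("lincons pipeline report\n")
  print(x$summary)
  invisible(x)
}

#' @method glance lincons_report
#' @export
glance.lincons_report <- function(x, ...) x$summary
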