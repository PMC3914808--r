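#' Pipeline configuration
#'
#' Assembles and validates the configuration consumed by
#' [run_pipeline()]. Two modes are supported. `"simulate"` generates a
#' toy genome, implants the configured rearrangements, simulates tumor
#' and normal read pairs, aCGH probes, a variant table and a DNA-content
#' histogram, then runs every analysis stage against the known truth.
#' `"fixtures"` runs the worked-example stages (partner filter, hotspot
#' scan, somatic-damaging report) on the packaged validated tables.
#' All randomness derives from the single `seed`.
#'
#' @param seed Master seed.
#' @param out_dir Output directory for the report bundle (created if
#'   missing); `NULL` suppresses file output.
#' @param mode `"simulate"` or `"fixtures"`.
#' @param genome_args Arguments to [build_toy_genome()].
#' @param events Rearrangement spec data.frame (see [rearrangements]).
#' @param model [insert_model()].
#' @param coverage Simulated fold coverage.
#' @param caller [caller_params()].
#' @param concordance [concordance_params()].
#' @param filters [filter_params()].
#' @param probe_spacing,probe_noise_sd aCGH simulation settings.
#' @param histogram_args Arguments to [simulate_histogram()].
#' @param variant_args Arguments to [simulate_variant_table()]
#'   (`n_germline`, `frac_lowprob`, ...).
#' @param n_somatic Number of truth somatic SNVs to implant.
#' @param hotspot_cluster Gene cluster for [hotspot_scan()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = NULL,
                            mode = c("simulate", "fixtures"),
                            genome_args = list(), events = NULL,
                            model = insert_model(), coverage = 30,
                            caller = caller_params(),
                            concordance = concordance_params(),
                            filters = filter_params(),
                            probe_spacing = 1000, probe_noise_sd = 0.2,
                            histogram_args = list(),
                            variant_args = list(),
                            n_somatic = 5,
                            hotspot_cluster = c("NAV3", "SYT1", "PAWR")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "insert_model"), inherits(caller, "caller_params"),
            inherits(concordance, "concordance_params"),
            inherits(filters, "filter_params"), coverage > 0)
  structure(list(seed = seed, out_dir = out_dir, mode = mode,
                 genome_args = genome_args, events = events, model = model,
                 coverage = coverage, caller = caller,
                 concordance = concordance, filters = filters,
                 probe_spacing = probe_spacing,
                 probe_noise_sd = probe_noise_sd,
                 histogram_args = histogram_args,
                 variant_args = variant_args, n_somatic = n_somatic,
                 hotspot_cluster = hotspot_cluster),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> classify -> call fusions -> segment/match ->
#' somatic filter -> ploidy (or the fixture worked example), writes the
#' report bundle to `config$out_dir` (fusion TSV + BEDPE, copy-number
#' segment and concordance TSVs, somatic report, ploidy JSON, hotspot
#' summary and a run manifest echoing seed and parameters) and returns
#' the bundle invisibly.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with per-stage outputs and
#'   (simulate mode) the generating truth.
#' @examples
#' \donttest{
#' g_ev <- rbind(sv_deletion("chr1", 50000, 80000))
#' cfg <- pipeline_config(seed = 7, events = g_ev, coverage = 10)
#' res <- run_pipeline(cfg)
#' res$fusions
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  out <- list(seed = seed, mode = config$mode)

  if (config$mode == "fixtures") {
    fus <- run_stage("fixtures", fixture_as_candidates(wdls_fixture("fusions")))
    fus <- run_stage("partner_filter", partner_filter(fus, config$caller))
    out$fusions <- fus
    out$hotspot <- run_stage("hotspot",
                             hotspot_scan(fus, config$hotspot_cluster))
    snv <- run_stage("somatic", {
      v <- fixture_as_variants(wdls_fixture("snvs"))
      select_damaging(filter_somatic(v, config$filters), config$filters)
    })
    out$somatic <- somatic_report(snv)
  } else {
    genome <- run_stage("genome",
      do.call(build_toy_genome, c(list(seed = derive_seed(seed, 1)),
                                  config$genome_args)))
    imp <- run_stage("implant", implant_events(genome, config$events))
    truth <- imp$truth

    tumor <- run_stage("simulate_tumor",
      simulate_pairs(imp$donor, config$model, config$coverage,
                     seed = derive_seed(seed, 2), sample = "tumor"))
    normal <- run_stage("simulate_normal",
      simulate_pairs(as_donor(genome), config$model, config$coverage,
                     seed = derive_seed(seed, 3), sample = "normal"))

    calls <- run_stage("call_fusions",
      call_fusions(tumor, normal, genome, config$model, config$caller))
    out$fusions <- calls
    out$hotspot <- hotspot_scan(calls, config$hotspot_cluster)

    probes <- run_stage("simulate_probes",
      simulate_probes(genome, truth$copy_number, config$probe_spacing,
                      config$probe_noise_sd, seed = derive_seed(seed, 4)))
    segments <- run_stage("segment",
      call_states(segment_probes(probes), config$concordance))
    out$segments <- segments
    out$concordance <- run_stage("match_breakpoints",
      match_breakpoints(segments, calls, config$concordance))

    som_truth <- run_stage("somatic_truth", {
      g <- genome$genes
      n <- min(config$n_somatic, nrow(g))
      pick <- with_seed(derive_seed(seed, 5), sample(nrow(g), n))
      bases <- c("A", "C", "G", "T")
      ref <- with_seed(derive_seed(seed, 6),
                       sample(bases, n, replace = TRUE))
      alt <- vapply(seq_len(n), function(i)
        setdiff(bases, ref[i])[1], character(1))
      data.frame(chrom = g$chrom[pick],
                 pos = as.integer((g$start[pick] + g$end[pick]) / 2),
                 ref = ref, alt = alt, stringsAsFactors = FALSE)
    })
    truth$somatic_variants <- som_truth
    variants <- run_stage("simulate_variants",
      do.call(simulate_variant_table,
              c(list(somatic = som_truth, genome = genome,
                     seed = derive_seed(seed, 7)), config$variant_args)))
    out$somatic <- run_stage("somatic_filter",
      somatic_report(select_damaging(
        filter_somatic(variants, config$filters), config$filters)))

    hist <- run_stage("simulate_histogram",
      do.call(simulate_histogram,
              c(list(seed = derive_seed(seed, 8)), config$histogram_args)))
    ref_ch <- hist$params$reference_channel
    out$ploidy <- run_stage("ploidy",
      estimate_ploidy(fit_dna_content(hist, n_peaks = 3),
                      reference_channel_hint = ref_ch))
    out$truth <- truth
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_fusion_table(out$fusions, p("fusions.tsv"))
    if (inherits(out$fusions, "fusion_calls"))
      write_bedpe(out$fusions, p("fusions.bedpe"))
    if (!is.null(out$segments)) {
      write_segments(out$segments, p("segments.tsv"))
      tsv_write(out$concordance$matched, p("breakpoint_concordance.tsv"))
    }
    tsv_write(out$somatic, p("somatic_report.tsv"))
    if (!is.null(out$ploidy))
      jsonlite::write_json(
        list(ploidy_index = out$ploidy$ploidy_index,
             dna_index = out$ploidy$dna_index,
             g2m_fraction = out$ploidy$g2m_fraction,
             cv_per_peak = as.list(out$ploidy$cv_per_peak)),
        p("ploidy.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(out$truth)) write_truth(out$truth, p("truth.json"))
    jsonlite::write_json(
      list(package = "pairfuse",
           version = as.character(utils::packageVersion("pairfuse")),
           seed = seed, mode = config$mode,
           hotspot = as.list(out$hotspot),
           insert_model = unclass(config$model),
           caller_params = unclass(config$caller),
           concordance_params = unclass(config$concordance),
           filter_params = unclass(config$filters)),
      p("manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  class(out) <- "pipeline_result"
  invisible(out)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result (mode %s, seed %s)\n", x$mode, x$seed))
  nf <- if (inherits(x$fusions, "fusion_calls")) nrow(x$fusions$candidates)
        else nrow(x$fusions)
  cat(sprintf("  fusions: %d; hotspot: %d of %d in cluster\n",
              nf, x$hotspot["n_in_cluster"], x$hotspot["n_total"]))
  cat(sprintf("  somatic damaging variants: %d\n", nrow(x$somatic)))
  if (!is.null(x$ploidy))
    cat(sprintf("  ploidy: %.1fN (G2/M %.0f%%)\n",
                round(x$ploidy$ploidy_index, 1),
                100 * x$ploidy$g2m_fraction))
  invisible(x)
}
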