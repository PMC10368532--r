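#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes every stage in order — simulate, editing score, somatic
#' filtering, mutation spectrum, karyotype profiling, progression trees —
#' writing each stage's tables under `out_dir` together with a
#' machine-readable JSON manifest recording the package version, the seed,
#' and per-stage record counts. Reruns with the same configuration and
#' seed produce identical outputs and manifests. If a stage fails, the
#' outputs of completed stages are preserved and the manifest marks the
#' failure point before the error is re-raised.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [cohort_config()]; its `seed` drives all randomness.
#' @param profile Somatic [filter_profile()] (default murine).
#' @param pad sgRNA-region exclusion padding in bases.
#' @param central_halfwidth Central window for the editing score.
#' @param broad_threshold Arm-level call threshold.
#' @param wgd_cutoff Ploidy cutoff for the WGD call.
#' @param fisher_p Compute per-position Fisher p-values in the editing
#'   stage.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(out_dir, config = cohort_config(),
                         profile = murine_filter_profile(),
                         pad = 50, central_halfwidth = 2,
                         broad_threshold = 0.2, wgd_cutoff = 3,
                         fisher_p = TRUE) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by cohort_config()",
      class = "mosaicevo_config_error"
    )
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "mosaicevo",
    version = as.character(utils::packageVersion("mosaicevo")),
    seed = config$seed,
    stages = list()
  )
  save_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      save_manifest()
      abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)))
    })
    manifest$stages[[name]] <<- c(list(status = "ok"), res$counts)
    res$value
  }

  bundle <- run_stage("simulate", function() {
    b <- simulate_cohort(config)
    write_variants(b$variants, file.path(out_dir, "variants.tsv"))
    readr::write_tsv(b$pileups, file.path(out_dir, "pileups.tsv"))
    write_seg(b$seg, file.path(out_dir, "exon_log2.tsv"))
    readr::write_tsv(b$baf, file.path(out_dir, "baf.tsv"))
    readr::write_tsv(b$grids, file.path(out_dir, "grids.tsv"))
    write_bed(b$targets, file.path(out_dir, "targets.bed"))
    write_bed(b$sgrna_targets, file.path(out_dir, "sgrna_targets.bed"))
    write_run_config(config, file.path(out_dir, "config.yaml"))
    jsonlite::write_json(
      list(
        ploidy = b$truth$ploidy, wgd = b$truth$wgd,
        arm_states = b$truth$arm_states
      ),
      file.path(out_dir, "truth.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    list(value = b, counts = list(
      mice = config$n_mice, samples = nrow(b$samples),
      variant_rows = nrow(b$variants)
    ))
  })

  editing <- run_stage("edit_score", function() {
    es <- score_editing(bundle$pileups,
      central_halfwidth = central_halfwidth, fisher_p = fisher_p
    )
    readr::write_tsv(es$samples, file.path(out_dir, "editing_scores.tsv"))
    readr::write_tsv(es$positions, file.path(out_dir, "editing_positions.tsv"))
    list(value = es, counts = list(samples_scored = nrow(es$samples)))
  })

  filtered <- run_stage("filter", function() {
    flt <- apply_filter(bundle$variants, profile)
    indel <- flt$variant_class %in% c("insertion", "deletion") &
      !is.na(flt$downstream_20nt)
    flt$repeat_screen <- NA_character_
    flt$repeat_screen[indel] <- repeat_filter(flt$downstream_20nt[indel])
    flt$kept <- flt$kept & (is.na(flt$repeat_screen) | flt$repeat_screen == "pass")
    flt$filter_reason[is.na(flt$filter_reason) & !flt$kept] <- "repeat_context"
    readr::write_tsv(flt, file.path(out_dir, "variants_filtered.tsv"))
    kept <- exclude_sgrna_regions(
      flt[flt$kept, ], bundle$sgrna_targets,
      pad = pad
    )
    readr::write_tsv(kept, file.path(out_dir, "variants_nondriver.tsv"))
    list(value = kept, counts = list(
      input = nrow(flt), kept = sum(flt$kept), nondriver = nrow(kept)
    ))
  })

  spectrum <- run_stage("spectrum", function() {
    snvs <- filtered[filtered$variant_class == "SNV", ]
    sp <- trinuc_spectrum(snvs)
    readr::write_tsv(sp, file.path(out_dir, "trinuc_spectrum.tsv"))
    burden <- mutational_burden(
      sum(snvs$exonic, na.rm = TRUE) / max(1, length(unique(snvs$sample))),
      callable_size_mb(bundle$targets)
    )
    readr::write_tsv(
      tibble(
        callable_mb = callable_size_mb(bundle$targets),
        mean_exonic_mutations_per_sample_per_mb = burden
      ),
      file.path(out_dir, "mutational_burden.tsv")
    )
    list(value = sp, counts = list(unique_snvs = sum(sp$count)))
  })

  karyo <- run_stage("karyotype", function() {
    arms <- arm_table(config$genome)
    per_sample <- purrr::map(bundle$samples$sample, function(s) {
      karyotype_profile(
        bundle$seg[bundle$seg$sample == s, ],
        arms,
        grid = bundle$grids[bundle$grids$sample == s, ],
        purity = config$purity,
        baf = bundle$baf[bundle$baf$sample == s, ],
        broad_threshold = broad_threshold,
        wgd_cutoff = wgd_cutoff
      )
    })
    names(per_sample) <- bundle$samples$sample
    summaries <- purrr::map_dfr(per_sample, ~ .x$summary, .id = "sample")
    calls <- purrr::map_dfr(per_sample, ~ .x$arms, .id = "sample")
    readr::write_tsv(summaries, file.path(out_dir, "karyotype_summary.tsv"))
    readr::write_tsv(calls, file.path(out_dir, "arm_calls.tsv"))
    list(
      value = list(profiles = per_sample, summaries = summaries),
      counts = list(samples_profiled = nrow(summaries))
    )
  })

  trees <- run_stage("tree", function() {
    mice <- unique(bundle$samples$mouse)
    res <- purrr::map(mice, function(m) {
      v <- filtered[filtered$mouse == m, ]
      if (length(unique(v$sample)) < 2) {
        return(NULL)
      }
      tr <- collapse_zero_branches(build_tree(v))
      write_newick(tr, file.path(out_dir, paste0("tree_", m, ".nwk")))
      sets <- mutation_sets(v)
      asg <- assign_branches(tr, sets)
      fr <- truncal_private_fractions(
        asg, sets,
        bundle$samples[bundle$samples$mouse == m, ]
      )
      list(tree = tr, assignment = asg, fractions = fr)
    })
    names(res) <- mice
    asg <- purrr::map_dfr(
      purrr::compact(res), ~ as_tibble(.x$assignment),
      .id = "mouse"
    )
    fr <- purrr::map_dfr(purrr::compact(res), "fractions", .id = "mouse")
    readr::write_tsv(asg, file.path(out_dir, "branch_assignments.tsv"))
    readr::write_tsv(fr, file.path(out_dir, "truncal_private_fractions.tsv"))
    list(value = res, counts = list(
      trees = sum(!vapply(res, is.null, logical(1))),
      assigned_mutations = nrow(asg)
    ))
  })

  save_manifest()
  invisible(list(
    bundle = bundle, editing = editing, variants = filtered,
    spectrum = spectrum, karyotype = karyo, trees = trees,
    manifest = manifest
  ))
}
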