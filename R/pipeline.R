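## End-to-end orchestration: instruments -> Wald-ratio MR -> Bonferroni gate
## -> colocalization gate -> Steiger directionality -> prioritization, driven
## by one YAML config, with a manifest recording inputs, thresholds, seeds
## and the per-stage funnel counts.

#' Default pipeline thresholds
#' @keywords internal
.defaultThresholds <- function() {
  list(p_instrument = 5e-8, r2 = 0.001, window_mb = 10, alpha = 0.05,
       pp4 = 0.70, het_p = 0.001, phewas_alpha = 0.05,
       coloc_half_window_kb = 500)
}

#' Read a pipeline run configuration
#'
#' Loads a YAML config and fills in defaults. Required keys: `eqtl`, `ld`,
#' `gwas` (a named map of trait -> file), `outdir`. Optional: `thresholds`
#' (see Details), `priors` (p1/p2/p12/wQuant/wCc), `annotations`,
#' `eqtl_study_n`, `seed`.
#'
#' Default thresholds: instrument p 5e-8, clump r-squared 0.001 in a 10 Mb
#' window, MR alpha 0.05 (Bonferroni over all tests run), PP4 0.70,
#' heterogeneity p 0.001, PheWAS follow-up alpha 0.05, colocalization
#' half-window 500 kb.
#'
#' @param path YAML file path.
#' @return A validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("eqtl", "ld", "gwas", "outdir")) {
    if (is.null(cfg[[key]])) stop("config is missing required key: ", key)
  }
  cfg$thresholds <- utils::modifyList(.defaultThresholds(),
                                      cfg$thresholds %||% list())
  cfg$priors <- do.call(colocPriors, cfg$priors %||% list())
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  files <- c(cfg$eqtl, cfg$ld, unlist(cfg$gwas), cfg$annotations)
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("config references missing file(s): ", paste(missing, collapse = ", "))
  }
  cfg
}

#' Run the full discovery pipeline
#'
#' Executes the study flow on a config: read and validate inputs, select
#' cis-eQTL instruments, run Wald-ratio MR of every instrument against every
#' outcome, gate on the Bonferroni threshold over all tests run, gate the
#' survivors on colocalization (PP4), attach Steiger directionality, and,
#' when an annotation table is configured, prioritize targets. All stage
#' outputs are written under `outdir`; the manifest records input checksums,
#' thresholds, the seed, and the funnel counts, so identical config and
#' inputs yield an identical manifest.
#'
#' @param config A config list from [readRunConfig()] or a YAML path.
#' @return List with `manifest`, `instruments`, `mr`, `hits` (Bonferroni +
#'   coloc survivors with Steiger columns), and `prioritized` (or `NULL`),
#'   invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  thr <- config$thresholds
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  eqtl <- readSumstats(config$eqtl, studyN = config$eqtl_study_n)
  ld <- readLdReference(config$ld)
  gwas <- lapply(config$gwas, readSumstats)

  instruments <- selectInstruments(eqtl, ld, pThreshold = thr$p_instrument,
                                   r2Threshold = thr$r2,
                                   windowBp = thr$window_mb * 1e6)
  if (is.null(instruments) || nrow(instruments) == 0) {
    stop("pipeline halted at stage 'instruments': no instrument survives selection")
  }
  utils::write.table(instruments, file.path(config$outdir, "instruments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  mr <- do.call(rbind, lapply(names(gwas), function(trait) {
    h <- harmonizeSumstats(instruments, gwas[[trait]])
    if (is.null(h) || nrow(h) == 0) return(NULL)
    h$trait_id_outcome <- trait
    h
  }))
  if (is.null(mr) || nrow(mr) == 0) {
    stop("pipeline halted at stage 'harmonize': no instrument found in any outcome GWAS")
  }
  nTests <- nrow(mr)
  wald <- mrWald(mr, alpha = thr$alpha, nTests = nTests)
  wald$se_std <- mr$se_std
  utils::write.table(wald, file.path(config$outdir, "mr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  gate1 <- wald[wald$passes_bonferroni, , drop = FALSE]
  gate1$pp4 <- NA_real_
  for (i in seq_len(nrow(gate1))) {
    gene <- eqtl[eqtl$gene_id == gate1$gene_id[i], , drop = FALSE]
    cr <- tryCatch(
      runColoc(gene, gwas[[gate1$trait_id[i]]],
               anchorVariant = gate1$variant_id[i],
               halfWindowBp = thr$coloc_half_window_kb * 1e3,
               priors = config$priors),
      error = function(e) NULL)
    if (!is.null(cr)) gate1$pp4[i] <- unname(posteriors(cr)["PP4"])
  }
  hits <- gate1[!is.na(gate1$pp4) & gate1$pp4 > thr$pp4, , drop = FALSE]

  if (nrow(hits) > 0) {
    key <- paste(hits$gene_id, hits$variant_id)
    instKey <- paste(instruments$gene_id, instruments$variant_id)
    inst <- instruments[match(key, instKey), , drop = FALSE]
    rGx <- rFromAssoc(inst$beta_std, inst$se_std, inst$n, "quantitative")
    perTrait <- lapply(seq_len(nrow(hits)), function(i) {
      g <- gwas[[hits$trait_id[i]]]
      j <- match(hits$variant_id[i], g$variant_id)
      st <- steigerTest(rGx[i], inst$n[i],
                        rFromAssoc(g$beta[j], g$se[j], g$n[j], "binary"),
                        g$n[j])
      list(direction_correct = st@directionCorrect, p_steiger = st@p)
    })
    hits$direction_correct <- vapply(perTrait, `[[`, logical(1), "direction_correct")
    hits$p_steiger <- vapply(perTrait, `[[`, numeric(1), "p_steiger")
  }
  targetReport(hits, file.path(config$outdir, "hits.tsv"))

  prioritized <- NULL
  if (!is.null(config$annotations) && nrow(hits) > 0) {
    ann <- utils::read.table(config$annotations, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    prioritized <- prioritizeTargets(hits, ann)
    utils::write.table(prioritized, file.path(config$outdir, "prioritized.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    inputs = as.list(tools::md5sum(c(eqtl = config$eqtl, ld = config$ld,
                                     unlist(config$gwas)))),
    thresholds = thr,
    priors = config$priors,
    seed = config$seed,
    counts = list(eqtl_records = nrow(eqtl),
                  instruments = nrow(instruments),
                  mr_tests = nTests,
                  bonferroni_survivors = nrow(gate1),
                  coloc_survivors = nrow(hits),
                  prioritized = if (is.null(prioritized)) NA_integer_
                                else sum(prioritized$prioritized))
  )
  yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))
  message(sprintf(
    "pipeline funnel: %d eQTL records -> %d instruments -> %d MR tests -> %d Bonferroni -> %d colocalized%s",
    nrow(eqtl), nrow(instruments), nTests, nrow(gate1), nrow(hits),
    if (is.null(prioritized)) "" else sprintf(" -> %d prioritized",
                                              sum(prioritized$prioritized))))
  invisible(list(manifest = manifest, instruments = instruments, mr = wald,
                 hits = hits, prioritized = prioritized))
}
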