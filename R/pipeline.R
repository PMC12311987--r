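#' Pipeline configuration
#'
#' Collects every knob of the three-stage workflow (screen, align, per-SNP
#' mediation with inference) in one validated object. Inputs may be given as
#' file paths (read with the package readers) or as in-memory objects.
#'
#' @param landmarks list of [landmark_curve()] or path to a long-format
#'   landmark CSV/TSV.
#' @param genotypes a [genotype_table()] or path to a `.raw`/CSV dosage file.
#' @param phenotypes `data.frame` with `subject_id`, outcome and covariate
#'   columns, or a CSV path.
#' @param outcomes character vector of outcome column names (processed
#'   independently).
#' @param covariates character vector of covariate column names (an
#'   intercept is added automatically).
#' @param n_grid shared evaluation grid size for the shape representation.
#' @param fdr_level FDR level for candidate-SNP selection.
#' @param basis a [basis_config()].
#' @param boot a [bootstrap_config()].
#' @param out_dir output directory for reports (`NULL` for no files).
#' @param seed master seed propagated to every stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(landmarks, genotypes, phenotypes, outcomes,
                            covariates = character(0), n_grid = 100L,
                            fdr_level = 0.05, basis = basis_config(),
                            boot = bootstrap_config(), out_dir = NULL,
                            seed = 1L) {
  for (p in c("landmarks", "genotypes", "phenotypes")) {
    v <- get(p)
    if (is.character(v) && !file.exists(v))
      stop("config path for ", p, " does not exist: ", v)
  }
  structure(list(landmarks = landmarks, genotypes = genotypes,
                 phenotypes = phenotypes, outcomes = outcomes,
                 covariates = covariates, n_grid = as.integer(n_grid),
                 fdr_level = fdr_level, basis = basis, boot = boot,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full screen-align-mediate workflow
#'
#' Three stages, logged and seeded: (1) per-SNP screen of each outcome with
#' FDR selection of the candidate set; (2) elastic-shape alignment of the
#' cohort contours to a Karcher-mean atlas, computed once and reused for
#' every SNP (the mediator does not depend on the variant); (3) for every
#' selected SNP and outcome, fit the two mediation models, compute the causal
#' estimands, and run the wild bootstrap for intervals, the SAIE band, and
#' significance calls. An empty candidate set is a valid run with an empty
#' causal report.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result`: `screen` (named list of
#'   `screen_result` per outcome), `alignment`, `fits` (list of
#'   `shape_mediation`), `causal_report` (data.frame), `counts` (per-outcome
#'   `n_candidates` and `n_causal`), `log` (character), `config`.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  log <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log <<- c(log, msg)
    message(msg)
  }
  lm_in <- config$landmarks
  if (is.character(lm_in)) lm_in <- read_landmarks(lm_in)
  gt <- config$genotypes
  if (is.character(gt)) gt <- read_genotypes(gt)
  ph <- config$phenotypes
  if (is.character(ph)) ph <- read_phenotypes(ph)
  n <- nrow(gt$dosages)
  if (length(lm_in) != n || nrow(ph) != n)
    stop("subject-count mismatch: ", length(lm_in), " contours, ", n,
         " genotype rows, ", nrow(ph), " phenotype rows")
  C <- cbind(intercept = 1,
             as.matrix(ph[, config$covariates, drop = FALSE]))
  set.seed(config$seed)

  say("stage screen: ", ncol(gt$dosages), " SNPs x ", length(config$outcomes),
      " outcomes, FDR level ", config$fdr_level)
  screens <- list()
  for (oc in config$outcomes) {
    screens[[oc]] <- tryCatch(
      genome_screen(ph[[oc]], gt, C, q_threshold = config$fdr_level),
      error = function(e) stop("stage screen failed for outcome ", oc, ": ",
                               conditionMessage(e)))
    say("  outcome ", oc, ": ", sum(screens[[oc]]$selected), " candidates")
  }

  say("stage align: ", n, " contours on a ", config$n_grid, "-point grid")
  alignment <- tryCatch(align_cohort(lm_in, n_grid = config$n_grid),
                        error = function(e)
                          stop("stage align failed: ", conditionMessage(e)))

  say("stage mediate: bootstrap n_boot = ", config$boot$n_boot)
  fits <- list()
  for (oc in config$outcomes) {
    sel <- screens[[oc]]$snp[screens[[oc]]$selected]
    for (snp in sel) {
      boot <- config$boot
      # per-(SNP, outcome) sub-seed keeps stages independent yet reproducible
      boot$seed <- (config$seed + 7919L * match(snp, gt$snp_ids) +
                      104729L * match(oc, config$outcomes)) %% .Machine$integer.max
      fit <- tryCatch(
        mediate_shape(ph[[oc]], alignment$M, gt$dosages[, snp], C,
                      basis = config$basis, boot = boot,
                      grid = alignment$grid, snp_id = snp,
                      outcome_name = oc),
        error = function(e) stop("stage mediate failed for SNP ", snp,
                                 ", outcome ", oc, ": ",
                                 conditionMessage(e)))
      fits[[paste(oc, snp, sep = ":")]] <- fit
    }
  }

  causal_report <- if (length(fits)) {
    r <- do.call(rbind, lapply(fits, function(f) {
      e <- f$effects
      data.frame(outcome = e$outcome_name, snp = e$snp_id, ate = e$ate,
                 ade = e$ade, aie = e$aie,
                 aie_lower = f$intervals$aie[1],
                 aie_upper = f$intervals$aie[2], mp = e$mp,
                 significant = f$significant[["aie"]],
                 stringsAsFactors = FALSE)
    }))
    rownames(r) <- NULL
    r
  } else {
    data.frame(outcome = character(0), snp = character(0), ate = numeric(0),
               ade = numeric(0), aie = numeric(0), aie_lower = numeric(0),
               aie_upper = numeric(0), mp = numeric(0),
               significant = logical(0))
  }

  counts <- data.frame(
    outcome = config$outcomes,
    n_candidates = vapply(config$outcomes,
                          function(oc) sum(screens[[oc]]$selected), integer(1)),
    n_causal = vapply(config$outcomes, function(oc)
      sum(causal_report$outcome == oc & causal_report$significant),
      integer(1)),
    row.names = NULL)
  say("done in ", format(round(difftime(Sys.time(), t0, units = "secs"), 1)))

  res <- structure(list(screen = screens, alignment = alignment, fits = fits,
                        causal_report = causal_report, counts = counts,
                        log = log, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (oc in names(res$screen))
    write_screen_result(res$screen[[oc]],
                        file.path(out_dir, paste0("screen_", oc, ".csv")))
  write_aligned_srvfs(res$alignment, file.path(out_dir, "aligned_srvfs.csv"))
  write.csv(res$causal_report, file.path(out_dir, "causal_report.csv"),
            row.names = FALSE)
  write.csv(res$counts, file.path(out_dir, "counts.csv"), row.names = FALSE)
  for (nm in names(res$fits))
    write_saie_band(res$fits[[nm]],
                    file.path(out_dir, paste0("saie_", gsub(":", "_", nm),
                                              ".csv")))
  meta <- list(package_version = as.character(utils::packageVersion("shapemed")),
               seed = res$config$seed, fdr_level = res$config$fdr_level,
               n_grid = res$config$n_grid,
               n_boot = res$config$boot$n_boot,
               multiplier = res$config$boot$multiplier,
               outcomes = res$config$outcomes,
               timestamp = format(Sys.time()))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(res$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$counts)
  if (nrow(x$causal_report)) {
    cat("\nCausal report:\n")
    print(x$causal_report, digits = 4)
  }
  invisible(x)
}
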